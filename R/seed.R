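# Random seeding of red blood cells into a vessel lumen.

rotation_matrix <- function(axis, angle) {
  a <- axis / sqrt(sum(axis^2))
  cth <- cos(angle); sth <- sin(angle)
  K <- matrix(c(0, -a[3], a[2], a[3], 0, -a[1], -a[2], a[1], 0), 3, 3,
              byrow = TRUE)
  diag(3) * cth + sth * K + (1 - cth) * outer(a, a)
}

random_rotation <- function(max_tilt = pi) {
  axis <- rnorm(3)
  rotation_matrix(axis, runif(1, 0, max_tilt))
}

#' Seed red blood cells into a lumen at a target hematocrit
#'
#' Places `n = round(Ht * V_lumen / V_cell)` resting biconcave cells with
#' random positions and orientations inside the lumen by rejection sampling:
#' every membrane vertex must clear the wall and other cells' vertices by
#' `clearance`. If the requested count cannot be placed within the retry
#' budget, the achieved count (and hematocrit) is reported in the result.
#'
#' @param field A `distance_field` (or `wall_mesh` with SDF closure) of the
#'   geometry.
#' @param hematocrit Target volume fraction of cells in (0, 0.45].
#' @param seed Integer seed fixing placements.
#' @param cell_template A `cell_membrane` to replicate (default: canonical
#'   biconcave at refinement 3).
#' @param clearance Minimum surface separation, um.
#' @param max_tilt Maximum tilt angle of the cell axis, radians (aligning
#'   cells roughly face-on to the flow axis eases placement in narrow tubes).
#' @param max_tries Placement attempts per cell.
#' @param lumen_volume Lumen volume in um^3; computed from the distance
#'   field when omitted.
#' @return List of placed `cell_membrane`s with attributes
#'   `target_hematocrit`, `achieved_hematocrit`, `lumen_volume`.
#' @export
seed_cells <- function(field, hematocrit, seed = 1, cell_template = NULL,
                       clearance = 0.1, max_tilt = pi / 5, max_tries = 400,
                       lumen_volume = NULL) {
  stopifnot(hematocrit >= 0, hematocrit <= 0.45)
  phi <- if (inherits(field, "wall_mesh")) field$phi else field$phi
  if (is.null(phi)) stop("geometry carries no signed-distance closure")
  if (is.null(lumen_volume)) {
    if (is.null(field$values)) stop("need a sampled distance_field or lumen_volume")
    lumen_volume <- sum(field$values < 0) * field$h^3
  }
  if (is.null(cell_template)) cell_template <- make_biconcave(n_refine = 3)
  v_cell <- cell_template$ref_volume
  n_target <- round(hematocrit * lumen_volume / v_cell)
  if (n_target == 0) {
    out <- list()
    attr(out, "target_hematocrit") <- hematocrit
    attr(out, "achieved_hematocrit") <- 0
    attr(out, "lumen_volume") <- lumen_volume
    return(out)
  }
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  # sample candidate centroids from the lumen interior
  if (!is.null(field$values)) {
    deep <- which(field$values < -1)
    grid_pts <- as.matrix(expand.grid(field$axes[[1]], field$axes[[2]],
                                      field$axes[[3]]))[deep, , drop = FALSE]
  } else stop("need a sampled distance_field for candidate positions")
  v0 <- cell_template$vertices
  placed <- list()
  occ <- NULL    # subsampled occupied vertices for overlap checks
  sub <- seq(1, nrow(v0), by = 3)
  for (ci in seq_len(n_target)) {
    done <- FALSE
    for (try in seq_len(max_tries)) {
      ctr <- grid_pts[sample(nrow(grid_pts), 1), ] +
        runif(3, -field$h / 2, field$h / 2)
      Rm <- random_rotation(max_tilt)
      vv <- v0 %*% t(Rm) + matrix(ctr, nrow(v0), 3, byrow = TRUE)
      if (max(phi(vv)) > -clearance) next
      if (!is.null(occ)) {
        dmin <- min(fields_min_dist(vv[sub, , drop = FALSE], occ))
        if (dmin < clearance + 0.4) next
      }
      cl <- cell_template
      cl$vertices <- vv
      placed[[length(placed) + 1]] <- cl
      occ <- rbind(occ, vv[sub, , drop = FALSE])
      done <- TRUE
      break
    }
    if (!done) break
  }
  achieved <- length(placed) * v_cell / lumen_volume
  if (length(placed) < n_target)
    warning(sprintf("placed %d of %d cells; achieved hematocrit %.3f",
                    length(placed), n_target, achieved))
  attr(placed, "target_hematocrit") <- hematocrit
  attr(placed, "achieved_hematocrit") <- achieved
  attr(placed, "lumen_volume") <- lumen_volume
  placed
}

# minimum distance from each row of a to the point set b (vectorized blocks)
fields_min_dist <- function(a, b) {
  out <- numeric(nrow(a))
  for (i in seq_len(nrow(a))) {
    d2 <- (b[, 1] - a[i, 1])^2 + (b[, 2] - a[i, 2])^2 + (b[, 3] - a[i, 3])^2
    out[i] <- sqrt(min(d2))
  }
  out
}
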