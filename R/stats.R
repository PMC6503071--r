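# Region-of-interest statistics for WSS and WSSG fields.
#
# ROIs are the per-vertex labels of the wall mesh: individual vessels,
# bifurcation regions, convergence regions. The ROI average is the
# area-weighted mean tau_bar = sum(tau dA) / A; the per-vessel variation is
# the normalized standard deviation tau' = sqrt(sum (tau_i - tau_bar)^2 /
# (N-1)) / tau_bar; temporal fluctuation statistics are per-vertex RMS
# values averaged over the ROI, absolute or relative to the ROI mean.

roi_select <- function(mesh, roi) {
  if (identical(roi, "all")) return(mesh$roi != "cap")
  mesh$roi %in% roi
}

field_values <- function(field) {
  if (inherits(field, "wss_field")) return(list(v = field$t_s,
                                                valid = field$valid))
  if (inherits(field, "wssg_field")) return(list(v = field$grad_mag,
                                                 valid = field$valid))
  list(v = field, valid = !is.na(field))
}

#' Area-weighted ROI average
#'
#' `tau_bar = sum(tau_v dA_v) / sum(dA_v)` over the valid vertices of the
#' region, with `dA` the per-vertex area weight of the mesh.
#'
#' @param field A `wss_field`, `wssg_field`, or plain per-vertex numeric
#'   vector.
#' @param mesh The `wall_mesh` carrying ROI labels and vertex areas.
#' @param roi ROI label(s) (e.g. `"vessel:1"`, `"bifurcation:1"`), or
#'   `"all"` for every non-cap vertex.
#' @return The area-weighted mean (scalar).
#' @export
roi_average <- function(field, mesh, roi = "all") {
  fv <- field_values(field)
  sel <- roi_select(mesh, roi) & fv$valid
  if (!any(sel)) stop(sprintf("ROI '%s' has no valid vertices",
                              paste(roi, collapse = ",")))
  sum(fv$v[sel] * mesh$vertex_area[sel]) / sum(mesh$vertex_area[sel])
}

#' Normalized per-vessel standard deviation of WSS
#'
#' `tau' = (1 / tau_bar) * sqrt( sum_i (tau_i - tau_bar)^2 / (N - 1) )`
#' over the vertices of a vessel: a coefficient-of-variation-like measure of
#' the spatial WSS variation along the vessel, invariant under rescaling of
#' the field.
#'
#' @inheritParams roi_average
#' @return Dimensionless tau'.
#' @export
vessel_std <- function(field, mesh, roi) {
  fv <- field_values(field)
  sel <- roi_select(mesh, roi) & fv$valid
  x <- fv$v[sel]
  if (length(x) < 2) stop("need at least 2 vertices")
  tau_bar <- sum(x * mesh$vertex_area[sel]) / sum(mesh$vertex_area[sel])
  if (tau_bar == 0) stop("tau_bar is zero: tau' undefined")
  sqrt(sum((x - tau_bar)^2) / (length(x) - 1)) / tau_bar
}

#' Temporal RMS statistics of a WSS or WSSG signal over a ROI
#'
#' From a time series of per-vertex values, computes at each vertex the RMS
#' of the fluctuation about its own time mean; the absolute ROI value is the
#' vertex average of these RMS values, and the relative ROI value divides
#' each vertex RMS by the magnitude of the ROI time-averaged value before
#' averaging.
#'
#' @param series Either a matrix (vertices x time samples) or a list of
#'   per-time `wss_field`/`wssg_field`/numeric vectors.
#' @param mesh The `wall_mesh`.
#' @param roi ROI label(s) or `"all"`.
#' @return One-row tibble: `roi`, `n_samples`, `mean` (ROI time-averaged
#'   value), `rms_abs`, `rms_rel`.
#' @export
temporal_rms <- function(series, mesh, roi = "all") {
  if (is.list(series)) {
    valid <- Reduce(`&`, lapply(series, function(s) field_values(s)$valid))
    series <- do.call(cbind, lapply(series, function(s) field_values(s)$v))
  } else valid <- rep(TRUE, nrow(series))
  if (ncol(series) < 8) stop("need at least 8 time samples")
  sel <- roi_select(mesh, roi) & valid
  x <- series[sel, , drop = FALSE]
  mu_t <- rowMeans(x)
  rms <- sqrt(rowMeans((x - mu_t)^2))
  w <- mesh$vertex_area[sel]
  roi_mean <- sum(mu_t * w) / sum(w)
  rms_abs <- mean(rms)
  rms_rel <- if (roi_mean == 0) NA_real_ else mean(rms) / abs(roi_mean)
  tibble::tibble(roi = paste(roi, collapse = ","), n_samples = ncol(series),
                 mean = roi_mean, rms_abs = rms_abs, rms_rel = rms_rel)
}

#' RBC-influence ratio of two WSS fields
#'
#' Pointwise and ROI-level ratio `tau_RBC / tau_pl` between a cell-laden and
#' a plasma-only field on the same mesh. ROI ratios are ratios of ROI
#' averages (not averages of pointwise ratios). Both runs must have used the
#' inlet-flow-rate boundary condition, since only then does the WSS change
#' express the cellular influence.
#'
#' @param wss_rbc,wss_pl `wss_field`s from the paired runs.
#' @param mesh The shared `wall_mesh`.
#' @param rois ROI labels to summarize (default: all labels present).
#' @param floor_frac Pointwise ratios where `|tau_pl|` is below this fraction
#'   of its ROI mean magnitude are flagged `NA`.
#' @param enforce_bc Set `FALSE` to bypass the flow-BC requirement (used by
#'   self-consistency checks).
#' @return List with `pointwise` (per-vertex ratio) and `by_roi` tibble
#'   (`roi`, `tau_rbc`, `tau_pl`, `ratio`).
#' @export
ratio_map <- function(wss_rbc, wss_pl, mesh, rois = NULL, floor_frac = 0.05,
                      enforce_bc = TRUE) {
  if (length(wss_rbc$t_s) != length(wss_pl$t_s))
    stop("fields live on different meshes")
  if (enforce_bc &&
      !(identical(wss_rbc$bc_kind, "inlet_flow_rate") &&
        identical(wss_pl$bc_kind, "inlet_flow_rate")))
    stop(paste("RBC-influence ratios require both runs to use the",
               "inlet_flow_rate boundary condition"))
  if (is.null(rois)) rois <- setdiff(unique(mesh$roi), "cap")
  ref <- mean(abs(wss_pl$t_s[wss_pl$valid]))
  pw <- ifelse(abs(wss_pl$t_s) > floor_frac * ref & wss_pl$valid &
                 wss_rbc$valid, wss_rbc$t_s / wss_pl$t_s, NA_real_)
  by_roi <- dplyr::bind_rows(lapply(rois, function(r) {
    tr <- roi_average(wss_rbc, mesh, r)
    tp <- roi_average(wss_pl, mesh, r)
    tibble::tibble(roi = r, tau_rbc = tr, tau_pl = tp, ratio = tr / tp)
  }))
  list(pointwise = pw, by_roi = by_roi)
}

#' Cross-sectional velocity and hematocrit profiles
#'
#' Samples the (time-averaged) axial velocity and the cell indicator along a
#' chord across a vessel lumen, and reports the bluntness index
#' `u_max / u_mean` and the side of the velocity-profile skewness (sign of
#' the first moment about the chord midpoint).
#'
#' @param fields List with `u`, `v`, `w` arrays (m/s) and optionally `ind`
#'   (cell indicator).
#' @param sys The `flow_system`.
#' @param point Chord center (on the vessel axis), um.
#' @param chord_dir Unit vector along the chord.
#' @param half_len Half-length of the sampled chord, um (reaching the walls).
#' @param axis Flow direction used for the velocity component.
#' @param n Number of sample points.
#' @return List with `profile` tibble (`s`, `u`, `ht`, `in_lumen`),
#'   `bluntness`, `skew_side` (-1, 0, +1) and `u_mean`, `u_max`.
#' @export
cross_section_profiles <- function(fields, sys, point, chord_dir = c(1, 0, 0),
                                   half_len, axis = c(0, 0, 1), n = 41) {
  s <- seq(-half_len, half_len, length.out = n)
  pts <- sweep(outer(s, chord_dir), 2, point, `+`)
  phi_v <- sys$field$phi(pts)
  inl <- phi_v < 0
  if (!any(inl)) stop("chord does not intersect the lumen")
  # the chord must cross a single lumen: one contiguous in-lumen run
  runs <- rle(inl)
  if (sum(runs$values) > 1)
    stop("chord crosses more than one lumen (plane through a junction?)")
  uvw <- interp_velocity(fields, sys$grid, pts)
  u_ax <- as.vector(uvw %*% axis)
  ht <- if (!is.null(fields$ind))
    interp_component(fields$ind, sys$grid, pts, "c") else rep(NA_real_, n)
  u_in <- u_ax[inl]
  # area-mean estimate assuming near-axisymmetry: weight chord samples by
  # their distance from the chord midpoint (the radius), so a parabolic
  # profile gives u_max / u_mean = 2 as for the cross-section average
  s_in <- s[inl]
  s_mid <- (min(s_in) + max(s_in)) / 2
  wgt <- abs(s_in - s_mid) + diff(s)[1] / 4
  u_mean <- sum(u_in * wgt) / sum(wgt)
  u_max <- max(abs(u_in)) * sign(u_mean)
  m1 <- sum(s_in * u_in) / sum(abs(u_in))
  ds <- s[2] - s[1]
  skew <- if (abs(m1) < ds / 2) 0 else sign(m1)
  list(profile = tibble::tibble(s = s, u = u_ax, ht = ht, in_lumen = inl),
       bluntness = u_max / u_mean, skew_side = skew,
       u_mean = u_mean, u_max = u_max)
}

#' Summaries for every ROI of a mesh
#'
#' Convenience wrapper building one row per ROI: area, area-weighted mean
#' WSS, normalized standard deviation, and (when a WSSG field is given) mean
#' gradient components and magnitude.
#'
#' @param wss A `wss_field`.
#' @param mesh The `wall_mesh`.
#' @param wssg_field Optional `wssg_field` on the same mesh.
#' @return Tibble with one row per ROI.
#' @export
roi_summary <- function(wss, mesh, wssg_field = NULL) {
  rois <- setdiff(unique(mesh$roi), "cap")
  rows <- lapply(rois, function(r) {
    sel <- roi_select(mesh, r)
    out <- tibble::tibble(
      roi = r,
      kind = sub(":.*", "", r),
      area = sum(mesh$vertex_area[sel]),
      tau_bar = roi_average(wss, mesh, r),
      tau_std = tryCatch(vessel_std(wss, mesh, r), error = function(e) NA_real_))
    if (!is.null(wssg_field)) {
      out$grad_s_bar <- roi_average(wssg_field$grad_s *
                                      ifelse(wssg_field$valid, 1, NA), mesh, r)
      out$grad_theta_bar <- roi_average(wssg_field$grad_theta *
                                          ifelse(wssg_field$valid, 1, NA), mesh, r)
      out$grad_mag_bar <- roi_average(wssg_field, mesh, r)
    }
    out
  })
  dplyr::bind_rows(rows)
}
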