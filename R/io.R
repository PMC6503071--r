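# Writers for run artifacts: legacy ASCII VTK surfaces with per-vertex
# arrays, JSON for specifications and placements, CSV tables.

#' Write a triangulated surface as legacy ASCII VTK
#'
#' Writes the mesh (and optional per-vertex scalar arrays, e.g. tau or WSSG
#' components) as VTK PolyData readable by ParaView and meshio.
#'
#' @param mesh A `wall_mesh` or `cell_membrane`.
#' @param path Output file path (.vtk).
#' @param point_data Named list of per-vertex numeric vectors.
#' @return `path`, invisibly.
#' @export
write_surface_vtk <- function(mesh, path, point_data = list()) {
  v <- mesh$vertices; tr <- mesh$triangles
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0", "microwss surface", "ASCII",
               "DATASET POLYDATA", sprintf("POINTS %d float", nrow(v))), con)
  utils::write.table(format(v, digits = 9, scientific = TRUE), con,
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  writeLines(sprintf("POLYGONS %d %d", nrow(tr), 4 * nrow(tr)), con)
  utils::write.table(cbind(3L, tr - 1L), con, row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  if (length(point_data)) {
    writeLines(sprintf("POINT_DATA %d", nrow(v)), con)
    for (nm in names(point_data)) {
      writeLines(c(sprintf("SCALARS %s float 1", nm),
                   "LOOKUP_TABLE default"), con)
      writeLines(format(point_data[[nm]], digits = 9, scientific = TRUE), con)
    }
  }
  invisible(path)
}

#' Serialize a network specification as JSON
#'
#' @param spec A `network_spec`.
#' @param path Output path (.json).
#' @return `path`, invisibly.
#' @export
write_network_json <- function(spec, path) {
  out <- list(
    horton_ratio = spec$horton_ratio, inlet = spec$inlet,
    outlet = spec$outlet,
    vessels = lapply(spec$vessels, function(v)
      list(id = v$id, diameter = v$diameter, order = v$order,
           class = v$class, centerline = unname(as.matrix(v$centerline)))),
    junctions = lapply(spec$junctions, function(j)
      list(id = j$id, kind = j$kind, feeders = j$feeders,
           daughters = j$daughters, center = j$center)))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a network specification from JSON
#' @param path Path written by [write_network_json()].
#' @return A `network_spec`.
#' @export
read_network_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  vessels <- lapply(seq_len(nrow(j$vessels)), function(i) {
    v <- j$vessels[i, ]
    list(id = v$id, diameter = v$diameter, order = as.integer(v$order),
         class = v$class, centerline = v$centerline[[1]])
  })
  junctions <- if (length(j$junctions))
    lapply(seq_len(nrow(j$junctions)), function(i) {
      jr <- j$junctions[i, ]
      list(id = jr$id, kind = jr$kind, feeders = unlist(jr$feeders),
           daughters = unlist(jr$daughters), center = unlist(jr$center))
    }) else list()
  network_spec(vessels, junctions, inlet = j$inlet, outlet = j$outlet,
               horton_ratio = j$horton_ratio, validate = FALSE)
}
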