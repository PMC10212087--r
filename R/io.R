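# Readers and writers for traced outlines (GeoJSON FeatureCollection).
# Real-mode TEM inputs arrive as vertex lists; the same format carries
# the synthetic ground truth.

#' Write cell and nucleus outlines as GeoJSON
#'
#' One `Polygon` feature per outline with properties `cell_id`, `role`
#' (`"cell"` or `"nucleus"`) and `region`; strip dimensions are stored in
#' the collection's top-level `properties`.
#'
#' @param cells A [sample_cell_tessellation()] or list of cells with
#'   `cell`/`nucleus` polygons, `cell_id`, `region`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_polygons_geojson <- function(cells, path) {
  ring <- function(xy) {
    xy <- rbind(xy, xy[1L, , drop = FALSE])  # closed ring
    lapply(seq_len(nrow(xy)), function(i) c(xy[i, 1L], xy[i, 2L]))
  }
  feats <- list()
  for (cl in cells) {
    for (role in c("cell", "nucleus")) {
      poly <- cl[[role]]
      if (is.null(poly)) next
      feats[[length(feats) + 1L]] <- list(
        type = "Feature",
        properties = list(cell_id = cl$cell_id, role = role,
                          region = cl$region %||% NA,
                          clipped = isTRUE(cl$clipped)),
        geometry = list(type = "Polygon", coordinates = list(ring(poly))))
    }
  }
  fc <- list(type = "FeatureCollection",
             properties = list(
               strip_length_um = attr(cells, "strip_length_um"),
               strip_height_um = attr(cells, "strip_height_um")),
             features = feats)
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read cell and nucleus outlines from GeoJSON
#'
#' Inverse of [write_polygons_geojson()]: rebuilds the cell list (cell +
#' nucleus matched by `cell_id`) with strip dimensions restored, ready
#' for [analyze_tem_strip()].
#'
#' @param path GeoJSON path.
#' @return A `cell_tessellation`.
#' @export
read_polygons_geojson <- function(path) {
  fc <- jsonlite::read_json(path)
  abort_if(!identical(fc$type, "FeatureCollection"),
           "expected a GeoJSON FeatureCollection")
  by_id <- list()
  for (ft in fc$features) {
    pr <- ft$properties
    coords <- ft$geometry$coordinates[[1L]]
    xy <- do.call(rbind, lapply(coords, function(p) c(p[[1L]], p[[2L]])))
    if (nrow(xy) > 1L &&
        isTRUE(all.equal(xy[1L, ], xy[nrow(xy), ])))
      xy <- xy[-nrow(xy), , drop = FALSE]  # drop closing vertex
    id <- as.character(pr$cell_id)
    if (is.null(by_id[[id]]))
      by_id[[id]] <- list(cell_id = pr$cell_id, region = pr$region,
                          clipped = isTRUE(pr$clipped))
    by_id[[id]][[pr$role]] <- xy
  }
  cells <- unname(Filter(function(cl) !is.null(cl$cell), by_id))
  cells <- lapply(cells, function(cl) {
    cl$centroid <- polygon_centroid(cl$cell)
    cl
  })
  structure(cells, class = "cell_tessellation",
            strip_length_um = fc$properties$strip_length_um,
            strip_height_um = fc$properties$strip_height_um,
            seed = NA_integer_)
}
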