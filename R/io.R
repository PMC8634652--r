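#' Read or write target areas as GeoJSON-style polygons
#'
#' Target areas are stored as a GeoJSON FeatureCollection of Polygon
#' features; coordinates are global slide micrometres and each feature's
#' `name` property carries the area name (plus optional `sections` range).
#'
#' @param areas List of [target_area()] objects.
#' @param path File path.
#' @export
write_target_areas <- function(areas, path) {
  feats <- lapply(areas, function(ar) {
    ring <- rbind(ar$polygon, ar$polygon[1, , drop = FALSE])
    props <- list(name = ar$name)
    if (!is.null(ar$sections)) props$sections <- as.integer(ar$sections)
    list(type = "Feature",
         properties = props,
         geometry = list(type = "Polygon",
                         coordinates = list(lapply(seq_len(nrow(ring)),
                                                   function(i) ring[i, ]))))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_target_areas
#' @export
read_target_areas <- function(path) {
  gj <- jsonlite::read_json(path, simplifyVector = FALSE)
  lapply(gj$features, function(f) {
    ring <- do.call(rbind, lapply(f$geometry$coordinates[[1]], unlist))
    if (all(ring[1, ] == ring[nrow(ring), ])) ring <- ring[-nrow(ring), ]
    sections <- f$properties$sections
    target_area(f$properties$name, ring,
                sections = if (is.null(sections)) NULL else unlist(sections))
  })
}
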