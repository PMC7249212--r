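# GeoJSON serialization of fire perimeters and evacuation plans.

ring_coords_closed <- function(ring) {
  closed <- ring_close(ring)
  lapply(seq_len(nrow(closed)), function(i) c(closed[i, 1], closed[i, 2]))
}

#' Write fire-perimeter snapshots as GeoJSON
#'
#' One Polygon/MultiPolygon feature per snapshot, each carrying a `t_min`
#' property (minutes since ignition).
#'
#' @param snapshots A list of [fire_perimeter()] objects (or a
#'   `fire_simulation`, whose snapshots are used).
#' @param path Output `.geojson` path.
#' @return Invisibly, `path`.
#' @export
write_perimeters <- function(snapshots, path) {
  if (inherits(snapshots, "fire_simulation")) snapshots <- snapshots$snapshots
  feats <- lapply(snapshots, function(p) {
    if (length(p$rings) == 1) {
      geom <- list(type = "Polygon",
                   coordinates = list(ring_coords_closed(p$rings[[1]])))
    } else {
      geom <- list(type = "MultiPolygon",
                   coordinates = lapply(p$rings, function(r)
                     list(ring_coords_closed(r))))
    }
    list(type = "Feature", properties = list(t_min = p$t_min),
         geometry = geom)
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_perimeters
#' @return `read_perimeters` returns a list of [fire_perimeter()] objects.
#' @export
read_perimeters <- function(path) {
  gj <- jsonlite::read_json(path)
  lapply(gj$features, function(f) {
    geom <- f$geometry
    to_ring <- function(coords) {
      m <- do.call(rbind, lapply(coords, function(p) c(p[[1]], p[[2]])))
      # drop the closing duplicate vertex
      if (nrow(m) > 1 && all(abs(m[1, ] - m[nrow(m), ]) < 1e-12))
        m <- m[-nrow(m), , drop = FALSE]
      m
    }
    rings <- switch(geom$type,
      Polygon = list(to_ring(geom$coordinates[[1]])),
      MultiPolygon = lapply(geom$coordinates, function(pg) to_ring(pg[[1]])),
      stop("unsupported geometry type: ", geom$type))
    fire_perimeter(rings, t_min = f$properties$t_min)
  })
}
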