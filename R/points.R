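#' Point set (ignitions, farms, junction registries)
#'
#' A carrier for identified points in the shared projected CRS: ignition
#' locations, farm/apiary registries, or any labelled point layer.
#'
#' @param id Character or integer vector of unique identifiers.
#' @param x,y Coordinates in projected metres.
#' @param kind_tag Free-text label, e.g. `"farm"` or `"ignition"`.
#' @return An object of class `fv_points`: a data.frame with columns
#'   `id`, `x`, `y` and attribute `kind_tag`.
#' @export
point_set <- function(id, x, y, kind_tag = "point") {
  id <- as.character(id)
  x <- as.numeric(x); y <- as.numeric(y)
  if (anyDuplicated(id)) stop("duplicate point id: ",
                              id[duplicated(id)][1])
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop("non-finite point coordinate")
  structure(data.frame(id = id, x = x, y = y, stringsAsFactors = FALSE),
            kind_tag = kind_tag, class = c("fv_points", "data.frame"))
}

#' Read a point set from CSV or GeoJSON
#'
#' CSV files need columns `id`, `x`, `y`; GeoJSON must be a FeatureCollection
#' of Point features with an `id` property (or feature `id`). Both encodings
#' of the same points yield equal point sets.
#'
#' @param path File path (`.csv` or `.geojson`/`.json`).
#' @param kind_tag Label attached to the result.
#' @return An [point_set()] object.
#' @export
read_points <- function(path, kind_tag = "point") {
  if (!file.exists(path)) stop("point file not found: ", path)
  if (grepl("\\.(geojson|json)$", path, ignore.case = TRUE)) {
    gj <- jsonlite::read_json(path)
    if (is.null(gj$features)) stop("GeoJSON FeatureCollection expected")
    rows <- lapply(gj$features, function(f) {
      if (!identical(f$geometry$type, "Point"))
        stop("GeoJSON geometry must be Point")
      id <- f$properties$id
      if (is.null(id)) id <- f$id
      if (is.null(id)) stop("GeoJSON point feature lacks an id")
      c(id = as.character(id),
        x = as.numeric(f$geometry$coordinates[[1]]),
        y = as.numeric(f$geometry$coordinates[[2]]))
    })
    df <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
    return(point_set(df$id, as.numeric(df$x), as.numeric(df$y), kind_tag))
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("id", "x", "y") %in% names(df)))
    stop("CSV point file must have columns id, x, y")
  if (!is.numeric(df$x) || !is.numeric(df$y))
    stop("non-numeric coordinate in ", path)
  point_set(df$id, df$x, df$y, kind_tag)
}

#' @rdname read_points
#' @param pts An `fv_points` object.
#' @param format `"csv"` or `"geojson"`.
#' @export
write_points <- function(pts, path, format = c("csv", "geojson")) {
  format <- match.arg(format)
  if (format == "csv") {
    utils::write.csv(as.data.frame(pts)[, c("id", "x", "y")], path,
                     row.names = FALSE, quote = FALSE)
  } else {
    feats <- lapply(seq_len(nrow(pts)), function(i) list(
      type = "Feature",
      properties = list(id = pts$id[i]),
      geometry = list(type = "Point",
                      coordinates = c(pts$x[i], pts$y[i]))))
    jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                         path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Spatially uniform wind observation
#'
#' Wind is uniform across the landscape within one simulation step; a
#' time-varying sequence is passed to the simulator as a list of these.
#'
#' @param speed Wind speed in m/h (>= 0).
#' @param direction Meteorological direction in degrees: where the wind
#'   blows *from*, clockwise from north. Normalized to \[0, 360).
#' @return Object of class `wind_field`.
#' @examples
#' wind_field(15000, 270)  # 15 km/h wind from the west
#' @export
wind_field <- function(speed, direction) {
  if (!is.finite(speed) || speed < 0) stop("wind speed must be >= 0")
  if (!is.finite(direction)) stop("wind direction must be finite")
  structure(list(speed = speed, direction = direction %% 360),
            class = "wind_field")
}

# Unit vector (east, north) pointing DOWNWIND (where the wind blows to).
downwind_vector <- function(wind) {
  to <- (wind$direction + 180) %% 360
  a <- to * pi / 180
  c(sin(a), cos(a))
}
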