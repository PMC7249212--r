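#' Georeferenced raster grid
#'
#' Lightweight in-memory raster used for every gridded layer the simulator
#' consumes: the digital elevation model (metres), the Anderson fuel
#' classification (integer classes 1..13) and vegetation humidity (fraction
#' in \[0, 1\]). The grid lives in a projected, metric coordinate system;
#' geographic (degree-unit) grids are rejected because spread rates are
#' metric speeds.
#'
#' Grid convention: `values[row, col]` maps to the *cell centre*; row 1 is
#' the northernmost row (the ESRI ASCII-grid convention). `origin` is the
#' top-left *corner* of the grid, so the centre of cell (r, c) is at
#' `origin + cell_size * (c - 0.5, -(r - 0.5))`.
#'
#' @param values Numeric matrix of cell values (row 1 = north).
#' @param origin Numeric length-2: (x, y) of the top-left grid corner, metres.
#' @param cell_size Cell edge length in metres (> 0).
#' @param nodata Sentinel value for missing cells (stored as `NA` internally).
#' @param crs_tag Free-text label of the projected CRS, e.g. `"UTM33N"`.
#' @param layer_kind One of `"dem"`, `"fuel"`, `"humidity"`, `"arrival"`,
#'   `"generic"`; layer-specific invariants are enforced.
#' @return An object of class `fv_raster`.
#' @examples
#' r <- fv_raster(matrix(100, 3, 3), origin = c(0, 60), cell_size = 20)
#' cell_center(r, 1, 1)
#' @export
fv_raster <- function(values, origin, cell_size, nodata = -9999,
                      crs_tag = "UTM", layer_kind = "generic") {
  stopifnot(is.matrix(values), length(origin) == 2, is.finite(origin))
  if (!is.numeric(cell_size) || length(cell_size) != 1 || cell_size <= 0)
    stop("cell_size must be a single positive number")
  if (nrow(values) < 1 || ncol(values) < 1) stop("values array is empty")
  storage.mode(values) <- "double"
  values[values == nodata] <- NA_real_
  r <- structure(
    list(values = values, origin = as.numeric(origin),
         cell_size = as.numeric(cell_size), nodata = nodata,
         crs_tag = crs_tag, layer_kind = layer_kind),
    class = "fv_raster")
  validate_raster(r)
  r
}

validate_raster <- function(r) {
  v <- r$values[!is.na(r$values)]
  switch(r$layer_kind,
    fuel = {
      if (length(v) && (any(v != round(v)) || any(v < 1) || any(v > 13)))
        stop("fuel class out of range: classes must be integers in 1..13")
    },
    humidity = {
      if (length(v) && (any(v < 0) || any(v > 1)))
        stop("humidity outside [0,1]")
    },
    arrival = {
      if (length(v) && any(v < 0)) stop("arrival times must be >= 0")
    })
  invisible(r)
}

#' @export
print.fv_raster <- function(x, ...) {
  v <- x$values[!is.na(x$values)]
  cat(sprintf("<fv_raster %s> %d x %d cells @ %g m, origin (%g, %g), crs %s\n",
              x$layer_kind, nrow(x$values), ncol(x$values), x$cell_size,
              x$origin[1], x$origin[2], x$crs_tag))
  if (length(v))
    cat(sprintf("  values: [%g, %g], %d nodata\n", min(v), max(v),
                sum(is.na(x$values))))
  invisible(x)
}

#' @rdname fv_raster
#' @param r An `fv_raster`.
#' @param row,col Cell indices (row 1 = northernmost).
#' @export
cell_center <- function(r, row, col) {
  cbind(x = r$origin[1] + (col - 0.5) * r$cell_size,
        y = r$origin[2] - (row - 0.5) * r$cell_size)
}

#' @rdname fv_raster
#' @param x,y Point coordinates in the raster's projected CRS.
#' @return `cell_at` returns a two-column matrix of (row, col), `NA` outside
#'   the extent.
#' @export
cell_at <- function(r, x, y) {
  col <- floor((x - r$origin[1]) / r$cell_size) + 1L
  row <- floor((r$origin[2] - y) / r$cell_size) + 1L
  bad <- row < 1L | row > nrow(r$values) | col < 1L | col > ncol(r$values)
  row[bad] <- NA_integer_; col[bad] <- NA_integer_
  cbind(row = row, col = col)
}

#' @rdname fv_raster
#' @return `raster_extent` returns c(xmin, ymin, xmax, ymax) of the outer
#'   grid edges.
#' @export
raster_extent <- function(r) {
  c(xmin = r$origin[1], ymin = r$origin[2] - nrow(r$values) * r$cell_size,
    xmax = r$origin[1] + ncol(r$values) * r$cell_size, ymax = r$origin[2])
}

# Nearest-cell sample (clamped to the extent edge). Returns NA for NA cells.
sample_raster <- function(r, x, y) {
  col <- pmin(pmax(floor((x - r$origin[1]) / r$cell_size) + 1L, 1L),
              ncol(r$values))
  row <- pmin(pmax(floor((r$origin[2] - y) / r$cell_size) + 1L, 1L),
              nrow(r$values))
  r$values[cbind(row, col)]
}

# Central-difference elevation gradient (dimensionless rise/run) at points,
# one-sided at grid borders. Returns an n x 2 matrix (d/dx, d/dy).
raster_gradient <- function(dem, x, y) {
  nr <- nrow(dem$values); nc <- ncol(dem$values); cs <- dem$cell_size
  col <- pmin(pmax(floor((x - dem$origin[1]) / cs) + 1L, 1L), nc)
  row <- pmin(pmax(floor((dem$origin[2] - y) / cs) + 1L, 1L), nr)
  cl <- pmax(col - 1L, 1L); cr <- pmin(col + 1L, nc)
  rn <- pmax(row - 1L, 1L); rs <- pmin(row + 1L, nr)
  zx <- (dem$values[cbind(row, cr)] - dem$values[cbind(row, cl)]) /
    ((cr - cl) * cs)
  # row index grows southwards, so north-positive d/dy flips the difference
  zy <- (dem$values[cbind(rn, col)] - dem$values[cbind(rs, col)]) /
    ((rs - rn) * cs)
  zx[!is.finite(zx)] <- 0; zy[!is.finite(zy)] <- 0
  cbind(zx, zy)
}

#' Check that rasters share one grid
#'
#' All layers entering the simulator must agree in shape, origin, cell size
#' and CRS tag; misaligned inputs are rejected.
#'
#' @param ... Two or more `fv_raster` objects.
#' @return Invisibly `TRUE`; errors on misalignment.
#' @export
check_alignment <- function(...) {
  rs <- list(...)
  stopifnot(length(rs) >= 2)
  ref <- rs[[1]]
  for (r in rs[-1]) {
    if (!identical(dim(r$values), dim(ref$values)))
      stop("raster alignment error: grid shapes differ")
    if (max(abs(r$origin - ref$origin)) > 1e-6)
      stop("raster alignment error: origins differ")
    if (abs(r$cell_size - ref$cell_size) > 1e-9)
      stop("raster alignment error: cell sizes differ")
    if (!identical(r$crs_tag, ref$crs_tag))
      stop("raster alignment error: CRS tags differ")
  }
  invisible(TRUE)
}

#' Read a raster layer from an ESRI ASCII grid
#'
#' Reads `.asc` grids into an [fv_raster], enforcing the layer's invariants
#' (fuel classes in 1..13, humidity in \[0, 1\]). The projection must be
#' metric: grids whose header is plausibly in geographic degrees (cell size
#' below 0.01 with origin inside \[-360, 360\]) are rejected, as are
#' GeoTIFFs (no GeoTIFF reader is bundled).
#'
#' @param path Path to an existing `.asc` file.
#' @param layer_kind One of `"dem"`, `"fuel"`, `"humidity"` (or `"arrival"`,
#'   `"generic"`).
#' @param crs_tag CRS label to attach (ASCII grids carry none).
#' @return An [fv_raster].
#' @seealso [write_raster()]
#' @export
read_raster <- function(path, layer_kind = "generic", crs_tag = "UTM") {
  if (!file.exists(path)) stop("raster file not found: ", path)
  head4 <- readBin(path, "raw", 4L)
  if (length(head4) == 4 &&
      (identical(head4[1:2], as.raw(c(0x49, 0x49))) ||
       identical(head4[1:2], as.raw(c(0x4d, 0x4d)))))
    stop("GeoTIFF input is not supported; convert to ESRI ASCII grid")
  lines <- readLines(path, warn = FALSE)
  hdr <- list(); i <- 1
  while (i <= length(lines) && grepl("^[A-Za-z]", lines[i])) {
    tok <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(tok[1])]] <- as.numeric(tok[2])
    i <- i + 1
  }
  need <- c("ncols", "nrows", "cellsize")
  if (!all(need %in% names(hdr)))
    stop("malformed ASCII grid header in ", path)
  ncols <- as.integer(hdr$ncols); nrows <- as.integer(hdr$nrows)
  cs <- hdr$cellsize
  xll <- if (!is.null(hdr$xllcorner)) hdr$xllcorner else hdr$xllcenter - cs / 2
  yll <- if (!is.null(hdr$yllcorner)) hdr$yllcorner else hdr$yllcenter - cs / 2
  nodata <- if (!is.null(hdr$nodata_value)) hdr$nodata_value else -9999
  if (cs < 0.01 && abs(xll) <= 360 && abs(yll) <= 360)
    stop("raster appears to use geographic (degree) units; ",
         "a metric projected CRS is required")
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  if (length(vals) != nrows * ncols)
    stop("ASCII grid body has ", length(vals), " values, expected ",
         nrows * ncols)
  m <- matrix(vals, nrow = nrows, ncol = ncols, byrow = TRUE)
  fv_raster(m, origin = c(xll, yll + nrows * cs), cell_size = cs,
            nodata = nodata, crs_tag = crs_tag, layer_kind = layer_kind)
}

#' Write a raster layer as an ESRI ASCII grid
#'
#' The writer is canonical: writing the result of [read_raster()] reproduces
#' a file previously produced by `write_raster()` byte for byte, which the
#' fixture round-trip tests rely on.
#'
#' @param r An [fv_raster].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_raster <- function(r, path) {
  v <- r$values
  v[is.na(v)] <- r$nodata
  fmt <- function(x) formatC(x, format = "g", digits = 10)
  hdr <- c(
    paste("ncols", ncol(v)),
    paste("nrows", nrow(v)),
    paste("xllcorner", fmt(r$origin[1])),
    paste("yllcorner", fmt(r$origin[2] - nrow(v) * r$cell_size)),
    paste("cellsize", fmt(r$cell_size)),
    paste("NODATA_value", fmt(r$nodata)))
  body <- apply(v, 1, function(row) paste(fmt(row), collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}
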