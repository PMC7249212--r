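# Seeded synthetic-data generators: landscapes, road graphs, farms and a
# bundled end-to-end demo scenario. They stand in for real GIS layers
# (elevation, fuel, humidity), road networks and farm registries so that
# every other module is testable offline and deterministically.

#' Synthetic fixture specification
#'
#' All generators draw from labelled sub-streams of one master seed, so
#' adding a generator never perturbs existing fixtures, and a fixed seed
#' yields byte-identical outputs.
#'
#' Defaults describe a 100 x 100-cell grid at 20 m resolution (the lower
#' bound of the 20–40 m DEM resolution the spread model is designed for),
#' i.e. a 2 km x 2 km landscape.
#'
#' @param seed Master integer seed.
#' @param nrow,ncol Grid shape in cells.
#' @param cell_size Cell edge, metres.
#' @param dem_style `"flat"`, `"ramp"` or `"gaussian_hill"`.
#' @param fuel_style `"uniform"` or `"mosaic"`.
#' @param fuel_class Class used by the uniform style (1..13).
#' @param humidity Scalar humidity fraction in \[0, 1\].
#' @param road_style `"chain"`, `"diamond"` or `"grid"`.
#' @param road_k Chain length, or grid side (k x k junctions).
#' @param farm_count Number of uniformly scattered farm points.
#' @param crs_tag CRS label shared by every layer.
#' @return Object of class `fixture_spec`.
#' @export
fixture_spec <- function(seed = 1, nrow = 100, ncol = 100, cell_size = 20,
                         dem_style = "flat", fuel_style = "uniform",
                         fuel_class = 8, humidity = 0.2,
                         road_style = "grid", road_k = 4, farm_count = 10,
                         crs_tag = "UTM33N-synthetic") {
  stopifnot(nrow >= 3, ncol >= 3, cell_size > 0,
            humidity >= 0, humidity <= 1,
            fuel_class %in% 1:13, road_k >= 2, farm_count >= 0)
  structure(list(seed = as.integer(seed), nrow = nrow, ncol = ncol,
                 cell_size = cell_size, dem_style = dem_style,
                 fuel_style = fuel_style, fuel_class = fuel_class,
                 humidity = humidity, road_style = road_style,
                 road_k = road_k, farm_count = farm_count,
                 crs_tag = crs_tag),
            class = "fixture_spec")
}

# Deterministic sub-seed from the master seed and a stream label,
# kept below 2^31.
sub_seed <- function(seed, label) {
  h <- 0
  for (ch in utf8ToInt(label)) h <- (h * 131 + ch) %% 1000003
  (as.numeric(seed) * 7919 + h * 104729) %% 2147483647
}

with_stream <- function(seed, label, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  set.seed(sub_seed(seed, label))
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  force(expr)
}

#' Generate a synthetic landscape
#'
#' Builds aligned DEM, fuel and humidity rasters plus a wind sequence on
#' the spec's shared grid. The flat DEM is constant (zero gradient); the
#' ramp rises eastwards at a constant 10% grade; the Gaussian hill is a
#' smooth bump centred on the grid. Mosaic fuel draws one Anderson class
#' (1..13) per 10 x 10-cell block; humidity is the scalar broadcast over
#' the grid.
#'
#' @param spec A [fixture_spec()].
#' @return List with elements `dem`, `fuel`, `humidity` ([fv_raster]s) and
#'   `wind` (list of [wind_field()], one per 10-min block of an hour).
#' @export
make_landscape <- function(spec) {
  nr <- spec$nrow; nc <- spec$ncol; cs <- spec$cell_size
  origin <- c(0, nr * cs)
  xs <- matrix(rep((seq_len(nc) - 0.5) * cs, each = nr), nr, nc)
  ys <- matrix(rep((nr - seq_len(nr) + 0.5) * cs, times = nc), nr, nc)
  dem_vals <- switch(spec$dem_style,
    flat = matrix(100, nr, nc),
    ramp = 100 + 0.1 * xs,
    gaussian_hill = {
      cx <- nc * cs / 2; cy <- nr * cs / 2
      sig <- min(nr, nc) * cs / 5
      100 + 300 * exp(-((xs - cx)^2 + (ys - cy)^2) / (2 * sig^2))
    },
    stop("invalid dem style: ", spec$dem_style))
  fuel_vals <- switch(spec$fuel_style,
    uniform = matrix(spec$fuel_class, nr, nc),
    mosaic = with_stream(spec$seed, "fuel", {
      bs <- 10
      br <- ceiling(nr / bs); bc <- ceiling(nc / bs)
      blocks <- matrix(sample(1:13, br * bc, replace = TRUE), br, bc)
      blocks[ceiling(seq_len(nr) / bs), ceiling(seq_len(nc) / bs),
             drop = FALSE]
    }),
    stop("invalid fuel style: ", spec$fuel_style))
  wind <- with_stream(spec$seed, "wind", {
    lapply(1:6, function(i)
      wind_field(stats::runif(1, 0, 20000), stats::runif(1, 0, 360)))
  })
  list(
    dem = fv_raster(dem_vals, origin, cs, crs_tag = spec$crs_tag,
                    layer_kind = "dem"),
    fuel = fv_raster(fuel_vals, origin, cs, crs_tag = spec$crs_tag,
                     layer_kind = "fuel"),
    humidity = fv_raster(matrix(spec$humidity, nr, nc), origin, cs,
                         crs_tag = spec$crs_tag, layer_kind = "humidity"),
    wind = wind)
}

#' Generate a synthetic road graph
#'
#' `chain`: k junctions in a line, forward and reverse edges. `diamond`:
#' the canonical 4-junction fixture with exactly two source-to-sink routes
#' (S -> A -> T and S -> B -> T), used by the router oracle tests. `grid`:
#' k x k junctions on the landscape extent with jittered coordinates,
#' 4-neighbour two-way edges and uniform-random traffic intensity phi.
#' All styles produce a strongly connected directed graph.
#'
#' @param spec A [fixture_spec()].
#' @param v_free Free-flow speed for every edge, m/h.
#' @return A [road_graph()].
#' @export
make_road_graph <- function(spec, v_free = 40000) {
  extent <- c(spec$ncol, spec$nrow) * spec$cell_size
  both_ways <- function(from, to, len, phi)
    data.frame(from = c(from, to), to = c(to, from),
               length = rep(len, 2), phi = rep(phi, 2),
               v_free = v_free, stringsAsFactors = FALSE)
  if (spec$road_style == "chain") {
    k <- spec$road_k
    nodes <- data.frame(id = paste0("n", seq_len(k)),
                        x = seq(0.1, 0.9, length.out = k) * extent[1],
                        y = rep(extent[2] / 2, k))
    phis <- with_stream(spec$seed, "chain_phi", stats::runif(k - 1))
    edges <- do.call(rbind, lapply(seq_len(k - 1), function(i)
      both_ways(nodes$id[i], nodes$id[i + 1],
                abs(nodes$x[i + 1] - nodes$x[i]), phis[i])))
    return(road_graph(nodes, edges))
  }
  if (spec$road_style == "diamond") {
    w <- extent[1]; h <- extent[2]
    nodes <- data.frame(id = c("S", "A", "B", "T"),
                        x = c(0.1, 0.5, 0.5, 0.9) * w,
                        y = c(0.5, 0.8, 0.2, 0.5) * h)
    phis <- with_stream(spec$seed, "diamond_phi", stats::runif(4))
    dst <- function(i, j) sqrt((nodes$x[i] - nodes$x[j])^2 +
                                 (nodes$y[i] - nodes$y[j])^2)
    edges <- data.frame(
      from = c("S", "A", "S", "B"), to = c("A", "T", "B", "T"),
      length = c(dst(1, 2), dst(2, 4), dst(1, 3), dst(3, 4)),
      phi = phis, v_free = v_free, stringsAsFactors = FALSE)
    return(road_graph(nodes, edges))
  }
  if (spec$road_style == "grid") {
    k <- spec$road_k
    base_x <- seq(0.1, 0.9, length.out = k) * extent[1]
    base_y <- seq(0.1, 0.9, length.out = k) * extent[2]
    spacing <- min(diff(base_x)[1], diff(base_y)[1])
    grid <- expand.grid(i = seq_len(k), j = seq_len(k))
    jit <- with_stream(spec$seed, "grid_jitter",
                       matrix(stats::runif(2 * k * k, -0.15, 0.15) * spacing,
                              ncol = 2))
    nodes <- data.frame(id = paste0("n", grid$i, "_", grid$j),
                        x = base_x[grid$i] + jit[, 1],
                        y = base_y[grid$j] + jit[, 2])
    rownames(nodes) <- nodes$id
    pairs <- list()
    for (i in seq_len(k)) for (j in seq_len(k)) {
      if (i < k) pairs[[length(pairs) + 1]] <-
          c(paste0("n", i, "_", j), paste0("n", i + 1, "_", j))
      if (j < k) pairs[[length(pairs) + 1]] <-
          c(paste0("n", i, "_", j), paste0("n", i, "_", j + 1))
    }
    phis <- with_stream(spec$seed, "grid_phi",
                        stats::runif(length(pairs), 0.05, 0.8))
    edges <- do.call(rbind, lapply(seq_along(pairs), function(p) {
      a <- pairs[[p]][1]; b <- pairs[[p]][2]
      len <- sqrt((nodes[a, "x"] - nodes[b, "x"])^2 +
                    (nodes[a, "y"] - nodes[b, "y"])^2)
      both_ways(a, b, len, phis[p])
    }))
    return(road_graph(nodes, edges))
  }
  stop("invalid road style: ", spec$road_style)
}

#' @rdname make_road_graph
#' @return `make_farms` returns a [point_set()] of farms scattered
#'   uniformly over the landscape extent.
#' @export
make_farms <- function(spec) {
  extent <- c(spec$ncol, spec$nrow) * spec$cell_size
  with_stream(spec$seed, "farms", {
    point_set(paste0("farm", seq_len(spec$farm_count)),
              stats::runif(spec$farm_count, 0.05, 0.95) * extent[1],
              stats::runif(spec$farm_count, 0.05, 0.95) * extent[2],
              kind_tag = "farm")
  })
}

#' Write a full fixture bundle to disk
#'
#' Materializes a spec as plain-text files: `dem.asc`, `fuel.asc`,
#' `humidity.asc`, `wind.json`, `roads.geojson` + `nodes.csv`, `farms.csv`,
#' `ignition.csv` (one point at the landscape centre) and a `manifest.json`
#' recording the spec.
#'
#' @param spec A [fixture_spec()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, the manifest path.
#' @export
write_fixtures <- function(spec, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  land <- make_landscape(spec)
  write_raster(land$dem, file.path(dir, "dem.asc"))
  write_raster(land$fuel, file.path(dir, "fuel.asc"))
  write_raster(land$humidity, file.path(dir, "humidity.asc"))
  jsonlite::write_json(lapply(land$wind, function(w)
    list(speed = w$speed, direction = w$direction)),
    file.path(dir, "wind.json"), auto_unbox = TRUE, digits = NA)
  graph <- make_road_graph(spec)
  write_road_graph(graph, file.path(dir, "roads.geojson"),
                   file.path(dir, "nodes.csv"))
  write_points(make_farms(spec), file.path(dir, "farms.csv"))
  extent <- c(spec$ncol, spec$nrow) * spec$cell_size
  ign <- point_set("ign1", extent[1] / 2, extent[2] / 2, "ignition")
  write_points(ign, file.path(dir, "ignition.csv"))
  manifest <- unclass(spec)
  manifest$files <- c("dem.asc", "fuel.asc", "humidity.asc", "wind.json",
                      "roads.geojson", "nodes.csv", "farms.csv",
                      "ignition.csv")
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(file.path(dir, "manifest.json"))
}
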