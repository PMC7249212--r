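#' Oriented, traffic-weighted road graph
#'
#' The road network is a directed graph G(N, E, phi): nodes are road
#' junctions with projected coordinates; every edge carries its length (m),
#' a normalized traffic-flow intensity phi in \[0, 1\] and a free-flow speed
#' (m/h). Two-way roads are encoded as two opposite edges.
#'
#' @param nodes data.frame with columns `id`, `x`, `y` (ids unique).
#' @param edges data.frame with columns `from`, `to`, `length`, `phi`,
#'   `v_free`.
#' @return Object of class `road_graph`.
#' @export
road_graph <- function(nodes, edges) {
  nodes$id <- as.character(nodes$id)
  edges$from <- as.character(edges$from)
  edges$to <- as.character(edges$to)
  if (anyDuplicated(nodes$id)) stop("duplicate node id")
  miss <- setdiff(c(edges$from, edges$to), nodes$id)
  if (length(miss)) stop("edge endpoint not in node set: ",
                         paste(miss, collapse = ", "))
  if (any(edges$length <= 0)) stop("edge length must be > 0")
  if (any(edges$phi < 0 | edges$phi > 1)) stop("phi must be in [0,1]")
  if (any(edges$v_free <= 0)) stop("v_free must be > 0")
  rownames(nodes) <- nodes$id
  structure(list(nodes = nodes[, c("id", "x", "y")],
                 edges = edges[, c("from", "to", "length", "phi", "v_free")]),
            class = "road_graph")
}

#' @export
print.road_graph <- function(x, ...) {
  cat(sprintf("<road_graph> %d junctions, %d directed edges\n",
              nrow(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Traffic-flow speed statistics
#'
#' Summaries of a per-vehicle speed sample on a road segment, as used to
#' characterize the likely speed over an edge: the time-mean speed (the
#' arithmetic mean over vehicles passing in a period), the space-mean speed
#' (the harmonic mean, i.e. the mean over a fixed distance — never above the
#' time mean), the 85th-percentile speed S85 (exceeded by only 15% of
#' vehicles; nearest-rank), and the modal speed V_mod (midpoint of the most
#' frequent histogram bin, ties resolved toward the lower bin).
#'
#' @param speeds Numeric vector of per-vehicle speeds, m/h, all > 0.
#' @return Speed in m/h.
#' @examples
#' time_mean_speed(c(30, 60))   # 45
#' space_mean_speed(c(30, 60))  # 40
#' @export
time_mean_speed <- function(speeds) {
  if (!length(speeds)) stop("empty speed sample")
  mean(speeds)
}

#' @rdname time_mean_speed
#' @export
space_mean_speed <- function(speeds) {
  if (!length(speeds)) stop("empty speed sample")
  if (any(speeds <= 0)) stop("speeds must be > 0")
  1 / mean(1 / speeds)
}

#' @rdname time_mean_speed
#' @export
s85 <- function(speeds) {
  if (!length(speeds)) stop("empty speed sample")
  sort(speeds)[ceiling(0.85 * length(speeds))]
}

#' @rdname time_mean_speed
#' @param bin_width Histogram bin width in m/h (> 0).
#' @export
v_mod <- function(speeds, bin_width) {
  if (!length(speeds)) stop("empty speed sample")
  if (bin_width <= 0) stop("bin_width must be > 0")
  bin <- floor(speeds / bin_width)
  counts <- table(bin)
  best <- as.numeric(names(counts))[counts == max(counts)]
  (min(best) + 0.5) * bin_width
}

#' Edge travel time under traffic
#'
#' Travel time in minutes for an edge, from a Greenshields-style linear
#' speed degradation: `v = v_free * max(1 - phi, phi_floor)`. The floor
#' (default 0.05) keeps saturated edges slow but traversable.
#'
#' @param length Edge length(s) in m.
#' @param phi Traffic intensity in \[0, 1\].
#' @param v_free Free-flow speed(s) in m/h.
#' @param phi_floor Minimum speed fraction retained at saturation.
#' @return Travel time(s) in minutes; strictly positive and finite.
#' @examples
#' edge_travel_time(1000, 0, 60000)    # 1 minute at free flow
#' edge_travel_time(1000, 0.5, 60000)  # 2 minutes at half intensity
#' @export
edge_travel_time <- function(length, phi, v_free, phi_floor = 0.05) {
  if (any(phi < 0 | phi > 1)) stop("phi must be in [0,1]")
  60 * length / (v_free * pmax(1 - phi, phi_floor))
}

#' Read/write a road graph as GeoJSON plus a nodes CSV
#'
#' Edges are LineString features with `from`, `to`, `length`, `phi`,
#' `v_free` properties; junctions live in a sibling CSV with columns
#' `id`, `x`, `y`. Write-then-read reproduces nodes, edges and phi exactly.
#'
#' @param edges_path Path to the edge GeoJSON.
#' @param nodes_path Path to the nodes CSV.
#' @return `read_road_graph` returns a [road_graph()].
#' @export
read_road_graph <- function(edges_path, nodes_path) {
  nodes <- utils::read.csv(nodes_path, stringsAsFactors = FALSE,
                           colClasses = c(id = "character"))
  gj <- jsonlite::read_json(edges_path)
  rows <- lapply(gj$features, function(f) {
    p <- f$properties
    data.frame(from = as.character(p$from), to = as.character(p$to),
               length = as.numeric(p$length), phi = as.numeric(p$phi),
               v_free = as.numeric(p$v_free), stringsAsFactors = FALSE)
  })
  road_graph(nodes, do.call(rbind, rows))
}

#' @rdname read_road_graph
#' @param graph A [road_graph()].
#' @export
write_road_graph <- function(graph, edges_path, nodes_path) {
  utils::write.csv(graph$nodes, nodes_path, row.names = FALSE, quote = FALSE)
  xy <- graph$nodes
  feats <- lapply(seq_len(nrow(graph$edges)), function(i) {
    e <- graph$edges[i, ]
    a <- xy[e$from, ]; b <- xy[e$to, ]
    list(type = "Feature",
         properties = list(from = e$from, to = e$to, length = e$length,
                           phi = e$phi, v_free = e$v_free),
         geometry = list(type = "LineString",
                         coordinates = list(c(a$x, a$y), c(b$x, b$y))))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       edges_path, auto_unbox = TRUE, digits = NA)
  invisible(edges_path)
}
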