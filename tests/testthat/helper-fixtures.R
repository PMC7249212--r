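# Shared fixture builders for the test suite. Everything is generated in
# code; nothing is read from disk except files the tests themselves write.

uniform_landscape <- function(n = 100, cell = 20, fuel_class = 8,
                              elevation = 100) {
  origin <- c(0, n * cell)
  list(
    dem = fv_raster(matrix(elevation, n, n), origin, cell,
                    layer_kind = "dem"),
    fuel = fv_raster(matrix(fuel_class, n, n), origin, cell,
                     layer_kind = "fuel"),
    humidity = fv_raster(matrix(0, n, n), origin, cell,
                         layer_kind = "humidity"))
}

# all 13 classes share one rate: isotropic growth at a known speed
flat_params <- function(ros = 600) {
  ros_params(ros_max_by_fuel = setNames(rep(ros, 13), 1:13),
             humidity_damping = 0)
}

calm <- function() wind_field(0, 0)

# random strongly-checked small directed graph for router oracle tests
random_router_instance <- function(seed) {
  set.seed(seed)
  n <- sample(4:10, 1)
  ids <- paste0("v", seq_len(n))
  nodes <- data.frame(id = ids, x = runif(n, 0, 2000), y = runif(n, 0, 2000))
  all_pairs <- expand.grid(from = ids, to = ids, stringsAsFactors = FALSE)
  all_pairs <- all_pairs[all_pairs$from != all_pairs$to, ]
  m <- sample(n:min(3 * n, nrow(all_pairs)), 1)
  pick <- all_pairs[sample(nrow(all_pairs), m), ]
  edges <- data.frame(from = pick$from, to = pick$to,
                      length = runif(m, 100, 2000), phi = runif(m),
                      v_free = 40000, stringsAsFactors = FALSE)
  graph <- road_graph(nodes, edges)
  arrival <- setNames(ifelse(runif(n) < 0.4, runif(n, 0, 5), Inf), ids)
  list(graph = graph, arrival = arrival,
       avail = availability(arrival, horizon = 10),
       source = "v1", sink = "v2")
}

# minimum-hop node count via the igraph BFS oracle; Inf if unreachable
min_hop_nodes <- function(graph, source, sink) {
  ig <- igraph::graph_from_data_frame(graph$edges[, c("from", "to")],
                                      vertices = graph$nodes$id)
  d <- igraph::distances(ig, v = source, to = sink, mode = "out")[1, 1]
  if (is.infinite(d)) Inf else d + 1
}
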