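#' Time-dependent node availability
#'
#' The binary function rho(node, t): 1 while a junction is still untouched
#' by the fire at time t, 0 once the fire has reached it. Availability is
#' derived from the simulator's arrival-time field: a junction is burned at
#' t if any grid cell within `safety_margin` metres of it (always including
#' the cell containing it) has fire arrival time <= t. Junctions outside
#' the raster extent are never burned. rho only ever switches from 1 to 0.
#'
#' For testing and for table-driven scenarios, `arrival` may instead be a
#' named numeric vector of per-junction arrival times (minutes, `Inf` =
#' never burned), keyed by node id.
#'
#' @param arrival An [fv_raster] arrival-time field (minutes, nodata = never
#'   burned), or a named numeric vector of per-node arrival times.
#' @param horizon The final simulation moment t* in minutes (> 0); times
#'   beyond it are outside the model.
#' @param safety_margin Metres around a junction that must be fire-free
#'   (raster mode only); default 0.
#' @return Object of class `fv_avail`.
#' @export
availability <- function(arrival, horizon, safety_margin = 0) {
  if (horizon <= 0) stop("horizon must be > 0")
  if (safety_margin < 0) stop("safety_margin must be >= 0")
  if (inherits(arrival, "fv_raster")) {
    kind <- "raster"
  } else if (is.numeric(arrival) && !is.null(names(arrival))) {
    kind <- "table"
  } else stop("arrival must be an fv_raster or a named numeric vector")
  structure(list(arrival = arrival, horizon = horizon,
                 safety_margin = safety_margin, kind = kind),
            class = "fv_avail")
}

# Earliest fire arrival near a point (raster mode); Inf if never burned or
# outside the extent.
node_arrival_time <- function(avail, x, y) {
  r <- avail$arrival
  rc <- cell_at(r, x, y)
  if (is.na(rc[1, 1])) return(Inf)
  if (avail$safety_margin <= 0) {
    a <- r$values[rc[1, 1], rc[1, 2]]
    return(if (is.na(a)) Inf else a)
  }
  cs <- r$cell_size
  reach <- ceiling(avail$safety_margin / cs)
  rows <- max(1, rc[1, 1] - reach):min(nrow(r$values), rc[1, 1] + reach)
  cols <- max(1, rc[1, 2] - reach):min(ncol(r$values), rc[1, 2] + reach)
  grid <- expand.grid(row = rows, col = cols)
  cc <- cell_center(r, grid$row, grid$col)
  d <- sqrt((cc[, 1] - x)^2 + (cc[, 2] - y)^2)
  sel <- d <= avail$safety_margin | (grid$row == rc[1, 1] & grid$col == rc[1, 2])
  a <- r$values[cbind(grid$row[sel], grid$col[sel])]
  if (all(is.na(a))) Inf else min(a, na.rm = TRUE)
}

#' Evaluate rho for a junction at a time
#'
#' @param avail An [availability()] object (`NULL` means no fire: rho == 1
#'   everywhere).
#' @param node Node id (character) when `graph` is given or availability is
#'   table-based; otherwise a length-2 numeric (x, y).
#' @param t Time in minutes; must lie in \[0, t*\].
#' @param graph Optional [road_graph()] used to resolve node ids to
#'   coordinates in raster mode.
#' @return 1 if the junction is still fire-free at `t`, else 0.
#' @export
rho <- function(avail, node, t, graph = NULL) {
  if (is.null(avail)) return(1L)
  if (t < 0 || t > avail$horizon)
    stop("t outside [0, t*]: ", t)
  if (avail$kind == "table") {
    a <- avail$arrival[as.character(node)]
    if (is.na(a)) a <- Inf
    return(if (a <= t) 0L else 1L)
  }
  if (is.character(node) || length(node) == 1) {
    if (is.null(graph)) stop("graph needed to resolve node id in raster mode")
    nd <- graph$nodes[as.character(node), ]
    if (is.na(nd$x)) stop("unknown node id: ", node)
    xy <- c(nd$x, nd$y)
  } else xy <- as.numeric(node)
  if (node_arrival_time(avail, xy[1], xy[2]) <= t) 0L else 1L
}

# Precompute per-node arrival times for the whole graph.
graph_arrivals <- function(avail, graph) {
  if (is.null(avail)) return(setNames(rep(Inf, nrow(graph$nodes)),
                                      graph$nodes$id))
  if (avail$kind == "table") {
    a <- avail$arrival[graph$nodes$id]
    a[is.na(a)] <- Inf
    return(setNames(as.numeric(a), graph$nodes$id))
  }
  setNames(vapply(seq_len(nrow(graph$nodes)), function(i)
    node_arrival_time(avail, graph$nodes$x[i], graph$nodes$y[i]),
    numeric(1)), graph$nodes$id)
}

empty_plan <- function(reason = "no fire-safe path", rejected = character(0)) {
  structure(list(nodes = character(0), visit_times = numeric(0),
                 opera_value = 0L, feasible = FALSE,
                 total_travel_min = NA_real_, phi_sum = NA_real_,
                 rejected = rejected, reason = reason),
            class = "evacuation_plan")
}

make_plan <- function(nodes, times, phi_sum, rejected = character(0)) {
  structure(list(nodes = nodes, visit_times = times,
                 opera_value = length(nodes), feasible = TRUE,
                 total_travel_min = times[length(times)] - times[1],
                 phi_sum = phi_sum, rejected = rejected, reason = NULL),
            class = "evacuation_plan")
}

#' @export
print.evacuation_plan <- function(x, ...) {
  if (x$feasible) {
    cat(sprintf("<evacuation_plan> feasible, %d nodes, %.2f min travel\n",
                x$opera_value, x$total_travel_min))
    cat("  route:", paste(x$nodes, collapse = " -> "), "\n")
  } else {
    cat("<evacuation_plan> infeasible:", x$reason, "\n")
  }
  if (length(x$rejected))
    cat("  fire-rejected junctions:", paste(x$rejected, collapse = ", "), "\n")
  invisible(x)
}

#' Optimal evacuation route under fire (OPERA)
#'
#' Finds, among all routes from `source` to `sink` whose every junction is
#' still fire-free at the moment the evacuating vehicle reaches it (and
#' reached within the simulation horizon t*), one minimizing the number of
#' visited junctions — the OPERA value. Ties are broken by smaller total
#' travel time, then by smaller summed traffic intensity phi (the
#' least-traffic successor rule). Visit times follow from
#' [edge_travel_time()]; waiting at junctions is not modelled (availability
#' only ever degrades, so waiting cannot help).
#'
#' The search is label-setting: labels (junction, arrival time, node count,
#' phi sum) are expanded in lexicographic (count, time, phi) order, and a
#' label is discarded when another label at the same junction is at least as
#' good in all three attributes. Junctions whose expansion was blocked
#' because the fire had already arrived are reported in `rejected` — the
#' "red cross" junctions of the case-study workflow.
#'
#' Infeasibility (no fire-safe route, or fire at the source at departure)
#' is a first-class result with `feasible = FALSE`, never an error.
#'
#' @param graph A [road_graph()].
#' @param avail An [availability()] object, or `NULL` for no fire.
#' @param source,sink Junction ids (distinct).
#' @param depart Departure time at `source` in minutes (default 0).
#' @return An `evacuation_plan`: ordered junction ids, visit times, the
#'   OPERA value (node count), feasibility, total travel minutes, summed
#'   phi, and the fire-rejected junction set.
#' @seealso [brute_force_opera()] for the exhaustive reference
#'   implementation, [validate_plan()] to certify a plan.
#' @export
find_opera <- function(graph, avail, source, sink, depart = 0) {
  source <- as.character(source); sink <- as.character(sink)
  if (!source %in% graph$nodes$id) stop("source not in graph: ", source)
  if (!sink %in% graph$nodes$id) stop("sink not in graph: ", sink)
  if (identical(source, sink)) stop("source and sink must differ")
  horizon <- if (is.null(avail)) Inf else avail$horizon
  arr <- graph_arrivals(avail, graph)
  if (arr[source] <= depart)
    return(empty_plan("fire at source at departure", rejected = source))

  edges <- graph$edges
  edges$tt <- edge_travel_time(edges$length, edges$phi, edges$v_free)
  out_by <- split(seq_len(nrow(edges)), edges$from)

  # label pool: columns node, time, count, phi, pred (index into pool)
  lab_node <- source; lab_time <- depart; lab_count <- 1
  lab_phi <- 0; lab_pred <- 0L
  open <- 1L        # indices of unexpanded labels
  settled <- list() # per node: matrix of settled (time, count, phi)
  rejected <- character(0)

  dominated <- function(node, time, count, phi) {
    s <- settled[[node]]
    if (is.null(s)) return(FALSE)
    any(s[, 1] <= time & s[, 2] <= count & s[, 3] <= phi)
  }

  repeat {
    if (!length(open)) return(empty_plan(rejected = unique(rejected)))
    # lexicographic (count, time, phi) extraction
    o <- open[order(lab_count[open], lab_time[open], lab_phi[open],
                    lab_node[open])]
    cur <- o[1]
    open <- setdiff(open, cur)
    nd <- lab_node[cur]
    if (dominated(nd, lab_time[cur], lab_count[cur], lab_phi[cur])) next
    settled[[nd]] <- rbind(settled[[nd]],
                           c(lab_time[cur], lab_count[cur], lab_phi[cur]))
    if (nd == sink) {
      path <- integer(0); p <- cur
      while (p != 0L) { path <- c(p, path); p <- lab_pred[p] }
      return(make_plan(lab_node[path], lab_time[path], lab_phi[cur],
                       rejected = unique(rejected)))
    }
    for (e in out_by[[nd]]) {
      v <- edges$to[e]
      t_v <- lab_time[cur] + edges$tt[e]
      if (t_v > horizon) next
      if (arr[v] <= t_v) { rejected <- c(rejected, v); next }
      cnt <- lab_count[cur] + 1
      ph <- lab_phi[cur] + edges$phi[e]
      if (dominated(v, t_v, cnt, ph)) next
      lab_node <- c(lab_node, v); lab_time <- c(lab_time, t_v)
      lab_count <- c(lab_count, cnt); lab_phi <- c(lab_phi, ph)
      lab_pred <- c(lab_pred, cur)
      open <- c(open, length(lab_node))
    }
  }
}

#' Exhaustive-enumeration reference router
#'
#' Enumerates every simple path from source to sink (graphs of at most
#' `max_nodes` junctions), applies the identical fire-safety, horizon and
#' tie-break rules as [find_opera()], and returns the best plan. Serves as
#' the independent reference semantics for testing the label-setting search.
#'
#' @inheritParams find_opera
#' @param max_nodes Enumeration guard (default 12).
#' @return An `evacuation_plan`.
#' @export
brute_force_opera <- function(graph, avail, source, sink, depart = 0,
                              max_nodes = 12) {
  source <- as.character(source); sink <- as.character(sink)
  if (nrow(graph$nodes) > max_nodes)
    stop("graph too large for exhaustive enumeration")
  if (!source %in% graph$nodes$id) stop("source not in graph: ", source)
  if (!sink %in% graph$nodes$id) stop("sink not in graph: ", sink)
  if (identical(source, sink)) stop("source and sink must differ")
  horizon <- if (is.null(avail)) Inf else avail$horizon
  arr <- graph_arrivals(avail, graph)
  if (arr[source] <= depart)
    return(empty_plan("fire at source at departure", rejected = source))
  edges <- graph$edges
  edges$tt <- edge_travel_time(edges$length, edges$phi, edges$v_free)
  out_by <- split(seq_len(nrow(edges)), edges$from)

  best <- NULL
  best_key <- c(Inf, Inf, Inf)
  walk <- function(path, times, phi_sum) {
    nd <- path[length(path)]
    if (nd == sink) {
      key <- c(length(path), times[length(times)] - depart, phi_sum)
      if (is.null(best) || lex_less(key, best_key)) {
        best <<- list(path = path, times = times, phi = phi_sum)
        best_key <<- key
      }
      return()
    }
    for (e in out_by[[nd]]) {
      v <- edges$to[e]
      if (v %in% path) next
      t_v <- times[length(times)] + edges$tt[e]
      # along a fixed path times are fixed, so an unsafe prefix can never
      # become safe: pruning is exact
      if (t_v > horizon || arr[v] <= t_v) next
      walk(c(path, v), c(times, t_v), phi_sum + edges$phi[e])
    }
  }
  walk(source, depart, 0)
  if (is.null(best)) return(empty_plan())
  make_plan(best$path, best$times, best$phi)
}

lex_less <- function(a, b) {
  for (k in seq_along(a)) {
    if (a[k] < b[k] - 1e-9) return(TRUE)
    if (a[k] > b[k] + 1e-9) return(FALSE)
  }
  FALSE
}

#' Certify an evacuation plan
#'
#' Checks a plan against the graph and the availability function and
#' returns the violations as data (never as exceptions): `connectivity` (a
#' consecutive junction pair is not a graph edge), `timing` (visit times do
#' not follow from the edge travel times), `safety` (a junction is visited
#' at or after fire arrival), and `horizon` (a visit exceeds t*).
#'
#' @param plan An `evacuation_plan`.
#' @param graph A [road_graph()].
#' @param avail An [availability()] or `NULL`.
#' @return data.frame with columns `type`, `node`, `detail`; zero rows for
#'   a valid plan.
#' @export
validate_plan <- function(plan, graph, avail = NULL) {
  v <- data.frame(type = character(0), node = character(0),
                  detail = character(0), stringsAsFactors = FALSE)
  add <- function(type, node, detail)
    v <<- rbind(v, data.frame(type = type, node = node, detail = detail,
                              stringsAsFactors = FALSE))
  if (!plan$feasible || length(plan$nodes) == 0) return(v)
  horizon <- if (is.null(avail)) Inf else avail$horizon
  arr <- graph_arrivals(avail, graph)
  edges <- graph$edges
  edges$tt <- edge_travel_time(edges$length, edges$phi, edges$v_free)
  for (k in seq_along(plan$nodes)) {
    nd <- plan$nodes[k]; tk <- plan$visit_times[k]
    if (!nd %in% graph$nodes$id) {
      add("connectivity", nd, "junction not in graph")
      next
    }
    if (tk > horizon) add("horizon", nd, sprintf("visit at %.3f > t*", tk))
    if (arr[nd] <= tk)
      add("safety", nd,
          sprintf("fire arrived at %.3f, visited at %.3f", arr[nd], tk))
    if (k > 1) {
      prev <- plan$nodes[k - 1]
      ei <- which(edges$from == prev & edges$to == nd)
      if (!length(ei)) {
        add("connectivity", nd, paste0("no edge ", prev, " -> ", nd))
      } else {
        expected <- plan$visit_times[k - 1] + edges$tt[ei]
        if (!any(abs(tk - expected) <= 1e-6))
          add("timing", nd,
              sprintf("visit %.6f, expected %.6f", tk, expected[1]))
      }
    }
  }
  v
}

#' Write an evacuation plan as GeoJSON plus a JSON summary
#'
#' The route is a LineString feature with per-junction ids and visit times;
#' the fire-rejected junctions are written as Point features flagged
#' `rejected = true`. The summary JSON carries `opera_value`, `feasible`
#' and `total_travel_min`.
#'
#' @param plan An `evacuation_plan`.
#' @param graph The [road_graph()] the plan refers to.
#' @param geojson_path,summary_path Output paths.
#' @return Invisibly, `geojson_path`.
#' @export
write_plan <- function(plan, graph, geojson_path, summary_path) {
  feats <- list()
  if (plan$feasible) {
    xy <- graph$nodes[plan$nodes, ]
    feats[[1]] <- list(
      type = "Feature",
      properties = list(kind = "route", nodes = plan$nodes,
                        t_min = plan$visit_times),
      geometry = list(
        type = "LineString",
        coordinates = lapply(seq_len(nrow(xy)),
                             function(i) c(xy$x[i], xy$y[i]))))
  }
  for (nd in plan$rejected) {
    n <- graph$nodes[nd, ]
    feats[[length(feats) + 1]] <- list(
      type = "Feature",
      properties = list(kind = "rejected", id = nd, rejected = TRUE),
      geometry = list(type = "Point", coordinates = c(n$x, n$y)))
  }
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       geojson_path, auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(list(opera_value = plan$opera_value,
                            feasible = plan$feasible,
                            total_travel_min = plan$total_travel_min,
                            rejected = as.list(plan$rejected)),
                       summary_path, auto_unbox = TRUE, digits = NA)
  invisible(geojson_path)
}
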