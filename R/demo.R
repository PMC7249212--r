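#' Bundled end-to-end demo scenario
#'
#' A packaged synthetic analogue of the case-study workflow: a farm
#' junction on one corner of a jittered road grid must be evacuated to a
#' safe sink junction on the opposite corner while a fire, ignited on top
#' of the central junction, spreads outward. The central junction burns
#' immediately, so the router must reject it (the "red cross" behaviour)
#' and detour; an equally short fire-safe route always exists on the grid,
#' so the returned plan is feasible.
#'
#' `make_case_demo` assembles the scenario; `run_case_demo` executes the
#' full pipeline (fire simulation, routing, farm exposure) and returns the
#' results. Both are deterministic for a fixed seed.
#'
#' @param seed Master integer seed.
#' @return `make_case_demo`: list with `spec`, `landscape`, `graph`,
#'   `ignition` (a [point_set()]), `farms`, `source`, `sink`, `params`,
#'   `dt`, `horizon`, `snapshot_every`, `depart`.
#' @export
make_case_demo <- function(seed = 1) {
  spec <- fixture_spec(seed = seed, nrow = 80, ncol = 80, cell_size = 20,
                       dem_style = "gaussian_hill", fuel_style = "uniform",
                       fuel_class = 4, humidity = 0.15,
                       road_style = "grid", road_k = 5, farm_count = 8)
  landscape <- make_landscape(spec)
  graph <- make_road_graph(spec)
  center <- graph$nodes["n3_3", ]
  ignition <- point_set("ign1", center$x, center$y, "ignition")
  params <- ros_params()
  list(spec = spec, landscape = landscape, graph = graph,
       ignition = ignition, farms = make_farms(spec),
       source = "n1_1", sink = "n5_5", params = params,
       dt = 1, horizon = 40, snapshot_every = 5, depart = 0)
}

#' @rdname make_case_demo
#' @return `run_case_demo`: list with the scenario (`demo`), the
#'   `fire_simulation` (`sim`), the `evacuation_plan` (`plan`), its
#'   violations (`violations`, empty for a valid plan) and the farm
#'   `exposure` report against the final fire footprint.
#' @export
run_case_demo <- function(seed = 1) {
  demo <- make_case_demo(seed)
  sim <- simulate_fire(demo$ignition, demo$landscape$dem,
                       demo$landscape$fuel, demo$landscape$humidity,
                       demo$landscape$wind, demo$params,
                       dt = demo$dt, horizon = demo$horizon,
                       snapshot_every = demo$snapshot_every)
  avail <- availability(sim$arrival, horizon = demo$horizon)
  plan <- find_opera(demo$graph, avail, demo$source, demo$sink,
                     depart = demo$depart)
  final <- sim$snapshots[[length(sim$snapshots)]]
  exposure <- classify_farms(demo$farms, final)
  list(demo = demo, sim = sim, plan = plan,
       violations = validate_plan(plan, demo$graph, avail),
       exposure = exposure)
}
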