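test_that("rho reflects fire arrival, margins and extent", {
  # raster mode: a 3x3 arrival field, centre cell burns at 10 min
  vals <- matrix(NA_real_, 3, 3)
  vals[2, 2] <- 10
  arr <- fv_raster(vals, c(0, 60), 20, layer_kind = "arrival")
  av <- availability(arr, horizon = 100)
  expect_equal(rho(av, c(30, 30), 5), 1L)
  expect_equal(rho(av, c(30, 30), 15), 0L)
  expect_equal(rho(av, c(30, 30), 10), 0L)   # reached at t counts as burned
  # unburned neighbouring cell
  expect_equal(rho(av, c(10, 30), 50), 1L)
  # outside the raster extent: never burned
  expect_equal(rho(av, c(1e5, 1e5), 50), 1L)
  # safety margin pulls in the burning neighbour cell
  av2 <- availability(arr, horizon = 100, safety_margin = 25)
  expect_equal(rho(av2, c(10, 30), 50), 0L)
  expect_error(rho(av, c(30, 30), 150), "outside")
  expect_error(rho(av, c(30, 30), -1), "outside")
  # no-fire mode
  expect_equal(rho(NULL, c(30, 30), 5), 1L)
  # table mode by node id
  avt <- availability(c(a = 3), horizon = 10)
  expect_equal(rho(avt, "a", 2), 1L)
  expect_equal(rho(avt, "a", 4), 0L)
  expect_equal(rho(avt, "unknown", 4), 1L)
})

test_that("a straight chain with no fire is the unique 3-node plan", {
  g <- make_road_graph(fixture_spec(seed = 1, road_style = "chain",
                                    road_k = 3))
  plan <- find_opera(g, NULL, "n1", "n3")
  expect_true(plan$feasible)
  expect_equal(plan$nodes, c("n1", "n2", "n3"))
  expect_equal(plan$opera_value, 3L)
  expect_equal(plan$visit_times[1], 0)
  expect_true(all(diff(plan$visit_times) > 0))
  expect_equal(nrow(validate_plan(plan, g, NULL)), 0)
})

test_that("a burned junction forces the alternative diamond route", {
  g <- make_road_graph(fixture_spec(seed = 3, road_style = "diamond"))
  av <- availability(c(A = 0.5), horizon = 100)
  plan <- find_opera(g, av, "S", "T")
  expect_true(plan$feasible)
  expect_equal(plan$nodes, c("S", "B", "T"))
  expect_true("A" %in% plan$rejected)   # the "red cross" junction
  expect_equal(nrow(validate_plan(plan, g, av)), 0)
  bf <- brute_force_opera(g, av, "S", "T")
  expect_equal(bf$nodes, plan$nodes)
  # with no fire the tie on node count is broken by travel time then phi
  p2 <- find_opera(g, NULL, "S", "T")
  b2 <- brute_force_opera(g, NULL, "S", "T")
  expect_equal(p2$nodes, b2$nodes)
  expect_equal(p2$total_travel_min, b2$total_travel_min)
})

test_that("label-setting matches the exhaustive oracle on random instances", {
  for (seed in 1:80) {
    inst <- random_router_instance(seed)
    a <- find_opera(inst$graph, inst$avail, inst$source, inst$sink)
    b <- brute_force_opera(inst$graph, inst$avail, inst$source, inst$sink)
    expect_equal(a$feasible, b$feasible, label = paste("seed", seed))
    expect_equal(a$opera_value, b$opera_value, label = paste("seed", seed))
    if (a$feasible) {
      expect_equal(a$total_travel_min, b$total_travel_min,
                   tolerance = 1e-9)
      expect_equal(nrow(validate_plan(a, inst$graph, inst$avail)), 0)
    }
  }
})

test_that("delaying the fire never worsens the route", {
  for (seed in 1:40) {
    inst <- random_router_instance(seed)
    base <- find_opera(inst$graph, inst$avail, inst$source, inst$sink)
    prev_val <- base$opera_value
    prev_feas <- base$feasible
    for (lambda in c(2, 10, Inf)) {
      av <- if (is.infinite(lambda)) NULL else
        availability(inst$arrival * lambda, horizon = 10)
      p <- find_opera(inst$graph, av, inst$source, inst$sink)
      if (prev_feas) {
        expect_true(p$feasible, label = paste("seed", seed, "lambda", lambda))
        expect_lte(p$opera_value, prev_val)
      }
      prev_val <- if (p$feasible) p$opera_value else prev_val
      prev_feas <- prev_feas || p$feasible
    }
  }
})

test_that("without fire the router degenerates to minimum-hop search", {
  skip_if_not_installed("igraph")
  for (seed in 1:40) {
    inst <- random_router_instance(seed)
    p <- find_opera(inst$graph, NULL, inst$source, inst$sink)
    hops <- min_hop_nodes(inst$graph, inst$source, inst$sink)
    if (is.infinite(hops)) expect_false(p$feasible)
    else expect_equal(p$opera_value, as.integer(hops))
  }
})

test_that("infeasibility is a result, not an exception", {
  nodes <- data.frame(id = c("a", "b", "c"), x = c(0, 100, 200), y = 0)
  edges <- data.frame(from = c("a"), to = c("b"), length = 100, phi = 0.1,
                      v_free = 40000)
  g <- road_graph(nodes, edges)
  # no path in the underlying graph
  p <- find_opera(g, NULL, "a", "c")
  expect_false(p$feasible)
  expect_equal(p$opera_value, 0L)
  expect_length(p$nodes, 0)
  b <- brute_force_opera(g, NULL, "a", "c")
  expect_false(b$feasible)
  # fire at the source at departure
  av <- availability(c(a = 0), horizon = 10)
  p2 <- find_opera(g, av, "a", "b")
  expect_false(p2$feasible)
  expect_match(p2$reason, "source")
  # horizon too short to reach the sink
  av3 <- availability(c(zz = 1), horizon = 1e-6)
  p3 <- find_opera(g, av3, "a", "b")
  expect_false(p3$feasible)
  # errors for malformed queries
  expect_error(find_opera(g, NULL, "a", "a"), "differ")
  expect_error(find_opera(g, NULL, "zz", "b"), "source")
  expect_error(brute_force_opera(g, NULL, "a", "a"), "differ")
  big <- road_graph(data.frame(id = as.character(1:20), x = 1:20, y = 0),
                    data.frame(from = as.character(1:19),
                               to = as.character(2:20), length = 1,
                               phi = 0, v_free = 1))
  expect_error(brute_force_opera(big, NULL, "1", "20"), "too large")
})

test_that("validate_plan reports safety, connectivity and timing violations", {
  g <- make_road_graph(fixture_spec(seed = 1, road_style = "chain",
                                    road_k = 3))
  plan <- find_opera(g, NULL, "n1", "n3")
  # plant a burned junction under the returned plan
  av <- availability(setNames(plan$visit_times[2] - 0.01, "n2"),
                     horizon = 100)
  v <- validate_plan(plan, g, av)
  expect_true("safety" %in% v$type)
  expect_true("n2" %in% v$node)
  # non-edge hop
  p2 <- plan
  p2$nodes <- c("n1", "n3")
  p2$visit_times <- plan$visit_times[c(1, 3)]
  expect_true("connectivity" %in% validate_plan(p2, g, NULL)$type)
  # inconsistent visit times
  p3 <- plan
  p3$visit_times[2] <- p3$visit_times[2] + 1
  expect_true("timing" %in% validate_plan(p3, g, NULL)$type)
  # infeasible plans validate trivially
  expect_equal(nrow(validate_plan(firevac:::empty_plan(), g, NULL)), 0)
})

test_that("plans serialize to GeoJSON with summary and rejected junctions", {
  tmp <- withr::local_tempdir()
  g <- make_road_graph(fixture_spec(seed = 3, road_style = "diamond"))
  av <- availability(c(A = 0.5), horizon = 100)
  plan <- find_opera(g, av, "S", "T")
  gp <- file.path(tmp, "plan.geojson"); sp <- file.path(tmp, "summary.json")
  write_plan(plan, g, gp, sp)
  s <- jsonlite::read_json(sp)
  expect_equal(s$opera_value, plan$opera_value)
  expect_true(s$feasible)
  gj <- jsonlite::read_json(gp)
  kinds <- vapply(gj$features, function(f) f$properties$kind, "")
  expect_true("route" %in% kinds)
  expect_true("rejected" %in% kinds)
})
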