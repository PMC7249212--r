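test_that("ros_max applies the fuel table with exponential humidity damping", {
  p <- ros_params(ros_max_by_fuel = c("5" = 100, "8" = 40),
                  humidity_damping = 1)
  expect_equal(ros_max(5, 0, p), 100)
  expect_equal(ros_max(5, 0.5, p), 100 * exp(-0.5))
  p0 <- ros_params(ros_max_by_fuel = c("5" = 100), humidity_damping = 0)
  expect_equal(ros_max(5, 0.9, p0), 100)
  expect_error(ros_max(7, 0, p), "unknown fuel class")
  expect_error(ros_max(5, 1.5, p), "humidity")
  # vectorized
  expect_equal(ros_max(c(5, 8), c(0, 0), p), c(100, 40))
})

test_that("wind_effect is a limiter in [0,1] with the documented geometry", {
  p <- ros_params(wind_saturation_speed = 30000)
  # calm: no limitation in any direction
  expect_equal(wind_effect(c(1, 0), wind_field(0, 123), p), 1)
  # straight downwind at saturation: still 1
  expect_equal(wind_effect(c(0, -1), wind_field(30000, 0), p), 1)
  # straight upwind at saturation: the form's minimum, 0
  expect_equal(wind_effect(c(0, 1), wind_field(30000, 0), p), 0)
  # straight upwind at half saturation: 1 - u = 0.5
  expect_equal(wind_effect(c(0, 1), wind_field(15000, 0), p), 0.5)
  # crosswind: (1 - u/2)
  expect_equal(wind_effect(c(1, 0), wind_field(30000, 0), p), 0.5)
  # speeds above saturation clamp to the saturation response
  expect_equal(wind_effect(c(0, 1), wind_field(90000, 0), p), 0)
  # property: in [0,1] for random directions and winds
  set.seed(7)
  for (i in 1:50) {
    a <- runif(1, 0, 2 * pi)
    w <- wind_field(runif(1, 0, 60000), runif(1, 0, 360))
    f <- wind_effect(c(cos(a), sin(a)), w, p)
    expect_gte(f, 0); expect_lte(f, 1)
  }
})

test_that("slope_effect damps downhill spread only", {
  p <- ros_params(slope_coefficient = 1)
  expect_equal(slope_effect(c(1, 0), c(0, 0), p), 1)
  # uphill (gradient along spread direction): unpenalized
  expect_equal(slope_effect(c(1, 0), c(0.5, 0), p), 1)
  # 45-degree downhill with s = 1: 1 - 1/(1+1) = 0.5
  expect_equal(slope_effect(c(1, 0), c(-1, 0), p), 0.5)
  # slope coefficient 0: no effect regardless of gradient
  p0 <- ros_params(slope_coefficient = 0)
  expect_equal(slope_effect(c(1, 0), c(-5, 0), p0), 1)
  # always in [0,1], uphill >= downhill at same |gradient|
  set.seed(8)
  for (i in 1:50) {
    g <- runif(1, 0, 3)
    up <- slope_effect(c(1, 0), c(g, 0), p)
    down <- slope_effect(c(1, 0), c(-g, 0), p)
    expect_gte(down, 0); expect_lte(up, 1)
    expect_gte(up, down)
  }
})

test_that("effective_ros is the bounded triple product", {
  expect_equal(effective_ros(100, 1, 1), 100)
  expect_equal(effective_ros(100, 0.5, 0.5), 25)
  expect_equal(effective_ros(100, 0, 0.9), 0)
  expect_error(effective_ros(100, 1.5, 1), "wind factor")
  expect_error(effective_ros(100, 1, -0.5), "slope factor")
  expect_error(effective_ros(-1, 1, 1), "ros_max")
})

test_that("uniform no-wind growth reproduces the analytic circle", {
  land <- uniform_landscape()
  p <- flat_params(ros = 600)
  seed <- firevac:::regular_ring(c(1000, 1000), 40, 64)
  sim <- simulate_fire(NULL, land$dem, land$fuel, land$humidity, calm(), p,
                       dt = 1, horizon = 30, snapshot_every = 5,
                       initial = fire_perimeter(seed))
  for (s in sim$snapshots) {
    expected <- 40 + 600 * s$t_min / 60
    r <- sqrt((s$rings[[1]][, 1] - 1000)^2 + (s$rings[[1]][, 2] - 1000)^2)
    expect_lt(max(abs(r - expected)) / expected, 0.02)
  }
})

test_that("zero spread rate leaves the perimeter unchanged", {
  land <- uniform_landscape(n = 20)
  p <- flat_params(ros = 0)
  seed <- firevac:::regular_ring(c(200, 200), 20, 16)
  st <- fire_perimeter(seed)
  st2 <- step_perimeter(st, land$dem, land$fuel, land$humidity, calm(), p,
                        dt = 5)
  expect_equal(st2$rings[[1]], st$rings[[1]], tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(st2$t_min, 5)
})

test_that("disjoint fronts merge into one simple ring preserving union area", {
  land <- uniform_landscape()
  p <- flat_params(ros = 1200)
  ign <- point_set(c("a", "b"), c(800, 1200), c(1000, 1000), "ignition")
  sim <- simulate_fire(ign, land$dem, land$fuel, land$humidity, calm(), p,
                       dt = 1, horizon = 20, snapshot_every = 5)
  final <- sim$snapshots[[length(sim$snapshots)]]
  expect_length(final$rings, 1)
  # union-area oracle: two analytic circles of radius r0 + ROS * t / 60
  r <- 20 + 1200 * 20 / 60
  d <- 400 / 2
  # area of union of two equal circles at half-distance d < r
  lens <- 2 * (r^2 * acos(d / r) - d * sqrt(r^2 - d^2))
  union_area <- 2 * pi * r^2 - lens
  expect_lt(abs(perimeter_area(final) - union_area) / union_area, 0.02)
})

test_that("simulation horizon 0 returns only the seed ring", {
  land <- uniform_landscape(n = 20)
  ign <- point_set("i", 200, 200, "ignition")
  sim <- simulate_fire(ign, land$dem, land$fuel, land$humidity, calm(),
                       flat_params(), dt = 1, horizon = 0)
  expect_length(sim$snapshots, 1)
  expect_equal(sim$snapshots[[1]]$t_min, 0)
})

test_that("arrival times match d/ROS in the uniform case and grow with distance", {
  land <- uniform_landscape()
  ros <- 600
  sim <- simulate_fire(point_set("i", 1000, 1000, "ignition"),
                       land$dem, land$fuel, land$humidity, calm(),
                       flat_params(ros), dt = 1, horizon = 40)
  arr <- sim$arrival
  # ignition cell burns at t = 0
  rc <- cell_at(arr, 1000, 1000)
  expect_equal(arr$values[rc[1, 1], rc[1, 2]], 0)
  # sample cells along the +x ray
  prev <- 0
  for (dist in seq(100, 380, by = 40)) {
    rc <- cell_at(arr, 1000 + dist, 1000)
    t_arr <- arr$values[rc[1, 1], rc[1, 2]]
    cc <- cell_center(arr, rc[1, 1], rc[1, 2])
    d_c <- sqrt((cc[1] - 1000)^2 + (cc[2] - 1000)^2)
    expected <- 60 * (d_c - 20) / ros    # seed ring already spans one cell
    expect_lte(abs(t_arr - expected), 1 + 1e-9)  # within one dt
    expect_gte(t_arr, prev)              # monotone along the ray
    prev <- t_arr
  }
  # cells never covered stay nodata
  expect_true(is.na(arr$values[1, 1]))
})

test_that("zero spread everywhere leaves only the seed burned", {
  land <- uniform_landscape(n = 30)
  sim <- simulate_fire(point_set("i", 300, 300, "ignition"),
                       land$dem, land$fuel, land$humidity, calm(),
                       flat_params(0), dt = 2, horizon = 10)
  burned <- which(!is.na(sim$arrival$values))
  expect_gt(length(burned), 0)
  expect_true(all(sim$arrival$values[burned] == 0))
  # every burned cell centre is within the 16-gon seed radius
  rc <- which(!is.na(sim$arrival$values), arr.ind = TRUE)
  cc <- cell_center(sim$arrival, rc[, 1], rc[, 2])
  expect_true(all(sqrt((cc[, 1] - 300)^2 + (cc[, 2] - 300)^2) <= 20 + 1e-9))
})

test_that("perimeters are contained in their successors (fire never retreats)", {
  spec <- fixture_spec(seed = 11, nrow = 60, ncol = 60,
                       dem_style = "gaussian_hill", fuel_style = "mosaic",
                       humidity = 0.25)
  land <- make_landscape(spec)
  ign <- point_set("i", 600, 600, "ignition")
  sim <- suppressWarnings(
    simulate_fire(ign, land$dem, land$fuel, land$humidity, land$wind,
                  ros_params(), dt = 2, horizon = 20))
  areas <- vapply(sim$snapshots, perimeter_area, numeric(1))
  expect_true(all(diff(areas) >= -1e-6))
  for (k in seq_len(length(sim$snapshots) - 1)) {
    old <- sim$snapshots[[k]]$rings
    new <- sim$snapshots[[k + 1]]$rings
    for (ring in old) {
      d <- firevac:::points_ring_distance(new, ring[, 1], ring[, 2])
      expect_true(all(d <= 1e-6))
    }
  }
})

test_that("no vertex moves farther than max ROS allows per step", {
  land <- uniform_landscape(n = 40)
  p <- flat_params(ros = 900)
  seed <- firevac:::regular_ring(c(400, 400), 30, 32)
  st <- fire_perimeter(seed)
  st2 <- step_perimeter(st, land$dem, land$fuel, land$humidity,
                        wind_field(20000, 45), p, dt = 3)
  bound <- 900 * 3 / 60 + 1e-9
  d <- firevac:::points_ring_distance(st$rings, st2$rings[[1]][, 1],
                                      st2$rings[[1]][, 2])
  expect_true(all(d <= bound))
})

test_that("simulation is deterministic and validates its inputs", {
  land <- uniform_landscape(n = 30)
  ign <- point_set("i", 300, 300, "ignition")
  s1 <- simulate_fire(ign, land$dem, land$fuel, land$humidity, calm(),
                      flat_params(), dt = 1, horizon = 10)
  s2 <- simulate_fire(ign, land$dem, land$fuel, land$humidity, calm(),
                      flat_params(), dt = 1, horizon = 10)
  expect_identical(s1$snapshots, s2$snapshots)
  expect_identical(s1$arrival$values, s2$arrival$values)
  expect_error(simulate_fire(point_set("i", 1e6, 300, "ignition"),
                             land$dem, land$fuel, land$humidity, calm(),
                             flat_params(), dt = 1, horizon = 10),
               "outside raster extent")
  expect_error(simulate_fire(ign, land$dem, land$fuel, land$humidity, calm(),
                             flat_params(), dt = 2, horizon = 10,
                             snapshot_every = 3),
               "multiple of dt")
})

test_that("perimeter GeoJSON round-trips snapshots", {
  tmp <- withr::local_tempdir()
  land <- uniform_landscape(n = 30)
  ign <- point_set(c("a", "b"), c(250, 350), c(300, 300), "ignition")
  sim <- simulate_fire(ign, land$dem, land$fuel, land$humidity, calm(),
                       flat_params(1200), dt = 1, horizon = 8,
                       snapshot_every = 4)
  path <- file.path(tmp, "peri.geojson")
  write_perimeters(sim, path)
  back <- read_perimeters(path)
  expect_length(back, length(sim$snapshots))
  for (k in seq_along(back)) {
    expect_equal(back[[k]]$t_min, sim$snapshots[[k]]$t_min)
    expect_equal(back[[k]]$rings, sim$snapshots[[k]]$rings,
                 ignore_attr = TRUE)
  }
})
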