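#' Rate-of-spread parameters
#'
#' Bundles the fuel-class table of maximum spread rates with the wind,
#' slope and humidity response coefficients. The effective spread rate at a
#' front vertex is the product
#' `ROS_effective = ROS_max * Wind_Effect * Slope_Effect`, where `ROS_max`
#' is the fuel- and humidity-determined ceiling and the two factors are
#' limiters in \[0, 1\] — the effective rate can never exceed `ROS_max`.
#'
#' The default `ROS_max` table (one entry per Anderson fuel class 1..13) is
#' shipped as data in `inst/extdata/ros_defaults.json`; the values are
#' order-of-magnitude figures for grass/shrub/timber/slash fuel groups and
#' are meant to be replaced with locally calibrated rates.
#'
#' @param ros_max_by_fuel Named numeric vector mapping fuel class `"1"`..`"13"`
#'   to `ROS_max` in m/h (all >= 0). Default: the shipped table.
#' @param humidity_damping Exponential humidity coefficient k >= 0:
#'   `ROS_max(fuel, h) = table[fuel] * exp(-k * h)`.
#' @param wind_saturation_speed Wind speed (m/h) at which the directional
#'   wind limitation saturates; must be > 0.
#' @param slope_coefficient Downhill damping coefficient >= 0.
#' @param wind_effect_fn,slope_effect_fn Optional replacement strategy
#'   functions with the same signatures as [wind_effect()] /
#'   [slope_effect()]; the shipped forms are documented stand-ins.
#' @return Object of class `ros_params`.
#' @export
ros_params <- function(ros_max_by_fuel = NULL,
                       humidity_damping = 3,
                       wind_saturation_speed = 30000,
                       slope_coefficient = 2,
                       wind_effect_fn = NULL,
                       slope_effect_fn = NULL) {
  if (is.null(ros_max_by_fuel)) {
    path <- system.file("extdata", "ros_defaults.json", package = "firevac")
    tab <- jsonlite::read_json(path, simplifyVector = TRUE)
    ros_max_by_fuel <- unlist(tab$ros_max_by_fuel)
  }
  ros_max_by_fuel <- unlist(ros_max_by_fuel)
  if (is.null(names(ros_max_by_fuel)) || any(names(ros_max_by_fuel) == ""))
    names(ros_max_by_fuel) <- as.character(seq_along(ros_max_by_fuel))
  if (any(ros_max_by_fuel < 0)) stop("ROS_max values must be >= 0")
  if (humidity_damping < 0) stop("humidity_damping must be >= 0")
  if (wind_saturation_speed <= 0) stop("wind_saturation_speed must be > 0")
  if (slope_coefficient < 0) stop("slope_coefficient must be >= 0")
  structure(list(ros_max_by_fuel = ros_max_by_fuel,
                 humidity_damping = humidity_damping,
                 wind_saturation_speed = wind_saturation_speed,
                 slope_coefficient = slope_coefficient,
                 wind_effect_fn = wind_effect_fn,
                 slope_effect_fn = slope_effect_fn),
            class = "ros_params")
}

#' Maximum rate of spread for a fuel class under a given humidity
#'
#' `ROS_max(fuel, h) = table[fuel] * exp(-k * h)` with k the humidity
#' damping coefficient: the table value at zero humidity, monotonically
#' damped as vegetation moisture rises.
#'
#' @param fuel_class Integer fuel class (1..13); vectorized.
#' @param humidity Humidity fraction in \[0, 1\]; vectorized.
#' @param params A [ros_params()] object.
#' @return Spread rate ceiling in m/h (>= 0).
#' @examples
#' p <- ros_params(ros_max_by_fuel = c("5" = 100), humidity_damping = 1)
#' ros_max(5, 0.5, p)  # 100 * exp(-0.5)
#' @export
ros_max <- function(fuel_class, humidity, params) {
  key <- as.character(as.integer(fuel_class))
  base <- params$ros_max_by_fuel[key]
  if (anyNA(base))
    stop("unknown fuel class: ",
         paste(unique(key[is.na(base)]), collapse = ", "))
  if (any(humidity < 0 | humidity > 1, na.rm = TRUE))
    stop("humidity outside [0,1]")
  unname(base * exp(-params$humidity_damping * humidity))
}

#' Directional wind limitation factor
#'
#' `Wind_Effect(theta, U) = 1 - (min(U, U_sat)/U_sat) * (1 - cos(theta))/2`,
#' where `theta` is the angle between the front vertex's outward normal
#' (the local spread direction) and the downwind direction, and `U_sat` is
#' the saturation speed. The factor is 1 under calm and for spread straight
#' downwind, falls to `1 - U/U_sat` straight upwind, and reaches 0 only
#' upwind at or above saturation. Always in \[0, 1\].
#'
#' @param spread_direction Unit vector(s) (n x 2 matrix or length-2 vector):
#'   the outward normal at the front vertex.
#' @param wind A [wind_field()].
#' @param params A [ros_params()] object (for the saturation speed).
#' @return Factor(s) in \[0, 1\].
#' @export
wind_effect <- function(spread_direction, wind, params) {
  if (!is.null(params$wind_effect_fn))
    return(params$wind_effect_fn(spread_direction, wind, params))
  if (is.null(dim(spread_direction)))
    spread_direction <- matrix(spread_direction, ncol = 2)
  if (wind$speed == 0) return(rep(1, nrow(spread_direction)))
  dw <- downwind_vector(wind)
  costh <- spread_direction[, 1] * dw[1] + spread_direction[, 2] * dw[2]
  costh <- pmin(pmax(costh, -1), 1)
  u <- min(wind$speed, params$wind_saturation_speed) /
    params$wind_saturation_speed
  1 - u * (1 - costh) / 2
}

#' Slope limitation factor
#'
#' Downhill spread is damped, uphill spread is not:
#' `Slope_Effect = 1 - s*d/(1 + s*d)` with `d = max(0, -g_along)` the
#' downhill component of the terrain gradient along the spread direction
#' (dimensionless rise/run) and `s` the slope coefficient. The factor is 1
#' on flat terrain and for any uphill spread, decays toward 0 on ever
#' steeper descents, and always stays in \[0, 1\].
#'
#' @param spread_direction Unit vector(s) (n x 2 matrix or length-2 vector).
#' @param local_gradient Terrain gradient vector(s) (n x 2 or length-2),
#'   rise/run, pointing uphill; from central differences on the DEM.
#' @param params A [ros_params()] object.
#' @return Factor(s) in \[0, 1\].
#' @export
slope_effect <- function(spread_direction, local_gradient, params) {
  if (!is.null(params$slope_effect_fn))
    return(params$slope_effect_fn(spread_direction, local_gradient, params))
  if (is.null(dim(spread_direction)))
    spread_direction <- matrix(spread_direction, ncol = 2)
  if (is.null(dim(local_gradient)))
    local_gradient <- matrix(local_gradient, ncol = 2,
                             nrow = nrow(spread_direction), byrow = TRUE)
  g_along <- spread_direction[, 1] * local_gradient[, 1] +
    spread_direction[, 2] * local_gradient[, 2]
  d <- pmax(0, -g_along)
  s <- params$slope_coefficient
  pmin(pmax(1 - s * d / (1 + s * d), 0), 1)
}

#' Effective rate of spread
#'
#' The product `ROS_max * Wind_Effect * Slope_Effect`. Both factors must lie
#' in \[0, 1\], so the result is bounded by `ROS_max`.
#'
#' @param ros_max Spread-rate ceiling(s), m/h, >= 0.
#' @param wind_factor,slope_factor Limitation factor(s) in \[0, 1\].
#' @return Effective spread rate(s) in m/h.
#' @examples
#' effective_ros(100, 0.5, 0.5)  # 25
#' @export
effective_ros <- function(ros_max, wind_factor, slope_factor) {
  if (any(ros_max < 0)) stop("ros_max must be >= 0")
  if (any(wind_factor < -1e-12 | wind_factor > 1 + 1e-12))
    stop("wind factor outside [0,1]")
  if (any(slope_factor < -1e-12 | slope_factor > 1 + 1e-12))
    stop("slope factor outside [0,1]")
  ros_max * pmin(pmax(wind_factor, 0), 1) * pmin(pmax(slope_factor, 0), 1)
}

#' Fire perimeter snapshot
#'
#' The burning front at one instant: one or more closed, simple,
#' counter-clockwise vertex rings in projected metres, plus the timestamp in
#' minutes since ignition.
#'
#' @param rings A single n x 2 matrix or a list of them (open rings: first
#'   vertex not repeated).
#' @param t_min Minutes since ignition (>= 0).
#' @return Object of class `fire_perimeter`.
#' @export
fire_perimeter <- function(rings, t_min = 0) {
  if (is.matrix(rings)) rings <- list(rings)
  for (r in rings) if (!is.matrix(r) || ncol(r) != 2 || nrow(r) < 3)
    stop("each ring needs an n x 2 matrix with >= 3 vertices")
  if (t_min < 0) stop("timestamp must be >= 0")
  rings <- lapply(rings, function(r) {
    colnames(r) <- c("x", "y")
    ensure_ccw(r)
  })
  structure(list(rings = rings, t_min = t_min), class = "fire_perimeter")
}

#' @export
print.fire_perimeter <- function(x, ...) {
  cat(sprintf("<fire_perimeter> t = %g min, %d ring(s), area %.1f m^2\n",
              x$t_min, length(x$rings), perimeter_area(x)))
  invisible(x)
}

#' @rdname fire_perimeter
#' @param perimeter A `fire_perimeter`.
#' @return `perimeter_area` returns the total enclosed area in m^2.
#' @export
perimeter_area <- function(perimeter) {
  sum(vapply(perimeter$rings, ring_area, numeric(1)))
}

#' Advance the fire perimeter by one time step
#'
#' Huygens-style front expansion: every ring vertex is displaced along its
#' outward normal by `ROS_effective(vertex) * dt / 60` metres, where the
#' effective rate combines the fuel/humidity ceiling with the wind and slope
#' limiters evaluated in the vertex's normal direction. The displaced rings
#' are then repaired (self-intersection loops removed, colliding rings
#' merged by polygon union under the nonzero winding rule) and refined to
#' roughly one-cell vertex spacing. Vertices that would leave the raster
#' extent are clipped to it with a warning. The burned area never shrinks.
#'
#' @param state A [fire_perimeter()].
#' @param dem,fuel,humidity Aligned [fv_raster] layers (humidity may be a
#'   single scalar, broadcast over the grid).
#' @param wind A [wind_field()] for this step.
#' @param params A [ros_params()].
#' @param dt Step length in minutes (> 0).
#' @return The advanced `fire_perimeter` with timestamp `state$t_min + dt`.
#' @export
step_perimeter <- function(state, dem, fuel, humidity, wind, params, dt) {
  if (dt <= 0) stop("dt must be > 0")
  if (is.numeric(humidity) && length(humidity) == 1)
    humidity <- fv_raster(matrix(humidity, nrow(dem$values), ncol(dem$values)),
                          dem$origin, dem$cell_size, crs_tag = dem$crs_tag,
                          layer_kind = "humidity")
  check_alignment(dem, fuel, humidity)
  ext <- raster_extent(dem)
  clipped <- FALSE
  new_rings <- lapply(state$rings, function(ring) {
    nr <- ring_normals(ring)
    x <- ring[, 1]; y <- ring[, 2]
    fc <- sample_raster(fuel, x, y)
    hu <- sample_raster(humidity, x, y)
    rmax <- numeric(length(x))
    ok <- !is.na(fc) & !is.na(hu)
    if (any(ok)) rmax[ok] <- ros_max(fc[ok], hu[ok], params)
    wf <- wind_effect(nr, wind, params)
    grad <- raster_gradient(dem, x, y)
    sf <- slope_effect(nr, grad, params)
    disp <- effective_ros(rmax, wf, sf) * dt / 60
    nx <- x + nr[, 1] * disp
    ny <- y + nr[, 2] * disp
    cx <- pmin(pmax(nx, ext["xmin"]), ext["xmax"])
    cy <- pmin(pmax(ny, ext["ymin"]), ext["ymax"])
    if (any(cx != nx) || any(cy != ny)) clipped <<- TRUE
    cbind(cx, cy)
  })
  if (clipped)
    warning("fire front reached the raster extent; vertices clipped")
  repaired <- union_rings(new_rings)
  repaired <- lapply(repaired, resample_ring, spacing = dem$cell_size)
  if (!length(repaired) || any(vapply(repaired, nrow, 1L) < 3))
    stop("perimeter degenerated below 3 vertices")
  fire_perimeter(repaired, t_min = state$t_min + dt)
}

#' Simulate discrete-time fire spread
#'
#' Runs [step_perimeter()] from the ignition seed(s) to the horizon,
#' collecting perimeter snapshots at the requested cadence and recording,
#' per grid cell, the first time step at which the cell centre falls inside
#' the burning polygon (the arrival-time field; cells never covered stay
#' nodata). Each ignition point is seeded as a regular 16-gon of radius one
#' cell size — a point has no normals, and this is the smallest
#' well-conditioned front.
#'
#' @param ignitions A [point_set()] of ignition points (inside the raster
#'   extent), or `NULL` if `initial` is given.
#' @param dem,fuel,humidity Aligned [fv_raster] layers; `humidity` may be a
#'   scalar.
#' @param wind_sequence A [wind_field()] or a list of them, one per step
#'   (the last is held for any remaining steps).
#' @param params A [ros_params()].
#' @param dt Step length, minutes (> 0).
#' @param horizon Total simulated span, minutes (`0` returns only the seed).
#' @param snapshot_every Snapshot cadence, minutes; must be a multiple of
#'   `dt`. Default `dt`.
#' @param initial Optional [fire_perimeter()] used as the seed instead of
#'   ignition 16-gons (e.g. an observed front).
#' @return Object of class `fire_simulation`: a list with `snapshots` (list
#'   of `fire_perimeter`, first at t = 0), `arrival` (an [fv_raster] of
#'   minutes, layer kind `"arrival"`), `dt`, `horizon`.
#' @export
simulate_fire <- function(ignitions, dem, fuel, humidity, wind_sequence,
                          params, dt, horizon, snapshot_every = dt,
                          initial = NULL) {
  if (dt <= 0) stop("dt must be > 0")
  if (horizon < 0) stop("horizon must be >= 0")
  if (abs(snapshot_every / dt - round(snapshot_every / dt)) > 1e-9)
    stop("snapshot_every must be a multiple of dt")
  if (inherits(wind_sequence, "wind_field")) wind_sequence <- list(wind_sequence)
  if (is.null(initial)) {
    if (is.null(ignitions) || nrow(ignitions) == 0)
      stop("no ignition points and no initial perimeter")
    ext <- raster_extent(dem)
    inside <- ignitions$x >= ext["xmin"] & ignitions$x <= ext["xmax"] &
      ignitions$y >= ext["ymin"] & ignitions$y <= ext["ymax"]
    if (!all(inside))
      stop("ignition outside raster extent: ",
           paste(ignitions$id[!inside], collapse = ", "))
    seed_rings <- lapply(seq_len(nrow(ignitions)), function(i)
      regular_ring(c(ignitions$x[i], ignitions$y[i]), dem$cell_size, 16))
    state <- fire_perimeter(union_rings(seed_rings), t_min = 0)
  } else {
    state <- initial
    state$t_min <- 0
  }

  nrw <- nrow(dem$values); ncl <- ncol(dem$values)
  arrival <- matrix(NA_real_, nrw, ncl)
  cc <- cell_center(dem, rep(seq_len(nrw), times = ncl),
                    rep(seq_len(ncl), each = nrw))
  burn_update <- function(t_now, rings) {
    unburned <- which(is.na(arrival))
    if (!length(unburned)) return()
    bb <- sapply(rings, function(r) c(range(r[, 1]), range(r[, 2])))
    inbb <- cc[unburned, 1] >= min(bb[1, ]) & cc[unburned, 1] <= max(bb[2, ]) &
      cc[unburned, 2] >= min(bb[3, ]) & cc[unburned, 2] <= max(bb[4, ])
    cand <- unburned[inbb]
    if (!length(cand)) return()
    hit <- points_in_rings(rings, cc[cand, 1], cc[cand, 2])
    arrival[cand[hit]] <<- t_now
  }
  burn_update(0, state$rings)

  snapshots <- list(state)
  n_steps <- floor(horizon / dt + 1e-9)
  snap_mult <- round(snapshot_every / dt)
  for (s in seq_len(n_steps)) {
    wind <- wind_sequence[[min(s, length(wind_sequence))]]
    state <- step_perimeter(state, dem, fuel, humidity, wind, params, dt)
    burn_update(state$t_min, state$rings)
    if (s %% snap_mult == 0) snapshots[[length(snapshots) + 1]] <- state
  }
  arr <- fv_raster(arrival, dem$origin, dem$cell_size, nodata = -9999,
                   crs_tag = dem$crs_tag, layer_kind = "arrival")
  structure(list(snapshots = snapshots, arrival = arr, dt = dt,
                 horizon = horizon, snapshot_every = snapshot_every),
            class = "fire_simulation")
}

#' @export
print.fire_simulation <- function(x, ...) {
  cat(sprintf("<fire_simulation> %d snapshots over %g min (dt = %g), %d cells burned\n",
              length(x$snapshots), x$horizon, x$dt,
              sum(!is.na(x$arrival$values))))
  invisible(x)
}
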