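#' Synthetic weather scenario parameters
#'
#' Describes an analytic, horizontally homogeneous weather scenario with
#' the vertical structure the migration model assumes: a wind profile
#' (uniform, or a low-level jet with a single speed maximum and direction
#' turning with height), a linear temperature profile (optionally crossing
#' the 13 degC flight ceiling aloft) and a constant/linear/parabolic
#' vertical diffusivity profile.  Scenarios are time-constant by default;
#' `time_ramp` adds a linear-in-time scaling of the wind from
#' `time_ramp[1]` at the first instant to `time_ramp[2]` at the last
#' (useful for exercising temporal interpolation analytically).
#'
#' Wind direction follows the meteorological convention: the direction the
#' wind blows FROM, degrees clockwise from north, so
#' `u = -speed * sin(dir)`, `v = -speed * cos(dir)`.
#'
#' @param lat_range,lon_range length-2 numeric domain bounds (degrees).
#' @param dlat,dlon grid spacing in degrees.
#' @param levels strictly increasing z* levels in m.
#' @param z_top model-top height in m (default: top level).
#' @param duration_h scenario length in hours (>= 2 instants, i.e. >= 1 h,
#'   but at least 2 h is required so downstream validation has a real span).
#' @param start UTC start instant.
#' @param wind list: `list(type = "uniform", u =, v =)` or
#'   `list(type = "jet", peak_speed =, peak_height =, direction =,
#'   turning_deg_per_km =, width = 800)`.  `width` is the Gaussian
#'   half-width (m) of the jet speed profile.
#' @param temp list: `list(surface_c =, lapse_c_per_km =)`.
#' @param kz list: `list(type = "constant", k0 =)`,
#'   `list(type = "linear", k0 =, slope =)` (slope in m/s, i.e. m^2/s per
#'   m) or `list(type = "parabolic", kmax =, top =)` giving
#'   `kmax * 4 z (top - z) / top^2`, floored at 0.
#' @param time_ramp NULL or length-2 multipliers applied to the wind,
#'   linear in time.
#' @return a validated `scenario_params` list.
#' @export
scenario_params <- function(lat_range = c(25, 35), lon_range = c(120, 132),
                            dlat = 0.5, dlon = 0.5,
                            levels = seq(0, 3000, by = 250),
                            z_top = NULL,
                            duration_h = 48,
                            start = "2021-04-30 10:00",
                            wind = list(type = "uniform", u = 10, v = 0),
                            temp = list(surface_c = 25, lapse_c_per_km = 6.5),
                            kz = list(type = "constant", k0 = 10),
                            time_ramp = NULL) {
  if (duration_h < 2) abort("duration_h must be >= 2 (need >= 2 hourly instants)")
  if (length(levels) < 2 || any(diff(levels) <= 0) || levels[1] < 0) {
    abort("levels must be strictly increasing and >= 0")
  }
  z_top <- z_top %||% max(levels)
  if (max(levels) > z_top) abort("levels exceed z_top")
  wind$type <- match.arg(wind$type, c("uniform", "jet"))
  if (wind$type == "jet") {
    if (is.null(wind$width)) wind$width <- 800
    if (wind$peak_speed < 0) abort("peak speed must be >= 0")
    if (wind$peak_height < min(levels) || wind$peak_height > max(levels)) {
      abort("jet peak height outside the level range")
    }
  }
  kz$type <- match.arg(kz$type, c("constant", "linear", "parabolic"))
  structure(list(lat_range = lat_range, lon_range = lon_range,
                 dlat = dlat, dlon = dlon, levels = levels, z_top = z_top,
                 duration_h = duration_h, start = parse_utc(start),
                 wind = wind, temp = temp, kz = kz, time_ramp = time_ramp),
            class = "scenario_params")
}

#' Vertical profiles of a synthetic scenario
#'
#' Evaluate the scenario's analytic profiles at arbitrary z* heights:
#' wind speed (m/s), wind direction (deg, FROM-convention), u, v,
#' temperature (degC) and vertical diffusivity (m^2/s).
#'
#' @param params a [scenario_params()].
#' @param zstar numeric heights in m.
#' @return a tibble with columns `zstar, speed, direction, u, v, temp_c, kz`.
#' @export
scenario_profile <- function(params, zstar) {
  w <- params$wind
  if (w$type == "uniform") {
    u <- rep(w$u, length(zstar)); v <- rep(w$v, length(zstar))
    speed <- sqrt(u^2 + v^2)
    dir <- (atan2(-u, -v) * 180 / pi) %% 360
  } else {
    speed <- w$peak_speed * exp(-((zstar - w$peak_height) / w$width)^2)
    dir <- (w$direction + w$turning_deg_per_km * (zstar - w$peak_height) / 1000) %% 360
    u <- -speed * sin(dir * pi / 180)
    v <- -speed * cos(dir * pi / 180)
  }
  temp_c <- params$temp$surface_c - params$temp$lapse_c_per_km * zstar / 1000
  kz <- switch(params$kz$type,
    constant = rep(params$kz$k0, length(zstar)),
    linear = params$kz$k0 + params$kz$slope * zstar,
    parabolic = pmax(params$kz$kmax * 4 * zstar *
                       (params$kz$top - zstar) / params$kz$top^2, 0))
  if (any(kz < 0)) abort("diffusivity profile is negative at some level")
  tibble::tibble(zstar = zstar, speed = speed, direction = dir,
                 u = u, v = v, temp_c = temp_c, kz = kz)
}

#' Generate a synthetic MetSeries
#'
#' `uniform_flow()` builds a horizontally homogeneous, constant-wind
#' scenario; `jet_scenario()` a low-level jet whose speed has a single
#' maximum at the configured peak height and whose direction rotates
#' linearly with height (Ekman-like turning).  Both use the scenario's
#' temperature and diffusivity profiles, set the z*-coordinate vertical
#' velocity to 0 and the terrain flat at 0, and pass [met_series()]
#' validation by construction.
#'
#' @param params a [scenario_params()] (with the matching `wind$type`).
#' @return a [met_series()].
#' @export
uniform_flow <- function(params) {
  if (params$wind$type != "uniform") abort("params$wind$type must be 'uniform'")
  build_scenario(params)
}

#' @rdname uniform_flow
#' @export
jet_scenario <- function(params) {
  if (params$wind$type != "jet") abort("params$wind$type must be 'jet'")
  build_scenario(params)
}

build_scenario <- function(params) {
  lats <- seq(params$lat_range[1], params$lat_range[2], by = params$dlat)
  lons <- seq(params$lon_range[1], params$lon_range[2], by = params$dlon)
  times <- params$start + 3600 * seq(0, params$duration_h)
  nt <- length(times); nl <- length(params$levels)
  nla <- length(lats); nlo <- length(lons)
  prof <- scenario_profile(params, params$levels)

  ramp <- rep(1, nt)
  if (!is.null(params$time_ramp)) {
    ramp <- seq(params$time_ramp[1], params$time_ramp[2], length.out = nt)
  }
  # (time, level) slab replicated over the horizontal dimensions
  expand <- function(tl) array(tl, dim = c(nt, nl, nla, nlo))
  u <- expand(outer(ramp, prof$u))
  v <- expand(outer(ramp, prof$v))
  w <- expand(matrix(0, nt, nl))
  temp <- expand(matrix(prof$temp_c, nt, nl, byrow = TRUE))
  kz <- expand(matrix(prof$kz, nt, nl, byrow = TRUE))
  met_series(lats = lats, lons = lons, levels = params$levels,
             z_top = params$z_top, terrain = 0, times = times,
             u = u, v = v, w = w, temp = temp, kz = kz)
}

#' Height at which a linear temperature profile crosses a threshold
#'
#' For a nocturnal profile `T(z) = surface_c - lapse_c_per_km * z/1000`,
#' returns the height (m) where T first reaches `threshold_c` (the flight
#' ceiling temperature), or `Inf` when the profile never crosses it
#' (non-positive lapse with a warm surface), or 0 when the whole column is
#' already at or below the threshold.
#'
#' @param surface_c surface temperature, degC.
#' @param lapse_c_per_km lapse rate, degC per km of height.
#' @param threshold_c threshold temperature, degC (default 13.0).
#' @return crossing height in m.
#' @export
#' @examples
#' ceiling_height(24, 7.33)  # ~1500 m
ceiling_height <- function(surface_c, lapse_c_per_km, threshold_c = 13) {
  if (surface_c <= threshold_c) return(0)
  if (lapse_c_per_km <= 0) return(Inf)
  (surface_c - threshold_c) / lapse_c_per_km * 1000
}
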