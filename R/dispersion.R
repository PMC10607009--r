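#' Simulation configuration for the migration integrator
#'
#' Collects the flight parameters of the Lagrangian moth model.  Defaults
#' are the operational values: a 3 m/s self-propelled airspeed added in
#' the leeward (downwind) direction, a 0.75 m/s dusk-ascent climb applied
#' from the run start until `ascent_end` seconds after it (one hour: later
#' take-offs ascend for less time), a 13.0 degC temperature ceiling the
#' moths will not cross into, a 48 h forecast horizon and a 120 s
#' integration step.  The vertical random-walk step is
#' `sqrt(24 Kz dt) * R` with R uniform on \[-0.5, 0.5\], so its variance
#' is exactly `2 Kz dt`.
#'
#' @param dt integration time step in s; must divide 3600.
#' @param flight_speed leeward self-propulsion airspeed, m/s.
#' @param ascent_speed climb speed during the ascent phase, m/s.
#' @param ascent_end end of the ascent phase, seconds after run start.
#' @param temp_min flight ceiling temperature, degC: vertical moves into
#'   air at or below this temperature are rejected.
#' @param horizon_h forecast horizon in hours.
#' @param top_boundary `"clamp"` (default) caps particles at the highest
#'   z* level; `"reflect"` mirrors them back below it (used for closed-
#'   column diffusion verification runs).
#' @return a `sim_config` list.
#' @export
sim_config <- function(dt = 120, flight_speed = 3.0, ascent_speed = 0.75,
                       ascent_end = 3600, temp_min = 13.0, horizon_h = 48,
                       top_boundary = c("clamp", "reflect")) {
  if (dt <= 0 || abs(3600 / dt - round(3600 / dt)) > 1e-9) {
    abort("dt must be positive and divide 3600 s")
  }
  if (horizon_h <= 0) abort("horizon_h must be > 0")
  if (flight_speed < 0) abort("flight_speed must be >= 0")
  if (ascent_end < 0) abort("ascent_end must be >= 0")
  structure(list(dt = dt, flight_speed = flight_speed,
                 ascent_speed = ascent_speed, ascent_end = ascent_end,
                 temp_min = temp_min, horizon_h = horizon_h,
                 top_boundary = match.arg(top_boundary)),
            class = "sim_config")
}

#' Leeward self-propulsion components
#'
#' The moth adds a fixed airspeed in the direction of the local wind:
#' `flight_speed * (u, v) / |(u, v)|`.  In calm air the heading is
#' undefined and the self-propulsion is (0, 0).
#'
#' @param u,v local wind components, m/s (vectorised).
#' @param flight_speed self-propulsion airspeed, m/s.
#' @return a list with components `sx`, `sy`.
#' @export
#' @examples
#' leeward_velocity(4, 3, 3)  # (2.4, 1.8)
leeward_velocity <- function(u, v, flight_speed = 3.0) {
  spd <- sqrt(u^2 + v^2)
  ok <- spd > 0
  f <- ifelse(ok, flight_speed / pmax(spd, .Machine$double.eps), 0)
  list(sx = u * f, sy = v * f)
}

#' Candidate vertical displacement for one step
#'
#' The vertical update sums advection by the z*-coordinate vertical wind,
#' the diffusivity-gradient drift, a uniform random-walk term and, during
#' the ascent phase, the climb speed:
#' `dz* = w* dt + dKz/dz* dt + sqrt(24 Kz dt) R + wc dt`
#' with R uniform on \[-0.5, 0.5\] (variance 1/12, so the random step
#' variance is `2 Kz dt`).  The ascent term applies while the elapsed time
#' since the run start is below `cfg$ascent_end`, to airborne particles
#' only.  Draws come from R's global random stream.
#'
#' @param w vertical wind at the particle, m/s (vector).
#' @param kz vertical diffusivity at the particle, m^2/s (vector).
#' @param kz_grad vertical diffusivity gradient at the particle, m/s.
#' @param cfg a [sim_config()].
#' @param ascending logical vector: is the ascent term active for this
#'   particle at this step?
#' @return numeric vector of candidate z* increments (m).
#' @export
vertical_increment <- function(w, kz, kz_grad, cfg, ascending = FALSE) {
  n <- length(w)
  r <- runif(n, -0.5, 0.5)
  w * cfg$dt + kz_grad * cfg$dt + sqrt(24 * kz * cfg$dt) * r +
    cfg$ascent_speed * cfg$dt * as.numeric(rep_len(ascending, n))
}

#' Apply vertical and horizontal boundaries to candidate positions
#'
#' Rules, in order: particles whose candidate horizontal position leaves
#' the met grid are deactivated at their last valid position; a candidate
#' below the ground (z* < 0) is reflected to -z*; a candidate above the
#' highest level is clamped there (or reflected, per
#' `cfg$top_boundary`); finally, if the air temperature interpolated at
#' the (bounded) candidate is at or below `cfg$temp_min`, the vertical
#' displacement is cancelled and the particle keeps its previous height —
#' the ceiling keeps moths from entering air too cold for wing-beating,
#' while the horizontal move stands.  No landing: the ground is purely
#' reflective and particles fly until the horizon or domain exit.
#'
#' @param met a [met_series()].
#' @param cfg a [sim_config()].
#' @param t instant of the candidate state (POSIXct UTC).
#' @param lat,lon candidate horizontal position (vectors).
#' @param z_old previous z* (vector).
#' @param z_cand candidate z* (vector).
#' @return list with `lat`, `lon`, `zstar`, and logical `exited`.
#' @export
apply_boundaries <- function(met, cfg, t, lat, lon, z_old, z_cand) {
  nla <- length(met$lats); nlo <- length(met$lons)
  exited <- lat < met$lats[1] | lat > met$lats[nla] |
    lon < met$lons[1] | lon > met$lons[nlo]
  z <- z_cand
  z <- ifelse(z < 0, -z, z)
  ztop <- met$levels[length(met$levels)]
  if (cfg$top_boundary == "reflect") {
    z <- ifelse(z > ztop, 2 * ztop - z, z)
    z <- pmin(pmax(z, 0), ztop)  # guard pathological overshoot
  } else {
    z <- pmin(z, ztop)
  }
  qlat <- ifelse(exited, NA_real_, lat)
  moved <- !exited & (abs(z - z_old) > 0)
  if (any(moved)) {
    tv <- met_interp(met, t, lat[moved], lon[moved], z[moved],
                     vars = "temp", clamp_z = TRUE)$temp
    block <- !is.na(tv) & tv <= cfg$temp_min
    idx <- which(moved)[block]
    z[idx] <- z_old[idx]
  }
  list(lat = lat, lon = lon, zstar = z, exited = exited)
}

# one integration step over the full particle state (internal).
# state: list(lat, lon, zstar, active, exited, takeoff (numeric s))
advance_state <- function(state, met, cfg, t_num, start_num) {
  airborne <- state$active & !state$exited & t_num >= state$takeoff
  out <- state
  if (!any(airborne)) return(out)
  i <- which(airborne)
  t <- as.POSIXct(t_num, origin = "1970-01-01", tz = "UTC")
  f <- met_interp(met, t, state$lat[i], state$lon[i], state$zstar[i],
                  vars = c("u", "v", "w", "kz", "kz_grad"), clamp_z = TRUE)
  # out-of-domain at the current position (shouldn't happen after
  # boundary handling, but deactivate defensively)
  bad <- f$oob
  if (any(bad)) {
    out$exited[i[bad]] <- TRUE
    i <- i[!bad]
    if (!length(i)) return(out)
    f <- lapply(f, function(x) x[!bad])
  }
  s <- leeward_velocity(f$u, f$v, cfg$flight_speed)
  dx <- (f$u + s$sx) * cfg$dt   # m east
  dy <- (f$v + s$sy) * cfg$dt   # m north
  lat2 <- state$lat[i] + dy / M_PER_DEG_LAT
  lon2 <- state$lon[i] + dx / (M_PER_DEG_LON_EQ * cos(state$lat[i] * pi / 180))
  ascending <- (t_num - start_num) < cfg$ascent_end
  dz <- vertical_increment(f$w, f$kz, f$kz_grad, cfg, ascending)
  b <- apply_boundaries(met, cfg, t + cfg$dt, lat2, lon2,
                        state$zstar[i], state$zstar[i] + dz)
  keep <- !b$exited
  out$lat[i[keep]] <- b$lat[keep]
  out$lon[i[keep]] <- b$lon[keep]
  out$zstar[i[keep]] <- b$zstar[keep]
  out$exited[i[!keep]] <- TRUE
  out
}

#' Advance a particle ensemble by one time step
#'
#' Applies the horizontal equation of motion (wind plus leeward
#' self-propulsion, converted from metres to degrees on the local tangent
#' plane), the vertical update and the boundary rules to every airborne
#' particle.  Particles whose take-off time is still in the future, and
#' particles deactivated by a domain exit, do not move.
#'
#' @param particles a tibble with columns
#'   `id, source, lat, lon, zstar, takeoff_utc, active, exited`.
#' @param met a [met_series()].
#' @param cfg a [sim_config()].
#' @param t current instant (POSIXct UTC); the returned state is at
#'   `t + cfg$dt`.
#' @param start run start (POSIXct UTC); defaults to the earliest
#'   take-off.  Controls the shared ascent-phase clock.
#' @return the particle tibble at `t + dt`.
#' @export
advance <- function(particles, met, cfg, t, start = min(particles$takeoff_utc)) {
  t_num <- as.numeric(parse_utc(t))
  if (t_num + cfg$dt > as.numeric(met$times[length(met$times)]) + 1e-6) {
    abort("met time span exceeded: simulation end")
  }
  state <- list(lat = particles$lat, lon = particles$lon,
                zstar = particles$zstar,
                active = particles$active %||% rep(TRUE, nrow(particles)),
                exited = particles$exited %||% rep(FALSE, nrow(particles)),
                takeoff = as.numeric(particles$takeoff_utc))
  state <- advance_state(state, met, cfg, t_num, as.numeric(parse_utc(start)))
  particles$lat <- state$lat
  particles$lon <- state$lon
  particles$zstar <- state$zstar
  particles$exited <- state$exited
  particles$active <- state$active & !state$exited
  particles
}

#' Run the full migration simulation
#'
#' Integrates every particle of a release plan from the run start to
#' `start + horizon_h` at steps of `cfg$dt`, recording a snapshot of all
#' particle positions every `record_every` steps (and always the final
#' state).  Deterministic for a fixed [set.seed()].
#'
#' @param release a release plan from [build_release()].
#' @param met a [met_series()] covering `[start, start + horizon_h]`.
#' @param cfg a [sim_config()].
#' @param record_every record a snapshot every this many steps (default 1
#'   = every integration step, which arrival detection relies on).
#' @return a `trajectory_set` tibble with columns
#'   `time_utc, id, source, abbrev, lat, lon, zstar, airborne, active` and
#'   attributes `start`, `cfg`.  `airborne` marks particles that have
#'   taken off and are still inside the domain; `active` is FALSE once a
#'   particle has exited.
#' @export
run_simulation <- function(release, met, cfg = sim_config(),
                           record_every = 1) {
  start <- attr(release, "start") %||% min(release$takeoff_utc)
  start_num <- as.numeric(start)
  end_num <- start_num + cfg$horizon_h * 3600
  if (as.numeric(met$times[1]) > start_num + 1e-6 ||
      as.numeric(met$times[length(met$times)]) < end_num - 1e-6) {
    abort("met coverage is shorter than the simulation horizon")
  }
  nstep <- round(cfg$horizon_h * 3600 / cfg$dt)
  n <- nrow(release)
  state <- list(lat = release$lat, lon = release$lon, zstar = release$zstar,
                active = rep(TRUE, n), exited = rep(FALSE, n),
                takeoff = as.numeric(release$takeoff_utc))
  rec_steps <- unique(c(seq(0, nstep, by = record_every), nstep))
  nrec <- length(rec_steps)
  lat_m <- matrix(NA_real_, nrec, n); lon_m <- matrix(NA_real_, nrec, n)
  z_m <- matrix(NA_real_, nrec, n)
  air_m <- matrix(FALSE, nrec, n); act_m <- matrix(TRUE, nrec, n)
  rec <- function(k, t_num) {
    r <- match(k, rec_steps)
    if (is.na(r)) return(invisible())
    lat_m[r, ] <<- state$lat; lon_m[r, ] <<- state$lon
    z_m[r, ] <<- state$zstar
    air_m[r, ] <<- !state$exited & t_num >= state$takeoff
    act_m[r, ] <<- !state$exited
    invisible()
  }
  rec(0, start_num)
  for (k in seq_len(nstep)) {
    t_num <- start_num + (k - 1) * cfg$dt
    state <- advance_state(state, met, cfg, t_num, start_num)
    rec(k, t_num + cfg$dt)
  }
  times <- as.POSIXct(start_num + rec_steps * cfg$dt,
                      origin = "1970-01-01", tz = "UTC")
  traj <- tibble::tibble(
    time_utc = rep(times, n),
    id = rep(release$id, each = nrec),
    source = rep(release$source, each = nrec),
    abbrev = rep(release$abbrev %||% release$source, each = nrec),
    lat = as.vector(lat_m), lon = as.vector(lon_m),
    zstar = as.vector(z_m),
    airborne = as.vector(air_m), active = as.vector(act_m))
  attr(traj, "start") <- start
  attr(traj, "cfg") <- cfg
  class(traj) <- c("trajectory_set", class(traj))
  traj
}
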