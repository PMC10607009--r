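# shared fixtures built in code: tiny analytic scenarios and releases

run_start <- function() parse_utc("2021-04-30 10:00")

# small still-air or uniform-wind column over a 4x4 degree box
calm_met <- function(u = 0, v = 0, kz = 0, surface_c = 25, lapse = 5,
                     levels = seq(0, 3000, 500), duration_h = 3,
                     dlat = 1, dlon = 1) {
  uniform_flow(scenario_params(
    lat_range = c(28, 32), lon_range = c(118, 122), dlat = dlat, dlon = dlon,
    levels = levels, duration_h = duration_h, start = run_start(),
    wind = list(type = "uniform", u = u, v = v),
    temp = list(surface_c = surface_c, lapse_c_per_km = lapse),
    kz = list(type = "constant", k0 = kz)))
}

# single-particle release plan at a fixed point
one_particle <- function(lat = 30, lon = 120, zstar = 0,
                         takeoff = run_start()) {
  rel <- tibble::tibble(id = 1L, source = "toy", abbrev = "TY",
                        takeoff_utc = takeoff, lat = lat, lon = lon,
                        zstar = zstar)
  attr(rel, "start") <- run_start()
  attr(rel, "window_s") <- 0
  rel
}

# n-particle release at one point (optionally with given heights)
point_release <- function(n, lat = 30, lon = 120, zstar = 0,
                          takeoff = run_start()) {
  rel <- tibble::tibble(id = seq_len(n), source = "toy", abbrev = "TY",
                        takeoff_utc = takeoff, lat = lat, lon = lon,
                        zstar = zstar)
  attr(rel, "start") <- run_start()
  attr(rel, "window_s") <- 0
  rel
}

unit_square_source <- function(lat0 = 25, lon0 = 121, half = 0.5) {
  tibble::tibble(
    name = "ToySource", abbrev = "TS",
    polygon = list(cbind(lon = lon0 + half * c(-1, 1, 1, -1, -1),
                         lat = lat0 + half * c(-1, -1, 1, 1, -1))))
}

koshi_inputs <- function() {
  list(pred = read_predictions(mothwind_example("koshi_2021_predictions.csv")),
       catch = read_catches(mothwind_example("koshi_2021_catches.csv")),
       marks = read_csv_marks(mothwind_example("koshi_2021_marks.csv")))
}

isahaya_inputs <- function() {
  list(pred = read_predictions(mothwind_example("isahaya_2021_predictions.csv")),
       catch = read_catches(mothwind_example("isahaya_2021_catches.csv")),
       marks = read_csv_marks(mothwind_example("isahaya_2021_marks.csv")))
}

read_csv_marks <- function(path) {
  readr::read_csv(path, comment = "#", show_col_types = FALSE)
}

# wide per-day marks (eval_3 / eval_5 columns) from a migration_eval
eval_marks <- function(ev) {
  wide <- tidyr::pivot_wider(dplyr::select(ev$days, site, date, window, mark),
                             names_from = window, values_from = mark,
                             names_prefix = "eval_")
  dplyr::mutate(wide, dplyr::across(dplyr::starts_with("eval_"),
                                    ~ unname(unlist(.x))))
}

# brute-force arrival oracle: scan every particle-trap-snapshot triple
brute_force_arrivals <- function(traj, traps, radius_km, horizon_h) {
  start <- attr(traj, "start")
  tmax <- as.numeric(start) + horizon_h * 3600
  rows <- list()
  for (k in seq_len(nrow(traps))) {
    for (src in unique(traj$source)) {
      best <- Inf
      sub <- traj[traj$source == src & traj$airborne &
                    as.numeric(traj$time_utc) <= tmax + 1e-6, ]
      for (i in seq_len(nrow(sub))) {
        d <- haversine_km(sub$lat[i], sub$lon[i], traps$lat[k], traps$lon[k])
        if (d <= radius_km + 1e-9) {
          best <- min(best, as.numeric(sub$time_utc[i]))
        }
      }
      if (is.finite(best)) {
        rows[[length(rows) + 1]] <- tibble::tibble(
          trap = traps$name[k], source = src,
          first_pass_utc = as.POSIXct(best, origin = "1970-01-01",
                                      tz = "UTC"),
          flight_time_h = as.integer(floor((best - as.numeric(start)) /
                                             3600 + 0.5)))
      }
    }
  }
  dplyr::bind_rows(rows)
}
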