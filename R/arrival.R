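#' Load a trap-site catalog
#'
#' Reads a CSV with columns `name`, `lat`, `lon` (an optional `year`
#' column is kept if present, and `year` filtering applied when
#' requested).  Coordinates are validated against
#' \[-90, 90\] x \[-180, 180\].
#'
#' @param path CSV path.
#' @param year optional: keep only rows of this year.
#' @return a tibble of trap sites.
#' @export
load_traps <- function(path, year = NULL) {
  if (!file.exists(path)) abort(paste0("traps file not found: ", path))
  tr <- read_csv_quiet(path)
  need <- c("name", "lat", "lon")
  miss <- setdiff(need, names(tr))
  if (length(miss)) {
    abort(paste0("traps file missing column(s): ", paste(miss, collapse = ", ")))
  }
  if (!is.null(year) && "year" %in% names(tr)) {
    tr <- dplyr::filter(tr, .data$year == !!year)
  }
  if (any(abs(tr$lat) > 90) || any(abs(tr$lon) > 180)) {
    abort("trap coordinates outside [-90, 90] x [-180, 180]")
  }
  tr
}

#' Detect trap arrivals in a trajectory set
#'
#' For every trap and source area, finds the earliest recorded instant at
#' which any airborne particle of that source lies within `radius_km` of
#' the trap (a distance exactly equal to the radius counts).  Detection is
#' checked at every recorded snapshot — trajectories recorded at every
#' integration step (the default of [run_simulation()]) ensure a fast
#' mover cannot skip across the detection disc between checks.  Flight
#' time is the first-passage time since the run start, rounded half-up to
#' whole hours.
#'
#' @param traj a `trajectory_set` from [run_simulation()].
#' @param traps a trap tibble from [load_traps()] (columns `name, lat, lon`).
#' @param radius_km detection radius around the trap, km.
#' @param horizon_h only passages within this many hours of the run start
#'   count.
#' @return an arrival tibble: `trap, source, abbrev, first_pass_utc,
#'   flight_time_h, min_distance_km`.
#' @export
detect_arrivals <- function(traj, traps, radius_km = 18, horizon_h = 48) {
  start <- attr(traj, "start") %||% min(traj$time_utc)
  tmax <- as.numeric(start) + horizon_h * 3600
  empty <- tibble::tibble(trap = character(), source = character(),
                          abbrev = character(),
                          first_pass_utc = as.POSIXct(character(),
                                                      tz = "UTC"),
                          flight_time_h = integer(),
                          min_distance_km = numeric())
  fly <- dplyr::filter(traj, .data$airborne,
                       as.numeric(.data$time_utc) <= tmax + 1e-6)
  if (nrow(fly) == 0) {
    attr(empty, "start") <- start
    return(empty)
  }
  out <- purrr::map(seq_len(nrow(traps)), function(k) {
    d <- haversine_km(fly$lat, fly$lon, traps$lat[k], traps$lon[k])
    hit <- d <= radius_km + 1e-9
    per_src <- dplyr::group_by(
      tibble::tibble(source = fly$source, abbrev = fly$abbrev,
                     time = fly$time_utc, d = d, hit = hit),
      .data$source, .data$abbrev)
    per_src <- dplyr::summarise(
      per_src,
      first_pass_utc = if (any(.data$hit)) min(.data$time[.data$hit]) else
        as.POSIXct(NA, tz = "UTC"),
      min_distance_km = min(.data$d), .groups = "drop")
    per_src <- dplyr::filter(per_src, !is.na(.data$first_pass_utc))
    if (nrow(per_src) == 0) return(NULL)
    dplyr::mutate(per_src,
                  trap = traps$name[k],
                  flight_time_h = as.integer(floor(
                    as.numeric(.data$first_pass_utc - as.POSIXct(start),
                               units = "secs") / 3600 + 0.5)),
                  .before = 1)
  })
  res <- dplyr::bind_rows(out)
  res <- if (nrow(res)) {
    dplyr::select(res, "trap", "source", "abbrev", "first_pass_utc",
                  "flight_time_h", "min_distance_km")
  } else {
    empty
  }
  attr(res, "start") <- start
  res
}

#' Daily prediction table from arrivals
#'
#' One row per trap: `predicted` is "Yes" when at least one arrival was
#' detected, with the source and flight time of the earliest arrival, and
#' "No" otherwise.  The run label is the JST calendar date following the
#' take-off evening: a run starting 10:00 UTC (19:00 JST) on day d is the
#' prediction for date d + 1.
#'
#' @param arrivals an arrival tibble from [detect_arrivals()].
#' @param traps a trap tibble (every trap gets a row).
#' @param run_start_utc the run start (POSIXct UTC or ISO string).
#' @return a tibble: `trap, run_date_jst, predicted, source, abbrev, ft_h`.
#' @export
make_daily_predictions <- function(arrivals, traps, run_start_utc) {
  start <- parse_utc(run_start_utc)
  label <- jst_date(start) + 1
  firsts <- if (nrow(arrivals)) {
    dplyr::slice_min(dplyr::group_by(arrivals, .data$trap),
                     .data$first_pass_utc, n = 1, with_ties = FALSE)
  } else {
    arrivals
  }
  out <- tibble::tibble(trap = traps$name, run_date_jst = label)
  out <- dplyr::left_join(out, firsts, by = "trap")
  dplyr::transmute(out,
                   trap = .data$trap, run_date_jst = .data$run_date_jst,
                   predicted = ifelse(is.na(.data$flight_time_h), "No", "Yes"),
                   source = .data$source, abbrev = .data$abbrev,
                   ft_h = .data$flight_time_h)
}

#' Snapshot of a trajectory set at one instant
#' @param traj a `trajectory_set`.
#' @param time POSIXct UTC (must match a recorded snapshot).
#' @return the snapshot rows.
#' @export
traj_snapshot <- function(traj, time) {
  time <- parse_utc(time)
  snap <- dplyr::filter(traj, abs(as.numeric(.data$time_utc) -
                                    as.numeric(time)) < 1e-6)
  if (nrow(snap) == 0) abort("no snapshot recorded at the requested time")
  snap
}
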