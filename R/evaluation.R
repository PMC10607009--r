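#' Read daily prediction and trap-catch tables
#'
#' `read_predictions()` expects columns `site, date, predicted, source,
#' ft_h` (`predicted` as "Yes"/"No" or logical; `date` is the JST
#' prediction label date).  `read_catches()` expects `site,
#' collection_date, count, interval_days`: a collection row covers the
#' `interval_days` days ending on `collection_date` (daily collections
#' have `interval_days = 1`).  Covered intervals within a site must not
#' overlap.
#'
#' @param path CSV path (lines starting with `#` are ignored).
#' @return a tibble.
#' @export
read_predictions <- function(path) {
  if (!file.exists(path)) abort(paste0("predictions file not found: ", path))
  pr <- read_csv_quiet(path)
  miss <- setdiff(c("site", "date", "predicted", "ft_h"), names(pr))
  if (length(miss)) {
    abort(paste0("predictions file missing column(s): ",
                 paste(miss, collapse = ", ")))
  }
  pr$date <- as.Date(pr$date)
  pr$predicted <- toupper(as.character(pr$predicted)) %in% c("YES", "Y", "TRUE")
  if (any(pr$predicted & is.na(pr$ft_h))) {
    abort("positive predictions must carry a flight time ft_h")
  }
  pr
}

#' @rdname read_predictions
#' @export
read_catches <- function(path) {
  if (!file.exists(path)) abort(paste0("catches file not found: ", path))
  ca <- read_csv_quiet(path)
  miss <- setdiff(c("site", "collection_date", "count"), names(ca))
  if (length(miss)) {
    abort(paste0("catches file missing column(s): ",
                 paste(miss, collapse = ", ")))
  }
  if (nrow(ca) == 0) abort("catches file is empty")
  ca$collection_date <- as.Date(ca$collection_date)
  if (!"interval_days" %in% names(ca)) ca$interval_days <- 1L
  ca$interval_days[is.na(ca$interval_days)] <- 1L
  if (any(ca$count < 0) || any(ca$interval_days < 1)) {
    abort("counts must be >= 0 and interval_days >= 1")
  }
  for (s in unique(ca$site)) {
    cs <- ca[ca$site == s, ]
    days <- unlist(purrr::map2(cs$collection_date, cs$interval_days,
                               ~ as.integer(.x) - seq_len(.y) + 1L))
    if (anyDuplicated(days)) {
      abort(paste0("catch intervals overlap within site '", s, "'"))
    }
  }
  ca
}

#' Predicted arrival instant of a positive prediction row
#'
#' A prediction row labelled with JST date d describes the run that took
#' off at `takeoff_hour_utc` (default 10:00 UTC) on the previous evening,
#' i.e. on d - 1; the arrival instant is that take-off plus the flight
#' time.
#'
#' @param row_date prediction label date (JST, a [Date]).
#' @param ft_h flight time in whole hours.
#' @param takeoff_hour_utc take-off hour (UTC) of the daily run.
#' @return POSIXct (UTC) arrival instant.
#' @export
arrival_instant <- function(row_date, ft_h, takeoff_hour_utc = 10) {
  takeoff <- as.POSIXct(paste0(as.Date(row_date) - 1, " 00:00:00"),
                        tz = "UTC") + takeoff_hour_utc * 3600
  takeoff + ft_h * 3600
}

#' First day of the positive-evaluation window
#'
#' Moths arriving before midday (JST) can be trapped during the same
#' night, so the catch window starts on the arrival's JST date; arrivals
#' from midday onward are first exposed to trapping the following night
#' and the window starts the next day.  The cutoff hour is exposed as a
#' parameter.
#'
#' @param arrival POSIXct (UTC) arrival instant.
#' @param cutoff_hour JST hour-of-day before which the window starts on
#'   the arrival date itself.
#' @return the window start as a JST [Date].
#' @export
#' @examples
#' arrival_window_start(arrival_instant(as.Date("2021-05-01"), 12))
arrival_window_start <- function(arrival, cutoff_hour = 12) {
  d <- jst_date(arrival)
  ifelse_date(jst_hour(arrival) < cutoff_hour, d, d + 1)
}

ifelse_date <- function(test, yes, no) {
  out <- yes
  out[!test] <- no[!test]
  out
}

# days covered by each collection row, as an integer-date set
catch_cover <- function(catches) {
  list(
    pos_dates = catches$collection_date[catches$count > 0],
    covered = unlist(purrr::map2(catches$collection_date,
                                 catches$interval_days,
                                 ~ as.integer(.x) - seq_len(.y) + 1L)),
    pos_covered = unlist(purrr::map2(
      catches$collection_date[catches$count > 0],
      catches$interval_days[catches$count > 0],
      ~ as.integer(.x) - seq_len(.y) + 1L)))
}

#' Classify one positive-prediction day
#'
#' The prediction is a hit when a nonzero catch was recorded on at least
#' one of the `L` consecutive days starting at the evaluation window
#' start: a nonzero interval collection counts on its collection date
#' (the day the catch was recorded); a zero collection certifies its
#' whole interval catch-free.  Windows truncated by the end of available
#' data are evaluated on the available days; a window with no catch
#' coverage at all is unevaluable.
#'
#' @param window_start first window day (JST [Date]), from
#'   [arrival_window_start()].
#' @param catches catch rows for the trap (see [read_catches()]).
#' @param L window length in days (3 or 5 in the published protocol).
#' @return `"hit"`, `"fail"` or `"unevaluable"`.
#' @export
classify_positive_day <- function(window_start, catches, L) {
  win <- as.integer(as.Date(window_start)) + 0:(L - 1)
  cov <- catch_cover(catches)
  if (any(as.integer(cov$pos_dates) %in% win)) return("hit")
  if (any(cov$covered %in% win)) return("fail")
  "unevaluable"
}

#' Classify one negative-prediction day
#'
#' A date within `L - 1` days after any positive-prediction row date is
#' excluded (catches there may stem from the predicted immigration, so
#' counting them against a negative prediction would bias the score).
#' Otherwise the negative prediction is a hit when the date is certified
#' catch-free and a fail when any collection covering it recorded a
#' nonzero count; dates with no catch coverage are unevaluated.
#'
#' @param date the day under evaluation (JST [Date]).
#' @param positive_row_dates label dates of the trap's positive
#'   prediction rows.
#' @param catches catch rows for the trap.
#' @param L window length in days.
#' @return `"hit"`, `"fail"`, `"excluded"` or `"unevaluated"`.
#' @export
classify_negative_day <- function(date, positive_row_dates, catches, L) {
  d <- as.integer(as.Date(date))
  p <- as.integer(as.Date(positive_row_dates))
  if (any(d - p >= 0 & d - p <= L - 1)) return("excluded")
  cov <- catch_cover(catches)
  if (any(cov$pos_covered %in% d)) return("fail")
  if (any(cov$covered %in% d)) return("hit")
  "unevaluated"
}

#' Evaluate daily migration predictions against trap catches
#'
#' Runs the full hitting-ratio protocol for each site and window length:
#' positive prediction days are classified through their arrival-based
#' catch windows ([classify_positive_day()]), negative days through the
#' exclusion-guarded catch-free rule ([classify_negative_day()]), and the
#' per-site hitting ratio is hits / (hits + fails) over all evaluated
#' days.
#'
#' @param predictions prediction tibble (see [read_predictions()]).
#' @param catches catch tibble (see [read_catches()]); may include
#'   collections outside `period` whose intervals reach into it.
#' @param windows integer window lengths, default `c(3, 5)`.
#' @param period optional length-2 Date range of evaluation days;
#'   defaults to the span of prediction dates.
#' @param cutoff_hour JST arrival cutoff passed to
#'   [arrival_window_start()].
#' @param takeoff_hour_utc daily run take-off hour (UTC).
#' @return a `migration_eval` object: list with `days` (per site x day x
#'   window classification tibble with columns `site, date, window, case,
#'   category, mark, window_start`), `ratios` (per site x window:
#'   `site, window, hits, fails, evaluated, ratio`) and the protocol
#'   parameters.
#' @export
evaluate_predictions <- function(predictions, catches, windows = c(3, 5),
                                 period = NULL, cutoff_hour = 12,
                                 takeoff_hour_utc = 10) {
  sites <- unique(predictions$site)
  missing_catch <- setdiff(sites, unique(catches$site))
  if (length(missing_catch)) {
    abort(paste0("no catch series for site(s): ",
                 paste(missing_catch, collapse = ", ")))
  }
  if (is.null(period)) period <- range(predictions$date)
  days_all <- seq(as.Date(period[1]), as.Date(period[2]), by = "day")

  rows <- list()
  for (s in sites) {
    pr <- dplyr::filter(predictions, .data$site == s,
                        .data$date %in% days_all)
    ca <- dplyr::filter(catches, .data$site == s)
    pos <- dplyr::filter(pr, .data$predicted)
    ws <- arrival_window_start(
      arrival_instant(pos$date, pos$ft_h, takeoff_hour_utc), cutoff_hour)
    for (L in windows) {
      cat_pos <- purrr::map_chr(seq_len(nrow(pos)), function(i) {
        classify_positive_day(ws[i], ca, L)
      })
      neg_days <- setdiff(days_all, pos$date)
      cat_neg <- purrr::map_chr(neg_days, function(d) {
        classify_negative_day(as.Date(d, origin = "1970-01-01"),
                              pos$date, ca, L)
      })
      rows[[length(rows) + 1]] <- dplyr::bind_rows(
        tibble::tibble(site = s, date = pos$date, window = L,
                       case = "positive", category = cat_pos,
                       window_start = as.Date(ws, origin = "1970-01-01")),
        tibble::tibble(site = s,
                       date = as.Date(neg_days, origin = "1970-01-01"),
                       window = L, case = "negative", category = cat_neg,
                       window_start = as.Date(NA)))
    }
  }
  days <- dplyr::arrange(dplyr::bind_rows(rows), .data$site, .data$window,
                         .data$date)
  days$mark <- c(hit = "H", fail = "F", excluded = "-",
                 unevaluable = NA, unevaluated = NA)[days$category]
  ratios <- dplyr::summarise(
    dplyr::group_by(days, .data$site, .data$window),
    hits = sum(.data$category == "hit"),
    fails = sum(.data$category == "fail"),
    evaluated = .data$hits + .data$fails,
    ratio = site_hitting_ratio(.data$category), .groups = "drop")
  structure(list(days = days, ratios = ratios, windows = windows,
                 period = range(days_all), cutoff_hour = cutoff_hour,
                 takeoff_hour_utc = takeoff_hour_utc),
            class = "migration_eval")
}

#' Hitting ratio of a set of day classifications
#'
#' hits / (hits + fails), rounded half-up to two decimals, the score the
#' protocol reports per site and window length.
#'
#' @param categories character vector of day categories (`"hit"`,
#'   `"fail"`, others ignored).
#' @return the ratio (2 decimals).
#' @export
site_hitting_ratio <- function(categories) {
  h <- sum(categories == "hit"); f <- sum(categories == "fail")
  if (h + f == 0) abort("no evaluated days: hitting ratio undefined")
  round_half_up(h / (h + f), 2)
}

#' Aggregate per-site hitting ratios
#'
#' Arithmetic means of already-rounded per-site ratios, per year and over
#' all site-years, rounded half-up to two decimals (the convention of the
#' published summary table, whose averages are means of the printed
#' rounded per-site values).
#'
#' @param ratios a tibble with columns `year`, `site` and one or more
#'   numeric ratio columns.
#' @param ratio_cols names of the ratio columns; defaults to every
#'   numeric column except `year`.
#' @return a tibble with one row per year plus a `"total"` row, carrying
#'   the mean of each ratio column and `n_sites`.
#' @export
aggregate_ratios <- function(ratios, ratio_cols = NULL) {
  if (nrow(ratios) == 0) abort("empty ratio table")
  if (is.null(ratio_cols)) {
    ratio_cols <- setdiff(names(ratios)[purrr::map_lgl(ratios, is.numeric)],
                          "year")
  }
  yearly <- dplyr::summarise(
    dplyr::group_by(ratios, year = as.character(.data$year)),
    dplyr::across(dplyr::all_of(ratio_cols), ~ round_half_up(mean(.x), 2)),
    n_sites = dplyr::n(), .groups = "drop")
  total <- dplyr::summarise(
    ratios, year = "total",
    dplyr::across(dplyr::all_of(ratio_cols), ~ round_half_up(mean(.x), 2)),
    n_sites = dplyr::n())
  dplyr::bind_rows(yearly, total)
}
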