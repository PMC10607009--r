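#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @export
print.migration_eval <- function(x, ...) {
  cat("<migration_eval>\n")
  cat(sprintf("  period : %s .. %s\n", x$period[1], x$period[2]))
  cat(sprintf("  windows: %s days\n", paste(x$windows, collapse = ", ")))
  cat("  hitting ratios:\n")
  r <- x$ratios
  for (i in seq_len(nrow(r))) {
    cat(sprintf("    %-16s %d-day  %d/%d = %.2f\n", r$site[i], r$window[i],
                r$hits[i], r$evaluated[i], r$ratio[i]))
  }
  invisible(x)
}

#' Tidy a migration evaluation
#'
#' Returns the per-day classification table (one row per site, day and
#' window length) with the printed-style mark: `H` hit, `F` fail, `-`
#' excluded, `NA` not evaluable from the available catch data.
#'
#' @param x a `migration_eval` from [evaluate_predictions()].
#' @param ... unused.
#' @return a tibble.
#' @method tidy migration_eval
#' @export
tidy.migration_eval <- function(x, ...) x$days

#' Summarise a migration evaluation
#'
#' One row per window length: total hits, fails, evaluated days and the
#' mean of the per-site hitting ratios.
#'
#' @inheritParams tidy.migration_eval
#' @return a one-row-per-window tibble.
#' @method glance migration_eval
#' @export
glance.migration_eval <- function(x, ...) {
  dplyr::summarise(dplyr::group_by(x$ratios, .data$window),
                   n_sites = dplyr::n(),
                   hits = sum(.data$hits), fails = sum(.data$fails),
                   evaluated = sum(.data$evaluated),
                   mean_ratio = round_half_up(mean(.data$ratio), 2),
                   .groups = "drop")
}

#' Plot a migration evaluation
#'
#' Calendar tile plot of the per-day classifications (hit / fail /
#' excluded), faceted by window length, one row per site.
#'
#' @param object a `migration_eval`.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot migration_eval
#' @export
autoplot.migration_eval <- function(object, ...) {
  d <- dplyr::mutate(object$days,
                     category = factor(.data$category,
                                       c("hit", "fail", "excluded",
                                         "unevaluated", "unevaluable")))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$date, y = .data$site,
                                  fill = .data$category)) +
    ggplot2::geom_tile(colour = "white") +
    ggplot2::facet_wrap(~ window, ncol = 1,
                        labeller = ggplot2::label_both) +
    ggplot2::scale_fill_manual(
      values = c(hit = "#2b8cbe", fail = "#e34a33", excluded = "grey70",
                 unevaluated = "grey90", unevaluable = "grey90"),
      drop = FALSE) +
    ggplot2::labs(x = NULL, y = NULL, fill = "Day class")
}
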