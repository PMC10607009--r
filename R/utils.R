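#' Round half away from zero
#'
#' Commercial ("half-up") rounding to a fixed number of decimals.  Used for
#' hitting ratios so that e.g. a mean of 0.765 prints as 0.77, matching how
#' the published ratio tables were rounded (base [round()] is half-even and
#' would give 0.76).
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return numeric vector rounded half away from zero.
#' @export
#' @examples
#' round_half_up(0.765, 2)  # 0.77
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

#' Great-circle distance in kilometres
#'
#' Haversine distance on a sphere of radius 6371.0 km, vectorised over all
#' arguments (recycled as usual).
#'
#' @param lat1,lon1,lat2,lon2 coordinates in decimal degrees.
#' @return distance in km.
#' @export
#' @examples
#' haversine_km(0, 0, 0, 1)           # ~111.19
#' haversine_km(32.88, 130.74, 32.83, 130.02)  # Koshi to Isahaya, ~67.5
haversine_km <- function(lat1, lon1, lat2, lon2) {
  n <- max(length(lat1), length(lon1), length(lat2), length(lon2))
  p1 <- cbind(rep_len(lon1, n), rep_len(lat1, n))
  p2 <- cbind(rep_len(lon2, n), rep_len(lat2, n))
  as.numeric(geosphere::distHaversine(p1, p2, r = 6371000)) / 1000
}

# metres of ground distance per degree, used for the per-step conversion of
# metric displacements to lat/lon increments on the local tangent plane
M_PER_DEG_LON_EQ <- 111320
M_PER_DEG_LAT <- 110540

#' Parse a UTC instant
#'
#' Accepts POSIXct (returned as-is, converted to UTC), ISO-8601 strings with
#' an optional trailing "Z", or "YYYY-MM-DD HH:MM(:SS)".
#'
#' @param x POSIXct or character scalar/vector.
#' @return POSIXct in UTC.
#' @export
parse_utc <- function(x) {
  if (inherits(x, "POSIXct")) {
    attr(x, "tzone") <- "UTC"
    return(x)
  }
  s <- gsub("Z$", "", gsub("T", " ", as.character(x)))
  out <- as.POSIXct(s, tz = "UTC",
                    tryFormats = c("%Y-%m-%d %H:%M:%S", "%Y-%m-%d %H:%M",
                                   "%Y-%m-%d"))
  if (anyNA(out)) abort(paste0("cannot parse UTC time: ", x[is.na(out)][1]))
  out
}

# JST = UTC + 9 h (no daylight saving)
JST_OFFSET_S <- 9 * 3600

#' Convert a UTC instant to its Japan Standard Time calendar date
#' @param t POSIXct (UTC).
#' @return a [Date].
#' @export
jst_date <- function(t) {
  as.Date(as.POSIXct(as.numeric(t) + JST_OFFSET_S,
                     origin = "1970-01-01", tz = "UTC"))
}

#' Hour-of-day (fractional) of a UTC instant in Japan Standard Time
#' @param t POSIXct (UTC).
#' @return numeric hours in [0, 24).
#' @export
jst_hour <- function(t) {
  s <- (as.numeric(t) + JST_OFFSET_S) %% 86400
  s / 3600
}

# writes the standard provenance header used by all file outputs
output_header <- function(seed = NULL, config = NULL) {
  c(paste0("# mothwind ", as.character(packageVersion("mothwind"))),
    paste0("# created_utc: ", format(Sys.time(), tz = "UTC", usetz = TRUE)),
    if (!is.null(seed)) paste0("# seed: ", seed),
    if (!is.null(config)) paste0("# config_hash: ", rlang::hash(config)))
}

write_csv_with_header <- function(df, path, seed = NULL, config = NULL) {
  writeLines(output_header(seed = seed, config = config), path)
  readr::write_csv(df, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

read_csv_quiet <- function(path, ...) {
  readr::read_csv(path, comment = "#", show_col_types = FALSE,
                  progress = FALSE, ...)
}
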