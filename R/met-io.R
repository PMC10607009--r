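#' Read and write met files
#'
#' Met files are a self-describing JSON container carrying the package's
#' gridded-meteorology convention: dimensions (time, level, lat, lon);
#' variables `u`, `v`, `w`, `temp`, `kz` stored flattened in column-major
#' order over that dimension order; coordinate vectors `lats`, `lons`,
#' `levels`; a `terrain` (lat x lon) matrix; the global attribute `z_top`;
#' times as ISO-8601 UTC strings; and a per-variable `units` map.  Numbers
#' are serialized at 17 significant digits, so coordinates and variables
#' round-trip exactly at double precision.  Temperatures with unit "K" are
#' converted to degrees C on load (the flight model's temperature ceiling
#' is expressed in degrees C).
#'
#' @param path file path.
#' @param met a [met_series()] object (for `save_met`).
#' @return `load_met` returns a validated [met_series()]; `save_met`
#'   (invisibly) the path written.
#' @export
load_met <- function(path) {
  if (!file.exists(path)) abort(paste0("met file not found: ", path))
  raw <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  need <- c("dims", "lats", "lons", "levels", "z_top", "terrain", "times")
  miss <- setdiff(need, names(raw))
  if (length(miss)) {
    abort(paste0("met file format error: missing ", paste(miss, collapse = ", ")))
  }
  if (is.null(raw$vars)) abort("met file format error: missing vars")
  for (nm in c("u", "v", "w", "temp", "kz")) {
    if (is.null(raw$vars[[nm]])) {
      abort(paste0("met file format error: missing variable '", nm, "'"))
    }
  }
  dims <- unlist(raw$dims)
  for (d in c("time", "level", "lat", "lon")) {
    if (is.na(dims[d])) {
      abort(paste0("met file format error: missing dimension '", d, "'"))
    }
  }
  want <- unname(dims[c("time", "level", "lat", "lon")])
  arr <- lapply(raw$vars, function(v) array(as.numeric(v), dim = want))
  temp <- arr$temp
  t_unit <- raw$units$temp %||% "degC"
  if (identical(t_unit, "K")) temp <- temp - 273.15
  met_series(lats = raw$lats, lons = raw$lons, levels = raw$levels,
             z_top = raw$z_top,
             terrain = matrix(as.numeric(unlist(raw$terrain)),
                              nrow = dims["lat"], ncol = dims["lon"]),
             times = parse_utc(raw$times),
             u = arr$u, v = arr$v, w = arr$w, temp = temp, kz = arr$kz)
}

#' @rdname load_met
#' @export
save_met <- function(met, path) {
  if (!inherits(met, "met_series")) abort("met must be a met_series")
  obj <- list(
    format = "mothwind-met-1",
    dims = list(time = length(met$times), level = length(met$levels),
                lat = length(met$lats), lon = length(met$lons)),
    lats = met$lats, lons = met$lons, levels = met$levels,
    z_top = met$z_top,
    terrain = as.vector(met$terrain),  # column-major over (lat, lon)
    times = format(met$times, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
    units = list(u = "m/s", v = "m/s", w = "m/s", temp = "degC",
                 kz = "m2/s", terrain = "m", z_top = "m"),
    vars = list(u = as.vector(met$u), v = as.vector(met$v),
                w = as.vector(met$w), temp = as.vector(met$temp),
                kz = as.vector(met$kz)))
  ok <- tryCatch({
    jsonlite::write_json(obj, path, digits = I(17), auto_unbox = TRUE)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) abort(paste0("cannot write met file '", path, "': ",
                                conditionMessage(ok)))
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
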