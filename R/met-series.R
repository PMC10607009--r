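#' Terrain-following vertical coordinate
#'
#' The simulator integrates vertical motion in the terrain-following z*
#' coordinate, defined by z* = (z - z_g) * z_t / (z_t - z_g), where z is
#' geometric height, z_g the local ground height and z_t the model-top
#' height.  z* equals 0 at the ground and z_t at the model top everywhere,
#' so a single set of z* levels spans the whole domain regardless of
#' terrain.  `z_of()` is the inverse transform.
#'
#' @param z geometric height in m (for `zstar_of`).
#' @param zstar z* height in m (for `z_of`).
#' @param z_g ground height in m.
#' @param z_t model-top height in m (> `z_g`).
#' @return height in m in the other coordinate.
#' @export
#' @examples
#' zstar_of(1475, z_g = 500, z_t = 20000)  # 1000
#' z_of(1000, z_g = 500, z_t = 20000)      # 1475
zstar_of <- function(z, z_g, z_t) {
  check_zcoord_args(z_g, z_t)
  if (any(z < z_g - 1e-9) || any(z > z_t + 1e-9)) {
    abort("z outside [z_g, z_t]")
  }
  (z - z_g) * z_t / (z_t - z_g)
}

#' @rdname zstar_of
#' @export
z_of <- function(zstar, z_g, z_t) {
  check_zcoord_args(z_g, z_t)
  if (any(zstar < -1e-9) || any(zstar > z_t + 1e-9)) {
    abort("z* outside [0, z_t]")
  }
  zstar * (z_t - z_g) / z_t + z_g
}

check_zcoord_args <- function(z_g, z_t) {
  if (any(!is.finite(z_g)) || any(!is.finite(z_t)) || any(z_g >= z_t)) {
    abort("require finite z_g < z_t")
  }
}

#' Gridded hourly meteorology in the z* coordinate
#'
#' Container for the five hourly fields the migration model consumes:
#' horizontal wind `u`, `v` (m/s), vertical velocity `w` in the z*
#' coordinate (m/s), air temperature `temp` (degrees C) and the vertical
#' diffusion coefficient `kz` (m^2/s).  All arrays share the dimension
#' order (time, level, lat, lon).  Times must be hourly; other cadences
#' are rejected rather than resampled.  A centred-difference vertical
#' gradient of `kz` (one-sided at the first and last level) is precomputed
#' at construction for the diffusivity-drift term of the vertical update.
#'
#' @param lats strictly increasing latitudes (degrees north).
#' @param lons strictly increasing longitudes (degrees east).
#' @param levels strictly increasing z* heights in m, all in `[0, z_top]`.
#' @param z_top model-top height z_t in m.
#' @param terrain ground-height matrix (lat x lon) in m, `0 <= terrain < z_top`.
#'   A scalar is recycled.
#' @param times POSIXct UTC instants at a fixed 1 h spacing (>= 2).
#' @param u,v,w,temp,kz arrays of dimension
#'   `c(length(times), length(levels), length(lats), length(lons))`.
#' @return an object of class `met_series`.
#' @export
met_series <- function(lats, lons, levels, z_top, terrain, times,
                       u, v, w, temp, kz) {
  times <- parse_utc(times)
  if (length(times) < 2) abort("times must contain at least 2 instants")
  dt <- diff(as.numeric(times))
  if (any(abs(dt - 3600) > 1e-6)) {
    abort("times must be uniform at a 1 h spacing (hourly input cadence)")
  }
  for (nm in c("lats", "lons", "levels")) {
    v_ <- get(nm)
    if (length(v_) < 2 || any(diff(v_) <= 0)) {
      abort(paste0(nm, " must be strictly increasing with length >= 2"))
    }
  }
  if (levels[1] < 0 || levels[length(levels)] > z_top + 1e-9) {
    abort("levels must lie within [0, z_top]")
  }
  if (length(terrain) == 1) {
    terrain <- matrix(terrain, length(lats), length(lons))
  }
  terrain <- as.matrix(terrain)
  if (!all(dim(terrain) == c(length(lats), length(lons)))) {
    abort("terrain must be a (lat x lon) matrix")
  }
  if (any(!is.finite(terrain)) || any(terrain < 0) || any(terrain >= z_top)) {
    abort("terrain must be finite, >= 0 and < z_top everywhere")
  }
  want <- c(length(times), length(levels), length(lats), length(lons))
  for (nm in c("u", "v", "w", "temp", "kz")) {
    a <- get(nm)
    if (is.null(dim(a)) || !all(dim(a) == want)) {
      abort(paste0("variable '", nm,
                   "' must have dim (time, level, lat, lon) = (",
                   paste(want, collapse = ", "), ")"))
    }
    if (anyNA(a)) abort(paste0("variable '", nm, "' contains NA"))
  }
  if (any(kz < 0)) abort("kz must be >= 0 everywhere")

  obj <- structure(
    list(lats = as.numeric(lats), lons = as.numeric(lons),
         levels = as.numeric(levels), z_top = as.numeric(z_top),
         terrain = terrain, times = times,
         u = u, v = v, w = w, temp = temp, kz = kz),
    class = "met_series")
  obj$kz_grad <- kz_gradient_field(obj)
  obj
}

# centred difference of kz along the level axis; one-sided at the ends.
# Exact for profiles linear in z*, which is what the drift-term check needs.
kz_gradient_field <- function(met) {
  lev <- met$levels
  nl <- length(lev)
  g <- met$kz
  if (nl == 2) {
    d <- (met$kz[, 2, , , drop = FALSE] - met$kz[, 1, , , drop = FALSE]) /
      (lev[2] - lev[1])
    g[, 1, , ] <- d
    g[, 2, , ] <- d
    return(g)
  }
  g[, 1, , ] <- (met$kz[, 2, , ] - met$kz[, 1, , ]) / (lev[2] - lev[1])
  g[, nl, , ] <- (met$kz[, nl, , ] - met$kz[, nl - 1, , ]) /
    (lev[nl] - lev[nl - 1])
  for (l in 2:(nl - 1)) {
    g[, l, , ] <- (met$kz[, l + 1, , ] - met$kz[, l - 1, , ]) /
      (lev[l + 1] - lev[l - 1])
  }
  g
}

#' @export
print.met_series <- function(x, ...) {
  cat("<met_series>\n")
  cat(sprintf("  times : %s .. %s (%d hourly instants)\n",
              format(x$times[1], "%Y-%m-%d %H:%M", tz = "UTC"),
              format(x$times[length(x$times)], "%Y-%m-%d %H:%M", tz = "UTC"),
              length(x$times)))
  cat(sprintf("  grid  : %d lat x %d lon (%g..%g N, %g..%g E)\n",
              length(x$lats), length(x$lons),
              min(x$lats), max(x$lats), min(x$lons), max(x$lons)))
  cat(sprintf("  levels: %d z* levels, %g..%g m (z_top %g m)\n",
              length(x$levels), min(x$levels), max(x$levels), x$z_top))
  invisible(x)
}
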