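#' Interpolate gridded met fields at arbitrary points
#'
#' Linear in time and trilinear in (lat, lon, z* level): the interpolated
#' value is a convex combination of the 16 surrounding grid nodes, exact at
#' grid nodes and bounded by the min/max of the surrounding node values.
#' Vectorised over query points at a common instant `t` (the integrator's
#' access pattern).
#'
#' Horizontal positions outside the grid bounding box, or instants outside
#' the time span, are flagged in `oob` and return NA; the dispersion module
#' uses that flag to deactivate particles.  Vertical queries outside the
#' level range are flagged too unless `clamp_z = TRUE`, which clamps them
#' into the level range (fields treated as constant beyond the first/last
#' level) — the integrator uses this because its vertical boundaries
#' already confine particles to `[0, top level]`.
#'
#' @param met a [met_series()].
#' @param t a single POSIXct (UTC) instant.
#' @param lat,lon,zstar equal-length numeric vectors of query points.
#' @param vars variables to interpolate, any of
#'   `c("u","v","w","temp","kz","kz_grad")`.
#' @param clamp_z clamp vertical queries into the level range?
#' @return a list with one numeric vector per requested variable plus a
#'   logical `oob`.  Out-of-domain points carry NA in every variable.
#' @export
met_interp <- function(met, t, lat, lon, zstar,
                       vars = c("u", "v", "w", "temp", "kz"),
                       clamp_z = FALSE) {
  stopifnot(inherits(met, "met_series"))
  n <- length(lat)
  stopifnot(length(lon) == n, length(zstar) == n)
  ts <- as.numeric(parse_utc(t))
  tt <- as.numeric(met$times)
  nt <- length(tt); nl <- length(met$levels)
  nla <- length(met$lats); nlo <- length(met$lons)

  oob_t <- ts < tt[1] - 1e-6 || ts > tt[nt] + 1e-6
  oob <- rep(oob_t, n)
  oob <- oob |
    lat < met$lats[1] | lat > met$lats[nla] |
    lon < met$lons[1] | lon > met$lons[nlo]
  z <- zstar
  if (clamp_z) {
    z <- pmin(pmax(z, met$levels[1]), met$levels[nl])
  } else {
    oob <- oob | z < met$levels[1] - 1e-9 | z > met$levels[nl] + 1e-9
  }

  # bracketing indices and normalised weights along each axis
  it <- min(max(findInterval(ts, tt), 1L), nt - 1L)
  wt <- (ts - tt[it]) / (tt[it + 1] - tt[it])
  bracket <- function(x, coords, ncoord) {
    i <- findInterval(x, coords)
    i[i < 1L] <- 1L; i[i >= ncoord] <- ncoord - 1L
    w <- (x - coords[i]) / (coords[i + 1] - coords[i])
    list(i = i, w = pmin(pmax(w, 0), 1))
  }
  bl <- bracket(z, met$levels, nl)
  ba <- bracket(lat, met$lats, nla)
  bo <- bracket(lon, met$lons, nlo)

  out <- lapply(vars, function(v) numeric(n))
  names(out) <- vars
  arrs <- lapply(vars, function(v) met[[v]])
  # accumulate over the 16 corners (2 per axis); time contributes 2 more
  for (dl in 0:1) for (da in 0:1) for (do_ in 0:1) {
    wspace <- (if (dl) bl$w else 1 - bl$w) *
      (if (da) ba$w else 1 - ba$w) *
      (if (do_) bo$w else 1 - bo$w)
    base <- (bl$i + dl - 1L) * nt +
      (ba$i + da - 1L) * (nt * nl) +
      (bo$i + do_ - 1L) * (nt * nl * nla)
    i0 <- it + base
    i1 <- it + 1L + base
    for (k in seq_along(vars)) {
      a <- arrs[[k]]
      out[[k]] <- out[[k]] + wspace * ((1 - wt) * a[i0] + wt * a[i1])
    }
  }
  if (any(oob)) for (k in seq_along(vars)) out[[k]][oob] <- NA_real_
  out$oob <- oob
  out
}

#' Vertical diffusivity gradient at query points
#'
#' Interpolates the precomputed centred-difference gradient of the
#' vertical diffusion coefficient (see [met_series()]) to arbitrary
#' points, for the drift term of the vertical update.
#'
#' @inheritParams met_interp
#' @return numeric vector of d(Kz*)/d(z*) values (m/s), NA out of domain.
#' @export
kz_gradient <- function(met, t, lat, lon, zstar, clamp_z = FALSE) {
  met_interp(met, t, lat, lon, zstar, vars = "kz_grad",
             clamp_z = clamp_z)$kz_grad
}
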