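#' Load emigration source areas from GeoJSON
#'
#' Reads a GeoJSON FeatureCollection of polygons, one feature per source
#' area (e.g. a province), each with a `name` property and optionally an
#' `abbrev` property used in prediction tables.  Each polygon's outer ring
#' must be closed, non-self-intersecting and of nonzero area; violations
#' raise an error naming the offending feature.
#'
#' @param path path to a GeoJSON file.
#' @return a tibble with columns `name`, `abbrev` and `polygon` (list
#'   column of two-column lon/lat matrices, closed rings).
#' @export
load_sources <- function(path) {
  if (!file.exists(path)) abort(paste0("sources file not found: ", path))
  gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!identical(gj$type, "FeatureCollection")) {
    abort("sources file must be a GeoJSON FeatureCollection")
  }
  rows <- lapply(gj$features, function(f) {
    nm <- f$properties$name
    if (is.null(nm) || !nzchar(nm)) {
      abort("GeoJSON feature without a 'name' property")
    }
    if (!identical(f$geometry$type, "Polygon")) {
      abort(paste0("feature '", nm, "': geometry must be a Polygon"))
    }
    ring <- f$geometry$coordinates[[1]]
    m <- do.call(rbind, purrr::map(ring, ~ as.numeric(.x[1:2])))
    colnames(m) <- c("lon", "lat")
    validate_ring(m, nm)
    tibble::tibble(name = nm, abbrev = f$properties$abbrev %||% nm,
                   polygon = list(m))
  })
  dplyr::bind_rows(rows)
}

validate_ring <- function(m, name) {
  if (nrow(m) < 4) abort(paste0("feature '", name, "': ring has < 4 points"))
  if (any(m[1, ] != m[nrow(m), ])) {
    abort(paste0("feature '", name, "': ring is not closed"))
  }
  if (ring_self_intersects(m)) {
    abort(paste0("feature '", name, "': polygon ring is self-intersecting"))
  }
  if (abs(shoelace_area(m)) < 1e-12) {
    abort(paste0("feature '", name, "': polygon has zero area"))
  }
  invisible(m)
}

# signed area in degree^2 (only used to reject degenerate rings)
shoelace_area <- function(m) {
  x <- m[, 1]; y <- m[, 2]; n <- nrow(m)
  sum(x[-n] * y[-1] - x[-1] * y[-n]) / 2
}

# O(n^2) proper-crossing test between non-adjacent edges; fine for the
# coarse rings this package ships (tens of vertices)
ring_self_intersects <- function(m) {
  n <- nrow(m) - 1  # edges
  seg <- function(i) rbind(m[i, ], m[i + 1, ])
  cross <- function(o, a, b) {
    (a[1] - o[1]) * (b[2] - o[2]) - (a[2] - o[2]) * (b[1] - o[1])
  }
  for (i in seq_len(n - 2)) {
    jmax <- if (i == 1) n - 1 else n
    for (j in (i + 2):jmax) {
      a <- m[i, ]; b <- m[i + 1, ]; c_ <- m[j, ]; d <- m[j + 1, ]
      d1 <- cross(c_, d, a); d2 <- cross(c_, d, b)
      d3 <- cross(a, b, c_); d4 <- cross(a, b, d)
      if (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
          ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))) {
        return(TRUE)
      }
    }
  }
  FALSE
}

#' Test points against a polygon ring
#'
#' @param polygon a closed two-column lon/lat matrix.
#' @param lat,lon coordinates of the points.
#' @return logical vector, TRUE where the point is inside.
#' @export
point_in_polygon <- function(polygon, lat, lon) {
  mgcv::in.out(polygon, cbind(as.numeric(lon), as.numeric(lat)))
}

#' Sample uniform random positions inside a source polygon
#'
#' Rejection sampling from the polygon's bounding box; positions are
#' uniform over the polygon's lon/lat extent.  Uses R's global random
#' number stream, so runs are reproducible under [set.seed()].
#'
#' @param polygon a closed two-column lon/lat matrix (or a one-row source
#'   tibble from [load_sources()]).
#' @param n number of points (>= 0).
#' @return a tibble with columns `lat`, `lon`.
#' @export
sample_positions <- function(polygon, n) {
  if (is.data.frame(polygon)) polygon <- polygon$polygon[[1]]
  if (n == 0) return(tibble::tibble(lat = numeric(), lon = numeric()))
  if (abs(shoelace_area(polygon)) < 1e-12) {
    abort("cannot sample from a zero-area polygon")
  }
  bbox <- apply(polygon, 2, range)
  lat <- numeric(0); lon <- numeric(0)
  while (length(lat) < n) {
    m <- max(2 * (n - length(lat)), 16)
    clon <- runif(m, bbox[1, "lon"], bbox[2, "lon"])
    clat <- runif(m, bbox[1, "lat"], bbox[2, "lat"])
    keep <- point_in_polygon(polygon, clat, clon)
    lat <- c(lat, clat[keep]); lon <- c(lon, clon[keep])
  }
  tibble::tibble(lat = lat[seq_len(n)], lon = lon[seq_len(n)])
}

#' Build a per-particle take-off schedule
#'
#' The first moth of every source takes off at `start`; take-offs then
#' continue at a constant temporal rate over the release window, i.e. the
#' i-th particle (i = 0, 1, ...) of a source takes off at
#' `start + i * window_s / n_per_source`.  Horizontal positions are drawn
#' uniformly within each source polygon; the initial height is z* = 0.
#'
#' @param sources a source tibble from [load_sources()].
#' @param start take-off start (UTC instant or ISO string), e.g. dusk
#'   10:00 UTC.
#' @param n_per_source particles released per source area.
#' @param window_s release window length in seconds.
#' @return a `release_plan` tibble with columns
#'   `id, source, abbrev, takeoff_utc, lat, lon, zstar` and attributes
#'   `start`, `window_s`.
#' @export
build_release <- function(sources, start, n_per_source = 500,
                          window_s = 3600) {
  if (!is.data.frame(sources) || nrow(sources) == 0) {
    abort("sources must be a non-empty source tibble")
  }
  if (n_per_source < 1) abort("n_per_source must be >= 1")
  start <- parse_utc(start)
  offs <- (seq_len(n_per_source) - 1) * window_s / n_per_source
  plan <- purrr::map2(sources$name, seq_len(nrow(sources)), function(nm, k) {
    pos <- sample_positions(sources$polygon[[k]], n_per_source)
    tibble::tibble(source = nm, abbrev = sources$abbrev[k],
                   takeoff_utc = start + offs,
                   lat = pos$lat, lon = pos$lon, zstar = 0)
  })
  plan <- dplyr::bind_rows(plan)
  plan <- dplyr::mutate(plan, id = dplyr::row_number(), .before = 1)
  attr(plan, "start") <- start
  attr(plan, "window_s") <- window_s
  class(plan) <- c("release_plan", class(plan))
  plan
}
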