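#' Map a migration snapshot
#'
#' Plots every airborne particle at the requested instant as an open
#' circle of about 18 km diameter (independent of flight height), coloured
#' by source area, with trap sites as labelled markers, over a plain
#' lat/lon (plate carree) East Asia extent.
#'
#' @param traj a `trajectory_set` from [run_simulation()].
#' @param time snapshot instant (POSIXct UTC or ISO string).
#' @param traps optional trap tibble (`name, lat, lon`).
#' @param circle_km drawn circle diameter in km.
#' @return a ggplot object.
#' @export
plot_migration_map <- function(traj, time, traps = NULL, circle_km = 18) {
  snap <- traj_snapshot(traj, time)
  fly <- dplyr::filter(snap, .data$airborne)
  p <- ggplot2::ggplot()
  if (nrow(fly)) {
    circ <- circle_polygons(fly$lat, fly$lon, fly$source, circle_km / 2)
    p <- p + ggplot2::geom_path(
      data = circ,
      ggplot2::aes(x = .data$lon, y = .data$lat, group = .data$grp,
                   colour = .data$source),
      linewidth = 0.3)
  }
  if (!is.null(traps) && nrow(traps)) {
    p <- p + ggplot2::geom_point(
      data = traps, ggplot2::aes(x = .data$lon, y = .data$lat),
      shape = 17, size = 2) +
      ggplot2::geom_text(
        data = traps,
        ggplot2::aes(x = .data$lon, y = .data$lat, label = .data$name),
        vjust = -0.8, size = 2.6)
  }
  p + ggplot2::coord_quickmap() +
    ggplot2::labs(x = "Longitude (deg E)", y = "Latitude (deg N)",
                  colour = "Source",
                  title = paste0("Migration snapshot ",
                                 format(parse_utc(time), "%Y-%m-%d %H:%M UTC")))
}

# small-circle outlines around points, on the lat/lon plane
circle_polygons <- function(lat, lon, source, radius_km, nseg = 24) {
  ang <- seq(0, 2 * pi, length.out = nseg + 1)
  n <- length(lat)
  lat0 <- rep(lat, each = nseg + 1)
  lon0 <- rep(lon, each = nseg + 1)
  tibble::tibble(
    grp = rep(seq_len(n), each = nseg + 1),
    source = rep(source, each = nseg + 1),
    lat = lat0 + radius_km / 110.54 * sin(rep(ang, n)),
    lon = lon0 + radius_km / (111.32 * cos(lat0 * pi / 180)) *
      cos(rep(ang, n)))
}

#' Export a migration snapshot as GeoJSON
#'
#' Writes one Point feature per airborne particle (properties: `source`,
#' `zstar_m`, `circle_km`) and one per trap (`kind = "trap"`).  The
#' feature count therefore equals airborne particles + traps.
#'
#' @inheritParams plot_migration_map
#' @param path output path.
#' @return (invisibly) the path.
#' @export
write_snapshot_geojson <- function(traj, time, traps = NULL, path,
                                   circle_km = 18) {
  snap <- traj_snapshot(traj, time)
  fly <- dplyr::filter(snap, .data$airborne)
  feats <- c(
    purrr::map(seq_len(nrow(fly)), function(i) {
      list(type = "Feature",
           geometry = list(type = "Point",
                           coordinates = c(fly$lon[i], fly$lat[i])),
           properties = list(kind = "moth", source = fly$source[i],
                             zstar_m = fly$zstar[i], circle_km = circle_km))
    }),
    if (!is.null(traps)) purrr::map(seq_len(nrow(traps)), function(i) {
      list(type = "Feature",
           geometry = list(type = "Point",
                           coordinates = c(traps$lon[i], traps$lat[i])),
           properties = list(kind = "trap", name = traps$name[i]))
    }))
  gj <- list(type = "FeatureCollection", features = feats)
  jsonlite::write_json(gj, path, auto_unbox = TRUE, digits = I(10))
  invisible(path)
}
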