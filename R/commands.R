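#' Generate a synthetic met file from a scenario spec
#'
#' Reads a YAML or JSON scenario description (the fields of
#' [scenario_params()]; `wind`, `temp` and `kz` as nested maps) and
#' writes a met file loadable by [load_met()].
#'
#' @param spec path to a YAML/JSON scenario file, or a ready
#'   [scenario_params()] object.
#' @param out output met file path.
#' @return (invisibly) the output path.
#' @export
synth_command <- function(spec, out) {
  if (!inherits(spec, "scenario_params")) {
    if (!file.exists(spec)) abort(paste0("scenario spec not found: ", spec))
    raw <- if (grepl("\\.ya?ml$", spec)) {
      if (!requireNamespace("yaml", quietly = TRUE)) {
        abort("YAML scenario specs require the 'yaml' package")
      }
      yaml::read_yaml(spec)
    } else {
      jsonlite::fromJSON(spec, simplifyVector = TRUE)
    }
    raw <- raw[intersect(names(raw), names(formals(scenario_params)))]
    if (!is.null(raw$levels)) raw$levels <- as.numeric(unlist(raw$levels))
    spec <- do.call(scenario_params, raw)
  }
  met <- if (spec$wind$type == "jet") jet_scenario(spec) else
    uniform_flow(spec)
  save_met(met, out)
  invisible(out)
}

#' Run a full migration prediction
#'
#' The end-to-end pipeline: release scheduling from the source polygons,
#' Lagrangian dispersion through the met fields, trap-arrival detection,
#' and file outputs (prediction table, trajectory CSV, snapshot GeoJSON
#' and optionally a PNG map).  Every output carries a header with the
#' package version, seed and a configuration hash; a given config + seed
#' reproduces byte-identical prediction tables.
#'
#' @param met path to a met file, or a [met_series()].
#' @param sources path to a GeoJSON source file, or a source tibble.
#' @param traps path to a trap CSV, or a trap tibble.
#' @param start run start (UTC), e.g. `"2021-04-30 10:00"`.
#' @param out_dir output directory (created if needed).
#' @param n_per_source particles per source area.
#' @param window_s release window, s.
#' @param cfg a [sim_config()].
#' @param radius_km trap detection radius, km.
#' @param seed integer seed for the release and diffusion randomness.
#' @param map also write a PNG snapshot map?
#' @param map_time snapshot instant for the map/GeoJSON outputs
#'   (default: end of the run).
#' @param quiet suppress stage logging?
#' @return (invisibly) a list with `predictions`, `arrivals`, `traj` and
#'   the output file paths.
#' @export
predict_command <- function(met, sources, traps, start, out_dir,
                            n_per_source = 500, window_s = 3600,
                            cfg = sim_config(), radius_km = 18,
                            seed = 1, map = FALSE, map_time = NULL,
                            quiet = TRUE) {
  say <- function(...) if (!quiet) message(sprintf(...))
  stage <- function(what, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("[", what, "] ", conditionMessage(e)))
    })
  }
  met <- stage("met", if (inherits(met, "met_series")) met else load_met(met))
  sources <- stage("sources",
                   if (is.data.frame(sources)) sources else
                     load_sources(sources))
  traps <- stage("traps",
                 if (is.data.frame(traps)) traps else load_traps(traps))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  config <- list(start = as.character(start), n_per_source = n_per_source,
                 window_s = window_s, cfg = unclass(cfg),
                 radius_km = radius_km)

  set.seed(seed)
  t0 <- Sys.time()
  release <- stage("release",
                   build_release(sources, start, n_per_source, window_s))
  say("release: %d particles from %d sources", nrow(release), nrow(sources))
  traj <- stage("dispersion", run_simulation(release, met, cfg))
  say("dispersion: %d snapshots in %.1f s", length(unique(traj$time_utc)),
      as.numeric(Sys.time() - t0, units = "secs"))
  arrivals <- stage("arrival",
                    detect_arrivals(traj, traps, radius_km, cfg$horizon_h))
  preds <- make_daily_predictions(arrivals, traps, start)

  paths <- list(
    predictions = file.path(out_dir, "predictions.csv"),
    trajectories = file.path(out_dir, "trajectories.csv"),
    geojson = file.path(out_dir, "snapshot.geojson"))
  write_csv_with_header(preds, paths$predictions, seed, config)
  traj_out <- dplyr::mutate(
    dplyr::select(traj, "time_utc", "id", "source", "lat", "lon",
                  zstar_m = "zstar", "airborne", "active"),
    time_utc = format(.data$time_utc, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"))
  write_csv_with_header(traj_out, paths$trajectories, seed, config)
  map_time <- map_time %||% max(traj$time_utc)
  write_snapshot_geojson(traj, map_time, traps, paths$geojson)
  if (map) {
    paths$map <- file.path(out_dir, "map.png")
    p <- plot_migration_map(traj, map_time, traps)
    ggplot2::ggsave(paths$map, p, width = 7, height = 5, dpi = 120)
  }
  say("outputs written to %s", out_dir)
  invisible(list(predictions = preds, arrivals = arrivals, traj = traj,
                 paths = paths))
}

#' Evaluate prediction tables against trap catches
#'
#' Runs [evaluate_predictions()] on CSV inputs and writes a per-day
#' classification table (H/F/- marks per window length) and a
#' hitting-ratio report.
#'
#' @param predictions path to a predictions CSV, or a tibble.
#' @param catches path to a catches CSV, or a tibble.
#' @param out_dir output directory.
#' @param windows window lengths in days.
#' @param period optional length-2 evaluation date range.
#' @param seed recorded in output headers (the evaluation itself is
#'   deterministic).
#' @return (invisibly) the `migration_eval` object.
#' @export
evaluate_command <- function(predictions, catches, out_dir,
                             windows = c(3, 5), period = NULL, seed = NULL) {
  pr <- if (is.data.frame(predictions)) predictions else
    read_predictions(predictions)
  ca <- if (is.data.frame(catches)) catches else read_catches(catches)
  ev <- evaluate_predictions(pr, ca, windows = windows, period = period)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  config <- list(windows = windows, period = as.character(ev$period))
  marks <- tidyr::pivot_wider(
    dplyr::select(ev$days, "site", "date", "window", "mark"),
    names_from = "window", names_prefix = "eval_", values_from = "mark")
  write_csv_with_header(marks, file.path(out_dir, "classifications.csv"),
                        seed, config)
  write_csv_with_header(ev$ratios, file.path(out_dir, "hitting_ratios.csv"),
                        seed, config)
  invisible(ev)
}
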