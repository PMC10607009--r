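#' Paths to packaged example data
#'
#' The package ships small plain-text transcriptions of the published
#' evaluation inputs: the 2020/2021 trap catalog (`traps.csv`), the
#' complete May 2021 prediction/catch/mark tables for the Koshi trap and
#' the (partially inferred) tables for the Isahaya trap, the published
#' per-site hitting-ratio matrix (`ratio_matrix.csv`), and coarse
#' simplified source-area polygons (`sources_simplified.geojson`).
#'
#' @param file file name, or NULL to list available files.
#' @return a file path (or a character vector of file names).
#' @export
#' @examples
#' mothwind_example()
#' read_predictions(mothwind_example("koshi_2021_predictions.csv"))
mothwind_example <- function(file = NULL) {
  if (is.null(file)) {
    return(dir(system.file("extdata", package = "mothwind")))
  }
  p <- system.file("extdata", file, package = "mothwind")
  if (!nzchar(p)) abort(paste0("no packaged file '", file, "'"))
  p
}
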