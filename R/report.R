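#' Write a screen report to disk
#'
#' Writes one TSV gene list per stage plus a machine-readable
#' `provenance.json` containing the thresholds, seed, package version and
#' per-stage cardinalities. Content is deterministic given an identical
#' `screen_result` (no timestamps or timings enter the files), so two runs
#' with the same config and seed produce byte-identical reports.
#'
#' @param result A `screen_result` from [run_full_screen()].
#' @param out_dir Output directory (created if absent).
#' @return Invisibly, the paths written.
#' @export
write_screen_report <- function(result, out_dir) {
  stopifnot(inherits(result, "screen_result"))
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory: ", out_dir)
  }
  if (file.access(out_dir, mode = 2) != 0)
    stop("output directory is not writable: ", out_dir)
  paths <- character(0)
  for (nm in names(result$stages)) {
    p <- file.path(out_dir, paste0("stage_", nm, ".tsv"))
    df <- data.frame(gene = result$stages[[nm]], stringsAsFactors = FALSE)
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, p)
  }
  th <- result$thresholds
  prov <- list(
    package = "mhcscreen",
    version = as.character(utils::packageVersion("mhcscreen")),
    seed = result$seed,
    focal_cohort = result$focal_cohort,
    thresholds = th[order(names(th))],
    scoring = list(kcdf = result$config$kcdf,
                   gsva_es = "difference of extreme deviations (v+ - v-)",
                   signature = result$config$signature),
    prognostic = list(endpoints = result$config$endpoints,
                      horizons = result$config$horizons,
                      alpha = result$config$alpha,
                      covariate = if (result$config$dichotomize_expression)
                        "median-dichotomized" else "z-scored continuous"),
    fraction_source = result$config$fraction_source,
    stage_cardinalities = as.list(result$cardinalities),
    n_candidates = length(result$candidates),
    n_dual_effectors = length(result$dual_effectors))
  pj <- file.path(out_dir, "provenance.json")
  writeLines(jsonlite::toJSON(prov, auto_unbox = TRUE, pretty = TRUE,
                              digits = NA, null = "null"), pj)
  invisible(c(paths, pj))
}
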