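#' Run the full analysis pipeline
#'
#' Orchestrates generate -> (tune k_max) -> extract -> contrast ->
#' classify as one reproducible run: every stage output is written under
#' `output_dir` as CSV, and a run manifest (configuration snapshot,
#' package version, selected k_max, file checksums, per-stage wall-clock)
#' is written as `run_manifest.json`. Outputs are pure functions of the
#' configuration and seeds, which the checksums make verifiable.
#'
#' @param config a [cohort_config()].
#' @param montage a [montage_spec()].
#' @param output_dir output directory; refuses to overwrite an existing
#'   run manifest unless `overwrite = TRUE`.
#' @param k_max integer, or `"auto"` to run the sweep/selection procedure.
#' @param candidates k_max candidates for `"auto"`.
#' @param alpha,direction,top_n channel-test settings (see
#'   [channel_tests()] / [top_channels()]).
#' @param schemes split schemes to evaluate (see [run_grid()]).
#' @param grid classifier grid.
#' @param cv_seeds cross-validation shuffle seeds.
#' @param n_folds CV folds.
#' @param compare_montage also run the full-vs-standard32 comparison.
#' @param overwrite overwrite an existing run.
#' @return The run manifest, invisibly (also written as JSON).
#' @export
run_pipeline <- function(config = cohort_config(),
                         montage = default_montage(), output_dir,
                         k_max = "auto",
                         candidates = c(2, 5, 20, 100, 150, 200, 400),
                         alpha = 0.05, direction = "a_less", top_n = 10,
                         schemes = c("subject_presentation",
                                     "subject_specific"),
                         grid = default_grid(), cv_seeds = c(0, 1, 2),
                         n_folds = 10, compare_montage = FALSE,
                         overwrite = FALSE) {
  mpath <- file.path(output_dir, "run_manifest.json")
  if (file.exists(mpath) && !overwrite)
    stop_hfd("output_dir already holds a run manifest; use overwrite = TRUE")
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  timings <- c(); files <- character(0)
  tick <- function(stage, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(expr, error = function(e)
      stop_hfd("pipeline stage '", stage, "' failed: ", conditionMessage(e)))
    timings[[stage]] <<- round(proc.time()[["elapsed"]] - t0, 2)
    res
  }
  emit <- function(df, name) {
    p <- file.path(output_dir, name)
    data.table::fwrite(as.data.frame(df), p)
    files <<- c(files, p)
  }

  cohort <- tick("generate", generate_cohort(config, montage))

  if (identical(k_max, "auto")) {
    sweep <- tick("tune_kmax", sweep_kmax(cohort, candidates))
    emit(sweep, "kmax_sweep.csv")
    k_max <- select_kmax(sweep)
  }
  params <- hfd_params(k_max)

  features <- tick("extract", extract_features(cohort, params))
  emit(features, "hfd_features.csv")

  contrasts <- tick("contrast", channel_tests(features, alpha = alpha,
                                              direction = direction))
  emit(contrasts, "channel_contrasts.csv")
  emit(top_channels(contrasts, top_n), "top_channels.csv")
  emit(channel_tests(features, alpha = alpha, direction = direction,
                     condition = "rest"), "rest_contrasts.csv")
  emit(style_contrast(features, alpha = alpha), "style_contrast_expert.csv")
  emit(export_topography(contrasts, montage), "topography.csv")

  samples <- assemble_samples(features)
  report <- tick("classify", run_grid(samples, schemes, grid, cv_seeds,
                                      n_folds))
  emit(report, "accuracy_report.csv")
  emit(best_per_scheme(report), "best_per_scheme.csv")
  if (compare_montage) {
    cmp <- tick("compare_montage",
                compare_channel_sets(features, montage,
                                     schemes = "subject_presentation",
                                     grid = grid, seeds = cv_seeds,
                                     n_folds = n_folds))
    emit(cmp, "channel_set_comparison.csv")
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("hfdeeg")),
    config = unclass(config), k_max = k_max, cv_seeds = cv_seeds,
    schemes = schemes,
    files = data.frame(file = basename(files),
                       md5 = unname(tools::md5sum(files)),
                       stringsAsFactors = FALSE),
    timings_seconds = as.list(timings))
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
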