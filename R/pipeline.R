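# End-to-end pipeline: simulate cohort -> extract features -> benchmark
# classifiers -> selection report, with seeded reproducibility and
# restartable on-disk artifacts.

#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end run. The defaults mirror the
#' study protocol: 20 PD patients (each in OFF and ON state) and 15
#' healthy controls, 18 trials per subject-state at the three
#' perturbation conditions, 100 Hz sampling, 30 s steady state with 2 s
#' sigmoidal ramps, 50-fold cross-validation and an 80% gate threshold.
#'
#' @param n_pd,n_hc cohort sizes.
#' @param effect_a_ml,effect_g_pelvis standardized PD effect sizes.
#' @param on_normalization ON-state normalization fraction.
#' @param between_sd_scale between-subject SD multiplier.
#' @param noise_accel,noise_gyro,noise_orient sensor noise SDs.
#' @param duration,fs,ramp_duration trajectory parameters.
#' @param k cross-validation folds.
#' @param threshold gate threshold, percent.
#' @param seed_cohort,seed_sessions,seed_folds seeds for the three
#'   random stages.
#' @return a list of class `pipeline_config`.
#' @export
pipeline_config <- function(n_pd = 20, n_hc = 15,
                            effect_a_ml = 1.5, effect_g_pelvis = 1.5,
                            on_normalization = 0.3,
                            between_sd_scale = 1,
                            noise_accel = 0.02, noise_gyro = 0.2,
                            noise_orient = 0.2,
                            duration = 30, fs = 100, ramp_duration = 2,
                            k = 50, threshold = 80,
                            seed_cohort = 11L, seed_sessions = 12L,
                            seed_folds = 13L) {
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Executes the four stages in order: cohort simulation, feature
#' extraction, classifier benchmarking and gate/goodness selection.
#' Identical configurations yield identical results. When `out_dir` is
#' given, each stage's output is written there (feature CSV, benchmark
#' JSON, report CSV + JSON and a run manifest), so any stage can be
#' re-run later from the on-disk artifacts.
#'
#' @param config a [pipeline_config()].
#' @param out_dir optional output directory.
#' @param progress print per-stage progress.
#' @return a list of class `pipeline_result`: `config`, `cohort`,
#'   `features`, `bench`, `report`, `best`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL,
                         progress = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  cohort <- sample_cohort(
    n_pd = config$n_pd, n_hc = config$n_hc,
    effect_a_ml = config$effect_a_ml,
    effect_g_pelvis = config$effect_g_pelvis,
    on_normalization = config$on_normalization,
    between_sd_scale = config$between_sd_scale,
    noise_accel = config$noise_accel, noise_gyro = config$noise_gyro,
    noise_orient = config$noise_orient,
    seed = config$seed_cohort
  )
  features <- extract_cohort_features(
    cohort, duration = config$duration, fs = config$fs,
    ramp_duration = config$ramp_duration, noise = TRUE,
    seed = config$seed_sessions, progress = progress
  )
  bench <- run_bench(features, k = config$k, seed = config$seed_folds,
                     progress = progress)
  report <- selection_report(bench, threshold = config$threshold)
  best <- select_best(report)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_features_csv(features, file.path(out_dir, "features.csv"))
    write_bench_json(bench, file.path(out_dir, "bench.json"))
    write_report(report, file.path(out_dir, "report.csv"))
    write_report(report, file.path(out_dir, "report.json"))
    manifest <- config
    class(manifest) <- NULL
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  structure(
    list(config = config, cohort = cohort, features = features,
         bench = bench, report = report, best = best),
    class = "pipeline_result"
  )
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  cat(sprintf("  cohort: %d subject-states, %d features\n",
              nrow(x$features), length(feature_columns(x$features))))
  cat(sprintf("  bench: %d experiment x classifier combinations\n",
              nrow(x$bench)))
  cat("  best classifiers:\n")
  b <- x$best
  for (i in seq_len(nrow(b))) {
    cat(sprintf("    %-8s %s%s\n", b$experiment[i], b$spec_id[i],
                ifelse(is.na(b$goodness[i]), "",
                       sprintf(" (G = %.2f, %s)", b$goodness[i],
                               b$category[i]))))
  }
  invisible(x)
}
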