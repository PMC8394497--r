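#' Run the full phantom analysis pipeline
#'
#' Convenience driver exercising every stage end-to-end on a synthetic
#' cohort: simulate subjects, estimate each subject's T2 map from the echo
#' pair, bring the anatomical-space labels into T2-map space (using the
#' known ground-truth transform, a rigid registration estimated per
#' subject, or no correction), extract the 38-feature regional vectors,
#' fold contralateral pairs, assemble the feature table and run the
#' univariate screen.
#'
#' @param spec a \code{\link{phantom_spec}}.
#' @param registration \code{"truth"} (apply the known misalignment
#'   correction; default, fast), \code{"estimate"} (run
#'   \code{\link{register_rigid}} per subject on the long-echo image), or
#'   \code{"none"} (use the echo-space truth labels directly).
#' @param clip_range_ms T2 clipping bounds.
#' @param top_frac screening pool fractions (see
#'   \code{\link{screen_features}}).
#' @param verbose print progress.
#' @return list with \code{cohort} (the \code{phantom_cohort}),
#'   \code{table} (a \code{feature_table}), \code{screen} (a
#'   \code{univariate_screen}), \code{demographics} (p-values), and
#'   \code{registration} (per-subject transform summaries when estimated).
#' @export
t2asym_pipeline <- function(spec = phantom_spec(),
                            registration = c("truth", "estimate", "none"),
                            clip_range_ms = c(1, 3000),
                            top_frac = c(signal_texture = 0.05,
                                         volume = 0.15, neuropsych = 1.0),
                            verbose = FALSE) {
  registration <- match.arg(registration)
  cohort <- simulate_cohort(spec)
  atlas <- cohort$atlas
  rows <- list()
  reg_info <- list()
  for (s in cohort$subjects) {
    t2m <- compute_t2_map(s$echo_a, s$echo_b, clip_range_ms)
    labels_echo <- switch(
      registration,
      none = s$labels_true,
      truth = resample_labels(s$labels, s$truth$transform_to_anat,
                              reference = s$labels_true),
      estimate = {
        fixed <- volume3d(s$echo_b$data, s$echo_b$spacing_mm,
                          s$echo_b$origin_mm)
        reg <- register_rigid(fixed, s$anatomical)
        reg_info[[s$subject_id]] <- reg$transform
        resample_labels(s$labels, reg$transform,
                        reference = s$labels_true)
      })
    feats <- extract_all(t2m, labels_echo, atlas)
    rows[[s$subject_id]] <- fold_contralateral(feats, atlas)
    if (verbose) message("processed ", s$subject_id)
  }
  table <- build_feature_table(rows, cohort$cohort, atlas)
  screen <- screen_features(table, top_frac = top_frac)
  list(cohort = cohort, table = table, screen = screen,
       demographics = demographics_tests(cohort$cohort),
       registration = reg_info)
}

#' Write a feature table (wide CSV) and its manifest (JSON)
#'
#' @param table a \code{feature_table}.
#' @param path CSV path; the manifest goes to \code{<path>.manifest.json}.
#' @return \code{path}, invisibly.
#' @export
write_feature_table <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  jsonlite::write_json(table_manifest(table),
                       paste0(path, ".manifest.json"), digits = NA)
  invisible(path)
}

#' Write univariate screening results as CSV
#'
#' @param screen a \code{\link{screen_features}} result.
#' @param path CSV path.
#' @return \code{path}, invisibly.
#' @export
write_screen_results <- function(screen, path) {
  utils::write.csv(screen$results, path, row.names = FALSE)
  invisible(path)
}

#' Write benchmark metrics and selection frequencies as CSV
#'
#' @param report a \code{\link{repeated_holdout}} result.
#' @param path metrics CSV path; selection frequencies go to
#'   \code{<path>.selection.csv}.
#' @return \code{path}, invisibly.
#' @export
write_benchmark_report <- function(report, path) {
  utils::write.csv(report$metrics, path, row.names = FALSE)
  utils::write.csv(selection_frequency(report)$by_filter,
                   paste0(path, ".selection.csv"), row.names = FALSE)
  invisible(path)
}
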