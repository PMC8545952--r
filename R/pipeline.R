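# End-to-end driver: simulate -> classify -> population -> pairs, writing a
# CSV + JSON report bundle. This is the programmatic equivalent of a
# run-all command; each stage is also callable on its own.

#' Run the full analysis pipeline
#'
#' Simulates (or loads) a session, classifies every unit, and runs the
#' population and pairwise stages, writing all stage outputs as CSV plus a
#' JSON summary into `out_dir`. Deterministic under the config seed.
#'
#' @param config a [sim_config()]; ignored when `session` is supplied.
#' @param out_dir output directory (`NULL` skips writing).
#' @param session optional pre-built `rs_session`.
#' @param n_perm permutations for the cluster tests.
#' @param seed seed for the permutation draws.
#' @return invisibly, a list with `session`, `classes`, `group_stats`,
#'   `positional`, `pairs` and `summary` (the JSON summary as a list).
#' @export
run_all <- function(config = sim_config(), out_dir = NULL, session = NULL,
                    n_perm = 1000, seed = 1L) {
  if (is.null(session)) session <- simulate_session(config)
  classes <- classify_units(session)
  grp <- relational_group_stats(session, classes)
  pos <- positional_effect(session, classes)
  prr <- pair_response_reactivation(session, classes)
  class_freq <- dplyr::count(classes, .data$region, .data$label)
  corr <- tryCatch(condition_response_correlation(session, classes),
                   error = function(e) NULL)
  summary <- list(
    session_id = session$session_id,
    n_trials = nrow(session$trials),
    n_units = nrow(session$units),
    class_counts = as.list(table(factor(classes$label, levels = UNIT_LABELS))),
    class_frequencies_by_region = class_freq,
    n_concept_pairs = nrow(concept_pairs(classes)),
    seed = seed
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_session(session, file.path(out_dir, "session"))
    readr::write_csv(classes, file.path(out_dir, "selectivity.csv"), na = "")
    readr::write_csv(grp$groups, file.path(out_dir, "relational_groups.csv"))
    readr::write_csv(pos$groups, file.path(out_dir, "positional_effects.csv"))
    readr::write_csv(prr$groups, file.path(out_dir, "pair_correlations.csv"))
    if (!is.null(corr)) {
      readr::write_csv(corr, file.path(out_dir, "condition_correlations.csv"))
    }
    summary_json <- summary
    summary_json$class_frequencies_by_region <- NULL
    jsonlite::write_json(summary_json, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(list(session = session, classes = classes, group_stats = grp,
                 positional = pos, pairs = prr, correlations = corr,
                 summary = summary))
}
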