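# The unit-classification cascade.
#
# (1) visually selective: the bin-wise signed-rank + Simes detector
#     (alpha = 1e-5) fires for exactly one of the four pictures in the main
#     condition, AND the preferred picture's 0-1000 ms rates exceed every
#     other picture's (Hedges' g > 0.3) within each of the three conditions;
# (2) concept: additionally, question-comparison questions naming the
#     preferred concept evoke higher firing than those naming each other
#     concept (Hedges' g > 0.3);
# (3) reactivated: concept neurons with higher firing 500-1300 ms after the
#     second picture in relational (preferred first) versus non-relational
#     (preferred absent) main trials (Mann-Whitney, alpha = 0.05); remaining
#     concept neurons are input-driven;
# (4) visually selective non-concept units are "visual";
# (5) units with no picture response whose mean prompt-aligned z exceeds 1
#     in 0-1500 ms (baseline -400 to 100 ms) are "non_visual_responder";
#     everything else is "unresponsive".

UNIT_LABELS <- c("concept_reactivated", "concept_input_driven", "visual",
                 "non_visual_responder", "unresponsive")

# event times at which a given picture is on screen, within a condition
picture_events <- function(trials, pic, condition = NULL) {
  if (!is.null(condition)) trials <- trials[trials$condition == condition, ]
  c(trials$t_pic1[trials$pic1_id == pic], trials$t_pic2[trials$pic2_id == pic])
}

window_rates <- function(spikes, event_times, window_ms) {
  w <- ms_to_s(window_ms)
  count_spikes(spikes, event_times + w[1], event_times + w[2]) / (w[2] - w[1])
}

#' Per-picture response detection
#'
#' Runs the bin-wise signed-rank detector with Simes correction for every
#' unit x picture combination, using all main-condition presentations of the
#' picture (either position).
#'
#' @param session an `rs_session`.
#' @param unit_ids units to test; defaults to all.
#' @param alpha Simes rejection level (default 1e-5).
#' @param scheme a [bin_scheme()].
#' @return tibble with one row per unit x picture: `unit_id`, `picture`,
#'   `simes_p`, `responds`, `min_bin_p`, and `bin_p` (list-column of the 19
#'   bin p-values).
#' @export
detect_responses <- function(session, unit_ids = NULL, alpha = 1e-5,
                             scheme = bin_scheme()) {
  if (is.null(unit_ids)) unit_ids <- session$units$unit_id
  pics <- session$picture_set
  purrr::map_dfr(unit_ids, function(uid) {
    spk <- unit_spikes(session, uid)
    purrr::map_dfr(pics, function(p) {
      ev <- picture_events(session$trials, p, condition = "main")
      br <- bin_rate_matrix(spk, ev, scheme)
      pv <- binwise_signed_rank(br$rates, br$baseline)
      sm <- simes_test(pv, alpha = alpha)
      tibble::tibble(unit_id = uid, picture = p, simes_p = sm$global_p,
                     responds = sm$reject, min_bin_p = min(pv),
                     bin_p = list(pv))
    })
  })
}

# mean prompt-aligned z over a window (baseline relative to the same event);
# equals the window mean of the 1-ms z series because z is linear in rate
prompt_mean_z <- function(spikes, prompt_times, window_ms = c(0, 1500),
                          baseline_ms = c(-400, 100)) {
  base <- window_rates(spikes, prompt_times, baseline_ms)
  mu <- mean(base)
  sd_b <- stats::sd(base)
  if (is.na(sd_b) || sd_b == 0) return(NA_real_)
  (mean(window_rates(spikes, prompt_times, window_ms)) - mu) / sd_b
}

classify_one <- function(session, uid, det, alpha, g_threshold,
                         reactivation_alpha, prompt_z_threshold,
                         response_window_ms, reactivation_window_ms) {
  spk <- unit_spikes(session, uid)
  tr <- session$trials
  pics <- session$picture_set
  d <- det[det$unit_id == uid, ]
  responsive <- d$picture[d$responds]
  n_resp <- length(responsive)
  pref <- if (n_resp == 1) responsive else NA_character_

  g_pic_min <- NA_real_
  g_question <- NA_real_
  reactivation_p <- NA_real_
  label <- "unresponsive"
  selective <- FALSE

  if (n_resp == 1) {
    # Hedges' g gate: preferred vs every other picture, each condition
    gs <- purrr::map_dbl(TRIAL_CONDITIONS, function(cond) {
      pref_rates <- window_rates(spk, picture_events(tr, pref, cond),
                                 response_window_ms)
      min(purrr::map_dbl(setdiff(pics, pref), function(p) {
        hedges_g(pref_rates,
                 window_rates(spk, picture_events(tr, p, cond),
                              response_window_ms))
      }))
    })
    g_pic_min <- min(gs)
    selective <- g_pic_min > g_threshold
  }

  if (selective) {
    # concept gate: question-period firing for questions naming the
    # preferred concept must exceed each other named-concept group,
    # mirroring the per-picture structure of the visual gate
    qc <- tr[tr$condition == "question_comparison", ]
    named <- !is.na(qc$named_concept) & qc$named_concept == pref
    q_rates_pref <- window_rates(spk, qc$t_question[named], response_window_ms)
    g_question <- min(purrr::map_dbl(setdiff(pics, pref), function(p) {
      other <- !is.na(qc$named_concept) & qc$named_concept == p
      hedges_g(q_rates_pref, window_rates(spk, qc$t_question[other],
                                          response_window_ms))
    }))
    if (g_question > g_threshold) {
      # reactivated gate: relational vs non-relational main trials
      mn <- tr[tr$condition == "main", ]
      rel <- mn$pic1_id == pref
      nonrel <- mn$pic1_id != pref & mn$pic2_id != pref
      r_rel <- window_rates(spk, mn$t_pic2[rel], reactivation_window_ms)
      r_non <- window_rates(spk, mn$t_pic2[nonrel], reactivation_window_ms)
      mw <- suppressWarnings(stats::wilcox.test(r_rel, r_non))
      reactivation_p <- mw$p.value
      label <- if (reactivation_p < reactivation_alpha &&
                     mean(r_rel) > mean(r_non)) {
        "concept_reactivated"
      } else "concept_input_driven"
    } else {
      label <- "visual"
    }
  }

  prompt_z <- NA_real_
  if (n_resp == 0) {
    qc_prompts <- tr$t_prompt[tr$condition == "question_comparison"]
    prompt_z <- prompt_mean_z(spk, qc_prompts)
    if (!is.na(prompt_z) && prompt_z > prompt_z_threshold) {
      label <- "non_visual_responder"
    }
  }
  if (n_resp > 1) label <- "unresponsive" # conservative: no single preference

  tibble::tibble(
    unit_id = uid, label = label, preferred_pic = pref,
    n_responsive_pics = n_resp,
    simes_p_min = min(d$simes_p),
    g_picture_min = g_pic_min, g_question = g_question,
    reactivation_p = reactivation_p, prompt_z = prompt_z
  )
}

#' Classify every unit of a session
#'
#' Runs the full response-detection and classification cascade (see the
#' file-level description) and returns one row per unit with the test
#' statistics and the final class label: `concept_reactivated`,
#' `concept_input_driven`, `visual`, `non_visual_responder` or
#' `unresponsive`. Units with Simes rejections for two or more pictures are
#' excluded from the selective classes (kept `unresponsive`) rather than
#' demoted to their best picture.
#'
#' @param session an `rs_session` containing all three conditions.
#' @param alpha Simes level of the response detector (default 1e-5).
#' @param g_threshold Hedges' g gate (default 0.3).
#' @param reactivation_alpha Mann-Whitney level for the reactivated gate
#'   (default 0.05).
#' @param prompt_z_threshold mean prompt-aligned z required of non-visual
#'   responders (default 1).
#' @param response_window_ms,reactivation_window_ms analysis windows, ms.
#' @param scheme detector [bin_scheme()].
#' @param detections optional precomputed [detect_responses()] table; the
#'   `responds` column is re-derived from `simes_p` at `alpha`.
#' @return tibble with one row per unit (classification result joined to the
#'   unit metadata).
#' @export
classify_units <- function(session, alpha = 1e-5, g_threshold = 0.3,
                           reactivation_alpha = 0.05, prompt_z_threshold = 1,
                           response_window_ms = c(0, 1000),
                           reactivation_window_ms = c(500, 1300),
                           scheme = bin_scheme(), detections = NULL) {
  for (cond in TRIAL_CONDITIONS) {
    if (!cond %in% session$trials$condition) {
      stop("classify_units: session lacks condition '", cond, "'")
    }
  }
  det <- if (is.null(detections)) {
    detect_responses(session, alpha = alpha, scheme = scheme)
  } else {
    dplyr::mutate(detections, responds = .data$simes_p <= alpha)
  }
  res <- purrr::map_dfr(session$units$unit_id, function(uid) {
    classify_one(session, uid, det, alpha, g_threshold, reactivation_alpha,
                 prompt_z_threshold, response_window_ms,
                 reactivation_window_ms)
  })
  dplyr::left_join(
    res,
    dplyr::select(session$units, "unit_id", "region", "hemisphere",
                  "bundle_id", "kind"),
    by = "unit_id"
  )
}
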