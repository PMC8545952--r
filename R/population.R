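# Population-level analyses: baseline-normalised firing-rate time series,
# cluster-based permutation tests, cross-condition response correlations,
# semantic/perceptual relational group statistics, positional effects and
# prompt-aligned reactivation.

ALIGN_COLS <- c(question = "t_question", pic1 = "t_pic1", pic2 = "t_pic2",
                prompt = "t_prompt")

#' Baseline-normalised smoothed firing-rate series
#'
#' Bins spikes at 1 ms around each event, averages across events, z-scores
#' by the mean and SD of per-trial baseline-window rates, and smooths with a
#' Gaussian kernel (truncated at +/- 4 sigma, renormalised at the edges).
#'
#' @param spikes sorted spike times (seconds).
#' @param event_times alignment event onsets (seconds).
#' @param window_ms series window, ms relative to the event.
#' @param baseline_event_times events to which the baseline window is
#'   anchored (defaults to `event_times`; pass first-picture onsets to use
#'   the pre-first-picture baseline).
#' @param baseline_ms baseline window, ms (default -500 to 0).
#' @param kernel_sigma_ms Gaussian kernel SD, ms (default 50).
#' @return tibble of class `rs_zscore` with columns `time_ms` (bin centres)
#'   and `z`; attributes `baseline_mean`, `baseline_sd`, `n_trials` and
#'   `excluded` (`TRUE` when the baseline SD is zero, in which case `z` is
#'   all `NA` and the unit must be dropped from population averages).
#' @export
zscore_series <- function(spikes, event_times, window_ms = c(-500, 1500),
                          baseline_event_times = event_times,
                          baseline_ms = c(-500, 0), kernel_sigma_ms = 50) {
  if (length(event_times) == 0) stop("zscore_series: no events")
  counts <- bin_counts_1ms(spikes, event_times, window_ms)
  psth <- colMeans(counts) * 1000 # Hz
  base <- window_rates(spikes, baseline_event_times, baseline_ms)
  mu <- mean(base)
  sd_b <- stats::sd(base)
  excluded <- is.na(sd_b) || sd_b == 0
  z <- if (excluded) rep(NA_real_, length(psth)) else {
    gauss_smooth((psth - mu) / sd_b, kernel_sigma_ms)
  }
  out <- tibble::tibble(
    time_ms = seq(window_ms[1], window_ms[2] - 1) + 0.5,
    z = z
  )
  class(out) <- c("rs_zscore", class(out))
  attr(out, "baseline_mean") <- mu
  attr(out, "baseline_sd") <- if (excluded) NA_real_ else sd_b
  attr(out, "n_trials") <- length(event_times)
  attr(out, "excluded") <- excluded
  out
}

#' Per-unit z series for a trial group
#'
#' Session-level wrapper around [zscore_series()]: selects the trial rows,
#' aligns to the requested event and anchors the normalisation baseline
#' before the first picture of the same trials (the population convention).
#'
#' @param session an `rs_session`.
#' @param unit_id unit to analyse.
#' @param trials trial subset (tibble); defaults to all trials.
#' @param align `"question"`, `"pic1"`, `"pic2"` or `"prompt"`.
#' @param window_ms series window, ms.
#' @param baseline_align event anchoring the baseline window (default
#'   `"pic1"`).
#' @inheritParams zscore_series
#' @return an `rs_zscore` tibble (see [zscore_series()]).
#' @export
unit_z_series <- function(session, unit_id, trials = NULL, align = "pic1",
                          window_ms = c(-500, 1500), baseline_align = "pic1",
                          baseline_ms = c(-500, 0), kernel_sigma_ms = 50) {
  if (is.null(trials)) trials <- session$trials
  align <- match.arg(align, names(ALIGN_COLS))
  baseline_align <- match.arg(baseline_align, names(ALIGN_COLS))
  zscore_series(unit_spikes(session, unit_id),
                trials[[ALIGN_COLS[align]]],
                window_ms = window_ms,
                baseline_event_times = trials[[ALIGN_COLS[baseline_align]]],
                baseline_ms = baseline_ms,
                kernel_sigma_ms = kernel_sigma_ms)
}

# units x time matrix of z series; trial_selector(trials, preferred_pic)
# returns the trial subset for one unit. Zero-baseline-SD units are dropped.
z_matrix <- function(session, units_tbl, trial_selector, align = "pic2",
                     window_ms = c(-500, 1500), baseline_align = "pic1",
                     baseline_ms = c(-500, 0), kernel_sigma_ms = 50) {
  rows <- list()
  kept <- character(0)
  for (i in seq_len(nrow(units_tbl))) {
    uid <- units_tbl$unit_id[i]
    pref <- units_tbl$preferred_pic[i]
    tr <- trial_selector(session$trials, pref)
    if (nrow(tr) == 0) next
    zs <- unit_z_series(session, uid, tr, align = align,
                        window_ms = window_ms, baseline_align = baseline_align,
                        baseline_ms = baseline_ms,
                        kernel_sigma_ms = kernel_sigma_ms)
    if (attr(zs, "excluded")) next
    rows[[length(rows) + 1L]] <- zs$z
    kept <- c(kept, uid)
  }
  m <- do.call(rbind, rows)
  if (is.null(m)) m <- matrix(numeric(0), nrow = 0,
                              ncol = window_ms[2] - window_ms[1])
  attr(m, "unit_id") <- kept
  attr(m, "time_ms") <- seq(window_ms[1], window_ms[2] - 1) + 0.5
  m
}

window_mean_z <- function(zs, window_ms) {
  mean(zs$z[zs$time_ms >= window_ms[1] & zs$time_ms < window_ms[2]])
}

#' Cluster-based permutation test on paired time series
#'
#' Paired two-sided t-tests per time bin (at `alpha_bin`) define contiguous
#' supra-threshold clusters, formed separately for positive and negative
#' signs. Each cluster's absolute t-sum is compared to the permutation null
#' of the maximum cluster |t-sum| under random per-unit condition-label
#' flips; a cluster is significant when its permutation p-value falls below
#' `cluster_alpha` (the "top percentile" criterion at the default 0.01).
#'
#' @param a,b units x time matrices of z values for the two conditions
#'   (same units, same order). `b = NULL` tests `a` against zero.
#' @param alpha_bin cluster-forming bin-wise level (default 0.01).
#' @param cluster_alpha cluster-level significance (default 0.01).
#' @param n_perm number of permutations (default 1000; fewer than 100 draws
#'   a warning).
#' @param seed integer seed for the permutation draws.
#' @param time_ms optional time axis (bin centres) for reporting.
#' @return object of class `rs_cluster_test`: list with `clusters` (tibble:
#'   `start_ms`, `end_ms`, `sign`, `t_sum`, `p_value`), `significant_mask`,
#'   `t_values`, `threshold`, and the test parameters. [tidy()] and
#'   [glance()] methods are provided.
#' @export
cluster_permutation <- function(a, b = NULL, alpha_bin = 0.01,
                                cluster_alpha = 0.01, n_perm = 1000,
                                seed = 1L, time_ms = NULL) {
  if (is.null(b)) b <- matrix(0, nrow = nrow(a), ncol = ncol(a))
  stopifnot(nrow(a) == nrow(b), ncol(a) == ncol(b))
  n <- nrow(a)
  if (n < 5) stop("cluster_permutation: need >= 5 units")
  if (n_perm < 100) warning("cluster_permutation: n_perm < 100 is unreliable")
  if (is.null(time_ms)) time_ms <- seq_len(ncol(a)) - 0.5
  d <- a - b
  ss <- colSums(d^2)
  t_of <- function(m_col) {
    v <- (ss - n * m_col^2) / (n - 1)
    tt <- m_col / sqrt(v / n)
    tt[!is.finite(tt)] <- 0
    tt
  }
  t_obs <- t_of(colMeans(d))
  thr <- stats::qt(1 - alpha_bin / 2, df = n - 1)

  find_clusters <- function(tv) {
    out <- list()
    for (sgn in c(1, -1)) {
      supra <- sgn * tv > thr
      r <- rle(supra)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      for (j in which(r$values)) {
        out[[length(out) + 1L]] <- tibble::tibble(
          start = starts[j], end = ends[j], sign = sgn,
          t_sum = sum(tv[starts[j]:ends[j]]))
      }
    }
    if (length(out) == 0) {
      tibble::tibble(start = integer(0), end = integer(0),
                     sign = numeric(0), t_sum = numeric(0))
    } else dplyr::bind_rows(out)
  }
  obs <- find_clusters(t_obs)

  signs <- with_seed(seed, matrix(sample(c(-1, 1), n_perm * n, replace = TRUE),
                                  nrow = n_perm))
  m_perm <- (signs %*% d) / n
  null_max <- vapply(seq_len(n_perm), function(k) {
    cl <- find_clusters(t_of(m_perm[k, ]))
    if (nrow(cl) == 0) 0 else max(abs(cl$t_sum))
  }, numeric(1))

  p_vals <- vapply(abs(obs$t_sum), function(s) {
    (1 + sum(null_max >= s)) / (n_perm + 1)
  }, numeric(1))
  obs$p_value <- p_vals
  mask <- rep(FALSE, ncol(a))
  for (j in which(p_vals < cluster_alpha)) mask[obs$start[j]:obs$end[j]] <- TRUE
  clusters <- tibble::tibble(
    start_ms = time_ms[obs$start] - 0.5, end_ms = time_ms[obs$end] + 0.5,
    sign = obs$sign, t_sum = obs$t_sum, p_value = obs$p_value)
  structure(
    list(clusters = clusters, significant_mask = mask, t_values = t_obs,
         time_ms = time_ms, threshold = thr, alpha_bin = alpha_bin,
         cluster_alpha = cluster_alpha, n_perm = n_perm, seed = seed,
         n_units = n),
    class = "rs_cluster_test"
  )
}

#' @export
print.rs_cluster_test <- function(x, ...) {
  cat("<rs_cluster_test> ", x$n_units, " units, ", x$n_perm,
      " permutations, bin alpha ", x$alpha_bin, "\n", sep = "")
  sig <- x$clusters[x$clusters$p_value < x$cluster_alpha, ]
  cat("  clusters: ", nrow(x$clusters), " (", nrow(sig), " significant at ",
      x$cluster_alpha, ")\n", sep = "")
  if (nrow(sig) > 0) print(sig)
  invisible(x)
}

# ---------------------------------------------------------------------------

concept_units <- function(classes) {
  classes[classes$label %in% c("concept_reactivated", "concept_input_driven"), ]
}

relational_selector <- function(condition) {
  function(trials, pref) {
    trials[trials$condition == condition & trials$pic1_id == pref, ]
  }
}

qcomp_named_selector <- function(trials, pref) {
  trials[trials$condition == "question_comparison" &
           !is.na(trials$named_concept) & trials$named_concept == pref, ]
}

#' Cross-condition response/reactivation correlations
#'
#' For every concept neuron, computes mean smoothed z in the response window
#' (0-1000 ms) after questions naming the preferred concept, and in the
#' reactivation window (500-1300 ms) after the second picture of relational
#' main trials and after both pictures of question-comparison trials naming
#' the preferred concept. Pearson correlations are then computed for the
#' four pairings relating main-condition reactivation and preferred-question
#' response strength to question-comparison reactivations.
#'
#' @param session an `rs_session`.
#' @param classes classification table from [classify_units()].
#' @param response_window_ms,reactivation_window_ms analysis windows, ms.
#' @return tibble with one row per pairing: `x`, `y`, `r`, `p`, `n`. The
#'   per-unit window means are attached as attribute `"values"`.
#' @export
condition_response_correlation <- function(session, classes,
                                           response_window_ms = c(0, 1000),
                                           reactivation_window_ms = c(500, 1300)) {
  cu <- concept_units(classes)
  if (nrow(cu) < 3) stop("condition_response_correlation: need >= 3 concept units")
  vals <- purrr::map_dfr(seq_len(nrow(cu)), function(i) {
    uid <- cu$unit_id[i]
    pref <- cu$preferred_pic[i]
    rel_main <- relational_selector("main")(session$trials, pref)
    qn <- qcomp_named_selector(session$trials, pref)
    mz <- function(trials, align, win) {
      zs <- unit_z_series(session, uid, trials, align = align,
                          window_ms = c(-500, 1500))
      if (attr(zs, "excluded")) NA_real_ else window_mean_z(zs, win)
    }
    tibble::tibble(
      unit_id = uid,
      react_main_p2 = mz(rel_main, "pic2", reactivation_window_ms),
      react_qcomp_p1 = mz(qn, "pic1", reactivation_window_ms),
      react_qcomp_p2 = mz(qn, "pic2", reactivation_window_ms),
      resp_qcomp_q = mz(qn, "question", response_window_ms)
    )
  })
  pairings <- tibble::tribble(
    ~x, ~y,
    "react_main_p2", "react_qcomp_p1",
    "react_main_p2", "react_qcomp_p2",
    "resp_qcomp_q", "react_qcomp_p1",
    "resp_qcomp_q", "react_qcomp_p2"
  )
  out <- purrr::pmap_dfr(pairings, function(x, y) {
    xv <- vals[[x]]
    yv <- vals[[y]]
    ok <- stats::complete.cases(xv, yv)
    ct <- stats::cor.test(xv[ok], yv[ok], method = "pearson")
    tibble::tibble(x = x, y = y, r = unname(ct$estimate), p = ct$p.value,
                   n = sum(ok))
  })
  attr(out, "values") <- vals
  out
}

#' Relational group statistics (semantic vs perceptual questions)
#'
#' Per classified unit, the mean reactivation-window z after the second
#' picture of relational main trials, split by question type (the perceptual
#' brightness question versus the semantic questions). Each
#' class x question-type group is tested against zero (Wilcoxon signed
#' rank), and all group pairs are compared with Mann-Whitney tests.
#'
#' @param session an `rs_session`.
#' @param classes classification table from [classify_units()].
#' @param perceptual_question label of the perceptual question.
#' @param reactivation_window_ms reactivation window, ms.
#' @return list with `unit_values` (per unit x question type), `groups`
#'   (per group: n, median, signed-rank p vs zero) and `pairwise`
#'   (Mann-Whitney p per group pair).
#' @export
relational_group_stats <- function(session, classes,
                                   perceptual_question = "Brighter?",
                                   reactivation_window_ms = c(500, 1300)) {
  keep <- classes[classes$label %in%
                    c("concept_reactivated", "concept_input_driven", "visual"), ]
  keep$class_group <- ifelse(keep$label == "visual", "visual", "concept")
  unit_values <- purrr::map_dfr(seq_len(nrow(keep)), function(i) {
    uid <- keep$unit_id[i]
    pref <- keep$preferred_pic[i]
    rel <- relational_selector("main")(session$trials, pref)
    purrr::map_dfr(c("semantic", "perceptual"), function(qt) {
      tr <- if (qt == "perceptual") {
        rel[rel$question_id == perceptual_question, ]
      } else {
        rel[rel$question_id != perceptual_question, ]
      }
      if (nrow(tr) == 0) {
        return(tibble::tibble(unit_id = uid, class_group = keep$class_group[i],
                              question_type = qt, mean_z = NA_real_))
      }
      zs <- unit_z_series(session, uid, tr, align = "pic2",
                          window_ms = c(-500, 1500))
      tibble::tibble(unit_id = uid, class_group = keep$class_group[i],
                     question_type = qt,
                     mean_z = if (attr(zs, "excluded")) NA_real_ else
                       window_mean_z(zs, reactivation_window_ms))
    })
  })
  groups <- dplyr::group_by(unit_values, .data$class_group, .data$question_type)
  groups <- dplyr::summarise(
    groups,
    n = sum(!is.na(.data$mean_z)),
    median_z = stats::median(.data$mean_z, na.rm = TRUE),
    p_vs_zero = if (sum(!is.na(.data$mean_z)) > 0) {
      signed_rank_test(.data$mean_z[!is.na(.data$mean_z)])$p_value
    } else NA_real_,
    .groups = "drop"
  )
  key <- paste(groups$class_group, groups$question_type, sep = ".")
  pairs <- utils::combn(seq_len(nrow(groups)), 2)
  pairwise <- purrr::map_dfr(seq_len(ncol(pairs)), function(k) {
    i <- pairs[1, k]; j <- pairs[2, k]
    xi <- unit_values$mean_z[unit_values$class_group == groups$class_group[i] &
                               unit_values$question_type == groups$question_type[i]]
    xj <- unit_values$mean_z[unit_values$class_group == groups$class_group[j] &
                               unit_values$question_type == groups$question_type[j]]
    xi <- xi[!is.na(xi)]; xj <- xj[!is.na(xj)]
    p <- if (length(xi) > 0 && length(xj) > 0) {
      suppressWarnings(stats::wilcox.test(xi, xj)$p.value)
    } else NA_real_
    tibble::tibble(group_a = key[i], group_b = key[j], p = p)
  })
  list(unit_values = unit_values, groups = groups, pairwise = pairwise)
}

#' Positional effect of the preferred picture
#'
#' Per concept neuron and condition, Hedges' g of the 0-1000 ms response to
#' the preferred picture in second versus first presentation position, and a
#' per region x condition Wilcoxon signed-rank test of g against zero.
#'
#' @param session an `rs_session`.
#' @param classes classification table from [classify_units()].
#' @param response_window_ms response window, ms.
#' @return list with `unit_effects` (per unit x condition g) and `groups`
#'   (per region x condition: n, median g, p vs zero; `NA` when fewer than
#'   two units).
#' @export
positional_effect <- function(session, classes,
                              response_window_ms = c(0, 1000)) {
  cu <- concept_units(classes)
  unit_effects <- purrr::map_dfr(seq_len(nrow(cu)), function(i) {
    uid <- cu$unit_id[i]
    pref <- cu$preferred_pic[i]
    spk <- unit_spikes(session, uid)
    purrr::map_dfr(TRIAL_CONDITIONS, function(cond) {
      tr <- session$trials[session$trials$condition == cond, ]
      second <- window_rates(spk, tr$t_pic2[tr$pic2_id == pref],
                             response_window_ms)
      first <- window_rates(spk, tr$t_pic1[tr$pic1_id == pref],
                            response_window_ms)
      g <- if (length(second) >= 2 && length(first) >= 2) {
        hedges_g(second, first)
      } else NA_real_
      tibble::tibble(unit_id = uid, region = cu$region[i], condition = cond,
                     g = g)
    })
  })
  groups <- dplyr::group_by(unit_effects, .data$region, .data$condition)
  groups <- dplyr::summarise(
    groups,
    n = sum(is.finite(.data$g)),
    median_g = stats::median(.data$g[is.finite(.data$g)]),
    p_vs_zero = if (sum(is.finite(.data$g)) >= 2) {
      signed_rank_test(.data$g[is.finite(.data$g)])$p_value
    } else NA_real_,
    .groups = "drop"
  )
  list(unit_effects = unit_effects, groups = groups)
}

#' Prompt-aligned reactivation analysis
#'
#' In question-comparison trials whose first picture is a concept neuron's
#' preferred stimulus, splits the prompt-aligned z series by whether the
#' response prompt refers back to the first (preferred) or the second
#' (non-preferred) picture, and runs the cluster permutation test between
#' the two prompt variants. The same split is computed for
#' non-visually-selective responder units (mean prompt z > 1 in 0-1500 ms,
#' detection baseline), whose qualifying trials are all question-comparison
#' trials.
#'
#' @param session an `rs_session`.
#' @param classes classification table from [classify_units()].
#' @param window_ms prompt-aligned series window, ms.
#' @param n_perm,seed,cluster_alpha cluster-test parameters (this contrast
#'   runs at cluster alpha 0.05).
#' @return list with elements `concept` and `responders`, each a list of
#'   `z_first`, `z_second` (units x time matrices with `time_ms`
#'   attribute) and `cluster` (an `rs_cluster_test`, `NULL` when fewer than
#'   5 units qualify).
#' @export
prompt_reactivation <- function(session, classes, window_ms = c(-500, 2000),
                                n_perm = 1000, seed = 1L,
                                cluster_alpha = 0.05) {
  qc <- session$trials[session$trials$condition == "question_comparison", ]
  if (nrow(qc) == 0) stop("prompt_reactivation: no question_comparison trials")
  split_series <- function(units_tbl, restrict_pref_first) {
    sel <- function(variant) {
      function(trials, pref) {
        tr <- trials[trials$condition == "question_comparison" &
                       trials$prompt_variant == variant, ]
        if (restrict_pref_first) tr <- tr[tr$pic1_id == pref, ]
        tr
      }
    }
    zf <- z_matrix(session, units_tbl, sel("first_picture"), align = "prompt",
                   window_ms = window_ms)
    zs <- z_matrix(session, units_tbl, sel("second_picture"), align = "prompt",
                   window_ms = window_ms)
    common <- intersect(attr(zf, "unit_id"), attr(zs, "unit_id"))
    zf2 <- zf[match(common, attr(zf, "unit_id")), , drop = FALSE]
    zs2 <- zs[match(common, attr(zs, "unit_id")), , drop = FALSE]
    cl <- if (length(common) >= 5) {
      cluster_permutation(zf2, zs2, cluster_alpha = cluster_alpha,
                          n_perm = n_perm, seed = seed,
                          time_ms = attr(zf, "time_ms"))
    } else NULL
    list(z_first = structure(zf2, unit_id = common,
                             time_ms = attr(zf, "time_ms")),
         z_second = structure(zs2, unit_id = common,
                              time_ms = attr(zf, "time_ms")),
         cluster = cl)
  }
  cu <- concept_units(classes)
  if (nrow(cu) > 0 &&
        !any(qc$pic1_id %in% cu$preferred_pic)) {
    stop("prompt_reactivation: no question_comparison trials with a ",
         "preferred first picture")
  }
  rsp <- classes[classes$label == "non_visual_responder", ]
  list(
    concept = split_series(cu, restrict_pref_first = TRUE),
    responders = split_series(rsp, restrict_pref_first = FALSE)
  )
}
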