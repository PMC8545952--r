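# Trial-category-partitioned pairwise response/reactivation correlations.
#
# For an ordered pair (n1, n2) of concept neurons with distinct preferred
# pictures, every main-condition trial falls into exactly one category by
# comparing the pair's preferred pictures with the presented sequence:
# both_preferred (n1's first, n2's second), only_second_preferred,
# only_first_preferred, or neither. Within each category the trial-wise
# association between n2's response (0-1000 ms after pic2) and n1's
# reactivation (500-1300 ms after pic2) is summarised by Spearman's rho.

PAIR_CATEGORIES <- c("both_preferred", "only_second_preferred",
                     "only_first_preferred", "neither")

#' Categorise main-condition trials for a pair
#'
#' @param trials trial tibble (main condition rows are categorised; others
#'   may be passed and are categorised the same way).
#' @param pref_n1,pref_n2 the two units' preferred pictures (distinct).
#' @return character vector over trials, one of
#'   `"both_preferred"`, `"only_second_preferred"`,
#'   `"only_first_preferred"`, `"neither"`.
#' @export
pair_trial_category <- function(trials, pref_n1, pref_n2) {
  stopifnot(pref_n1 != pref_n2)
  first <- trials$pic1_id == pref_n1
  second <- trials$pic2_id == pref_n2
  dplyr::case_when(
    first & second ~ "both_preferred",
    second ~ "only_second_preferred",
    first ~ "only_first_preferred",
    .default = "neither"
  )
}

#' Enumerate concept-neuron pairs
#'
#' Ordered pairs (n1, n2) of concept neurons with distinct preferred
#' pictures from the same hemisphere but different micro-wire bundles
#' (`locality = "across_bundle"`) or the same bundle (`"within_bundle"`;
#' units on one bundle are assumed to come from different wires after
#' curation).
#'
#' @param classes classification table from [classify_units()].
#' @return tibble with columns `n1`, `n2`, `pref_n1`, `pref_n2`, `locality`.
#' @export
concept_pairs <- function(classes) {
  cu <- concept_units(classes)
  if (nrow(cu) < 2) {
    return(tibble::tibble(n1 = character(0), n2 = character(0),
                          pref_n1 = character(0), pref_n2 = character(0),
                          locality = character(0)))
  }
  g <- tidyr::expand_grid(i = seq_len(nrow(cu)), j = seq_len(nrow(cu)))
  g <- g[g$i != g$j, ]
  out <- tibble::tibble(
    n1 = cu$unit_id[g$i], n2 = cu$unit_id[g$j],
    pref_n1 = cu$preferred_pic[g$i], pref_n2 = cu$preferred_pic[g$j],
    hemi_n1 = cu$hemisphere[g$i], hemi_n2 = cu$hemisphere[g$j],
    bundle_n1 = cu$bundle_id[g$i], bundle_n2 = cu$bundle_id[g$j]
  )
  out <- out[out$pref_n1 != out$pref_n2 & out$hemi_n1 == out$hemi_n2, ]
  out$locality <- ifelse(out$bundle_n1 == out$bundle_n2,
                         "within_bundle", "across_bundle")
  dplyr::select(out, "n1", "n2", "pref_n1", "pref_n2", "locality")
}

# per-trial rate z-scored by the unit's main-condition pre-pic1 baseline
trial_z_rates <- function(session, unit_id, event_times, window_ms) {
  spk <- unit_spikes(session, unit_id)
  mn <- session$trials[session$trials$condition == "main", ]
  base <- window_rates(spk, mn$t_pic1, c(-500, 0))
  mu <- mean(base)
  sd_b <- stats::sd(base)
  if (is.na(sd_b) || sd_b == 0) return(rep(NA_real_, length(event_times)))
  (window_rates(spk, event_times, window_ms) - mu) / sd_b
}

#' Pairwise response/reactivation correlations by trial category
#'
#' For each ordered concept-neuron pair (see [concept_pairs()]), computes
#' per main-condition trial the normalised response of n2 (0-1000 ms after
#' the second picture) and the normalised reactivation of n1 (500-1300 ms
#' after the second picture), splits trials by [pair_trial_category()], and
#' summarises each pair x category with Spearman's rho (categories with
#' fewer than `min_trials` trials are excluded). Per category and locality,
#' rho values are tested against zero with the Wilcoxon signed-rank test,
#' and trials of the `both_preferred` category are pooled across pairs for
#' a trial-level Pearson correlation.
#'
#' @param session an `rs_session`.
#' @param classes classification table from [classify_units()].
#' @param response_window_ms,reactivation_window_ms analysis windows, ms,
#'   both relative to the second-picture onset.
#' @param min_trials minimum trials per pair x category cell (default 4).
#' @return list with `pair_rho` (per pair x category rho), `groups`
#'   (per category x locality: n pairs, median rho, signed-rank p vs zero)
#'   and `pooled` (per locality: trial-level Pearson r and p for
#'   `both_preferred` trials pooled across pairs).
#' @export
pair_response_reactivation <- function(session, classes,
                                       response_window_ms = c(0, 1000),
                                       reactivation_window_ms = c(500, 1300),
                                       min_trials = 4) {
  prs <- concept_pairs(classes)
  mn <- session$trials[session$trials$condition == "main", ]
  per_pair <- purrr::map_dfr(seq_len(nrow(prs)), function(k) {
    cat_k <- pair_trial_category(mn, prs$pref_n1[k], prs$pref_n2[k])
    z2 <- trial_z_rates(session, prs$n2[k], mn$t_pic2, response_window_ms)
    z1 <- trial_z_rates(session, prs$n1[k], mn$t_pic2, reactivation_window_ms)
    purrr::map_dfr(PAIR_CATEGORIES, function(cc) {
      sel <- cat_k == cc & !is.na(z1) & !is.na(z2)
      rho <- if (sum(sel) >= min_trials) {
        suppressWarnings(stats::cor(z2[sel], z1[sel], method = "spearman"))
      } else NA_real_
      tibble::tibble(n1 = prs$n1[k], n2 = prs$n2[k],
                     locality = prs$locality[k], category = cc,
                     n_trials = sum(sel), rho = rho,
                     z2_trials = list(z2[sel]), z1_trials = list(z1[sel]))
    })
  })
  pair_rho <- dplyr::select(per_pair, -"z2_trials", -"z1_trials")
  groups <- dplyr::group_by(pair_rho, .data$category, .data$locality)
  groups <- dplyr::summarise(
    groups,
    n_pairs = sum(!is.na(.data$rho)),
    median_rho = stats::median(.data$rho, na.rm = TRUE),
    p_vs_zero = if (sum(!is.na(.data$rho)) >= 2) {
      signed_rank_test(.data$rho[!is.na(.data$rho)])$p_value
    } else NA_real_,
    .groups = "drop"
  )
  bp <- per_pair[per_pair$category == "both_preferred", ]
  pooled <- purrr::map_dfr(unique(bp$locality), function(loc) {
    x <- unlist(bp$z2_trials[bp$locality == loc])
    y <- unlist(bp$z1_trials[bp$locality == loc])
    if (length(x) >= 3) {
      ct <- stats::cor.test(x, y, method = "pearson")
      tibble::tibble(locality = loc, r = unname(ct$estimate), p = ct$p.value,
                     n_trials = length(x))
    } else {
      tibble::tibble(locality = loc, r = NA_real_, p = NA_real_,
                     n_trials = length(x))
    }
  })
  list(pair_rho = pair_rho, groups = groups, pooled = pooled)
}
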