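# Trial-by-trial cross-correlograms with shift-predictor correction.
#
# Coincidences are counted by discretising each train into 1-ms bins over
# the analysis window and cross-correlating the count vectors (equivalent to
# pair counting at this resolution). Values are coincidences per bin x 1000,
# divided by the geometric mean of the two units' main-condition baseline
# rates. Lag convention: positive lag = the second-listed unit fires after
# the first-listed unit.

# cross-correlation of two equal-length count vectors at lags
# -max_lag..max_lag: c(tau) = sum_t a(t) * b(t + tau), FFT-based.
xcorr_counts <- function(a, b, max_lag) {
  n <- length(a)
  nfft <- stats::nextn(n + max_lag + 1L, 2)
  fa <- stats::fft(c(a, numeric(nfft - n)))
  fb <- stats::fft(c(b, numeric(nfft - n)))
  cc <- Re(stats::fft(Conj(fa) * fb, inverse = TRUE)) / nfft
  # index tau >= 0 at cc[tau + 1]; tau < 0 wraps to cc[nfft + tau + 1]
  c(cc[(nfft - max_lag + 1L):nfft], cc[1L:(max_lag + 1L)])
}

ccg_lag_axis <- function(max_lag_ms) seq(-max_lag_ms, max_lag_ms)

# trials x lags matrix of normalised coincidence values
ccg_trial_matrix <- function(spikes_a, spikes_b, event_times, window_ms,
                             max_lag_ms, norm) {
  A <- bin_counts_1ms(spikes_a, event_times, window_ms)
  B <- bin_counts_1ms(spikes_b, event_times, window_ms)
  t(vapply(seq_len(nrow(A)), function(i) {
    xcorr_counts(A[i, ], B[i, ], max_lag_ms) * 1000 / norm
  }, numeric(2 * max_lag_ms + 1)))
}

#' Trial-by-trial cross-correlogram with shift predictor
#'
#' For each alignment event, counts coincident spikes of the two trains at
#' every 1-ms lag up to `max_lag_ms` over `window_ms`, scales by 1000 and by
#' the geometric mean of the two baseline rates, smooths each trial's
#' correlogram with a Gaussian kernel (sigma 10 ms) and averages over
#' trials. When `predictor = TRUE` (requires >= 2 events) the shift
#' predictor is computed from unit A's trial i against unit B's trial i+1
#' (cyclically closed), boxcar-smoothed over 100 ms, and subtracted to give
#' the corrected correlogram capturing stimulus-independent interaction.
#'
#' @param spikes_a,spikes_b sorted spike times (seconds). Positive lags mean
#'   `spikes_b` fires after `spikes_a`.
#' @param event_times alignment onsets (seconds), one per trial.
#' @param baseline_rates length-2 numeric: the two units' baseline firing
#'   rates (Hz), typically main-condition -500 to 0 ms rates. Both must be
#'   positive; zero-baseline pairs are excluded upstream.
#' @param window_ms coincidence-counting window, ms after the event.
#' @param max_lag_ms maximum lag, ms.
#' @param kernel_sigma_ms Gaussian smoothing of the simultaneous CCG, ms.
#' @param predictor_boxcar_ms boxcar width for the shift predictor, ms.
#' @param predictor compute the shift predictor and corrected CCG?
#' @return tibble of class `rs_ccg` with columns `lag_ms`, `raw` (smoothed,
#'   trial-averaged), `raw_unsmoothed`, and when `predictor` is `TRUE`
#'   `shift_predictor` and `corrected`; attribute `n_trials`.
#' @export
ccg <- function(spikes_a, spikes_b, event_times, baseline_rates,
                window_ms = c(0, 1500), max_lag_ms = 750,
                kernel_sigma_ms = 10, predictor_boxcar_ms = 100,
                predictor = TRUE) {
  n_tr <- length(event_times)
  if (n_tr < 1) stop("ccg: need at least one trial")
  if (any(baseline_rates <= 0)) {
    stop("ccg: zero baseline rate; pair must be excluded")
  }
  norm <- sqrt(prod(baseline_rates))
  M <- ccg_trial_matrix(spikes_a, spikes_b, event_times, window_ms,
                        max_lag_ms, norm)
  raw_unsmoothed <- colMeans(M)
  raw <- colMeans(gauss_smooth(M, kernel_sigma_ms))
  out <- tibble::tibble(lag_ms = ccg_lag_axis(max_lag_ms),
                        raw = raw, raw_unsmoothed = raw_unsmoothed)
  if (predictor) {
    if (n_tr < 2) stop("ccg: shift predictor undefined for a single trial")
    A <- bin_counts_1ms(spikes_a, event_times, window_ms)
    B <- bin_counts_1ms(spikes_b, event_times, window_ms)
    nxt <- c(seq_len(n_tr)[-1], 1L) # trial i paired with i+1, wrapped
    P <- t(vapply(seq_len(n_tr), function(i) {
      xcorr_counts(A[i, ], B[nxt[i], ], max_lag_ms) * 1000 / norm
    }, numeric(2 * max_lag_ms + 1)))
    pred <- boxcar_smooth(colMeans(P), predictor_boxcar_ms)
    out$shift_predictor <- pred
    out$corrected <- raw - pred
  }
  class(out) <- c("rs_ccg", class(out))
  attr(out, "n_trials") <- n_tr
  out
}

# main-condition baseline rate (-500..0 ms before pic1), Hz
main_baseline_rate <- function(session, unit_id) {
  mn <- session$trials[session$trials$condition == "main", ]
  mean(window_rates(unit_spikes(session, unit_id), mn$t_pic1, c(-500, 0)))
}

#' Session-level pair cross-correlogram
#'
#' Wraps [ccg()] for a pair of classified units: qualifying trials of the
#' requested condition are those presenting both preferred pictures
#' (optionally restricted to one picture order), alignment is to the first
#' or second picture onset, and normalisation uses the geometric mean of the
#' two units' main-condition baseline rates.
#'
#' @param session an `rs_session`.
#' @param classes classification table from [classify_units()].
#' @param unit_a,unit_b unit ids; must have distinct preferred pictures.
#' @param condition trial condition (`"main"`, `"no_comparison"`,
#'   `"question_comparison"`, or `"controls"` for both controls pooled).
#' @param align `"pic1"` or `"pic2"`.
#' @param order `"both"`, `"a_first"` (unit A's preferred picture first) or
#'   `"b_first"`.
#' @inheritParams ccg
#' @return an `rs_ccg` tibble (see [ccg()]).
#' @export
pair_ccg <- function(session, classes, unit_a, unit_b, condition = "main",
                     align = "pic2", order = "both", window_ms = c(0, 1500),
                     max_lag_ms = 750, kernel_sigma_ms = 10,
                     predictor = TRUE) {
  pref_a <- classes$preferred_pic[classes$unit_id == unit_a]
  pref_b <- classes$preferred_pic[classes$unit_id == unit_b]
  if (length(pref_a) != 1 || length(pref_b) != 1 ||
        is.na(pref_a) || is.na(pref_b)) {
    stop("pair_ccg: both units need a preferred picture")
  }
  if (pref_a == pref_b) stop("pair_ccg: identical preferred pictures")
  tr <- session$trials
  tr <- if (condition == "controls") {
    tr[tr$condition != "main", ]
  } else tr[tr$condition == condition, ]
  qual <- (tr$pic1_id == pref_a & tr$pic2_id == pref_b) |
    (tr$pic1_id == pref_b & tr$pic2_id == pref_a)
  if (order == "a_first") qual <- qual & tr$pic1_id == pref_a
  if (order == "b_first") qual <- qual & tr$pic1_id == pref_b
  tr <- tr[qual, ]
  if (nrow(tr) == 0) stop("pair_ccg: no qualifying trials")
  align <- match.arg(align, c("pic1", "pic2"))
  base <- c(main_baseline_rate(session, unit_a),
            main_baseline_rate(session, unit_b))
  ccg(unit_spikes(session, unit_a), unit_spikes(session, unit_b),
      tr[[ALIGN_COLS[align]]], baseline_rates = base, window_ms = window_ms,
      max_lag_ms = max_lag_ms, kernel_sigma_ms = kernel_sigma_ms,
      predictor = predictor && nrow(tr) >= 2)
}

#' Cluster contrast of cross-correlograms between conditions
#'
#' Stacks one CCG column per pair for two conditions and runs the cluster
#' permutation test over the lag axis (pairs play the role of units).
#'
#' @param ccgs_a,ccgs_b lists of `rs_ccg` tibbles, one per pair, same pairs
#'   and order in both lists.
#' @param value which column to contrast (`"corrected"` or `"raw"`).
#' @param cluster_alpha cluster-level significance; the corrected-CCG
#'   contrast runs at 0.05.
#' @param alpha_bin,n_perm,seed cluster-test parameters.
#' @return an `rs_cluster_test` over the lag axis.
#' @export
ccg_condition_contrast <- function(ccgs_a, ccgs_b, value = "corrected",
                                   cluster_alpha = 0.05, alpha_bin = 0.01,
                                   n_perm = 1000, seed = 1L) {
  if (length(ccgs_a) < 3 || length(ccgs_a) != length(ccgs_b)) {
    stop("ccg_condition_contrast: need >= 3 pairs, same pairs per condition")
  }
  ma <- do.call(rbind, lapply(ccgs_a, function(x) x[[value]]))
  mb <- do.call(rbind, lapply(ccgs_b, function(x) x[[value]]))
  cluster_permutation(ma, mb, alpha_bin = alpha_bin,
                      cluster_alpha = cluster_alpha, n_perm = n_perm,
                      seed = seed, time_ms = ccgs_a[[1]]$lag_ms)
}
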