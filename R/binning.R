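# The response detector's bin scheme: nineteen overlapping 100-ms bins
# stepped by 50 ms across the 0-1000 ms post-stimulus window, each compared
# against the per-trial baseline rate from -400 to 100 ms.

#' Response-detection bin scheme
#'
#' @param window_ms response window, ms post-stimulus.
#' @param bin_width_ms bin width, ms.
#' @param step_ms bin step, ms.
#' @param baseline_ms baseline window, ms relative to stimulus onset. The
#'   stated baseline (-400 to 100 ms) overlaps stimulus onset by 100 ms and
#'   is kept verbatim.
#' @return a `bin_scheme` list with precomputed bin starts; the default has
#'   19 bins.
#' @export
bin_scheme <- function(window_ms = c(0, 1000), bin_width_ms = 100,
                       step_ms = 50, baseline_ms = c(-400, 100)) {
  starts <- seq(window_ms[1], window_ms[2] - bin_width_ms, by = step_ms)
  structure(list(window_ms = window_ms, bin_width_ms = bin_width_ms,
                 step_ms = step_ms, baseline_ms = baseline_ms,
                 bin_starts_ms = starts, n_bins = length(starts)),
            class = "bin_scheme")
}

# events x bins rate matrix (Hz) plus per-event baseline rates (Hz)
bin_rate_matrix <- function(spikes, event_times, scheme = bin_scheme()) {
  n_ev <- length(event_times)
  if (n_ev == 0) stop("bin_rate_matrix: no events")
  starts <- ms_to_s(scheme$bin_starts_ms)
  width <- ms_to_s(scheme$bin_width_ms)
  a <- rep(event_times, times = scheme$n_bins) +
    rep(starts, each = n_ev)
  counts <- count_spikes(spikes, a, a + width)
  rates <- matrix(counts, nrow = n_ev, ncol = scheme$n_bins) / width
  base_w <- ms_to_s(scheme$baseline_ms)
  baseline <- count_spikes(spikes, event_times + base_w[1],
                           event_times + base_w[2]) / (base_w[2] - base_w[1])
  list(rates = rates, baseline = baseline, scheme = scheme)
}

#' Binned firing rates around events
#'
#' Computes, for one spike train and a set of alignment events, the firing
#' rate (Hz) in every bin of the detection scheme together with the
#' per-event baseline rate. Bins are half-open.
#'
#' @param spikes sorted numeric vector of spike times (seconds).
#' @param event_times event onsets (seconds).
#' @param scheme a [bin_scheme()].
#' @return tibble with columns `event`, `bin`, `t_start_ms`, `rate_hz`,
#'   `baseline_hz`.
#' @export
bin_rates <- function(spikes, event_times, scheme = bin_scheme()) {
  br <- bin_rate_matrix(spikes, event_times, scheme)
  tibble::tibble(
    event = rep(seq_along(event_times), times = scheme$n_bins),
    bin = rep(seq_len(scheme$n_bins), each = length(event_times)),
    t_start_ms = rep(scheme$bin_starts_ms, each = length(event_times)),
    rate_hz = as.vector(br$rates),
    baseline_hz = rep(br$baseline, times = scheme$n_bins)
  )
}

#' Bin-wise signed-rank p-values
#'
#' Runs the paired Wilcoxon signed-rank test of each bin's rate against the
#' per-trial baseline rate across events.
#'
#' @param rates events x bins numeric matrix (Hz).
#' @param baseline per-event baseline rates (Hz).
#' @return numeric vector of two-sided p-values, one per bin.
#' @export
binwise_signed_rank <- function(rates, baseline) {
  apply(rates, 2, function(col) signed_rank_test(col, baseline)$p_value)
}
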