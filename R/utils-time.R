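# Spike times are stored in seconds; every analysis window is specified in
# milliseconds relative to an alignment event. All conversions funnel through
# these helpers so the convention lives in exactly one place.

#' Convert milliseconds to seconds
#' @param ms numeric vector of millisecond values.
#' @return numeric vector of seconds.
#' @keywords internal
ms_to_s <- function(ms) ms / 1000

# Evaluate `code` under a fixed seed, then restore the caller's RNG stream.
# Seeded helpers must not clobber the global stream, or otherwise
# independent simulations interleaved with them become coupled.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv(), inherits = FALSE)
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  code
}

#' Count spikes in half-open windows
#'
#' Windows are half-open `[start, end)`: a spike exactly at `start` is
#' counted, a spike exactly at `end` is not. This prevents double counting
#' when adjacent or overlapping bins share an edge.
#'
#' @param spikes sorted numeric vector of spike times (seconds).
#' @param starts,ends numeric vectors (seconds), recycled to common length.
#' @return integer vector of counts, one per window.
#' @export
#' @examples
#' count_spikes(c(0.1, 0.2, 0.3), starts = 0.1, ends = 0.3) # 2: 0.3 excluded
count_spikes <- function(spikes, starts, ends) {
  stopifnot(is.numeric(spikes), !is.unsorted(spikes))
  n <- max(length(starts), length(ends))
  starts <- rep_len(starts, n)
  ends <- rep_len(ends, n)
  findInterval(ends, spikes, left.open = TRUE) -
    findInterval(starts, spikes, left.open = TRUE)
}

#' Spike times relative to events
#'
#' Collects, for each event, the spikes falling in `window_ms` around it and
#' returns them as a long tibble of relative times in milliseconds.
#'
#' @param spikes sorted numeric vector of spike times (seconds).
#' @param event_times numeric vector of event onsets (seconds).
#' @param window_ms length-2 numeric, half-open window in ms relative to event.
#' @return tibble with columns `event` (index) and `t_ms` (relative time).
#' @export
relative_spike_times <- function(spikes, event_times, window_ms = c(-500, 1500)) {
  lo <- findInterval(event_times + ms_to_s(window_ms[1]), spikes, left.open = TRUE)
  hi <- findInterval(event_times + ms_to_s(window_ms[2]), spikes, left.open = TRUE)
  n <- pmax(hi - lo, 0L)
  idx <- sequence(n, from = lo + 1L)
  ev <- rep.int(seq_along(event_times), n)
  tibble::tibble(event = ev, t_ms = (spikes[idx] - event_times[ev]) * 1000)
}

#' Per-event spike counts binned at 1 ms
#'
#' Returns an events x bins matrix of spike counts on a uniform 1-ms grid
#' covering `window_ms` (half-open bins).
#'
#' @inheritParams relative_spike_times
#' @return integer matrix, `length(event_times)` rows.
#' @keywords internal
bin_counts_1ms <- function(spikes, event_times, window_ms) {
  n_bins <- as.integer(window_ms[2] - window_ms[1])
  rel <- relative_spike_times(spikes, event_times, window_ms)
  bin <- floor(rel$t_ms - window_ms[1]) + 1L
  keep <- bin >= 1L & bin <= n_bins
  m <- matrix(0L, nrow = length(event_times), ncol = n_bins)
  if (any(keep)) {
    tab <- table(factor(rel$event[keep], levels = seq_along(event_times)),
                 factor(bin[keep], levels = seq_len(n_bins)))
    m <- matrix(as.integer(tab), nrow = length(event_times))
  }
  m
}

#' Gaussian smoothing with edge renormalisation
#'
#' Convolves each row of `x` with a Gaussian kernel truncated at +/- 4 sigma.
#' Near the series edges the kernel is renormalised over the available
#' support (no reflection), so endpoints are unbiased averages of the
#' observed mass.
#'
#' @param x numeric vector or matrix (rows smoothed independently).
#' @param sigma kernel standard deviation in samples; 0 returns `x`.
#' @return object of the same shape as `x`.
#' @export
gauss_smooth <- function(x, sigma) {
  if (sigma <= 0) return(x)
  half <- ceiling(4 * sigma)
  k <- stats::dnorm(seq(-half, half), sd = sigma)
  k <- k / sum(k)
  smooth_vec <- function(v) {
    n <- length(v)
    num <- stats::filter(c(rep(0, half), v, rep(0, half)), k, sides = 2)
    den <- stats::filter(c(rep(0, half), rep(1, n), rep(0, half)), k, sides = 2)
    (num / den)[(half + 1):(half + n)]
  }
  if (is.matrix(x)) t(apply(x, 1, smooth_vec)) else as.numeric(smooth_vec(x))
}

#' Boxcar smoothing with edge renormalisation
#' @param x numeric vector.
#' @param width kernel width in samples (rounded up to odd).
#' @return numeric vector, same length.
#' @export
boxcar_smooth <- function(x, width) {
  if (width <= 1) return(x)
  w <- as.integer(width)
  if (w %% 2L == 0L) w <- w + 1L
  half <- (w - 1L) %/% 2L
  k <- rep(1 / w, w)
  n <- length(x)
  num <- stats::filter(c(rep(0, half), x, rep(0, half)), k, sides = 2)
  den <- stats::filter(c(rep(0, half), rep(1, n), rep(0, half)), k, sides = 2)
  as.numeric((num / den)[(half + 1):(half + n)])
}
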