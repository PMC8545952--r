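# Test statistics used by the unit-selection cascade.
#
# The response detector runs a paired Wilcoxon signed-rank test per time bin
# at alpha = 1e-5. At that level the normal approximation is useless for
# small trial counts (at n = 25 even a uniformly positive sample only reaches
# ~1e-5 under the approximation), and rate data are full of ties, so the
# implementation computes the exact null distribution of the signed-rank
# statistic under ties via a shift-algorithm convolution over doubled
# midranks. The normal approximation (with tie and continuity corrections)
# is used only beyond `exact_max_n`.

#' Paired Wilcoxon signed-rank test
#'
#' Two-sided test of median difference zero for paired samples. Zero
#' differences are dropped (standard Wilcoxon convention); ties among the
#' absolute differences receive midranks. For `n <= exact_max_n` retained
#' pairs the p-value comes from the exact sign-flip distribution of the
#' midrank statistic (computed by dynamic convolution, valid under ties);
#' larger samples use the normal approximation with tie-corrected variance
#' and a 0.5 continuity correction.
#'
#' @param x,y paired numeric vectors; `y` omitted tests `x` against zero.
#' @param exact_max_n largest retained-pair count for which the exact
#'   distribution is used (default 25).
#' @return list with `statistic` (W+, sum of positive-signed midranks),
#'   `p_value`, `n_used` (pairs retained after dropping zeros) and `method`.
#' @export
signed_rank_test <- function(x, y = NULL, exact_max_n = 25) {
  d <- if (is.null(y)) x else x - y
  d <- d[!is.na(d) & d != 0]
  n <- length(d)
  if (n == 0) {
    return(list(statistic = NA_real_, p_value = 1, n_used = 0L,
                method = "degenerate"))
  }
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  if (n <= exact_max_n) {
    r2 <- as.integer(round(2 * r)) # doubled midranks are integers
    s <- sum(r2)
    f <- numeric(s + 1L)
    f[1L] <- 1
    for (ri in r2) {
      g <- 0.5 * f
      g[(ri + 1L):(s + 1L)] <- g[(ri + 1L):(s + 1L)] + 0.5 * f[1L:(s + 1L - ri)]
      f <- g
    }
    w2 <- as.integer(round(2 * w))
    p_ge <- sum(f[(w2 + 1L):(s + 1L)])
    p_le <- sum(f[1L:(w2 + 1L)])
    p <- min(1, 2 * min(p_ge, p_le))
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    if (sigma2 <= 0) {
      return(list(statistic = w, p_value = 1, n_used = n,
                  method = "degenerate"))
    }
    z <- (w - mu - sign(w - mu) * 0.5) / sqrt(sigma2)
    p <- 2 * stats::pnorm(-abs(z))
    p <- min(1, p)
    method <- "normal"
  }
  list(statistic = w, p_value = p, n_used = as.integer(n), method = method)
}

#' Simes global test
#'
#' Combines m p-values into a global p-value
#' `min_k p_(k) * m / k` over the order statistics, rejecting when it falls
#' at or below `alpha`. Used to correct the 19 bin-wise signed-rank tests of
#' the response detector.
#'
#' @param pvalues numeric vector of p-values in (0, 1].
#' @param alpha rejection level (default 1e-5, the detector's level).
#' @return list with `global_p` and `reject`.
#' @export
simes_test <- function(pvalues, alpha = 1e-5) {
  if (length(pvalues) == 0) stop("simes_test: empty p-value vector")
  if (any(is.na(pvalues)) || any(pvalues <= 0) || any(pvalues > 1)) {
    stop("simes_test: p-values must lie in (0, 1]")
  }
  m <- length(pvalues)
  global_p <- min(sort(pvalues) * m / seq_len(m))
  list(global_p = global_p, reject = global_p <= alpha)
}

#' Hedges' g effect size
#'
#' Standardised mean difference `(mean(a) - mean(b)) / s_pooled` with the
#' small-sample bias correction `1 - 3 / (4 (n1 + n2) - 9)`. Positive values
#' mean group `a` fires more. A zero pooled SD yields 0 for equal means and
#' signed infinity otherwise.
#'
#' @param a,b numeric vectors (each of length >= 2).
#' @return scalar effect size.
#' @export
hedges_g <- function(a, b) {
  n1 <- length(a)
  n2 <- length(b)
  if (n1 < 2 || n2 < 2) stop("hedges_g: each group needs >= 2 values")
  sp2 <- ((n1 - 1) * stats::var(a) + (n2 - 1) * stats::var(b)) / (n1 + n2 - 2)
  dm <- mean(a) - mean(b)
  if (sp2 == 0) {
    return(if (dm == 0) 0 else sign(dm) * Inf)
  }
  j <- 1 - 3 / (4 * (n1 + n2) - 9)
  j * dm / sqrt(sp2)
}
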