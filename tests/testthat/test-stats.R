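# Oracles for the statistics primitives.

# exhaustive sign-flip oracle for the signed-rank p-value (midranks, two
# sided); valid with ties, feasible for n <= 12
signed_rank_oracle <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- signs %*% r
  p_ge <- mean(w_all >= w_obs)
  p_le <- mean(w_all <= w_obs)
  min(1, 2 * min(p_ge, p_le))
}

test_that("exact signed-rank p-values match the exhaustive sign-flip oracle", {
  set.seed(42)
  for (i in 1:20) {
    n <- sample(4:10, 1)
    # integer-valued data produce plenty of ties and zero differences
    x <- rpois(n, 4)
    y <- rpois(n, 4)
    d <- x - y
    if (all(d == 0)) next
    expect_equal(signed_rank_test(x, y)$p_value, signed_rank_oracle(d),
                 tolerance = 1e-12)
  }
})

test_that("tie-free exact p-values agree with the distribution-based oracle", {
  set.seed(7)
  for (i in 1:10) {
    n <- sample(6:20, 1)
    x <- rnorm(n)
    y <- rnorm(n)
    ours <- signed_rank_test(x, y)$p_value
    ref <- stats::wilcox.test(x, y, paired = TRUE, exact = TRUE)$p.value
    expect_equal(ours, ref, tolerance = 1e-12)
  }
})

test_that("degenerate and large-sample signed-rank behaviour is sane", {
  expect_equal(signed_rank_test(rep(2, 10), rep(2, 10))$p_value, 1)
  # uniformly positive differences at n = 150 must reach far below 1e-5
  res <- signed_rank_test(rep(1, 150) + runif(150), rep(0, 150))
  expect_lt(res$p_value, 1e-10)
  expect_identical(res$method, "normal")
  # a strong planted response is detectable below 1e-5 at 25 trials
  set.seed(1)
  resp <- rpois(25, 20) / 0.1
  base <- rpois(25, 2.5) / 0.5
  expect_lt(signed_rank_test(resp, base)$p_value, 1e-5)
})

test_that("Simes global p equals the brute-force rank minimisation", {
  expect_equal(simes_test(1e-6, alpha = 1e-5)$global_p, 1e-6)
  expect_true(simes_test(1e-6, alpha = 1e-5)$reject)
  # hand evaluation: min(0.02*3/1, 0.03*3/2, 0.04*3/3) = 0.04
  expect_equal(simes_test(c(0.02, 0.03, 0.04))$global_p, 0.04)
  expect_false(simes_test(rep(0.5, 19), alpha = 1e-5)$reject)
  set.seed(3)
  for (i in 1:25) {
    p <- runif(sample(1:19, 1))^2
    m <- length(p)
    brute <- min(vapply(seq_len(m), function(k) sort(p)[k] * m / k, 1))
    expect_equal(simes_test(p)$global_p, brute)
  }
  expect_error(simes_test(numeric(0)), "empty")
  expect_error(simes_test(c(0.5, 0)), "0, 1")
})

test_that("Hedges' g matches the textbook formula and its invariances", {
  g_oracle <- function(a, b) {
    n1 <- length(a); n2 <- length(b)
    sp <- sqrt(((n1 - 1) * var(a) + (n2 - 1) * var(b)) / (n1 + n2 - 2))
    (1 - 3 / (4 * (n1 + n2) - 9)) * (mean(a) - mean(b)) / sp
  }
  a <- c(2, 4); b <- c(1, 3)
  expect_equal(hedges_g(a, b), g_oracle(a, b))
  expect_equal(hedges_g(a, b), (4 / 7) * 1 / sqrt(2))
  set.seed(9)
  for (i in 1:10) {
    a <- rnorm(sample(2:30, 1)); b <- rnorm(sample(2:30, 1))
    expect_equal(hedges_g(a, b), g_oracle(a, b))
    expect_equal(hedges_g(a, b), -hedges_g(b, a))
    # common affine rescaling (change of measurement units) leaves g fixed
    expect_equal(hedges_g(3 * a + 2, 3 * b + 2), hedges_g(a, b))
  }
  expect_equal(hedges_g(c(1, 1), c(1, 1)), 0)
  expect_equal(hedges_g(c(2, 2), c(1, 1)), Inf)
  expect_equal(hedges_g(c(0, 0), c(1, 1)), -Inf)
  expect_error(hedges_g(1, c(1, 2)), ">= 2")
})
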