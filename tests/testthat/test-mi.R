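test_that("entropy matches hand values and validates its input", {
  expect_identical(entropy_bits(rep(1 / 8, 8)), 3)
  expect_identical(entropy_bits(c(1, 0, 0)), 0)
  expect_identical(entropy_bits(c(0.5, 0.5)), 1)
  expect_error(entropy_bits(c(0.6, 0.6)), "sum to 1")
  expect_error(entropy_bits(c(-0.1, 1.1)), "non-negative")
})

test_that("plug-in estimator equals the brute-force double sum", {
  tab <- matrix(c(20, 5, 0, 5, 20, 5, 0, 5, 20), 3, 3, byrow = TRUE)
  smp <- table_to_samples(tab)
  expect_equal(mi_plugin(smp$s, smp$z, response_bins = 3),
               brute_force_mi(tab), tolerance = 1e-12)
  # and on random tables
  set.seed(31)
  for (i in 1:20) {
    tb <- matrix(rpois(24, 8) + 1, 4, 6)
    sm <- table_to_samples(tb)
    expect_equal(mi_plugin(sm$s, sm$z, response_bins = 6),
                 brute_force_mi(tb), tolerance = 1e-12)
  }
})

test_that("a perfect binary channel carries exactly one bit", {
  d <- data.frame(s = rep(0:1, each = 5000))
  d$z <- as.numeric(d$s)
  est <- mi(z ~ s, d, seed = 1)
  expect_equal(est$mi_bits, 1, tolerance = 1e-9)
  expect_identical(est$n_signal_bins, 2L)
})

test_that("independent signal and response estimate to (almost) zero bits", {
  set.seed(32)
  d <- data.frame(s = factor(rep(1:8, each = 1250)), z = rnorm(10000))
  est <- mi(z ~ s, d, boot = 0, seed = 2)
  expect_lte(est$mi_bits, 0.02)
  expect_lt(est$mi_bits, est$plugin_bits)  # correction removes upward bias
})

test_that("estimates respect non-negativity and the log2-bin ceiling", {
  set.seed(33)
  for (i in 1:10) {
    ns <- sample(2:6, 1)
    d <- data.frame(s = factor(sample(ns, 500, replace = TRUE)),
                    z = rnorm(500))
    nb <- sample(2:8, 1)
    est <- mi(z ~ s, d, response_bins = nb, boot = 0, seed = i)
    expect_gte(est$mi_bits, 0)
    expect_lte(est$mi_bits, min(log2(ns), log2(nb)) + 1e-9)
  }
})

test_that("merging adjacent response bins never increases plug-in MI", {
  set.seed(34)
  for (i in 1:50) {
    tab <- matrix(rpois(64, 5), 8, 8)
    full <- brute_force_mi(tab)
    j <- sample(7, 1)
    merged <- tab
    merged[, j] <- merged[, j] + merged[, j + 1]
    merged <- merged[, -(j + 1), drop = FALSE]
    expect_lte(brute_force_mi(merged), full + 1e-12)
  }
})

test_that("estimates converge to the analytic MI of a discretized Gaussian channel", {
  # S uniform on 8 levels mu = 1..8, Z = mu + N(0,1); response binned at the
  # population octiles of the mixture marginal. The true MI of the binned
  # system comes from Gaussian tail probabilities (closed form per cell).
  mu <- 1:8
  marg_cdf <- function(z) mean(pnorm(z, mean = mu))
  oct <- vapply(seq_len(7) / 8, function(q)
    uniroot(function(z) marg_cdf(z) - q, c(-10, 20))$root, numeric(1))
  edges <- c(-Inf, oct, Inf)
  tab <- t(vapply(mu, function(m)
    diff(pnorm(edges, mean = m)), numeric(8))) / 8
  truth <- brute_force_mi(tab * 1e9)      # scale-free in brute_force_mi
  set.seed(35)
  err <- vapply(c(1e3, 1e4, 1e5), function(n) {
    reps <- vapply(1:20, function(r) {
      s <- sample(mu, n, replace = TRUE)
      z <- s + rnorm(n)
      mi(z ~ s, data.frame(s = factor(s), z = z),
         response_bins = 8, boot = 0)$mi_bits
    }, numeric(1))
    abs(mean(reps) - truth)
  }, numeric(1))
  expect_true(all(diff(err) < 0))          # monotone convergence in n
  expect_lt(err[3], 0.01)
})

test_that("quantile signal discretization gives exact equal-count bins", {
  set.seed(36)
  x <- 10^runif(8000, 1, 3)               # log-uniform on [10, 1000]
  f <- discretize_signal(x, bins = 8)
  expect_identical(as.vector(table(f)), rep(1000L, 8))
  expect_length(attr(f, "breaks"), 9)

  # categorical input passes through unchanged
  g <- factor(rep(letters[1:3], 5))
  expect_identical(discretize_signal(g), g)

  # constant signal collapses to one bin and zero information
  d <- data.frame(s = rep(5, 400), z = rnorm(400))
  expect_warning(est <- mi(z ~ s, d, boot = 0, seed = 3), "fewer than 2")
  expect_identical(est$mi_bits, 0)
})

test_that("MI is invariant under strictly monotone response transforms", {
  set.seed(37)
  d <- data.frame(s = factor(rep(1:8, each = 250)))
  d$z <- 100 + as.integer(d$s) * 10 + rnorm(2000, sd = 15)^2
  a <- mi(z ~ s, d, boot = 0, seed = 11)$mi_bits
  d$zl <- log(d$z)
  b <- mi(zl ~ s, d, boot = 0, seed = 11)$mi_bits
  d$za <- 3 * d$z + 7
  cc <- mi(za ~ s, d, boot = 0, seed = 11)$mi_bits
  # equal-count bins are rank-based, so the estimate is exactly invariant
  expect_identical(a, b)
  expect_identical(a, cc)
})

test_that("sparse stimulus levels trigger the documented warning", {
  set.seed(38)
  d <- data.frame(s = factor(c(rep("a", 200), rep("b", 3))),
                  z = rnorm(203))
  expect_warning(mi(z ~ s, d, response_bins = 4, boot = 0, seed = 4),
                 "fewer samples than response bins")
})

test_that("bootstrap SE and confidence interval behave sensibly", {
  set.seed(39)
  d <- data.frame(s = rep(0:1, each = 1000))
  d$z <- d$s + rnorm(2000, sd = 0.8)
  est <- mi(z ~ s, d, boot = 60, seed = 5)
  expect_true(is.finite(est$se_bits) && est$se_bits > 0)
  ci <- confint(est)
  expect_lt(ci[1], est$mi_bits)
  expect_gt(ci[2], est$mi_bits)
  expect_gte(ci[1], 0)
  expect_output(print(est), "Mutual information")
  expect_output(summary(est), "plug-in")
})
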