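test_that("perturbation tags map to the documented parameter changes", {
  m <- erk_model(fast_fb = 1.66, slow_fb = 100)
  expect_identical(apply_perturbation(m, "control"), m)
  fb <- apply_perturbation(m, "feedback_broken")
  expect_identical(fb$params$fast_fb, 0)
  expect_identical(fb$params$slow_fb, 0)
  up <- apply_perturbation(m, "slow_fb_increased", factor = 4)
  expect_identical(up$params$slow_fb, 400)
  expect_error(apply_perturbation(m, "slow_fb_increased", factor = 0.5))
  rm_ <- apply_perturbation(m, "slow_fb_removed")
  expect_true(rm_$chx)
  expect_identical(rm_$params, m$params)
  expect_error(apply_perturbation(m, "nonsense"))
})

test_that("the synthesis-block analogue zeroes phosphatase production after onset", {
  m <- apply_perturbation(erk_model(1.66, 100), "slow_fb_removed")
  # the stored network still carries production (pre-equilibration uses it)
  expect_gt(m$network$rates[m$network$reaction_names == "pase2_prod"], 0)
  # but a stimulated run from a P2-rich state only ever loses P2
  set.seed(51)
  st <- equilibrate(m, total_sub = 7943)
  st[["S"]] <- 1000L
  net_stim <- m$network
  net_stim$rates[net_stim$reaction_names == "pase2_prod"] <- 0
  tr <- gillespie(net_stim, st, t_end = 3600, record_times = c(600, 3600))
  expect_true(all(diff(c(st[["P2"]], tr$states[, "P2"])) <= 0))
})

test_that("a 1x1 feedback grid equals the direct ensemble + MI composition", {
  seed <- 9
  g <- feedback_grid(fast_fb = 1.66, slow_fb = 100, times = 60, nsim = 120,
                     seed = seed, boot = 20)
  cell_seed <- erksense:::derive_seed(seed, 1)
  m <- erk_model(fast_fb = 1.66, slow_fb = 100)
  ens <- simulate(m, nsim = 120, seed = cell_seed, times = 60)
  est <- mi(pSub ~ S, ens, signal_bins = 8, boot = 20,
            seed = erksense:::derive_seed(cell_seed, 1))
  rng <- response_range(ens, pSub ~ S, time = NULL, signal_bins = 8)$range
  expect_identical(g$mi_bits, est$mi_bits)
  expect_identical(g$mi_se, est$se_bits)
  expect_identical(g$response_range, rng)
  expect_true(all(is.na(g$error)))
})

test_that("feedback grids are reproducible and order-independent", {
  g1 <- feedback_grid(fast_fb = c(1.66, 330), slow_fb = 1, times = 30,
                      nsim = 100, seed = 4, boot = 10)
  g2 <- feedback_grid(fast_fb = c(1.66, 330), slow_fb = 1, times = 30,
                      nsim = 100, seed = 4, boot = 10)
  expect_identical(g1, g2)
  expect_identical(nrow(g1), 2L)
  expect_true(all(g1$mi_bits >= 0 & g1$mi_bits <= 3))
  m <- plot(g1, time = 30)
  expect_identical(dim(m), c(2L, 1L))
})

test_that("population summaries reproduce group means and response range", {
  # constant response: range 0
  d <- data.frame(S = rep(c(10, 100, 1000), each = 50), pSub = 5,
                  time_min = 60)
  ps <- population_summary(d)
  expect_true(all(ps$mean == 5))
  expect_identical(attr(ps, "range")$range, 0)

  # noiseless synthetic cells: grouped means equal the configured curve
  cfg <- noiseless_config(cells = 50)
  cells <- simulate_cells(cfg, seed = 52)
  ps2 <- population_summary(cells, response ~ stimulus)
  expected <- vapply(sort(unique(cells$stimulus)), function(cc)
    mean_response(cc, 5, cfg) + 135, numeric(1))
  expect_equal(sort(ps2$mean), sort(expected), tolerance = 1e-9)

  # simulated ensemble: range equals a brute-force recomputation
  m <- erk_model(fast_fb = 1.66, slow_fb = 1)
  ens <- simulate(m, nsim = 150, seed = 53, times = c(30, 60))
  rng <- response_range(ens)
  for (tt in c(30, 60)) {
    sub <- ens[ens$time_min == tt, ]
    f <- discretize_signal(sub$S, 8)
    mm <- tapply(sub$pSub, f, mean)
    expect_equal(rng$range[rng$time_min == tt], max(mm) - min(mm),
                 tolerance = 1e-9)
  }
})

test_that("MI time courses track the kinetic profile of the assay", {
  cfg <- assay_config(times = c(5, 360), cells_per_condition = 800)
  cells <- simulate_cells(cfg, seed = 54)
  tc <- mi_timecourse(cells, response ~ stimulus, boot = 40, seed = 11)
  expect_identical(tc$time_min, c(5, 360))
  # transient kinetics: early information exceeds late information (3 SE)
  margin <- 3 * sqrt(sum(tc$se_bits^2))
  expect_gt(tc$mi_bits[1] - tc$mi_bits[2], margin)

  # noiseless assay: 3 bits at every time point
  ncells <- simulate_cells(noiseless_config(times = c(5, 60)), seed = 55)
  ntc <- mi_timecourse(ncells, response ~ stimulus, boot = 0, seed = 11)
  expect_equal(ntc$mi_bits, c(3, 3), tolerance = 0.01)

  # single time point and missing time point
  one <- mi_timecourse(cells, response ~ stimulus, times = 5, boot = 0)
  expect_identical(nrow(one), 1L)
  expect_warning(mi_timecourse(cells, response ~ stimulus, times = c(5, 99),
                               boot = 0), "no samples")
})
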