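test_that("expected response follows the Hill x kinetic structure", {
  cfg <- assay_config()
  expect_identical(mean_response(0, 5, cfg), cfg$basal)
  expect_identical(mean_response(0, 360, cfg), cfg$basal)
  # saturating stimulus at the kinetic peak approaches basal + amplitude
  tpk <- with(cfg, rise_min * decay_min / (decay_min - rise_min) *
                log(decay_min / rise_min))
  expect_equal(mean_response(1, tpk, cfg), cfg$basal + cfg$amplitude,
               tolerance = 1e-6)
  # transient profile: saturating response at 360 min is < 20% of 5 min
  r5 <- mean_response(1e-6, 5, cfg) - cfg$basal
  r360 <- mean_response(1e-6, 360, cfg) - cfg$basal
  expect_lt(r360, 0.2 * r5)
  # sustained profile plateaus instead
  cfs <- assay_config(profile = "sustained")
  s360 <- mean_response(1e-6, 360, cfs) - cfs$basal
  s5 <- mean_response(1e-6, 5, cfs) - cfs$basal
  expect_gt(s360, 0.9 * s5)
})

test_that("a noiseless 8-level assay transmits exactly 3 bits", {
  cells <- simulate_cells(noiseless_config(), seed = 41)
  est <- mi(response ~ stimulus, cells, seed = 6, boot = 0)
  expect_equal(est$mi_bits, 3, tolerance = 0.01)
})

test_that("a flat assay (zero amplitude) transmits nothing", {
  cfg <- assay_config(amplitude = 0, times = 5)
  cells <- simulate_cells(cfg, seed = 42)
  est <- mi(response ~ stimulus, cells, seed = 6, boot = 0)
  expect_lte(est$mi_bits, 0.02)
})

test_that("default heterogeneous assay sits strictly between 0 and 3 bits and noise lowers MI", {
  cfg <- assay_config(times = 5)
  cells <- simulate_cells(cfg, seed = 43)
  est <- mi(response ~ stimulus, cells, seed = 6, boot = 30)
  expect_gt(est$mi_bits, 0.1)
  expect_lt(est$mi_bits, 3)
  cfg2 <- assay_config(times = 5, noise_cv = 2 * cfg$noise_cv,
                       amp_cv = 2 * cfg$amp_cv)
  cells2 <- simulate_cells(cfg2, seed = 43)
  est2 <- mi(response ~ stimulus, cells2, seed = 6, boot = 30)
  expect_lt(est2$mi_bits, est$mi_bits)
})

test_that("background is added, never subtracted, and generation is deterministic", {
  cfg <- assay_config(times = c(5, 60))
  a <- simulate_cells(cfg, seed = 44)
  b <- simulate_cells(cfg, seed = 44)
  expect_identical(a, b)
  expect_true(all(a$response >= cfg$background[1]))
  expect_identical(sort(unique(a$time_min)), c(5, 60))
  expect_equal(length(unique(a$well)),
               cfg$wells * length(cfg$stimulus_levels) * 2)
  expect_equal(nrow(a),
               cfg$cells_per_condition * length(cfg$stimulus_levels) * 2)
})

test_that("MI of generated data is invariant under monotone response transforms", {
  cfg <- assay_config(times = 5, cells_per_condition = 500)
  cells <- simulate_cells(cfg, seed = 45)
  a <- mi(response ~ stimulus, cells, seed = 8, boot = 0)$mi_bits
  cells$logr <- log(cells$response)
  b <- mi(logr ~ stimulus, cells, seed = 8, boot = 0)$mi_bits
  expect_identical(a, b)
})

test_that("corrected MI is stable in the number of cells per condition", {
  e1 <- mi(response ~ stimulus,
           simulate_cells(assay_config(times = 5, cells_per_condition = 1000),
                          seed = 46), seed = 9, boot = 40)
  e2 <- mi(response ~ stimulus,
           simulate_cells(assay_config(times = 5, cells_per_condition = 10000),
                          seed = 46), seed = 9, boot = 40)
  se <- sqrt(e1$se_bits^2 + e2$se_bits^2)
  expect_lt(abs(e1$mi_bits - e2$mi_bits), 3 * se)
})

test_that("receptor covariate scales the response saturably", {
  cfg <- assay_config(cells_per_condition = 5000, receptor = TRUE)
  cells <- simulate_receptor_cells(cfg, seed = 47)
  expect_identical(length(unique(cells$stimulus)), 1L)
  expect_true(all(c("receptor", "response") %in% names(cells)))
  # rank into bins of 500 cells with increasing receptor level:
  # binned mean response must be non-decreasing (3 SE slack per step)
  ord <- order(cells$receptor)
  bins <- split(ord, ceiling(seq_along(ord) / 500))
  m <- vapply(bins, function(i) mean(cells$response[i]), numeric(1))
  s <- vapply(bins, function(i)
    sd(cells$response[i]) / sqrt(length(i)), numeric(1))
  step_se <- sqrt(s[-1]^2 + s[-length(s)]^2)
  expect_true(all(diff(m) > -3 * step_se))
  expect_gt(m[length(m)], m[1])
  # and receptor level carries information about the response
  est <- mi(response ~ receptor, cells, seed = 10, boot = 0)
  expect_gt(est$mi_bits, 0.1)
})

test_that("disabling receptor scaling makes receptor and response independent", {
  cfg <- assay_config(cells_per_condition = 10000, receptor = TRUE,
                      receptor_scaling = FALSE)
  cells <- simulate_receptor_cells(cfg, seed = 48)
  est <- mi(response ~ receptor, cells, seed = 10, boot = 0)
  expect_lte(est$mi_bits, 0.02)
})

test_that("assay configuration is validated", {
  expect_error(assay_config(background = c(150, 120)))
  expect_error(assay_config(ec50 = 0))
  expect_error(assay_config(rise_min = 30, decay_min = 25))
  expect_error(assay_config(times = c(-5, 60)))
})
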