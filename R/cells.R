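#' Configuration of a synthetic single-cell imaging assay
#'
#' Describes a phenomenological generator of single-cell imaging-like data:
#' a population of cells, each measured once (snapshot) at one
#' (stimulus, time) condition, whose expected response follows a Hill
#' dose-response curve modulated by a kinetic profile, with log-normal
#' cell-to-cell heterogeneity on amplitude and EC50, multiplicative log-normal
#' measurement noise, and an additive unsubtracted background in arbitrary
#' fluorescence units (AFU). Defaults emulate a GnRH-stimulated nuclear ppERK
#' assay: 8 stimulus levels (0 plus 1e-12 to 1e-6 M in decade steps), time
#' points 5--360 min, a transient kinetic profile (maximal near 5 min, near
#' basal by 60--360 min) and a 120--150 AFU background that is never
#' subtracted. A `sustained` profile (fast rise to a plateau) emulates
#' phorbol-ester-like kinetics.
#'
#' @param stimulus_levels stimulus concentrations (M), including 0.
#' @param times measurement time points, minutes.
#' @param cells_per_condition cells per (stimulus, time) condition.
#' @param wells number of replicate wells per condition (cells are assigned
#'   round-robin; wells are pooled before analysis, as in high-content
#'   imaging practice).
#' @param background range (min, max) of the additive uniform background, AFU.
#' @param basal basal response above background, AFU.
#' @param amplitude maximal stimulus-driven response above basal, AFU.
#' @param ec50 half-maximal stimulus concentration, M.
#' @param hill Hill slope.
#' @param profile kinetic profile: `"transient"` (fast rise, exponential
#'   decay) or `"sustained"` (fast rise, plateau), unit peak either way.
#' @param rise_min,decay_min rise and decay time constants, minutes.
#' @param amp_cv log-normal coefficient of variation of the per-cell
#'   amplitude factor (mean 1).
#' @param ec50_sdlog log-normal SD (natural log scale) of the per-cell EC50
#'   factor (median 1).
#' @param noise_cv log-normal CV of the multiplicative measurement noise.
#' @param receptor logical: draw a per-cell receptor expression covariate
#'   (log-normal, AFU) that scales the response amplitude saturably?
#' @param receptor_meanlog,receptor_sdlog log-normal law of the receptor AFU.
#' @param receptor_r50 receptor level giving half-maximal amplitude scaling.
#' @param receptor_scaling if FALSE the receptor covariate is drawn but does
#'   not influence the response (independence control).
#' @return validated list of class `assay_config`.
#' @export
assay_config <- function(stimulus_levels = c(0, 10^seq(-12, -6)),
                         times = c(5, 15, 30, 60, 360),
                         cells_per_condition = 1000,
                         wells = 3,
                         background = c(120, 150),
                         basal = 200,
                         amplitude = 300,
                         ec50 = 1e-9,
                         hill = 1,
                         profile = c("transient", "sustained"),
                         rise_min = 2,
                         decay_min = 25,
                         amp_cv = 0.5,
                         ec50_sdlog = 0.35,
                         noise_cv = 0.2,
                         receptor = FALSE,
                         receptor_meanlog = log(500),
                         receptor_sdlog = 0.6,
                         receptor_r50 = 500,
                         receptor_scaling = TRUE) {
  profile <- match.arg(profile)
  cfg <- as.list(environment())
  stopifnot(all(cfg$stimulus_levels >= 0), length(cfg$stimulus_levels) >= 1,
            all(cfg$times > 0), cfg$cells_per_condition >= 1,
            cfg$wells >= 1, length(cfg$background) == 2,
            all(cfg$background >= 0), diff(cfg$background) >= 0,
            cfg$basal >= 0, cfg$amplitude >= 0, cfg$ec50 > 0,
            cfg$hill > 0, cfg$rise_min > 0, cfg$decay_min > cfg$rise_min,
            cfg$amp_cv >= 0, cfg$ec50_sdlog >= 0, cfg$noise_cv >= 0)
  structure(cfg, class = "assay_config")
}

# Unit-peak kinetic profile at time t (minutes).
kinetic_profile <- function(t, config) {
  r <- config$rise_min
  d <- config$decay_min
  if (config$profile == "transient") {
    tpk <- r * d / (d - r) * log(d / r)
    peak <- exp(-tpk / d) - exp(-tpk / r)
    (exp(-t / d) - exp(-t / r)) / peak
  } else {
    1 - exp(-t / r)
  }
}

hill_fraction <- function(conc, ec50, hill) {
  ifelse(conc <= 0, 0, conc^hill / (conc^hill + ec50^hill))
}

#' Expected (noise-free) response of the synthetic assay
#'
#' `basal + amplitude * kinetic(t) * Hill(conc)` in AFU above background.
#' `Hill(0) = 0`, so zero stimulus returns the basal level; a saturating
#' stimulus at the kinetic peak returns `basal + amplitude`.
#'
#' @param conc stimulus concentration, M.
#' @param t time, minutes.
#' @param config an [assay_config()].
#' @return expected AFU (without background or noise).
#' @export
mean_response <- function(conc, t, config) {
  stopifnot(inherits(config, "assay_config"))
  config$basal + config$amplitude * kinetic_profile(t, config) *
    hill_fraction(conc, config$ec50, config$hill)
}

#' Generate a synthetic single-cell imaging dataset
#'
#' For each (stimulus level, time) condition, draws `cells_per_condition`
#' independent cells. Per cell: a log-normal amplitude factor (mean 1), a
#' log-normal EC50 factor (median 1) and, if enabled, a log-normal receptor
#' level that scales the amplitude saturably (normalized to 1 at the median
#' receptor level). The measured response is
#' `(basal + amp_i * amplitude * kinetic(t) * Hill(conc; ec50_i)) * noise +
#' background`, with multiplicative log-normal noise (mean 1) and an additive
#' uniform background draw. The background is never subtracted, so every
#' generated AFU is at least the background minimum. Deterministic given
#' `seed`.
#'
#' @param config an [assay_config()].
#' @param seed integer seed (optional; uses and advances the current RNG
#'   stream when NULL).
#' @return data.frame with columns `cell_id`, `well`, `stimulus`, `time_min`,
#'   `response` and (if enabled) `receptor`.
#' @export
simulate_cells <- function(config, seed = NULL) {
  stopifnot(inherits(config, "assay_config"))
  with_seed(seed, {
    conditions <- expand.grid(stimulus = config$stimulus_levels,
                              time_min = config$times,
                              KEEP.OUT.ATTRS = FALSE)
    m <- config$cells_per_condition
    amp_sdlog <- sqrt(log(1 + config$amp_cv^2))
    noise_sdlog <- sqrt(log(1 + config$noise_cv^2))
    out <- vector("list", nrow(conditions))
    next_id <- 0L
    for (ci in seq_len(nrow(conditions))) {
      conc <- conditions$stimulus[ci]
      t <- conditions$time_min[ci]
      amp_f <- if (config$amp_cv > 0)
        rlnorm(m, -amp_sdlog^2 / 2, amp_sdlog) else rep(1, m)
      ec50_i <- config$ec50 *
        (if (config$ec50_sdlog > 0) rlnorm(m, 0, config$ec50_sdlog)
         else rep(1, m))
      rec <- NULL
      rec_scale <- 1
      if (config$receptor) {
        rec <- rlnorm(m, config$receptor_meanlog, config$receptor_sdlog)
        if (config$receptor_scaling) {
          # saturating scaling, normalized to 1 at receptor_r50
          rr <- rec / config$receptor_r50
          rec_scale <- 2 * rr / (1 + rr)
        }
      }
      mu <- config$basal + rec_scale * amp_f * config$amplitude *
        kinetic_profile(t, config) * hill_fraction(conc, ec50_i, config$hill)
      noise <- if (config$noise_cv > 0)
        rlnorm(m, -noise_sdlog^2 / 2, noise_sdlog) else rep(1, m)
      bg <- runif(m, config$background[1], config$background[2])
      df <- data.frame(
        cell_id = next_id + seq_len(m),
        well = paste0("c", ci, "w", rep_len(seq_len(config$wells), m)),
        stimulus = conc, time_min = t,
        response = mu * noise + bg)
      if (config$receptor) df$receptor <- rec
      next_id <- next_id + m
      out[[ci]] <- df
    }
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res
  })
}

#' Generate a receptor-covariate dataset at a fixed saturating stimulus
#'
#' Convenience wrapper around [simulate_cells()] with the receptor covariate
#' enabled and the assay restricted to the highest configured stimulus level
#' at the earliest (peak) time point: the setting in which mutual information
#' between per-cell receptor expression and response is measured. Response
#' amplitude scales monotonically (saturably) with receptor level unless
#' `receptor_scaling` is disabled in the config.
#'
#' @inheritParams simulate_cells
#' @return data.frame as [simulate_cells()], with a `receptor` column, single
#'   stimulus level and time point.
#' @export
simulate_receptor_cells <- function(config, seed = NULL) {
  stopifnot(inherits(config, "assay_config"))
  cfg <- config
  cfg$receptor <- TRUE
  cfg$stimulus_levels <- max(config$stimulus_levels)
  cfg$times <- min(config$times)
  simulate_cells(cfg, seed = seed)
}
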