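#' Perturbation analogues of the experimental feedback manipulations
#'
#' Returns a modified [erk_model()] implementing one of the in-silico
#' analogues of the wet-lab feedback perturbations:
#'
#' * `control`: parameters unchanged.
#' * `feedback_broken`: `fast_fb = 0` and `slow_fb = 0` -- the analogue of
#'   expressing catalytically inactive kinase, which breaks both
#'   ERK-mediated loops.
#' * `slow_fb_increased`: promoter copy number multiplied by `factor`
#'   (>= 1) -- the analogue of driving extra inducible-phosphatase expression.
#' * `slow_fb_removed`: inducible-phosphatase production disabled from
#'   stimulus onset while pre-equilibration is unchanged -- the analogue of a
#'   protein-synthesis block added shortly before stimulation, so
#'   pre-existing basal phosphatase persists but no more is induced.
#'
#' @param model an [erk_model()].
#' @param tag perturbation tag (see above).
#' @param factor multiplier for `slow_fb_increased` (>= 1).
#' @return an [erk_model()] with modified parameters.
#' @export
apply_perturbation <- function(model,
                               tag = c("control", "feedback_broken",
                                       "slow_fb_increased", "slow_fb_removed"),
                               factor = 4) {
  stopifnot(inherits(model, "erk_model"))
  tag <- match.arg(tag)
  p <- model$params
  switch(tag,
    control = model,
    feedback_broken = {
      p$fast_fb <- 0
      p$slow_fb <- 0
      erk_model(params = do.call(erk_params, unclass(p)))
    },
    slow_fb_increased = {
      stopifnot(factor >= 1)
      p$slow_fb <- round(p$slow_fb * factor)
      erk_model(params = do.call(erk_params, unclass(p)))
    },
    slow_fb_removed = {
      m <- model
      m$chx <- TRUE
      m
    })
}

#' Mutual-information time course from paired samples
#'
#' Splits a table of paired (stimulus, response) records by time point and
#' estimates MI at each with shared estimator settings. Time points with no
#' data are skipped with a warning.
#'
#' @param data data.frame with a time column and the formula variables
#'   (e.g. an [simulate.erk_model()] ensemble or [simulate_cells()] output).
#' @param formula `response ~ stimulus`, default `pSub ~ S` (ensembles); use
#'   e.g. `response ~ stimulus` for synthetic imaging tables.
#' @param time name of the time column (minutes).
#' @param times which time points to analyse (default: all present).
#' @param ... passed to [mi()] (bins, correction, boot, seed ...).
#' @return data.frame with columns `time_min`, `mi_bits`, `se_bits`, `n`.
#' @export
mi_timecourse <- function(data, formula = pSub ~ S, time = "time_min",
                          times = NULL, ...) {
  stopifnot(time %in% names(data))
  if (is.null(times)) times <- sort(unique(data[[time]]))
  rows <- lapply(times, function(tt) {
    sub <- data[data[[time]] == tt, , drop = FALSE]
    if (nrow(sub) == 0L) {
      warning("no samples at time ", tt, " min; skipped")
      return(NULL)
    }
    est <- mi(formula, sub, ...)
    data.frame(time_min = tt, mi_bits = est$mi_bits, se_bits = est$se_bits,
               n = est$n)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Population-averaged response summary and response range
#'
#' Grouped means and standard errors of the response per (stimulus, time),
#' i.e. the population-averaged dose-response curves, plus the response range
#' (max - min of the signal-binned means) per time point -- the
#' population-level counterpart of the information measure. A continuous
#' stimulus is first discretized with [discretize_signal()].
#'
#' @param data data.frame of paired records.
#' @param formula `response ~ stimulus`, default `pSub ~ S`.
#' @param time name of the time column; set NULL if there is none.
#' @param signal_bins bins for a continuous stimulus.
#' @return data.frame with columns `stimulus`, `time_min` (if present), `n`,
#'   `mean`, `se`; attribute `range` holds a per-time data.frame of response
#'   ranges.
#' @export
population_summary <- function(data, formula = pSub ~ S, time = "time_min",
                               signal_bins = 8) {
  stopifnot(nrow(data) > 0)
  mf <- stats::model.frame(formula, data, na.action = stats::na.fail)
  z <- mf[[1]]
  s <- discretize_signal(mf[[2]], bins = signal_bins)
  g <- if (!is.null(time) && time %in% names(data))
    data.frame(stimulus = s, time_min = data[[time]])
  else data.frame(stimulus = s)
  agg <- aggregate(z, g, function(v) c(n = length(v), mean = mean(v),
                                       se = sd(v) / sqrt(length(v))))
  out <- cbind(agg[setdiff(names(agg), "x")], as.data.frame(agg$x))
  if ("time_min" %in% names(out)) {
    rng <- aggregate(mean ~ time_min, out,
                     function(v) max(v) - min(v))
    names(rng)[2] <- "range"
  } else {
    rng <- data.frame(range = max(out$mean) - min(out$mean))
  }
  attr(out, "range") <- rng
  out
}

#' Response range of an ensemble or cell table
#'
#' max - min of the signal-binned mean response, per time point.
#'
#' @inheritParams population_summary
#' @return data.frame with `time_min` (if present) and `range`.
#' @export
response_range <- function(data, formula = pSub ~ S, time = "time_min",
                           signal_bins = 8) {
  attr(population_summary(data, formula, time, signal_bins), "range")
}

#' Sweep feedback strengths and map information transfer
#'
#' For every cell of a (fast feedback, slow feedback) grid, simulates an
#' ensemble of model runs ([simulate.erk_model()]), estimates the mutual
#' information between the log-uniformly drawn signal and the phosphorylated
#' substrate at each readout time (signal discretized into 8 equal-count
#' log-quantile bins), and computes the population response range (max - min
#' of the signal-binned mean response). Grid cells whose simulation fails are
#' marked in the `error` column rather than dropped. Deterministic given
#' `seed`; per-cell seeds are derived from `seed` and the cell index, so the
#' result does not depend on evaluation order.
#'
#' @param fast_fb,slow_fb vectors of feedback strengths defining the grid
#'   (defaults: 9 log-spaced values over 10^-0.5..10^3.5 and 10^0..10^4).
#' @param times readout times, minutes.
#' @param nsim runs per grid cell; at least 100 is advisable for MI
#'   estimation (a warning is raised below that).
#' @param seed root seed.
#' @param params base [erk_params()] whose feedback fields are overridden
#'   per grid cell.
#' @param signal_bins signal discretization for the MI estimate.
#' @param boot bootstrap resamples per MI estimate.
#' @return data.frame of class `feedback_grid` with columns `fast_fb`,
#'   `slow_fb`, `time_min`, `mi_bits`, `mi_se`, `response_range`, `n_runs`,
#'   `error`.
#' @export
feedback_grid <- function(fast_fb = 10^seq(-0.5, 3.5, length.out = 9),
                          slow_fb = round(10^seq(0, 4, length.out = 9)),
                          times = c(5, 60, 180),
                          nsim = 500,
                          seed = 1,
                          params = erk_params(),
                          signal_bins = 8,
                          boot = 50) {
  stopifnot(length(fast_fb) >= 1, length(slow_fb) >= 1)
  if (nsim < 100)
    warning("fewer than 100 runs per grid cell: MI estimates will be noisy")
  cells <- expand.grid(fast_fb = fast_fb, slow_fb = slow_fb,
                       KEEP.OUT.ATTRS = FALSE)
  rows <- vector("list", nrow(cells))
  for (ci in seq_len(nrow(cells))) {
    ff <- cells$fast_fb[ci]
    sf <- cells$slow_fb[ci]
    cell_seed <- derive_seed(seed, ci)
    res <- tryCatch({
      pp <- unclass(params)
      pp$fast_fb <- ff
      pp$slow_fb <- sf
      model <- erk_model(params = do.call(erk_params, pp))
      ens <- simulate(model, nsim = nsim, seed = cell_seed, times = times)
      per_time <- lapply(times, function(tt) {
        sub <- ens[ens$time_min == tt, ]
        est <- mi(pSub ~ S, sub, signal_bins = signal_bins, boot = boot,
                  seed = derive_seed(cell_seed, match(tt, times)))
        rng <- response_range(sub, pSub ~ S, time = NULL,
                              signal_bins = signal_bins)$range
        data.frame(fast_fb = ff, slow_fb = sf, time_min = tt,
                   mi_bits = est$mi_bits, mi_se = est$se_bits,
                   response_range = rng, n_runs = nsim,
                   error = NA_character_)
      })
      do.call(rbind, per_time)
    }, error = function(e) {
      data.frame(fast_fb = ff, slow_fb = sf, time_min = times,
                 mi_bits = NA_real_, mi_se = NA_real_,
                 response_range = NA_real_, n_runs = nsim,
                 error = conditionMessage(e))
    })
    rows[[ci]] <- res
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "seed") <- seed
  attr(out, "nsim") <- nsim
  class(out) <- c("feedback_grid", "data.frame")
  out
}

#' Heat map of a feedback grid surface
#'
#' @param x a [feedback_grid()] result.
#' @param time which readout time (minutes) to plot.
#' @param what `"mi_bits"` or `"response_range"`.
#' @param ... passed to [graphics::image()].
#' @return invisibly, the plotted matrix.
#' @export
plot.feedback_grid <- function(x, time = NULL,
                               what = c("mi_bits", "response_range"), ...) {
  what <- match.arg(what)
  if (is.null(time)) time <- x$time_min[1]
  sub <- x[x$time_min == time, ]
  ff <- sort(unique(sub$fast_fb))
  sf <- sort(unique(sub$slow_fb))
  m <- matrix(NA_real_, length(ff), length(sf))
  for (i in seq_len(nrow(sub)))
    m[match(sub$fast_fb[i], ff), match(sub$slow_fb[i], sf)] <- sub[[what]][i]
  graphics::image(log10(ff), log10(sf), m,
                  xlab = "log10 fast feedback", ylab = "log10 slow feedback",
                  main = sprintf("%s at %g min", what, time), ...)
  invisible(m)
}
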