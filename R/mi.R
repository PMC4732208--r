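#' Shannon entropy of a discrete distribution, in bits
#'
#' Computes \eqn{-\sum_i p_i \log_2 p_i} with the convention
#' \eqn{0 \log_2 0 = 0}.
#'
#' @param p non-negative probabilities summing to 1 (tolerance 1e-9).
#' @return entropy in bits.
#' @examples
#' entropy_bits(rep(1 / 8, 8)) # a uniform 8-level input carries 3 bits
#' @export
entropy_bits <- function(p) {
  if (any(!is.finite(p)) || any(p < 0))
    stop("probabilities must be non-negative and finite")
  if (abs(sum(p) - 1) > 1e-9)
    stop("probabilities must sum to 1 (got ", format(sum(p)), ")")
  p <- p[p > 0]
  -sum(p * log2(p))
}

# Deterministic equal-count (quantile) binning of a numeric response.
# Ties spanning a bin edge are assigned left-closed via findInterval. When
# there are no more distinct values than bins, each value is its own bin.
bin_response <- function(z, nbins) {
  uz <- unique(z)
  if (length(uz) <= nbins) return(match(z, sort(uz)))
  br <- unique(quantile(z, seq(0, 1, length.out = nbins + 1),
                        names = FALSE, type = 7))
  if (length(br) < 2L) return(rep(1L, length(z)))
  findInterval(z, br, rightmost.closed = TRUE)
}

# Plug-in mutual information I = H(Z) - sum_s p(s) H(Z | S = s) on a joint
# count table (signal rows x response columns), in bits.
plugin_mi_table <- function(tab) {
  n <- sum(tab)
  if (n <= 0) return(0)
  pz <- colSums(tab) / n
  ps <- rowSums(tab) / n
  hz <- entropy_bits(pz)
  hz_s <- 0
  for (i in seq_len(nrow(tab))) {
    ni <- sum(tab[i, ])
    if (ni > 0) hz_s <- hz_s + (ni / n) * entropy_bits(tab[i, ] / ni)
  }
  hz - hz_s
}

#' Uncorrected plug-in mutual information between a signal and a response
#'
#' Discretizes the response into `response_bins` equal-count bins and
#' evaluates the plug-in estimator on the joint count table. Mostly useful
#' for diagnostics; [mi()] adds bias correction and uncertainty.
#'
#' @param s signal: factor, character, or discrete labels.
#' @param z numeric response.
#' @param response_bins number of response bins (>= 2).
#' @return plug-in MI in bits.
#' @export
mi_plugin <- function(s, z, response_bins) {
  s <- as.factor(s)
  plugin_mi_table(table(s, bin_response(z, response_bins)))
}

#' Discretize a positive numeric signal into equal-count log10 bins
#'
#' Replaces a continuous positive signal (e.g. a log-uniformly drawn stimulus
#' copy number) by equal-count quantile bin labels on the log10 scale, as
#' needed for the conditional entropy in [mi()]. Factors and non-numeric
#' inputs are returned unchanged (already categorical). Ties spanning a bin
#' edge are assigned deterministically to the left-closed bin.
#'
#' @param x signal values (positive numeric, or an already-categorical
#'   factor/character vector).
#' @param bins number of equal-count bins (default 8).
#' @return a factor with a `breaks` attribute recording the bin edges on the
#'   original scale (numeric input), or `x` coerced to factor (categorical
#'   input).
#' @export
discretize_signal <- function(x, bins = 8) {
  if (is.factor(x)) return(x)
  if (!is.numeric(x)) return(as.factor(x))
  if (length(unique(x)) <= bins) {
    # already (at most) `bins` discrete levels: keep them as labels
    f <- factor(x, levels = sort(unique(x)))
    attr(f, "breaks") <- sort(unique(x))
    return(f)
  }
  if (any(x <= 0)) stop("numeric signal must be positive for log10 binning")
  lx <- log10(x)
  br <- unique(quantile(lx, seq(0, 1, length.out = bins + 1), names = FALSE))
  idx <- findInterval(lx, br, rightmost.closed = TRUE)
  f <- factor(idx, levels = seq_len(length(br) - 1))
  attr(f, "breaks") <- 10^br
  f
}

#' Estimate mutual information from paired stimulus/response samples
#'
#' Estimates \eqn{I(S; Z) = H(Z) - H(Z | S)} in bits from single-cell records
#' of a stimulus and a response. The response is discretized into equal-count
#' quantile bins; a categorical stimulus keeps its labels, a continuous one is
#' discretized by [discretize_signal()]. The plug-in estimate is
#' bias-corrected by subsampling extrapolation: the plug-in MI is computed at
#' sample fractions 1, 1/2 and 1/4 (disjoint random splits, averaged) and the
#' linear model `MI(n) = MI_inf + a/n` is extrapolated to infinite sample
#' size. Uncertainty is a nonparametric bootstrap over cells.
#'
#' @param formula a formula `response ~ stimulus` naming columns of `data`.
#' @param data a data.frame with no missing values in the two variables.
#' @param response_bins number of equal-count response bins; default
#'   `floor(sqrt(n/10))`, clamped to `[2, 64]` (stable occupancy of the joint
#'   table).
#' @param signal_bins bins for a continuous stimulus (default 8).
#' @param correction `"jackknife"` (subsampling extrapolation, default) or
#'   `"none"` (raw plug-in).
#' @param boot bootstrap resamples for the standard error (0 disables).
#' @param seed optional seed making the correction splits and bootstrap
#'   reproducible without touching the caller's RNG stream.
#' @return object of class `mi_estimate`: list with `mi_bits`, `se_bits`,
#'   `plugin_bits`, `n`, `n_response_bins`, `n_signal_bins`, `correction`.
#' @examples
#' set.seed(1)
#' d <- data.frame(s = rep(0:1, each = 500))
#' d$z <- d$s + rnorm(1000, sd = 0.1)
#' mi(z ~ s, d) # close to 1 bit: two well-separated inputs
#' @export
mi <- function(formula, data, response_bins = NULL, signal_bins = 8,
               correction = c("jackknife", "none"), boot = 100, seed = NULL) {
  correction <- match.arg(correction)
  stopifnot(inherits(formula, "formula"), length(formula) == 3L)
  mf <- stats::model.frame(formula, data, na.action = stats::na.fail)
  z <- mf[[1]]
  s <- mf[[2]]
  if (!is.numeric(z)) stop("response must be numeric")
  n <- length(z)
  s <- discretize_signal(s, bins = signal_bins)
  s <- droplevels(s)
  if (nlevels(s) < 2L)
    warning("fewer than 2 distinct stimulus levels: MI is 0 by construction")
  if (is.null(response_bins))
    response_bins <- max(2L, min(64L, floor(sqrt(n / 10))))
  if (response_bins < 2L) stop("response_bins must be >= 2")
  small <- table(s) < response_bins
  if (any(small))
    warning("stimulus level(s) with fewer samples than response bins: ",
            paste(names(which(small)), collapse = ", "))

  est <- with_seed(seed, {
    point <- mi_corrected(s, z, response_bins, correction)
    se <- NA_real_
    if (boot > 0) {
      bs <- vapply(seq_len(boot), function(b) {
        idx <- sample.int(n, n, replace = TRUE)
        mi_corrected(s[idx], z[idx], response_bins, correction)["mi"]
      }, numeric(1))
      se <- sd(bs)
    }
    c(point, se = se)
  })

  cap <- min(log2(max(nlevels(s), 2L)), log2(response_bins))
  structure(
    list(mi_bits = min(max(est[["mi"]], 0), cap),
         se_bits = est[["se"]],
         plugin_bits = est[["plugin"]],
         n = n,
         n_response_bins = as.integer(response_bins),
         n_signal_bins = nlevels(s),
         correction = correction,
         boot = boot,
         call = match.call()),
    class = "mi_estimate")
}

# Corrected MI for a given discretized signal and numeric response.
# Returns c(mi = corrected, plugin = full-sample plug-in).
mi_corrected <- function(s, z, response_bins, correction) {
  n <- length(z)
  full <- mi_plugin(s, z, response_bins)
  if (correction == "none" || n < 16L)
    return(c(mi = full, plugin = full))
  perm <- sample.int(n)
  halves <- split(perm, rep(1:2, length.out = n))
  quarters <- split(perm, rep(1:4, length.out = n))
  mi_half <- mean(vapply(halves, function(idx)
    mi_plugin(s[idx], z[idx], response_bins), numeric(1)))
  mi_quarter <- mean(vapply(quarters, function(idx)
    mi_plugin(s[idx], z[idx], response_bins), numeric(1)))
  sizes <- c(n, n / 2, n / 4)
  fit <- lm(mi ~ inv_n,
            data = data.frame(mi = c(full, mi_half, mi_quarter),
                              inv_n = 1 / sizes))
  c(mi = unname(coef(fit)[1]), plugin = full)
}

#' @export
print.mi_estimate <- function(x, ...) {
  cat(sprintf("Mutual information: %.4f bits", x$mi_bits))
  if (is.finite(x$se_bits)) cat(sprintf(" (bootstrap SE %.4f)", x$se_bits))
  cat("\n")
  cat(sprintf("  n = %d cells, %d signal levels x %d response bins, correction: %s\n",
              x$n, x$n_signal_bins, x$n_response_bins, x$correction))
  invisible(x)
}

#' @export
summary.mi_estimate <- function(object, ...) {
  cat("Mutual information estimate (bits)\n")
  cat(sprintf("  corrected:   %.4f\n", object$mi_bits))
  cat(sprintf("  plug-in:     %.4f\n", object$plugin_bits))
  cat(sprintf("  bootstrap SE: %s (%d resamples)\n",
              ifelse(is.finite(object$se_bits),
                     sprintf("%.4f", object$se_bits), "not computed"),
              object$boot))
  cat(sprintf("  ceiling:     %.4f (min of log2 signal and response bins)\n",
              min(log2(max(object$n_signal_bins, 2L)),
                  log2(object$n_response_bins))))
  cat(sprintf("  n = %d, %d signal levels, %d response bins\n",
              object$n, object$n_signal_bins, object$n_response_bins))
  invisible(object)
}

#' @export
confint.mi_estimate <- function(object, parm = "mi_bits", level = 0.95, ...) {
  if (!is.finite(object$se_bits))
    stop("no bootstrap SE available (boot = 0)")
  zq <- qnorm(1 - (1 - level) / 2)
  lo <- max(0, object$mi_bits - zq * object$se_bits)
  hi <- object$mi_bits + zq * object$se_bits
  out <- matrix(c(lo, hi), 1, 2,
                dimnames = list("mi_bits",
                                paste0(100 * c((1 - level) / 2,
                                               1 - (1 - level) / 2), " %")))
  out
}
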