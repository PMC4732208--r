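#' Stochastic ERK activation model with two negative feedback loops
#'
#' Constructs the model object used throughout the package: a stimulus `S`
#' activates an upstream effector (`E -> Ea`); both effector forms
#' phosphorylate ERK (`Sub -> pSub`), the inactive form at a much lower
#' constitutive leak rate; a constitutive phosphatase dephosphorylates
#' `pSub`. Fast negative feedback is the reversible inactivating binding of
#' `pSub` to `E`/`Ea` (strength `fast_fb`); slow negative feedback is
#' `pSub`-driven expression of a second phosphatase from `slow_fb` promoter
#' copies. The constructor also derives the mean-field fixed point at `S = 0`
#' and the slowest relaxation time, which set the pre-equilibration burn-in
#' (ten times the relaxation time).
#'
#' @param fast_fb fast feedback strength; the anchors 0.01 / 1.66 / 330 are
#'   low / intermediate / high.
#' @param slow_fb promoter copy number for the inducible phosphatase; anchors
#'   1 / 100 / 10000 are low / intermediate / high.
#' @param params optional full [erk_params()] object (overrides the two
#'   strength arguments if given).
#' @param ... further arguments passed to [erk_params()].
#' @return object of class `erk_model`: list with `params`, `network`,
#'   `fixed_point` (mean-field S = 0 steady state at median substrate),
#'   `relax_time` (seconds) and `chx` (whether inducible-phosphatase
#'   production is disabled at stimulus onset; see [apply_perturbation()]).
#' @examples
#' m <- erk_model(fast_fb = 1.66, slow_fb = 100)
#' print(m)
#' @export
erk_model <- function(fast_fb = 1.66, slow_fb = 100, params = NULL, ...) {
  if (is.null(params))
    params <- erk_params(fast_fb = fast_fb, slow_fb = slow_fb, ...)
  stopifnot(inherits(params, "erk_params"))
  network <- build_erk_network(params)
  fp <- meanfield_fixed_point(network, erk_init(params))
  rt <- relaxation_time_at(network, fp)
  structure(list(params = params, network = network, fixed_point = fp,
                 relax_time = rt, chx = FALSE),
            class = "erk_model")
}

#' @export
print.erk_model <- function(x, ...) {
  p <- x$params
  cat("Stochastic ERK activation model (two negative feedback loops)\n")
  cat(sprintf("  fast feedback strength: %g   slow feedback promoters: %d\n",
              p$fast_fb, as.integer(p$slow_fb)))
  cat(sprintf("  leak/active phosphorylation: %g / %g per molecule per s\n",
              p$leak_rate, p$active_rate))
  cat(sprintf("  total substrate: log10-normal(%g, %g); signal: log-uniform [%d, %d]\n",
              p$total_sub_log10_mean, p$total_sub_log10_sd,
              as.integer(p$signal_low), as.integer(p$signal_high)))
  cat(sprintf("  mean-field basal pSub: %.1f; burn-in: %.0f s (10x relaxation %.0f s)\n",
              x$fixed_point[["pSub"]], 10 * x$relax_time, x$relax_time))
  if (isTRUE(x$chx))
    cat("  perturbation: inducible-phosphatase production disabled at stimulus onset\n")
  invisible(x)
}

# Mean-field (mass-action ODE) right-hand side for a reaction network,
# in deSolve form. Continuous concentrations; propensity k * prod(y_i^m).
network_rhs <- function(network) {
  reactant <- network$reactant
  net <- network$net
  rates <- network$rates
  nrxn <- length(rates)
  need <- lapply(seq_len(nrxn), function(j) which(reactant[, j] > 0))
  pow <- lapply(seq_len(nrxn), function(j) reactant[reactant[, j] > 0, j])
  function(t, y, parms) {
    a <- rates
    for (j in seq_len(nrxn)) {
      if (a[j] == 0 || length(need[[j]]) == 0L) next
      a[j] <- a[j] * prod(pmax(y[need[[j]]], 0)^pow[[j]])
    }
    list(drop(net %*% a))
  }
}

#' Mean-field (deterministic mass-action) solution of the ERK model
#'
#' Integrates the mass-action ODE system matching the stochastic network --
#' the large-copy-number limit of the jump process -- from a given state with
#' a fixed signal level.
#'
#' @param model an [erk_model()] (or a bare [reaction_network()]).
#' @param times readout times, minutes.
#' @param init initial state; defaults to the model's S = 0 fixed point.
#' @param signal signal copy number held constant during the integration.
#' @return matrix with a `time_min` column and one column per species.
#' @export
mean_field <- function(model, times = c(5, 10, 30, 60, 180, 360),
                       init = NULL, signal = 0) {
  network <- if (inherits(model, "erk_model")) model$network else model
  stopifnot(inherits(network, "reaction_network"))
  if (is.null(init)) {
    stopifnot(inherits(model, "erk_model"))
    init <- model$fixed_point
  }
  y0 <- setNames(as.numeric(init), network$species)
  if ("S" %in% network$species) y0[["S"]] <- signal
  tt <- sort(unique(c(0, times * 60)))
  sol <- deSolve::lsoda(y0, tt, network_rhs(network), parms = NULL,
                        rtol = 1e-8, atol = 1e-8)
  out <- sol[match(times * 60, sol[, "time"]), -1, drop = FALSE]
  cbind(time_min = times, out)
}

# S = 0 fixed point by long integration of the mean-field ODE.
meanfield_fixed_point <- function(network, init, horizon = 5e5) {
  rhs <- network_rhs(network)
  y0 <- setNames(as.numeric(init), network$species)
  sol <- deSolve::lsoda(y0, c(0, horizon / 4, horizon), rhs, parms = NULL,
                        rtol = 1e-10, atol = 1e-8)
  fp <- sol[nrow(sol), -1]
  setNames(as.numeric(fp), network$species)
}

# Slowest relaxation time (seconds) of the mean-field system at a state:
# 1 / min |Re(eigenvalue)| of the Jacobian, excluding the zero modes that
# come from conservation laws (and the constant signal).
relaxation_time_at <- function(network, state, zero_tol = 1e-9) {
  rhs <- network_rhs(network)
  f <- function(y) unlist(rhs(0, setNames(y, network$species), NULL))
  J <- pracma::jacobian(f, as.numeric(state))
  ev <- eigen(J, only.values = TRUE)$values
  re <- abs(Re(ev))
  re <- re[re > zero_tol]
  if (!length(re)) return(0)
  1 / min(re)
}

#' Unstimulated steady state and relaxation time
#'
#' @param model an [erk_model()].
#' @return `steady_state` returns the named mean-field fixed point at S = 0;
#'   `relaxation_time` the slowest mean-field relaxation time in seconds.
#' @export
steady_state <- function(model) {
  stopifnot(inherits(model, "erk_model"))
  model$fixed_point
}

#' @rdname steady_state
#' @export
relaxation_time <- function(model) {
  stopifnot(inherits(model, "erk_model"))
  model$relax_time
}
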