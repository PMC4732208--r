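#' Exact stochastic simulation of a reaction network (Gillespie direct method)
#'
#' Samples one exact trajectory of the continuous-time Markov jump process
#' defined by the network's mass-action propensities. The state recorded at
#' each requested time is the state immediately before the first reaction
#' event after that time (i.e. the jump-process value at that time). A state
#' with zero total propensity is absorbing: it is held constant to `t_end`
#' rather than raising an error. Randomness comes from R's RNG, so results
#' are reproducible under [set.seed()].
#'
#' @param network a [reaction_network()].
#' @param init named (or network-ordered) non-negative integer state vector.
#' @param t_end end of the simulated window, seconds.
#' @param record_times times (seconds, within `[t_start, t_end]`) at which to
#'   record the state.
#' @param t_start start time, seconds (default 0).
#' @param event_cap abort with an error if the number of reaction events
#'   exceeds this cap (a parameter-pathology guard), default 1e8.
#' @param log_events if positive, also return up to this many event times
#'   (used to test exactness of the inter-event time distribution).
#' @return an object of class `trajectory`: list with `times`, `states`
#'   (times x species matrix), `final` (named state at `t_end`), `events`
#'   (event count) and `event_times` (numeric, possibly empty).
#' @examples
#' net <- reaction_network("A",
#'   list(list(name = "death", reactants = c(A = 1), products = integer(0),
#'             rate = 0.1)))
#' set.seed(1)
#' tr <- gillespie(net, c(A = 50L), t_end = 30, record_times = c(10, 20, 30))
#' tr$states
#' @export
gillespie <- function(network, init, t_end, record_times = numeric(0),
                      t_start = 0, event_cap = 1e8, log_events = 0L) {
  stopifnot(inherits(network, "reaction_network"))
  init <- as_state(network, init)
  if (any(init < 0)) stop("all initial counts must be non-negative integers")
  record_times <- sort(as.numeric(record_times))
  if (length(record_times) &&
      (record_times[1] < t_start || record_times[length(record_times)] > t_end))
    stop("record_times must lie within [t_start, t_end]")
  out <- ssa_run_cpp(init, network$reactant, network$net, network$rates,
                     as.numeric(t_start), as.numeric(t_end), record_times,
                     as.numeric(event_cap), as.integer(log_events))
  states <- out$states
  dimnames(states) <- list(NULL, network$species)
  structure(
    list(times = record_times, states = states,
         final = setNames(out$final, network$species),
         events = out$events, event_times = out$event_times),
    class = "trajectory")
}

as_state <- function(network, init) {
  sp <- network$species
  if (!is.null(names(init))) {
    full <- setNames(integer(length(sp)), sp)
    unknown <- setdiff(names(init), sp)
    if (length(unknown))
      stop("unknown species in state: ", paste(unknown, collapse = ", "))
    full[names(init)] <- as.integer(round(init))
    full
  } else {
    if (length(init) != length(sp))
      stop("state length does not match species count")
    setNames(as.integer(round(init)), sp)
  }
}

#' @export
print.trajectory <- function(x, ...) {
  cat("SSA trajectory:", x$events, "events,",
      length(x$times), "recorded times\n")
  if (length(x$times)) print(head(cbind(t = x$times, x$states), 6))
  invisible(x)
}

#' Pre-equilibrate the ERK model at S = 0
#'
#' Runs the network without stimulation to steady state before the signal is
#' introduced. The burn-in duration is ten times the slowest mean-field
#' relaxation time at the unstimulated fixed point (computed once per
#' parameter set, see [relaxation_time()]), capped at `max_burn_in`; if the
#' cap binds, a warning attribute is attached to the returned state.
#'
#' @param model an [erk_model()].
#' @param init initial state with `S = 0`; defaults to [erk_init()] at the
#'   given total substrate.
#' @param total_sub total substrate copy number used when `init` is NULL.
#' @param max_burn_in cap on the burn-in duration, seconds.
#' @return named integer state after burn-in (still `S = 0`), with attributes
#'   `burn_in` (seconds) and, if the cap bound, `warning`.
#' @export
equilibrate <- function(model, init = NULL, total_sub = NULL,
                        max_burn_in = 2e5) {
  stopifnot(inherits(model, "erk_model"))
  if (is.null(init)) init <- erk_init(model$params, total_sub)
  init <- as_state(model$network, init)
  if (init[["S"]] != 0) stop("pre-equilibration requires S = 0")
  burn <- 10 * model$relax_time
  warn <- NULL
  if (!is.finite(burn) || burn > max_burn_in) {
    warn <- sprintf("burn-in capped at %g s (10x relaxation time = %g s)",
                    max_burn_in, burn)
    burn <- max_burn_in
  }
  if (all(model$network$rates == 0) || burn <= 0) {
    st <- init
    attr(st, "burn_in") <- 0
    return(st)
  }
  tr <- gillespie(model$network, init, t_end = burn,
                  event_cap = model$params$event_cap)
  st <- tr$final
  attr(st, "burn_in") <- burn
  if (!is.null(warn)) attr(st, "warning") <- warn
  st
}

#' Simulate an ensemble of single-cell runs of the ERK model
#'
#' The headline simulation protocol: for each run, total substrate is drawn
#' log10-normally, the network is pre-equilibrated without stimulation
#' ([equilibrate()]), a signal copy number is drawn log-uniformly (or fixed
#' via `signal`), and the stimulated network is simulated with the
#' phosphorylated substrate `pSub` recorded at each readout time -- an
#' in-silico analogue of a fixed-cell snapshot stain. Runs are independent
#' given per-run child seeds derived deterministically from `seed`, so an
#' ensemble is a pure function of (parameters, `nsim`, `times`, `seed`).
#'
#' @param object an [erk_model()].
#' @param nsim number of independent runs (cells).
#' @param seed root seed (integer); required for reproducibility, defaults to
#'   the current RNG if NULL.
#' @param times readout times in minutes.
#' @param signal optional fixed signal copy number (recycled over runs);
#'   if NULL, drawn log-uniformly per run.
#' @param ... unused.
#' @return a data.frame of class `erk_ensemble` with columns `run`, `seed`,
#'   `S`, `total_sub`, `time_min`, `pSub` (one row per run x readout time) and
#'   attributes `root_seed`, `times`, `fingerprint`.
#' @export
simulate.erk_model <- function(object, nsim = 1, seed = NULL,
                               times = c(5, 10, 30, 60, 180, 360),
                               signal = NULL, ...) {
  stopifnot(nsim >= 1, length(times) >= 1, all(times > 0))
  if (is.null(seed)) seed <- as.integer(runif(1, 1, 2^30))
  times <- sort(unique(as.numeric(times)))
  t_end <- max(times) * 60
  p <- object$params
  net_stim <- object$network
  if (isTRUE(object$chx)) {
    # cycloheximide analogue: P2 production disabled from stimulus onset;
    # pre-equilibration (and hence basal P2) is untouched.
    net_stim$rates[net_stim$reaction_names == "pase2_prod"] <- 0
  }
  if (!is.null(signal)) signal <- rep_len(as.integer(signal), nsim)
  rows <- vector("list", nsim)
  for (i in seq_len(nsim)) {
    child <- derive_seed(seed, i)
    rows[[i]] <- with_seed(child, {
      total_sub <- sample_total_substrate(1, p)
      st <- equilibrate(object, total_sub = total_sub)
      s_i <- if (is.null(signal)) sample_signal(1, p) else signal[i]
      st[["S"]] <- s_i
      tr <- gillespie(net_stim, st, t_end = t_end,
                      record_times = times * 60, event_cap = p$event_cap)
      data.frame(run = i, seed = child, S = s_i, total_sub = total_sub,
                 time_min = times, pSub = tr$states[, "pSub"])
    })
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "root_seed") <- seed
  attr(out, "times") <- times
  attr(out, "fingerprint") <- model_fingerprint(object)
  class(out) <- c("erk_ensemble", "data.frame")
  out
}

model_fingerprint <- function(model) {
  p <- model$params
  paste0("fast_fb=", p$fast_fb, ";slow_fb=", p$slow_fb,
         ";chx=", isTRUE(model$chx))
}
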