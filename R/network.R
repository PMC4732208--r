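#' Construct a mass-action reaction network
#'
#' A reaction network is a list of named molecular species together with a set
#' of reactions, each given by reactant and product stoichiometries and a
#' non-negative rate constant. Propensities follow stochastic mass-action
#' kinetics: first-order constants are per second, second-order constants per
#' molecule per second.
#'
#' @param species character vector of species names (ordered; order defines
#'   the state vector layout).
#' @param reactions list of reactions; each a list with elements `name`,
#'   `reactants` (named integer vector of stoichiometries), `products`
#'   (named integer vector) and `rate` (non-negative number).
#' @param sub_mass optional named integer vector giving, per species, how many
#'   units of conserved substrate mass that species carries (used to assert
#'   substrate conservation for the ERK network).
#' @return an object of class `reaction_network` with fields `species`,
#'   `reactant` and `net` stoichiometry matrices (species x reactions),
#'   `rates` and `reaction_names`.
#' @seealso [build_erk_network()], [gillespie()]
#' @export
reaction_network <- function(species, reactions, sub_mass = NULL) {
  stopifnot(is.character(species), length(species) > 0L, !anyDuplicated(species))
  nrxn <- length(reactions)
  reactant <- matrix(0L, length(species), nrxn,
                     dimnames = list(species, NULL))
  net <- reactant
  rates <- numeric(nrxn)
  rnames <- character(nrxn)
  for (j in seq_len(nrxn)) {
    rx <- reactions[[j]]
    rnames[j] <- if (!is.null(rx$name)) rx$name else paste0("r", j)
    if (is.null(rx$rate) || is.na(rx$rate))
      stop("missing rate constant for reaction '", rnames[j], "'")
    if (rx$rate < 0)
      stop("negative rate constant for reaction '", rnames[j], "'")
    rates[j] <- rx$rate
    for (side in c("reactants", "products")) {
      st <- rx[[side]]
      if (length(st) == 0L) next
      if (is.null(names(st)) || !all(names(st) %in% species))
        stop("reaction '", rnames[j], "' references undeclared species: ",
             paste(setdiff(names(st), species), collapse = ", "))
      if (any(st < 0) || any(st != round(st)))
        stop("stoichiometries must be non-negative integers (reaction '",
             rnames[j], "')")
      for (sp in names(st)) {
        if (side == "reactants") {
          reactant[sp, j] <- reactant[sp, j] + as.integer(st[[sp]])
          net[sp, j] <- net[sp, j] - as.integer(st[[sp]])
        } else {
          net[sp, j] <- net[sp, j] + as.integer(st[[sp]])
        }
      }
    }
  }
  colnames(reactant) <- colnames(net) <- rnames
  structure(
    list(species = species, reactant = reactant, net = net,
         rates = rates, reaction_names = rnames, sub_mass = sub_mass),
    class = "reaction_network")
}

#' @export
print.reaction_network <- function(x, ...) {
  cat("Mass-action reaction network:", length(x$species), "species,",
      length(x$rates), "reactions\n")
  cat("  species:", paste(x$species, collapse = ", "), "\n")
  for (j in seq_along(x$rates)) {
    lhs <- x$reactant[, j]
    rhs <- x$reactant[, j] + x$net[, j]
    side <- function(v) {
      nz <- v > 0
      if (!any(nz)) return("0")
      paste(ifelse(v[nz] > 1, paste0(v[nz], " "), ""), x$species[nz],
            sep = "", collapse = " + ")
    }
    cat(sprintf("  %-16s %s -> %s   k = %g\n", x$reaction_names[j],
                side(lhs), side(rhs), x$rates[j]))
  }
  invisible(x)
}

#' Net change in conserved substrate mass per reaction
#'
#' Symbolically evaluates, for every reaction, the net change of total
#' substrate (free + phosphorylated + bound in any complex). For a valid ERK
#' network all entries are zero: no reaction creates or destroys substrate.
#'
#' @param network a [reaction_network()] with a `sub_mass` annotation.
#' @return named numeric vector, one entry per reaction.
#' @export
substrate_balance <- function(network) {
  stopifnot(inherits(network, "reaction_network"))
  if (is.null(network$sub_mass))
    stop("network carries no substrate-mass annotation")
  w <- setNames(rep(0, length(network$species)), network$species)
  w[names(network$sub_mass)] <- network$sub_mass
  drop(w %*% network$net)
}

#' Default parameter set for the stochastic ERK activation model
#'
#' Parameters of the two-feedback ERK activation network. The signal `S`
#' converts the inactive effector `E` to its active form `Ea`; both forms
#' phosphorylate substrate (`Sub -> pSub`), the inactive form at a much lower
#' constitutive "leak" rate. A constitutive phosphatase (`Pase1`)
#' dephosphorylates `pSub`. Fast negative feedback is the reversible,
#' inactivating binding of `pSub` to `E` and `Ea`; its strength `fast_fb`
#' scales the association rate constant (`fast_fb * fb_unit`, per molecule per
#' second). Slow negative feedback is `pSub`-dependent activation of `slow_fb`
#' promoter copies that express a second phosphatase (`P2`), which is removed
#' by first-order decay and dephosphorylates `pSub`.
#'
#' Total substrate is log10-normal across runs (mean 3.9, SD 0.1) and the
#' signal is log-uniform on 10--1000 molecules, matching the simulation
#' protocol the model is designed for. `fast_fb` anchors 0.01 / 1.66 / 330
#' correspond to low / intermediate / high fast feedback; `slow_fb` anchors
#' 1 / 100 / 10000 to low / intermediate / high slow feedback.
#'
#' @param fast_fb fast-feedback strength (scales the pSub-effector
#'   association rate; dimensionless multiplier of `fb_unit`, >= 0).
#' @param slow_fb number of promoter copies expressing phosphatase 2
#'   (non-negative integer).
#' @param leak_rate rate of substrate phosphorylation by inactive `E`
#'   (per molecule per second); must be below `active_rate`.
#' @param active_rate rate of substrate phosphorylation by active `Ea`.
#' @param e_total total effector copy number.
#' @param pase1_count copy number of the constitutive phosphatase.
#' @param k_act signal-dependent effector activation rate (per molecule of S,
#'   per molecule of E, per second).
#' @param k_deact first-order effector deactivation rate (per second).
#' @param k_pase1 rate of pSub dephosphorylation per Pase1 molecule.
#' @param fb_unit base association rate constant for fast feedback binding.
#' @param fb_off dissociation rate of the pSub:effector complexes (per s).
#' @param k_prom_on,k_prom_off pSub-promoter binding and unbinding rates.
#' @param k_pase2_prod production rate of P2 per active promoter (per s).
#' @param k_pase2_deg first-order removal rate of P2 (per s).
#' @param k_pase2 rate of pSub dephosphorylation per P2 molecule.
#' @param total_sub_log10_mean,total_sub_log10_sd log10-normal law of total
#'   substrate across runs.
#' @param signal_low,signal_high support of the log-uniform signal draw
#'   (molecules, positive integers, low < high).
#' @param event_cap maximum number of reaction events per run before the
#'   simulator aborts (guards against parameter pathologies).
#' @return a validated list of class `erk_params`.
#' @export
erk_params <- function(fast_fb = 1.66,
                       slow_fb = 100,
                       leak_rate = 1.75e-5,
                       active_rate = 1.75e-4,
                       e_total = 60,
                       pase1_count = 50,
                       k_act = 2e-4,
                       k_deact = 0.01,
                       k_pase1 = 4e-5,
                       fb_unit = 0.015,
                       fb_off = 0.1,
                       k_prom_on = 2e-7,
                       k_prom_off = 6e-5,
                       k_pase2_prod = 1e-3,
                       k_pase2_deg = 2e-4,
                       k_pase2 = 1e-5,
                       total_sub_log10_mean = 3.9,
                       total_sub_log10_sd = 0.1,
                       signal_low = 10,
                       signal_high = 1000,
                       event_cap = 1e8) {
  p <- as.list(environment())
  validate_erk_params(p)
  structure(p, class = "erk_params")
}

validate_erk_params <- function(p) {
  if (p$fast_fb < 0) stop("fast_fb must be >= 0")
  if (p$slow_fb < 0 || p$slow_fb != round(p$slow_fb))
    stop("slow_fb must be a non-negative integer (promoter copies)")
  if (!(p$leak_rate < p$active_rate))
    stop("leak_rate must be below active_rate (constitutive activation is slower)")
  rates <- p[c("leak_rate", "active_rate", "k_act", "k_deact", "k_pase1",
               "fb_unit", "fb_off", "k_prom_on", "k_prom_off",
               "k_pase2_prod", "k_pase2_deg", "k_pase2")]
  bad <- names(rates)[vapply(rates, function(v) !is.finite(v) || v < 0, TRUE)]
  if (length(bad))
    stop("negative or non-finite rate constant: ", paste(bad, collapse = ", "))
  if (p$e_total < 0 || p$pase1_count < 0)
    stop("species counts must be non-negative")
  sl <- p$signal_low; sh <- p$signal_high
  if (!(sl > 0 && sh > 0 && sl <= sh && sl == round(sl) && sh == round(sh)))
    stop("signal bounds must be positive integers with signal_low <= signal_high")
  invisible(p)
}

# Species layout of the ERK network. PromA holds one pSub molecule, so it
# carries one unit of substrate mass, as do the two feedback complexes.
erk_species <- function() {
  c("S", "E", "Ea", "Sub", "pSub", "Pase1", "CE", "CEa", "Prom", "PromA", "P2")
}

erk_sub_mass <- function() {
  c(Sub = 1L, pSub = 1L, CE = 1L, CEa = 1L, PromA = 1L)
}

#' Build the two-feedback stochastic ERK activation network
#'
#' Assembles the mass-action reaction set: (1) signal-dependent effector
#' activation `S + E -> S + Ea` and reversion `Ea -> E`; (2) substrate
#' phosphorylation by `Ea` (active rate) and by `E` (constitutive leak);
#' (3) constitutive dephosphorylation of `pSub` by `Pase1`; (4) fast feedback,
#' the reversible binding of `pSub` to `E` and `Ea` (the bound effector cannot
#' phosphorylate substrate); (5) slow feedback, `pSub`-dependent promoter
#' activation, production of phosphatase `P2` from active promoters,
#' first-order removal of `P2`, and `P2`-catalysed dephosphorylation of
#' `pSub`. Setting `fast_fb = 0` and `slow_fb = 0` yields the feedback-broken
#' topology (the binding reactions have zero rate and there is no promoter to
#' express `P2`).
#'
#' @param params an [erk_params()] object.
#' @return a [reaction_network()] over the 11 ERK model species.
#' @export
build_erk_network <- function(params) {
  if (!inherits(params, "erk_params")) params <- do.call(erk_params, params)
  validate_erk_params(params)
  k_on <- params$fast_fb * params$fb_unit
  rx <- list(
    list(name = "activation",    reactants = c(S = 1, E = 1),
         products = c(S = 1, Ea = 1),       rate = params$k_act),
    list(name = "deactivation",  reactants = c(Ea = 1),
         products = c(E = 1),               rate = params$k_deact),
    list(name = "phospho_active", reactants = c(Ea = 1, Sub = 1),
         products = c(Ea = 1, pSub = 1),    rate = params$active_rate),
    list(name = "phospho_leak",  reactants = c(E = 1, Sub = 1),
         products = c(E = 1, pSub = 1),     rate = params$leak_rate),
    list(name = "dephospho_p1",  reactants = c(pSub = 1, Pase1 = 1),
         products = c(Sub = 1, Pase1 = 1),  rate = params$k_pase1),
    list(name = "fb_bind_E",     reactants = c(pSub = 1, E = 1),
         products = c(CE = 1),              rate = k_on),
    list(name = "fb_unbind_E",   reactants = c(CE = 1),
         products = c(pSub = 1, E = 1),     rate = params$fb_off),
    list(name = "fb_bind_Ea",    reactants = c(pSub = 1, Ea = 1),
         products = c(CEa = 1),             rate = k_on),
    list(name = "fb_unbind_Ea",  reactants = c(CEa = 1),
         products = c(pSub = 1, Ea = 1),    rate = params$fb_off),
    list(name = "prom_bind",     reactants = c(Prom = 1, pSub = 1),
         products = c(PromA = 1),           rate = params$k_prom_on),
    list(name = "prom_unbind",   reactants = c(PromA = 1),
         products = c(Prom = 1, pSub = 1),  rate = params$k_prom_off),
    list(name = "pase2_prod",    reactants = c(PromA = 1),
         products = c(PromA = 1, P2 = 1),   rate = params$k_pase2_prod),
    list(name = "pase2_decay",   reactants = c(P2 = 1),
         products = integer(0),             rate = params$k_pase2_deg),
    list(name = "dephospho_p2",  reactants = c(pSub = 1, P2 = 1),
         products = c(Sub = 1, P2 = 1),     rate = params$k_pase2)
  )
  reaction_network(erk_species(), rx, sub_mass = erk_sub_mass())
}

#' Initial state of the ERK network
#'
#' All substrate unphosphorylated, all effector inactive, all promoters
#' inactive and no inducible phosphatase; `S = 0` (pre-equilibration runs
#' without stimulation).
#'
#' @param params an [erk_params()] object.
#' @param total_sub total substrate copy number for this run (integer >= 0);
#'   defaults to the round median of the configured log10-normal law.
#' @return named integer vector over the network species.
#' @export
erk_init <- function(params, total_sub = NULL) {
  if (is.null(total_sub))
    total_sub <- round(10^params$total_sub_log10_mean)
  stopifnot(total_sub >= 0, total_sub == round(total_sub))
  setNames(as.integer(c(0, params$e_total, 0, total_sub, 0,
                        params$pase1_count, 0, 0, params$slow_fb, 0, 0)),
           erk_species())
}

#' Sample a per-run total substrate copy number
#'
#' Draws `round(10^x)` with `x ~ Normal(mean, sd)` on the log10 scale
#' (defaults: mean 3.9, SD 0.1). Rounding (not truncation) keeps the draw
#' unbiased at the distribution median; the result is at least 1.
#'
#' @param n number of draws.
#' @param params an [erk_params()] object supplying the log10 mean and SD.
#' @return integer vector of length `n`.
#' @export
sample_total_substrate <- function(n = 1, params = erk_params()) {
  x <- rnorm(n, params$total_sub_log10_mean, params$total_sub_log10_sd)
  pmax(1L, as.integer(round(10^x)))
}

#' Sample a signal copy number, log-uniform
#'
#' Draws `round(10^u)` with `u ~ Uniform(log10 low, log10 high)`; defaults
#' 10--1000 molecules.
#'
#' @inheritParams sample_total_substrate
#' @return integer vector of length `n`, within `[signal_low, signal_high]`.
#' @export
sample_signal <- function(n = 1, params = erk_params()) {
  u <- runif(n, log10(params$signal_low), log10(params$signal_high))
  s <- as.integer(round(10^u))
  pmin(pmax(s, as.integer(params$signal_low)), as.integer(params$signal_high))
}

#' Serialize / read a reaction network as JSON
#'
#' The JSON document lists species, substrate-mass annotation and one record
#' per reaction (name, reactant and product stoichiometries, rate constant).
#'
#' @param network a [reaction_network()].
#' @param path file path.
#' @return `write_network_json` returns `path` invisibly;
#'   `read_network_json` returns a [reaction_network()].
#' @export
write_network_json <- function(network, path) {
  stopifnot(inherits(network, "reaction_network"))
  rx <- lapply(seq_along(network$rates), function(j) {
    lhs <- network$reactant[, j]
    rhs <- network$reactant[, j] + network$net[, j]
    list(name = network$reaction_names[j],
         reactants = as.list(lhs[lhs > 0]),
         products = as.list(rhs[rhs > 0]),
         rate = network$rates[j])
  })
  doc <- list(species = network$species,
              sub_mass = as.list(network$sub_mass),
              reactions = rx)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_network_json
#' @export
read_network_json <- function(path) {
  doc <- jsonlite::read_json(path)
  rx <- lapply(doc$reactions, function(r) {
    list(name = r$name,
         reactants = unlist(r$reactants),
         products = if (length(r$products)) unlist(r$products) else integer(0),
         rate = r$rate)
  })
  sub_mass <- if (length(doc$sub_mass))
    setNames(as.integer(unlist(doc$sub_mass)), names(doc$sub_mass)) else NULL
  reaction_network(unlist(doc$species), rx, sub_mass = sub_mass)
}
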