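#include <Rcpp.h>
using namespace Rcpp;

// Exact stochastic simulation, Gillespie direct method.
//
// state0      initial copy numbers (one per species)
// reactant    species x reactions reactant stoichiometry matrix
// net         species x reactions net stoichiometry matrix
// rates       per-reaction mass-action rate constants
// t0, t_end   simulated time window (seconds)
// record_times  sorted times at which to record the state; the recorded
//               state is the state immediately before the first reaction
//               event occurring after that time
// event_cap   abort (R error) if the event count exceeds this
// max_event_log  if > 0, also return up to this many event times
//
// Uses R's RNG (exp_rand / unif_rand), so results are reproducible under
// set.seed() on the R side.
// [[Rcpp::export]]
List ssa_run_cpp(IntegerVector state0, IntegerMatrix reactant,
                 IntegerMatrix net, NumericVector rates, double t0,
                 double t_end, NumericVector record_times, double event_cap,
                 int max_event_log) {
  const int nspec = state0.size();
  const int nrxn = rates.size();
  if (reactant.nrow() != nspec || net.nrow() != nspec ||
      reactant.ncol() != nrxn || net.ncol() != nrxn)
    stop("stoichiometry matrices do not match state/rate dimensions");

  std::vector<double> x(nspec);
  for (int i = 0; i < nspec; ++i) {
    if (state0[i] < 0) stop("negative initial copy number");
    x[i] = state0[i];
  }

  // Per-reaction reactant and net-change index lists (sparse evaluation).
  std::vector<std::vector<std::pair<int, int> > > need(nrxn), change(nrxn);
  for (int j = 0; j < nrxn; ++j)
    for (int i = 0; i < nspec; ++i) {
      if (reactant(i, j) > 0)
        need[j].push_back(std::make_pair(i, reactant(i, j)));
      if (net(i, j) != 0)
        change[j].push_back(std::make_pair(i, net(i, j)));
    }
  std::vector<double> kr(rates.begin(), rates.end());

  const int nrec = record_times.size();
  NumericMatrix rec(nrec, nspec);
  std::vector<double> evt;
  if (max_event_log > 0) evt.reserve(max_event_log);

  std::vector<double> a(nrxn);
  double t = t0;
  double events = 0.0;
  int irec = 0;
  bool absorbed = false;

  while (true) {
    double a0 = 0.0;
    if (!absorbed) {
      for (int j = 0; j < nrxn; ++j) {
        double aj = kr[j];
        if (aj > 0.0) {
          const std::vector<std::pair<int, int> >& nd = need[j];
          for (size_t q = 0; q < nd.size(); ++q) {
            const int i = nd[q].first;
            const int m = nd[q].second;
            for (int k = 0; k < m; ++k) aj *= (x[i] - k);
          }
          if (aj < 0.0) aj = 0.0;
        }
        a[j] = aj;
        a0 += aj;
      }
    }
    double tnext;
    if (a0 <= 0.0) {
      // zero total propensity: state is absorbing, hold to t_end
      absorbed = true;
      tnext = R_PosInf;
    } else {
      tnext = t + exp_rand() / a0;
    }
    while (irec < nrec && record_times[irec] < tnext) {
      if (record_times[irec] > t_end) break;
      for (int i = 0; i < nspec; ++i) rec(irec, i) = x[i];
      ++irec;
    }
    if (tnext > t_end) break;
    t = tnext;
    double u = unif_rand() * a0;
    double c = 0.0;
    int j = 0;
    for (; j < nrxn - 1; ++j) {
      c += a[j];
      if (u <= c) break;
    }
    const std::vector<std::pair<int, int> >& ch = change[j];
    for (size_t q = 0; q < ch.size(); ++q) x[ch[q].first] += ch[q].second;
    events += 1.0;
    if (max_event_log > 0 && (int)evt.size() < max_event_log)
      evt.push_back(t);
    if (events > event_cap)
      stop("event cap of %.0f events exceeded at t = %.3f s", event_cap, t);
    if (((long long)events & 0xFFFFF) == 0) checkUserInterrupt();
  }

  while (irec < nrec) {
    for (int i = 0; i < nspec; ++i) rec(irec, i) = x[i];
    ++irec;
  }
  IntegerVector final_state(nspec);
  for (int i = 0; i < nspec; ++i) final_state[i] = (int)x[i];

  return List::create(_["states"] = rec, _["final"] = final_state,
                      _["events"] = events,
                      _["event_times"] = NumericVector(evt.begin(), evt.end()));
}
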