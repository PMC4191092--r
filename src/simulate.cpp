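#include <Rcpp.h>
using namespace Rcpp;

// All transition tables are Omega x (N+1): row = environment index (0-based
// here), column = mutant count i = 0..N.  All draws use R's global RNG so that
// set.seed() governs reproducibility.

static inline int draw_env(const NumericMatrix& mu, int s, int omega) {
  double u = unif_rand();
  double acc = 0.0;
  for (int k = 0; k < omega - 1; ++k) {
    acc += mu(s, k);
    if (u < acc) return k;
  }
  return omega - 1;
}

// one elementary discrete step: population move with the step-start
// environment, then the environment move — the same factorisation as the
// joint step kernel.
static inline void step_discrete(const NumericMatrix& tp, const NumericMatrix& tm,
                                 const NumericMatrix& mu, int omega,
                                 int& i, int& s) {
  double up = tp(s, i), dn = tm(s, i);
  double u = unif_rand();
  if (u < up) {
    ++i;
  } else if (u < up + dn) {
    --i;
  }
  s = draw_env(mu, s, omega);
}

// [[Rcpp::export]]
List cpp_simulate_discrete(NumericMatrix tp, NumericMatrix tm, NumericMatrix mu,
                           int i0, int s0, double max_steps, bool absorbing,
                           int record_every) {
  const int N = tp.ncol() - 1, omega = tp.nrow();
  std::vector<double> times;
  std::vector<int> pops, envs;
  int i = i0, s = s0;
  double step = 0.0;
  bool absorbed = absorbing && (i == 0 || i == N);
  times.push_back(0.0); pops.push_back(i); envs.push_back(s + 1);
  double absorb_time = absorbed ? 0.0 : NA_REAL;
  long rec = 0;
  while (!absorbed && step < max_steps) {
    step_discrete(tp, tm, mu, omega, i, s);
    step += 1.0;
    if (++rec == record_every) {
      rec = 0;
      times.push_back(step); pops.push_back(i); envs.push_back(s + 1);
    }
    if (absorbing && (i == 0 || i == N)) {
      absorbed = true;
      absorb_time = step;
      if (rec != 0) { times.push_back(step); pops.push_back(i); envs.push_back(s + 1); }
    }
  }
  if (!absorbed && rec != 0) { times.push_back(step); pops.push_back(i); envs.push_back(s + 1); }
  return List::create(_["time"] = wrap(times), _["pop"] = wrap(pops),
                      _["env"] = wrap(envs), _["absorbed"] = absorbed,
                      _["final_pop"] = i, _["absorb_time"] = absorb_time);
}

// [[Rcpp::export]]
List cpp_fixation_ensemble(NumericMatrix tp, NumericMatrix tm, NumericMatrix mu,
                           int i0, IntegerVector s0, double max_steps) {
  const int N = tp.ncol() - 1, omega = tp.nrow();
  const int n = s0.size();
  LogicalVector fixed(n), absorbed(n);
  NumericVector steps(n);
  for (int r = 0; r < n; ++r) {
    int i = i0, s = s0[r];
    double step = 0.0;
    while (i != 0 && i != N && step < max_steps) {
      step_discrete(tp, tm, mu, omega, i, s);
      step += 1.0;
    }
    absorbed[r] = (i == 0 || i == N);
    fixed[r] = (i == N);
    steps[r] = step;
    if ((r & 1023) == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["fixed"] = fixed, _["absorbed"] = absorbed,
                      _["steps"] = steps);
}

// Histogram of the population state over an ensemble of runs with mutation:
// counts(i, k) accumulates over runs at step k * sample_every.
// [[Rcpp::export]]
IntegerMatrix cpp_ensemble_hist(NumericMatrix tp, NumericMatrix tm,
                                NumericMatrix mu, int i0, IntegerVector s0,
                                double total_steps, int sample_every) {
  const int N = tp.ncol() - 1, omega = tp.nrow();
  const int n = s0.size();
  const int nsamp = (int)(total_steps / sample_every);
  IntegerMatrix counts(N + 1, nsamp);
  for (int r = 0; r < n; ++r) {
    int i = i0, s = s0[r];
    for (int k = 0; k < nsamp; ++k) {
      for (int j = 0; j < sample_every; ++j) step_discrete(tp, tm, mu, omega, i, s);
      counts(i, k) += 1;
    }
    if ((r & 255) == 0) Rcpp::checkUserInterrupt();
  }
  return counts;
}

// [[Rcpp::export]]
IntegerMatrix cpp_one_step_counts(NumericMatrix tp, NumericMatrix tm,
                                  NumericMatrix mu, int i0, int s0,
                                  int n_draws) {
  const int omega = tp.nrow();
  IntegerMatrix counts(3, omega);  // rows: move -1, 0, +1; cols: next env
  for (int r = 0; r < n_draws; ++r) {
    int i = i0, s = s0;
    step_discrete(tp, tm, mu, omega, i, s);
    counts(i - i0 + 1, s) += 1;
  }
  return counts;
}

// Continuous time: environment switching and birth-death are separate
// rate-driven events (Gillespie).  mrates has zero diagonal.
// [[Rcpp::export]]
List cpp_simulate_gillespie(NumericMatrix rp, NumericMatrix rm,
                            NumericMatrix mrates, int i0, int s0,
                            double t_max, bool absorbing, int record_every) {
  const int N = rp.ncol() - 1, omega = rp.nrow();
  NumericVector mtot(omega);
  for (int s = 0; s < omega; ++s) {
    double a = 0.0;
    for (int k = 0; k < omega; ++k) if (k != s) a += mrates(s, k);
    mtot[s] = a;
  }
  std::vector<double> times;
  std::vector<int> pops, envs;
  int i = i0, s = s0;
  double t = 0.0;
  bool absorbed = absorbing && (i == 0 || i == N);
  double absorb_time = absorbed ? 0.0 : NA_REAL;
  times.push_back(0.0); pops.push_back(i); envs.push_back(s + 1);
  long rec = 0, guard = 0;
  while (!absorbed && t < t_max) {
    double up = absorbing && (i == 0 || i == N) ? 0.0 : rp(s, i);
    double dn = absorbing && (i == 0 || i == N) ? 0.0 : rm(s, i);
    double total = up + dn + mtot[s];
    if (total <= 0.0) break;  // frozen state, nothing can happen
    t += exp_rand() / total;
    if (t > t_max) { t = t_max; break; }
    double u = unif_rand() * total;
    if (u < up) {
      ++i;
    } else if (u < up + dn) {
      --i;
    } else {
      u -= up + dn;
      double acc = 0.0;
      int snew = s;
      for (int k = 0; k < omega; ++k) {
        if (k == s) continue;
        acc += mrates(s, k);
        if (u < acc) { snew = k; break; }
      }
      s = snew;
    }
    if (++rec >= record_every) {
      rec = 0;
      times.push_back(t); pops.push_back(i); envs.push_back(s + 1);
    }
    if (absorbing && (i == 0 || i == N)) {
      absorbed = true;
      absorb_time = t;
      if (rec != 0) { times.push_back(t); pops.push_back(i); envs.push_back(s + 1); }
    }
    if ((++guard & 65535) == 0) Rcpp::checkUserInterrupt();
  }
  if (!absorbed && rec != 0) { times.push_back(t); pops.push_back(i); envs.push_back(s + 1); }
  return List::create(_["time"] = wrap(times), _["pop"] = wrap(pops),
                      _["env"] = wrap(envs), _["absorbed"] = absorbed,
                      _["final_pop"] = i, _["absorb_time"] = absorb_time);
}

// [[Rcpp::export]]
List cpp_fixation_ensemble_ct(NumericMatrix rp, NumericMatrix rm,
                              NumericMatrix mrates, int i0, IntegerVector s0,
                              double t_max) {
  const int N = rp.ncol() - 1, omega = rp.nrow();
  NumericVector mtot(omega);
  for (int s = 0; s < omega; ++s) {
    double a = 0.0;
    for (int k = 0; k < omega; ++k) if (k != s) a += mrates(s, k);
    mtot[s] = a;
  }
  const int n = s0.size();
  LogicalVector fixed(n), absorbed(n);
  NumericVector times(n);
  for (int r = 0; r < n; ++r) {
    int i = i0, s = s0[r];
    double t = 0.0;
    while (i != 0 && i != N && t < t_max) {
      double up = rp(s, i), dn = rm(s, i);
      double total = up + dn + mtot[s];
      if (total <= 0.0) break;
      t += exp_rand() / total;
      double u = unif_rand() * total;
      if (u < up) {
        ++i;
      } else if (u < up + dn) {
        --i;
      } else {
        u -= up + dn;
        double acc = 0.0;
        for (int k = 0; k < omega; ++k) {
          if (k == s) continue;
          acc += mrates(s, k);
          if (u < acc) { s = k; break; }
        }
      }
    }
    absorbed[r] = (i == 0 || i == N);
    fixed[r] = (i == N);
    times[r] = t;
    if ((r & 1023) == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["fixed"] = fixed, _["absorbed"] = absorbed,
                      _["times"] = times);
}
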