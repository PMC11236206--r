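#include <Rcpp.h>
using namespace Rcpp;

// Survival simulation for the plain BOA process (epsilon = 0) on a line of N
// patches, started from every patch holding fresh seeds (age 1).  One
// generation: seeds germinate, each patch with plants is wiped with
// probability p_ext, surviving plants re-seed their own and both neighbouring
// patches (age reset to 1); unseeded cohorts age and die past age H+1.
// A replicate survives if at least one patch shows plants at generation T.
// Uses R's RNG so results are governed by set.seed().
// [[Rcpp::export]]
LogicalVector boa_survival_sim(int N, int T, int n_reps, double p_ext, int H) {
  LogicalVector survived(n_reps);
  std::vector<int> age(N), nxt(N);
  std::vector<unsigned char> obs(N);
  for (int r = 0; r < n_reps; ++r) {
    std::fill(age.begin(), age.end(), 1);
    bool surv = false;
    for (int t = 0; t < T; ++t) {
      int n_occ = 0;
      for (int i = 0; i < N; ++i) {
        obs[i] = (age[i] > 0) && (unif_rand() > p_ext);
        if (obs[i]) ++n_occ;
      }
      if (t == T - 1) { surv = n_occ > 0; break; }
      bool any_seed = false;
      for (int i = 0; i < N; ++i) {
        bool nbr = obs[i] || (i > 0 && obs[i - 1]) || (i < N - 1 && obs[i + 1]);
        if (nbr) nxt[i] = 1;
        else {
          int a = age[i] > 0 ? age[i] + 1 : 0;
          nxt[i] = (a > H + 1) ? 0 : a;
        }
        if (nxt[i] > 0) any_seed = true;
      }
      if (!any_seed) { surv = false; break; }
      std::swap(age, nxt);
    }
    survived[r] = surv;
    Rcpp::checkUserInterrupt();
  }
  return survived;
}

// Exact per-patch log-likelihoods of a complete (no missing entries)
// observation matrix under the (noisy) BOA hidden Markov model.
//
// Conditional on the full observation matrix, each patch's hidden seed-bank
// age propagates deterministically: it resets to 1 one generation after the
// patch or an in-bounds neighbour shows plants, and otherwise increments
// until it exceeds H+1 (then the cohort is no longer viable, state EMPTY).
// Only the initial age (EMPTY with prior mass 1-s, or uniform on {1..H+1}
// with total mass s) is latent, so the patch likelihood is a sum over H+2
// initial states of a product of emission probabilities:
//   viable -> 1 : (1-p_ext) + p_ext*eps     viable -> 0 : p_ext*(1-eps)
//   EMPTY  -> 1 : eps                        EMPTY  -> 0 : 1-eps
// obs is an N x T integer matrix with entries 0/1.
// [[Rcpp::export]]
NumericVector boa_patch_logliks(IntegerMatrix obs, double s, double p_ext,
                                int H, double eps) {
  const int N = obs.nrow(), T = obs.ncol();
  const double e1v = std::log1p(-p_ext * (1.0 - eps)); // log((1-p)+p*eps)
  const double e0v = std::log(p_ext) + std::log1p(-eps);
  const double e1e = std::log(eps);
  const double e0e = std::log1p(-eps);
  const double lw_empty = std::log1p(-s);
  const double lw_age = std::log(s) - std::log((double)(H + 1));

  NumericVector out(N);
  std::vector<int> last(T); // most recent reset-causing generation before t
  std::vector<double> lla(H + 2);
  for (int i = 0; i < N; ++i) {
    int cur = 0; // 0 = no reset yet; generations are 1-based here
    for (int t = 0; t < T; ++t) {
      last[t] = cur;
      bool nbr = obs(i, t) == 1 || (i > 0 && obs(i - 1, t) == 1) ||
                 (i < N - 1 && obs(i + 1, t) == 1);
      if (nbr) cur = t + 1;
    }
    for (int a = 0; a <= H + 1; ++a) {
      double ll = (a == 0) ? lw_empty : lw_age;
      for (int t = 0; t < T; ++t) {
        bool viable;
        if (last[t] > 0)
          viable = (t + 1 - last[t]) <= H + 1;
        else
          viable = a > 0 && (a + t) <= H + 1; // age at emission t is a + t
        if (obs(i, t) == 1)
          ll += viable ? e1v : e1e;
        else
          ll += viable ? e0v : e0e;
        if (ll == R_NegInf) break;
      }
      lla[a] = ll;
    }
    double m = R_NegInf;
    for (int a = 0; a <= H + 1; ++a) m = std::max(m, lla[a]);
    if (m == R_NegInf) { out[i] = R_NegInf; continue; }
    double acc = 0.0;
    for (int a = 0; a <= H + 1; ++a)
      if (lla[a] > R_NegInf) acc += std::exp(lla[a] - m);
    out[i] = m + std::log(acc);
  }
  return out;
}

// Sum of boa_patch_logliks, returned without allocating the vector path on
// the hot MCMC loop.
// [[Rcpp::export]]
double boa_segment_loglik_cpp(IntegerMatrix obs, double s, double p_ext,
                              int H, double eps) {
  NumericVector ll = boa_patch_logliks(obs, s, p_ext, H, eps);
  double tot = 0.0;
  for (int i = 0; i < ll.size(); ++i) {
    if (ll[i] == R_NegInf) return R_NegInf;
    tot += ll[i];
  }
  return tot;
}
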