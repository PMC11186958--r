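#include <Rcpp.h>
using namespace Rcpp;

// Term codes shared with R/spec.R: 1 = edges, 2 = nodematch (hemisphere),
// 3 = nodematch (homotopic partner), 4 = gwesp (fixed decay tau).

namespace {

// number of common neighbours of a and b
inline int sp_count(const IntegerMatrix &adj, int a, int b, int N) {
  int w = 0;
  for (int m = 0; m < N; ++m)
    if (adj(a, m) && adj(b, m)) ++w;
  return w;
}

// Change statistics for ADDING the (absent) dyad (i, j).
// For gwesp: the new edge contributes e^tau * (1 - u^c) with c the number of
// common neighbours (u = 1 - e^-tau); each existing edge (i,k), (j,k) with
// k a common neighbour gains one shared partner, contributing u^w where w is
// its shared-partner count before the toggle.
void add_delta(const IntegerMatrix &adj, int i, int j,
               const IntegerVector &terms, const IntegerVector &hemi,
               const IntegerVector &partner, double tau,
               std::vector<double> &out) {
  const int N = adj.nrow();
  const int p = terms.size();
  bool need_gwesp = false;
  for (int t = 0; t < p; ++t) if (terms[t] == 4) need_gwesp = true;

  double dg = 0.0;
  if (need_gwesp) {
    const double u = 1.0 - std::exp(-tau);
    int c = 0;
    for (int k = 0; k < N; ++k) {
      if (adj(i, k) && adj(j, k)) {
        ++c;
        dg += std::pow(u, (double)sp_count(adj, i, k, N));
        dg += std::pow(u, (double)sp_count(adj, j, k, N));
      }
    }
    dg += std::exp(tau) * (1.0 - std::pow(u, (double)c));
  }

  for (int t = 0; t < p; ++t) {
    switch (terms[t]) {
    case 1: out[t] = 1.0; break;
    case 2: out[t] = (hemi[i] == hemi[j]) ? 1.0 : 0.0; break;
    case 3: out[t] = (partner[i] == j) ? 1.0 : 0.0; break;
    case 4: out[t] = dg; break;
    default: stop("unknown term code");
    }
  }
}

} // namespace

// [[Rcpp::export]]
NumericVector cpp_summary_stats(const IntegerMatrix &adj,
                                const IntegerVector &terms,
                                const IntegerVector &hemi,
                                const IntegerVector &partner, double tau) {
  const int N = adj.nrow();
  const int p = terms.size();
  NumericVector s(p);
  const double u = 1.0 - std::exp(-tau);
  for (int i = 0; i < N - 1; ++i) {
    for (int j = i + 1; j < N; ++j) {
      if (!adj(i, j)) continue;
      for (int t = 0; t < p; ++t) {
        switch (terms[t]) {
        case 1: s[t] += 1.0; break;
        case 2: s[t] += (hemi[i] == hemi[j]); break;
        case 3: s[t] += (partner[i] == j); break;
        case 4: {
          int w = sp_count(adj, i, j, N);
          s[t] += std::exp(tau) * (1.0 - std::pow(u, (double)w));
          break;
        }
        }
      }
    }
  }
  return s;
}

// [[Rcpp::export]]
NumericVector cpp_change_stats(const IntegerMatrix &adj, int i, int j,
                               const IntegerVector &terms,
                               const IntegerVector &hemi,
                               const IntegerVector &partner, double tau) {
  if (adj(i, j) != 0) stop("cpp_change_stats expects the dyad to be absent");
  std::vector<double> d(terms.size());
  add_delta(adj, i, j, terms, hemi, partner, tau, d);
  return wrap(d);
}

// Single-dyad toggle Metropolis-Hastings run; returns the final adjacency and
// its summary statistics. Uses R's RNG so set.seed() governs reproducibility.
// [[Rcpp::export]]
List cpp_simulate_ergm(const IntegerMatrix &adj0, const NumericVector &theta,
                       int n_aux, const IntegerVector &terms,
                       const IntegerVector &hemi, const IntegerVector &partner,
                       double tau) {
  const int N = adj0.nrow();
  const int p = terms.size();
  if ((int)theta.size() != p) stop("theta length does not match term count");
  IntegerMatrix adj = clone(adj0);
  const int ndyads = N * (N - 1) / 2;
  std::vector<int> di(ndyads), dj(ndyads);
  {
    int k = 0;
    for (int i = 0; i < N - 1; ++i)
      for (int j = i + 1; j < N; ++j) { di[k] = i; dj[k] = j; ++k; }
  }
  std::vector<double> d(p);
  NumericVector s = cpp_summary_stats(adj, terms, hemi, partner, tau);

  for (int it = 0; it < n_aux; ++it) {
    int k = (int)(unif_rand() * ndyads);
    if (k >= ndyads) k = ndyads - 1;
    const int i = di[k], j = dj[k];
    const bool present = adj(i, j) != 0;
    if (present) { adj(i, j) = 0; adj(j, i) = 0; }
    add_delta(adj, i, j, terms, hemi, partner, tau, d);
    double lr = 0.0;
    for (int t = 0; t < p; ++t) lr += theta[t] * d[t];
    if (present) lr = -lr;
    if (lr >= 0.0 || std::log(unif_rand()) < lr) {
      // toggle accepted: flip the state
      if (!present) { adj(i, j) = 1; adj(j, i) = 1; }
      for (int t = 0; t < p; ++t) s[t] += present ? -d[t] : d[t];
    } else if (present) {
      adj(i, j) = 1; adj(j, i) = 1; // restore
    }
  }
  return List::create(_["adjacency"] = adj, _["stats"] = s);
}

// Edgewise shared-partner counts EP_w, w = 0 .. N-2.
// [[Rcpp::export]]
IntegerVector cpp_esp_counts(const IntegerMatrix &adj) {
  const int N = adj.nrow();
  IntegerVector ep(N > 1 ? N - 1 : 1);
  for (int i = 0; i < N - 1; ++i)
    for (int j = i + 1; j < N; ++j)
      if (adj(i, j)) ep[sp_count(adj, i, j, N)] += 1;
  return ep;
}
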