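// Collapsed Gibbs sampler for a Dirichlet-process binomial mixture over a
// discrete cellular-prevalence grid. Cluster parameters are per-sample grid
// indices; because the base measure is uniform over the grid, both the
// new-cluster marginal and parameter updates are exact finite sums, which
// keeps the sampler fully deterministic given R's RNG seed.

#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// draw an index in [0, w.size()) proportional to w (unnormalized, >= 0)
static int sample_index(const std::vector<double>& w) {
  double total = 0.0;
  for (double x : w) total += x;
  double u = unif_rand() * total;
  double acc = 0.0;
  for (size_t i = 0; i < w.size(); ++i) {
    acc += w[i];
    if (u <= acc) return (int)i;
  }
  return (int)w.size() - 1;
}

// sample a grid index proportional to exp(loglik) with max-subtraction
static int sample_grid(const double* ll, int G) {
  double m = R_NegInf;
  for (int g = 0; g < G; ++g) if (ll[g] > m) m = ll[g];
  std::vector<double> w(G);
  for (int g = 0; g < G; ++g) w[g] = std::exp(ll[g] - m);
  return sample_index(w);
}

// loglik: numeric array n x G x S (per-mutation log binomial likelihood at
// each grid point in each sample). Returns co-assignment proportions over
// retained sweeps plus diagnostics.
// [[Rcpp::export(name = ".dp_gibbs")]]
List dp_gibbs(NumericVector loglik, int n, int G, int S,
              double alpha, int n_iter, int burn_in) {
  const double* LL = REAL(loglik);
  // LL index: i + n * (g + G * s)
  auto ll_at = [&](int i, int g, int s) { return LL[i + (R_xlen_t)n * (g + (R_xlen_t)G * s)]; };

  // log of the uniform-base-measure marginal for a singleton cluster,
  // factorized over samples: sum_s log( mean_g exp(ll(i,g,s)) )
  std::vector<double> log_marg(n, 0.0);
  for (int i = 0; i < n; ++i) {
    for (int s = 0; s < S; ++s) {
      double m = R_NegInf;
      for (int g = 0; g < G; ++g) m = std::max(m, ll_at(i, g, s));
      double acc = 0.0;
      for (int g = 0; g < G; ++g) acc += std::exp(ll_at(i, g, s) - m);
      log_marg[i] += m + std::log(acc / G);
    }
  }

  std::vector<int> z(n, 0);                 // cluster index per mutation
  std::vector<std::vector<int>> members(1); // mutation ids per cluster
  std::vector<std::vector<int>> par(1, std::vector<int>(S, G / 2)); // grid idx
  for (int i = 0; i < n; ++i) members[0].push_back(i);

  std::vector<double> coassign((size_t)n * n, 0.0);
  IntegerVector k_trace(n_iter);
  int retained = 0;

  // temp buffer for cluster-sum loglik over grid
  std::vector<double> cl_sum(G);

  for (int iter = 0; iter < n_iter; ++iter) {
    // CRP reassignment sweep
    for (int i = 0; i < n; ++i) {
      int ci = z[i];
      // remove i from its cluster
      std::vector<int>& mem = members[ci];
      mem.erase(std::find(mem.begin(), mem.end(), i));
      if (mem.empty()) {
        // delete empty cluster, relabel the last one into its slot
        int last = (int)members.size() - 1;
        if (ci != last) {
          members[ci] = members[last];
          par[ci] = par[last];
          for (int j : members[ci]) z[j] = ci;
        }
        members.pop_back();
        par.pop_back();
      }
      int K = (int)members.size();
      std::vector<double> logw(K + 1);
      for (int c = 0; c < K; ++c) {
        double lw = std::log((double)members[c].size());
        for (int s = 0; s < S; ++s) lw += ll_at(i, par[c][s], s);
        logw[c] = lw;
      }
      logw[K] = std::log(alpha) + log_marg[i];
      double m = R_NegInf;
      for (double x : logw) m = std::max(m, x);
      std::vector<double> w(K + 1);
      for (int c = 0; c <= K; ++c) w[c] = std::exp(logw[c] - m);
      int pick = sample_index(w);
      if (pick == K) {
        // open a new cluster; draw its parameters from the singleton posterior
        std::vector<int> gs(S);
        std::vector<double> ll_row(G);
        for (int s = 0; s < S; ++s) {
          for (int g = 0; g < G; ++g) ll_row[g] = ll_at(i, g, s);
          gs[s] = sample_grid(ll_row.data(), G);
        }
        members.push_back(std::vector<int>{i});
        par.push_back(gs);
        z[i] = K;
      } else {
        members[pick].push_back(i);
        z[i] = pick;
      }
    }

    // refresh cluster parameters from their posteriors
    for (size_t c = 0; c < members.size(); ++c) {
      for (int s = 0; s < S; ++s) {
        std::fill(cl_sum.begin(), cl_sum.end(), 0.0);
        for (int i : members[c]) {
          for (int g = 0; g < G; ++g) cl_sum[g] += ll_at(i, g, s);
        }
        par[c][s] = sample_grid(cl_sum.data(), G);
      }
    }

    k_trace[iter] = (int)members.size();
    if (iter >= burn_in) {
      ++retained;
      for (const std::vector<int>& mem : members) {
        for (size_t a = 0; a < mem.size(); ++a) {
          for (size_t b = 0; b < mem.size(); ++b) {
            coassign[(size_t)mem[a] * n + mem[b]] += 1.0;
          }
        }
      }
    }
  }

  NumericMatrix co(n, n);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < n; ++j) {
      co(i, j) = retained > 0 ? coassign[(size_t)i * n + j] / retained : 0.0;
    }
  }
  return List::create(_["coassign"] = co, _["k_trace"] = k_trace,
                      _["retained"] = retained);
}
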