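#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Truncated stick-breaking Dirichlet-process binomial mixture over CCF space.
//
// y, N        : n x D alt/total read counts (N == 0 marks a missing cell)
// cmat        : n x D linear VAF coefficients, f_id = pi * c_id where
//               c_id = rho_d * m_id / (rho_d * n_id + (1 - rho_d) * 2)
// grid        : candidate cluster locations (includes 0, up to the CCF cap)
// K           : truncation level
// Cluster locations are sampled on the grid from their full conditional;
// assignments from categorical conditionals; alpha (optionally) by the
// Escobar-West auxiliary scheme under a Gamma(prior_shape, prior_rate) prior.
// All randomness goes through R's RNG so set.seed() controls the run.

// [[Rcpp::export]]
List dp_gibbs_cpp(IntegerMatrix y, IntegerMatrix N, NumericMatrix cmat,
                  NumericVector grid, int K, int n_iter, int burn_in, int thin,
                  double alpha_init, bool sample_alpha,
                  double prior_shape, double prior_rate,
                  IntegerVector z_init) {
  const int n = y.nrow(), D = y.ncol(), G = grid.size();
  if (n < 1) stop("no mutations");

  // Per-region unique c values (few distinct copy states) for fast
  // grid updates of cluster locations.
  std::vector< std::vector<double> > uval(D);
  std::vector< std::vector<int> > uidx(D, std::vector<int>(n, -1));
  for (int d = 0; d < D; ++d) {
    for (int i = 0; i < n; ++i) {
      if (N(i, d) <= 0) continue;
      double c = cmat(i, d);
      int at = -1;
      for (size_t u = 0; u < uval[d].size(); ++u)
        if (std::abs(uval[d][u] - c) < 1e-12) { at = (int)u; break; }
      if (at < 0) { uval[d].push_back(c); at = (int)uval[d].size() - 1; }
      uidx[d][i] = at;
    }
  }
  int Umax = 1;
  for (int d = 0; d < D; ++d) Umax = std::max(Umax, (int)uval[d].size());

  // Lookup tables: log(grid) and log1p(-grid*c) for every region's unique
  // c values (locations live on the grid, so no logs in the hot loops).
  std::vector<double> LG(G);
  for (int g = 0; g < G; ++g)
    LG[g] = (grid[g] > 0.0) ? std::log(grid[g]) : R_NegInf;
  std::vector< std::vector<double> > LT(D);
  for (int d = 0; d < D; ++d) {
    const int U = (int)uval[d].size();
    LT[d].assign((size_t)G * std::max(U, 1), 0.0);
    for (int g = 0; g < G; ++g)
      for (int u = 0; u < U; ++u) {
        double f = grid[g] * uval[d][u];
        if (f >= 1.0 - 1e-9) f = 1.0 - 1e-9;
        LT[d][(size_t)g * U + u] = std::log1p(-f);
      }
  }

  // State (cluster locations as grid indices)
  std::vector<int> z(n, 0);
  std::vector<int> gi((size_t)K * D, 0);
  double alpha = alpha_init;
  // init: caller-provided assignments (0-based), locations uniform on grid
  // (overwritten from their conditionals on the first sweep)
  for (int i = 0; i < n; ++i)
    z[i] = (z_init.size() == n) ? (z_init[i] % K) : (i % K);
  for (int k = 0; k < K; ++k)
    for (int d = 0; d < D; ++d)
      gi[(size_t)k * D + d] = (int)std::floor(unif_rand() * G);

  std::vector<double> logw(K, -std::log((double)K));
  std::vector<double> Lg(G), prob(G > K ? G : K);

  const int n_keep = (n_iter - burn_in + thin - 1) / thin;
  IntegerMatrix z_trace(n_keep, n);
  NumericVector pi_trace(n_keep * K * D);
  NumericVector alpha_trace(n_keep);
  IntegerVector kocc_trace(n_keep);
  NumericMatrix cocl(n, n);
  int kept = 0;

  std::vector<double> Ysum(K * D), Ssum(K * D * Umax);
  std::vector<int> nk(K);

  for (int it = 0; it < n_iter; ++it) {
    // --- cluster counts
    std::fill(nk.begin(), nk.end(), 0);
    for (int i = 0; i < n; ++i) nk[z[i]]++;

    // --- stick-breaking weights
    {
      double logrest = 0.0;
      int tail = n;
      for (int k = 0; k < K; ++k) {
        tail -= nk[k];
        if (k == K - 1) { logw[k] = logrest; break; }
        double v = R::rbeta(1.0 + nk[k], alpha + tail);
        if (v < 1e-12) v = 1e-12;
        if (v > 1.0 - 1e-12) v = 1.0 - 1e-12;
        logw[k] = logrest + std::log(v);
        logrest += std::log1p(-v);
      }
    }

    // --- cluster locations: grid conditional per (k, d)
    std::fill(Ysum.begin(), Ysum.end(), 0.0);
    std::fill(Ssum.begin(), Ssum.end(), 0.0);
    for (int i = 0; i < n; ++i) {
      const int k = z[i];
      for (int d = 0; d < D; ++d) {
        if (N(i, d) <= 0) continue;
        Ysum[k * D + d] += y(i, d);
        Ssum[(k * D + d) * Umax + uidx[d][i]] += (double)(N(i, d) - y(i, d));
      }
    }
    for (int k = 0; k < K; ++k) {
      for (int d = 0; d < D; ++d) {
        const double Yk = Ysum[k * D + d];
        const int U = (int)uval[d].size();
        bool empty = true;
        for (int u = 0; u < U; ++u)
          if (Ssum[(k * D + d) * Umax + u] > 0.0 || Yk > 0.0) { empty = false; break; }
        if (empty) { // prior: uniform over grid
          gi[(size_t)k * D + d] = (int)std::floor(unif_rand() * G);
          continue;
        }
        double mx = R_NegInf;
        for (int g = 0; g < G; ++g) {
          double L;
          if (grid[g] <= 0.0) {
            L = (Yk > 0.0) ? R_NegInf : 0.0;
          } else {
            L = Yk * LG[g];
            for (int u = 0; u < U; ++u) {
              const double S = Ssum[(k * D + d) * Umax + u];
              if (S > 0.0) L += S * LT[d][(size_t)g * U + u];
            }
            // y*log(c) term is constant in g and omitted
          }
          Lg[g] = L;
          if (L > mx) mx = L;
        }
        double tot = 0.0;
        for (int g = 0; g < G; ++g) {
          prob[g] = (Lg[g] == R_NegInf) ? 0.0 : std::exp(Lg[g] - mx);
          tot += prob[g];
        }
        double r = unif_rand() * tot, acc = 0.0;
        int pick = G - 1;
        for (int g = 0; g < G; ++g) { acc += prob[g]; if (r <= acc) { pick = g; break; } }
        gi[(size_t)k * D + d] = pick;
      }
    }

    // --- assignments (table lookups: f = grid[g]*c, log f = LG[g] + log c;
    //     y*log(c_id) is constant across clusters and omitted).
    //     Region-major accumulation into Lmat for cache locality.
    {
      std::vector<double> Lmat((size_t)n * K);
      for (int k = 0; k < K; ++k) {
        const double w0 = logw[k];
        for (int i = 0; i < n; ++i) Lmat[(size_t)i * K + k] = w0;
      }
      std::vector<double> lgk(K);
      std::vector<const double*> ltk(K);
      for (int d = 0; d < D; ++d) {
        const int U = (int)uval[d].size();
        if (U == 0) continue;
        for (int k = 0; k < K; ++k) {
          const int g = gi[(size_t)k * D + d];
          lgk[k] = LG[g];           // -inf when grid[g] == 0
          ltk[k] = &LT[d][(size_t)g * U];
        }
        for (int i = 0; i < n; ++i) {
          if (N(i, d) <= 0) continue;
          const double yy = (double)y(i, d);
          const double nn = (double)(N(i, d) - y(i, d));
          const int u = uidx[d][i];
          double* Li = &Lmat[(size_t)i * K];
          if (yy > 0.0) {
            for (int k = 0; k < K; ++k) Li[k] += yy * lgk[k] + nn * ltk[k][u];
          } else if (nn > 0.0) {
            for (int k = 0; k < K; ++k) Li[k] += nn * ltk[k][u];
          }
        }
      }
      for (int i = 0; i < n; ++i) {
        const double* Li = &Lmat[(size_t)i * K];
        double mx = R_NegInf;
        for (int k = 0; k < K; ++k) if (Li[k] > mx) mx = Li[k];
        double tot = 0.0;
        for (int k = 0; k < K; ++k) {
          prob[k] = R_FINITE(Li[k]) ? std::exp(Li[k] - mx) : 0.0;
          tot += prob[k];
        }
        double r = unif_rand() * tot, acc = 0.0;
        int pick = K - 1;
        for (int k = 0; k < K; ++k) { acc += prob[k]; if (r <= acc) { pick = k; break; } }
        z[i] = pick;
      }
    }

    // --- concentration parameter (Escobar & West 1995)
    int kocc = 0;
    {
      std::fill(nk.begin(), nk.end(), 0);
      for (int i = 0; i < n; ++i) nk[z[i]]++;
      for (int k = 0; k < K; ++k) if (nk[k] > 0) kocc++;
    }
    if (sample_alpha) {
      double eta = R::rbeta(alpha + 1.0, (double)n);
      double b = prior_rate - std::log(eta);
      double odds = (prior_shape + kocc - 1.0) / ((double)n * b);
      double shape = (unif_rand() < odds / (1.0 + odds))
                       ? prior_shape + kocc : prior_shape + kocc - 1.0;
      alpha = R::rgamma(shape, 1.0 / b);
      if (alpha < 1e-6) alpha = 1e-6;
    }

    // --- record
    if (it >= burn_in && ((it - burn_in) % thin == 0) && kept < n_keep) {
      for (int i = 0; i < n; ++i) z_trace(kept, i) = z[i] + 1;
      for (int k = 0; k < K; ++k)
        for (int d = 0; d < D; ++d)
          pi_trace[kept + n_keep * (k + K * d)] = grid[gi[(size_t)k * D + d]];
      alpha_trace[kept] = alpha;
      kocc_trace[kept] = kocc;
      for (int i = 0; i < n; ++i)
        for (int j = i + 1; j < n; ++j)
          if (z[i] == z[j]) { cocl(i, j) += 1.0; }
      kept++;
    }
  }

  for (int i = 0; i < n; ++i) {
    cocl(i, i) = (double)kept;
    for (int j = i + 1; j < n; ++j) cocl(j, i) = cocl(i, j);
  }
  if (kept > 0) {
    for (int i = 0; i < n; ++i)
      for (int j = 0; j < n; ++j) cocl(i, j) /= (double)kept;
  }

  pi_trace.attr("dim") = IntegerVector::create(n_keep, K, D);
  return List::create(_["z_trace"] = z_trace,
                      _["pi_trace"] = pi_trace,
                      _["alpha_trace"] = alpha_trace,
                      _["k_occupied"] = kocc_trace,
                      _["coclustering"] = cocl,
                      _["n_kept"] = kept);
}
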