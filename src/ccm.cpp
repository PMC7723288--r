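#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Convergent cross mapping core. For every target row, a library of the
// requested size is drawn uniformly without replacement from that target's
// candidate pool (rows within the calendar-proximity constraint, prepared
// in R). The k nearest library rows in state space predict the target's
// covariate as an exponentially weighted average, u_i = exp(-d_i / d_1)
// (all-equal weights when d_1 == 0). One Pearson rho per draw, computed
// over all non-skipped targets. Uses R's RNG so draws are reproducible
// draw-for-draw under set.seed().
// [[Rcpp::export]]
List ccm_cpp(NumericMatrix coords, NumericVector cov, List pools,
             IntegerVector lib_sizes, int k, int n_draws, bool uniform) {
  const int n = coords.nrow();
  const int d = coords.ncol();
  const int n_sizes = lib_sizes.size();
  NumericMatrix rho(n_draws, n_sizes);
  IntegerVector n_used(n_sizes);

  std::vector<std::vector<int>> pool(n);
  for (int i = 0; i < n; ++i) {
    IntegerVector p = pools[i];
    pool[i] = std::vector<int>(p.begin(), p.end());
  }

  std::vector<int> buf;
  std::vector<double> dist;
  std::vector<int> ord;

  for (int si = 0; si < n_sizes; ++si) {
    const int L = lib_sizes[si];
    int used = 0;
    for (int i = 0; i < n; ++i) if ((int)pool[i].size() >= L) ++used;
    n_used[si] = used;
    for (int dr = 0; dr < n_draws; ++dr) {
      std::vector<double> pred, obs;
      pred.reserve(used);
      obs.reserve(used);
      for (int i = 0; i < n; ++i) {
        const int m = (int)pool[i].size();
        if (m < L) continue;
        buf = pool[i];
        // partial Fisher-Yates: first L entries are the drawn library
        for (int t = 0; t < L; ++t) {
          int j = t + (int)(unif_rand() * (m - t));
          if (j >= m) j = m - 1;
          std::swap(buf[t], buf[j]);
        }
        dist.assign(L, 0.0);
        for (int t = 0; t < L; ++t) {
          double s = 0.0;
          const int r = buf[t];
          for (int c = 0; c < d; ++c) {
            const double df = coords(i, c) - coords(r, c);
            s += df * df;
          }
          dist[t] = std::sqrt(s);
        }
        ord.resize(L);
        for (int t = 0; t < L; ++t) ord[t] = t;
        std::partial_sort(ord.begin(), ord.begin() + k, ord.end(),
                          [&](int a, int b) {
                            return dist[a] < dist[b] ||
                                   (dist[a] == dist[b] && a < b);
                          });
        const double d1 = dist[ord[0]];
        double wsum = 0.0, psum = 0.0;
        for (int t = 0; t < k; ++t) {
          double w = 1.0;
          if (!uniform && d1 > 0.0) w = std::exp(-dist[ord[t]] / d1);
          wsum += w;
          psum += w * cov[buf[ord[t]]];
        }
        pred.push_back(psum / wsum);
        obs.push_back(cov[i]);
      }
      const int np = (int)pred.size();
      if (np < 3) {
        rho(dr, si) = NA_REAL;
        continue;
      }
      double mp = 0.0, mo = 0.0;
      for (int t = 0; t < np; ++t) { mp += pred[t]; mo += obs[t]; }
      mp /= np; mo /= np;
      double sxy = 0.0, sxx = 0.0, syy = 0.0;
      for (int t = 0; t < np; ++t) {
        const double a = pred[t] - mp, b = obs[t] - mo;
        sxy += a * b; sxx += a * a; syy += b * b;
      }
      rho(dr, si) = (sxx > 0.0 && syy > 0.0)
                        ? sxy / std::sqrt(sxx * syy)
                        : NA_REAL;
    }
  }
  return List::create(_["rho"] = rho, _["n_used"] = n_used);
}
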