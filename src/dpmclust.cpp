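// Collapsed Gibbs sampler for the Dirichlet process Gaussian mixture with a
// conjugate normal-inverse-gamma / normal-inverse-Wishart base measure, plus
// the quadratic-cost posterior summaries (posterior similarity matrix and
// PSM-based candidate scores).  All randomness goes through R's RNG so that
// set.seed() in R controls the chain.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

namespace {

// conjugate model with flat-array sufficient statistics (d kept small);
// cluster stats are (m, s[d], ss[d*d]) with ss the raw sum of outer products
struct ConjModel {
  int d;
  std::vector<double> mu0, delta2;  // delta2 is d*d row-major
  double c, nu;
  double logc, logdet_delta2, lmvg_nu;
  std::vector<double> lmvg;  // lmvg[m] = log multivariate gamma((nu+m)/2)
  mutable std::vector<double> lam;  // scratch d*d

  ConjModel(const arma::vec& mu0_, double c_, double nu_,
            const arma::mat& delta2_, int nmax)
      : d(mu0_.n_elem), c(c_), nu(nu_) {
    mu0.assign(mu0_.begin(), mu0_.end());
    delta2.resize(d * d);
    for (int a = 0; a < d; ++a)
      for (int b = 0; b < d; ++b) delta2[a * d + b] = delta2_(a, b);
    logc = std::log(c);
    double sign;
    arma::log_det(logdet_delta2, sign, delta2_);
    lmvg.resize(nmax + 2);
    for (int m = 0; m <= nmax + 1; ++m) lmvg[m] = lmvgamma((nu + m) / 2.0);
    lmvg_nu = lmvg[0];
    lam.resize(d * d);
  }

  double lmvgamma(double a) const {
    double out = 0.25 * d * (d - 1) * std::log(M_PI);
    for (int i = 1; i <= d; ++i) out += std::lgamma(a + (1.0 - i) / 2.0);
    return out;
  }

  // log marginal likelihood from sufficient statistics
  double lml(int m, const double* s, const double* ss) const {
    if (m == 0) return 0.0;
    const double cn = c + m;
    for (int a = 0; a < d; ++a) {
      const double ya = s[a] / m, da = ya - mu0[a];
      for (int b = 0; b < d; ++b) {
        const double yb = s[b] / m, db = yb - mu0[b];
        lam[a * d + b] = delta2[a * d + b] + ss[a * d + b] - m * ya * yb +
                         (c * m / cn) * da * db;
      }
    }
    double logdet_n;
    if (d == 1) {
      logdet_n = std::log(lam[0]);
    } else if (d == 2) {
      logdet_n = std::log(lam[0] * lam[3] - lam[1] * lam[2]);
    } else {
      arma::mat L(&lam[0], d, d);
      double sign;
      arma::log_det(logdet_n, sign, L);
    }
    return -0.5 * m * d * std::log(M_PI) +
           0.5 * d * (logc - std::log(cn)) + lmvg[m] - lmvg_nu +
           0.5 * nu * logdet_delta2 - 0.5 * (nu + m) * logdet_n;
  }
};

// canonical order-of-appearance relabelling of z (values in 1..n) into row
// `row` of out
void canonical_row(const std::vector<int>& z, IntegerMatrix& out, int row) {
  int n = z.size();
  std::vector<int> map(n + 1, 0);
  int next = 0;
  for (int i = 0; i < n; ++i) {
    int lab = z[i];
    if (map[lab] == 0) map[lab] = ++next;
    out(row, i) = map[lab];
  }
}

}  // namespace

// [[Rcpp::export(name = ".cpp_dp_gibbs")]]
IntegerMatrix cpp_dp_gibbs(const arma::mat& y, const arma::vec& mu0, double c,
                           double nu, const arma::mat& delta2, double alpha,
                           int iterations, int burn_in, int thinning,
                           IntegerVector z_init) {
  const int n = y.n_rows, d = y.n_cols;
  ConjModel mod(mu0, c, nu, delta2, n);
  const int dd = d * d;

  // row-major copy of the data and per-observation outer products
  std::vector<double> ydat(n * d), yout(n * dd);
  for (int i = 0; i < n; ++i)
    for (int a = 0; a < d; ++a) {
      ydat[i * d + a] = y(i, a);
      for (int b = 0; b < d; ++b)
        yout[i * dd + a * d + b] = y(i, a) * y(i, b);
    }

  // cluster slots: counts, sums, sums of outer products, cached lml
  std::vector<int> count;
  std::vector<double> sum, ssq, clml;  // sum: K*d, ssq: K*dd
  std::vector<int> z(n);               // slot index per observation

  {
    std::vector<int> map;
    for (int i = 0; i < n; ++i) {
      int lab = z_init[i], slot = -1;
      for (size_t j = 0; j < map.size(); ++j)
        if (map[j] == lab) { slot = j; break; }
      if (slot < 0) {
        slot = map.size();
        map.push_back(lab);
        count.push_back(0);
        sum.insert(sum.end(), d, 0.0);
        ssq.insert(ssq.end(), dd, 0.0);
        clml.push_back(0.0);
      }
      z[i] = slot;
      count[slot] += 1;
      for (int a = 0; a < d; ++a) sum[slot * d + a] += ydat[i * d + a];
      for (int a = 0; a < dd; ++a) ssq[slot * dd + a] += yout[i * dd + a];
    }
    for (size_t j = 0; j < count.size(); ++j)
      clml[j] = mod.lml(count[j], &sum[j * d], &ssq[j * dd]);
  }

  // lml of each observation as a singleton (constant over sweeps)
  std::vector<double> lml1(n);
  for (int i = 0; i < n; ++i)
    lml1[i] = mod.lml(1, &ydat[i * d], &yout[i * dd]);

  // draw count contract: floor((iterations - burn_in) / thinning) kept draws
  const int n_keep = (iterations - burn_in) / thinning;
  IntegerMatrix draws(n_keep, n);

  std::vector<double> logw, cumw, lml_with, stmp(d), sstmp(dd);
  int stored = 0;
  for (int t = 1; t <= iterations; ++t) {
    for (int i = 0; i < n; ++i) {
      const double* yi = &ydat[i * d];
      const double* yyi = &yout[i * dd];
      int slot = z[i];
      // remove i from its cluster
      count[slot] -= 1;
      for (int a = 0; a < d; ++a) sum[slot * d + a] -= yi[a];
      for (int a = 0; a < dd; ++a) ssq[slot * dd + a] -= yyi[a];
      if (count[slot] == 0) {
        int last = count.size() - 1;
        if (slot != last) {
          count[slot] = count[last];
          for (int a = 0; a < d; ++a) sum[slot * d + a] = sum[last * d + a];
          for (int a = 0; a < dd; ++a)
            ssq[slot * dd + a] = ssq[last * dd + a];
          clml[slot] = clml[last];
          for (int u = 0; u < n; ++u)
            if (z[u] == last) z[u] = slot;
        }
        count.pop_back();
        sum.resize(sum.size() - d);
        ssq.resize(ssq.size() - dd);
        clml.pop_back();
      } else {
        clml[slot] = mod.lml(count[slot], &sum[slot * d], &ssq[slot * dd]);
      }

      const int K = count.size();
      logw.assign(K + 1, 0.0);
      lml_with.assign(K, 0.0);
      for (int j = 0; j < K; ++j) {
        for (int a = 0; a < d; ++a) stmp[a] = sum[j * d + a] + yi[a];
        for (int a = 0; a < dd; ++a) sstmp[a] = ssq[j * dd + a] + yyi[a];
        lml_with[j] = mod.lml(count[j] + 1, &stmp[0], &sstmp[0]);
        logw[j] = std::log((double)count[j]) + lml_with[j] - clml[j];
      }
      logw[K] = std::log(alpha) + lml1[i];

      double mx = logw[0];
      for (int j = 1; j <= K; ++j) mx = std::max(mx, logw[j]);
      cumw.assign(K + 1, 0.0);
      double tot = 0.0;
      for (int j = 0; j <= K; ++j) {
        tot += std::exp(logw[j] - mx);
        cumw[j] = tot;
      }
      double u = unif_rand() * tot;
      int pick = 0;
      while (pick < K && u > cumw[pick]) ++pick;

      if (pick == K) {  // open a new cluster
        count.push_back(1);
        sum.insert(sum.end(), yi, yi + d);
        ssq.insert(ssq.end(), yyi, yyi + dd);
        clml.push_back(lml1[i]);
        z[i] = K;
      } else {
        count[pick] += 1;
        for (int a = 0; a < d; ++a) sum[pick * d + a] += yi[a];
        for (int a = 0; a < dd; ++a) ssq[pick * dd + a] += yyi[a];
        clml[pick] = lml_with[pick];
        z[i] = pick;
      }
    }
    if (t > burn_in && (t - burn_in) % thinning == 0 && stored < n_keep) {
      std::vector<int> z1(n);
      for (int i = 0; i < n; ++i) z1[i] = z[i] + 1;
      canonical_row(z1, draws, stored);
      ++stored;
    }
  }
  return draws;
}

// [[Rcpp::export(name = ".cpp_psm")]]
NumericMatrix cpp_psm(const IntegerMatrix& draws) {
  const int M = draws.nrow(), n = draws.ncol();
  NumericMatrix P(n, n);
  double* p = REAL(P);
  std::vector<int> zi(n);
  for (int m = 0; m < M; ++m) {
    for (int i = 0; i < n; ++i) zi[i] = draws(m, i);
    for (int i = 0; i < n; ++i) {
      const int a = zi[i];
      double* col = p + (size_t)i * n;  // column i (symmetric target)
      for (int j = i + 1; j < n; ++j)
        if (zi[j] == a) col[j] += 1.0;
    }
  }
  for (int i = 0; i < n; ++i) {
    P(i, i) = 1.0;
    for (int j = i + 1; j < n; ++j) {
      double v = p[(size_t)i * n + j] / M;
      P(j, i) = v;
      P(i, j) = v;
    }
  }
  return P;
}

// posterior-expected Binder loss of each candidate row, computed from the
// PSM: sum_{i<j} p_ij + sum over within-cluster pairs of (1 - 2 p_ij)
// [[Rcpp::export(name = ".cpp_expected_binder")]]
NumericVector cpp_expected_binder(const IntegerMatrix& cands,
                                  const NumericMatrix& psm) {
  const int C = cands.nrow(), n = cands.ncol();
  const double* p = REAL(psm);
  double base = 0.0;
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) base += p[(size_t)i * n + j];
  NumericVector out(C);
  std::vector<int> zi(n);
  std::vector<std::vector<int> > members;
  for (int c = 0; c < C; ++c) {
    int k = 0;
    for (int i = 0; i < n; ++i) {
      zi[i] = cands(c, i);
      k = std::max(k, zi[i]);
    }
    members.assign(k, std::vector<int>());
    for (int i = 0; i < n; ++i) members[zi[i] - 1].push_back(i);
    double s = base;
    for (int g = 0; g < k; ++g) {
      const std::vector<int>& mem = members[g];
      for (size_t a = 0; a < mem.size(); ++a) {
        const double* col = p + (size_t)mem[a] * n;
        for (size_t b = a + 1; b < mem.size(); ++b)
          s += 1.0 - 2.0 * col[mem[b]];
      }
    }
    out[c] = s;
  }
  return out;
}

// PSM-based variation-of-information criterion (Jensen-swapped expected VI,
// natural logarithms) of each candidate row:
// (1/n) sum_i [ log n_{z_i} + log sum_j p_ij - 2 log sum_{j in cl(i)} p_ij ]
// [[Rcpp::export(name = ".cpp_vi_lb")]]
NumericVector cpp_vi_lb(const IntegerMatrix& cands,
                        const NumericMatrix& psm) {
  const int C = cands.nrow(), n = cands.ncol();
  const double* p = REAL(psm);
  std::vector<double> logrow(n);
  for (int i = 0; i < n; ++i) {
    double s = 0.0;
    const double* col = p + (size_t)i * n;
    for (int j = 0; j < n; ++j) s += col[j];
    logrow[i] = std::log(s);
  }
  NumericVector out(C);
  std::vector<int> zi(n);
  std::vector<std::vector<int> > members;
  for (int c = 0; c < C; ++c) {
    int k = 0;
    for (int i = 0; i < n; ++i) {
      zi[i] = cands(c, i);
      k = std::max(k, zi[i]);
    }
    members.assign(k, std::vector<int>());
    for (int i = 0; i < n; ++i) members[zi[i] - 1].push_back(i);
    double tot = 0.0;
    for (int g = 0; g < k; ++g) {
      const std::vector<int>& mem = members[g];
      const double logsize = std::log((double)mem.size());
      for (size_t a = 0; a < mem.size(); ++a) {
        const double* col = p + (size_t)mem[a] * n;
        double s = 0.0;
        for (size_t b = 0; b < mem.size(); ++b) s += col[mem[b]];
        tot += logsize + logrow[mem[a]] - 2.0 * std::log(s);
      }
    }
    out[c] = tot / n;
  }
  return out;
}

// unnormalized log posterior (DP EPPF + conjugate marginal likelihoods) of
// each candidate row
// [[Rcpp::export(name = ".cpp_log_post")]]
NumericVector cpp_log_post(const IntegerMatrix& cands, const arma::mat& y,
                           const arma::vec& mu0, double c, double nu,
                           const arma::mat& delta2, double alpha) {
  const int C = cands.nrow(), n = cands.ncol(), d = y.n_cols;
  const int dd = d * d;
  ConjModel mod(mu0, c, nu, delta2, n);
  std::vector<double> ydat(n * d), yout(n * dd);
  for (int i = 0; i < n; ++i)
    for (int a = 0; a < d; ++a) {
      ydat[i * d + a] = y(i, a);
      for (int b = 0; b < d; ++b)
        yout[i * dd + a * d + b] = y(i, a) * y(i, b);
    }
  const double eppf_const = std::lgamma(alpha) - std::lgamma(alpha + n);
  NumericVector out(C);
  std::vector<int> count;
  std::vector<double> sum, ssq;
  for (int cc = 0; cc < C; ++cc) {
    int k = 0;
    for (int i = 0; i < n; ++i) k = std::max(k, cands(cc, i));
    count.assign(k, 0);
    sum.assign(k * d, 0.0);
    ssq.assign(k * dd, 0.0);
    for (int i = 0; i < n; ++i) {
      int g = cands(cc, i) - 1;
      count[g] += 1;
      for (int a = 0; a < d; ++a) sum[g * d + a] += ydat[i * d + a];
      for (int a = 0; a < dd; ++a) ssq[g * dd + a] += yout[i * dd + a];
    }
    double lp = eppf_const + k * std::log(alpha);
    for (int g = 0; g < k; ++g)
      lp += std::lgamma((double)count[g]) +
            mod.lml(count[g], &sum[g * d], &ssq[g * dd]);
    out[cc] = lp;
  }
  return out;
}
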