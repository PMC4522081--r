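#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Single-chain Gibbs sampler for the weighted linear mixed model
//   y = 1 mu + X g + Z a + e,  e ~ N(0, D sigma2_e), d_ii = 1/w_i,
// with g ~ N(0, I sigma2_g) (model 0, "Bayesian BLUP") or a four-component
// normal mixture with fixed proportions and ordered variances (model 1),
// and an optional polygenic effect a ~ N(0, A sigma2_a) updated single-site
// through the sparse A-inverse. Variance components get the flat-prior
// conditionals: scaled inverse-chi-square with df = count - 2 (floored at 1)
// and scale = weighted sum of squares. Uses R's RNG, so chains are
// reproducible from set.seed() on the R side.
//
// Ainv is passed in compressed sparse column form (full pattern, both
// triangles). train_animal maps each phenotype row to its 0-based index in
// the a vector (the a vector spans all animals: unphenotyped animals are
// carried in the chain through the pedigree prior alone).

static inline double rinvchisq_scaled(double df, double scale) {
  double chi = R::rchisq(df);
  if (chi <= 0) chi = 1e-12;
  double v = scale / chi;
  return v > 1e-12 ? v : 1e-12;
}

// [[Rcpp::export]]
List gibbs_core(NumericVector y, NumericMatrix X, NumericVector w,
                IntegerVector Ai, IntegerVector Ap, NumericVector Ax,
                int n_all, IntegerVector train_animal,
                int model, NumericVector prop,
                int chain_length, int burn_in, int thin,
                bool update_vars, bool include_polygenic,
                NumericVector var_g0, double var_a0, double var_e0,
                bool keep_samples) {
  const int n = y.size();
  const int q = X.ncol();
  const int K = (model == 1) ? 4 : 1;
  if (X.nrow() != n) stop("X rows do not match y");
  if (burn_in >= chain_length) stop("burn_in must be smaller than chain_length");
  if ((int)var_g0.size() != K) stop("var_g0 must have length %d", K);

  std::vector<double> g(q, 0.0), a(n_all, 0.0), e(n);
  double mu = 0.0, sw = 0.0;
  for (int i = 0; i < n; ++i) { mu += w[i] * y[i]; sw += w[i]; }
  mu /= sw;
  for (int i = 0; i < n; ++i) e[i] = y[i] - mu;

  // sparse-column view of X (haploblock designs are mostly zeros; SNP
  // dosage matrices also benefit) with pre-weighted values, plus the
  // weighted column sums of squares
  std::vector<double> xtwx(q);
  std::vector<size_t> cptr(q + 1, 0);
  std::vector<int> ridx;
  std::vector<double> val, wval;
  for (int j = 0; j < q; ++j) {
    const double *xj = &X(0, j);
    double s = 0.0;
    for (int i = 0; i < n; ++i) {
      if (xj[i] != 0.0) {
        ridx.push_back(i);
        val.push_back(xj[i]);
        wval.push_back(w[i] * xj[i]);
        s += w[i] * xj[i] * xj[i];
      }
    }
    xtwx[j] = s;
    cptr[j + 1] = ridx.size();
  }

  // animal -> phenotype row (-1 if unphenotyped)
  std::vector<int> pheno_row(n_all, -1);
  for (int i = 0; i < n; ++i) {
    int an = train_animal[i];
    if (an >= 0) pheno_row[an] = i;
  }

  std::vector<double> var_k(var_g0.begin(), var_g0.end());
  double var_a = var_a0, var_e = var_e0;
  std::vector<int> label(q, 0);

  const int n_keep = (chain_length - burn_in) / thin +
                     (((chain_length - burn_in) % thin) ? 1 : 0);
  std::vector<double> mu_sum(1, 0.0), g_sum(q, 0.0), a_sum(n_all, 0.0);
  std::vector<double> vark_sum(K, 0.0);
  double vara_sum = 0.0, vare_sum = 0.0;
  std::vector<double> label_prob(model == 1 ? (size_t)q * 4 : 0, 0.0);
  NumericMatrix var_trace(n_keep, K + 2);
  NumericMatrix samples(keep_samples ? n_keep : 0,
                        keep_samples ? 1 + q + n_all : 0);
  int kept = 0;

  for (int cyc = 0; cyc < chain_length; ++cyc) {
    // --- general mean ---
    double swe = 0.0;
    for (int i = 0; i < n; ++i) swe += w[i] * (e[i] + mu);
    double mu_new = swe / sw + R::norm_rand() * std::sqrt(var_e / sw);
    for (int i = 0; i < n; ++i) e[i] -= (mu_new - mu);
    mu = mu_new;

    // --- marker / haploblock effects ---
    for (int j = 0; j < q; ++j) {
      const size_t lo = cptr[j], hi = cptr[j + 1];
      double gj = g[j];
      double r = 0.0;
      for (size_t t = lo; t < hi; ++t) r += wval[t] * e[ridx[t]];
      r += xtwx[j] * gj;          // rhs with effect j removed from residual
      double rhs = r / var_e;
      int k = 0;
      if (model == 1) {
        double logw[4], mx = -INFINITY;
        for (int c = 0; c < 4; ++c) {
          double C = xtwx[j] / var_e + 1.0 / var_k[c];
          logw[c] = std::log(prop[c]) - 0.5 * std::log(var_k[c]) -
                    0.5 * std::log(C) + 0.5 * rhs * rhs / C;
          if (logw[c] > mx) mx = logw[c];
        }
        double tot = 0.0, cum[4];
        for (int c = 0; c < 4; ++c) { tot += std::exp(logw[c] - mx); cum[c] = tot; }
        double u = R::unif_rand() * tot;
        while (k < 3 && u > cum[k]) ++k;
        label[j] = k;
      }
      double C = xtwx[j] / var_e + 1.0 / var_k[k];
      double gnew = rhs / C + R::norm_rand() / std::sqrt(C);
      if (xtwx[j] > 0.0) {       // zero column: gnew is already a prior draw
        double diff = gnew - gj;
        for (size_t t = lo; t < hi; ++t) e[ridx[t]] -= val[t] * diff;
      }
      g[j] = gnew;
    }

    // --- polygenic effects (single-site through sparse A-inverse) ---
    if (include_polygenic) {
      for (int an = 0; an < n_all; ++an) {
        double diagv = 0.0, off = 0.0;
        for (int kk = Ap[an]; kk < Ap[an + 1]; ++kk) {
          int row = Ai[kk];
          if (row == an) diagv = Ax[kk];
          else off += Ax[kk] * a[row];
        }
        double C = diagv / var_a, rhs2 = -off / var_a;
        int pr = pheno_row[an];
        if (pr >= 0) {
          C += w[pr] / var_e;
          rhs2 += w[pr] * (e[pr] + a[an]) / var_e;
        }
        double anew = rhs2 / C + R::norm_rand() / std::sqrt(C);
        if (pr >= 0) e[pr] -= (anew - a[an]);
        a[an] = anew;
      }
    }

    // --- variance components ---
    if (update_vars) {
      if (model == 0) {
        double ss = 0.0;
        for (int j = 0; j < q; ++j) ss += g[j] * g[j];
        double df = q - 2 >= 1 ? q - 2 : 1;
        var_k[0] = rinvchisq_scaled(df, ss);
      } else {
        double ss[4] = {0, 0, 0, 0};
        int cnt[4] = {0, 0, 0, 0};
        for (int j = 0; j < q; ++j) { ss[label[j]] += g[j] * g[j]; ++cnt[label[j]]; }
        double cand[4];
        bool ok = false;
        for (int attempt = 0; attempt < 10 && !ok; ++attempt) {
          for (int c = 0; c < 4; ++c) {
            if (cnt[c] == 0) { cand[c] = var_k[c]; continue; }
            double df = cnt[c] - 2 >= 1 ? cnt[c] - 2 : 1;
            cand[c] = rinvchisq_scaled(df, ss[c]);
          }
          ok = cand[0] < cand[1] && cand[1] < cand[2] && cand[2] < cand[3];
        }
        if (!ok) std::sort(cand, cand + 4);       // sort-projection fallback
        for (int c = 0; c < 4; ++c) var_k[c] = cand[c];
        // strictness guard after sorting ties
        for (int c = 1; c < 4; ++c)
          if (var_k[c] <= var_k[c - 1]) var_k[c] = var_k[c - 1] * (1.0 + 1e-8);
      }
      if (include_polygenic) {
        double ssa = 0.0;
        for (int an = 0; an < n_all; ++an)
          for (int kk = Ap[an]; kk < Ap[an + 1]; ++kk)
            ssa += a[an] * Ax[kk] * a[Ai[kk]];
        double df = n_all - 2 >= 1 ? n_all - 2 : 1;
        var_a = rinvchisq_scaled(df, ssa);
      }
      double sse = 0.0;
      for (int i = 0; i < n; ++i) sse += w[i] * e[i] * e[i];
      double dfe = n - 2 >= 1 ? n - 2 : 1;
      var_e = rinvchisq_scaled(dfe, sse);
    }

    for (int i = 0; i < n; ++i) {
      if (!R_FINITE(e[i]))
        stop("non-finite residual at cycle %d (row %d)", cyc + 1, i + 1);
    }

    // --- accumulate posterior means after burn-in ---
    if (cyc >= burn_in && (cyc - burn_in) % thin == 0) {
      mu_sum[0] += mu;
      for (int j = 0; j < q; ++j) g_sum[j] += g[j];
      for (int an = 0; an < n_all; ++an) a_sum[an] += a[an];
      for (int c = 0; c < K; ++c) { vark_sum[c] += var_k[c]; var_trace(kept, c) = var_k[c]; }
      var_trace(kept, K) = var_a;
      var_trace(kept, K + 1) = var_e;
      vara_sum += var_a;
      vare_sum += var_e;
      if (model == 1)
        for (int j = 0; j < q; ++j) label_prob[(size_t)j * 4 + label[j]] += 1.0;
      if (keep_samples) {
        samples(kept, 0) = mu;
        for (int j = 0; j < q; ++j) samples(kept, 1 + j) = g[j];
        for (int an = 0; an < n_all; ++an) samples(kept, 1 + q + an) = a[an];
      }
      ++kept;
    }
  }

  NumericVector g_mean(q), a_mean(n_all), vark_mean(K);
  for (int j = 0; j < q; ++j) g_mean[j] = g_sum[j] / kept;
  for (int an = 0; an < n_all; ++an) a_mean[an] = a_sum[an] / kept;
  for (int c = 0; c < K; ++c) vark_mean[c] = vark_sum[c] / kept;
  NumericMatrix lp(model == 1 ? q : 0, model == 1 ? 4 : 0);
  if (model == 1)
    for (int j = 0; j < q; ++j)
      for (int c = 0; c < 4; ++c) lp(j, c) = label_prob[(size_t)j * 4 + c] / kept;

  return List::create(
    _["mu"] = mu_sum[0] / kept,
    _["g"] = g_mean,
    _["a"] = a_mean,
    _["var_g"] = vark_mean,
    _["var_a"] = vara_sum / kept,
    _["var_e"] = vare_sum / kept,
    _["n_retained"] = kept,
    _["var_trace"] = var_trace,
    _["label_prob"] = lp,
    _["samples"] = samples
  );
}
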