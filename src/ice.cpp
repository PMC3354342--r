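#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Marginal log-likelihood terms and BLUP for the single-SNP model
// y = b g + e, Var(g) = s2, Var(e) = I ve.  Only the pieces that differ
// between mixture components are needed inside the sweep: the data-dependent
// terms y'y and n log(ve) cancel in the posterior odds.
static inline void component_terms(double bty, double btb,
                                   double s2, double ve,
                                   double &ghat, double &llpart) {
  if (s2 <= 0.0 || btb <= 0.0) {
    ghat = 0.0;
    llpart = 0.0; // log(btb*0/ve + 1) = 0; quadratic correction 0
    return;
  }
  ghat = bty / (btb + ve / s2);
  // -0.5*log(b'b s2/ve + 1) + 0.5 * y'b ghat / ve
  llpart = -0.5 * std::log(btb * s2 / ve + 1.0) + 0.5 * bty * ghat / ve;
}

// Posterior probability of the big component, log-space with clamping.
static inline double posterior_big(double pi, double llbig, double llsmall) {
  double z = std::log1p(-pi) - std::log(pi) + llsmall - llbig;
  if (z > 700.0) z = 700.0;
  if (z < -700.0) z = -700.0;
  return 1.0 / (1.0 + std::exp(z));
}

// Iterative conditional expectation solver for the two-component mixture
// prior.  B is n x M standardized genotypes, y the records.  pi, s1, s2 are
// the mixture proportion and component variances, ve the residual variance.
// Residual maintained incrementally; recomputed from scratch every
// `recompute_every` sweeps and at convergence to bound drift.
// [[Rcpp::export]]
List mixp_fit_cpp(const NumericMatrix &B, const NumericVector &y,
                  double pi, double s1, double s2, double ve,
                  double tol, int max_iter, int recompute_every) {
  const int n = B.nrow(), M = B.ncol();
  std::vector<double> g(M, 0.0), prob(M, pi), btb(M);
  for (int i = 0; i < M; ++i) {
    double s = 0.0;
    for (int j = 0; j < n; ++j) s += B(j, i) * B(j, i);
    btb[i] = s;
  }
  double mu = mean(y);
  std::vector<double> r(n);
  for (int j = 0; j < n; ++j) r[j] = y[j] - mu;

  int iter = 0;
  bool converged = false;
  double dsq = 0.0, ssq = 0.0;
  while (iter < max_iter && !converged) {
    ++iter;
    // mean update first, once per sweep
    double dbar = 0.0;
    for (int j = 0; j < n; ++j) dbar += r[j];
    dbar /= n;
    mu += dbar;
    for (int j = 0; j < n; ++j) r[j] -= dbar;

    dsq = 0.0;
    for (int i = 0; i < M; ++i) {
      if (btb[i] <= 0.0) continue; // constant column: effect fixed at 0
      double bty = 0.0;
      for (int j = 0; j < n; ++j) bty += B(j, i) * r[j];
      bty += btb[i] * g[i]; // b' ytilde, ytilde = r + b g_old
      double g1, g2, ll1, ll2;
      component_terms(bty, btb[i], s1, ve, g1, ll1);
      component_terms(bty, btb[i], s2, ve, g2, ll2);
      double p1 = posterior_big(pi, ll1, ll2);
      double gnew = p1 * g1 + (1.0 - p1) * g2;
      if (!std::isfinite(gnew))
        stop("non-finite effect update at SNP %d", i + 1);
      double d = gnew - g[i];
      if (d != 0.0) for (int j = 0; j < n; ++j) r[j] -= B(j, i) * d;
      dsq += d * d;
      g[i] = gnew;
      prob[i] = p1;
    }
    ssq = 0.0;
    for (int i = 0; i < M; ++i) ssq += g[i] * g[i];
    if (dsq == 0.0 || (ssq > 0.0 && dsq < tol * ssq)) converged = true;
    if (converged || iter % recompute_every == 0) {
      for (int j = 0; j < n; ++j) {
        double f = y[j] - mu;
        for (int i = 0; i < M; ++i) f -= B(j, i) * g[i];
        r[j] = f;
      }
    }
  }
  return List::create(_["g_hat"] = NumericVector(g.begin(), g.end()),
                      _["mu"] = mu,
                      _["prob_big"] = NumericVector(prob.begin(), prob.end()),
                      _["residual"] = NumericVector(r.begin(), r.end()),
                      _["iterations"] = iter,
                      _["converged"] = converged,
                      _["change_sq_sum"] = dsq,
                      _["solution_sq_sum"] = ssq);
}

// Gauss-Seidel SNP-BLUP: single normal prior with variance s2 for every
// marker, same sweep schedule and convergence rule as the mixture solver.
// [[Rcpp::export]]
List gblup_gs_cpp(const NumericMatrix &B, const NumericVector &y,
                  double s2, double ve, double tol, int max_iter,
                  int recompute_every) {
  const int n = B.nrow(), M = B.ncol();
  std::vector<double> g(M, 0.0), btb(M);
  for (int i = 0; i < M; ++i) {
    double s = 0.0;
    for (int j = 0; j < n; ++j) s += B(j, i) * B(j, i);
    btb[i] = s;
  }
  double mu = mean(y);
  std::vector<double> r(n);
  for (int j = 0; j < n; ++j) r[j] = y[j] - mu;
  int iter = 0;
  bool converged = false;
  while (iter < max_iter && !converged) {
    ++iter;
    double dbar = 0.0;
    for (int j = 0; j < n; ++j) dbar += r[j];
    dbar /= n;
    mu += dbar;
    for (int j = 0; j < n; ++j) r[j] -= dbar;
    double dsq = 0.0;
    for (int i = 0; i < M; ++i) {
      if (btb[i] <= 0.0) continue;
      double bty = 0.0;
      for (int j = 0; j < n; ++j) bty += B(j, i) * r[j];
      bty += btb[i] * g[i];
      double gnew = bty / (btb[i] + ve / s2);
      if (!std::isfinite(gnew))
        stop("non-finite effect update at SNP %d", i + 1);
      double d = gnew - g[i];
      if (d != 0.0) for (int j = 0; j < n; ++j) r[j] -= B(j, i) * d;
      dsq += d * d;
      g[i] = gnew;
    }
    double ssq = 0.0;
    for (int i = 0; i < M; ++i) ssq += g[i] * g[i];
    if (dsq == 0.0 || (ssq > 0.0 && dsq < tol * ssq)) converged = true;
    if (converged || iter % recompute_every == 0) {
      for (int j = 0; j < n; ++j) {
        double f = y[j] - mu;
        for (int i = 0; i < M; ++i) f -= B(j, i) * g[i];
        r[j] = f;
      }
    }
  }
  return List::create(_["g_hat"] = NumericVector(g.begin(), g.end()),
                      _["mu"] = mu, _["iterations"] = iter,
                      _["converged"] = converged);
}

// BayesB-style Gibbs sampler.  Two-component normal mixture on effects:
// a fraction pi of SNP in a big component with locus-specific variance under
// a scaled inverse-chi^2(df, S1) prior, the rest share one small variance
// under scaled inverse-chi^2(df, S2).  Component indicator sampled from the
// marginal (effect-integrated) likelihood ratio; effect from its Gaussian
// full conditional; residual variance known and fixed.  Uses R's RNG.
// [[Rcpp::export]]
List bayesb_cpp(const NumericMatrix &B, const NumericVector &y,
                double pi, double s1, double s2, double ve, double df,
                int n_iter, int n_burnin, int thin) {
  const int n = B.nrow(), M = B.ncol();
  const double S1 = s1 * (df - 2.0) / df; // prior mean of inv-chi2(df,S) is df*S/(df-2)
  const double S2 = s2 * (df - 2.0) / df;
  std::vector<double> g(M, 0.0), btb(M), v1(M, s1);
  std::vector<int> ind(M, 0);
  for (int i = 0; i < M; ++i) {
    double s = 0.0;
    for (int j = 0; j < n; ++j) s += B(j, i) * B(j, i);
    btb[i] = s;
  }
  double mu = mean(y), v2 = s2;
  std::vector<double> r(n);
  for (int j = 0; j < n; ++j) r[j] = y[j] - mu;

  std::vector<double> gsum(M, 0.0), gsqsum(M, 0.0), psum(M, 0.0);
  double musum = 0.0;
  int nkept = 0;
  int nthin = (n_iter + thin - 1) / thin;
  NumericMatrix chain(nthin, 4); // iter, mu, sum g^2, n_big
  int crow = 0;

  for (int it = 1; it <= n_iter; ++it) {
    // mean: Gaussian full conditional
    double dbar = 0.0;
    for (int j = 0; j < n; ++j) dbar += r[j];
    dbar /= n;
    double mu_new = mu + dbar + norm_rand() * std::sqrt(ve / n);
    for (int j = 0; j < n; ++j) r[j] += mu - mu_new;
    mu = mu_new;

    int nbig = 0;
    double ssq_small = 0.0;
    int nsmall = 0;
    for (int i = 0; i < M; ++i) {
      if (btb[i] <= 0.0) continue;
      double bty = 0.0;
      for (int j = 0; j < n; ++j) bty += B(j, i) * r[j];
      bty += btb[i] * g[i];
      double g1, g2, ll1, ll2;
      component_terms(bty, btb[i], v1[i], ve, g1, ll1);
      component_terms(bty, btb[i], v2, ve, g2, ll2);
      double p1 = posterior_big(pi, ll1, ll2);
      int z = (unif_rand() < p1) ? 1 : 0;
      double v = z ? v1[i] : v2;
      double cvar = ve / (btb[i] + ve / v);
      double cmean = bty / (btb[i] + ve / v);
      double gnew = cmean + norm_rand() * std::sqrt(cvar);
      double d = gnew - g[i];
      if (d != 0.0) for (int j = 0; j < n; ++j) r[j] -= B(j, i) * d;
      g[i] = gnew;
      ind[i] = z;
      if (z) {
        ++nbig;
        v1[i] = (df * S1 + gnew * gnew) / R::rchisq(df + 1.0);
      } else {
        ssq_small += gnew * gnew;
        ++nsmall;
        v1[i] = df * S1 / R::rchisq(df); // prior draw when unoccupied
      }
    }
    v2 = (df * S2 + ssq_small) / R::rchisq(df + nsmall);

    if (it > n_burnin) {
      ++nkept;
      musum += mu;
      for (int i = 0; i < M; ++i) {
        gsum[i] += g[i];
        gsqsum[i] += g[i] * g[i];
        psum[i] += ind[i];
      }
    }
    if (it % thin == 0 && crow < nthin) {
      double gsq = 0.0;
      for (int i = 0; i < M; ++i) gsq += g[i] * g[i];
      chain(crow, 0) = it;
      chain(crow, 1) = mu;
      chain(crow, 2) = gsq;
      chain(crow, 3) = nbig;
      ++crow;
    }
  }
  NumericVector gh(M), gsd(M), pb(M);
  for (int i = 0; i < M; ++i) {
    gh[i] = gsum[i] / nkept;
    double v = gsqsum[i] / nkept - gh[i] * gh[i];
    gsd[i] = v > 0 ? std::sqrt(v) : 0.0;
    pb[i] = psum[i] / nkept;
  }
  return List::create(_["g_hat"] = gh, _["g_sd"] = gsd, _["prob_big"] = pb,
                      _["mu"] = musum / nkept,
                      _["chain"] = chain(Range(0, crow - 1), _));
}
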