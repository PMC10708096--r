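#include <Rcpp.h>
using namespace Rcpp;

// Admixture-model Gibbs sampler for unphased biallelic genotypes.
//
// Data: dosage matrix X (n x L), entries 0/1/2 or NA (missing calls
// contribute no allele copies). Model: each of the two allele copies of
// individual i at locus l originates from cluster z ~ Categorical(q_i) and
// is the alternate allele with probability p_{z,l}. Priors: q_i ~
// Dirichlet(alpha, ..., alpha) with alpha fixed; p_{k,l} ~ Beta(1,1)
// independently, or, under the correlated-frequencies (F-model) prior,
// p_{k,l} ~ Beta(pA_l (1-F_k)/F_k, (1-pA_l)(1-F_k)/F_k) with pA and F
// updated by Metropolis steps.
//
// All randomness flows through R's RNG (RNGScope), so runs are exactly
// reproducible from set.seed() on the R side.

static inline double rbeta_safe(double a, double b) {
  double x = R::rbeta(a, b);
  if (x < 1e-9) x = 1e-9;
  if (x > 1 - 1e-9) x = 1 - 1e-9;
  return x;
}

// [[Rcpp::export(name = ".gibbs_admixture_cpp")]]
List gibbs_admixture_cpp(IntegerMatrix X, int K, int burn_in, int run_length,
                         double alpha, bool correlated) {
  if (K < 1) stop("K must be >= 1");
  const int n = X.nrow(), L = X.ncol();
  RNGScope scope;

  NumericMatrix P(K, L);   // cluster allele frequencies
  NumericMatrix Q(n, K);   // membership coefficients
  NumericVector pA(L);     // F-model ancestral frequencies
  NumericVector Fk(K, 0.1);

  for (int k = 0; k < K; ++k)
    for (int l = 0; l < L; ++l) P(k, l) = rbeta_safe(1.0, 1.0);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < K; ++k) Q(i, k) = 1.0 / K;
  for (int l = 0; l < L; ++l) pA[l] = 0.5;

  NumericMatrix q_sum(n, K), p_sum(K, L);
  std::vector<double> ll_trace;
  ll_trace.reserve(run_length);

  std::vector<double> prob(K);
  // sufficient statistics refreshed each sweep
  NumericMatrix n1(K, L), n0(K, L);
  NumericMatrix m(n, K);

  const int total = burn_in + run_length;
  for (int it = 0; it < total; ++it) {
    std::fill(n1.begin(), n1.end(), 0.0);
    std::fill(n0.begin(), n0.end(), 0.0);
    std::fill(m.begin(), m.end(), 0.0);

    // latent origins of each allele copy
    for (int i = 0; i < n; ++i) {
      for (int l = 0; l < L; ++l) {
        int x = X(i, l);
        if (x == NA_INTEGER) continue;
        for (int copy = 0; copy < 2; ++copy) {
          int a = (x == 2) ? 1 : (x == 0 ? 0 : copy); // het: one 0, one 1
          if (K == 1) {
            if (a == 1) n1(0, l) += 1; else n0(0, l) += 1;
            m(i, 0) += 1;
            continue;
          }
          double tot = 0.0;
          for (int k = 0; k < K; ++k) {
            double lik = a == 1 ? P(k, l) : 1.0 - P(k, l);
            prob[k] = Q(i, k) * lik;
            tot += prob[k];
          }
          double u = unif_rand() * tot, cum = 0.0;
          int z = K - 1;
          for (int k = 0; k < K; ++k) {
            cum += prob[k];
            if (u <= cum) { z = k; break; }
          }
          if (a == 1) n1(z, l) += 1; else n0(z, l) += 1;
          m(i, z) += 1;
        }
      }
    }

    // allele frequencies
    for (int k = 0; k < K; ++k) {
      double apar = 1.0, bpar = 1.0;
      for (int l = 0; l < L; ++l) {
        if (correlated) {
          double lambda = (1.0 - Fk[k]) / Fk[k];
          apar = pA[l] * lambda;
          bpar = (1.0 - pA[l]) * lambda;
        }
        P(k, l) = rbeta_safe(apar + n1(k, l), bpar + n0(k, l));
      }
    }

    if (correlated) {
      // Metropolis update of ancestral frequencies pA_l
      for (int l = 0; l < L; ++l) {
        double cur = pA[l];
        double prop = cur + (unif_rand() - 0.5) * 0.1;
        if (prop <= 0.001 || prop >= 0.999) continue;
        double logr = 0.0;
        for (int k = 0; k < K; ++k) {
          double lam = (1.0 - Fk[k]) / Fk[k];
          logr += R::dbeta(P(k, l), prop * lam, (1 - prop) * lam, 1) -
                  R::dbeta(P(k, l), cur * lam, (1 - cur) * lam, 1);
        }
        if (log(unif_rand()) < logr) pA[l] = prop;
      }
      // Metropolis update of per-cluster drift F_k
      for (int k = 0; k < K; ++k) {
        double cur = Fk[k];
        double prop = cur + (unif_rand() - 0.5) * 0.05;
        if (prop <= 0.001 || prop >= 0.999) continue;
        double lam_c = (1.0 - cur) / cur, lam_p = (1.0 - prop) / prop;
        double logr = 0.0;
        for (int l = 0; l < L; ++l) {
          logr += R::dbeta(P(k, l), pA[l] * lam_p, (1 - pA[l]) * lam_p, 1) -
                  R::dbeta(P(k, l), pA[l] * lam_c, (1 - pA[l]) * lam_c, 1);
        }
        if (log(unif_rand()) < logr) Fk[k] = prop;
      }
    }

    // membership coefficients: Dirichlet(alpha + copy counts)
    for (int i = 0; i < n; ++i) {
      double tot = 0.0;
      for (int k = 0; k < K; ++k) {
        double gdraw = R::rgamma(alpha + m(i, k), 1.0);
        if (gdraw < 1e-300) gdraw = 1e-300;
        Q(i, k) = gdraw;
        tot += gdraw;
      }
      for (int k = 0; k < K; ++k) Q(i, k) /= tot;
    }

    if (it >= burn_in) {
      // log-likelihood of the genotypes given (Q, P)
      double ll = 0.0;
      for (int i = 0; i < n; ++i) {
        for (int l = 0; l < L; ++l) {
          int x = X(i, l);
          if (x == NA_INTEGER) continue;
          double r = 0.0;
          for (int k = 0; k < K; ++k) r += Q(i, k) * P(k, l);
          if (r < 1e-12) r = 1e-12;
          if (r > 1 - 1e-12) r = 1 - 1e-12;
          double pr = x == 0 ? (1 - r) * (1 - r)
                    : x == 1 ? 2 * r * (1 - r)
                             : r * r;
          ll += log(pr);
        }
      }
      if (!R_finite(ll)) stop("non-finite likelihood during sampling");
      ll_trace.push_back(ll);
      for (int i = 0; i < n; ++i)
        for (int k = 0; k < K; ++k) q_sum(i, k) += Q(i, k);
      for (int k = 0; k < K; ++k)
        for (int l = 0; l < L; ++l) p_sum(k, l) += P(k, l);
    }
  }

  const double R = (double) run_length;
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < K; ++k) q_sum(i, k) /= R;
  for (int k = 0; k < K; ++k)
    for (int l = 0; l < L; ++l) p_sum(k, l) /= R;

  return List::create(_["q_mean"] = q_sum, _["freq_mean"] = p_sum,
                      _["loglik"] = NumericVector(ll_trace.begin(),
                                                  ll_trace.end()));
}
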