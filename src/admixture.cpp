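#include <Rcpp.h>
using namespace Rcpp;

// Gibbs sampler for the standard admixture model of population structure.
//
// geno:       n_ind x n_cols integer matrix of allele codes (0..J_l-1),
//             -1 for missing; one column per allele copy (haploid loci carry
//             one column, diploid loci two).
// col_locus:  0-based locus index per column.
// n_alleles:  number of distinct alleles per locus.
// Updates: allele-copy cluster labels Z given (Q, P); cluster allele
// frequencies P ~ Dirichlet(lambda + counts); ancestry Q ~ Dirichlet(alpha +
// counts); alpha by random-walk Metropolis with uniform prior on
// (0, alpha_max]. The data log-likelihood log P(X | P, Q) is recorded each
// retained sweep for the posterior-probability estimator.
// [[Rcpp::export]]
List gibbs_admixture_cpp(IntegerMatrix geno, IntegerVector col_locus,
                         IntegerVector n_alleles, int K, int burn_in,
                         int reps, double lambda, double alpha_init,
                         double alpha_max, double alpha_propsd,
                         bool admixture) {
  const int n = geno.nrow();
  const int C = geno.ncol();
  const int L = n_alleles.size();

  std::vector<int> offset(L, 0);
  int tot_alleles = 0;
  for (int l = 0; l < L; ++l) {
    offset[l] = tot_alleles;
    tot_alleles += n_alleles[l];
  }

  NumericMatrix Q(n, K);
  // P is allele-major: entry (offset[l]+x)*K + k, so sweeps over k are
  // contiguous in memory
  std::vector<double> P((size_t)K * tot_alleles);
  std::fill(Q.begin(), Q.end(), 1.0 / K);
  for (int l = 0; l < L; ++l)
    for (int j = 0; j < n_alleles[l]; ++j)
      for (int k = 0; k < K; ++k)
        P[(size_t)(offset[l] + j) * K + k] = 1.0 / n_alleles[l];

  double alpha = alpha_init;
  NumericMatrix Qsum(n, K);
  std::vector<double> Psum((size_t)K * tot_alleles, 0.0);
  double alpha_sum = 0.0;
  NumericVector loglik(reps);

  std::vector<double> cntP((size_t)K * tot_alleles);
  std::vector<double> cntQ((size_t)n * K);
  std::vector<double> prob(K);
  std::vector<double> g(K);

  const int total = burn_in + reps;
  for (int sweep = 0; sweep < total; ++sweep) {
    std::fill(cntP.begin(), cntP.end(), 0.0);
    std::fill(cntQ.begin(), cntQ.end(), 0.0);

    if (admixture) {
      for (int i = 0; i < n; ++i) {
        for (int c = 0; c < C; ++c) {
          int x = geno(i, c);
          if (x < 0) continue;
          const double *pa = &P[(size_t)(offset[col_locus[c]] + x) * K];
          double s = 0.0;
          for (int k = 0; k < K; ++k) {
            prob[k] = Q(i, k) * pa[k];
            s += prob[k];
          }
          double u = R::runif(0.0, s);
          int k = 0;
          double acc = prob[0];
          while (u > acc && k < K - 1) acc += prob[++k];
          cntP[(size_t)(offset[col_locus[c]] + x) * K + k] += 1.0;
          cntQ[(size_t)i * K + k] += 1.0;
        }
      }
    } else {
      // no-admixture model: one cluster label per individual
      for (int i = 0; i < n; ++i) {
        double mx = -1e300;
        for (int k = 0; k < K; ++k) prob[k] = 0.0;
        for (int c = 0; c < C; ++c) {
          int x = geno(i, c);
          if (x < 0) continue;
          const double *pa = &P[(size_t)(offset[col_locus[c]] + x) * K];
          for (int k = 0; k < K; ++k) prob[k] += std::log(pa[k]);
        }
        for (int k = 0; k < K; ++k) if (prob[k] > mx) mx = prob[k];
        double s = 0.0;
        for (int k = 0; k < K; ++k) {
          prob[k] = std::exp(prob[k] - mx);
          s += prob[k];
        }
        double u = R::runif(0.0, s);
        int k = 0;
        double acc = prob[0];
        while (u > acc && k < K - 1) acc += prob[++k];
        for (int c = 0; c < C; ++c) {
          int x = geno(i, c);
          if (x < 0) continue;
          cntP[(size_t)(offset[col_locus[c]] + x) * K + k] += 1.0;
        }
        cntQ[(size_t)i * K + k] += 1.0;
      }
    }

    // P | Z  ~ Dirichlet(lambda + counts)
    for (int k = 0; k < K; ++k) {
      for (int l = 0; l < L; ++l) {
        double s = 0.0;
        for (int j = 0; j < n_alleles[l]; ++j) {
          double d = R::rgamma(lambda + cntP[(size_t)(offset[l] + j) * K + k], 1.0);
          P[(size_t)(offset[l] + j) * K + k] = d;
          s += d;
        }
        for (int j = 0; j < n_alleles[l]; ++j)
          P[(size_t)(offset[l] + j) * K + k] /= s;
      }
    }

    // Q | Z ~ Dirichlet(alpha + counts)
    if (admixture) {
      for (int i = 0; i < n; ++i) {
        double s = 0.0;
        for (int k = 0; k < K; ++k) {
          double d = R::rgamma(alpha + cntQ[(size_t)i * K + k], 1.0);
          g[k] = d;
          s += d;
        }
        for (int k = 0; k < K; ++k) Q(i, k) = g[k] / s;
      }
      // alpha by random-walk Metropolis, uniform prior on (0, alpha_max]
      if (K > 1) {
        double a_new = alpha + R::norm_rand() * alpha_propsd;
        if (a_new > 0 && a_new <= alpha_max) {
          double slq = 0.0;
          for (int i = 0; i < n; ++i)
            for (int k = 0; k < K; ++k) slq += std::log(Q(i, k) + 1e-300);
          double lr = n * (R::lgammafn(K * a_new) - K * R::lgammafn(a_new)
                           - R::lgammafn(K * alpha) + K * R::lgammafn(alpha))
                      + (a_new - alpha) * slq;
          if (std::log(R::unif_rand()) < lr) alpha = a_new;
        }
      }
    } else {
      for (int i = 0; i < n; ++i) {
        double tot_i = 0.0;
        for (int k = 0; k < K; ++k) tot_i += cntQ[(size_t)i * K + k];
        for (int k = 0; k < K; ++k)
          Q(i, k) = tot_i > 0 ? cntQ[(size_t)i * K + k] / tot_i : 1.0 / K;
      }
    }

    if (sweep >= burn_in) {
      double ll = 0.0;
      for (int i = 0; i < n; ++i) {
        for (int c = 0; c < C; ++c) {
          int x = geno(i, c);
          if (x < 0) continue;
          const double *pa = &P[(size_t)(offset[col_locus[c]] + x) * K];
          double s = 0.0;
          for (int k = 0; k < K; ++k) s += Q(i, k) * pa[k];
          ll += std::log(s + 1e-300);
        }
      }
      loglik[sweep - burn_in] = ll;
      alpha_sum += alpha;
      for (int i = 0; i < n; ++i)
        for (int k = 0; k < K; ++k) Qsum(i, k) += Q(i, k);
      for (size_t z = 0; z < Psum.size(); ++z) Psum[z] += P[z];
    }
  }

  NumericMatrix Qmean(n, K);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < K; ++k) Qmean(i, k) = Qsum(i, k) / reps;
  NumericMatrix Pmean(K, tot_alleles);
  for (int k = 0; k < K; ++k)
    for (int j = 0; j < tot_alleles; ++j)
      Pmean(k, j) = Psum[(size_t)j * K + k] / reps;

  return List::create(_["Q"] = Qmean, _["P"] = Pmean,
                      _["alpha"] = alpha_sum / reps,
                      _["loglik"] = loglik);
}
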