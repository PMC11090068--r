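#include <Rcpp.h>
using namespace Rcpp;

// Diploid Li-Stephens forward-backward over the K x K haplotype-pair state
// space.  Transitions factorise per haplotype: with no-switch probability q
// between consecutive sites, a haplotype either stays put or switches to a
// uniformly chosen panel haplotype (including itself), so the per-haplotype
// kernel is q * I + (1 - q)/K.  Applying it to a K x K mass matrix costs
// O(K^2) via row/column sums instead of O(K^3).
//
// gl:        S x 3 genotype likelihoods (need not be normalised; must be >= 0)
// hap:       K x S matrix of panel alleles in {0, 1}
// no_switch: length S; element t is q between sites t-1 and t (element 0 unused)
// eps:       miscopy probability (panel allele read with error eps)
//
// Returns posterior genotype probabilities (S x 3), the total log-likelihood,
// and the per-site scaling factors.

static void transition_inplace(const std::vector<double>& src,
                               std::vector<double>& dst,
                               std::vector<double>& rowsum,
                               std::vector<double>& colsum,
                               int K, double q) {
  const double s = (1.0 - q) / K;
  std::fill(rowsum.begin(), rowsum.end(), 0.0);
  std::fill(colsum.begin(), colsum.end(), 0.0);
  // src[j + K*k]: first haplotype index j varies fastest
  for (int k = 0; k < K; ++k) {
    for (int j = 0; j < K; ++j) {
      const double v = src[j + K * k];
      rowsum[j] += v;  // sum over k for fixed j
      colsum[k] += v;  // sum over j for fixed k
    }
  }
  // one step in haplotype 1: A[j,k] = q*src[j,k] + s*colsum[k]
  // then haplotype 2:        B[j,k] = q*A[j,k] + s * sum_k A[j, k]
  // sum_k A[j,k] = q*rowsum[j] + s * total, with total = sum(src)
  double total = 0.0;
  for (int k = 0; k < K; ++k) total += colsum[k];
  for (int k = 0; k < K; ++k) {
    for (int j = 0; j < K; ++j) {
      const double a = q * src[j + K * k] + s * colsum[k];
      const double arow = q * rowsum[j] + s * total;
      dst[j + K * k] = q * a + s * arow;
    }
  }
}

// [[Rcpp::export(name = ".ls_diploid_fb")]]
List ls_diploid_fb(NumericMatrix gl, IntegerMatrix hap, NumericVector no_switch,
                   double eps) {
  const int S = gl.nrow();
  const int K = hap.nrow();
  if (K < 2) stop("reference panel must contain at least 2 haplotypes");
  if (gl.ncol() != 3) stop("gl must have 3 columns");
  if (hap.ncol() != S) stop("hap must have one column per site");
  if (no_switch.size() != S) stop("no_switch must have one entry per site");

  const int KK = K * K;
  // p_alt[k, t] = P(read alt allele | copying haplotype k) with miscopying
  std::vector<double> palt(K);

  // store scaled forward matrices for the backward/posterior pass
  std::vector<double> alpha((size_t)S * KK);
  std::vector<double> emis((size_t)S * KK);
  std::vector<double> scale(S);
  std::vector<double> cur(KK), nxt(KK), rowsum(K), colsum(K);

  for (int t = 0; t < S; ++t) {
    for (int k = 0; k < K; ++k)
      palt[k] = hap(k, t) == 1 ? 1.0 - eps : eps;
    const double g0 = gl(t, 0), g1 = gl(t, 1), g2 = gl(t, 2);
    double* et = &emis[(size_t)t * KK];
    for (int k = 0; k < K; ++k) {
      const double pk = palt[k];
      for (int j = 0; j < K; ++j) {
        const double pj = palt[j];
        et[j + K * k] = g0 * (1.0 - pj) * (1.0 - pk) +
                        g1 * (pj * (1.0 - pk) + (1.0 - pj) * pk) +
                        g2 * pj * pk;
      }
    }
  }

  // forward
  double loglik = 0.0;
  for (int t = 0; t < S; ++t) {
    const double* et = &emis[(size_t)t * KK];
    double* at = &alpha[(size_t)t * KK];
    if (t == 0) {
      const double init = 1.0 / KK;
      for (int i = 0; i < KK; ++i) at[i] = init * et[i];
    } else {
      const double* prev = &alpha[(size_t)(t - 1) * KK];
      std::copy(prev, prev + KK, cur.begin());
      transition_inplace(cur, nxt, rowsum, colsum, K, no_switch[t]);
      for (int i = 0; i < KK; ++i) at[i] = nxt[i] * et[i];
    }
    double c = 0.0;
    for (int i = 0; i < KK; ++i) c += at[i];
    if (c <= 0) stop("forward pass underflowed to zero mass at a site");
    for (int i = 0; i < KK; ++i) at[i] /= c;
    scale[t] = c;
    loglik += std::log(c);
  }

  // backward + posterior genotype probabilities
  NumericMatrix gp(S, 3);
  std::vector<double> beta(KK, 1.0);
  std::vector<double> tmp(KK);
  for (int t = S - 1; t >= 0; --t) {
    const double* at = &alpha[(size_t)t * KK];
    const double* et = &emis[(size_t)t * KK];
    // posterior over states: alpha_t * beta_t (both scaled); normalise
    double z = 0.0;
    for (int i = 0; i < KK; ++i) {
      tmp[i] = at[i] * beta[i];
      z += tmp[i];
    }
    for (int i = 0; i < KK; ++i) tmp[i] /= z;
    // genotype posterior: split each state's mass over genotypes using the
    // miscopy-perturbed allele-pair distribution reweighted by the GLs
    for (int k = 0; k < K; ++k)
      palt[k] = hap(k, t) == 1 ? 1.0 - eps : eps;
    const double g0 = gl(t, 0), g1 = gl(t, 1), g2 = gl(t, 2);
    double p0 = 0.0, p1 = 0.0, p2 = 0.0;
    for (int k = 0; k < K; ++k) {
      const double pk = palt[k];
      for (int j = 0; j < K; ++j) {
        const double pj = palt[j];
        const double w0 = g0 * (1.0 - pj) * (1.0 - pk);
        const double w1 = g1 * (pj * (1.0 - pk) + (1.0 - pj) * pk);
        const double w2 = g2 * pj * pk;
        const double wsum = w0 + w1 + w2;
        if (wsum > 0) {
          const double m = tmp[j + K * k] / wsum;
          p0 += m * w0;
          p1 += m * w1;
          p2 += m * w2;
        }
      }
    }
    const double psum = p0 + p1 + p2;
    gp(t, 0) = p0 / psum;
    gp(t, 1) = p1 / psum;
    gp(t, 2) = p2 / psum;

    // recurse beta to site t-1: beta_{t-1} = T^T (e_t * beta_t) / c_t
    if (t > 0) {
      for (int i = 0; i < KK; ++i) cur[i] = et[i] * beta[i];
      transition_inplace(cur, nxt, rowsum, colsum, K, no_switch[t]);
      for (int i = 0; i < KK; ++i) beta[i] = nxt[i] / scale[t];
    }
  }

  return List::create(_["gp"] = gp, _["loglik"] = loglik,
                      _["scale"] = NumericVector(scale.begin(), scale.end()));
}
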