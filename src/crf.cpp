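// Linear-chain CRF over BIO labels with sparse indicator features.
// Parameter layout (L = 3 labels, F = feature count):
//   emission  par[f*L + y]           f in 0..F-1
//   transition par[L*F + yp*L + y]
//   start     par[L*F + L*L + y]
// The objective is the L2-penalized negative log-likelihood,
// penalty ||w||^2 / (2C); gradients come from forward-backward marginals.
#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static const int L = 3;

static inline double logsumexp3(double a, double b, double c) {
  double m = a > b ? (a > c ? a : c) : (b > c ? b : c);
  return m + std::log(std::exp(a - m) + std::exp(b - m) + std::exp(c - m));
}

// [[Rcpp::export]]
List crf_nll_grad(NumericVector par, IntegerVector feats,
                  IntegerVector tok_ptr, IntegerVector seq_ptr,
                  IntegerVector labels, int n_feat, double C) {
  const int n_seq = seq_ptr.size() - 1;
  const int off_trans = L * n_feat;
  const int off_start = off_trans + L * L;
  NumericVector grad(par.size());
  double nll = 0.0;

  std::vector<double> score, alpha, beta, marg;
  for (int s = 0; s < n_seq; ++s) {
    const int t0 = seq_ptr[s], t1 = seq_ptr[s + 1];
    const int T = t1 - t0;
    if (T == 0) continue;
    score.assign((size_t)T * L, 0.0);
    for (int t = 0; t < T; ++t) {
      for (int k = tok_ptr[t0 + t]; k < tok_ptr[t0 + t + 1]; ++k) {
        const int base = feats[k] * L;
        score[t * L + 0] += par[base + 0];
        score[t * L + 1] += par[base + 1];
        score[t * L + 2] += par[base + 2];
      }
    }
    // forward
    alpha.assign((size_t)T * L, 0.0);
    for (int y = 0; y < L; ++y)
      alpha[y] = par[off_start + y] + score[y];
    for (int t = 1; t < T; ++t)
      for (int y = 0; y < L; ++y)
        alpha[t * L + y] = score[t * L + y] + logsumexp3(
            alpha[(t - 1) * L + 0] + par[off_trans + 0 * L + y],
            alpha[(t - 1) * L + 1] + par[off_trans + 1 * L + y],
            alpha[(t - 1) * L + 2] + par[off_trans + 2 * L + y]);
    const double logZ = logsumexp3(alpha[(T - 1) * L],
                                   alpha[(T - 1) * L + 1],
                                   alpha[(T - 1) * L + 2]);
    // backward
    beta.assign((size_t)T * L, 0.0);
    for (int t = T - 2; t >= 0; --t)
      for (int y = 0; y < L; ++y)
        beta[t * L + y] = logsumexp3(
            par[off_trans + y * L + 0] + score[(t + 1) * L + 0] + beta[(t + 1) * L + 0],
            par[off_trans + y * L + 1] + score[(t + 1) * L + 1] + beta[(t + 1) * L + 1],
            par[off_trans + y * L + 2] + score[(t + 1) * L + 2] + beta[(t + 1) * L + 2]);

    // gold path score
    double gold = par[off_start + labels[t0]] + score[labels[t0]];
    for (int t = 1; t < T; ++t)
      gold += par[off_trans + labels[t0 + t - 1] * L + labels[t0 + t]] +
              score[t * L + labels[t0 + t]];
    nll += logZ - gold;

    // node marginals and expected minus observed counts
    marg.assign((size_t)T * L, 0.0);
    for (int t = 0; t < T; ++t)
      for (int y = 0; y < L; ++y)
        marg[t * L + y] = std::exp(alpha[t * L + y] + beta[t * L + y] - logZ);
    for (int t = 0; t < T; ++t) {
      for (int k = tok_ptr[t0 + t]; k < tok_ptr[t0 + t + 1]; ++k) {
        const int base = feats[k] * L;
        grad[base + 0] += marg[t * L + 0];
        grad[base + 1] += marg[t * L + 1];
        grad[base + 2] += marg[t * L + 2];
        grad[base + labels[t0 + t]] -= 1.0;
      }
      grad[off_start + labels[t0]] -= (t == 0 ? 1.0 : 0.0);
    }
    for (int y = 0; y < L; ++y)
      grad[off_start + y] += marg[y];
    // edge marginals
    for (int t = 1; t < T; ++t) {
      grad[off_trans + labels[t0 + t - 1] * L + labels[t0 + t]] -= 1.0;
      for (int yp = 0; yp < L; ++yp)
        for (int y = 0; y < L; ++y)
          grad[off_trans + yp * L + y] += std::exp(
              alpha[(t - 1) * L + yp] + par[off_trans + yp * L + y] +
              score[t * L + y] + beta[t * L + y] - logZ);
    }
  }

  // L2 penalty
  const double inv_C = 1.0 / C;
  double pen = 0.0;
  for (R_xlen_t i = 0; i < par.size(); ++i) {
    pen += par[i] * par[i];
    grad[i] += par[i] * inv_C;
  }
  nll += 0.5 * pen * inv_C;
  return List::create(_["value"] = nll, _["grad"] = grad);
}

// [[Rcpp::export]]
IntegerVector crf_viterbi(NumericVector par, IntegerVector feats,
                          IntegerVector tok_ptr, IntegerVector seq_ptr,
                          int n_feat) {
  const int n_seq = seq_ptr.size() - 1;
  const int off_trans = L * n_feat;
  const int off_start = off_trans + L * L;
  IntegerVector out(tok_ptr.size() - 1);
  std::vector<double> delta;
  std::vector<int> back;
  for (int s = 0; s < n_seq; ++s) {
    const int t0 = seq_ptr[s], t1 = seq_ptr[s + 1];
    const int T = t1 - t0;
    if (T == 0) continue;
    delta.assign((size_t)T * L, 0.0);
    back.assign((size_t)T * L, 0);
    for (int t = 0; t < T; ++t) {
      double sc[L] = {0.0, 0.0, 0.0};
      for (int k = tok_ptr[t0 + t]; k < tok_ptr[t0 + t + 1]; ++k) {
        const int base = feats[k] * L;
        sc[0] += par[base]; sc[1] += par[base + 1]; sc[2] += par[base + 2];
      }
      for (int y = 0; y < L; ++y) {
        if (t == 0) {
          delta[y] = par[off_start + y] + sc[y];
        } else {
          double best = -1e300; int arg = 0;
          for (int yp = 0; yp < L; ++yp) {
            double v = delta[(t - 1) * L + yp] + par[off_trans + yp * L + y];
            if (v > best) { best = v; arg = yp; }
          }
          delta[t * L + y] = best + sc[y];
          back[t * L + y] = arg;
        }
      }
    }
    int y = 0;
    double best = delta[(T - 1) * L];
    for (int k = 1; k < L; ++k)
      if (delta[(T - 1) * L + k] > best) { best = delta[(T - 1) * L + k]; y = k; }
    for (int t = T - 1; t >= 0; --t) {
      out[t0 + t] = y;
      y = back[t * L + y];
    }
  }
  return out;
}
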