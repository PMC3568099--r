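// Margin-based (SVM-style) BIO token chunkers: binary max-margin
// classifiers trained with averaged passive-aggressive (PA-I) updates on
// sparse indicator features, composed one-vs-one or one-vs-all, decoded
// greedily left-to-right with the previous predicted label as a feature
// (forward-parsing chunker emulation). The degree-2 polynomial kernel is
// realized as an explicit hashed pairwise-conjunction feature map.
#include <Rcpp.h>
#include <cstdint>
#include <vector>
using namespace Rcpp;

static const int L = 3;        // B, I, O
static const int BOS = 3;      // previous-label slot for sequence start

static inline uint64_t pair_hash(int i, int j) {
  uint64_t h = (uint64_t)(uint32_t)i * 0x9E3779B97F4A7C15ULL;
  h ^= (uint64_t)(uint32_t)j * 0xC2B2AE3D27D4EB4FULL + (h << 6) + (h >> 2);
  h ^= h >> 29;
  return h;
}

// Build the augmented id list for one token: base features, previous-label
// indicator, bias, and (optionally) hashed pairwise conjunctions of the
// base + previous-label ids.
static void augment(const int* f, int nf, int prev, int n_feat, bool poly2,
                    int hash_dim, std::vector<int>& out) {
  out.clear();
  const int base_dim = n_feat + 5;   // + 4 prev slots + bias
  for (int k = 0; k < nf; ++k) out.push_back(f[k]);
  out.push_back(n_feat + prev);
  if (poly2) {
    const int na = nf + 1;           // base + prev participate in pairs
    for (int a = 0; a < na; ++a)
      for (int b = a + 1; b < na; ++b) {
        int ia = a < nf ? f[a] : n_feat + prev;
        int ib = b < nf ? f[b] : n_feat + prev;
        out.push_back(base_dim + (int)(pair_hash(ia, ib) % (uint64_t)hash_dim));
      }
  }
  out.push_back(n_feat + 4);         // bias
}

struct XorShift {
  uint64_t s;
  explicit XorShift(uint64_t seed) : s(seed * 2685821657736338717ULL + 1ULL) {}
  uint64_t next() {
    s ^= s << 13; s ^= s >> 7; s ^= s << 17;
    return s;
  }
  int below(int n) { return (int)(next() % (uint64_t)n); }
};

// [[Rcpp::export]]
List svm_train_cpp(IntegerVector feats, IntegerVector tok_ptr,
                   IntegerVector seq_ptr, IntegerVector labels,
                   int n_feat, int scheme, bool poly2, double C,
                   int epochs, int hash_dim, int seed) {
  const int n_tok = tok_ptr.size() - 1;
  const int n_seq = seq_ptr.size() - 1;
  const int dim = n_feat + 5 + (poly2 ? hash_dim : 0);

  // previous gold label per token (teacher forcing)
  std::vector<int> prev(n_tok, BOS);
  for (int s = 0; s < n_seq; ++s)
    for (int t = seq_ptr[s] + 1; t < seq_ptr[s + 1]; ++t)
      prev[t] = labels[t - 1];

  // precompute augmented ids once (CSR)
  std::vector<int> aug, aug_ptr(n_tok + 1, 0);
  {
    std::vector<int> tmp;
    for (int t = 0; t < n_tok; ++t) {
      augment(&feats[0] + tok_ptr[t], tok_ptr[t + 1] - tok_ptr[t], prev[t],
              n_feat, poly2, hash_dim, tmp);
      aug.insert(aug.end(), tmp.begin(), tmp.end());
      aug_ptr[t + 1] = (int)aug.size();
    }
  }

  // binary problems: ovo pairs (B,I),(B,O),(I,O); ova class c vs rest
  const int probs = 3;
  const int pa[3] = {0, 0, 1}, pb[3] = {1, 2, 2};
  NumericMatrix W(probs, dim);
  IntegerVector pos_n(probs), neg_n(probs);

  std::vector<double> w(dim), wa(dim);
  std::vector<int> members;
  for (int p = 0; p < probs; ++p) {
    members.clear();
    for (int t = 0; t < n_tok; ++t) {
      int y;
      if (scheme == 0) { // one-vs-one
        if (labels[t] == pa[p]) y = 1;
        else if (labels[t] == pb[p]) y = -1;
        else continue;
      } else {
        y = labels[t] == p ? 1 : -1;
      }
      members.push_back(t);
      if (y > 0) pos_n[p]++; else neg_n[p]++;
    }
    std::fill(w.begin(), w.end(), 0.0);
    std::fill(wa.begin(), wa.end(), 0.0);
    if (pos_n[p] > 0 && neg_n[p] > 0) {
      XorShift rng((uint64_t)seed + 1000003ULL * (uint64_t)(p + 1));
      double tstep = 1.0;
      std::vector<int> order(members);
      for (int e = 0; e < epochs; ++e) {
        for (int i = (int)order.size() - 1; i > 0; --i)
          std::swap(order[i], order[rng.below(i + 1)]);
        for (size_t oi = 0; oi < order.size(); ++oi) {
          const int t = order[oi];
          double y;
          if (scheme == 0) y = labels[t] == pa[p] ? 1.0 : -1.0;
          else y = labels[t] == p ? 1.0 : -1.0;
          double dot = 0.0;
          const int k0 = aug_ptr[t], k1 = aug_ptr[t + 1];
          for (int k = k0; k < k1; ++k) dot += w[aug[k]];
          const double loss = 1.0 - y * dot;
          if (loss > 0.0) {
            double tau = loss / (double)(k1 - k0);
            if (tau > C) tau = C;
            const double step = tau * y;
            for (int k = k0; k < k1; ++k) {
              w[aug[k]] += step;
              wa[aug[k]] += tstep * step;
            }
          }
          tstep += 1.0;
        }
      }
      for (int d = 0; d < dim; ++d)
        W(p, d) = w[d] - wa[d] / tstep;   // averaged weights
    }
  }
  return List::create(_["W"] = W, _["pos_n"] = pos_n, _["neg_n"] = neg_n);
}

// [[Rcpp::export]]
IntegerVector svm_predict_cpp(NumericMatrix W, IntegerVector pos_n,
                              IntegerVector neg_n, IntegerVector feats,
                              IntegerVector tok_ptr, IntegerVector seq_ptr,
                              int n_feat, int scheme, bool poly2,
                              int hash_dim) {
  const int n_tok = tok_ptr.size() - 1;
  const int n_seq = seq_ptr.size() - 1;
  const int pa[3] = {0, 0, 1}, pb[3] = {1, 2, 2};
  IntegerVector out(n_tok);
  std::vector<int> ids;
  for (int s = 0; s < n_seq; ++s) {
    int prev = BOS;
    for (int t = seq_ptr[s]; t < seq_ptr[s + 1]; ++t) {
      double m[3];
      for (int p = 0; p < 3; ++p) {
        if (pos_n[p] == 0 && neg_n[p] == 0) { m[p] = 0.0; continue; }
        if (pos_n[p] == 0) { m[p] = -1e30; continue; }
        if (neg_n[p] == 0) { m[p] = 1e30; continue; }
        m[p] = 0.0;
      }
      augment(&feats[0] + tok_ptr[t], tok_ptr[t + 1] - tok_ptr[t], prev,
              n_feat, poly2, hash_dim, ids);
      for (int p = 0; p < 3; ++p) {
        if (m[p] != 0.0 && (pos_n[p] == 0 || neg_n[p] == 0)) continue;
        double dot = 0.0;
        for (size_t k = 0; k < ids.size(); ++k) dot += W(p, ids[k]);
        m[p] = dot;
      }
      int y;
      if (scheme == 0) { // one-vs-one: majority vote, margin-sum tie-break
        int votes[3] = {0, 0, 0};
        double acc[3] = {0.0, 0.0, 0.0};
        for (int p = 0; p < 3; ++p) {
          if (m[p] >= 0) votes[pa[p]]++; else votes[pb[p]]++;
          acc[pa[p]] += m[p];
          acc[pb[p]] -= m[p];
        }
        y = 0;
        for (int c = 1; c < 3; ++c)
          if (votes[c] > votes[y] || (votes[c] == votes[y] && acc[c] > acc[y]))
            y = c;
      } else {          // one-vs-all: argmax margin
        y = 0;
        for (int c = 1; c < 3; ++c)
          if (m[c] > m[y]) y = c;
      }
      out[t] = y;
      prev = y;
    }
  }
  return out;
}
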