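#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Skip-gram trainer over random-walk corpora (word2vec-style SGD).
// Single-threaded on purpose: with one worker and R's RNG the result is
// bitwise-reproducible for a given seed. Supports negative sampling and
// hierarchical softmax over a Huffman tree built from corpus frequencies.

namespace {

struct HuffmanCode {
  std::vector<int> point;   // inner-node indices on the root path
  std::vector<int> code;    // 0/1 branch labels
};

// Classic two-pointer Huffman construction over sorted counts.
std::vector<HuffmanCode> build_huffman(const std::vector<double> &cnt) {
  const int V = static_cast<int>(cnt.size());
  std::vector<long long> count(2 * V - 1);
  std::vector<int> parent(2 * V - 1), binary(2 * V - 1, 0);
  std::vector<int> order(V);
  for (int i = 0; i < V; ++i) order[i] = i;
  std::sort(order.begin(), order.end(),
            [&](int a, int b) { return cnt[a] > cnt[b]; });
  for (int i = 0; i < V; ++i)
    count[i] = static_cast<long long>(cnt[order[i]] * 1e6) + 1;
  int pos1 = V - 1, pos2 = V;
  for (int a = 0; a < V - 1; ++a) {
    // inner nodes V .. V+a-1 exist at this point
    int min1, min2;
    if (pos1 >= 0 && (pos2 >= V + a || count[pos1] < count[pos2]))
      min1 = pos1--;
    else
      min1 = pos2++;
    if (pos1 >= 0 && (pos2 >= V + a || count[pos1] < count[pos2]))
      min2 = pos1--;
    else
      min2 = pos2++;
    count[V + a] = count[min1] + count[min2];
    parent[min1] = V + a;
    parent[min2] = V + a;
    binary[min2] = 1;
  }
  std::vector<HuffmanCode> codes(V);
  for (int i = 0; i < V; ++i) {
    HuffmanCode hc;
    int node = i;
    while (node != 2 * V - 2) {
      hc.code.push_back(binary[node]);
      hc.point.push_back(parent[node] - V);
      node = parent[node];
    }
    std::reverse(hc.code.begin(), hc.code.end());
    std::reverse(hc.point.begin(), hc.point.end());
    codes[order[i]] = hc;
  }
  return codes;
}

inline double sigmoid(double x) {
  if (x > 8.0) return 1.0;
  if (x < -8.0) return 0.0;
  return 1.0 / (1.0 + std::exp(-x));
}

}  // namespace

// walks: list of integer vectors with 1-based vocab ids; vocab_size V.
// objective: 0 = negative sampling, 1 = hierarchical softmax.
// [[Rcpp::export(name = ".skipgram_train")]]
NumericMatrix skipgram_train(List walks, int vocab_size, int dim, int window,
                             int epochs, int negative, int objective,
                             double alpha) {
  const int V = vocab_size, d = dim;
  if (V < 1) stop("empty vocabulary");

  // Corpus frequencies drive both the Huffman tree and the noise table.
  std::vector<double> cnt(V, 0.0);
  long long total_tokens = 0;
  std::vector<std::vector<int>> corp(walks.size());
  for (int w = 0; w < walks.size(); ++w) {
    IntegerVector wk = walks[w];
    corp[w].assign(wk.begin(), wk.end());
    for (int id : corp[w]) {
      if (id < 1 || id > V) stop("walk token outside vocabulary");
      cnt[id - 1] += 1.0;
      ++total_tokens;
    }
  }
  if (total_tokens == 0) stop("empty corpus");

  // Noise distribution: unigram^0.75, sampled by inverse CDF.
  std::vector<double> cdf(V);
  double z = 0.0;
  for (int i = 0; i < V; ++i) {
    z += std::pow(cnt[i], 0.75);
    cdf[i] = z;
  }
  for (int i = 0; i < V; ++i) cdf[i] /= z;

  std::vector<HuffmanCode> codes;
  if (objective == 1) codes = build_huffman(cnt);

  std::vector<double> syn0(static_cast<size_t>(V) * d);
  std::vector<double> syn1(static_cast<size_t>(std::max(V - 1, V)) * d, 0.0);
  for (size_t i = 0; i < syn0.size(); ++i)
    syn0[i] = (unif_rand() - 0.5) / d;

  const double min_alpha = 1e-4;
  const long long total_work = total_tokens * static_cast<long long>(epochs);
  long long processed = 0;
  std::vector<double> grad(d);

  for (int ep = 0; ep < epochs; ++ep) {
    for (const std::vector<int> &walk : corp) {
      const int L = static_cast<int>(walk.size());
      for (int i = 0; i < L; ++i) {
        double lr = alpha * (1.0 - static_cast<double>(processed) / total_work);
        if (lr < min_alpha) lr = min_alpha;
        ++processed;
        const int center = walk[i] - 1;
        // word2vec's shrunk window: effective radius in [1, window]
        const int shrink = static_cast<int>(unif_rand() * window);
        const int win = window - shrink;
        for (int a = -win; a <= win; ++a) {
          if (a == 0) continue;
          const int j = i + a;
          if (j < 0 || j >= L) continue;
          const int context = walk[j] - 1;
          double *v_in = &syn0[static_cast<size_t>(context) * d];
          std::fill(grad.begin(), grad.end(), 0.0);
          if (objective == 0) {
            for (int neg = 0; neg <= negative; ++neg) {
              int target;
              double label;
              if (neg == 0) {
                target = center;
                label = 1.0;
              } else {
                double u = unif_rand();
                target = static_cast<int>(
                    std::lower_bound(cdf.begin(), cdf.end(), u) - cdf.begin());
                if (target >= V) target = V - 1;
                if (target == center) continue;
                label = 0.0;
              }
              double *v_out = &syn1[static_cast<size_t>(target) * d];
              double dot = 0.0;
              for (int k = 0; k < d; ++k) dot += v_in[k] * v_out[k];
              const double g = (label - sigmoid(dot)) * lr;
              for (int k = 0; k < d; ++k) {
                grad[k] += g * v_out[k];
                v_out[k] += g * v_in[k];
              }
            }
          } else {
            const HuffmanCode &hc = codes[center];
            for (size_t b = 0; b < hc.code.size(); ++b) {
              double *v_out = &syn1[static_cast<size_t>(hc.point[b]) * d];
              double dot = 0.0;
              for (int k = 0; k < d; ++k) dot += v_in[k] * v_out[k];
              const double g = (1.0 - hc.code[b] - sigmoid(dot)) * lr;
              for (int k = 0; k < d; ++k) {
                grad[k] += g * v_out[k];
                v_out[k] += g * v_in[k];
              }
            }
          }
          for (int k = 0; k < d; ++k) v_in[k] += grad[k];
        }
      }
    }
  }

  NumericMatrix out(V, d);
  for (int i = 0; i < V; ++i)
    for (int k = 0; k < d; ++k) out(i, k) = syn0[static_cast<size_t>(i) * d + k];
  return out;
}
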