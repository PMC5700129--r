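#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Global (Needleman-Wunsch) alignment with affine gaps via the three-state
// recurrence: M ends in an aligned pair, D in a gap-in-query column
// (deletion, consumes reference), I in a gap-in-reference column (insertion,
// consumes query). A gap run of length L costs gap_open + L * gap_extend and
// switching directly between D and I reopens. Ties are broken M > D > I at
// every cell so the traceback is deterministic; indels are subsequently
// left-shifted on the R side.
// [[Rcpp::export]]
List nw_align_cpp(std::string ref, std::string query,
                  double match, double mismatch,
                  double gap_open, double gap_extend) {
  const int m = (int) ref.size();
  const int n = (int) query.size();
  const double NEG = -1e18;
  const int W = n + 1;
  std::vector<double> M((m + 1) * W, NEG), D((m + 1) * W, NEG),
      I((m + 1) * W, NEG);
  // predecessor state per cell and state: 0 = M, 1 = D, 2 = I
  std::vector<signed char> bM((m + 1) * W, -1), bD((m + 1) * W, -1),
      bI((m + 1) * W, -1);

  M[0] = 0.0;
  for (int i = 1; i <= m; ++i) {
    D[i * W] = gap_open + i * gap_extend;
    bD[i * W] = (i == 1) ? 0 : 1;
  }
  for (int j = 1; j <= n; ++j) {
    I[j] = gap_open + j * gap_extend;
    bI[j] = (j == 1) ? 0 : 2;
  }

  for (int i = 1; i <= m; ++i) {
    for (int j = 1; j <= n; ++j) {
      const int c = i * W + j, cu = (i - 1) * W + j, cl = i * W + j - 1,
                cd = (i - 1) * W + j - 1;
      const double s = (ref[i - 1] == query[j - 1]) ? match : mismatch;
      double best; signed char bs;

      best = M[cd]; bs = 0;
      if (D[cd] > best) { best = D[cd]; bs = 1; }
      if (I[cd] > best) { best = I[cd]; bs = 2; }
      M[c] = best + s; bM[c] = bs;

      best = M[cu] + gap_open + gap_extend; bs = 0;
      if (D[cu] + gap_extend > best) { best = D[cu] + gap_extend; bs = 1; }
      if (I[cu] + gap_open + gap_extend > best) {
        best = I[cu] + gap_open + gap_extend; bs = 2;
      }
      D[c] = best; bD[c] = bs;

      best = M[cl] + gap_open + gap_extend; bs = 0;
      if (D[cl] + gap_open + gap_extend > best) {
        best = D[cl] + gap_open + gap_extend; bs = 1;
      }
      if (I[cl] + gap_extend > best) { best = I[cl] + gap_extend; bs = 2; }
      I[c] = best; bI[c] = bs;
    }
  }

  const int end = m * W + n;
  double score = M[end]; int state = 0;
  if (D[end] > score) { score = D[end]; state = 1; }
  if (I[end] > score) { score = I[end]; state = 2; }
  if (m == 0 && n == 0) { score = 0.0; }

  std::string ra, qa;
  ra.reserve(m + n); qa.reserve(m + n);
  int i = m, j = n;
  while (i > 0 || j > 0) {
    if (state == 0) {
      const int c = i * W + j;
      ra.push_back(ref[i - 1]); qa.push_back(query[j - 1]);
      state = bM[c]; --i; --j;
    } else if (state == 1) {
      const int c = i * W + j;
      ra.push_back(ref[i - 1]); qa.push_back('-');
      state = bD[c]; --i;
    } else {
      const int c = i * W + j;
      ra.push_back('-'); qa.push_back(query[j - 1]);
      state = bI[c]; --j;
    }
  }
  std::reverse(ra.begin(), ra.end());
  std::reverse(qa.begin(), qa.end());

  return List::create(_["ref_aligned"] = ra, _["query_aligned"] = qa,
                      _["score"] = score);
}
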