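#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Global (Needleman-Wunsch) alignment with affine gaps, Gotoh three-state
// DP. A gap of length L costs gap_open + L * gap_ext (both negative).
// Deterministic tie-breaking in the traceback:
//   * state choice at a cell prefers M (mismatch over gap), then X (gap in
//     target) over Y (gap in reference);
//   * within a gap state, extending the gap is preferred over re-opening,
//     which together with the M preference places equal-scoring gaps
//     leftmost in the alignment.
// States: M = ref[i] aligned to tgt[j]; X = ref[i] against a gap in the
// target; Y = tgt[j] against a gap in the reference.

// [[Rcpp::export(name = ".align_affine_cpp")]]
List align_affine_cpp(std::string ref, std::string tgt,
                      int match, int mismatch, int gap_open, int gap_ext) {
  const int n = ref.size();
  const int m = tgt.size();
  const long NEG = -1000000000L;
  const int W = m + 1;
  std::vector<long> M((n + 1) * W, NEG), X((n + 1) * W, NEG), Y((n + 1) * W, NEG);
  // traceback: predecessor state 0=M 1=X 2=Y
  std::vector<unsigned char> tbM((n + 1) * W), tbX((n + 1) * W), tbY((n + 1) * W);

  M[0] = 0;
  for (int i = 1; i <= n; ++i) {
    X[i * W] = gap_open + (long)gap_ext * i;
    tbX[i * W] = 1;
  }
  tbX[1 * W] = 0;
  for (int j = 1; j <= m; ++j) {
    Y[j] = gap_open + (long)gap_ext * j;
    tbY[j] = 2;
  }
  tbY[1] = 0;

  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      const int idx = i * W + j;
      const int dia = (i - 1) * W + (j - 1);
      const int up = (i - 1) * W + j;
      const int lef = i * W + (j - 1);
      const int s = (ref[i - 1] == tgt[j - 1]) ? match : mismatch;
      // M: predecessor priority M > X > Y
      long best = M[dia];
      unsigned char tb = 0;
      if (X[dia] > best) { best = X[dia]; tb = 1; }
      if (Y[dia] > best) { best = Y[dia]; tb = 2; }
      M[idx] = best + s;
      tbM[idx] = tb;
      // X (gap in target, consume ref): prefer extend (X) then M then Y
      long ext = X[up] + gap_ext;
      long opn = M[up] + gap_open + gap_ext;
      long opy = Y[up] + gap_open + gap_ext;
      best = ext; tb = 1;
      if (opn > best) { best = opn; tb = 0; }
      if (opy > best) { best = opy; tb = 2; }
      X[idx] = best;
      tbX[idx] = tb;
      // Y (gap in reference, consume tgt): prefer extend (Y) then M then X
      long eyt = Y[lef] + gap_ext;
      long oym = M[lef] + gap_open + gap_ext;
      long oyx = X[lef] + gap_open + gap_ext;
      best = eyt; tb = 2;
      if (oym > best) { best = oym; tb = 0; }
      if (oyx > best) { best = oyx; tb = 1; }
      Y[idx] = best;
      tbY[idx] = tb;
    }
  }

  const int end = n * W + m;
  long best = M[end];
  int state = 0;
  if (X[end] > best) { best = X[end]; state = 1; }
  if (Y[end] > best) { best = Y[end]; state = 2; }

  std::string ra, ta;
  ra.reserve(n + m);
  ta.reserve(n + m);
  int i = n, j = m;
  while (i > 0 || j > 0) {
    const int idx = i * W + j;
    if (state == 0) {
      const int prev = tbM[idx];
      ra.push_back(ref[i - 1]);
      ta.push_back(tgt[j - 1]);
      --i; --j;
      state = prev;
    } else if (state == 1) {
      const int prev = tbX[idx];
      ra.push_back(ref[i - 1]);
      ta.push_back('-');
      --i;
      state = prev;
    } else {
      const int prev = tbY[idx];
      ra.push_back('-');
      ta.push_back(tgt[j - 1]);
      --j;
      state = prev;
    }
  }
  std::reverse(ra.begin(), ra.end());
  std::reverse(ta.begin(), ta.end());
  return List::create(_["ref_aln"] = ra, _["tgt_aln"] = ta,
                      _["score"] = (double)best);
}
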