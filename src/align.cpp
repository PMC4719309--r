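#include <Rcpp.h>
using namespace Rcpp;

// Global (Needleman-Wunsch) alignment with linear gap scoring.  Among all
// optimal-score alignments the one with the most identical columns is
// selected (and, among those, the fewest alignment columns), so the percent
// identity reported by pairwise_identity() is well defined even when the
// score optimum is degenerate.  The DP therefore tracks, per cell, the
// lexicographic optimum of (score, matches, -columns).

// [[Rcpp::export]]
List nw_align_stats(std::string a, std::string b,
                    double match, double mismatch, double gap) {
  const int n = a.size(), m = b.size();
  std::vector<double> S_prev(m + 1), S_cur(m + 1);
  std::vector<int> M_prev(m + 1), M_cur(m + 1);
  std::vector<int> C_prev(m + 1), C_cur(m + 1);

  for (int j = 0; j <= m; ++j) {
    S_prev[j] = gap * j; M_prev[j] = 0; C_prev[j] = j;
  }
  for (int i = 1; i <= n; ++i) {
    S_cur[0] = gap * i; M_cur[0] = 0; C_cur[0] = i;
    for (int j = 1; j <= m; ++j) {
      bool is_match = a[i - 1] == b[j - 1];
      double s_diag = S_prev[j - 1] + (is_match ? match : mismatch);
      double s_up = S_prev[j] + gap;
      double s_left = S_cur[j - 1] + gap;

      double best_s = s_diag;
      int best_m = M_prev[j - 1] + (is_match ? 1 : 0);
      int best_c = C_prev[j - 1] + 1;

      // consider up
      if (s_up > best_s ||
          (s_up == best_s && (M_prev[j] > best_m ||
                              (M_prev[j] == best_m && C_prev[j] + 1 < best_c)))) {
        best_s = s_up; best_m = M_prev[j]; best_c = C_prev[j] + 1;
      }
      // consider left
      if (s_left > best_s ||
          (s_left == best_s && (M_cur[j - 1] > best_m ||
                                (M_cur[j - 1] == best_m && C_cur[j - 1] + 1 < best_c)))) {
        best_s = s_left; best_m = M_cur[j - 1]; best_c = C_cur[j - 1] + 1;
      }
      S_cur[j] = best_s; M_cur[j] = best_m; C_cur[j] = best_c;
    }
    std::swap(S_prev, S_cur);
    std::swap(M_prev, M_cur);
    std::swap(C_prev, C_cur);
  }
  return List::create(_["score"] = S_prev[m],
                      _["matches"] = M_prev[m],
                      _["columns"] = C_prev[m]);
}
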