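#include <Rcpp.h>
#include <vector>
#include <string>
#include <algorithm>
using namespace Rcpp;

// Global (Needleman-Wunsch) alignment with linear gap penalty; no
// end-gap forgiveness.  Among score-optimal alignments the DP selects,
// lexicographically, the one with the most identical columns and then
// the shortest alignment, so the reported identity statistics are a
// well-defined function of the unordered sequence pair.  Traceback ties
// (fully equal alternatives) prefer diagonal, then up, then left.
// [[Rcpp::export(name = ".nwAlign")]]
List nwAlign(std::string a, std::string b, double match = 1.0,
             double mismatch = -1.0, double gap = -2.0) {
  const int n = (int)a.size(), m = (int)b.size();
  const int W = m + 1;
  std::vector<double> S((n + 1) * W);
  std::vector<int> M((n + 1) * W), L((n + 1) * W);
  std::vector<unsigned char> T((n + 1) * W); // 0 diag, 1 up, 2 left
  for (int i = 1; i <= n; ++i) {
    S[i * W] = i * gap; M[i * W] = 0; L[i * W] = i; T[i * W] = 1;
  }
  for (int j = 1; j <= m; ++j) {
    S[j] = j * gap; M[j] = 0; L[j] = j; T[j] = 2;
  }
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      const int id = (a[i - 1] == b[j - 1]) ? 1 : 0;
      const int cd = (i - 1) * W + (j - 1), cu = (i - 1) * W + j,
                cl = i * W + (j - 1), cc = i * W + j;
      double s[3] = { S[cd] + (id ? match : mismatch), S[cu] + gap,
                      S[cl] + gap };
      int mm[3] = { M[cd] + id, M[cu], M[cl] };
      int ll[3] = { L[cd] + 1, L[cu] + 1, L[cl] + 1 };
      int best = 0;
      for (int t = 1; t < 3; ++t) {
        if (s[t] > s[best] ||
            (s[t] == s[best] &&
             (mm[t] > mm[best] ||
              (mm[t] == mm[best] && ll[t] < ll[best]))))
          best = t;
      }
      S[cc] = s[best]; M[cc] = mm[best]; L[cc] = ll[best];
      T[cc] = (unsigned char)best;
    }
  }
  std::string aa, ab;
  aa.reserve(n + m); ab.reserve(n + m);
  int i = n, j = m;
  while (i > 0 || j > 0) {
    int t = (i == 0) ? 2 : (j == 0) ? 1 : T[i * W + j];
    if (t == 0) {
      aa.push_back(a[i - 1]); ab.push_back(b[j - 1]); --i; --j;
    } else if (t == 1) {
      aa.push_back(a[i - 1]); ab.push_back('-'); --i;
    } else {
      aa.push_back('-'); ab.push_back(b[j - 1]); --j;
    }
  }
  std::reverse(aa.begin(), aa.end());
  std::reverse(ab.begin(), ab.end());
  const int cc = n * W + m;
  return List::create(_["score"] = S[cc], _["matches"] = M[cc],
                      _["length"] = L[cc], _["aligned_a"] = aa,
                      _["aligned_b"] = ab);
}
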