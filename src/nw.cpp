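#include <Rcpp.h>
using namespace Rcpp;

// Global (Needleman-Wunsch) alignment with linear gap penalty.
// Traceback preference on score ties: diagonal > up (gap in b) > left
// (gap in a), which makes the reported alignment deterministic.
// [[Rcpp::export(name = ".nw_align_cpp")]]
List nw_align_cpp(std::string a, std::string b,
                  double match, double mismatch, double gap) {
  const int n = a.size(), m = b.size();
  NumericMatrix H(n + 1, m + 1);
  IntegerMatrix P(n + 1, m + 1); // 0 = diag, 1 = up, 2 = left
  for (int i = 1; i <= n; ++i) { H(i, 0) = i * gap; P(i, 0) = 1; }
  for (int j = 1; j <= m; ++j) { H(0, j) = j * gap; P(0, j) = 2; }
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      double s = (a[i - 1] == b[j - 1]) ? match : mismatch;
      double d = H(i - 1, j - 1) + s;
      double u = H(i - 1, j) + gap;
      double l = H(i, j - 1) + gap;
      double best = d; int ptr = 0;
      if (u > best) { best = u; ptr = 1; }
      if (l > best) { best = l; ptr = 2; }
      H(i, j) = best; P(i, j) = ptr;
    }
  }
  std::string aa, ab;
  aa.reserve(n + m); ab.reserve(n + m);
  int i = n, j = m;
  while (i > 0 || j > 0) {
    int ptr = (i == 0) ? 2 : (j == 0) ? 1 : P(i, j);
    if (ptr == 0)      { aa += a[i - 1]; ab += b[j - 1]; --i; --j; }
    else if (ptr == 1) { aa += a[i - 1]; ab += '-';      --i; }
    else               { aa += '-';      ab += b[j - 1]; --j; }
  }
  std::reverse(aa.begin(), aa.end());
  std::reverse(ab.begin(), ab.end());
  return List::create(_["score"] = H(n, m),
                      _["aligned_a"] = aa,
                      _["aligned_b"] = ab);
}
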