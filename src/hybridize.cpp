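// Local hybridization scoring between a lncRNA and an mRNA: Smith-Waterman
// style DP on the lncRNA (5'->3') against the mRNA read 3'->5' (antiparallel
// duplex). Pair contributions: G:C = 3, A:U = 2, G:U = 1 (arbitrary units);
// mismatch or gap costs 4. dG = -(best local score).
#include <Rcpp.h>
#include <string>
#include <vector>
#include <algorithm>

using namespace Rcpp;

static inline char norm(char c) {
  if (c >= 'a' && c <= 'z') c -= 32;
  if (c == 'U') c = 'T';
  return c;
}

static inline int pairScore(char a, char b) {
  // a from lncRNA, b from mRNA (both normalised to DNA alphabet)
  if ((a == 'G' && b == 'C') || (a == 'C' && b == 'G')) return 3;
  if ((a == 'A' && b == 'T') || (a == 'T' && b == 'A')) return 2;
  if ((a == 'G' && b == 'T') || (a == 'T' && b == 'G')) return 1;
  return -4;
}

static double bestLocal(const std::string &l, const std::string &mRev,
                        double gap) {
  const int n = (int)l.size(), m = (int)mRev.size();
  std::vector<double> prev(m + 1, 0.0), cur(m + 1, 0.0);
  double best = 0.0;
  for (int i = 1; i <= n; ++i) {
    cur[0] = 0.0;
    const char a = l[i - 1];
    for (int j = 1; j <= m; ++j) {
      double h = prev[j - 1] + pairScore(a, mRev[j - 1]);
      h = std::max(h, prev[j] - gap);
      h = std::max(h, cur[j - 1] - gap);
      h = std::max(h, 0.0);
      cur[j] = h;
      if (h > best) best = h;
    }
    std::swap(prev, cur);
  }
  return best;
}

static void checkAlphabet(const std::string &s, const char *what) {
  for (char c : s) {
    char u = norm(c);
    if (u != 'A' && u != 'C' && u != 'G' && u != 'T')
      stop("%s contains a base outside {A,C,G,U/T}", what);
  }
}

// [[Rcpp::export]]
double cpp_hybridize(std::string lnc, std::string mrna, double gap) {
  if (lnc.empty() || mrna.empty()) stop("sequences must be non-empty");
  checkAlphabet(lnc, "lncRNA sequence");
  checkAlphabet(mrna, "mRNA sequence");
  for (auto &c : lnc) c = norm(c);
  for (auto &c : mrna) c = norm(c);
  std::string mRev(mrna.rbegin(), mrna.rend());
  return bestLocal(lnc, mRev, gap);
}

// Cross scoring: matrix of best local scores, lncRNAs x mRNAs.
// [[Rcpp::export]]
NumericMatrix cpp_hybridize_cross(CharacterVector lncs, CharacterVector mrnas,
                                  double gap) {
  const int nl = lncs.size(), nm = mrnas.size();
  std::vector<std::string> L(nl), M(nm);
  for (int i = 0; i < nl; ++i) {
    L[i] = as<std::string>(lncs[i]);
    if (L[i].empty()) stop("sequences must be non-empty");
    checkAlphabet(L[i], "lncRNA sequence");
    for (auto &c : L[i]) c = norm(c);
  }
  for (int j = 0; j < nm; ++j) {
    M[j] = as<std::string>(mrnas[j]);
    if (M[j].empty()) stop("sequences must be non-empty");
    checkAlphabet(M[j], "mRNA sequence");
    for (auto &c : M[j]) c = norm(c);
    std::reverse(M[j].begin(), M[j].end());
  }
  NumericMatrix out(nl, nm);
  for (int i = 0; i < nl; ++i)
    for (int j = 0; j < nm; ++j)
      out(i, j) = bestLocal(L[i], M[j], gap);
  return out;
}
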