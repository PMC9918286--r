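#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// match +1, mismatch -1 (N never matches), linear gap -2, end gaps penalized
static const int GAP = -2;

static inline int base_code(char c) {
  switch (c) {
    case 'A': return 0; case 'C': return 1;
    case 'G': return 2; case 'T': return 3;
    default:  return 4; // N and friends: mismatch against everything
  }
}

static std::vector<int> encode(const std::string& s) {
  std::vector<int> v(s.size());
  for (size_t i = 0; i < s.size(); ++i) v[i] = base_code(s[i]);
  return v;
}

static std::vector<int> revcomp_codes(const std::vector<int>& a) {
  std::vector<int> v(a.size());
  for (size_t i = 0; i < a.size(); ++i) {
    int c = a[a.size() - 1 - i];
    v[i] = (c < 4) ? 3 - c : 4;
  }
  return v;
}

// Needleman-Wunsch global score, two-row DP
static int nw_score(const std::vector<int>& a, const std::vector<int>& b) {
  const size_t n = a.size(), m = b.size();
  std::vector<int> prev(m + 1), cur(m + 1);
  for (size_t j = 0; j <= m; ++j) prev[j] = GAP * (int)j;
  for (size_t i = 1; i <= n; ++i) {
    cur[0] = GAP * (int)i;
    const int ai = a[i - 1];
    for (size_t j = 1; j <= m; ++j) {
      int best = prev[j - 1] + ((ai == b[j - 1] && ai < 4) ? 1 : -1);
      const int up = prev[j] + GAP;
      if (up > best) best = up;
      const int left = cur[j - 1] + GAP;
      if (left > best) best = left;
      cur[j] = best;
    }
    std::swap(prev, cur);
  }
  return prev[m];
}

//' @noRd
// [[Rcpp::export(name = ".cyclic_nw_best")]]
List cyclic_nw_best(std::string a, std::string b) {
  const std::vector<int> av = encode(a);
  const std::vector<int> bfwd = encode(b);
  const size_t m = bfwd.size();
  int best = INT_MIN, best_rot = 0;
  char best_strand = '+';
  // tie-break: smallest rotation index, then forward strand
  for (size_t k = 0; k < m; ++k) {
    for (int s = 0; s < 2; ++s) {
      std::vector<int> bs = (s == 0) ? bfwd : revcomp_codes(bfwd);
      std::vector<int> rot(m);
      for (size_t i = 0; i < m; ++i) rot[i] = bs[(i + k) % m];
      const int sc = nw_score(av, rot);
      if (sc > best) {
        best = sc; best_rot = (int)k; best_strand = (s == 0) ? '+' : '-';
      }
    }
  }
  return List::create(_["score"] = best,
                      _["rotation"] = best_rot,
                      _["strand"] = std::string(1, best_strand));
}

//' @noRd
// [[Rcpp::export(name = ".nw_global_score")]]
int nw_global_score(std::string a, std::string b) {
  return nw_score(encode(a), encode(b));
}
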