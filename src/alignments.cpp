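#include <Rcpp.h>
#include <string>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Legal RNA pairs for stem formation: Watson-Crick plus G-U wobble.
static inline bool legal_pair(char x, char y) {
  return (x == 'C' && y == 'G') || (x == 'G' && y == 'C') ||
         (x == 'A' && y == 'U') || (x == 'U' && y == 'A') ||
         (x == 'G' && y == 'U') || (x == 'U' && y == 'G');
}

static const int NEG = -1000000;

// Max number of legal pairs in a free-end-gap alignment of a against c,
// with at most max_bulges internal gap runs of length <= max_bulge_len.
// Mismatched columns are allowed and score 0. dp[i][j][g] = best score of
// an alignment whose last column aligns a[i] with c[j] using g bulges.
static int pairing_dp(const std::string &a, const std::string &c,
                      int max_bulges, int max_bulge_len) {
  const int n = a.size(), m = c.size(), G = max_bulges;
  if (n == 0 || m == 0) return 0;
  std::vector<int> dp((size_t)n * m * (G + 1), NEG);
  auto at = [&](int i, int j, int g) -> int & {
    return dp[((size_t)i * m + j) * (G + 1) + g];
  };
  int best = 0;
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < m; ++j) {
      int sc = legal_pair(a[i], c[j]) ? 1 : 0;
      for (int g = 0; g <= G; ++g) {
        int prev = 0; // start a fresh alignment (leading gaps are free)
        if (i > 0 && j > 0 && at(i - 1, j - 1, g) > prev)
          prev = at(i - 1, j - 1, g);
        if (g > 0) {
          for (int k = 1; k <= max_bulge_len; ++k) {
            if (i - 1 - k >= 0 && j - 1 >= 0 &&
                at(i - 1 - k, j - 1, g - 1) > prev)
              prev = at(i - 1 - k, j - 1, g - 1);
            if (i - 1 >= 0 && j - 1 - k >= 0 &&
                at(i - 1, j - 1 - k, g - 1) > prev)
              prev = at(i - 1, j - 1 - k, g - 1);
          }
        }
        at(i, j, g) = prev + sc;
        if (at(i, j, g) > best) best = at(i, j, g);
      }
    }
  }
  return best;
}

// [[Rcpp::export(name = ".pairing_score_cpp")]]
int pairing_score_cpp(std::string a, std::string b, int max_bulges = 2,
                      int max_bulge_len = 2) {
  std::string c(b.rbegin(), b.rend());
  return pairing_dp(a, c, max_bulges, max_bulge_len);
}

// Slide a window of length window_len over region (local coordinates),
// scoring each window against the peak sequence; windows overlapping the
// peak interval by >= exclude_frac * window_len are skipped (the peak
// itself is not its own partner). Returns the best window start and score.
// [[Rcpp::export(name = ".partner_scan_cpp")]]
List partner_scan_cpp(std::string peak, std::string region,
                      int peak_local_start, int max_bulges = 2,
                      int max_bulge_len = 2, double exclude_frac = 0.9) {
  const int L = peak.size();
  const int n = region.size();
  int best_start = -1, best_score = -1;
  if (L == 0 || n < L) {
    return List::create(_["start"] = -1, _["score"] = -1);
  }
  const int pk_lo = peak_local_start, pk_hi = peak_local_start + L;
  for (int w = 0; w + L <= n; ++w) {
    int ov_lo = std::max(w, pk_lo), ov_hi = std::min(w + L, pk_hi);
    int ov = std::max(0, ov_hi - ov_lo);
    if (ov >= exclude_frac * L) continue;
    std::string win = region.substr(w, L);
    std::string c(win.rbegin(), win.rend());
    int sc = pairing_dp(peak, c, max_bulges, max_bulge_len);
    if (sc > best_score) {
      best_score = sc;
      best_start = w;
    }
  }
  return List::create(_["start"] = best_start, _["score"] = best_score);
}

// Semiglobal alignment of a short pattern against a text, minimizing
// mismatches + indels, forbidding two adjacent indel columns. Returns one
// row (start, end, edits) per text end position with edits <= max_edits;
// coordinates are 0-based half-open on the text.
// [[Rcpp::export(name = ".edit_hits_cpp")]]
IntegerMatrix edit_hits_cpp(std::string pattern, std::string text,
                            int max_edits = 3) {
  const int m = pattern.size(), n = text.size();
  const int INF = 1000000;
  // state s: 0 = last column match/mismatch, 1 = last column indel
  std::vector<int> dp((size_t)(m + 1) * (n + 1) * 2, INF);
  std::vector<int> st((size_t)(m + 1) * (n + 1) * 2, -1);
  auto D = [&](int i, int j, int s) -> int & {
    return dp[((size_t)i * (n + 1) + j) * 2 + s];
  };
  auto S = [&](int i, int j, int s) -> int & {
    return st[((size_t)i * (n + 1) + j) * 2 + s];
  };
  for (int j = 0; j <= n; ++j) {
    D(0, j, 0) = 0;
    S(0, j, 0) = j; // alignment starts at text position j
  }
  for (int i = 1; i <= m; ++i) {
    for (int j = 0; j <= n; ++j) {
      // deletion: consume pattern[i-1], gap in text
      if (D(i - 1, j, 0) + 1 < D(i, j, 1)) {
        D(i, j, 1) = D(i - 1, j, 0) + 1;
        S(i, j, 1) = S(i - 1, j, 0);
      }
      if (j >= 1) {
        // match / mismatch
        int sub = (pattern[i - 1] == text[j - 1]) ? 0 : 1;
        for (int s = 0; s < 2; ++s) {
          if (D(i - 1, j - 1, s) + sub < D(i, j, 0)) {
            D(i, j, 0) = D(i - 1, j - 1, s) + sub;
            S(i, j, 0) = S(i - 1, j - 1, s);
          }
        }
        // insertion: consume text[j-1], gap in pattern
        if (D(i, j - 1, 0) + 1 < D(i, j, 1)) {
          D(i, j, 1) = D(i, j - 1, 0) + 1;
          S(i, j, 1) = S(i, j - 1, 0);
        }
      }
    }
  }
  std::vector<int> starts, ends, edits;
  for (int j = 1; j <= n; ++j) {
    for (int s = 0; s < 2; ++s) {
      int e = D(m, j, s);
      if (e <= max_edits) {
        starts.push_back(S(m, j, s));
        ends.push_back(j);
        edits.push_back(e);
      }
    }
  }
  IntegerMatrix out(starts.size(), 3);
  for (size_t k = 0; k < starts.size(); ++k) {
    out(k, 0) = starts[k];
    out(k, 1) = ends[k];
    out(k, 2) = edits[k];
  }
  colnames(out) = CharacterVector::create("start", "end", "edits");
  return out;
}
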