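#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Suffix array by prefix doubling with counting sort (O(n log n)).
static std::vector<int> suffix_array(const std::vector<int>& s) {
  int n = s.size();
  std::vector<int> sa(n), r(n), tmp(n), cnt;
  int maxv = 0;
  for (int i = 0; i < n; ++i) { r[i] = s[i]; maxv = std::max(maxv, s[i]); }
  int classes = maxv + 1;
  cnt.assign(std::max(classes, n), 0);
  for (int i = 0; i < n; ++i) cnt[r[i]]++;
  for (int i = 1; i < classes; ++i) cnt[i] += cnt[i - 1];
  for (int i = n - 1; i >= 0; --i) sa[--cnt[r[i]]] = i;
  tmp[sa[0]] = 0;
  for (int i = 1; i < n; ++i)
    tmp[sa[i]] = tmp[sa[i - 1]] + (r[sa[i]] != r[sa[i - 1]] ? 1 : 0);
  r = tmp;
  classes = r[sa[n - 1]] + 1;
  std::vector<int> sa2(n);
  for (int k = 1; classes < n; k <<= 1) {
    // sort by second key: positions shifted left by k
    int p = 0;
    for (int i = n - k; i < n; ++i) sa2[p++] = i;       // empty second key
    for (int i = 0; i < n; ++i)
      if (sa[i] >= k) sa2[p++] = sa[i] - k;
    // stable counting sort by first key
    cnt.assign(classes, 0);
    for (int i = 0; i < n; ++i) cnt[r[i]]++;
    for (int i = 1; i < classes; ++i) cnt[i] += cnt[i - 1];
    for (int i = n - 1; i >= 0; --i) sa[--cnt[r[sa2[i]]]] = sa2[i];
    tmp[sa[0]] = 0;
    for (int i = 1; i < n; ++i) {
      int a = sa[i - 1], b = sa[i];
      int a2 = a + k < n ? r[a + k] : -1;
      int b2 = b + k < n ? r[b + k] : -1;
      tmp[b] = tmp[a] + ((r[a] != r[b] || a2 != b2) ? 1 : 0);
    }
    r = tmp;
    classes = r[sa[n - 1]] + 1;
  }
  return sa;
}

// LZ76 exhaustive-history phrase count. Each phrase is the longest prefix
// of the remaining sequence that occurs starting at an earlier position
// (overlap with the phrase itself allowed), plus one innovation symbol;
// the trailing reproducible suffix counts as one final phrase. The longest
// previous match at each position is max LCP with the lexicographically
// nearest suffixes of smaller text position (PSV/NSV over the suffix
// array), computed by direct comparison (amortized linear).
// [[Rcpp::export(name = ".lz76_count")]]
int lz76_count(IntegerVector sv) {
  int n = sv.size();
  if (n == 0) return 0;
  if (n == 1) return 1;
  std::vector<int> s(sv.begin(), sv.end());
  std::vector<int> sa = suffix_array(s);
  std::vector<int> psv(n, -1), nsv(n, -1);
  {
    std::vector<int> stack;
    for (int r = 0; r < n; ++r) {
      int x = sa[r];
      while (!stack.empty() && stack.back() > x) {
        nsv[stack.back()] = x;
        stack.pop_back();
      }
      psv[x] = stack.empty() ? -1 : stack.back();
      stack.push_back(x);
    }
  }
  auto match_len = [&](int i, int j) {  // lcp of suffixes i (source) and j
    if (i < 0) return 0;
    int k = 0;
    while (j + k < n && s[i + k] == s[j + k]) ++k;
    return k;
  };
  int c = 0, l = 0;
  while (l < n) {
    int m = std::max(match_len(psv[l], l), match_len(nsv[l], l));
    ++c;
    if (l + m >= n) break;   // reproducible (or empty) suffix -> last phrase
    l += m + 1;              // phrase = longest match + innovation symbol
  }
  return c;
}
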