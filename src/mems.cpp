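#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <array>
#include <algorithm>
#include <string>
using namespace Rcpp;

// Suffix array by prefix doubling with radix sort; O(n log n).
static std::vector<int> build_sa(const std::vector<int>& s_in) {
  int n = (int)s_in.size();
  std::vector<int> sa(n), rank_(n), tmp(n), cnt;
  int alpha = 0;
  for (int v : s_in) alpha = std::max(alpha, v + 1);
  cnt.assign(std::max(alpha, n) + 1, 0);
  for (int i = 0; i < n; ++i) cnt[s_in[i]]++;
  for (int i = 1; i < (int)cnt.size(); ++i) cnt[i] += cnt[i - 1];
  for (int i = n - 1; i >= 0; --i) sa[--cnt[s_in[i]]] = i;
  rank_[sa[0]] = 0;
  for (int i = 1; i < n; ++i)
    rank_[sa[i]] = rank_[sa[i - 1]] + (s_in[sa[i]] != s_in[sa[i - 1]] ? 1 : 0);
  for (int len = 1; len < n; len <<= 1) {
    // sort by (rank[i], rank[i+len]) using two counting passes
    std::vector<int> sa2(n);
    int p = 0;
    for (int i = n - len; i < n; ++i) sa2[p++] = i; // suffixes with empty 2nd key
    for (int i = 0; i < n; ++i)
      if (sa[i] >= len) sa2[p++] = sa[i] - len;
    cnt.assign(n + 1, 0);
    for (int i = 0; i < n; ++i) cnt[rank_[i]]++;
    for (int i = 1; i <= n; ++i) cnt[i] += cnt[i - 1];
    for (int i = n - 1; i >= 0; --i) sa[--cnt[rank_[sa2[i]]]] = sa2[i];
    tmp[sa[0]] = 0;
    for (int i = 1; i < n; ++i) {
      int a = sa[i - 1], b = sa[i];
      bool same = rank_[a] == rank_[b] &&
                  ((a + len < n ? rank_[a + len] : -1) ==
                   (b + len < n ? rank_[b + len] : -1));
      tmp[b] = tmp[a] + (same ? 0 : 1);
    }
    rank_ = tmp;
    if (rank_[sa[n - 1]] == n - 1) break;
  }
  return sa;
}

// Kasai LCP: lcp[i] = LCP(suffix sa[i-1], suffix sa[i]), lcp[0] = 0.
static std::vector<int> build_lcp(const std::vector<int>& s,
                                  const std::vector<int>& sa) {
  int n = (int)s.size();
  std::vector<int> rank_(n), lcp(n, 0);
  for (int i = 0; i < n; ++i) rank_[sa[i]] = i;
  int h = 0;
  for (int i = 0; i < n; ++i) {
    if (rank_[i] > 0) {
      int j = sa[rank_[i] - 1];
      while (i + h < n && j + h < n && s[i + h] == s[j + h]) ++h;
      lcp[rank_[i]] = h;
      if (h) --h;
    } else h = 0;
  }
  return lcp;
}

struct Mem { int qpos, rpos, len; };

// Stack entry for maximal-pair enumeration: a set of already-seen suffix
// positions grouped by (sequence-of-origin, preceding character class), all of
// which share longest-common-prefix `v` with any not-yet-processed suffix.
struct Block {
  int v;
  // groups[seq] maps prev-char (0 = sequence start -> always left-diverse)
  std::array<std::vector<std::pair<unsigned char, std::vector<int> > >, 2> groups;
};

static void group_add(Block& b, int seq, unsigned char prev, int pos) {
  for (auto& g : b.groups[seq])
    if (g.first == prev) { g.second.push_back(pos); return; }
  b.groups[seq].push_back({prev, std::vector<int>{pos}});
}

static void block_merge(Block& dst, Block& src) {
  for (int s = 0; s < 2; ++s)
    for (auto& g : src.groups[s])
      for (int p : g.second) group_add(dst, s, g.first, p);
}

// Emit maximal pairs between the positions stored in `b` and the single new
// suffix (seq_y, prev_y, pos_y) at match length `len`.
static void emit_pairs(const Block& b, int seq_y, unsigned char prev_y,
                       int pos_y, int len, int nq, std::vector<Mem>& out) {
  int seq_x = 1 - seq_y;
  for (const auto& g : b.groups[seq_x]) {
    if (g.first != 0 && prev_y != 0 && g.first == prev_y) continue; // not left-maximal
    for (int px : g.second) {
      int qp = (seq_x == 0) ? px : pos_y;
      int rp = (seq_x == 0) ? pos_y : px;
      out.push_back({qp, rp - (nq + 1), len});
    }
  }
}

// Count occurrences of s[from, from+len) in the region [lo, hi) of the
// concatenated text via binary search over the suffix array.
static int count_occurrences(const std::vector<int>& s, const std::vector<int>& sa,
                             int from, int len, int lo, int hi) {
  int n = (int)s.size();
  // lower bound: first suffix with prefix >= pattern
  auto cmp_lt = [&](int suf) { // suffix < pattern ?
    for (int i = 0; i < len; ++i) {
      if (suf + i >= n) return true;
      if (s[suf + i] < s[from + i]) return true;
      if (s[suf + i] > s[from + i]) return false;
    }
    return false;
  };
  auto cmp_le = [&](int suf) { // suffix's first len chars <= pattern ?
    for (int i = 0; i < len; ++i) {
      if (suf + i >= n) return true;
      if (s[suf + i] < s[from + i]) return true;
      if (s[suf + i] > s[from + i]) return false;
    }
    return true;
  };
  int a = 0, b = (int)sa.size();
  while (a < b) { int m = (a + b) / 2; if (cmp_lt(sa[m])) a = m + 1; else b = m; }
  int first = a;
  a = first; b = (int)sa.size();
  while (a < b) { int m = (a + b) / 2; if (cmp_le(sa[m])) a = m + 1; else b = m; }
  int last = a;
  int cnt = 0;
  for (int i = first; i < last; ++i)
    if (sa[i] >= lo && sa[i] < hi && sa[i] + len <= (lo == 0 ? hi : n)) ++cnt;
  return cnt;
}

// All maximal exact matches of length >= min_len between q and r (forward
// strand of both). mum = TRUE keeps only matches whose matched substring
// occurs exactly once in q and once in r. 0-based coordinates.
// [[Rcpp::export]]
DataFrame find_mems_cpp(std::string q, std::string r, int min_len, bool mum) {
  int nq = (int)q.size(), nr = (int)r.size();
  std::vector<int> s;
  s.reserve(nq + nr + 2);
  for (char c : q) s.push_back((unsigned char)std::toupper((unsigned char)c) + 2);
  s.push_back(1); // separator, unique-low
  for (char c : r) s.push_back((unsigned char)std::toupper((unsigned char)c) + 2);
  s.push_back(0); // terminator
  int n = (int)s.size();
  std::vector<Mem> mems;
  if (nq >= min_len && nr >= min_len) {
    std::vector<int> sa = build_sa(s);
    std::vector<int> lcp = build_lcp(s, sa);
    auto seq_of = [&](int pos) { return pos < nq ? 0 : (pos > nq ? 1 : -1); };
    auto prev_of = [&](int pos) -> unsigned char {
      if (pos == 0 || pos == nq + 1) return 0; // sequence start
      return (unsigned char)s[pos - 1];
    };
    std::vector<Block> stack;
    for (int i = 0; i < n; ++i) {
      int pos = sa[i];
      int h = (i == 0) ? 0 : lcp[i];
      int sy = seq_of(pos);
      unsigned char py = (sy >= 0) ? prev_of(pos) : 0;
      // collapse entries whose v exceeds h; their lcp with the new suffix is h
      Block merged; merged.v = h;
      bool have_merged = false;
      while (!stack.empty() && stack.back().v > h) {
        block_merge(merged, stack.back());
        stack.pop_back();
        have_merged = true;
      }
      if (sy >= 0) {
        if (have_merged && h >= min_len)
          emit_pairs(merged, sy, py, pos, h, nq, mems);
        // remaining entries pair with the new suffix at their own (exact) v
        for (auto it = stack.rbegin(); it != stack.rend() && it->v >= min_len; ++it)
          emit_pairs(*it, sy, py, pos, it->v, nq, mems);
      }
      if (have_merged) {
        if (!stack.empty() && stack.back().v == h) block_merge(stack.back(), merged);
        else stack.push_back(std::move(merged));
      }
      if (sy >= 0) {
        Block self; self.v = n + 1; // lcp of a suffix with itself: effectively infinite
        group_add(self, sy, py, pos);
        stack.push_back(std::move(self));
      } else {
        // separator suffix: acts as an lcp-0 barrier handled by h above
        Block self; self.v = n + 1;
        stack.push_back(std::move(self));
      }
    }
    if (mum) {
      std::vector<int> sa2 = sa; // reuse for occurrence counting
      std::vector<Mem> kept;
      for (const Mem& m : mems) {
        int occ_q = count_occurrences(s, sa2, m.qpos, m.len, 0, nq);
        int occ_r = count_occurrences(s, sa2, nq + 1 + m.rpos, m.len, nq + 1, nq + 1 + nr);
        if (occ_q == 1 && occ_r == 1) kept.push_back(m);
      }
      mems.swap(kept);
    }
  }
  std::sort(mems.begin(), mems.end(), [](const Mem& a, const Mem& b) {
    if (a.qpos != b.qpos) return a.qpos < b.qpos;
    if (a.rpos != b.rpos) return a.rpos < b.rpos;
    return a.len < b.len;
  });
  IntegerVector qs(mems.size()), rs(mems.size()), ln(mems.size());
  for (size_t i = 0; i < mems.size(); ++i) {
    qs[i] = mems[i].qpos; rs[i] = mems[i].rpos; ln[i] = mems[i].len;
  }
  return DataFrame::create(_["q_start"] = qs, _["r_start"] = rs,
                           _["length"] = ln);
}
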