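#include <Rcpp.h>
#include <vector>
#include <string>
#include <algorithm>
#include <unordered_map>
#include <cstdint>
using namespace Rcpp;

static const int NEG_INF = -1000000000;

// Affine-gap ("Gotoh") alignment of a vs b with an optional band constraint
// |(j - i) - diag| <= band (band <= 0 disables banding, i.e. full DP).
// local = TRUE: Smith-Waterman best local hit; FALSE: global over both
// strings. A gap of length g costs gap_open + g * gap_extend (both <= 0).
// Three-state traceback reports matches and aligned columns exactly.
struct AlnOut {
  int score, a_start, a_end, b_start, b_end, matches, cols;
};

static AlnOut gotoh(const std::string& a, const std::string& b, int match,
                    int mismatch, int gap_open, int gap_extend, bool local,
                    int band, int diag) {
  const int la = (int)a.size(), lb = (int)b.size();
  // band-compressed storage: row i holds columns lo(i)..hi(i)
  auto lo = [&](int i) {
    return band <= 0 ? 0 : std::max(0, std::min(lb, i + diag - band));
  };
  auto hi = [&](int i) {
    return band <= 0 ? lb : std::max(0, std::min(lb, i + diag + band));
  };
  const int stride = band <= 0 ? lb + 1 : 2 * band + 2;
  const size_t N = (size_t)(la + 1) * (size_t)stride;
  std::vector<int> H(N, NEG_INF), E(N, NEG_INF), F(N, NEG_INF);
  // tbH: 0 diag, 1 from E, 2 from F, 3 local start / origin
  // tbE, tbF: 0 opened from H, 1 extended
  std::vector<uint8_t> tbH(N, 3), tbE(N, 0), tbF(N, 0);
  auto valid = [&](int i, int j) {
    return i >= 0 && i <= la && j >= lo(i) && j <= hi(i);
  };
  auto idx = [&](int i, int j) {
    return (size_t)i * (size_t)stride + (size_t)(j - lo(i));
  };
  auto getv = [&](std::vector<int>& M, int i, int j) {
    return valid(i, j) ? M[idx(i, j)] : NEG_INF;
  };
  if (valid(0, 0)) H[idx(0, 0)] = 0;
  for (int j = std::max(1, lo(0)); j <= hi(0); ++j) {
    size_t c = idx(0, j);
    if (local) { H[c] = 0; continue; }
    E[c] = gap_open + j * gap_extend;
    tbE[c] = (j == 1) ? 0 : 1;
    H[c] = E[c];
    tbH[c] = 1;
  }
  for (int i = 1; i <= la; ++i) {
    if (lo(i) > 0) continue;
    size_t c = idx(i, 0);
    if (local) { H[c] = 0; tbH[c] = 3; continue; }
    F[c] = gap_open + i * gap_extend;
    tbF[c] = (i == 1) ? 0 : 1;
    H[c] = F[c];
    tbH[c] = 2;
  }
  int best = local ? 0 : NEG_INF, bi = 0, bj = 0;
  for (int i = 1; i <= la; ++i) {
    for (int j = std::max(1, lo(i)); j <= hi(i); ++j) {
      size_t c = idx(i, j);
      // E: gap in a, consume b[j-1]
      int hl = getv(H, i, j - 1), el = getv(E, i, j - 1);
      int e = NEG_INF;
      uint8_t te = 0;
      if (hl > NEG_INF / 2) e = hl + gap_open + gap_extend;
      if (el > NEG_INF / 2 && el + gap_extend > e) {
        e = el + gap_extend; te = 1;
      }
      // F: gap in b, consume a[i-1]
      int hu = getv(H, i - 1, j), fu = getv(F, i - 1, j);
      int f = NEG_INF;
      uint8_t tf = 0;
      if (hu > NEG_INF / 2) f = hu + gap_open + gap_extend;
      if (fu > NEG_INF / 2 && fu + gap_extend > f) {
        f = fu + gap_extend; tf = 1;
      }
      int sub = (std::toupper((unsigned char)a[i - 1]) ==
                 std::toupper((unsigned char)b[j - 1]))
                    ? match : mismatch;
      int hd = getv(H, i - 1, j - 1);
      int m = (hd > NEG_INF / 2) ? hd + sub : NEG_INF;
      int h = m;
      uint8_t th = 0;
      if (e > h) { h = e; th = 1; }
      if (f > h) { h = f; th = 2; }
      if (local && h < 0) { h = 0; th = 3; }
      H[c] = h; E[c] = e; F[c] = f;
      tbH[c] = th; tbE[c] = te; tbF[c] = tf;
      if (local && h > best) { best = h; bi = i; bj = j; }
    }
  }
  AlnOut out{0, 0, 0, 0, 0, 0, 0};
  if (!local) {
    bi = la; bj = lb;
    best = valid(la, lb) ? H[idx(la, lb)] : NEG_INF;
  }
  out.score = best;
  if (local && best <= 0) return out;
  int i = bi, j = bj, matches = 0, cols = 0, state = 0; // 0=H,1=E,2=F
  while (i > 0 || j > 0) {
    size_t c = idx(i, j);
    if (state == 0) {
      uint8_t t = tbH[c];
      if (t == 3) break; // local origin
      if (t == 0) {
        cols++;
        if (std::toupper((unsigned char)a[i - 1]) ==
            std::toupper((unsigned char)b[j - 1])) matches++;
        --i; --j;
        if (local && valid(i, j) && tbH[idx(i, j)] == 3) break;
      } else state = t;
    } else if (state == 1) {
      cols++;
      uint8_t t = tbE[c];
      --j;
      state = (t == 0) ? 0 : 1;
    } else {
      cols++;
      uint8_t t = tbF[c];
      --i;
      state = (t == 0) ? 0 : 2;
    }
  }
  out.a_start = i; out.a_end = bi; out.b_start = j; out.b_end = bj;
  out.matches = matches; out.cols = cols;
  return out;
}

// [[Rcpp::export]]
List align_pair_cpp(std::string a, std::string b, int match, int mismatch,
                    int gap_open, int gap_extend, bool local, int band,
                    int diag) {
  AlnOut o = gotoh(a, b, match, mismatch, gap_open, gap_extend, local, band, diag);
  return List::create(
      _["score"] = o.score, _["a_start"] = o.a_start, _["a_end"] = o.a_end,
      _["b_start"] = o.b_start, _["b_end"] = o.b_end,
      _["matches"] = o.matches, _["aligned_cols"] = o.cols);
}

// Best local alignment of a short fragment against a long reference,
// seeded by shared words of length seed_len: seed diagonals are voted into
// buckets of width max(band, 16); the top `top_n` buckets are each refined
// with a banded local alignment over a window of the reference.
// [[Rcpp::export]]
List best_fragment_hit_cpp(std::string frag, std::string ref, int seed_len,
                           int band, int top_n, int match, int mismatch,
                           int gap_open, int gap_extend) {
  const int lf = (int)frag.size(), lr = (int)ref.size();
  List empty = List::create(
      _["score"] = 0, _["a_start"] = 0, _["a_end"] = 0, _["b_start"] = 0,
      _["b_end"] = 0, _["matches"] = 0, _["aligned_cols"] = 0);
  if (lf < seed_len || lr < seed_len) return empty;
  auto code = [](char ch) {
    switch (std::toupper((unsigned char)ch)) {
      case 'A': return 0; case 'C': return 1; case 'G': return 2;
      case 'T': return 3; default: return -1;
    }
  };
  std::unordered_map<uint64_t, std::vector<int> > idx;
  uint64_t mask = (seed_len == 32) ? ~0ULL : ((1ULL << (2 * seed_len)) - 1);
  {
    uint64_t w = 0; int run = 0;
    for (int i = 0; i < lf; ++i) {
      int c = code(frag[i]);
      if (c < 0) { run = 0; w = 0; continue; }
      w = ((w << 2) | (uint64_t)c) & mask;
      if (++run >= seed_len) idx[w].push_back(i - seed_len + 1);
    }
  }
  if (idx.empty()) return empty;
  int bucket_w = std::max(band, 16);
  std::unordered_map<int, int> votes;
  {
    uint64_t w = 0; int run = 0;
    for (int j = 0; j < lr; ++j) {
      int c = code(ref[j]);
      if (c < 0) { run = 0; w = 0; continue; }
      w = ((w << 2) | (uint64_t)c) & mask;
      if (++run >= seed_len) {
        auto it = idx.find(w);
        if (it != idx.end()) {
          int rpos = j - seed_len + 1;
          for (int fpos : it->second) {
            int d = rpos - fpos;
            votes[d >= 0 ? d / bucket_w : -((-d) / bucket_w) - 1]++;
          }
        }
      }
    }
  }
  if (votes.empty()) return empty;
  std::vector<std::pair<int, int> > vv(votes.begin(), votes.end());
  std::sort(vv.begin(), vv.end(),
            [](const std::pair<int, int>& x, const std::pair<int, int>& y) {
              return x.second > y.second;
            });
  AlnOut best{0, 0, 0, 0, 0, 0, 0};
  int tried = 0;
  for (auto& v : vv) {
    if (tried++ >= top_n) break;
    int d_center = v.first * bucket_w + bucket_w / 2;
    int wlo = std::max(0, d_center - band - bucket_w);
    int whi = std::min(lr, d_center + lf + band + bucket_w);
    if (whi - wlo < seed_len) continue;
    std::string win = ref.substr((size_t)wlo, (size_t)(whi - wlo));
    AlnOut o = gotoh(frag, win, match, mismatch, gap_open, gap_extend, true,
                     band + bucket_w, d_center - wlo);
    if (o.score > best.score) {
      o.b_start += wlo; o.b_end += wlo;
      best = o;
    }
  }
  return List::create(
      _["score"] = best.score, _["a_start"] = best.a_start,
      _["a_end"] = best.a_end, _["b_start"] = best.b_start,
      _["b_end"] = best.b_end, _["matches"] = best.matches,
      _["aligned_cols"] = best.cols);
}
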