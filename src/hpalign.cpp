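#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Homopolymer-aware local alignment scoring.
//
// Gap segments falling inside a homopolymer run of the reference are granted
// free gaps before the affine penalty applies: a run of length h forgives 0
// gaps for h <= 3, 1 gap for h == 4 and 2 gaps for h >= 5. Deleted reference
// bases draw on the budget of the run they belong to; inserted read bases
// draw on the budget of an adjacent run only when every inserted base equals
// that run's base (an overcall extends the run). Remaining gaps in a segment
// are charged open + (k - 1) * extend.

static inline int free_gaps_for_run(int h) {
  if (h >= 5) return 2;
  if (h == 4) return 1;
  return 0;
}

static inline int affine(int k, int open, int extend) {
  return k <= 0 ? 0 : open + (k - 1) * extend;
}

// per-position run ids and lengths of a (linear) reference segment
static void run_info(const std::string& b, std::vector<int>& run_id,
                     std::vector<int>& run_len) {
  int n = (int)b.size();
  run_id.assign(n, 0);
  run_len.assign(n, 0);
  int id = 0, start = 0;
  for (int j = 0; j < n; ++j) {
    if (j > 0 && b[j] != b[j - 1]) {
      int len = j - start;
      for (int t = start; t < j; ++t) run_len[t] = len;
      ++id;
      start = j;
    }
    run_id[j] = id;
  }
  int len = n - start;
  for (int t = start; t < n; ++t) run_len[t] = len;
}

// cost of deleting reference positions j_end-g+1 .. j_end (0-based)
static int del_cost(int j_end, int g, const std::vector<int>& run_id,
                    const std::vector<int>& run_len, int open, int extend) {
  int chargeable = 0;
  int p = j_end - g + 1;
  while (p <= j_end) {
    int id = run_id[p];
    int cnt = 0;
    while (p <= j_end && run_id[p] == id) { ++cnt; ++p; }
    int f = free_gaps_for_run(run_len[p - 1]);
    if (cnt > f) chargeable += cnt - f;
  }
  return affine(chargeable, open, extend);
}

// cost of inserting read bases a[i_end-g+1 .. i_end] after reference
// position j (0-based; j == -1 means before the first base)
static int ins_cost(const std::string& a, int i_end, int g, const std::string& b,
                    int j, const std::vector<int>& run_len, int open, int extend) {
  char x = a[i_end];
  bool same = true;
  for (int t = i_end - g + 1; t <= i_end; ++t)
    if (a[t] != x) { same = false; break; }
  int f = 0;
  if (same) {
    if (j >= 0 && b[j] == x) f = std::max(f, free_gaps_for_run(run_len[j]));
    int n = (int)b.size();
    if (j + 1 < n && b[j + 1] == x) f = std::max(f, free_gaps_for_run(run_len[j + 1]));
  }
  int chargeable = g - f;
  return affine(chargeable, open, extend);
}

// Exhaustive full-matrix local alignment score (test oracle): no seeding,
// no banding; O(m * n * max_gap).
// [[Rcpp::export]]
int hp_dp_score_cpp(std::string a, std::string b, int match, int mismatch,
                    int gap_open, int gap_extend, int max_gap) {
  int m = (int)a.size(), n = (int)b.size();
  std::vector<int> run_id, run_len;
  run_info(b, run_id, run_len);
  std::vector<std::vector<int>> H(m + 1, std::vector<int>(n + 1, 0));
  int best = 0;
  for (int i = 1; i <= m; ++i) {
    for (int j = 1; j <= n; ++j) {
      int s = (a[i - 1] == b[j - 1]) ? match : -mismatch;
      int h = H[i - 1][j - 1] + s;
      int gmax = std::min(max_gap, j);
      for (int g = 1; g <= gmax; ++g) {
        int cand = H[i][j - g] - del_cost(j - 1, g, run_id, run_len, gap_open, gap_extend);
        if (cand > h) h = cand;
      }
      gmax = std::min(max_gap, i);
      for (int g = 1; g <= gmax; ++g) {
        int cand = H[i - g][j] - ins_cost(a, i - 1, g, b, j - 1, run_len, gap_open, gap_extend);
        if (cand > h) h = cand;
      }
      if (h < 0) h = 0;
      H[i][j] = h;
      if (h > best) best = h;
    }
  }
  return best;
}

// Banded local alignment with traceback. The read position i is expected to
// map near window position i + band; cells outside |j - i - band| <= band are
// not computed. Gap segment costs are precomputed: deletions in a table over
// (end position, length), insertions from the read's same-base suffix runs
// plus a per-cell free-gap budget. Returns score, read span, window span, op
// string (M/X/I/D, one symbol per alignment column) and mismatch count.
// [[Rcpp::export]]
List hp_banded_align_cpp(std::string a, std::string b, int band, int match,
                         int mismatch, int gap_open, int gap_extend, int max_gap) {
  const int NEG = -100000000;
  int m = (int)a.size(), n = (int)b.size();
  std::vector<int> run_id, run_len;
  run_info(b, run_id, run_len);
  // delc[j][g-1]: cost of deleting ref positions j-g+1..j (0-based j)
  std::vector<std::vector<int>> delc(n, std::vector<int>(max_gap, 0));
  for (int j = 0; j < n; ++j) {
    int chargeable = 0, cnt = 0, cur_run = -1;
    for (int g = 1; g <= max_gap && j - g + 1 >= 0; ++g) {
      int p = j - g + 1;
      if (run_id[p] == cur_run) ++cnt;
      else { cur_run = run_id[p]; cnt = 1; }
      if (cnt > free_gaps_for_run(run_len[p])) ++chargeable;
      delc[j][g - 1] = affine(chargeable, gap_open, gap_extend);
    }
  }
  // same_run[i]: length of the maximal same-character suffix of a[0..i]
  std::vector<int> same_run(m, 1);
  for (int i = 1; i < m; ++i)
    same_run[i] = (a[i] == a[i - 1]) ? same_run[i - 1] + 1 : 1;
  std::vector<std::vector<int>> H(m + 1, std::vector<int>(n + 1, NEG));
  std::vector<std::vector<signed char>> mv(m + 1, std::vector<signed char>(n + 1, 0));
  std::vector<std::vector<signed char>> gl(m + 1, std::vector<signed char>(n + 1, 0));
  for (int j = 0; j <= n; ++j) H[0][j] = 0;
  for (int i = 0; i <= m; ++i) H[i][0] = 0;
  int best = 0, bi = 0, bj = 0;
  for (int i = 1; i <= m; ++i) {
    int jlo = std::max(1, i), jhi = std::min(n, i + 2 * band);
    for (int j = jlo; j <= jhi; ++j) {
      int s = (a[i - 1] == b[j - 1]) ? match : -mismatch;
      int diag = H[i - 1][j - 1];
      if (diag < 0) diag = 0; // local restart at the band edge
      int h = diag + s;
      signed char bmv = 1, bgl = 0;
      int gmax = std::min(max_gap, j);
      for (int g = 1; g <= gmax; ++g) {
        if (H[i][j - g] <= NEG / 2) continue;
        int cand = H[i][j - g] - delc[j - 1][g - 1];
        if (cand > h) { h = cand; bmv = 2; bgl = (signed char)g; }
      }
      // free-gap budget for insertions of a[i-1]'s character at this anchor
      int f_cell = 0;
      {
        char x = a[i - 1];
        if (j - 1 >= 0 && b[j - 1] == x)
          f_cell = std::max(f_cell, free_gaps_for_run(run_len[j - 1]));
        if (j < n && b[j] == x)
          f_cell = std::max(f_cell, free_gaps_for_run(run_len[j]));
      }
      gmax = std::min(max_gap, i);
      for (int g = 1; g <= gmax; ++g) {
        if (H[i - g][j] <= NEG / 2) continue;
        int chargeable = (g <= same_run[i - 1]) ? std::max(0, g - f_cell) : g;
        int cand = H[i - g][j] - affine(chargeable, gap_open, gap_extend);
        if (cand > h) { h = cand; bmv = 3; bgl = (signed char)g; }
      }
      if (h <= 0) { h = 0; bmv = 0; bgl = 0; }
      H[i][j] = h;
      mv[i][j] = bmv;
      gl[i][j] = bgl;
      if (h > best) { best = h; bi = i; bj = j; }
    }
  }
  if (best <= 0) {
    return List::create(_["score"] = 0, _["read_start"] = NA_INTEGER,
                        _["read_end"] = NA_INTEGER, _["win_start"] = NA_INTEGER,
                        _["win_end"] = NA_INTEGER, _["ops"] = "",
                        _["mismatches"] = NA_INTEGER);
  }
  std::string ops;
  int i = bi, j = bj, mism = 0;
  while (i > 0 && j > 0 && H[i][j] > 0 && mv[i][j] != 0) {
    signed char t = mv[i][j];
    if (t == 1) {
      if (a[i - 1] == b[j - 1]) ops.push_back('M');
      else { ops.push_back('X'); ++mism; }
      --i; --j;
    } else if (t == 2) {
      for (int g = 0; g < gl[i][j]; ++g) ops.push_back('D');
      j -= gl[i][j];
    } else {
      for (int g = 0; g < gl[i][j]; ++g) ops.push_back('I');
      i -= gl[i][j];
    }
  }
  std::reverse(ops.begin(), ops.end());
  return List::create(_["score"] = best, _["read_start"] = i + 1,
                      _["read_end"] = bi, _["win_start"] = j + 1,
                      _["win_end"] = bj, _["ops"] = ops,
                      _["mismatches"] = mism);
}
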