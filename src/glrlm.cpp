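// Gray-level run-length matrix (GLRLM) kernels.
// Runs are maximal sequences of identical quantized levels along a
// direction; directions are coded 0, 45, 90, 135 degrees with 0 = along
// rows (horizontal), 90 = along columns, 45 = up-right diagonal,
// 135 = down-right diagonal.

#include <Rcpp.h>
using namespace Rcpp;

static void scan_line(const IntegerMatrix& img, int r, int c, int dr, int dc,
                      IntegerMatrix& counts) {
  int nr = img.nrow(), nc = img.ncol();
  int maxrun = counts.ncol();
  int cur = img(r, c), len = 1;
  r += dr; c += dc;
  while (r >= 0 && r < nr && c >= 0 && c < nc) {
    int v = img(r, c);
    if (v == cur) {
      ++len;
    } else {
      counts(cur - 1, std::min(len, maxrun) - 1) += 1;
      cur = v; len = 1;
    }
    r += dr; c += dc;
  }
  counts(cur - 1, std::min(len, maxrun) - 1) += 1;
}

static void dir_step(int deg, int& dr, int& dc) {
  switch (deg) {
    case 0:   dr = 0;  dc = 1; break;   // horizontal
    case 45:  dr = -1; dc = 1; break;   // up-right
    case 90:  dr = 1;  dc = 0; break;   // vertical
    case 135: dr = 1;  dc = 1; break;   // down-right
    default: stop("direction must be one of 0, 45, 90, 135");
  }
}

// [[Rcpp::export]]
IntegerMatrix glrlm_cpp(IntegerMatrix img, int nlevels, IntegerVector directions) {
  int nr = img.nrow(), nc = img.ncol();
  if (nr == 0 || nc == 0) stop("empty image");
  int maxrun = std::max(nr, nc);
  IntegerMatrix counts(nlevels, maxrun);
  for (int d = 0; d < directions.size(); ++d) {
    int dr, dc; dir_step(directions[d], dr, dc);
    // start from every cell without an in-bounds predecessor
    for (int r = 0; r < nr; ++r)
      for (int c = 0; c < nc; ++c) {
        int pr = r - dr, pc = c - dc;
        if (pr >= 0 && pr < nr && pc >= 0 && pc < nc) continue;
        scan_line(img, r, c, dr, dc, counts);
      }
  }
  return counts;
}

static double lrhgle_of(const IntegerMatrix& counts) {
  double num = 0.0, nr_runs = 0.0;
  for (int j = 0; j < counts.ncol(); ++j)
    for (int i = 0; i < counts.nrow(); ++i) {
      int p = counts(i, j);
      if (p == 0) continue;
      double gi = i + 1.0, rj = j + 1.0;
      num += p * gi * gi * rj * rj;
      nr_runs += p;
    }
  return num / nr_runs;
}

static inline int reflect_idx(int i, int n) {
  // symmetric reflection (edge value repeated): -1 -> 0, n -> n-1
  while (i < 0 || i >= n) {
    if (i < 0) i = -i - 1;
    if (i >= n) i = 2 * n - i - 1;
  }
  return i;
}

// Sliding-window LRHGLE map over a pre-quantized image. If reflect is
// false (shrink policy) only interior pixels are mapped and the output is
// (nr - window + 1) x (nc - window + 1).
// [[Rcpp::export]]
NumericMatrix lrhgle_map_cpp(IntegerMatrix img, int window, int nlevels,
                             IntegerVector directions, bool reflect) {
  int nr = img.nrow(), nc = img.ncol();
  int half = window / 2;
  int or_ = reflect ? nr : nr - window + 1;
  int oc = reflect ? nc : nc - window + 1;
  NumericMatrix out(or_, oc);
  IntegerMatrix win(window, window);
  for (int co = 0; co < oc; ++co) {
    for (int ro = 0; ro < or_; ++ro) {
      int rc = reflect ? ro : ro + half;   // window center
      int cc = reflect ? co : co + half;
      for (int dj = -half; dj <= half; ++dj)
        for (int di = -half; di <= half; ++di) {
          int ri = rc + di, ci = cc + dj;
          if (reflect) { ri = reflect_idx(ri, nr); ci = reflect_idx(ci, nc); }
          win(di + half, dj + half) = img(ri, ci);
        }
      IntegerMatrix counts(nlevels, window);
      for (int d = 0; d < directions.size(); ++d) {
        int dr, dc; dir_step(directions[d], dr, dc);
        for (int r = 0; r < window; ++r)
          for (int c = 0; c < window; ++c) {
            int pr = r - dr, pc = c - dc;
            if (pr >= 0 && pr < window && pc >= 0 && pc < window) continue;
            scan_line(win, r, c, dr, dc, counts);
          }
      }
      out(ro, co) = lrhgle_of(counts);
    }
  }
  return out;
}
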