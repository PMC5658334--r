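#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Online per-pixel Gaussian-mixture background model (Stauffer-Grimson style),
// grayscale. State matrices are npix x K and are updated in place; the caller
// owns them inside an environment so R copy-on-modify semantics are not
// violated. A pixel is foreground when its matched component is not part of
// the background set (components, sorted by weight/sd, whose cumulative
// weight first reaches bg_ratio).
//
// w == 0 across a row marks an uninitialised pixel: it is seeded from the
// first frame and reported as background.
// [[Rcpp::export(name = ".mog_update_cpp")]]
LogicalVector mog_update_cpp(NumericMatrix w, NumericMatrix mu, NumericMatrix var,
                             NumericVector x, double lr, double var_thresh,
                             double bg_ratio, double init_var, double min_var) {
  const int n = w.nrow(), K = w.ncol();
  if (x.size() != n) stop("frame size does not match model");
  LogicalVector fg(n);
  std::vector<int> ord(K);
  for (int i = 0; i < n; ++i) {
    double wsum = 0.0;
    for (int k = 0; k < K; ++k) wsum += w(i, k);
    if (wsum <= 0.0) {                     // first observation of this pixel
      w(i, 0) = 1.0; mu(i, 0) = x[i]; var(i, 0) = init_var;
      fg[i] = false;
      continue;
    }
    // rank components by w / sd (descending); K is tiny, selection sort
    for (int k = 0; k < K; ++k) ord[k] = k;
    for (int a = 0; a < K - 1; ++a) {
      int best = a;
      for (int b = a + 1; b < K; ++b) {
        double sa = w(i, ord[best]) / std::sqrt(var(i, ord[best]) + 1e-12);
        double sb = w(i, ord[b]) / std::sqrt(var(i, ord[b]) + 1e-12);
        if (sb > sa) best = b;
      }
      std::swap(ord[a], ord[best]);
    }
    // background set: first components whose cumulative weight reaches bg_ratio
    int n_bg = 0; double cum = 0.0;
    for (int a = 0; a < K; ++a) {
      ++n_bg; cum += w(i, ord[a]) / wsum;
      if (cum >= bg_ratio) break;
    }
    // first matching component in rank order
    int match = -1, match_rank = -1;
    for (int a = 0; a < K; ++a) {
      int k = ord[a];
      if (w(i, k) <= 0.0) continue;
      double d = x[i] - mu(i, k);
      if (d * d < var_thresh * var(i, k)) { match = k; match_rank = a; break; }
    }
    if (match >= 0) {
      fg[i] = (match_rank >= n_bg);
      for (int k = 0; k < K; ++k)
        w(i, k) = (1.0 - lr) * w(i, k) + (k == match ? lr : 0.0);
      double d = x[i] - mu(i, match);
      mu(i, match) += lr * d;
      var(i, match) = (1.0 - lr) * var(i, match) + lr * d * d;
      if (var(i, match) < min_var) var(i, match) = min_var;
    } else {
      fg[i] = true;                        // unseen value: new component
      int weakest = ord[K - 1];
      w(i, weakest) = lr; mu(i, weakest) = x[i]; var(i, weakest) = init_var;
    }
    // renormalise weights
    double s = 0.0;
    for (int k = 0; k < K; ++k) s += w(i, k);
    for (int k = 0; k < K; ++k) w(i, k) /= s;
  }
  return fg;
}

// 8-connected component labeling of a logical matrix, flood fill with an
// explicit stack. Labels are 1..n in scan order of first encounter.
// [[Rcpp::export(name = ".label8_cpp")]]
IntegerMatrix label8_cpp(LogicalMatrix mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  std::vector<int> stack;
  int next = 0;
  for (int j = 0; j < nc; ++j) for (int i = 0; i < nr; ++i) {
    if (!mask(i, j) || lab(i, j)) continue;
    ++next;
    stack.push_back(i + j * nr);
    lab(i, j) = next;
    while (!stack.empty()) {
      int p = stack.back(); stack.pop_back();
      int pi = p % nr, pj = p / nr;
      for (int dj = -1; dj <= 1; ++dj) for (int di = -1; di <= 1; ++di) {
        if (!di && !dj) continue;
        int qi = pi + di, qj = pj + dj;
        if (qi < 0 || qi >= nr || qj < 0 || qj >= nc) continue;
        if (mask(qi, qj) && !lab(qi, qj)) {
          lab(qi, qj) = next;
          stack.push_back(qi + qj * nr);
        }
      }
    }
  }
  lab.attr("n") = next;
  return lab;
}

// Moore-neighbour boundary trace of one labeled component; returns the closed
// pixel path (row, col), 1-based, first pixel repeated at the end.
// [[Rcpp::export(name = ".trace_boundary_cpp")]]
IntegerMatrix trace_boundary_cpp(IntegerMatrix lab, int id) {
  const int nr = lab.nrow(), nc = lab.ncol();
  int si = -1, sj = -1;
  for (int j = 0; j < nc && si < 0; ++j)
    for (int i = 0; i < nr; ++i)
      if (lab(i, j) == id) { si = i; sj = j; break; }
  if (si < 0) stop("label not present");
  // Moore neighbourhood in clockwise order starting west
  const int di[8] = { 0, -1, -1, -1,  0,  1, 1, 1};
  const int dj[8] = {-1, -1,  0,  1,  1,  1, 0, -1};
  std::vector<int> path_i, path_j;
  int ci = si, cj = sj, back = 0;       // entered from the west
  path_i.push_back(ci); path_j.push_back(cj);
  for (int guard = 0; guard < 4 * nr * nc; ++guard) {
    int found = -1;
    for (int t = 0; t < 8; ++t) {
      int dir = (back + 1 + t) % 8;
      int qi = ci + di[dir], qj = cj + dj[dir];
      if (qi < 0 || qi >= nr || qj < 0 || qj >= nc) continue;
      if (lab(qi, qj) == id) { found = dir; ci = qi; cj = qj; break; }
    }
    if (found < 0) break;               // isolated pixel
    back = (found + 4) % 8;             // direction pointing back where we came from
    if (ci == si && cj == sj) break;
    path_i.push_back(ci); path_j.push_back(cj);
  }
  path_i.push_back(si); path_j.push_back(sj);
  IntegerMatrix out(path_i.size(), 2);
  for (size_t t = 0; t < path_i.size(); ++t) {
    out(t, 0) = path_i[t] + 1; out(t, 1) = path_j[t] + 1;
  }
  colnames(out) = CharacterVector::create("row", "col");
  return out;
}

// Draw filled discs of constant intensity onto a copy of the background image.
// Coordinates in pixels (1-based, row/col), radii in pixels.
// [[Rcpp::export(name = ".draw_discs_cpp")]]
NumericMatrix draw_discs_cpp(NumericMatrix bg, NumericVector row, NumericVector col,
                             NumericVector r, double value) {
  NumericMatrix img = clone(bg);
  const int nr = img.nrow(), nc = img.ncol();
  for (int d = 0; d < row.size(); ++d) {
    double cr = row[d] - 1.0, cc = col[d] - 1.0, rad = r[d];
    if (!R_finite(cr) || !R_finite(cc) || rad <= 0) continue;
    int i0 = std::max(0, (int)std::floor(cr - rad)), i1 = std::min(nr - 1, (int)std::ceil(cr + rad));
    int j0 = std::max(0, (int)std::floor(cc - rad)), j1 = std::min(nc - 1, (int)std::ceil(cc + rad));
    double r2 = rad * rad;
    for (int j = j0; j <= j1; ++j) {
      double dj = j - cc;
      for (int i = i0; i <= i1; ++i) {
        double di = i - cr;
        if (di * di + dj * dj <= r2) img(i, j) = value;
      }
    }
  }
  return img;
}
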