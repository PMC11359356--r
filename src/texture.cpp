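#include <Rcpp.h>
using namespace Rcpp;

// Texture matrix constructions on quantized, masked ROIs.
// `levels` holds gray levels 1..ng inside the mask; values outside the mask
// are ignored. All constructions respect the mask: pixel pairs, runs, zones
// and neighborhoods never cross out-of-mask pixels.

// [[Rcpp::export(name = ".glcm_counts")]]
NumericMatrix glcm_counts(IntegerMatrix levels, LogicalMatrix mask, int ng,
                          IntegerVector dr, IntegerVector dc) {
  int nr = levels.nrow(), nc = levels.ncol();
  NumericMatrix out(ng, ng);
  for (int k = 0; k < dr.size(); ++k) {
    int ddr = dr[k], ddc = dc[k];
    for (int i = 0; i < nr; ++i) {
      for (int j = 0; j < nc; ++j) {
        if (!mask(i, j)) continue;
        int i2 = i + ddr, j2 = j + ddc;
        if (i2 < 0 || i2 >= nr || j2 < 0 || j2 >= nc) continue;
        if (!mask(i2, j2)) continue;
        int a = levels(i, j) - 1, b = levels(i2, j2) - 1;
        // symmetric matrix: count the pair in both orders
        out(a, b) += 1.0;
        out(b, a) += 1.0;
      }
    }
  }
  return out;
}

// Runs along one direction; each maximal same-level in-mask run counted once.
// [[Rcpp::export(name = ".glrlm_counts")]]
NumericMatrix glrlm_counts(IntegerMatrix levels, LogicalMatrix mask, int ng,
                           int dr, int dc) {
  int nr = levels.nrow(), nc = levels.ncol();
  int maxlen = std::max(nr, nc);
  NumericMatrix out(ng, maxlen);
  for (int i = 0; i < nr; ++i) {
    for (int j = 0; j < nc; ++j) {
      if (!mask(i, j)) continue;
      int ip = i - dr, jp = j - dc;
      bool starts = ip < 0 || ip >= nr || jp < 0 || jp >= nc ||
                    !mask(ip, jp) || levels(ip, jp) != levels(i, j);
      if (!starts) continue;
      int len = 1, i2 = i + dr, j2 = j + dc;
      while (i2 >= 0 && i2 < nr && j2 >= 0 && j2 < nc && mask(i2, j2) &&
             levels(i2, j2) == levels(i, j)) {
        ++len; i2 += dr; j2 += dc;
      }
      out(levels(i, j) - 1, len - 1) += 1.0;
    }
  }
  return out;
}

// 8-connected zones of equal level; returns one row per zone: (level, size).
// [[Rcpp::export(name = ".glszm_zones")]]
IntegerMatrix glszm_zones(IntegerMatrix levels, LogicalMatrix mask) {
  int nr = levels.nrow(), nc = levels.ncol();
  std::vector<bool> seen(nr * nc, false);
  std::vector<int> zl, zs, stack;
  for (int i = 0; i < nr; ++i) {
    for (int j = 0; j < nc; ++j) {
      int idx = i + j * nr;
      if (!mask(i, j) || seen[idx]) continue;
      int lev = levels(i, j), size = 0;
      stack.clear(); stack.push_back(idx); seen[idx] = true;
      while (!stack.empty()) {
        int cur = stack.back(); stack.pop_back(); ++size;
        int ci = cur % nr, cj = cur / nr;
        for (int di = -1; di <= 1; ++di) {
          for (int dj = -1; dj <= 1; ++dj) {
            if (di == 0 && dj == 0) continue;
            int ni = ci + di, nj = cj + dj;
            if (ni < 0 || ni >= nr || nj < 0 || nj >= nc) continue;
            int nidx = ni + nj * nr;
            if (seen[nidx] || !mask(ni, nj) || levels(ni, nj) != lev) continue;
            seen[nidx] = true; stack.push_back(nidx);
          }
        }
      }
      zl.push_back(lev); zs.push_back(size);
    }
  }
  IntegerMatrix out(zl.size(), 2);
  for (size_t k = 0; k < zl.size(); ++k) { out(k, 0) = zl[k]; out(k, 1) = zs[k]; }
  return out;
}

// Topographic prominence of local maxima of y at (1-based) indices pk:
// walk outward on each side while below the peak, tracking the minimum;
// the base is the higher of the two side minima.
// [[Rcpp::export(name = ".peak_prominence_cpp")]]
NumericVector peak_prominence_cpp(NumericVector y, IntegerVector pk) {
  int n = y.size();
  NumericVector out(pk.size());
  for (int k = 0; k < pk.size(); ++k) {
    int p = pk[k] - 1;
    double lo = y[p];
    double lmin = lo, rmin = lo;
    for (int j = p - 1; j >= 0 && y[j] <= lo; --j) lmin = std::min(lmin, y[j]);
    for (int j = p + 1; j < n && y[j] <= lo; ++j) rmin = std::min(rmin, y[j]);
    out[k] = lo - std::max(lmin, rmin);
  }
  return out;
}

// Amadasun-King neighborhood sums: for each in-mask pixel with at least one
// in-mask 8-neighbor, accumulate |level - mean(neighbor levels)| per level.
// [[Rcpp::export(name = ".ngtdm_table")]]
List ngtdm_table(IntegerMatrix levels, LogicalMatrix mask, int ng) {
  int nr = levels.nrow(), nc = levels.ncol();
  NumericVector s(ng);
  IntegerVector n(ng);
  for (int i = 0; i < nr; ++i) {
    for (int j = 0; j < nc; ++j) {
      if (!mask(i, j)) continue;
      double sum = 0.0; int cnt = 0;
      for (int di = -1; di <= 1; ++di) {
        for (int dj = -1; dj <= 1; ++dj) {
          if (di == 0 && dj == 0) continue;
          int ni = i + di, nj = j + dj;
          if (ni < 0 || ni >= nr || nj < 0 || nj >= nc) continue;
          if (!mask(ni, nj)) continue;
          sum += levels(ni, nj); ++cnt;
        }
      }
      if (cnt == 0) continue;
      int lev = levels(i, j) - 1;
      s[lev] += std::abs(levels(i, j) - sum / cnt);
      n[lev] += 1;
    }
  }
  return List::create(_["s"] = s, _["n"] = n);
}
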