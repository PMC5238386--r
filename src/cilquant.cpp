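#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

// Decompose EIC traces into chromatographic peaks.
//
// Input centroids must be sorted by (trace, scan).  Within a trace,
// centroids are aggregated per scan, split into segments wherever more
// than `max_gap` consecutive scans are empty, and each segment is
// decomposed at valleys between local maxima.  A valley separates two
// peaks only when it drops below `valley_frac` times the lower of the
// two apexes; shallower dips are treated as noise on a single peak.
//
// Returned indices (idx_start/idx_end, 1-based) delimit the contiguous
// block of input centroids belonging to each peak.
// [[Rcpp::export]]
DataFrame decompose_traces_cpp(IntegerVector trace, IntegerVector scan,
                               NumericVector mz, NumericVector intensity,
                               double min_height, int min_scans, int max_gap,
                               double valley_frac) {
  int n = trace.size();
  std::vector<double> out_mz, out_height, out_area;
  std::vector<int> out_trace, out_apex, out_start, out_end, out_nscans,
      out_i0, out_i1;

  int i = 0;
  while (i < n) {
    int j = i;
    while (j < n && trace[j] == trace[i]) ++j;  // trace block [i, j)

    // aggregate per scan (multiple centroids can fall in one scan)
    std::vector<int> s, first_idx, last_idx;
    std::vector<double> y, wmz;
    int k = i;
    while (k < j) {
      int k2 = k;
      double ysum = 0.0, msum = 0.0;
      while (k2 < j && scan[k2] == scan[k]) {
        ysum += intensity[k2];
        msum += mz[k2] * intensity[k2];
        ++k2;
      }
      s.push_back(scan[k]);
      y.push_back(ysum);
      wmz.push_back(msum);
      first_idx.push_back(k);
      last_idx.push_back(k2 - 1);
      k = k2;
    }
    int m = (int)s.size();

    int a = 0;
    while (a < m) {
      int b = a;
      while (b + 1 < m && s[b + 1] - s[b] <= max_gap + 1) ++b;  // segment [a,b]

      // local maxima (right edge of any plateau)
      std::vector<int> keep;
      for (int t = a; t <= b; ++t) {
        double yl = (t > a) ? y[t - 1] : -1.0;
        double yr = (t < b) ? y[t + 1] : -1.0;
        if (y[t] >= yl && y[t] > yr && y[t] >= min_height) keep.push_back(t);
      }

      if (!keep.empty()) {
        // absorb maxima separated only by shallow valleys
        bool merged = true;
        while (merged && keep.size() > 1) {
          merged = false;
          for (size_t q = 0; q + 1 < keep.size(); ++q) {
            double vmin = R_PosInf;
            for (int t = keep[q]; t <= keep[q + 1]; ++t)
              vmin = std::min(vmin, y[t]);
            double lower = std::min(y[keep[q]], y[keep[q + 1]]);
            if (vmin >= valley_frac * lower) {
              if (y[keep[q]] < y[keep[q + 1]])
                keep.erase(keep.begin() + q);
              else
                keep.erase(keep.begin() + q + 1);
              merged = true;
              break;
            }
          }
        }

        std::vector<int> lo(keep.size()), hi(keep.size());
        lo[0] = a;
        hi[keep.size() - 1] = b;
        for (size_t q = 0; q + 1 < keep.size(); ++q) {
          int vpos = keep[q];
          double vmin = R_PosInf;
          for (int t = keep[q]; t <= keep[q + 1]; ++t)
            if (y[t] < vmin) { vmin = y[t]; vpos = t; }
          hi[q] = vpos;
          lo[q + 1] = vpos + 1;
        }

        for (size_t q = 0; q < keep.size(); ++q) {
          int nsc = hi[q] - lo[q] + 1;
          double h = y[keep[q]];
          if (nsc >= min_scans && h >= min_height) {
            double area = 0.0, msum = 0.0;
            for (int t = lo[q]; t <= hi[q]; ++t) {
              area += y[t];
              msum += wmz[t];
            }
            out_trace.push_back(trace[i]);
            out_mz.push_back(msum / area);
            out_height.push_back(h);
            out_area.push_back(area);
            out_apex.push_back(s[keep[q]]);
            out_start.push_back(s[lo[q]]);
            out_end.push_back(s[hi[q]]);
            out_nscans.push_back(nsc);
            out_i0.push_back(first_idx[lo[q]] + 1);
            out_i1.push_back(last_idx[hi[q]] + 1);
          }
        }
      }
      a = b + 1;
    }
    i = j;
  }

  return DataFrame::create(
      _["trace"] = out_trace, _["mz"] = out_mz, _["scan_apex"] = out_apex,
      _["scan_start"] = out_start, _["scan_end"] = out_end,
      _["height"] = out_height, _["area_raw"] = out_area,
      _["n_scans"] = out_nscans, _["idx_start"] = out_i0,
      _["idx_end"] = out_i1);
}

// Greedy consensus clustering of peak pairs across runs.
//
// Pairs must arrive sorted by descending weight (total intensity),
// ties broken by ascending m/z, so cluster seeds are the strongest
// pairs and the procedure is deterministic.  A pair joins the closest
// existing row whose running intensity-weighted consensus lies within
// `ppm_tol` (relative to the consensus m/z) and `rt_tol`, provided the
// pair's run is not already represented in that row; otherwise it
// founds a new row.
// [[Rcpp::export]]
IntegerVector align_pairs_cpp(NumericVector mz, NumericVector rt,
                              NumericVector weight, IntegerVector run,
                              int n_runs, double ppm_tol, double rt_tol) {
  int n = mz.size();
  IntegerVector assign(n);
  std::vector<double> cmz, crt, cw;
  std::vector<std::vector<char> > member;

  for (int i = 0; i < n; ++i) {
    int best = -1;
    double bestd = R_PosInf;
    for (size_t r = 0; r < cmz.size(); ++r) {
      double dm = std::fabs(mz[i] - cmz[r]);
      if (dm > ppm_tol * 1e-6 * cmz[r]) continue;
      if (std::fabs(rt[i] - crt[r]) > rt_tol) continue;
      if (member[r][run[i] - 1]) continue;
      // ppm distance dominates; rt only breaks near-exact ties
      double d = dm / cmz[r] + std::fabs(rt[i] - crt[r]) / (rt_tol * 1e9);
      if (d < bestd) { bestd = d; best = (int)r; }
    }
    if (best < 0) {
      cmz.push_back(mz[i]);
      crt.push_back(rt[i]);
      cw.push_back(weight[i]);
      member.push_back(std::vector<char>(n_runs, 0));
      member.back()[run[i] - 1] = 1;
      assign[i] = (int)cmz.size();
    } else {
      double W = cw[best], w = weight[i];
      cmz[best] = (cmz[best] * W + mz[i] * w) / (W + w);
      crt[best] = (crt[best] * W + rt[i] * w) / (W + w);
      cw[best] += w;
      member[best][run[i] - 1] = 1;
      assign[i] = best + 1;
    }
  }
  return assign;
}
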