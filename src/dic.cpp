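#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Zero-normalized cross-correlation of one subset pair.
// r0, c0 are 0-based top-left corners of the subset in ref;
// dr, dc the integer shift applied in cur.
static double zncc(const NumericMatrix& ref, const NumericMatrix& cur,
                   int r0, int c0, int dr, int dc, int size,
                   double fmean, double fsd) {
  double gsum = 0.0, gsum2 = 0.0, fg = 0.0;
  const int n = size * size;
  for (int j = 0; j < size; ++j) {
    for (int i = 0; i < size; ++i) {
      const double g = cur(r0 + i + dr, c0 + j + dc);
      const double f = ref(r0 + i, c0 + j);
      gsum += g;
      gsum2 += g * g;
      fg += f * g;
    }
  }
  const double gmean = gsum / n;
  const double gvar = gsum2 - n * gmean * gmean;
  if (gvar <= 1e-12) return NA_REAL;
  // fg - n*fmean*gmean is the zero-mean cross term
  return (fg - n * fmean * gmean) / (fsd * std::sqrt(gvar));
}

// One-dimensional parabolic sub-sample refinement around a discrete peak.
static double parafit(double cm, double c0, double cp) {
  const double denom = cm - 2.0 * c0 + cp;
  if (denom >= -1e-15) return 0.0;  // degenerate / flat top
  double d = 0.5 * (cm - cp) / denom;
  if (d > 0.5) d = 0.5;
  if (d < -0.5) d = -0.5;
  return d;
}

// [[Rcpp::export(name = ".dic_match_cpp")]]
NumericMatrix dic_match_cpp(NumericMatrix ref, NumericMatrix cur,
                            IntegerVector center_row, IntegerVector center_col,
                            int subset_size, int search_radius) {
  const int n_pts = center_row.size();
  const int H = ref.nrow(), W = ref.ncol();
  const int half = subset_size / 2;
  NumericMatrix out(n_pts, 3);  // du_row, du_col, quality
  const int span = 2 * search_radius + 1;
  std::vector<double> corr(span * span);

  for (int p = 0; p < n_pts; ++p) {
    const int r0 = center_row[p] - 1 - half;  // 0-based top-left
    const int c0 = center_col[p] - 1 - half;
    out(p, 0) = NA_REAL; out(p, 1) = NA_REAL; out(p, 2) = NA_REAL;
    if (r0 < 0 || c0 < 0 || r0 + subset_size > H || c0 + subset_size > W)
      continue;

    // reference subset statistics
    double fsum = 0.0, fsum2 = 0.0;
    for (int j = 0; j < subset_size; ++j)
      for (int i = 0; i < subset_size; ++i) {
        const double f = ref(r0 + i, c0 + j);
        fsum += f; fsum2 += f * f;
      }
    const int nsub = subset_size * subset_size;
    const double fmean = fsum / nsub;
    const double fvar = fsum2 - nsub * fmean * fmean;
    if (fvar <= 1e-12) continue;  // flat texture: flagged invalid
    const double fsd = std::sqrt(fvar);

    // shift range clamped so the shifted subset stays inside cur
    const int dr_lo = std::max(-search_radius, -r0);
    const int dr_hi = std::min(search_radius, H - subset_size - r0);
    const int dc_lo = std::max(-search_radius, -c0);
    const int dc_hi = std::min(search_radius, W - subset_size - c0);
    if (dr_lo > dr_hi || dc_lo > dc_hi) continue;

    double best = -2.0;
    int best_dr = 0, best_dc = 0;
    std::fill(corr.begin(), corr.end(), NA_REAL);
    for (int dc = dc_lo; dc <= dc_hi; ++dc) {
      for (int dr = dr_lo; dr <= dr_hi; ++dr) {
        const double c = zncc(ref, cur, r0, c0, dr, dc, subset_size,
                              fmean, fsd);
        corr[(dc + search_radius) * span + (dr + search_radius)] = c;
        if (!ISNAN(c) && c > best) { best = c; best_dr = dr; best_dc = dc; }
      }
    }
    if (best <= -2.0) continue;

    // a (numerically) perfect correlation is an exact integer match:
    // report it as-is without refinement
    const bool exact = best >= 1.0 - 1e-9;
    // otherwise a peak on the boundary of the searched shift range never
    // localized a maximum (displacement out of range, or subset pinned at
    // the image border): flag invalid rather than report a wrong zero
    if (!exact && (best_dr == dr_lo || best_dr == dr_hi ||
                   best_dc == dc_lo || best_dc == dc_hi))
      continue;

    double sub_r = 0.0, sub_c = 0.0;
    const int ir = best_dr + search_radius, ic = best_dc + search_radius;
    if (!exact) {
    if (best_dr > dr_lo && best_dr < dr_hi) {
      const double cm = corr[ic * span + ir - 1], cp = corr[ic * span + ir + 1];
      if (!ISNAN(cm) && !ISNAN(cp)) sub_r = parafit(cm, best, cp);
    }
    if (best_dc > dc_lo && best_dc < dc_hi) {
      const double cm = corr[(ic - 1) * span + ir], cp = corr[(ic + 1) * span + ir];
      if (!ISNAN(cm) && !ISNAN(cp)) sub_c = parafit(cm, best, cp);
    }
    }

    out(p, 0) = best_dr + sub_r;
    out(p, 1) = best_dc + sub_c;
    out(p, 2) = best > 1.0 ? 1.0 : best;
  }
  return out;
}
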