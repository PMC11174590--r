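#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Eight co-occurrence features from an aggregated cell list (i, j, p).
// COR is NaN when either marginal has zero variance.
static void featuresFromCells(const std::vector<int>& gi,
                              const std::vector<int>& gj,
                              const std::vector<double>& p,
                              double* out) {
  double mi = 0.0, mj = 0.0;
  size_t ncell = p.size();
  for (size_t k = 0; k < ncell; ++k) {
    mi += gi[k] * p[k];
    mj += gj[k] * p[k];
  }
  double vi = 0.0, vj = 0.0, cov = 0.0;
  double hom = 0.0, con = 0.0, dis = 0.0, ent = 0.0, sem = 0.0;
  for (size_t k = 0; k < ncell; ++k) {
    double di = gi[k] - mi, dj = gj[k] - mj;
    double d = gi[k] - gj[k];
    vi += di * di * p[k];
    vj += dj * dj * p[k];
    cov += di * dj * p[k];
    hom += p[k] / (1.0 + d * d);
    con += d * d * p[k];
    dis += std::abs(d) * p[k];
    ent -= p[k] * std::log(p[k]);
    sem += p[k] * p[k];
  }
  out[0] = mi;           // MEA
  out[1] = vi;           // VAR
  out[2] = hom;          // HOM
  out[3] = con;          // CON
  out[4] = dis;          // DIS
  out[5] = ent;          // ENT
  out[6] = sem;          // SEM
  out[7] = (vi > 0.0 && vj > 0.0) ? cov / std::sqrt(vi * vj)
                                  : NA_REAL;  // COR
}

// Sliding-window GLCM feature map over a quantized integer matrix.
// q: quantized gray levels (0-based), NA allowed for masked pixels.
// A window center is valid iff the full window lies inside the matrix
// and contains no masked pixel; co-occurring pairs are taken at
// displacement (dr, dc) within the window, counted symmetrically when
// `symmetric`. Returns an (nValid x 10) matrix: window center row,
// col (1-based), then MEA VAR HOM CON DIS ENT SEM COR.
// [[Rcpp::export]]
NumericMatrix glcm_feature_map(IntegerMatrix q, int window, int dr,
                               int dc, int levels, bool symmetric) {
  int nr = q.nrow(), nc = q.ncol();
  if (window < 3 || window % 2 == 0)
    stop("window must be an odd integer >= 3");
  if (levels < 2) stop("levels must be >= 2");
  int adr = std::abs(dr), adc = std::abs(dc);
  if (adr == 0 && adc == 0) stop("offset must be nonzero");
  if (window - adr <= 0 || window - adc <= 0)
    stop("offset larger than window: no co-occurring pairs");
  int half = window / 2;
  std::vector<double> rows, cols, feats;
  std::vector<int> codes, gi, gj;
  std::vector<double> pr;
  double f[8];

  for (int r0 = 0; r0 + window <= nr; ++r0) {
    for (int c0 = 0; c0 + window <= nc; ++c0) {
      bool ok = true;
      for (int a = r0; a < r0 + window && ok; ++a)
        for (int b = c0; b < c0 + window; ++b)
          if (IntegerMatrix::is_na(q(a, b))) { ok = false; break; }
      if (!ok) continue;
      codes.clear();
      // enumerate within-window pairs at displacement (dr, dc)
      int ra = (dr >= 0) ? r0 : r0 + adr;
      int rb = (dr >= 0) ? r0 + window - adr : r0 + window;
      int ca = (dc >= 0) ? c0 : c0 + adc;
      int cb = (dc >= 0) ? c0 + window - adc : c0 + window;
      for (int a = ra; a < rb; ++a) {
        for (int b = ca; b < cb; ++b) {
          int i = q(a, b), j = q(a + dr, b + dc);
          codes.push_back(i * levels + j);
          if (symmetric) codes.push_back(j * levels + i);
        }
      }
      std::sort(codes.begin(), codes.end());
      gi.clear(); gj.clear(); pr.clear();
      double tot = (double)codes.size();
      for (size_t k = 0; k < codes.size();) {
        size_t k2 = k;
        while (k2 < codes.size() && codes[k2] == codes[k]) ++k2;
        gi.push_back(codes[k] / levels);
        gj.push_back(codes[k] % levels);
        pr.push_back((k2 - k) / tot);
        k = k2;
      }
      featuresFromCells(gi, gj, pr, f);
      rows.push_back(r0 + half + 1);
      cols.push_back(c0 + half + 1);
      for (int k = 0; k < 8; ++k) feats.push_back(f[k]);
    }
  }
  int nwin = rows.size();
  NumericMatrix out(nwin, 10);
  for (int w = 0; w < nwin; ++w) {
    out(w, 0) = rows[w];
    out(w, 1) = cols[w];
    for (int k = 0; k < 8; ++k) out(w, k + 2) = feats[w * 8 + k];
  }
  colnames(out) = CharacterVector::create("row", "col", "MEA", "VAR",
                                          "HOM", "CON", "DIS", "ENT",
                                          "SEM", "COR");
  return out;
}
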