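#include <Rcpp.h>
using namespace Rcpp;

// C++ kernels for the O(n^2) inner loops of the composite energy and the
// contact metrics.  The term definitions and all constants live in R;
// this file only evaluates them.

static inline double dist3(const NumericMatrix& x, int i, int j) {
  double dx = x(i, 0) - x(j, 0);
  double dy = x(i, 1) - x(j, 1);
  double dz = x(i, 2) - x(j, 2);
  return std::sqrt(dx * dx + dy * dy + dz * dz);
}

static inline double clamp01(double x) {
  return x < 0.0 ? 0.0 : (x > 1.0 ? 1.0 : x);
}

// shortest distance between segments (p1,p2) and (q1,q2)
static double segDist(const double* p1, const double* p2,
                      const double* q1, const double* q2) {
  double u[3], v[3], w[3];
  for (int d = 0; d < 3; ++d) {
    u[d] = p2[d] - p1[d];
    v[d] = q2[d] - q1[d];
    w[d] = p1[d] - q1[d];
  }
  double a = 0, b = 0, c = 0, dd = 0, e = 0;
  for (int d = 0; d < 3; ++d) {
    a += u[d] * u[d];
    b += u[d] * v[d];
    c += v[d] * v[d];
    dd += u[d] * w[d];
    e += v[d] * w[d];
  }
  double den = a * c - b * b;
  double s = (den < 1e-12) ? 0.0 : (b * e - c * dd) / den;
  s = clamp01(s);
  double t = (c < 1e-12) ? 0.0 : (b * s + e) / c;
  t = clamp01(t);
  s = (a < 1e-12) ? 0.0 : clamp01((b * t - dd) / a);
  double out = 0;
  for (int d = 0; d < 3; ++d) {
    double diff = (p1[d] + s * u[d]) - (q1[d] + t * v[d]);
    out += diff * diff;
  }
  return std::sqrt(out);
}

// All residue-pair and SSE-pair sums of the composite energy in one pass.
//
// coordsList: per SSE, a (5m) x 3 coordinate matrix (atom order
//           N, CA, C, O, CB per residue)
// firsts, lasts: per SSE, 1-based inclusive sequence bounds (sorted)
// hydFull:  normalized hydrophobicity per sequence position
// sseType:  per SSE, 0 = helix, 1 = strand
// axP1/axP2: per SSE, axis segment endpoints (k x 3)
// axDir:    per SSE, unit axis direction (k x 3)
// consts:   named numeric vector of term constants
// [[Rcpp::export(name = ".energyKernel")]]
NumericVector energyKernel(const List& coordsList,
                           const IntegerVector& firsts,
                           const IntegerVector& lasts,
                           const NumericVector& hydFull,
                           const IntegerVector& sseType,
                           const NumericMatrix& axP1,
                           const NumericMatrix& axP2,
                           const NumericMatrix& axDir,
                           const NumericVector& consts) {
  const int k = sseType.size();
  int n = 0;
  for (int i = 0; i < k; ++i) n += lasts[i] - firsts[i] + 1;
  NumericMatrix cb(n, 3), ca(n, 3);
  IntegerVector resno(n), sseId(n);
  NumericVector hyd(n);
  NumericMatrix anchorC(k, 3), anchorN(k, 3);
  IntegerVector nLoop(k > 1 ? k - 1 : 0);
  {
    int pos = 0;
    for (int i = 0; i < k; ++i) {
      NumericMatrix co = coordsList[i];
      int m = lasts[i] - firsts[i] + 1;
      for (int r = 0; r < m; ++r) {
        for (int d = 0; d < 3; ++d) {
          ca(pos, d) = co(r * 5 + 1, d);
          cb(pos, d) = co(r * 5 + 4, d);
        }
        resno[pos] = firsts[i] + r;
        sseId[pos] = i + 1;
        hyd[pos] = hydFull[firsts[i] + r - 1];
        ++pos;
      }
      for (int d = 0; d < 3; ++d) {
        anchorC(i, d) = co((m - 1) * 5 + 2, d);
        anchorN(i, d) = co(0, d);
      }
      if (i > 0) nLoop[i - 1] = firsts[i] - lasts[i - 1] - 1;
    }
  }
  const double clashDist = consts["clash_dist"];
  const double kappa = consts["clash_kappa"];
  const double pairCutoff = consts["pair_cutoff"];
  const int pairMinSep = (int)consts["pair_min_sep"];
  const double nbCutoff = consts["neighbor_cutoff"];
  const double nbRef = consts["neighbor_ref"];
  const double nbScale = consts["neighbor_scale"];
  const double contactCutoff = consts["contact_cutoff"];

  double clash = 0, pair = 0, coSum = 0;
  int nContacts = 0;
  std::vector<int> ncount(n, 0);
  for (int i = 0; i < n - 1; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double d = dist3(cb, i, j);
      int sep = std::abs(resno[i] - resno[j]);
      if (sseId[i] != sseId[j] && d < clashDist) {
        double o = clashDist - d;
        clash += kappa * o * o;
      }
      if (sep >= pairMinSep && d < pairCutoff)
        pair += -hyd[i] * hyd[j] * (1.0 - d / pairCutoff);
      if (d < nbCutoff) {
        ncount[i] += 1;
        ncount[j] += 1;
      }
      if (sep >= 1 && d < contactCutoff) {
        coSum += sep;
        nContacts += 1;
      }
    }
  }
  double solv = 0;
  for (int i = 0; i < n; ++i)
    solv += -hyd[i] * std::tanh((ncount[i] - nbRef) / nbScale);

  // SSE-pair geometry
  const double packRange = consts["packing_range"];
  const double packWidth = consts["packing_width"];
  const double packHH = consts["packing_ideal_hh"];
  const double packHS = consts["packing_ideal_hs"];
  const double clashHH = consts["sse_clash_hh"];
  const double clashHS = consts["sse_clash_hs"];
  const double clashSS = consts["sse_clash_ss"];
  const double spIdeal = consts["strand_pair_ideal"];
  const double spWidth = consts["strand_pair_width"];
  double sseClash = 0, packing = 0, pairing = 0;
  // per-SSE CA row ranges (residue-major, SSEs contiguous and ordered)
  std::vector<int> sseFrom(k, -1), sseTo(k, -1);
  for (int i = 0; i < n; ++i) {
    int s = sseId[i] - 1;
    if (sseFrom[s] < 0) sseFrom[s] = i;
    sseTo[s] = i;
  }
  for (int i = 0; i < k - 1; ++i) {
    double p1i[3], p2i[3];
    for (int d = 0; d < 3; ++d) { p1i[d] = axP1(i, d); p2i[d] = axP2(i, d); }
    for (int j = i + 1; j < k; ++j) {
      double q1[3], q2[3];
      for (int d = 0; d < 3; ++d) { q1[d] = axP1(j, d); q2[d] = axP2(j, d); }
      double d = segDist(p1i, p2i, q1, q2);
      bool ss = sseType[i] == 1 && sseType[j] == 1;
      bool hh = sseType[i] == 0 && sseType[j] == 0;
      double dmin = ss ? clashSS : (hh ? clashHH : clashHS);
      if (d < dmin) sseClash += kappa * (dmin - d) * (dmin - d);
      if (ss) {
        // mean nearest CA-CA pairing distance, symmetrized
        double mi = 0, mj = 0;
        int ni = 0, nj = 0;
        for (int a = sseFrom[i]; a <= sseTo[i]; ++a) {
          double best = R_PosInf;
          for (int b = sseFrom[j]; b <= sseTo[j]; ++b) {
            double dd = dist3(ca, a, b);
            if (dd < best) best = dd;
          }
          mi += best; ni += 1;
        }
        for (int b = sseFrom[j]; b <= sseTo[j]; ++b) {
          double best = R_PosInf;
          for (int a = sseFrom[i]; a <= sseTo[i]; ++a) {
            double dd = dist3(ca, a, b);
            if (dd < best) best = dd;
          }
          mj += best; nj += 1;
        }
        double dp = 0.5 * (mi / ni + mj / nj);
        double dev = (dp - spIdeal) / spWidth;
        double well = 1.0 - dev * dev;
        if (well > 0) pairing -= well;
      } else if (d < packRange) {
        double ideal = hh ? packHH : packHS;
        double dev = (d - ideal) / packWidth;
        double well = 1.0 - dev * dev;
        if (well > 0) {
          double cosang = 0;
          for (int dd = 0; dd < 3; ++dd) cosang += axDir(i, dd) * axDir(j, dd);
          packing -= well * (0.5 + 0.5 * std::fabs(cosang));
        }
      }
    }
  }

  // loop terms over adjacent SSE pairs
  const double loopPerRes = consts["loop_per_res"];
  const double closurePenalty = consts["closure_penalty"];
  double ll = 0, lc = 0;
  for (int i = 0; i + 1 < k; ++i) {
    double g = 0;
    for (int d = 0; d < 3; ++d) {
      double diff = anchorC(i, d) - anchorN(i + 1, d);
      g += diff * diff;
    }
    g = std::sqrt(g);
    double r = g / std::sqrt((double)nLoop[i] + 1.0) - loopPerRes;
    if (r > 0) ll += r * r;
    if (g > 2.56 * (nLoop[i] + 1.0) + 2.0) lc += closurePenalty;
  }

  // radius of gyration over CA
  double cx = 0, cy = 0, cz = 0;
  for (int i = 0; i < n; ++i) { cx += ca(i, 0); cy += ca(i, 1); cz += ca(i, 2); }
  cx /= n; cy /= n; cz /= n;
  double rg2 = 0;
  for (int i = 0; i < n; ++i) {
    double dx = ca(i, 0) - cx, dy = ca(i, 1) - cy, dz = ca(i, 2) - cz;
    rg2 += dx * dx + dy * dy + dz * dz;
  }
  double rg = std::sqrt(rg2 / n);
  double rgExp = consts["rg_coef"] * std::pow((double)n, consts["rg_exp"]);
  double rgDev = (rg - rgExp) / rgExp;

  const double L = consts["seq_len"];
  double rco = nContacts > 0 ? (coSum / nContacts) / L : 0.0;
  double rcoDev = (rco - consts["rco_target"]) / consts["rco_width"];

  NumericVector out = NumericVector::create(
    _["aa_clash"] = clash, _["aa_pair_distance"] = pair,
    _["aa_solvation"] = solv, _["sse_pair_clash"] = sseClash,
    _["sse_packing"] = packing, _["strand_pairing"] = pairing,
    _["loop_length"] = ll, _["loop_closure"] = lc,
    _["radius_of_gyration"] = rgDev * rgDev,
    _["contact_order"] = rcoDev * rcoDev);
  return out;
}

// Residue-residue contacts: pairs with |i - j| >= minSep and d(CB) < cutoff.
// Returns a 2-column matrix of 1-based sequence indices (i < j).
// [[Rcpp::export(name = ".contactPairs")]]
IntegerMatrix contactPairs(const NumericMatrix& cb, const IntegerVector& resno,
                           int minSep, double cutoff) {
  const int n = cb.nrow();
  std::vector<int> ii, jj;
  for (int i = 0; i < n - 1; ++i) {
    for (int j = i + 1; j < n; ++j) {
      if (std::abs(resno[i] - resno[j]) < minSep) continue;
      if (dist3(cb, i, j) < cutoff) {
        int a = resno[i], b = resno[j];
        if (a > b) std::swap(a, b);
        ii.push_back(a);
        jj.push_back(b);
      }
    }
  }
  IntegerMatrix out(ii.size(), 2);
  for (size_t k = 0; k < ii.size(); ++k) {
    out(k, 0) = ii[k];
    out(k, 1) = jj[k];
  }
  return out;
}
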