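#include <Rcpp.h>
using namespace Rcpp;

// Build P(t) = U diag(exp(lam * t)) Uinv for a 4-state reversible generator.
static void pmat(const double* U, const double* Uinv, const double* lam,
                 double t, double* P) {
  double e[4];
  for (int k = 0; k < 4; ++k) e[k] = std::exp(lam[k] * t);
  for (int i = 0; i < 4; ++i) {
    for (int j = 0; j < 4; ++j) {
      double s = 0.0;
      // column-major storage: U[i + 4*k], Uinv[k + 4*j]
      for (int k = 0; k < 4; ++k) s += U[i + 4 * k] * e[k] * Uinv[k + 4 * j];
      P[i + 4 * j] = s < 0.0 ? 0.0 : s;
    }
  }
}

// Pruning likelihood of an unrooted quartet ((A,B),(C,D)).
//
// U, Uinv, lam: eigensystem of the scaled generator Q (Q = U diag(lam) Uinv).
// pi: stationary base frequencies (A,C,G,T order assumed consistent with Q).
// b:  branch lengths (A, B, C, D, internal) in expected substitutions/site.
// rates: gamma category multipliers, equal weights; p_inv: invariant fraction.
// tips: npat x 4 integer matrix of states 0..3, or -1 for missing/ambiguous
//       (partial likelihood 1 in every state).
// counts: pattern multiplicities (double, so bootstrap weights are allowed).
//
// Returns sum over patterns of count * log(site likelihood).
// [[Rcpp::export]]
double quartet_lnl_cpp(NumericMatrix U, NumericMatrix Uinv, NumericVector lam,
                       NumericVector pi, NumericVector b, NumericVector rates,
                       double p_inv, IntegerMatrix tips, NumericVector counts) {
  const int npat = tips.nrow();
  const int ncat = rates.size();
  const double wcat = 1.0 / ncat;
  std::vector<double> sitelik(npat, 0.0);

  double P[5][16];
  for (int c = 0; c < ncat; ++c) {
    const double r = rates[c];
    for (int e = 0; e < 5; ++e)
      pmat(REAL(U), REAL(Uinv), REAL(lam), b[e] * r, P[e]);
    for (int s = 0; s < npat; ++s) {
      const int sA = tips(s, 0), sB = tips(s, 1), sC = tips(s, 2), sD = tips(s, 3);
      double Lu[4], Rv[4];
      for (int x = 0; x < 4; ++x) {
        const double la = sA < 0 ? 1.0 : P[0][x + 4 * sA];
        const double lb = sB < 0 ? 1.0 : P[1][x + 4 * sB];
        Lu[x] = la * lb;
        const double lc = sC < 0 ? 1.0 : P[2][x + 4 * sC];
        const double ld = sD < 0 ? 1.0 : P[3][x + 4 * sD];
        Rv[x] = lc * ld;
      }
      double lik = 0.0;
      for (int x = 0; x < 4; ++x) {
        double m = 0.0;
        for (int y = 0; y < 4; ++y) m += P[4][x + 4 * y] * Rv[y];
        lik += pi[x] * Lu[x] * m;
      }
      sitelik[s] += wcat * lik;
    }
  }

  double lnl = 0.0;
  for (int s = 0; s < npat; ++s) {
    double lik = sitelik[s];
    if (p_inv > 0.0) {
      // invariant class: nonzero only when all observed tips share one base
      int base = -1;
      bool invariant = true;
      for (int t = 0; t < 4 && invariant; ++t) {
        const int st = tips(s, t);
        if (st < 0) continue;
        if (base < 0) base = st;
        else if (st != base) invariant = false;
      }
      double l0 = 0.0;
      if (invariant) l0 = base < 0 ? 1.0 : pi[base];
      lik = p_inv * l0 + (1.0 - p_inv) * lik;
    }
    if (lik < 1e-300) lik = 1e-300;
    lnl += counts[s] * std::log(lik);
  }
  return lnl;
}

static double eval_lnl(const double* U, const double* Uinv, const double* lam,
                       const double* pi, const double* b, const double* rates,
                       int ncat, double p_inv, const IntegerMatrix& tips,
                       const double* counts) {
  const int npat = tips.nrow();
  const double wcat = 1.0 / ncat;
  std::vector<double> sitelik(npat, 0.0);
  double P[5][16];
  for (int c = 0; c < ncat; ++c) {
    for (int e = 0; e < 5; ++e) pmat(U, Uinv, lam, b[e] * rates[c], P[e]);
    for (int s = 0; s < npat; ++s) {
      const int sA = tips(s, 0), sB = tips(s, 1), sC = tips(s, 2), sD = tips(s, 3);
      double Lu[4], Rv[4];
      for (int x = 0; x < 4; ++x) {
        Lu[x] = (sA < 0 ? 1.0 : P[0][x + 4 * sA]) * (sB < 0 ? 1.0 : P[1][x + 4 * sB]);
        Rv[x] = (sC < 0 ? 1.0 : P[2][x + 4 * sC]) * (sD < 0 ? 1.0 : P[3][x + 4 * sD]);
      }
      double lik = 0.0;
      for (int x = 0; x < 4; ++x) {
        double m = 0.0;
        for (int y = 0; y < 4; ++y) m += P[4][x + 4 * y] * Rv[y];
        lik += pi[x] * Lu[x] * m;
      }
      sitelik[s] += wcat * lik;
    }
  }
  double lnl = 0.0;
  for (int s = 0; s < npat; ++s) {
    double lik = sitelik[s];
    if (p_inv > 0.0) {
      int base = -1; bool inv = true;
      for (int t = 0; t < 4 && inv; ++t) {
        const int st = tips(s, t);
        if (st < 0) continue;
        if (base < 0) base = st; else if (st != base) inv = false;
      }
      double l0 = inv ? (base < 0 ? 1.0 : pi[base]) : 0.0;
      lik = p_inv * l0 + (1.0 - p_inv) * lik;
    }
    if (lik < 1e-300) lik = 1e-300;
    lnl += counts[s] * std::log(lik);
  }
  return lnl;
}

// Coordinate golden-section optimization of the five branch lengths with
// the substitution parameters held fixed. Each branch is maximized over
// [max(lo, b/shrink), min(hi, b*shrink + 0.08)] (the full [lo, hi] when
// shrink <= 0), `iters` golden-section steps, `rounds` passes over the
// branches. Returns the optimized lengths and the log-likelihood.
// [[Rcpp::export]]
List quartet_refit_cpp(NumericMatrix U, NumericMatrix Uinv, NumericVector lam,
                       NumericVector pi, NumericVector rates, double p_inv,
                       IntegerMatrix tips, NumericVector counts,
                       NumericVector b0, int rounds, double shrink,
                       double lo, double hi, int iters) {
  const double gr = 0.6180339887498949;
  double b[5];
  for (int e = 0; e < 5; ++e) b[e] = b0[e];
  const int ncat = rates.size();
  double cur = eval_lnl(REAL(U), REAL(Uinv), REAL(lam), REAL(pi), b,
                        REAL(rates), ncat, p_inv, tips, REAL(counts));
  for (int r = 0; r < rounds; ++r) {
    for (int e = 0; e < 5; ++e) {
      double a = lo, c = hi;
      if (shrink > 0) {
        a = std::max(lo, b[e] / shrink);
        c = std::min(hi, b[e] * shrink + 0.08);
      }
      auto f = [&](double v) {
        double bb[5];
        for (int k = 0; k < 5; ++k) bb[k] = b[k];
        bb[e] = v;
        return eval_lnl(REAL(U), REAL(Uinv), REAL(lam), REAL(pi), bb,
                        REAL(rates), ncat, p_inv, tips, REAL(counts));
      };
      double x1 = c - gr * (c - a), x2 = a + gr * (c - a);
      double f1 = f(x1), f2 = f(x2);
      for (int it = 0; it < iters; ++it) {
        if (f1 >= f2) { c = x2; x2 = x1; f2 = f1; x1 = c - gr * (c - a); f1 = f(x1); }
        else          { a = x1; x1 = x2; f1 = f2; x2 = a + gr * (c - a); f2 = f(x2); }
      }
      double xb = f1 >= f2 ? x1 : x2, fb = f1 >= f2 ? f1 : f2;
      if (fb > cur) { b[e] = xb; cur = fb; }
    }
  }
  return List::create(_["lnL"] = cur,
                      _["b"] = NumericVector(b, b + 5));
}

// As quartet_refit_cpp, but the objective is the sum of partition
// log-likelihoods, each partition with its own substitution parameters
// (shared topology and branch lengths). Used by the partitioned
// concatenation analysis.
// [[Rcpp::export]]
List quartet_refit_multi_cpp(List Us, List Uinvs, List lams, List pis,
                             List ratess, NumericVector p_invs,
                             List tipss, List countss,
                             NumericVector b0, int rounds, double shrink,
                             double lo, double hi, int iters) {
  const double gr = 0.6180339887498949;
  const int np = Us.size();
  std::vector<NumericMatrix> U(np), Uinv(np), tips(np);
  std::vector<NumericVector> lam(np), pi(np), rates(np), counts(np);
  std::vector<IntegerMatrix> tp(np);
  for (int i = 0; i < np; ++i) {
    U[i] = as<NumericMatrix>(Us[i]);
    Uinv[i] = as<NumericMatrix>(Uinvs[i]);
    lam[i] = as<NumericVector>(lams[i]);
    pi[i] = as<NumericVector>(pis[i]);
    rates[i] = as<NumericVector>(ratess[i]);
    counts[i] = as<NumericVector>(countss[i]);
    tp[i] = as<IntegerMatrix>(tipss[i]);
  }
  double b[5];
  for (int e = 0; e < 5; ++e) b[e] = b0[e];
  auto total = [&](const double* bb) {
    double s = 0.0;
    for (int i = 0; i < np; ++i)
      s += eval_lnl(REAL(U[i]), REAL(Uinv[i]), REAL(lam[i]), REAL(pi[i]), bb,
                    REAL(rates[i]), rates[i].size(), p_invs[i], tp[i],
                    REAL(counts[i]));
    return s;
  };
  double cur = total(b);
  for (int r = 0; r < rounds; ++r) {
    for (int e = 0; e < 5; ++e) {
      double a = lo, c = hi;
      if (shrink > 0) {
        a = std::max(lo, b[e] / shrink);
        c = std::min(hi, b[e] * shrink + 0.08);
      }
      auto f = [&](double v) {
        double bb[5];
        for (int k = 0; k < 5; ++k) bb[k] = b[k];
        bb[e] = v;
        return total(bb);
      };
      double x1 = c - gr * (c - a), x2 = a + gr * (c - a);
      double f1 = f(x1), f2 = f(x2);
      for (int it = 0; it < iters; ++it) {
        if (f1 >= f2) { c = x2; x2 = x1; f2 = f1; x1 = c - gr * (c - a); f1 = f(x1); }
        else          { a = x1; x1 = x2; f1 = f2; x2 = a + gr * (c - a); f2 = f(x2); }
      }
      double xb = f1 >= f2 ? x1 : x2, fb = f1 >= f2 ? f1 : f2;
      if (fb > cur) { b[e] = xb; cur = fb; }
    }
  }
  NumericVector per(np);
  for (int i = 0; i < np; ++i)
    per[i] = eval_lnl(REAL(U[i]), REAL(Uinv[i]), REAL(lam[i]), REAL(pi[i]), b,
                      REAL(rates[i]), rates[i].size(), p_invs[i], tp[i],
                      REAL(counts[i]));
  return List::create(_["lnL"] = cur, _["b"] = NumericVector(b, b + 5),
                      _["per_partition"] = per);
}
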