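#include <Rcpp.h>
using namespace Rcpp;

// Greedy per-variant sign selection and score statistic, evaluated over many
// phenotype columns at once (observed + permutations).
//
// A       k x k Gram matrix of the centered gene genotype columns
// C       k x (B+1) cross-products t(Gc) %*% centered phenotype columns,
//         column 0 = observed phenotype
// sigma2  MLE variance of the phenotype (permutation-invariant)
// poly    which variants are polymorphic; others are pinned to sign 0
// reselect  re-run the selection on every column (TRUE, the valid default)
//           or select once on column 0 and keep that coding fixed
//
// Statistic for sign vector s: (s'c)^2 / (sigma2 * s'As), 0 when the pooled
// regressor is degenerate. Selection: single forward pass in genomic order,
// s initialized to +1, each coordinate set to the value in {+1, -1, 0} that
// maximizes the statistic; ties keep the earlier candidate (+1 > -1 > 0).
// [[Rcpp::export]]
List seqAsumKernel(NumericMatrix A, NumericMatrix C, double sigma2,
                   LogicalVector poly, bool reselect) {
  const int k = A.nrow();
  const int ncols = C.ncol();
  NumericVector stats(ncols);
  NumericVector sObs(k);

  double maxdiag = 1.0;
  for (int i = 0; i < k; ++i) if (A(i, i) > maxdiag) maxdiag = A(i, i);
  const double tol = 1e-12 * maxdiag;
  const double cand[3] = {1.0, -1.0, 0.0};

  if (sigma2 <= 0.0) return List::create(_["stats"] = stats, _["s"] = sObs);

  std::vector<double> s(k), r(k);

  for (int col = 0; col < ncols; ++col) {
    const double *c = &C(0, col);

    if (reselect || col == 0) {
      // initialize s = +1 on polymorphic variants, r = A s, U, Q
      double U = 0.0, Q = 0.0;
      for (int i = 0; i < k; ++i) s[i] = poly[i] ? 1.0 : 0.0;
      for (int i = 0; i < k; ++i) {
        double ri = 0.0;
        for (int j = 0; j < k; ++j) ri += A(i, j) * s[j];
        r[i] = ri;
        U += s[i] * c[i];
        Q += s[i] * ri;
      }
      for (int i = 0; i < k; ++i) {
        if (!poly[i]) continue;
        double bestStat = -1.0, bestVal = s[i], bestU = U, bestQ = Q;
        for (int m = 0; m < 3; ++m) {
          const double d = cand[m] - s[i];
          const double U2 = U + d * c[i];
          const double Q2 = Q + 2.0 * d * r[i] + d * d * A(i, i);
          const double st = (Q2 <= tol) ? 0.0 : U2 * U2 / (sigma2 * Q2);
          // exact ties: prefer the coding under which the pooled regressor
          // is positively associated (so s carries the effect direction),
          // then the earlier candidate (+1 > -1 > 0)
          if (st > bestStat || (st == bestStat && U2 > 0.0 && bestU <= 0.0)) {
            bestStat = st; bestVal = cand[m]; bestU = U2; bestQ = Q2;
          }
        }
        const double d = bestVal - s[i];
        if (d != 0.0) {
          for (int j = 0; j < k; ++j) r[j] += d * A(j, i);
          s[i] = bestVal; U = bestU; Q = bestQ;
        }
      }
      stats[col] = (Q <= tol) ? 0.0 : U * U / (sigma2 * Q);
      if (col == 0)
        for (int i = 0; i < k; ++i) sObs[i] = s[i];
    } else {
      // fixed coding from column 0
      double U = 0.0, Q = 0.0;
      for (int i = 0; i < k; ++i) U += sObs[i] * c[i];
      for (int i = 0; i < k; ++i) {
        double ri = 0.0;
        for (int j = 0; j < k; ++j) ri += A(i, j) * sObs[j];
        Q += sObs[i] * ri;
      }
      stats[col] = (Q <= tol) ? 0.0 : U * U / (sigma2 * Q);
    }
  }
  return List::create(_["stats"] = stats, _["s"] = sObs);
}
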