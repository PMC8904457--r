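#include <Rcpp.h>
using namespace Rcpp;

// Torsion-space loop closure and perturbation.
//
// Coordinates are an natoms x 3 matrix in chain storage order. A rotatable
// bond k is (from[k], to[k]); rotating it moves every atom with index
// >= moveStart[k] (1-based, as passed from R). Rotations are rigid
// (Rodrigues), so bond lengths and angles are untouched by construction.

static inline void rotate_block(NumericMatrix &X, int start0,
                                const double o[3], const double u[3],
                                double theta) {
  const double c = std::cos(theta), s = std::sin(theta);
  for (int i = start0; i < X.nrow(); ++i) {
    double v0 = X(i, 0) - o[0], v1 = X(i, 1) - o[1], v2 = X(i, 2) - o[2];
    double cx0 = u[1] * v2 - u[2] * v1;
    double cx1 = u[2] * v0 - u[0] * v2;
    double cx2 = u[0] * v1 - u[1] * v0;
    double du = u[0] * v0 + u[1] * v1 + u[2] * v2;
    X(i, 0) = o[0] + v0 * c + cx0 * s + u[0] * du * (1.0 - c);
    X(i, 1) = o[1] + v1 * c + cx1 * s + u[1] * du * (1.0 - c);
    X(i, 2) = o[2] + v2 * c + cx2 * s + u[2] * du * (1.0 - c);
  }
}

static inline double anchor_rmsd(const NumericMatrix &X,
                                 const IntegerVector &targetIdx,
                                 const NumericMatrix &target) {
  double ss = 0.0;
  for (int t = 0; t < targetIdx.size(); ++t) {
    int i = targetIdx[t] - 1;
    for (int d = 0; d < 3; ++d) {
      double dd = X(i, d) - target(t, d);
      ss += dd * dd;
    }
  }
  return std::sqrt(ss / targetIdx.size());
}

// Apply fixed torsion increments (radians) to each rotatable bond in order.
// [[Rcpp::export(name = ".apply_torsions_cpp")]]
NumericMatrix apply_torsions_cpp(NumericMatrix coords, IntegerVector from,
                                 IntegerVector to, IntegerVector moveStart,
                                 NumericVector delta) {
  NumericMatrix X = clone(coords);
  for (int k = 0; k < from.size(); ++k) {
    if (delta[k] == 0.0) continue;
    int a = from[k] - 1, b = to[k] - 1;
    double o[3] = {X(a, 0), X(a, 1), X(a, 2)};
    double u[3] = {X(b, 0) - o[0], X(b, 1) - o[1], X(b, 2) - o[2]};
    double n = std::sqrt(u[0] * u[0] + u[1] * u[1] + u[2] * u[2]);
    if (n < 1e-12) continue;
    u[0] /= n; u[1] /= n; u[2] /= n;
    rotate_block(X, moveStart[k] - 1, o, u, delta[k]);
  }
  return X;
}

// Cyclic coordinate descent: sweep the rotatable bonds, at each bond apply
// the closed-form angle minimising the squared distance of the (three)
// mobile anchor atoms to their fixed targets (Canutescu & Dunbrack 2003).
// [[Rcpp::export(name = ".ccd_close_cpp")]]
List ccd_close_cpp(NumericMatrix coords, IntegerVector from, IntegerVector to,
                   IntegerVector moveStart, IntegerVector targetIdx,
                   NumericMatrix target, int maxIter, double tol) {
  NumericMatrix X = clone(coords);
  const int nt = targetIdx.size();
  double rmsd = anchor_rmsd(X, targetIdx, target);
  bool converged = rmsd < tol;
  int iter = 0;

  while (!converged && iter < maxIter) {
    ++iter;
    for (int k = 0; k < from.size(); ++k) {
      int ai = from[k] - 1, bi = to[k] - 1;
      double o[3] = {X(ai, 0), X(ai, 1), X(ai, 2)};
      double u[3] = {X(bi, 0) - o[0], X(bi, 1) - o[1], X(bi, 2) - o[2]};
      double n = std::sqrt(u[0] * u[0] + u[1] * u[1] + u[2] * u[2]);
      if (n < 1e-12) continue;
      u[0] /= n; u[1] /= n; u[2] /= n;

      double a = 0.0, b = 0.0;
      for (int t = 0; t < nt; ++t) {
        int mi = targetIdx[t] - 1;
        double m[3] = {X(mi, 0), X(mi, 1), X(mi, 2)};
        double w[3] = {m[0] - o[0], m[1] - o[1], m[2] - o[2]};
        double d = w[0] * u[0] + w[1] * u[1] + w[2] * u[2];
        double ocl[3] = {o[0] + d * u[0], o[1] + d * u[1], o[2] + d * u[2]};
        double r[3] = {m[0] - ocl[0], m[1] - ocl[1], m[2] - ocl[2]};
        double rl = std::sqrt(r[0] * r[0] + r[1] * r[1] + r[2] * r[2]);
        if (rl < 1e-9) continue;
        double rh[3] = {r[0] / rl, r[1] / rl, r[2] / rl};
        double sh[3] = {u[1] * rh[2] - u[2] * rh[1],
                        u[2] * rh[0] - u[0] * rh[2],
                        u[0] * rh[1] - u[1] * rh[0]};
        double f[3] = {target(t, 0) - ocl[0], target(t, 1) - ocl[1],
                       target(t, 2) - ocl[2]};
        a += rl * (f[0] * rh[0] + f[1] * rh[1] + f[2] * rh[2]);
        b += rl * (f[0] * sh[0] + f[1] * sh[1] + f[2] * sh[2]);
      }
      if (a == 0.0 && b == 0.0) continue;
      double theta = std::atan2(b, a);
      rotate_block(X, moveStart[k] - 1, o, u, theta);
    }
    rmsd = anchor_rmsd(X, targetIdx, target);
    if (rmsd < tol) converged = true;
  }

  return List::create(_["coords"] = X, _["converged"] = converged,
                      _["iterations"] = iter, _["anchor_rmsd"] = rmsd);
}
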