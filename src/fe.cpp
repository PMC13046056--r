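// Total-Lagrangian tet4 kernels for the compressible neo-Hookean law
//   W(F) = mu/2 (I1 - 3) - mu ln J + lambda/2 (ln J)^2
// One-point quadrature: F is constant per element.
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// [[Rcpp::export]]
List cpp_tet_precompute(NumericMatrix nodes, IntegerMatrix tets) {
  int m = tets.nrow();
  NumericMatrix gradN(m, 12);   // rows: grad N_a (a = 1..4), components xyz
  NumericVector vol(m);
  for (int e = 0; e < m; ++e) {
    int n1 = tets(e, 0) - 1, n2 = tets(e, 1) - 1,
        n3 = tets(e, 2) - 1, n4 = tets(e, 3) - 1;
    double d[3][3];
    for (int c = 0; c < 3; ++c) {
      d[c][0] = nodes(n2, c) - nodes(n1, c);
      d[c][1] = nodes(n3, c) - nodes(n1, c);
      d[c][2] = nodes(n4, c) - nodes(n1, c);
    }
    double det =
        d[0][0] * (d[1][1] * d[2][2] - d[1][2] * d[2][1]) -
        d[0][1] * (d[1][0] * d[2][2] - d[1][2] * d[2][0]) +
        d[0][2] * (d[1][0] * d[2][1] - d[1][1] * d[2][0]);
    vol[e] = det / 6.0;
    // inv(Dm): rows are grad N_2, N_3, N_4; grad N_1 = -(sum)
    double inv[3][3];
    inv[0][0] =  (d[1][1] * d[2][2] - d[1][2] * d[2][1]) / det;
    inv[0][1] = -(d[0][1] * d[2][2] - d[0][2] * d[2][1]) / det;
    inv[0][2] =  (d[0][1] * d[1][2] - d[0][2] * d[1][1]) / det;
    inv[1][0] = -(d[1][0] * d[2][2] - d[1][2] * d[2][0]) / det;
    inv[1][1] =  (d[0][0] * d[2][2] - d[0][2] * d[2][0]) / det;
    inv[1][2] = -(d[0][0] * d[1][2] - d[0][2] * d[1][0]) / det;
    inv[2][0] =  (d[1][0] * d[2][1] - d[1][1] * d[2][0]) / det;
    inv[2][1] = -(d[0][0] * d[2][1] - d[0][1] * d[2][0]) / det;
    inv[2][2] =  (d[0][0] * d[1][1] - d[0][1] * d[1][0]) / det;
    for (int c = 0; c < 3; ++c) {
      gradN(e, 0 + c) = -(inv[0][c] + inv[1][c] + inv[2][c]);
      gradN(e, 3 + c) = inv[0][c];
      gradN(e, 6 + c) = inv[1][c];
      gradN(e, 9 + c) = inv[2][c];
    }
  }
  return List::create(_["gradN"] = gradN, _["vol"] = vol);
}

// Assemble internal forces, strain energy and (optionally) the consistent
// tangent as COO triplets (1-based). Returns min J across elements; if
// min J <= 0 the force/tangent are not meaningful and the caller must reject
// the trial state.
// [[Rcpp::export]]
List cpp_nh_assemble(IntegerMatrix tets, NumericMatrix gradN, NumericVector vol,
                     NumericVector mu, NumericVector lam, NumericVector u,
                     bool want_K) {
  int m = tets.nrow();
  int ndof = u.size();
  NumericVector f(ndof);
  double minJ = R_PosInf, energy = 0.0;
  IntegerVector ii, jj;
  NumericVector xx;
  int *pi = nullptr, *pj = nullptr;
  double *px = nullptr;
  R_xlen_t nt = 0;
  if (want_K) {
    ii = IntegerVector((R_xlen_t)m * 144);
    jj = IntegerVector((R_xlen_t)m * 144);
    xx = NumericVector((R_xlen_t)m * 144);
    pi = INTEGER(ii); pj = INTEGER(jj); px = REAL(xx);
  }
  for (int e = 0; e < m; ++e) {
    int nd[4] = {tets(e, 0) - 1, tets(e, 1) - 1, tets(e, 2) - 1, tets(e, 3) - 1};
    double G[4][3];
    for (int a = 0; a < 4; ++a)
      for (int c = 0; c < 3; ++c) G[a][c] = gradN(e, 3 * a + c);
    // F = I + sum_a u_a (x) grad N_a
    double F[3][3] = {{1, 0, 0}, {0, 1, 0}, {0, 0, 1}};
    for (int a = 0; a < 4; ++a) {
      double ux = u[3 * nd[a]], uy = u[3 * nd[a] + 1], uz = u[3 * nd[a] + 2];
      for (int Jc = 0; Jc < 3; ++Jc) {
        F[0][Jc] += ux * G[a][Jc];
        F[1][Jc] += uy * G[a][Jc];
        F[2][Jc] += uz * G[a][Jc];
      }
    }
    double J =
        F[0][0] * (F[1][1] * F[2][2] - F[1][2] * F[2][1]) -
        F[0][1] * (F[1][0] * F[2][2] - F[1][2] * F[2][0]) +
        F[0][2] * (F[1][0] * F[2][1] - F[1][1] * F[2][0]);
    if (J < minJ) minJ = J;
    if (J <= 0.0) continue;  // caller rejects via minJ
    double Fi[3][3];  // F^{-1}
    Fi[0][0] =  (F[1][1] * F[2][2] - F[1][2] * F[2][1]) / J;
    Fi[0][1] = -(F[0][1] * F[2][2] - F[0][2] * F[2][1]) / J;
    Fi[0][2] =  (F[0][1] * F[1][2] - F[0][2] * F[1][1]) / J;
    Fi[1][0] = -(F[1][0] * F[2][2] - F[1][2] * F[2][0]) / J;
    Fi[1][1] =  (F[0][0] * F[2][2] - F[0][2] * F[2][0]) / J;
    Fi[1][2] = -(F[0][0] * F[1][2] - F[0][2] * F[1][0]) / J;
    Fi[2][0] =  (F[1][0] * F[2][1] - F[1][1] * F[2][0]) / J;
    Fi[2][1] = -(F[0][0] * F[2][1] - F[0][1] * F[2][0]) / J;
    Fi[2][2] =  (F[0][0] * F[1][1] - F[0][1] * F[1][0]) / J;
    double lnJ = std::log(J);
    double mue = mu[e], lame = lam[e], V = vol[e];
    double I1 = 0.0;
    for (int i = 0; i < 3; ++i)
      for (int Jc = 0; Jc < 3; ++Jc) I1 += F[i][Jc] * F[i][Jc];
    energy += V * (0.5 * mue * (I1 - 3.0) - mue * lnJ + 0.5 * lame * lnJ * lnJ);
    // P = mu (F - F^{-T}) + lambda lnJ F^{-T};  F^{-T}[i][J] = Fi[J][i]
    double P[3][3];
    for (int i = 0; i < 3; ++i)
      for (int Jc = 0; Jc < 3; ++Jc)
        P[i][Jc] = mue * (F[i][Jc] - Fi[Jc][i]) + lame * lnJ * Fi[Jc][i];
    for (int a = 0; a < 4; ++a)
      for (int i = 0; i < 3; ++i) {
        double s = 0.0;
        for (int Jc = 0; Jc < 3; ++Jc) s += P[i][Jc] * G[a][Jc];
        f[3 * nd[a] + i] += V * s;
      }
    if (want_K) {
      // s_a = F^{-T} grad N_a ;  dP_iJ/dF_kL = mu d_ik d_JL
      //   + (mu - lambda lnJ) Fi[J][k] Fi[L][i] + lambda Fi[J][i] Fi[L][k]
      double S[4][3];
      for (int a = 0; a < 4; ++a)
        for (int i = 0; i < 3; ++i) {
          double s = 0.0;
          for (int Jc = 0; Jc < 3; ++Jc) s += Fi[Jc][i] * G[a][Jc];
          S[a][i] = s;
        }
      double c2 = mue - lame * lnJ, c3 = lame;
      for (int a = 0; a < 4; ++a)
        for (int b = 0; b < 4; ++b) {
          double gg = G[a][0] * G[b][0] + G[a][1] * G[b][1] + G[a][2] * G[b][2];
          for (int i = 0; i < 3; ++i)
            for (int k = 0; k < 3; ++k) {
              double kv = V * ((i == k ? mue * gg : 0.0) +
                               c2 * S[a][k] * S[b][i] + c3 * S[a][i] * S[b][k]);
              pi[nt] = 3 * nd[a] + i + 1;
              pj[nt] = 3 * nd[b] + k + 1;
              px[nt] = kv;
              ++nt;
            }
        }
    }
  }
  List out = List::create(_["f"] = f, _["minJ"] = minJ, _["energy"] = energy);
  if (want_K) {
    out["i"] = ii; out["j"] = jj; out["x"] = xx;
  }
  return out;
}

// Volume-weighted mean voxel value per element by fixed-order quadrature with
// nearest-voxel lookup; out-of-mask samples take the nearest in-mask voxel
// (expanding Chebyshev shells), counted in n_outside.
// [[Rcpp::export]]
List cpp_element_mean_voxel(NumericMatrix nodes, IntegerMatrix tets,
                            NumericVector vox, LogicalVector mask,
                            IntegerVector dims, NumericVector origin,
                            double spacing, NumericMatrix qp) {
  int m = tets.nrow(), nq = qp.nrow();
  int nx = dims[0], ny = dims[1], nz = dims[2];
  NumericVector vbar(m);
  int n_outside = 0;
  bool any_unresolved = false;
  for (int e = 0; e < m; ++e) {
    double acc = 0.0;
    for (int q = 0; q < nq; ++q) {
      double p[3] = {0, 0, 0};
      for (int a = 0; a < 4; ++a) {
        int nd = tets(e, a) - 1;
        double b = qp(q, a);
        p[0] += b * nodes(nd, 0);
        p[1] += b * nodes(nd, 1);
        p[2] += b * nodes(nd, 2);
      }
      int i = (int)std::floor((p[0] - origin[0]) / spacing);
      int j = (int)std::floor((p[1] - origin[1]) / spacing);
      int k = (int)std::floor((p[2] - origin[2]) / spacing);
      if (i < 0) i = 0; if (i >= nx) i = nx - 1;
      if (j < 0) j = 0; if (j >= ny) j = ny - 1;
      if (k < 0) k = 0; if (k >= nz) k = nz - 1;
      R_xlen_t idx = (R_xlen_t)i + nx * ((R_xlen_t)j + (R_xlen_t)ny * k);
      if (!mask[idx]) {
        ++n_outside;
        bool found = false;
        int rmax = std::max(nx, std::max(ny, nz));
        for (int r = 1; r <= rmax && !found; ++r) {
          double best = R_PosInf; R_xlen_t besti = -1;
          for (int dk = -r; dk <= r; ++dk) {
            int kk = k + dk; if (kk < 0 || kk >= nz) continue;
            for (int dj = -r; dj <= r; ++dj) {
              int jj = j + dj; if (jj < 0 || jj >= ny) continue;
              for (int di = -r; di <= r; ++di) {
                if (std::max(std::abs(di), std::max(std::abs(dj), std::abs(dk))) != r)
                  continue;  // shell only
                int ii = i + di; if (ii < 0 || ii >= nx) continue;
                R_xlen_t id2 = (R_xlen_t)ii + nx * ((R_xlen_t)jj + (R_xlen_t)ny * kk);
                if (mask[id2]) {
                  double d2 = (double)di * di + (double)dj * dj + (double)dk * dk;
                  if (d2 < best) { best = d2; besti = id2; }
                }
              }
            }
          }
          if (besti >= 0) { idx = besti; found = true; }
        }
        if (!found) any_unresolved = true;
      }
      acc += vox[idx];
    }
    vbar[e] = acc / nq;
  }
  return List::create(_["vbar"] = vbar, _["n_outside"] = n_outside,
                      _["unresolved"] = any_unresolved);
}

// Map COO triplets onto positions in a fixed CSC pattern (binary search per
// column slice). ii/jj are 1-based reduced indices; p/ri are the dgCMatrix
// slots (0-based). Returns 1-based positions into x.
// [[Rcpp::export]]
IntegerVector cpp_csc_map(IntegerVector ii, IntegerVector jj,
                          IntegerVector p, IntegerVector ri) {
  R_xlen_t n = ii.size();
  IntegerVector out(n);
  for (R_xlen_t t = 0; t < n; ++t) {
    int row = ii[t] - 1, col = jj[t] - 1;
    int lo = p[col], hi = p[col + 1] - 1, pos = -1;
    while (lo <= hi) {
      int mid = (lo + hi) / 2;
      if (ri[mid] == row) { pos = mid; break; }
      if (ri[mid] < row) lo = mid + 1; else hi = mid - 1;
    }
    if (pos < 0) stop("triplet outside the cached sparsity pattern");
    out[t] = pos + 1;
  }
  return out;
}

// Accumulate triplet values into a CSC value vector by precomputed positions.
// [[Rcpp::export]]
NumericVector cpp_csc_accumulate(IntegerVector map, NumericVector x,
                                 int nnz) {
  NumericVector out(nnz);
  R_xlen_t n = map.size();
  for (R_xlen_t t = 0; t < n; ++t) out[map[t] - 1] += x[t];
  return out;
}
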