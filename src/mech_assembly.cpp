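// Total-Lagrangian assembly for quadratic (10-node) tetrahedra with the
// exponential orthotropic strain-energy law, volumetric penalty, active
// fibre stress and a follower (deformation-dependent) pressure load on
// quadratic triangular faces.  Element node ordering: 4 corners followed
// by midside nodes of edges (1,2),(1,3),(1,4),(2,3),(2,4),(3,4); face
// ordering: 3 corners then midside nodes of edges (1,2),(2,3),(3,1).

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace arma;

// 4-point degree-2 quadrature on the reference tetrahedron
static const double QA = 0.5854101966249685;
static const double QB = 0.1381966011250105;
static const double qpts[4][3] = {
  {QB, QB, QB}, {QA, QB, QB}, {QB, QA, QB}, {QB, QB, QA}
};

// shape functions / derivatives of the 10-node tet at (x1,x2,x3)
static void tet10_shape(const double xi[3], vec &N, mat &dN) {
  double l2 = xi[0], l3 = xi[1], l4 = xi[2];
  double l1 = 1.0 - l2 - l3 - l4;
  N.set_size(10);
  dN.set_size(10, 3);
  double l[4] = {l1, l2, l3, l4};
  // dl/dxi: l1 -> (-1,-1,-1), l2 -> e1, l3 -> e2, l4 -> e3
  double dl[4][3] = {{-1, -1, -1}, {1, 0, 0}, {0, 1, 0}, {0, 0, 1}};
  for (int a = 0; a < 4; ++a) {
    N(a) = l[a] * (2.0 * l[a] - 1.0);
    for (int d = 0; d < 3; ++d) dN(a, d) = (4.0 * l[a] - 1.0) * dl[a][d];
  }
  static const int ed[6][2] = {{0, 1}, {0, 2}, {0, 3}, {1, 2}, {1, 3}, {2, 3}};
  for (int e = 0; e < 6; ++e) {
    int i = ed[e][0], j = ed[e][1];
    N(4 + e) = 4.0 * l[i] * l[j];
    for (int d = 0; d < 3; ++d)
      dN(4 + e, d) = 4.0 * (dl[i][d] * l[j] + l[i] * dl[j][d]);
  }
}

// quadratic triangle shape functions at area coords (l1,l2,l3)
static void tri6_shape(double lxi, double leta, vec &N, mat &dN) {
  double l2 = lxi, l3 = leta, l1 = 1.0 - lxi - leta;
  N.set_size(6);
  dN.set_size(6, 2); // derivatives wrt (xi, eta)
  double l[3] = {l1, l2, l3};
  double dl[3][2] = {{-1, -1}, {1, 0}, {0, 1}};
  for (int a = 0; a < 3; ++a) {
    N(a) = l[a] * (2.0 * l[a] - 1.0);
    for (int d = 0; d < 2; ++d) dN(a, d) = (4.0 * l[a] - 1.0) * dl[a][d];
  }
  static const int ed[3][2] = {{0, 1}, {1, 2}, {2, 0}};
  for (int e = 0; e < 3; ++e) {
    int i = ed[e][0], j = ed[e][1];
    N(3 + e) = 4.0 * l[i] * l[j];
    for (int d = 0; d < 2; ++d)
      dN(3 + e, d) = 4.0 * (dl[i][d] * l[j] + l[i] * dl[j][d]);
  }
}

// material stress and tangent (dS/dE) in the global frame
static void material_response(const mat &E, const mat &Rf, const mat &B,
                              double C0, double kappa, bool wantK,
                              mat &S, double c4[3][3][3][3], double &J) {
  mat Ehat = Rf.t() * E * Rf;
  double Q = accu(B % Ehat % Ehat);
  double eQ = std::exp(Q);
  mat BE = B % Ehat;
  mat Shat = C0 * eQ * BE;
  mat C = 2.0 * E + eye(3, 3);
  double detC = det(C);
  J = (detC > 0.0) ? std::sqrt(detC) : -1.0;
  if (J <= 0.0) return;
  mat Ci = inv_sympd(symmatu(C));
  double lnJ = std::log(J);
  S = Rf * Shat * Rf.t() + kappa * J * lnJ * Ci;

  if (!wantK) return;
  // deviatoric tangent in fibre frame:
  //   C0 e^Q [ 2 (BoE)_ij (BoE)_kl + B_ij (d_ik d_jl + d_il d_jk)/2 ]
  double chat[3][3][3][3];
  for (int i = 0; i < 3; ++i)
    for (int j = 0; j < 3; ++j)
      for (int k = 0; k < 3; ++k)
        for (int l = 0; l < 3; ++l) {
          double v = 2.0 * BE(i, j) * BE(k, l);
          double del = 0.0;
          if (i == k && j == l) del += 0.5;
          if (i == l && j == k) del += 0.5;
          v += B(i, j) * del;
          chat[i][j][k][l] = C0 * eQ * v;
        }
  // rotate to the global frame by four successive single-index
  // contractions, then add the volumetric tangent
  double t1[3][3][3][3], t2[3][3][3][3];
  for (int i = 0; i < 3; ++i)
    for (int j = 0; j < 3; ++j)
      for (int k = 0; k < 3; ++k)
        for (int L = 0; L < 3; ++L) {
          double s = 0.0;
          for (int l = 0; l < 3; ++l) s += chat[i][j][k][l] * Rf(L, l);
          t1[i][j][k][L] = s;
        }
  for (int i = 0; i < 3; ++i)
    for (int j = 0; j < 3; ++j)
      for (int K = 0; K < 3; ++K)
        for (int L = 0; L < 3; ++L) {
          double s = 0.0;
          for (int k = 0; k < 3; ++k) s += t1[i][j][k][L] * Rf(K, k);
          t2[i][j][K][L] = s;
        }
  for (int i = 0; i < 3; ++i)
    for (int Jj = 0; Jj < 3; ++Jj)
      for (int K = 0; K < 3; ++K)
        for (int L = 0; L < 3; ++L) {
          double s = 0.0;
          for (int j = 0; j < 3; ++j) s += t2[i][j][K][L] * Rf(Jj, j);
          t1[i][Jj][K][L] = s;
        }
  double k1 = kappa * J * (lnJ + 1.0);
  double k2 = kappa * J * lnJ;
  for (int I = 0; I < 3; ++I)
    for (int Jj = 0; Jj < 3; ++Jj)
      for (int K = 0; K < 3; ++K)
        for (int L = 0; L < 3; ++L) {
          double s = 0.0;
          for (int i = 0; i < 3; ++i) s += t1[i][Jj][K][L] * Rf(I, i);
          s += k1 * Ci(I, Jj) * Ci(K, L) -
               k2 * (Ci(I, K) * Ci(Jj, L) + Ci(I, L) * Ci(Jj, K));
          c4[I][Jj][K][L] = s;
        }
}

// [[Rcpp::export]]
Rcpp::List mech_system(const arma::mat &nodes, const arma::imat &elems,
                       const arma::mat &disp, const arma::mat &fsn,
                       double C0, const arma::vec &bpar, double kappa,
                       const arma::vec &Ta, const arma::imat &pfaces,
                       double pval, bool wantK) {
  const int nn = nodes.n_rows, ne = elems.n_rows, npf = pfaces.n_rows;
  vec R(3 * nn, fill::zeros);
  const int ntrip = wantK ? ne * 900 + npf * 324 : 0;
  ivec Ki(ntrip), Kj(ntrip);
  vec Kx(ntrip);
  int tp = 0;
  double minJ = datum::inf;
  bool ok = true;

  mat B = {{bpar(0), bpar(3), bpar(4)},
           {bpar(3), bpar(1), bpar(5)},
           {bpar(4), bpar(5), bpar(2)}};

  vec N;
  mat dNxi;
  mat X(10, 3), x(10, 3);
  double c4[3][3][3][3];

  for (int e = 0; e < ne && ok; ++e) {
    for (int a = 0; a < 10; ++a) {
      int id = elems(e, a);
      for (int d = 0; d < 3; ++d) {
        X(a, d) = nodes(id, d);
        x(a, d) = nodes(id, d) + disp(id, d);
      }
    }
    mat Rf(3, 3);
    for (int d = 0; d < 3; ++d) {
      Rf(d, 0) = fsn(e, d);
      Rf(d, 1) = fsn(e, 3 + d);
      Rf(d, 2) = fsn(e, 6 + d);
    }
    mat Ke;
    if (wantK) Ke.zeros(30, 30);
    vec Re(30, fill::zeros);

    for (int q = 0; q < 4; ++q) {
      tet10_shape(qpts[q], N, dNxi);
      mat Jac = X.t() * dNxi;          // 3x3
      double dJ = det(Jac);
      mat dNdX = dNxi * inv(Jac);      // 10x3
      double w = std::abs(dJ) / 24.0;  // |detJ| * (1/6) * (1/4)
      mat F = x.t() * dNdX;            // 3x3
      double Jdef = det(F);
      if (Jdef <= 0.0) { ok = false; minJ = std::min(minJ, Jdef); break; }
      mat E = 0.5 * (F.t() * F - eye(3, 3));
      mat S;
      double Jm;
      material_response(E, Rf, B, C0, kappa, wantK, S, c4, Jm);
      if (Jm <= 0.0) { ok = false; break; }
      minJ = std::min(minJ, Jdef);
      // active fibre stress (reference fibre direction)
      if (Ta(e) != 0.0) {
        vec f0 = Rf.col(0);
        S += Ta(e) * (f0 * f0.t());
      }
      mat P = F * S; // first Piola-Kirchhoff
      for (int a = 0; a < 10; ++a)
        for (int i = 0; i < 3; ++i)
          Re(3 * a + i) += w * dot(P.row(i).t(), dNdX.row(a).t());

      if (wantK) {
        mat Sgg = dNdX * S * dNdX.t(); // 10x10 geometric kernel
        // material part: A_{ai,KL} = F_iK g_aL (minor symmetry handled by c4)
        // H[a][i](K? ) precompute T_{iL,b j}? direct quadruple loop over nodes
        // precompute D_{i l}[a] = sum_K F_iK c4[K][l][.][.] ... do direct:
        for (int a = 0; a < 10; ++a) {
          for (int i = 0; i < 3; ++i) {
            // W_{MN} = sum_{K,L} F_iK g_aL c4[K][L][M][N]
            mat W(3, 3, fill::zeros);
            for (int K = 0; K < 3; ++K) {
              double FiK = F(i, K);
              if (FiK == 0.0) continue;
              for (int L = 0; L < 3; ++L) {
                double fg = FiK * dNdX(a, L);
                if (fg == 0.0) continue;
                for (int M = 0; M < 3; ++M)
                  for (int Nn = 0; Nn < 3; ++Nn)
                    W(M, Nn) += fg * c4[K][L][M][Nn];
              }
            }
            for (int b = 0; b < 10; ++b)
              for (int j = 0; j < 3; ++j) {
                // v = sum_{M,N} W(M,N) F_jM g_bN
                double v = 0.0;
                for (int M = 0; M < 3; ++M) {
                  double FjM = F(j, M);
                  if (FjM == 0.0) continue;
                  double s = 0.0;
                  for (int Nn = 0; Nn < 3; ++Nn) s += W(M, Nn) * dNdX(b, Nn);
                  v += FjM * s;
                }
                Ke(3 * a + i, 3 * b + j) += w * v;
              }
            }
        }
        for (int a = 0; a < 10; ++a)
          for (int b = 0; b < 10; ++b) {
            double g = w * Sgg(a, b);
            for (int i = 0; i < 3; ++i) Ke(3 * a + i, 3 * b + i) += g;
          }
      }
    }
    if (!ok) break;
    for (int a = 0; a < 10; ++a) {
      int ia = elems(e, a);
      for (int i = 0; i < 3; ++i) R(3 * ia + i) += Re(3 * a + i);
    }
    if (wantK) {
      for (int a = 0; a < 10; ++a)
        for (int i = 0; i < 3; ++i) {
          int gi = 3 * elems(e, a) + i;
          for (int b = 0; b < 10; ++b)
            for (int j = 0; j < 3; ++j) {
              Ki(tp) = gi + 1;
              Kj(tp) = 3 * elems(e, b) + j + 1;
              Kx(tp) = Ke(3 * a + i, 3 * b + j);
              ++tp;
            }
        }
    }
  }

  // follower pressure on quadratic triangular faces (outward-from-tissue
  // orientation); traction t = -p n on the deformed surface
  if (ok && pval != 0.0 && npf > 0) {
    static const double tq[3][2] = {{0.5, 0.0}, {0.5, 0.5}, {0.0, 0.5}};
    vec Nf;
    mat dNf;
    mat xf(6, 3);
    for (int fidx = 0; fidx < npf; ++fidx) {
      for (int a = 0; a < 6; ++a) {
        int id = pfaces(fidx, a);
        for (int d = 0; d < 3; ++d) xf(a, d) = nodes(id, d) + disp(id, d);
      }
      mat Kf;
      if (wantK) Kf.zeros(18, 18);
      vec Rface(18, fill::zeros);
      for (int q = 0; q < 3; ++q) {
        tri6_shape(tq[q][0], tq[q][1], Nf, dNf);
        vec xxi = xf.t() * dNf.col(0);
        vec xeta = xf.t() * dNf.col(1);
        vec cn = cross(xxi, xeta);
        double wq = 1.0 / 6.0;
        // residual R = Fint - Fext, Fext_a = -p int N_a cn
        for (int a = 0; a < 6; ++a)
          for (int i = 0; i < 3; ++i)
            Rface(3 * a + i) += pval * wq * Nf(a) * cn(i);
        if (wantK) {
          mat skx = {{0, -xxi(2), xxi(1)}, {xxi(2), 0, -xxi(0)},
                     {-xxi(1), xxi(0), 0}};
          mat ske = {{0, -xeta(2), xeta(1)}, {xeta(2), 0, -xeta(0)},
                     {-xeta(1), xeta(0), 0}};
          for (int a = 0; a < 6; ++a)
            for (int b = 0; b < 6; ++b) {
              mat blk = pval * wq * Nf(a) *
                        (-ske * dNf(b, 0) + skx * dNf(b, 1));
              for (int i = 0; i < 3; ++i)
                for (int j = 0; j < 3; ++j)
                  Kf(3 * a + i, 3 * b + j) += blk(i, j);
            }
        }
      }
      for (int a = 0; a < 6; ++a) {
        int ia = pfaces(fidx, a);
        for (int i = 0; i < 3; ++i) R(3 * ia + i) += Rface(3 * a + i);
      }
      if (wantK) {
        for (int a = 0; a < 6; ++a)
          for (int i = 0; i < 3; ++i) {
            int gi = 3 * pfaces(fidx, a) + i;
            for (int b = 0; b < 6; ++b)
              for (int j = 0; j < 3; ++j) {
                Ki(tp) = gi + 1;
                Kj(tp) = 3 * pfaces(fidx, b) + j + 1;
                Kx(tp) = Kf(3 * a + i, 3 * b + j);
                ++tp;
              }
          }
      }
    }
  }

  Rcpp::List out = Rcpp::List::create(
      Rcpp::Named("res") = R, Rcpp::Named("ok") = ok,
      Rcpp::Named("minJ") = minJ);
  if (wantK && ok) {
    out["Ki"] = Rcpp::IntegerVector(Ki.begin(), Ki.begin() + tp);
    out["Kj"] = Rcpp::IntegerVector(Kj.begin(), Kj.begin() + tp);
    out["Kx"] = Rcpp::NumericVector(Kx.begin(), Kx.begin() + tp);
  }
  return out;
}

// deformation gradient at each element centroid
// [[Rcpp::export]]
arma::mat mech_deformation(const arma::mat &nodes, const arma::imat &elems,
                           const arma::mat &disp) {
  const int ne = elems.n_rows;
  mat out(ne, 9);
  vec N;
  mat dNxi;
  double cq[3] = {0.25, 0.25, 0.25};
  mat X(10, 3), x(10, 3);
  for (int e = 0; e < ne; ++e) {
    for (int a = 0; a < 10; ++a) {
      int id = elems(e, a);
      for (int d = 0; d < 3; ++d) {
        X(a, d) = nodes(id, d);
        x(a, d) = nodes(id, d) + disp(id, d);
      }
    }
    tet10_shape(cq, N, dNxi);
    mat Jac = X.t() * dNxi;
    mat dNdX = dNxi * inv(Jac);
    mat F = x.t() * dNdX;
    for (int i = 0; i < 3; ++i)
      for (int j = 0; j < 3; ++j) out(e, 3 * i + j) = F(i, j);
  }
  return out;
}
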