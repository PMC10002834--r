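// Element-level assembly kernels for the stabilized equal-order (P1-P1)
// finite-element discretization of incompressible Newtonian flow and for
// SUPG/discontinuity-capturing advection-diffusion scalar transport.
// Linear simplices in 2D (triangles) and 3D (tetrahedra); CGS units.
//
// Dof ordering: velocity (node a, component i) -> a*dim + i, pressure ->
// nnode*dim + a.  Triplets are returned 1-based for Matrix::sparseMatrix.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

namespace {

struct ElemGeom {
  double vol;                 // measure (area / volume)
  double gradN[4][3];         // shape function gradients (constant, P1)
  double G[3][3];             // covariant metric sum_a>0 gradN_a (x) gradN_a
};

// Compute P1 geometry for one simplex. Returns false if degenerate.
bool elem_geom(const double* nd, int nnode, int dim,
               const int* conn, int nen, ElemGeom& eg) {
  double J[3][3];
  const int a0 = conn[0];
  for (int i = 0; i < dim; ++i)
    for (int k = 0; k < dim; ++k)
      J[i][k] = nd[conn[k + 1] + i * (size_t)nnode] - nd[a0 + i * (size_t)nnode];
  double det;
  double Jinv[3][3];
  if (dim == 2) {
    det = J[0][0] * J[1][1] - J[0][1] * J[1][0];
    if (det == 0.0) return false;
    Jinv[0][0] =  J[1][1] / det; Jinv[0][1] = -J[0][1] / det;
    Jinv[1][0] = -J[1][0] / det; Jinv[1][1] =  J[0][0] / det;
    eg.vol = 0.5 * det;
  } else {
    det = J[0][0] * (J[1][1] * J[2][2] - J[1][2] * J[2][1])
        - J[0][1] * (J[1][0] * J[2][2] - J[1][2] * J[2][0])
        + J[0][2] * (J[1][0] * J[2][1] - J[1][1] * J[2][0]);
    if (det == 0.0) return false;
    const double id = 1.0 / det;
    Jinv[0][0] = (J[1][1] * J[2][2] - J[1][2] * J[2][1]) * id;
    Jinv[0][1] = (J[0][2] * J[2][1] - J[0][1] * J[2][2]) * id;
    Jinv[0][2] = (J[0][1] * J[1][2] - J[0][2] * J[1][1]) * id;
    Jinv[1][0] = (J[1][2] * J[2][0] - J[1][0] * J[2][2]) * id;
    Jinv[1][1] = (J[0][0] * J[2][2] - J[0][2] * J[2][0]) * id;
    Jinv[1][2] = (J[0][2] * J[1][0] - J[0][0] * J[1][2]) * id;
    Jinv[2][0] = (J[1][0] * J[2][1] - J[1][1] * J[2][0]) * id;
    Jinv[2][1] = (J[0][1] * J[2][0] - J[0][0] * J[2][1]) * id;
    Jinv[2][2] = (J[0][0] * J[1][1] - J[0][1] * J[1][0]) * id;
    eg.vol = det / 6.0;
  }
  // gradN_a: rows of Jinv are grad of reference coords; N_{a>=1} = xi_{a-1}
  for (int i = 0; i < dim; ++i) {
    double s = 0.0;
    for (int a = 1; a < nen; ++a) {
      eg.gradN[a][i] = Jinv[a - 1][i];
      s += Jinv[a - 1][i];
    }
    eg.gradN[0][i] = -s;
  }
  for (int i = 0; i < dim; ++i)
    for (int j = 0; j < dim; ++j) {
      double s = 0.0;
      for (int k = 0; k < dim; ++k) s += Jinv[k][i] * Jinv[k][j];
      eg.G[i][j] = s;
    }
  return true;
}

// quadrature rules exact to degree 2
void quad_rule(int dim, int& nq, double qp[4][4], double qw[4]) {
  if (dim == 2) {
    nq = 3;
    const double pts[3][3] = {{2.0/3, 1.0/6, 1.0/6},
                              {1.0/6, 2.0/3, 1.0/6},
                              {1.0/6, 1.0/6, 2.0/3}};
    for (int q = 0; q < nq; ++q) {
      qw[q] = 1.0 / 3.0;
      for (int a = 0; a < 3; ++a) qp[q][a] = pts[q][a];
    }
  } else {
    nq = 4;
    const double al = 0.5854101966249685, be = 0.1381966011250105;
    for (int q = 0; q < nq; ++q) {
      qw[q] = 0.25;
      for (int a = 0; a < 4; ++a) qp[q][a] = (a == q) ? al : be;
    }
  }
}

} // namespace

// [[Rcpp::export]]
List ns_assemble_cpp(NumericMatrix nodes, IntegerMatrix cells,
                     NumericMatrix vel, NumericVector pres,
                     NumericMatrix vdot,
                     double rho, double mu,
                     double inv_dt2,   // 4/dt^2 in tau_m (0 in steady mode)
                     double c_dot,     // d(vdot)/d(unknown) chain factor
                     double c_vel,     // d(v)/d(unknown) chain factor
                     bool include_mass,
                     double ci = 36.0) {
  const int dim = nodes.ncol();
  const int nnode = nodes.nrow();
  const int nen = dim + 1;
  const int nel = cells.nrow();
  const double nu = mu / rho;
  const int ndof_v = nnode * dim;
  const int ndof = ndof_v + nnode;
  const int block = nen * (dim + 1);          // dofs per element
  const size_t ntrip = (size_t)nel * block * block;

  NumericVector resid(ndof);
  IntegerVector ti(ntrip), tj(ntrip);
  NumericVector tx(ntrip);

  const double* nd = REAL(nodes);
  int nq; double qp[4][4], qw[4];
  quad_rule(dim, nq, qp, qw);

  int conn[4];
  double ve[4][3], vde[4][3], pe[4];
  double Rl[16];     // local residual (nen * (dim+1))
  double Jl[16][16]; // local jacobian
  size_t tcnt = 0;

  for (int e = 0; e < nel; ++e) {
    for (int a = 0; a < nen; ++a) conn[a] = cells(e, a) - 1;
    ElemGeom eg;
    if (!elem_geom(nd, nnode, dim, conn, nen, eg))
      stop("assembly stage: degenerate element %d", e + 1);
    if (eg.vol <= 0.0)
      stop("assembly stage: non-positively-oriented element %d", e + 1);
    for (int a = 0; a < nen; ++a) {
      pe[a] = pres[conn[a]];
      for (int i = 0; i < dim; ++i) {
        ve[a][i] = vel(conn[a], i);
        vde[a][i] = vdot(conn[a], i);
      }
    }
    // constant (P1) gradients of v and p
    double gradv[3][3] = {{0}}, gradp[3] = {0};
    double divv = 0.0;
    for (int i = 0; i < dim; ++i) {
      for (int j = 0; j < dim; ++j) {
        double s = 0.0;
        for (int a = 0; a < nen; ++a) s += ve[a][i] * eg.gradN[a][j];
        gradv[i][j] = s;
      }
      divv += gradv[i][i];
      double sp = 0.0;
      for (int a = 0; a < nen; ++a) sp += pe[a] * eg.gradN[a][i];
      gradp[i] = sp;
    }
    // element mean velocity for tau
    double vbar[3] = {0, 0, 0};
    for (int a = 0; a < nen; ++a)
      for (int i = 0; i < dim; ++i) vbar[i] += ve[a][i] / nen;
    double vGv = 0.0, GG = 0.0, trG = 0.0;
    for (int i = 0; i < dim; ++i) {
      trG += eg.G[i][i];
      for (int j = 0; j < dim; ++j) {
        vGv += vbar[i] * eg.G[i][j] * vbar[j];
        GG += eg.G[i][j] * eg.G[i][j];
      }
    }
    const double tau = 1.0 / std::sqrt(inv_dt2 + vGv + ci * nu * nu * GG);
    const double tauc = 1.0 / (tau * trG);   // kinematic grad-div coefficient

    for (int k = 0; k < block; ++k) {
      Rl[k] = 0.0;
      for (int l = 0; l < block; ++l) Jl[k][l] = 0.0;
    }
    // index helpers within the local block: velocity (a,i) -> a*dim+i,
    // pressure a -> nen*dim + a
    const int poff = nen * dim;

    // quadrature loop (Galerkin advective/mass terms and stabilization)
    for (int q = 0; q < nq; ++q) {
      const double w = qw[q] * eg.vol;
      double vq[3] = {0, 0, 0}, vdq[3] = {0, 0, 0};
      for (int a = 0; a < nen; ++a)
        for (int i = 0; i < dim; ++i) {
          vq[i] += qp[q][a] * ve[a][i];
          vdq[i] += qp[q][a] * vde[a][i];
        }
      double conv[3], rm[3];
      for (int i = 0; i < dim; ++i) {
        double s = 0.0;
        for (int j = 0; j < dim; ++j) s += vq[j] * gradv[i][j];
        conv[i] = rho * s;
        rm[i] = conv[i] + gradp[i];
        if (include_mass) rm[i] += rho * vdq[i];
      }
      double vdotgN[4];  // v_q . gradN_a
      for (int a = 0; a < nen; ++a) {
        double s = 0.0;
        for (int i = 0; i < dim; ++i) s += vq[i] * eg.gradN[a][i];
        vdotgN[a] = s;
      }
      for (int a = 0; a < nen; ++a) {
        const double Na = qp[q][a];
        // momentum residual
        for (int i = 0; i < dim; ++i) {
          double r = Na * conv[i];
          if (include_mass) r += Na * rho * vdq[i];
          r += tau * vdotgN[a] * rm[i];            // SUPG ((tau/rho)*rho*v.gradNa)
          Rl[a * dim + i] += w * r;
        }
        // continuity residual (Galerkin + PSPG)
        {
          double r = Na * divv;
          double s = 0.0;
          for (int i = 0; i < dim; ++i) s += eg.gradN[a][i] * rm[i];
          r += tau / rho * s;
          Rl[poff + a] += w * r;
        }
        for (int b = 0; b < nen; ++b) {
          const double Nb = qp[q][b];
          // d conv_i / d v_b[j] (without c_vel): rho*(Nb*gradv[i][j] + dij*(vq.gradNb))
          // d rm_i / d v_b[j]: same + c_dot/c_vel handling below
          for (int i = 0; i < dim; ++i) {
            for (int j = 0; j < dim; ++j) {
              double dconv = rho * Nb * gradv[i][j];
              if (i == j) dconv += rho * vdotgN[b];
              double drm = c_vel * dconv;
              if (include_mass && i == j) drm += c_dot * rho * Nb;
              double Jv = c_vel * Na * dconv;
              if (include_mass && i == j) Jv += c_dot * Na * rho * Nb;
              Jv += tau * vdotgN[a] * drm;         // SUPG
              // derivative of the SUPG weight advection v.grad(w)
              Jv += c_vel * tau * Nb * eg.gradN[a][j] * rm[i];
              Jl[a * dim + i][b * dim + j] += w * Jv;
              // continuity wrt v_b[j]: Galerkin + PSPG
            }
          }
          // continuity row a, velocity column (b,j)
          for (int j = 0; j < dim; ++j) {
            double Jc = c_vel * Na * eg.gradN[b][j];
            // PSPG: tau/rho * sum_i gradNa[i] * drm_i/dv_b[j]
            double s = 0.0;
            for (int i = 0; i < dim; ++i) {
              double dconv = rho * Nb * gradv[i][j];
              if (i == j) dconv += rho * vdotgN[b];
              double drm = c_vel * dconv;
              if (include_mass && i == j) drm += c_dot * rho * Nb;
              s += eg.gradN[a][i] * drm;
            }
            Jc += tau / rho * s;
            Jl[poff + a][b * dim + j] += w * Jc;
          }
          // momentum row (a,i), pressure column b: SUPG part
          for (int i = 0; i < dim; ++i)
            Jl[a * dim + i][poff + b] +=
              w * tau * vdotgN[a] * eg.gradN[b][i];
          // continuity row a, pressure column b: PSPG
          {
            double s = 0.0;
            for (int i = 0; i < dim; ++i) s += eg.gradN[a][i] * eg.gradN[b][i];
            Jl[poff + a][poff + b] += w * tau / rho * s;
          }
        }
      }
    }
    // constant-gradient terms (exact integrals): viscous stress, pressure
    // gradient, grad-div
    for (int a = 0; a < nen; ++a) {
      for (int i = 0; i < dim; ++i) {
        double r = 0.0;
        for (int j = 0; j < dim; ++j)
          r += mu * (gradv[i][j] + gradv[j][i]) * eg.gradN[a][j];
        // pressure term: - int p dNa/dxi ; p varies linearly -> use mean
        double pm = 0.0;
        for (int b = 0; b < nen; ++b) pm += pe[b] / nen;
        r -= pm * eg.gradN[a][i];
        r += rho * tauc * divv * eg.gradN[a][i];   // grad-div
        Rl[a * dim + i] += eg.vol * r;
        for (int b = 0; b < nen; ++b) {
          for (int j = 0; j < dim; ++j) {
            double gg = 0.0;
            for (int k2 = 0; k2 < dim; ++k2)
              gg += eg.gradN[a][k2] * eg.gradN[b][k2];
            double Jv = mu * c_vel *
              ((i == j ? gg : 0.0) + eg.gradN[a][j] * eg.gradN[b][i]);
            Jv += rho * tauc * c_vel * eg.gradN[a][i] * eg.gradN[b][j];
            Jl[a * dim + i][b * dim + j] += eg.vol * Jv;
          }
          Jl[a * dim + i][poff + b] += -eg.vol * eg.gradN[a][i] / nen;
        }
      }
    }
    // scatter
    int gdof[16];
    for (int a = 0; a < nen; ++a) {
      for (int i = 0; i < dim; ++i) gdof[a * dim + i] = conn[a] * dim + i;
      gdof[poff + a] = ndof_v + conn[a];
    }
    for (int k = 0; k < block; ++k) {
      resid[gdof[k]] += Rl[k];
      for (int l = 0; l < block; ++l) {
        ti[tcnt] = gdof[k] + 1;
        tj[tcnt] = gdof[l] + 1;
        tx[tcnt] = Jl[k][l];
        ++tcnt;
      }
    }
  }
  return List::create(_["resid"] = resid, _["i"] = ti, _["j"] = tj,
                      _["x"] = tx, _["ndof"] = ndof);
}

// Advection-diffusion assembly on a frozen velocity field, backward-Euler in
// time with SUPG and residual-based discontinuity capturing (kappa_DC lagged
// from the previous solution).  Returns triplets for the implicit system
// matrix A and the right-hand-side operator B such that A phi^{n+1} = B phi^n.
// With dt <= 0 the time terms are dropped (steady transport operator).
// [[Rcpp::export]]
List scalar_assemble_cpp(NumericMatrix nodes, IntegerMatrix cells,
                         NumericMatrix vel, NumericVector phi_lag,
                         NumericVector phi_prev,
                         double kappa, double dt, double dc_scale = 1.0) {
  const int dim = nodes.ncol();
  const int nnode = nodes.nrow();
  const int nen = dim + 1;
  const int nel = cells.nrow();
  const double inv_dt2 = dt > 0 ? 4.0 / (dt * dt) : 0.0;
  const int block = nen * nen;
  const size_t ntrip = (size_t)nel * block;

  IntegerVector ti(ntrip), tj(ntrip);
  NumericVector ax(ntrip), bx(ntrip);
  NumericVector kdc_out(nel);

  const double* nd = REAL(nodes);
  int nq; double qp[4][4], qw[4];
  quad_rule(dim, nq, qp, qw);

  int conn[4];
  size_t tcnt = 0;
  for (int e = 0; e < nel; ++e) {
    for (int a = 0; a < nen; ++a) conn[a] = cells(e, a) - 1;
    ElemGeom eg;
    if (!elem_geom(nd, nnode, dim, conn, nen, eg) || eg.vol <= 0.0)
      stop("scalar assembly stage: bad element %d", e + 1);
    double ve[4][3], phe[4];
    double dphidt = 0.0;
    for (int a = 0; a < nen; ++a) {
      phe[a] = phi_lag[conn[a]];
      if (dt > 0)
        dphidt += (phi_lag[conn[a]] - phi_prev[conn[a]]) / (dt * nen);
      for (int i = 0; i < dim; ++i) ve[a][i] = vel(conn[a], i);
    }
    double gphi[3] = {0, 0, 0};
    for (int i = 0; i < dim; ++i)
      for (int a = 0; a < nen; ++a) gphi[i] += phe[a] * eg.gradN[a][i];
    double vbar[3] = {0, 0, 0};
    for (int a = 0; a < nen; ++a)
      for (int i = 0; i < dim; ++i) vbar[i] += ve[a][i] / nen;
    // discontinuity-capturing diffusivity from the lagged residual
    // L(phi) ~ dphi/dt + v.grad(phi) (the time term supplies crosswind
    // damping at stagnant nodes where the advective part vanishes)
    double vdg = 0.0;
    for (int i = 0; i < dim; ++i) vdg += vbar[i] * gphi[i];
    double gXg = 0.0;
    for (int i = 0; i < dim; ++i)
      for (int j = 0; j < dim; ++j) gXg += gphi[i] * eg.G[i][j] * gphi[j];
    double kdc = 0.0;
    if (gXg > 1e-30)
      kdc = dc_scale * std::fabs(dphidt + vdg) / (2.0 * std::sqrt(gXg));
    // cap at the first-order-upwind level so slivers cannot blow the
    // system scaling up
    {
      double trG_ = 0.0, vnorm = 0.0;
      for (int i = 0; i < dim; ++i) {
        trG_ += eg.G[i][i];
        vnorm += vbar[i] * vbar[i];
      }
      const double h_e = std::sqrt((double)dim / trG_);
      double cap = h_e * std::sqrt(vnorm) + 2.0 * h_e * h_e / (dt > 0 ? dt : 1.0);
      if (kdc > cap) kdc = cap;
    }
    kdc_out[e] = kdc;
    const double keff = kappa + kdc;
    double vGv = 0.0, GG = 0.0;
    for (int i = 0; i < dim; ++i)
      for (int j = 0; j < dim; ++j) {
        vGv += vbar[i] * eg.G[i][j] * vbar[j];
        GG += eg.G[i][j] * eg.G[i][j];
      }
    const double tau = 1.0 / std::sqrt(inv_dt2 + vGv + 3.0 * keff * keff * GG);

    double Ae[4][4] = {{0}}, Be[4][4] = {{0}};
    for (int q = 0; q < nq; ++q) {
      const double w = qw[q] * eg.vol;
      double vq[3] = {0, 0, 0};
      for (int a = 0; a < nen; ++a)
        for (int i = 0; i < dim; ++i) vq[i] += qp[q][a] * ve[a][i];
      double vdgN[4];
      for (int a = 0; a < nen; ++a) {
        double s = 0.0;
        for (int i = 0; i < dim; ++i) s += vq[i] * eg.gradN[a][i];
        vdgN[a] = s;
      }
      for (int a = 0; a < nen; ++a) {
        const double Na = qp[q][a];
        const double Wa = Na + tau * vdgN[a];   // SUPG-weight
        for (int b = 0; b < nen; ++b) {
          const double Nb = qp[q][b];
          double A = Wa * vdgN[b];   // advection (diffusion added exactly below)
          if (dt > 0) {
            A += Wa * Nb / dt;
            Be[a][b] += w * Wa * Nb / dt;
          }
          Ae[a][b] += w * A;
        }
      }
    }
    // diffusion (constant gradients; exact)
    for (int a = 0; a < nen; ++a)
      for (int b = 0; b < nen; ++b) {
        double gg = 0.0;
        for (int i = 0; i < dim; ++i) gg += eg.gradN[a][i] * eg.gradN[b][i];
        Ae[a][b] += eg.vol * keff * gg;
      }
    for (int a = 0; a < nen; ++a)
      for (int b = 0; b < nen; ++b) {
        ti[tcnt] = conn[a] + 1;
        tj[tcnt] = conn[b] + 1;
        ax[tcnt] = Ae[a][b];
        bx[tcnt] = Be[a][b];
        ++tcnt;
      }
  }
  return List::create(_["i"] = ti, _["j"] = tj, _["ax"] = ax, _["bx"] = bx,
                      _["kappa_dc"] = kdc_out);
}

// Per-element constant gradients of a nodal field (columns = components)
// plus element measures; used for wall-traction gradient recovery.
// [[Rcpp::export]]
List element_gradients_cpp(NumericMatrix nodes, IntegerMatrix cells,
                           NumericMatrix field) {
  const int dim = nodes.ncol();
  const int nnode = nodes.nrow();
  const int nen = dim + 1;
  const int nel = cells.nrow();
  const int nc = field.ncol();
  NumericMatrix grads(nel, nc * dim);  // column (c*dim + i) = d field_c / d x_i
  NumericVector vols(nel);
  const double* nd = REAL(nodes);
  int conn[4];
  for (int e = 0; e < nel; ++e) {
    for (int a = 0; a < nen; ++a) conn[a] = cells(e, a) - 1;
    ElemGeom eg;
    if (!elem_geom(nd, nnode, dim, conn, nen, eg))
      stop("gradient stage: degenerate element %d", e + 1);
    vols[e] = eg.vol;
    for (int c = 0; c < nc; ++c)
      for (int i = 0; i < dim; ++i) {
        double s = 0.0;
        for (int a = 0; a < nen; ++a) s += field(conn[a], c) * eg.gradN[a][i];
        grads(e, c * dim + i) = s;
      }
  }
  return List::create(_["grads"] = grads, _["vols"] = vols);
}

// Accumulate triplet values into pre-mapped unique-entry slots (cached
// sparsity pattern path of the assembly).
// [[Rcpp::export]]
NumericVector accumulate_triplets_cpp(IntegerVector map, NumericVector x,
                                      int nnz) {
  NumericVector out(nnz);
  const int n = x.size();
  for (int k = 0; k < n; ++k) out[map[k] - 1] += x[k];
  return out;
}
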