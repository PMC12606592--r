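// Dense pairwise kernels for the charge-based boundary element solver.
//
// Conventions (all SI):
//   * The solver unknown is g = rho / (2 eps0), which has E-field units
//     (V/m).  In these units the collocation equation at face n reads
//        g_n - K_n n_n . sum_{m != n} A_m g_m (r_n - r_m) / (2 pi |r_n - r_m|^3)
//            = K_n n_n . E_inc(r_n)
//     and no eps0 appears anywhere.
//   * Faces closer than `nb_radius` to the evaluation point are integrated
//     with a barycentric subdivision rule (k-way edge split, k^2 congruent
//     sub-triangles, built on the fly from the face vertices); points closer
//     than the local face scale get a finer split.  Split factors avoid
//     k = 1, 2 mod 3 patterns that place a sub-centroid on the parent
//     centroid.
//   * Sub-points that coincide with the evaluation point (r < 1e-12 m)
//     contribute zero (principal value).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static const double MU0_OVER_4PI = 1e-7;
static const double INV_2PI = 1.0 / (2.0 * datum::pi);

struct FaceGeo {
  const mat &A, &B, &C;      // vertex coordinates, F x 3 each
  const mat &centers;
  const vec &areas;
};

// Integral over face m of (p - r')/(2 pi |p - r'|^3) dS' (gradient kernel)
// and of 1/(2 pi |p - r'|) dS' (potential kernel), via k^2 sub-centroids.
static inline void face_integrals_sub(const FaceGeo& g, unsigned int m,
                                      const vec& p, int k,
                                      bool want_grad, bool want_pot,
                                      vec& grad_out, double& pot_out) {
  vec a = g.A.row(m).t(), ab = g.B.row(m).t() - a, ac = g.C.row(m).t() - a;
  double a_sub = g.areas(m) / (k * k);
  grad_out.zeros();
  pot_out = 0.0;
  for (int i = 0; i < k; ++i) {
    for (int j = 0; j < k - i; ++j) {
      // "up" sub-triangle centroid
      double bu = (3.0 * i + 1) / (3.0 * k), cu = (3.0 * j + 1) / (3.0 * k);
      vec q = a + ab * bu + ac * cu;
      vec d = p - q;
      double r2 = dot(d, d);
      if (r2 > 1e-24) {
        double r = std::sqrt(r2);
        if (want_grad) grad_out += d * (a_sub * INV_2PI / (r2 * r));
        if (want_pot) pot_out += a_sub * INV_2PI / r;
      }
      if (i + j < k - 1) {  // "down" sub-triangle centroid
        double bd = (3.0 * i + 2) / (3.0 * k), cd = (3.0 * j + 2) / (3.0 * k);
        vec q2 = a + ab * bd + ac * cd;
        vec d2 = p - q2;
        double s2 = dot(d2, d2);
        if (s2 > 1e-24) {
          double s = std::sqrt(s2);
          if (want_grad) grad_out += d2 * (a_sub * INV_2PI / (s2 * s));
          if (want_pot) pot_out += a_sub * INV_2PI / s;
        }
      }
    }
  }
}

static inline int split_for(double dist2, double area) {
  // finer splits as the point approaches the face scale
  if (dist2 < 0.0625 * area) return 45;
  if (dist2 < 0.36 * area) return 18;
  return 6;
}

// Gradient kernel integrated over face m at point p, with near-field rule.
static inline vec face_grad_kernel(const FaceGeo& g, unsigned int m,
                                   const vec& p, double nb_r2) {
  vec d = p - g.centers.row(m).t();
  double r2 = dot(d, d);
  if (r2 >= nb_r2) {
    double r = std::sqrt(r2);
    return d * (g.areas(m) * INV_2PI / (r2 * r));
  }
  vec grad(3);
  double pot;
  face_integrals_sub(g, m, p, split_for(r2, g.areas(m)), true, false,
                     grad, pot);
  return grad;
}

// [[Rcpp::export]]
arma::vec cpp_bem_matvec(const arma::mat& centers, const arma::mat& normals,
                         const arma::vec& areas, const arma::vec& K,
                         const arma::mat& va, const arma::mat& vb,
                         const arma::mat& vc, const arma::vec& g,
                         double nb_radius) {
  unsigned int F = centers.n_rows;
  double nb_r2 = nb_radius * nb_radius;
  FaceGeo geo{va, vb, vc, centers, areas};
  const double *cx = centers.colptr(0), *cy = centers.colptr(1),
               *cz = centers.colptr(2), *ar = areas.memptr(),
               *gv = g.memptr();
  vec out(F);
  for (unsigned int n = 0; n < F; ++n) {
    const double px = cx[n], py = cy[n], pz = cz[n];
    const double nx = normals(n, 0), ny = normals(n, 1), nz = normals(n, 2);
    double accx = 0.0, accy = 0.0, accz = 0.0;
    for (unsigned int m = 0; m < F; ++m) {
      double dx = px - cx[m], dy = py - cy[m], dz = pz - cz[m];
      double r2 = dx * dx + dy * dy + dz * dz;
      if (r2 >= nb_r2) {
        double w = gv[m] * ar[m] * INV_2PI / (r2 * std::sqrt(r2));
        accx += dx * w; accy += dy * w; accz += dz * w;
      } else if (m != n) {
        vec p = {px, py, pz}, grad(3);
        double pot;
        face_integrals_sub(geo, m, p, split_for(r2, ar[m]), true, false,
                           grad, pot);
        accx += gv[m] * grad(0); accy += gv[m] * grad(1);
        accz += gv[m] * grad(2);
      }
    }
    out(n) = gv[n] - K(n) * (nx * accx + ny * accy + nz * accz);
  }
  return out;
}

// Dense operator matrix A with A x = cpp_bem_matvec(x).
// [[Rcpp::export]]
arma::mat cpp_bem_dense(const arma::mat& centers, const arma::mat& normals,
                        const arma::vec& areas, const arma::vec& K,
                        const arma::mat& va, const arma::mat& vb,
                        const arma::mat& vc, double nb_radius) {
  unsigned int F = centers.n_rows;
  double nb_r2 = nb_radius * nb_radius;
  FaceGeo geo{va, vb, vc, centers, areas};
  const double *cx = centers.colptr(0), *cy = centers.colptr(1),
               *cz = centers.colptr(2), *ar = areas.memptr();
  mat A(F, F);
  for (unsigned int n = 0; n < F; ++n) {
    const double px = cx[n], py = cy[n], pz = cz[n];
    const double nx = normals(n, 0), ny = normals(n, 1), nz = normals(n, 2);
    const double Kn = K(n);
    for (unsigned int m = 0; m < F; ++m) {
      if (m == n) { A(n, n) = 1.0; continue; }
      double dx = px - cx[m], dy = py - cy[m], dz = pz - cz[m];
      double r2 = dx * dx + dy * dy + dz * dz;
      if (r2 >= nb_r2) {
        double w = ar[m] * INV_2PI / (r2 * std::sqrt(r2));
        A(n, m) = -Kn * (nx * dx + ny * dy + nz * dz) * w;
      } else {
        vec p = {px, py, pz}, grad(3);
        double pot;
        face_integrals_sub(geo, m, p, split_for(r2, ar[m]), true, false,
                           grad, pot);
        A(n, m) = -Kn * (nx * grad(0) + ny * grad(1) + nz * grad(2));
      }
    }
  }
  return A;
}

// Single-layer potential matrix S (P x F): phi(p) = S g, near-field
// corrected (including a face's own center).
// [[Rcpp::export]]
arma::mat cpp_single_layer_dense(const arma::mat& centers, const arma::vec& areas,
                                 const arma::mat& va, const arma::mat& vb,
                                 const arma::mat& vc, const arma::mat& points,
                                 double nb_radius) {
  unsigned int F = centers.n_rows, P = points.n_rows;
  double nb_r2 = nb_radius * nb_radius;
  FaceGeo geo{va, vb, vc, centers, areas};
  const double *cx = centers.colptr(0), *cy = centers.colptr(1),
               *cz = centers.colptr(2), *ar = areas.memptr();
  mat S(P, F);
  for (unsigned int q = 0; q < P; ++q) {
    const double px = points(q, 0), py = points(q, 1), pz = points(q, 2);
    for (unsigned int m = 0; m < F; ++m) {
      double dx = px - cx[m], dy = py - cy[m], dz = pz - cz[m];
      double r2 = dx * dx + dy * dy + dz * dz;
      if (r2 >= nb_r2) {
        S(q, m) = ar[m] * INV_2PI / std::sqrt(r2);
      } else {
        vec p = {px, py, pz}, grad(3);
        double pot;
        face_integrals_sub(geo, m, p, split_for(r2, ar[m]), false, true,
                           grad, pot);
        S(q, m) = pot;
      }
    }
  }
  return S;
}

// Coulomb (secondary) E-field of the charges at arbitrary points (P x 3):
// E_sec(p) = sum_m A_m g_m (p - r_m) / (2 pi |p - r_m|^3).
// [[Rcpp::export]]
arma::mat cpp_coulomb_E(const arma::mat& centers, const arma::vec& areas,
                        const arma::mat& va, const arma::mat& vb,
                        const arma::mat& vc, const arma::vec& g,
                        const arma::mat& points, double nb_radius) {
  unsigned int F = centers.n_rows, P = points.n_rows;
  double nb_r2 = nb_radius * nb_radius;
  FaceGeo geo{va, vb, vc, centers, areas};
  const double *cx = centers.colptr(0), *cy = centers.colptr(1),
               *cz = centers.colptr(2), *ar = areas.memptr(),
               *gv = g.memptr();
  mat E(P, 3, fill::zeros);
  for (unsigned int q = 0; q < P; ++q) {
    const double px = points(q, 0), py = points(q, 1), pz = points(q, 2);
    double accx = 0.0, accy = 0.0, accz = 0.0;
    for (unsigned int m = 0; m < F; ++m) {
      double dx = px - cx[m], dy = py - cy[m], dz = pz - cz[m];
      double r2 = dx * dx + dy * dy + dz * dz;
      if (r2 >= nb_r2) {
        double w = gv[m] * ar[m] * INV_2PI / (r2 * std::sqrt(r2));
        accx += dx * w; accy += dy * w; accz += dz * w;
      } else {
        vec p = {px, py, pz}, grad(3);
        double pot;
        face_integrals_sub(geo, m, p, split_for(r2, ar[m]), true, false,
                           grad, pot);
        accx += gv[m] * grad(0); accy += gv[m] * grad(1);
        accz += gv[m] * grad(2);
      }
    }
    E(q, 0) = accx; E(q, 1) = accy; E(q, 2) = accz;
  }
  return E;
}

// Primary E-field of a set of current elements (1/r kernel):
// E(p) = -(mu0/4pi) sum_j s_j / |p - p_j|, svec rows = s_j * dIdt_j.
// [[Rcpp::export]]
arma::mat cpp_primary_E(const arma::mat& elem_pos, const arma::mat& svec,
                        const arma::mat& points) {
  unsigned int L = elem_pos.n_rows, P = points.n_rows;
  mat E(P, 3, fill::zeros);
  for (unsigned int q = 0; q < P; ++q) {
    vec p = points.row(q).t();
    vec acc(3, fill::zeros);
    for (unsigned int j = 0; j < L; ++j) {
      vec d = p - elem_pos.row(j).t();
      acc += svec.row(j).t() / norm(d);
    }
    E.row(q) = (-MU0_OVER_4PI) * acc.t();
  }
  return E;
}

// Dipole field/potential kernels at a point.
static inline vec dipole_E_at(const vec& p, const vec& rd, const vec& md,
                              double c) {
  vec u = p - rd;
  double r = norm(u);
  u /= r;
  return c * (3.0 * dot(md, u) * u - md) / (r * r * r);
}

static inline double dipole_phi_at(const vec& p, const vec& rd, const vec& md,
                                   double c) {
  vec u = p - rd;
  double r = norm(u);
  return c * dot(md, u) / (r * r * r);
}

// Face-averaged evaluation (k-way barycentric split) of the dipole kernels:
// faces close to a dipole see a near-singular field for which the one-point
// centroid sample is a poor test functional; averaging over sub-centroids
// restores the Galerkin-style face mean.
template <typename Fn>
static inline double face_mean(const FaceGeo& g, unsigned int m, int k,
                               Fn&& f) {
  vec a = g.A.row(m).t(), ab = g.B.row(m).t() - a, ac = g.C.row(m).t() - a;
  double acc = 0.0;
  int cnt = 0;
  for (int i = 0; i < k; ++i) {
    for (int j = 0; j < k - i; ++j) {
      vec q = a + ab * ((3.0 * i + 1) / (3.0 * k)) +
        ac * ((3.0 * j + 1) / (3.0 * k));
      acc += f(q); ++cnt;
      if (i + j < k - 1) {
        vec q2 = a + ab * ((3.0 * i + 2) / (3.0 * k)) +
          ac * ((3.0 * j + 2) / (3.0 * k));
        acc += f(q2); ++cnt;
      }
    }
  }
  return acc / cnt;
}

// Right-hand sides for dipole-driven charge solves (direct leadfield path):
// F x N matrix of K_n n_n . E_i, with face-averaged E_i on faces within
// nb_radius of the dipole.
// [[Rcpp::export]]
arma::mat cpp_dipole_rhs(const arma::mat& centers, const arma::mat& normals,
                         const arma::vec& K, const arma::vec& areas,
                         const arma::mat& va, const arma::mat& vb,
                         const arma::mat& vc, const arma::mat& dip_pos,
                         const arma::mat& dip_mom, const arma::vec& sigma_d,
                         double nb_radius) {
  unsigned int F = centers.n_rows, N = dip_pos.n_rows;
  double nb_r2 = nb_radius * nb_radius;
  FaceGeo geo{va, vb, vc, centers, areas};
  mat R(F, N);
  for (unsigned int d = 0; d < N; ++d) {
    vec rd = dip_pos.row(d).t();
    vec md = dip_mom.row(d).t();
    double c = 1.0 / (4.0 * datum::pi * sigma_d(d));
    for (unsigned int n = 0; n < F; ++n) {
      vec p = centers.row(n).t();
      vec nn = normals.row(n).t();
      double r2 = dot(p - rd, p - rd);
      double v;
      if (r2 >= nb_r2) {
        v = dot(nn, dipole_E_at(p, rd, md, c));
      } else {
        v = face_mean(geo, n, split_for(r2, areas(n)),
                      [&](const vec& q) {
                        return dot(nn, dipole_E_at(q, rd, md, c));
                      });
      }
      R(n, d) = K(n) * v;
    }
  }
  return R;
}

// Primary (infinite-medium) potential of dipoles at face centers (P x N),
// face-averaged near the dipole.  Rows correspond to the faces whose
// geometry is supplied; pass nb_radius = 0 for plain point evaluation at
// arbitrary points.
// [[Rcpp::export]]
arma::mat cpp_dipole_phi(const arma::mat& dip_pos, const arma::mat& dip_mom,
                         const arma::vec& sigma_d, const arma::mat& points,
                         const arma::vec& areas, const arma::mat& va,
                         const arma::mat& vb, const arma::mat& vc,
                         double nb_radius) {
  unsigned int P = points.n_rows, N = dip_pos.n_rows;
  double nb_r2 = nb_radius * nb_radius;
  FaceGeo geo{va, vb, vc, points, areas};
  mat Phi(P, N);
  for (unsigned int d = 0; d < N; ++d) {
    vec rd = dip_pos.row(d).t();
    vec md = dip_mom.row(d).t();
    double c = 1.0 / (4.0 * datum::pi * sigma_d(d));
    for (unsigned int q = 0; q < P; ++q) {
      vec p = points.row(q).t();
      double r2 = dot(p - rd, p - rd);
      if (nb_radius > 0 && r2 < nb_r2) {
        Phi(q, d) = face_mean(geo, q, split_for(r2, areas(q)),
                              [&](const vec& s) {
                                return dipole_phi_at(s, rd, md, c);
                              });
      } else {
        Phi(q, d) = dipole_phi_at(p, rd, md, c);
      }
    }
  }
  return Phi;
}

// Geselowitz volume-current weights.  Returns list(x, y, z), each Q x F,
// such that B_v(q) = W %*% phi with
//   W[q,m] = -(mu0/4pi) (sigma_in - sigma_out)_m A_m [n_m x (p_q - r_m)] / |p_q - r_m|^3.
// [[Rcpp::export]]
Rcpp::List cpp_geselowitz_weights(const arma::mat& centers, const arma::mat& normals,
                                  const arma::vec& areas, const arma::vec& sjump,
                                  const arma::mat& points) {
  unsigned int F = centers.n_rows, Q = points.n_rows;
  mat Wx(Q, F), Wy(Q, F), Wz(Q, F);
  const double *cx = centers.colptr(0), *cy = centers.colptr(1),
               *cz = centers.colptr(2), *ar = areas.memptr(),
               *nx = normals.colptr(0), *ny = normals.colptr(1),
               *nz = normals.colptr(2), *sj = sjump.memptr();
  for (unsigned int q = 0; q < Q; ++q) {
    const double px = points(q, 0), py = points(q, 1), pz = points(q, 2);
    for (unsigned int m = 0; m < F; ++m) {
      double dx = px - cx[m], dy = py - cy[m], dz = pz - cz[m];
      double r2 = dx * dx + dy * dy + dz * dz;
      double c = -MU0_OVER_4PI * sj[m] * ar[m] / (r2 * std::sqrt(r2));
      Wx(q, m) = c * (ny[m] * dz - nz[m] * dy);
      Wy(q, m) = c * (nz[m] * dx - nx[m] * dz);
      Wz(q, m) = c * (nx[m] * dy - ny[m] * dx);
    }
  }
  return Rcpp::List::create(Rcpp::Named("x") = Wx, Rcpp::Named("y") = Wy,
                            Rcpp::Named("z") = Wz);
}
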