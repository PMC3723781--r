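// Backbone geometry kernels: torsion -> Cartesian chain building (NeRF),
// dihedral measurement, Kabsch superposition RMSD, and the distance-based
// terms of the reference coarse-grained scorer. Coordinates are stored as a
// (3n x 3) matrix with atom order N, CA, C per residue.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static const double kDeg2Rad = M_PI / 180.0;
static const double kRad2Deg = 180.0 / M_PI;

// Place atom D at distance `bond` from C, with angle B-C-D = `angle` and
// dihedral A-B-C-D = `dihedral` (both radians). Standard NeRF step.
static arma::rowvec3 nerf_place(const arma::rowvec3& A, const arma::rowvec3& B,
                                const arma::rowvec3& C, double bond,
                                double angle, double dihedral) {
  arma::rowvec3 bc = arma::normalise(C - B);
  arma::rowvec3 ab = B - A;
  arma::rowvec3 n = arma::normalise(arma::cross(ab, bc));
  arma::rowvec3 m = arma::cross(n, bc);

  double d2 = bond * std::sin(angle);
  arma::rowvec3 d;
  d[0] = -bond * std::cos(angle);
  d[1] = d2 * std::cos(dihedral);
  d[2] = -d2 * std::sin(dihedral);

  return C + d[0] * bc + d[1] * m + d[2] * n;
}

// torsions: n x 3 matrix (phi, psi, omega) in degrees.
// bonds: c(N-CA, CA-C, C-N) in Angstrom.
// angles: c(N-CA-C, CA-C-N, C-N-CA) in degrees.
// Returns 3n x 3 coordinates (N, CA, C per residue). phi[1], psi[n] and
// omega[n] do not influence the chain and are ignored.
// [[Rcpp::export]]
NumericMatrix build_backbone_cpp(NumericMatrix torsions, NumericVector bonds,
                                 NumericVector angles) {
  int n = torsions.nrow();
  if (n < 1) stop("need at least one residue");
  double b_nca = bonds[0], b_cac = bonds[1], b_cn = bonds[2];
  double a_ncac = angles[0] * kDeg2Rad;
  double a_cacn = angles[1] * kDeg2Rad;
  double a_cnca = angles[2] * kDeg2Rad;

  arma::mat xyz(3 * n, 3);

  // Canonical frame for residue 1: N at origin, CA on +x, C in the xy plane.
  arma::rowvec3 N1 = {0.0, 0.0, 0.0};
  arma::rowvec3 CA1 = {b_nca, 0.0, 0.0};
  arma::rowvec3 C1 = {b_nca - b_cac * std::cos(a_ncac),
                      b_cac * std::sin(a_ncac), 0.0};
  xyz.row(0) = N1;
  xyz.row(1) = CA1;
  xyz.row(2) = C1;

  for (int i = 1; i < n; ++i) {
    arma::rowvec3 Np = xyz.row(3 * (i - 1));
    arma::rowvec3 CAp = xyz.row(3 * (i - 1) + 1);
    arma::rowvec3 Cp = xyz.row(3 * (i - 1) + 2);

    double psi_p = torsions(i - 1, 1) * kDeg2Rad;
    double omega_p = torsions(i - 1, 2) * kDeg2Rad;
    double phi_i = torsions(i, 0) * kDeg2Rad;

    arma::rowvec3 Ni = nerf_place(Np, CAp, Cp, b_cn, a_cacn, psi_p);
    arma::rowvec3 CAi = nerf_place(CAp, Cp, Ni, b_nca, a_cnca, omega_p);
    arma::rowvec3 Ci = nerf_place(Cp, Ni, CAi, b_cac, a_ncac, phi_i);

    xyz.row(3 * i) = Ni;
    xyz.row(3 * i + 1) = CAi;
    xyz.row(3 * i + 2) = Ci;
  }
  return wrap(xyz);
}

static double dihedral4(const arma::rowvec3& a, const arma::rowvec3& b,
                        const arma::rowvec3& c, const arma::rowvec3& d) {
  arma::rowvec3 b1 = b - a, b2 = c - b, b3 = d - c;
  arma::rowvec3 n1 = arma::cross(b1, b2);
  arma::rowvec3 n2 = arma::cross(b2, b3);
  arma::rowvec3 m = arma::cross(n1, arma::normalise(b2));
  double x = arma::dot(n1, n2);
  double y = arma::dot(m, n2);
  return std::atan2(y, x) * kRad2Deg;
}

// Inverse of build_backbone_cpp: measure (phi, psi, omega) per residue from
// a 3n x 3 backbone matrix. Undefined entries (phi of the first residue,
// psi/omega of the last) are returned as NA.
// [[Rcpp::export]]
NumericMatrix measure_torsions_cpp(NumericMatrix coords) {
  arma::mat xyz = as<arma::mat>(coords);
  int n = xyz.n_rows / 3;
  NumericMatrix out(n, 3);
  std::fill(out.begin(), out.end(), NA_REAL);
  for (int i = 0; i < n; ++i) {
    arma::rowvec3 N = xyz.row(3 * i);
    arma::rowvec3 CA = xyz.row(3 * i + 1);
    arma::rowvec3 C = xyz.row(3 * i + 2);
    if (i > 0) {
      arma::rowvec3 Cp = xyz.row(3 * (i - 1) + 2);
      out(i, 0) = dihedral4(Cp, N, CA, C); // phi
    }
    if (i < n - 1) {
      arma::rowvec3 Nn = xyz.row(3 * (i + 1));
      arma::rowvec3 CAn = xyz.row(3 * (i + 1) + 1);
      out(i, 1) = dihedral4(N, CA, C, Nn);   // psi
      out(i, 2) = dihedral4(CA, C, Nn, CAn); // omega
    }
  }
  return out;
}

// Minimum RMSD over rigid-body superpositions (Kabsch, SVD with reflection
// guard). x, y: m x 3 point sets in correspondence.
// [[Rcpp::export]]
double kabsch_rmsd_cpp(NumericMatrix x, NumericMatrix y) {
  arma::mat X = as<arma::mat>(x);
  arma::mat Y = as<arma::mat>(y);
  if (X.n_rows != Y.n_rows) stop("point sets differ in size");
  int m = X.n_rows;
  arma::rowvec cx = arma::mean(X, 0), cy = arma::mean(Y, 0);
  X.each_row() -= cx;
  Y.each_row() -= cy;

  arma::mat H = X.t() * Y;
  arma::mat U, V;
  arma::vec s;
  arma::svd(U, s, V, H);
  double d = arma::det(V * U.t());
  arma::vec sign = {1.0, 1.0, (d < 0.0) ? -1.0 : 1.0};

  double e0 = arma::accu(X % X) + arma::accu(Y % Y);
  double msd = (e0 - 2.0 * arma::dot(s, sign)) / m;
  if (msd < 0.0) msd = 0.0; // numerical noise at identity
  return std::sqrt(msd);
}

// Reference coarse-grained score terms from CA coordinates (m x 3):
//   clash: sum over |i-j| >= 3 of max(0, 4 - d_ij)^2
//   rg:    (Rg - 2.2 * m^0.38)^2
//   hb:    -1 per i with d(CA_i, CA_{i+3}) in [4.5, 5.5]
// Returns c(clash, rg, hb); weighting happens in R.
// [[Rcpp::export]]
NumericVector reference_terms_cpp(NumericMatrix ca) {
  arma::mat X = as<arma::mat>(ca);
  int m = X.n_rows;
  double clash = 0.0;
  for (int i = 0; i < m; ++i) {
    for (int j = i + 3; j < m; ++j) {
      double d = arma::norm(X.row(i) - X.row(j));
      if (d < 4.0) {
        double v = 4.0 - d;
        clash += v * v;
      }
    }
  }
  arma::rowvec c = arma::mean(X, 0);
  arma::mat Xc = X;
  Xc.each_row() -= c;
  double rg = std::sqrt(arma::accu(Xc % Xc) / m);
  double rg_target = 2.2 * std::pow((double)m, 0.38);
  double rg_term = (rg - rg_target) * (rg - rg_target);

  double hb = 0.0;
  for (int i = 0; i + 3 < m; ++i) {
    double d = arma::norm(X.row(i) - X.row(i + 3));
    if (d >= 4.5 && d <= 5.5) hb -= 1.0;
  }
  return NumericVector::create(clash, rg_term, hb);
}
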