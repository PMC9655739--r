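#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Red-black successive over-relaxation for the finite-difference
// linearized Poisson-Boltzmann equation
//   sum_faces eps_f (phi_nb - phi_c) / h^2 - kap2_c phi_c = -src_c / h^2
// on a regular grid with Dirichlet boundary values already stored in phi.
// epsx/epsy/epsz are face dielectrics between node i and i+1 along each
// axis (dimension reduced by one along that axis); kap2h2 is the screening
// term pre-multiplied by h^2; src is 4*pi*f*q/h per node.
// [[Rcpp::export(name = ".pb_sor")]]
List pb_sor(NumericVector phi_, NumericVector epsx_, NumericVector epsy_,
            NumericVector epsz_, NumericVector kap2h2_, NumericVector src_,
            IntegerVector dims, double omega, double tol, int max_iter) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  NumericVector phi = clone(phi_);
  double *p = phi.begin();
  const double *ex = epsx_.begin(), *ey = epsy_.begin(), *ez = epsz_.begin();
  const double *k2 = kap2h2_.begin(), *sc = src_.begin();
  const int sx = 1, sy = nx, sz = nx * ny;
  // face strides: epsx has dims (nx-1, ny, nz); epsy (nx, ny-1, nz); epsz (nx, ny, nz-1)
  const int exy = nx - 1, exz = (nx - 1) * ny;
  const int eyy = nx, eyz = nx * (ny - 1);
  const int ezy = nx, ezz = nx * ny;
  int iter = 0;
  double maxphi = 1e-300, maxdiff = 0.0;
  for (iter = 1; iter <= max_iter; ++iter) {
    maxdiff = 0.0; maxphi = 1e-300;
    for (int color = 0; color < 2; ++color) {
      for (int k = 1; k < nz - 1; ++k) {
        for (int j = 1; j < ny - 1; ++j) {
          int istart = 1 + ((1 + j + k + color) & 1);
          for (int i = istart; i < nx - 1; i += 2) {
            const int c = i * sx + j * sy + k * sz;
            const double eW = ex[(i - 1) + j * exy + k * exz];
            const double eE = ex[i + j * exy + k * exz];
            const double eS = ey[i + (j - 1) * eyy + k * eyz];
            const double eN = ey[i + j * eyy + k * eyz];
            const double eD = ez[i + j * ezy + (k - 1) * ezz];
            const double eU = ez[i + j * ezy + k * ezz];
            const double denom = eW + eE + eS + eN + eD + eU + k2[c];
            const double rhs = eW * p[c - sx] + eE * p[c + sx] +
                               eS * p[c - sy] + eN * p[c + sy] +
                               eD * p[c - sz] + eU * p[c + sz] + sc[c];
            const double nv = (1.0 - omega) * p[c] + omega * rhs / denom;
            const double d = std::fabs(nv - p[c]);
            if (d > maxdiff) maxdiff = d;
            const double a = std::fabs(nv);
            if (a > maxphi) maxphi = a;
            p[c] = nv;
          }
        }
      }
    }
    if (maxdiff < tol * maxphi) break;
  }
  return List::create(_["phi"] = phi, _["iterations"] = iter,
                      _["residual"] = maxdiff / maxphi);
}
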