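#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Successive over-relaxation sweep solver for the finite-difference
// linearized Poisson-Boltzmann equation in Gaussian units:
//   sum_faces eps_f (phi_nb - phi_c) - kap2h2_c phi_c = -src_c
// with node-centred dielectric maps (face values = harmonic means),
// Dirichlet boundaries fixed in `phi` on entry.
// phi: potential in e/Angstrom units; src = 4*pi*q/h; kap2h2 = eps_w*kappa^2*h^2.
// [[Rcpp::export(name = ".lpbe_sor_cpp")]]
List lpbe_sor_cpp(NumericVector phi, NumericVector eps, NumericVector kap2h2,
                  NumericVector src, IntegerVector dims, double omega,
                  double tol, int max_iter) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t sx = 1, sy = nx, sz = (R_xlen_t)nx * ny;
  std::vector<double> hist;
  double maxdiff = 0.0;
  int iter = 0;
  for (iter = 0; iter < max_iter; ++iter) {
    maxdiff = 0.0;
    for (int k = 1; k < nz - 1; ++k) {
      for (int j = 1; j < ny - 1; ++j) {
        R_xlen_t base = sy * j + sz * k;
        for (int i = 1; i < nx - 1; ++i) {
          R_xlen_t c = base + i;
          double ec = eps[c];
          double exm = 2.0 * ec * eps[c - sx] / (ec + eps[c - sx]);
          double exp_ = 2.0 * ec * eps[c + sx] / (ec + eps[c + sx]);
          double eym = 2.0 * ec * eps[c - sy] / (ec + eps[c - sy]);
          double eyp = 2.0 * ec * eps[c + sy] / (ec + eps[c + sy]);
          double ezm = 2.0 * ec * eps[c - sz] / (ec + eps[c - sz]);
          double ezp = 2.0 * ec * eps[c + sz] / (ec + eps[c + sz]);
          double denom = exm + exp_ + eym + eyp + ezm + ezp + kap2h2[c];
          double num = exm * phi[c - sx] + exp_ * phi[c + sx] +
                       eym * phi[c - sy] + eyp * phi[c + sy] +
                       ezm * phi[c - sz] + ezp * phi[c + sz] + src[c];
          double newv = (1.0 - omega) * phi[c] + omega * num / denom;
          double d = std::fabs(newv - phi[c]);
          if (d > maxdiff) maxdiff = d;
          phi[c] = newv;
        }
      }
    }
    hist.push_back(maxdiff);
    if (maxdiff < tol) { ++iter; break; }
  }
  return List::create(Named("phi") = phi, Named("iterations") = iter,
                      Named("max_update") = maxdiff,
                      Named("residual_history") = wrap(hist),
                      Named("converged") = maxdiff < tol);
}
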