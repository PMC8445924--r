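#include <Rcpp.h>
using namespace Rcpp;

// Damped iterative back-projection for the linear tensor model r' U r.
// Each row of `mu` is one instance's signal set over the shared direction
// list `dirs` (P x 3, unit rows). `order` is a 0-based visiting order of
// length k_max (typically n_passes cyclic sweeps). The relaxation factor is
// lambda0 * 2^(-k / tau) with k = 1..k_max. Returns one row per instance
// holding the 6 free components (xx, yy, zz, xy, xz, yz) of the symmetric
// tensor U; the update r r' * residual preserves symmetry exactly.
// [[Rcpp::export]]
NumericMatrix recon_batch_cpp(NumericMatrix mu, NumericMatrix dirs,
                              double lambda0, double tau,
                              IntegerVector order) {
  const int n_inst = mu.nrow();
  const int P = dirs.nrow();
  const int k_max = order.size();
  if (mu.ncol() != P)
    stop("signal matrix and direction list disagree in length");

  // per-projection quadratic monomials
  std::vector<double> rxx(P), ryy(P), rzz(P), rxy(P), rxz(P), ryz(P);
  for (int i = 0; i < P; ++i) {
    const double x = dirs(i, 0), y = dirs(i, 1), z = dirs(i, 2);
    rxx[i] = x * x; ryy[i] = y * y; rzz[i] = z * z;
    rxy[i] = x * y; rxz[i] = x * z; ryz[i] = y * z;
  }
  std::vector<double> lam(k_max);
  for (int k = 0; k < k_max; ++k)
    lam[k] = lambda0 * std::pow(2.0, -(double)(k + 1) / tau);
  std::vector<int> ord(k_max);
  for (int k = 0; k < k_max; ++k) {
    ord[k] = order[k];
    if (ord[k] < 0 || ord[k] >= P) stop("projection order index out of range");
  }

  NumericMatrix out(n_inst, 6);
  for (int s = 0; s < n_inst; ++s) {
    double Uxx = 0, Uyy = 0, Uzz = 0, Uxy = 0, Uxz = 0, Uyz = 0;
    const NumericMatrix::Row row = mu(s, _);
    for (int k = 0; k < k_max; ++k) {
      const int i = ord[k];
      const double pred = Uxx * rxx[i] + Uyy * ryy[i] + Uzz * rzz[i]
        + 2.0 * (Uxy * rxy[i] + Uxz * rxz[i] + Uyz * ryz[i]);
      const double upd = lam[k] * (row[i] - pred);
      Uxx += upd * rxx[i]; Uyy += upd * ryy[i]; Uzz += upd * rzz[i];
      Uxy += upd * rxy[i]; Uxz += upd * rxz[i]; Uyz += upd * ryz[i];
    }
    out(s, 0) = Uxx; out(s, 1) = Uyy; out(s, 2) = Uzz;
    out(s, 3) = Uxy; out(s, 4) = Uxz; out(s, 5) = Uyz;
  }
  return out;
}
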