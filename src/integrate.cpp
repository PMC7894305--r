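// Crank-Nicolson integration of the linear moment system
//   d phi / d tau = A phi + B,   A = DX/nu1 + DY/nu2 + m12 G12 + m21 G21
// constant within an epoch. The moment operator is banded under column-major
// ordering of the two-population spectrum, so the step matrix I - dt/2 A is
// factorized once per epoch with LAPACK's banded LU and reused across steps;
// the explicit half-step is a dense matrix-vector product. The full epoch
// sequence, including the genomic-island mixture branches, runs in one call
// so that optimizer loops pay no per-epoch interface cost.

#include <RcppArmadillo.h>
#include <R_ext/Lapack.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static void cn_integrate(vec &phi, const mat &A, const vec &B,
                         const double T, const int steps) {
  const int n = phi.n_elem;
  const double dt = T / steps;

  int kl = 0, ku = 0;
  for (int j = 0; j < n; ++j)
    for (int i = 0; i < n; ++i)
      if (A(i, j) != 0.0) {
        if (i - j > kl) kl = i - j;
        if (j - i > ku) ku = j - i;
      }

  const int ldab = 2 * kl + ku + 1;
  mat AB(ldab, n, fill::zeros);
  for (int j = 0; j < n; ++j) {
    const int ilo = std::max(0, j - ku), ihi = std::min(n - 1, j + kl);
    for (int i = ilo; i <= ihi; ++i)
      AB(kl + ku + i - j, j) = (i == j ? 1.0 : 0.0) - 0.5 * dt * A(i, j);
  }
  ivec ipiv(n);
  int info = 0;
  F77_CALL(dgbtrf)(&n, &n, &kl, &ku, AB.memptr(), &ldab, ipiv.memptr(),
                   &info);
  if (info != 0)
    Rcpp::stop("integrate: banded LU failed (info %d)", info);

  const char trans = 'N';
  const int one = 1;
  vec rhs(n);
  for (int s = 0; s < steps; ++s) {
    rhs = phi + (0.5 * dt) * (A * phi) + dt * B;
    F77_CALL(dgbtrs)(&trans, &n, &kl, &ku, &one, AB.memptr(), &ldab,
                     ipiv.memptr(), rhs.memptr(), &n, &info FCONE);
    if (info != 0)
      Rcpp::stop("integrate: banded solve failed (info %d)", info);
    phi = rhs;
  }
  if (!phi.is_finite())
    Rcpp::stop("integrate: non-finite spectrum (integration diverged)");
}

// [[Rcpp::export(name = ".integrate_epoch_cpp")]]
Rcpp::NumericVector integrate_epoch_cpp(Rcpp::NumericVector phi0,
                                        Rcpp::NumericMatrix Amat,
                                        Rcpp::NumericVector Bvec,
                                        double T, int steps) {
  const int n = phi0.size();
  if (Amat.nrow() != n || Amat.ncol() != n || Bvec.size() != n)
    Rcpp::stop("integrate_epoch: dimension mismatch");
  if (T < 0) Rcpp::stop("integrate_epoch: negative duration");
  vec phi(phi0.begin(), n);
  if (T == 0.0 || steps <= 0) return Rcpp::wrap(phi);
  const mat A(Amat.begin(), n, n, false);
  const vec B(Bvec.begin(), n);
  cn_integrate(phi, A, B, T, steps);
  return Rcpp::wrap(phi);
}

// epochs: one row per epoch with columns
//   nu1, nu2, m12, m21, T, steps, P, b
// applied oldest to newest; the island mixture mixes at each epoch end.
// [[Rcpp::export(name = ".integrate_epochs_cpp")]]
Rcpp::NumericVector integrate_epochs_cpp(Rcpp::NumericVector phi0,
                                         Rcpp::NumericMatrix DXm,
                                         Rcpp::NumericMatrix DYm,
                                         Rcpp::NumericMatrix G12m,
                                         Rcpp::NumericMatrix G21m,
                                         Rcpp::NumericVector Bvec,
                                         Rcpp::NumericMatrix epochs) {
  const int n = phi0.size();
  if (DXm.nrow() != n || DYm.nrow() != n || G12m.nrow() != n ||
      G21m.nrow() != n || Bvec.size() != n)
    Rcpp::stop("integrate_epochs: dimension mismatch");
  const mat DX(DXm.begin(), n, n, false);
  const mat DY(DYm.begin(), n, n, false);
  const mat G12(G12m.begin(), n, n, false);
  const mat G21(G21m.begin(), n, n, false);
  const vec B(Bvec.begin(), n);
  vec phi(phi0.begin(), n);
  mat A(n, n);

  for (int e = 0; e < epochs.nrow(); ++e) {
    const double nu1 = epochs(e, 0), nu2 = epochs(e, 1);
    const double m12 = epochs(e, 2), m21 = epochs(e, 3);
    const double T = epochs(e, 4);
    const int steps = (int) epochs(e, 5);
    const double P = epochs(e, 6), b = epochs(e, 7);
    if (T <= 0.0 || steps <= 0) continue;
    if (nu1 <= 0.0 || nu2 <= 0.0)
      Rcpp::stop("integrate_epochs: non-positive population size");

    A = DX / nu1 + DY / nu2 + m12 * G12 + m21 * G21;
    const bool islands = P > 0.0 && b < 1.0 && (m12 > 0.0 || m21 > 0.0);
    vec main = phi;
    cn_integrate(main, A, B, T, steps);
    if (islands) {
      A = DX / nu1 + DY / nu2 + (b * m12) * G12 + (b * m21) * G21;
      vec isl = phi;
      cn_integrate(isl, A, B, T, steps);
      phi = (1.0 - P) * main + P * isl;
    } else {
      phi = main;
    }
  }
  return Rcpp::wrap(phi);
}
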