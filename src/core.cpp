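// Piecewise-constant unitary propagation and GRAPE fidelity/gradient core.
// All Hamiltonians are Hermitian and given in angular-frequency units (rad/s);
// slice propagators are exp(-i H dt) computed by eigendecomposition, and the
// control derivatives use the exact Daleckii-Krein (Frechet) formula, so the
// analytic gradient matches finite differences to solver precision.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static const cx_double IM(0.0, 1.0);

// exp(-i H dt) for Hermitian H; optionally return eigensystem for reuse.
static cx_mat expm_herm(const cx_mat& H, double dt, cx_mat& V, vec& lam) {
  eig_sym(lam, V, H);
  cx_vec ph = exp(-IM * conv_to<cx_vec>::from(lam) * dt);
  return V * diagmat(ph) * V.t();
}

// Frechet derivative of exp(-i H dt) at H in direction K (Hermitian), given
// the eigensystem of H.  F_ij = (f_i - f_j)/(l_i - l_j), F_ii = -i dt f_i.
static cx_mat dexpm_herm(const cx_mat& V, const vec& lam, double dt,
                         const cx_mat& K) {
  const uword d = lam.n_elem;
  cx_vec f = exp(-IM * conv_to<cx_vec>::from(lam) * dt);
  cx_mat F(d, d);
  for (uword i = 0; i < d; ++i) {
    for (uword j = 0; j < d; ++j) {
      double dl = lam(i) - lam(j);
      if (std::abs(dl) < 1e-12) {
        F(i, j) = -IM * dt * f(i);
      } else {
        F(i, j) = (f(i) - f(j)) / dl;
      }
    }
  }
  cx_mat Kt = V.t() * K * V;
  return V * (Kt % F) * V.t();
}

// Propagate through n slices with H_k = sum_j coef(k, j) * ops_j.
// Returns final propagator; optionally cumulative propagators after each
// slice (steps) and at slice midpoints (mids, used for toggling-frame
// averages evaluated by the midpoint rule).
// [[Rcpp::export]]
Rcpp::List cpp_slice_propagate(const arma::cx_cube& ops,
                               const arma::mat& coef,
                               double dt,
                               const arma::cx_mat& U0,
                               bool keep_steps,
                               bool keep_mids) {
  const uword d = ops.n_rows, n = coef.n_rows, K = ops.n_slices;
  if (coef.n_cols != K)
    Rcpp::stop("coefficient matrix has %d columns but %d operators supplied",
               (int)coef.n_cols, (int)K);
  cx_mat U = U0;
  cx_cube steps, mids;
  if (keep_steps) steps.set_size(d, d, n);
  if (keep_mids) mids.set_size(d, d, n);
  cx_mat V; vec lam;
  for (uword k = 0; k < n; ++k) {
    cx_mat H(d, d, fill::zeros);
    for (uword j = 0; j < K; ++j) H += coef(k, j) * ops.slice(j);
    if (keep_mids) {
      cx_mat Uh = expm_herm(H, dt / 2.0, V, lam);
      mids.slice(k) = Uh * U;
      cx_vec ph = exp(-IM * conv_to<cx_vec>::from(lam) * (dt / 2.0));
      U = (V * diagmat(ph) * V.t()) * mids.slice(k);
    } else {
      U = expm_herm(H, dt, V, lam) * U;
    }
    if (keep_steps) steps.slice(k) = U;
  }
  Rcpp::List out = Rcpp::List::create(Rcpp::Named("U") = U);
  if (keep_steps) out["steps"] = steps;
  if (keep_mids) out["mids"] = mids;
  return out;
}

// GRAPE fidelity (and gradient) for a single control channel over an
// ensemble.  Member m, slice k Hamiltonian:
//   H = zcoef(m, k) * Z + b1(m) * (ux(k) * X + uy(k) * Y) + Hstat
// ux, uy in rad/s.  target_kind: 0 = cyclic propagator |Tr U|/d,
// 1 = state lock Re Tr(T^dag U rho0 U^dag)/Tr(T^dag T) (raw overlap),
// 2 = phase-locked cyclic Re Tr(U)/d (forces the global phase to +1;
//     smoother optimization surface because ensemble members cannot
//     settle on opposite +/-1 branches).
// Returns mean fidelity over members, per-member values and, if requested,
// d(mean fidelity)/d ux, uy.
// [[Rcpp::export]]
Rcpp::List cpp_grape(const arma::vec& ux, const arma::vec& uy, double dt,
                     const arma::mat& zcoef, const arma::vec& b1,
                     const arma::cx_mat& X, const arma::cx_mat& Y,
                     const arma::cx_mat& Z, const arma::cx_mat& Hstat,
                     int target_kind,
                     const arma::cx_mat& rho0, const arma::cx_mat& Tgt,
                     bool want_grad) {
  const uword n = ux.n_elem, M = zcoef.n_rows, d = X.n_rows;
  if (zcoef.n_cols != n) Rcpp::stop("zcoef must be n_members x n_slices");
  const double dd = (double)d;
  double normT = 1.0;
  cx_mat Tadj;
  if (target_kind == 1) {
    Tadj = Tgt.t();
    normT = std::real(trace(Tadj * Tgt));
    if (normT <= 0) Rcpp::stop("zero-norm target");
  }
  vec fid_m(M, fill::zeros);
  vec gx(n, fill::zeros), gy(n, fill::zeros);

  cx_cube Us(d, d, n), cums(d, d, n);
  cube lams(d, 1, n);
  cx_cube Vs(d, d, n);

  for (uword m = 0; m < M; ++m) {
    // forward pass
    cx_mat U(d, d, fill::eye);
    for (uword k = 0; k < n; ++k) {
      cx_mat H = zcoef(m, k) * Z + b1(m) * (ux(k) * X + uy(k) * Y) + Hstat;
      cx_mat V; vec lam;
      cx_mat Uk = expm_herm(H, dt, V, lam);
      Us.slice(k) = Uk;
      Vs.slice(k) = V;
      lams.slice(k).col(0) = lam;
      U = Uk * U;
      cums.slice(k) = U;
    }
    // fidelity
    cx_double phi;
    double f;
    if (target_kind == 0) {
      phi = trace(U);
      f = std::abs(phi) / dd;
    } else if (target_kind == 2) {
      phi = trace(U);
      f = std::real(phi) / dd;
    } else {
      f = std::real(trace(Tadj * U * rho0 * U.t())) / normT;
    }
    fid_m(m) = f;
    if (!want_grad) continue;

    // backward pass: L = U_n ... U_{k+1}
    cx_mat L(d, d, fill::eye);
    cx_mat UrhoU, Ut;
    if (target_kind == 1) { Ut = U.t(); UrhoU = U * rho0 * Ut; }
    cx_double phin = phi;
    double aphi = (target_kind == 0) ? std::abs(phin) : 0.0;
    for (uword kk = n; kk-- > 0;) {
      cx_mat R = (kk == 0) ? cx_mat(d, d, fill::eye) : cums.slice(kk - 1);
      vec lam = lams.slice(kk).col(0);
      const cx_mat& V = Vs.slice(kk);
      for (int q = 0; q < 2; ++q) {
        cx_mat K = b1(m) * (q == 0 ? X : Y);
        cx_mat dUk = dexpm_herm(V, lam, dt, K);
        cx_mat dU = L * dUk * R;
        double g;
        if (target_kind == 0) {
          if (aphi < 1e-14) { g = 0.0; }
          else g = std::real(std::conj(phin) / aphi * trace(dU)) / dd;
        } else if (target_kind == 2) {
          g = std::real(trace(dU)) / dd;
        } else {
          cx_double t1 = trace(Tadj * dU * rho0 * Ut);
          cx_double t2 = trace(Tadj * U * rho0 * dU.t());
          g = std::real(t1 + t2) / normT;
        }
        if (q == 0) gx(kk) += g; else gy(kk) += g;
      }
      L = L * Us.slice(kk);
    }
  }

  Rcpp::List out = Rcpp::List::create(
      Rcpp::Named("fidelity") = mean(fid_m),
      Rcpp::Named("per_member") = fid_m);
  if (want_grad) {
    out["grad_x"] = gx / (double)M;
    out["grad_y"] = gy / (double)M;
  }
  return out;
}
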