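// Pseudo-spectral integrator for the laterally periodic Min
// reaction--diffusion--advection system (1D lateral geometry, bulk
// vertically integrated out).
//
// Field order (columns): m_d, m_de, c_DD, c_DT, c_Er, c_Ei.
// Linear transport (diffusion + uniform bulk advection) is applied exactly
// in Fourier space; reactions are advanced with classical RK4; the two are
// combined by Strang splitting.  The q = 0 Fourier multiplier is exactly 1,
// so both splitting sub-steps conserve the spatial means of all fields to
// round-off; the reaction RHS conserves MinD and MinE pointwise by
// construction, so total densities are conserved to machine precision.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

namespace {

struct Kinetics {
  double k_D, k_dD, k_dEr, k_dEi, k_de, lambda, mu;
  bool reduced;    // reduced switch model: bulk MinE slaved, uniform
  double n_E;      // total MinE density (needed for the reduced model)
};

// Reaction right-hand side.  For the reduced switch model the bulk MinE
// pools are spatially uniform scalars obtained from the quasi-steady-state
// balance of the reactive pool and MinE mass conservation, slaved to the
// instantaneous global membrane state.
void reaction_rhs(const mat& f, const Kinetics& k, mat& out) {
  const vec& m_d  = f.col(0);
  const vec& m_de = f.col(1);
  const vec& c_DD = f.col(2);
  const vec& c_DT = f.col(3);

  if (k.reduced) {
    const double md_m  = mean(m_d);
    const double mde_m = mean(m_de);
    const double er = k.k_de * mde_m / (k.k_dEr * md_m + k.mu);
    double ei = k.n_E - mde_m - er;
    if (ei < 0.0) ei = 0.0;
    const vec attach = (k.k_D + k.k_dD * m_d) % c_DT;
    const vec recruitE = (k.k_dEr * er + k.k_dEi * ei) * m_d;
    out.col(0) = attach - recruitE;
    out.col(1) = recruitE - k.k_de * m_de;
    out.col(2) = k.k_de * m_de - k.lambda * c_DD;
    out.col(3) = -attach + k.lambda * c_DD;
    out.col(4).zeros();
    out.col(5).zeros();
    return;
  }
  const vec& c_Er = f.col(4);
  const vec& c_Ei = f.col(5);
  const uword n = f.n_rows;
  const double* pmd = m_d.memptr();
  const double* pmde = m_de.memptr();
  const double* pdd = c_DD.memptr();
  const double* pdt = c_DT.memptr();
  const double* per = c_Er.memptr();
  const double* pei = c_Ei.memptr();
  for (uword i = 0; i < n; ++i) {
    const double attach = (k.k_D + k.k_dD * pmd[i]) * pdt[i];
    const double recruitE = (k.k_dEr * per[i] + k.k_dEi * pei[i]) * pmd[i];
    out.at(i, 0) = attach - recruitE;                              // f_d
    out.at(i, 1) = recruitE - k.k_de * pmde[i];                    // f_de
    out.at(i, 2) = k.k_de * pmde[i] - k.lambda * pdd[i];           // f_DD - lambda c_DD
    out.at(i, 3) = -attach + k.lambda * pdd[i];                    // f_DT + lambda c_DD
    out.at(i, 4) = -k.k_dEr * pmd[i] * per[i] + k.k_de * pmde[i] -
                   k.mu * per[i];
    out.at(i, 5) = -k.k_dEi * pmd[i] * pei[i] + k.mu * per[i];
  }
}

void rk4_step(mat& f, const Kinetics& k, double dt, mat& k1, mat& k2,
              mat& k3, mat& k4, mat& tmp) {
  reaction_rhs(f, k, k1);
  tmp = f + 0.5 * dt * k1;
  reaction_rhs(tmp, k, k2);
  tmp = f + 0.5 * dt * k2;
  reaction_rhs(tmp, k, k3);
  tmp = f + dt * k3;
  reaction_rhs(tmp, k, k4);
  f += (dt / 6.0) * (k1 + 2.0 * k2 + 2.0 * k3 + k4);
}

// Apply exp(dt*(-D q^2 - i a v q)) per field in Fourier space.
void linear_step(mat& f, const cx_mat& mult, const uvec& active) {
  for (uword j = 0; j < active.n_elem; ++j) {
    const uword c = active(j);
    cx_vec fh = fft(cx_vec(f.col(c), vec(f.n_rows, fill::zeros)));
    fh %= mult.col(c);
    f.col(c) = real(ifft(fh));
  }
}

} // namespace

// [[Rcpp::export]]
Rcpp::List sim_core(const arma::mat& fields0,
                    double L,
                    Rcpp::NumericVector rates,   // k_D k_dD k_dEr k_dEi k_de lambda mu
                    double D_m, double D_c, double v_f,
                    bool advect_minE,
                    bool reduced, double n_E,
                    double dt, int n_steps, int save_every,
                    double neg_abort) {
  const uword N = fields0.n_rows;
  if (fields0.n_cols != 6) Rcpp::stop("state must have 6 field columns");

  Kinetics kin;
  kin.k_D = rates[0]; kin.k_dD = rates[1]; kin.k_dEr = rates[2];
  kin.k_dEi = rates[3]; kin.k_de = rates[4]; kin.lambda = rates[5];
  kin.mu = rates[6]; kin.reduced = reduced; kin.n_E = n_E;

  // wavenumbers (periodic, standard FFT ordering)
  vec q(N);
  for (uword k = 0; k < N; ++k) {
    double kk = (k <= N / 2) ? double(k) : double(k) - double(N);
    q(k) = 2.0 * datum::pi * kk / L;
  }

  const double diffc[6] = {D_m, D_m, D_c, D_c, D_c, D_c};
  const double advc[6]  = {0.0, 0.0, 1.0, 1.0,
                           advect_minE ? 1.0 : 0.0,
                           advect_minE ? 1.0 : 0.0};
  // exponential high-order spectral filter: negligible below 2/3 of the
  // Nyquist wavenumber, strong at the grid scale; suppresses Gibbs
  // oscillations at steep pulse edges without touching resolved scales or
  // the q = 0 (mass) mode
  const double qmax = datum::pi * double(N) / L;
  cx_mat mult(N, 6);
  const double dt2 = 0.5 * dt;
  for (uword c = 0; c < 6; ++c)
    for (uword k = 0; k < N; ++k) {
      double filt = std::exp(-36.0 * std::pow(std::abs(q(k)) / qmax, 36.0));
      mult(k, c) = filt *
        std::exp(cx_double(-diffc[c] * q(k) * q(k) * dt2,
                           -advc[c] * v_f * q(k) * dt2));
    }

  // fields that undergo spectral transport
  std::vector<uword> act;
  for (uword c = 0; c < (reduced ? 4u : 6u); ++c) act.push_back(c);
  uvec active(act);

  mat f = fields0;
  mat k1(N, 6), k2(N, 6), k3(N, 6), k4(N, 6), tmp(N, 6);

  const int n_save = n_steps / save_every + 1;
  cube out(N, 6, n_save);
  vec times(n_save);
  int isave = 0;
  out.slice(isave) = f; times(isave) = 0.0; ++isave;

  long clipped = 0;
  for (int s = 1; s <= n_steps; ++s) {
    linear_step(f, mult, active);
    // adaptive substepping: the explicit reaction step must resolve the
    // fastest local kinetic rate, which grows with the pattern amplitude
    // (both the bulk-MinE decay ~ k_dEr m_d and the membrane-MinD decay
    // ~ k_dEr c_Er can be the stiff direction)
    double md_max = f.col(0).max();
    double cdt_max = f.col(3).max();
    double cer_max, cei_max;
    if (kin.reduced) {
      const double md_m = mean(f.col(0)), mde_m = mean(f.col(1));
      cer_max = kin.k_de * mde_m / (kin.k_dEr * md_m + kin.mu);
      cei_max = std::max(0.0, kin.n_E - mde_m - cer_max);
    } else {
      cer_max = f.col(4).max();
      cei_max = f.col(5).max();
    }
    double rate = (kin.k_dEr + kin.k_dEi) * std::max(md_max, 0.0) +
                  kin.k_dEr * std::max(cer_max, 0.0) +
                  kin.k_dEi * std::max(cei_max, 0.0) +
                  kin.k_dD * std::max(cdt_max, 0.0) +
                  kin.k_D + kin.k_de + kin.lambda + kin.mu;
    int n_sub = std::max(1, (int)std::ceil(dt * rate / 1.5));
    if (n_sub > 1000) Rcpp::stop("reaction stiffness overflow at step %d", s);
    const double dts = dt / n_sub;
    for (int j = 0; j < n_sub; ++j)
      rk4_step(f, kin, dts, k1, k2, k3, k4, tmp);
    linear_step(f, mult, active);

    if (s % 25 == 0 || s == n_steps) {
      if (!f.is_finite())
        Rcpp::stop("non-finite field values at step %d (t = %g s); reduce dt",
                   s, s * dt);
      const double mn = f.min();
      if (mn < -neg_abort)
        Rcpp::stop("negative concentration %g beyond tolerance at step %d",
                   mn, s);
    }
    if (s % save_every == 0 && isave < n_save) {
      mat snap = f;
      if (reduced) {  // store the slaved uniform MinE pools for inspection
        const double md_m = mean(snap.col(0)), mde_m = mean(snap.col(1));
        const double er = kin.k_de * mde_m / (kin.k_dEr * md_m + kin.mu);
        snap.col(4).fill(er);
        snap.col(5).fill(std::max(0.0, kin.n_E - mde_m - er));
      }
      out.slice(isave) = snap;
      times(isave) = s * dt;
      ++isave;
    }
  }

  return Rcpp::List::create(Rcpp::Named("states") = out,
                            Rcpp::Named("times") = times,
                            Rcpp::Named("clipped") = clipped);
}
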