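// Two-pool Bloch-McConnell propagation.
//
// State vector M = (MxA, MyA, MzA, MzB): transverse and longitudinal free
// pool plus longitudinal bound pool.  The bound pool's transverse
// magnetization is not tracked; its RF response enters as a saturation rate
// R_RFB = pi * |omega1|^2 * G(offset) with G the absorption lineshape.
//
// Over an interval where omega1 is constant the system is a linear ODE
// dM/dt = A M + b, solved exactly by the matrix exponential of the 5x5
// augmented matrix [[A, b], [0, 0]].  A shaped pulse is propagated as the
// composition of the per-sample affine maps, so a whole pulse train reduces
// to one cached affine map (Phi, b) with M_out = Phi M_in + b.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// tissue = (T1A, T2A, T1B, T2B, psr, R)  [s, s, s, s, -, Hz]
static void build_A_b(const arma::vec& tissue, double w1x, double w1y,
                      double f_eff_hz, double G, arma::mat& A, arma::vec& b) {
  const double T1A = tissue[0], T2A = tissue[1], T1B = tissue[2];
  const double psr = tissue[4], R = tissue[5];
  const double RA = 1.0 / T1A, RB = 1.0 / T1B;
  const double M0A = 1.0 - psr, M0B = psr;
  const double w = 2.0 * M_PI * f_eff_hz;
  const double rrfb = M_PI * (w1x * w1x + w1y * w1y) * G;

  A.zeros(4, 4);
  b.zeros(4);
  A(0, 0) = -1.0 / T2A; A(0, 1) = -w;         A(0, 2) = -w1y;
  A(1, 0) = w;          A(1, 1) = -1.0 / T2A; A(1, 2) = w1x;
  A(2, 0) = w1y;        A(2, 1) = -w1x;
  A(2, 2) = -(RA + R * M0B);                  A(2, 3) = R * M0A;
  A(3, 2) = R * M0B;    A(3, 3) = -(RB + rrfb + R * M0A);
  b[2] = RA * M0A;
  b[3] = RB * M0B;
}

static void step_affine(const arma::mat& A, const arma::vec& b, double dt,
                        arma::mat& Phi, arma::vec& bstep) {
  arma::mat Aug(5, 5, arma::fill::zeros);
  Aug.submat(0, 0, 3, 3) = A;
  Aug.submat(0, 4, 3, 4) = b;
  arma::mat E = arma::expmat(Aug * dt);
  Phi = E.submat(0, 0, 3, 3);
  bstep = E.submat(0, 4, 3, 4);
}

//' @noRd
// [[Rcpp::export(name = ".bmc_pulse_affine")]]
List bmc_pulse_affine(NumericVector tissue, NumericVector w1re,
                      NumericVector w1im, double f_eff_hz, double G,
                      double dt) {
  arma::vec tis(tissue.begin(), tissue.size());
  const int n = w1re.size();
  arma::mat Phi(4, 4, arma::fill::eye), A;
  arma::vec b(4, arma::fill::zeros), bv, bstep;
  arma::mat Pstep;
  for (int i = 0; i < n; ++i) {
    build_A_b(tis, w1re[i], w1im[i], f_eff_hz, G, A, bv);
    step_affine(A, bv, dt, Pstep, bstep);
    Phi = Pstep * Phi;
    b = Pstep * b + bstep;
  }
  return List::create(_["Phi"] = wrap(Phi), _["b"] = wrap(b));
}

//' @noRd
// [[Rcpp::export(name = ".bmc_free_affine")]]
List bmc_free_affine(NumericVector tissue, double f_hz, double duration) {
  arma::vec tis(tissue.begin(), tissue.size());
  arma::mat A, Phi;
  arma::vec b, bstep;
  build_A_b(tis, 0.0, 0.0, f_hz, 0.0, A, b);
  step_affine(A, b, duration, Phi, bstep);
  return List::create(_["Phi"] = wrap(Phi), _["b"] = wrap(bstep));
}
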