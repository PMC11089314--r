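// MUSCL-Rusanov right-hand side for the 1-D vessel equations.
// Mirrors the scheme documented in R/vessel.R: minmod-limited
// reconstruction of (P, U) at interior faces, Rusanov numerical fluxes,
// exact boundary-face fluxes, and the 22*pi*mu*U/(rho*A) friction sink.

#include <Rcpp.h>
using namespace Rcpp;

static inline double minmod(double a, double b) {
  if (a > 0.0 && b > 0.0) return a < b ? a : b;
  if (a < 0.0 && b < 0.0) return a > b ? a : b;
  return 0.0;
}

// [[Rcpp::export(name = ".muscl_rhs_cpp")]]
List muscl_rhs_cpp(NumericVector A, NumericVector U,
                   NumericVector bA0_cell, NumericVector sA0_cell,
                   NumericVector A0_face,
                   double P0, double c0, double rho, double dx,
                   double A_in, double U_in, double A_out, double U_out,
                   double bA0_face_in, double sA0_face_in,
                   double bA0_face_out, double sA0_face_out,
                   double mu) {
  const int N = A.size();
  const double two_rc2 = 2.0 * rho * c0 * c0;
  const double fric_c = 22.0 * M_PI * mu / rho;

  std::vector<double> P(N), sP(N, 0.0), sU(N, 0.0);
  for (int i = 0; i < N; ++i)
    P[i] = P0 + bA0_cell[i] * (std::sqrt(A[i]) - sA0_cell[i]);
  for (int i = 1; i < N - 1; ++i) {
    sP[i] = minmod(P[i] - P[i - 1], P[i + 1] - P[i]);
    sU[i] = minmod(U[i] - U[i - 1], U[i + 1] - U[i]);
  }

  // face fluxes, 0..N (0 and N are the boundary faces)
  std::vector<double> Fm(N + 1), Gm(N + 1);
  const double P_b_in = P0 + bA0_face_in * (std::sqrt(A_in) - sA0_face_in);
  const double P_b_out = P0 + bA0_face_out * (std::sqrt(A_out) - sA0_face_out);
  Fm[0] = A_in * U_in;
  Gm[0] = 0.5 * U_in * U_in + P_b_in / rho;
  Fm[N] = A_out * U_out;
  Gm[N] = 0.5 * U_out * U_out + P_b_out / rho;

  for (int f = 1; f < N; ++f) {
    const int iL = f - 1, iR = f;
    const double P_L = P[iL] + 0.5 * sP[iL], P_R = P[iR] - 0.5 * sP[iR];
    const double U_L = U[iL] + 0.5 * sU[iL], U_R = U[iR] - 0.5 * sU[iR];
    double r_L = 1.0 + (P_L - P0) / two_rc2;
    double r_R = 1.0 + (P_R - P0) / two_rc2;
    if (r_L < 0.05) r_L = 0.05;
    if (r_R < 0.05) r_R = 0.05;
    const double A0f = A0_face[f];  // A0_face has length N+1, face f index f
    const double A_L = A0f * r_L * r_L, A_R = A0f * r_R * r_R;
    const double c_L = c0 * std::sqrt(r_L), c_R = c0 * std::sqrt(r_R);
    const double sL = std::fabs(U_L) + c_L, sR = std::fabs(U_R) + c_R;
    const double smax = sL > sR ? sL : sR;
    Fm[f] = 0.5 * (A_L * U_L + A_R * U_R) - 0.5 * smax * (A_R - A_L);
    Gm[f] = 0.5 * (0.5 * U_L * U_L + P_L / rho + 0.5 * U_R * U_R + P_R / rho)
            - 0.5 * smax * (U_R - U_L);
  }

  NumericVector dA(N), dU(N);
  for (int i = 0; i < N; ++i) {
    dA[i] = -(Fm[i + 1] - Fm[i]) / dx;
    dU[i] = -(Gm[i + 1] - Gm[i]) / dx - fric_c * U[i] / A[i];
  }
  return List::create(_["dA"] = dA, _["dU"] = dU,
                      _["F_in"] = Fm[0], _["F_out"] = Fm[N]);
}
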