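// Compiled core of the MEST adaptive-foraging vector field.
//
// State layout (length 2n + 4):
//   y[0]            F0   mutualist biomass
//   y[1 .. n]       Fi   exploiter biomasses
//   y[n+1]          C    specialist predator biomass
//   y[n+2]          P    top predator biomass
//   y[n+3 .. 2n+3]  theta_j, foraging efforts of P on F0..Fn
// theta_C = 1 - sum(theta) is always derived, never stored.
//
// Parameter pack layout (see pack_params() in R/params.R):
//   [0]  n
//   [1]  r0    [2] alpha0 [3] alphaC [4] alphaP [5] aC
//   [6]  u0    [7] uC     [8] q      [9] eC     [10] eP
//   [11] d0    [12] dC    [13] dP    [14] g
//   [15 .. 15+n-1]        ri
//   [15+n .. 15+2n-1]     ui
//   [15+2n .. 15+3n-1]    di
//   [15+3n]               0 = shared scalar beta, 1 = full matrix
//   then beta scalar, or (n+1)^2 entries column-major; beta[j,i] is the
//   competitive effect of species j on species i over {F0, F1..Fn}.

#include <Rcpp.h>
using namespace Rcpp;

namespace {

struct Pack {
  int n;
  double r0, alpha0, alphaC, alphaP, aC, u0, uC, q, eC, eP, d0, dC, dP, g;
  const double *ri, *ui, *di;
  bool beta_mat;
  double beta;          // scalar case
  const double *betam;  // matrix case, (n+1)x(n+1) column-major
  double beta_ji(int j, int i) const {  // effect of j on i, j,i in 0..n
    if (j == i) return 0.0;
    return beta_mat ? betam[j + (n + 1) * i] : beta;
  }
};

Pack unpack(const NumericVector &p) {
  Pack k;
  k.n = (int)p[0];
  k.r0 = p[1]; k.alpha0 = p[2]; k.alphaC = p[3]; k.alphaP = p[4];
  k.aC = p[5]; k.u0 = p[6]; k.uC = p[7]; k.q = p[8];
  k.eC = p[9]; k.eP = p[10]; k.d0 = p[11]; k.dC = p[12]; k.dP = p[13];
  k.g = p[14];
  k.ri = &p[15];
  k.ui = &p[15 + k.n];
  k.di = &p[15 + 2 * k.n];
  int off = 15 + 3 * k.n;
  k.beta_mat = p[off] != 0.0;
  if (k.beta_mat) { k.beta = NA_REAL; k.betam = &p[off + 1]; }
  else            { k.beta = p[off + 1]; k.betam = nullptr; }
  return k;
}

const double EPS_CAP = 1e-12;  // F0 clamp inside the capacity F0/q only
// Cap on the exploiter per-capita decline rate. When the mutualist collapses
// the capacity F0/q -> 0 and the raw bracket diverges like -ri*q*Fi/F0; the
// cap bounds the decline at 1000 per unit time (a doomed exploiter still
// crosses the 1e-12 extinction threshold from biomass 1 within 0.03 time
// units) and keeps the field integrable without altering survivor sets.
const double BRACKET_CAP = 1e3;

// consumption rate of P on resource k (k = 0..n over F0..Fn)
inline double u_of(const Pack &k, int j) { return j == 0 ? k.u0 : k.ui[j - 1]; }

void derivs(const Pack &k, const double *y, double *dy) {
  int n = k.n;
  const double *F = y;             // F[0] = F0, F[1..n] exploiters
  double C = y[n + 1], P = y[n + 2];
  const double *th = y + n + 3;

  double Ssp = 0.0;                // sum of F0..Fn (shared-beta fast path)
  for (int i = 0; i <= n; ++i) Ssp += F[i];
  double Sth = 0.0;
  for (int j = 0; j <= n; ++j) Sth += th[j];
  double thC = 1.0 - Sth;

  // mutualist
  double comp0;
  if (k.beta_mat) {
    comp0 = 0.0;
    for (int i = 1; i <= n; ++i) comp0 += k.beta_ji(i, 0) * F[i];
  } else comp0 = k.beta * (Ssp - F[0]);
  double B0 = k.r0 - k.alpha0 * F[0] - comp0 - k.aC * C - th[0] * k.u0 * P - k.d0;
  dy[0] = F[0] * B0;

  // exploiters; mutualist-set capacity K = F0/q (F0 clamped from below),
  // entering as 1 - Fi*q/F0; q = 0 removes the mutualist dependence
  double F0c = F[0] > EPS_CAP ? F[0] : EPS_CAP;
  double invK = k.q / F0c;
  for (int i = 1; i <= n; ++i) {
    double comp;
    if (k.beta_mat) {
      comp = 0.0;
      for (int j = 0; j <= n; ++j) if (j != i) comp += k.beta_ji(j, i) * F[j];
    } else comp = k.beta * (Ssp - F[i]);
    double Bi = k.ri[i - 1] * (1.0 - F[i] * invK) - comp -
                th[i] * k.ui[i - 1] * P - k.di[i - 1];
    if (Bi < -BRACKET_CAP) Bi = -BRACKET_CAP;
    dy[i] = F[i] * Bi;
  }

  // specialist predator
  double BC = k.eC * k.aC * F[0] - thC * k.uC * P - k.dC - k.alphaC * C;
  dy[n + 1] = C * BC;

  // top predator fitness W_P
  double gain = 0.0;
  for (int j = 0; j <= n; ++j) gain += th[j] * u_of(k, j) * F[j];
  double WP = k.eP * gain + k.eP * thC * k.uC * C - k.dP - k.alphaP * P;
  dy[n + 2] = P * WP;

  // replicator on the full simplex: mean gradient includes theta_C * w_C
  double wC = k.eP * k.uC * C;
  double wbar = thC * wC;
  for (int j = 0; j <= n; ++j) wbar += th[j] * k.eP * u_of(k, j) * F[j];
  for (int j = 0; j <= n; ++j) {
    double wj = k.eP * u_of(k, j) * F[j];
    dy[n + 3 + j] = k.g * th[j] * (wj - wbar);
  }
}

// analytic Jacobian of the full field in the independent coordinates
// (F0..Fn, C, P, theta_0..theta_n); theta_C-mediated terms use
// d(theta_C)/d(theta_j) = -1.  J is (2n+4)^2, column-major, J(a,b) = dfa/dyb.
void jac(const Pack &k, const double *y, double *J) {
  int n = k.n, d = 2 * n + 4;
  const double *F = y;
  double C = y[n + 1], P = y[n + 2];
  const double *th = y + n + 3;
  int iC = n + 1, iP = n + 2, iT = n + 3;

  std::fill(J, J + d * d, 0.0);
  double Ssp = 0.0, Sth = 0.0;
  for (int i = 0; i <= n; ++i) Ssp += F[i];
  for (int j = 0; j <= n; ++j) Sth += th[j];
  double thC = 1.0 - Sth;
  double F0c = F[0] > EPS_CAP ? F[0] : EPS_CAP;
  double invK = k.q / F0c;

  auto at = [&](int a, int b) -> double & { return J[a + d * b]; };

  // row F0
  double comp0 = k.beta_mat ? 0.0 : k.beta * (Ssp - F[0]);
  if (k.beta_mat) for (int i = 1; i <= n; ++i) comp0 += k.beta_ji(i, 0) * F[i];
  double B0 = k.r0 - k.alpha0 * F[0] - comp0 - k.aC * C - th[0] * k.u0 * P - k.d0;
  at(0, 0) = B0 - k.alpha0 * F[0];
  for (int i = 1; i <= n; ++i) at(0, i) = -k.beta_ji(i, 0) * F[0];
  at(0, iC) = -k.aC * F[0];
  at(0, iP) = -th[0] * k.u0 * F[0];
  at(0, iT + 0) = -k.u0 * P * F[0];

  // rows Fi
  for (int i = 1; i <= n; ++i) {
    double comp;
    if (k.beta_mat) {
      comp = 0.0;
      for (int j = 0; j <= n; ++j) if (j != i) comp += k.beta_ji(j, i) * F[j];
    } else comp = k.beta * (Ssp - F[i]);
    double ri = k.ri[i - 1], ui = k.ui[i - 1];
    double Bi = ri * (1.0 - F[i] * invK) - comp - th[i] * ui * P - k.di[i - 1];
    if (Bi < -BRACKET_CAP) {         // capped decline: dFi = -CAP * Fi
      at(i, i) = -BRACKET_CAP;
      continue;
    }
    // capacity term d/dF0 [ -ri q Fi / F0 ] = ri q Fi / F0^2; 0 when clamped
    double dcap = F[0] > EPS_CAP ? ri * k.q * F[i] / (F0c * F0c) : 0.0;
    at(i, 0) = F[i] * (dcap - k.beta_ji(0, i));
    at(i, i) = Bi - F[i] * ri * invK;
    for (int j = 1; j <= n; ++j)
      if (j != i) at(i, j) = -k.beta_ji(j, i) * F[i];
    at(i, iP) = -th[i] * ui * F[i];
    at(i, iT + i) = -ui * P * F[i];
  }

  // row C
  double BC = k.eC * k.aC * F[0] - thC * k.uC * P - k.dC - k.alphaC * C;
  at(iC, 0) = k.eC * k.aC * C;
  at(iC, iC) = BC - k.alphaC * C;
  at(iC, iP) = -thC * k.uC * C;
  for (int j = 0; j <= n; ++j) at(iC, iT + j) = k.uC * P * C;

  // row P
  double gain = 0.0;
  for (int j = 0; j <= n; ++j) gain += th[j] * u_of(k, j) * F[j];
  double WP = k.eP * gain + k.eP * thC * k.uC * C - k.dP - k.alphaP * P;
  for (int j = 0; j <= n; ++j) at(iP, j) = k.eP * th[j] * u_of(k, j) * P;
  at(iP, iC) = k.eP * thC * k.uC * P;
  at(iP, iP) = WP - k.alphaP * P;
  for (int j = 0; j <= n; ++j)
    at(iP, iT + j) = P * k.eP * (u_of(k, j) * F[j] - k.uC * C);

  // rows theta_j
  double wC = k.eP * k.uC * C;
  double wbar = thC * wC;
  for (int j = 0; j <= n; ++j) wbar += th[j] * k.eP * u_of(k, j) * F[j];
  for (int j = 0; j <= n; ++j) {
    double wj = k.eP * u_of(k, j) * F[j];
    // biomass columns: dw_j/dF_k = delta_jk eP u_j; dwbar/dF_k = theta_k eP u_k
    for (int kk = 0; kk <= n; ++kk) {
      double term = (kk == j ? k.eP * u_of(k, j) : 0.0) -
                    th[kk] * k.eP * u_of(k, kk);
      at(iT + j, kk) = k.g * th[j] * term;
    }
    at(iT + j, iC) = -k.g * th[j] * thC * k.eP * k.uC;
    // effort columns: dwbar/dtheta_l = w_l - w_C
    for (int l = 0; l <= n; ++l) {
      double wl = k.eP * u_of(k, l) * F[l];
      double v = -k.g * th[j] * (wl - wC);
      if (l == j) v += k.g * (wj - wbar);
      at(iT + j, iT + l) = v;
    }
  }
}

}  // namespace

// [[Rcpp::export]]
NumericVector mest_rhs_cpp(NumericVector y, NumericVector pack) {
  Pack k = unpack(pack);
  NumericVector dy(y.size());
  derivs(k, REAL(y), REAL(dy));
  return dy;
}

// [[Rcpp::export]]
NumericMatrix mest_jac_cpp(NumericVector y, NumericVector pack) {
  Pack k = unpack(pack);
  int d = 2 * k.n + 4;
  NumericMatrix J(d, d);
  jac(k, REAL(y), REAL(J));
  return J;
}

// Per-capita (bracket) growth terms whose zeros define coexistence
// equilibria: B0, Bi (i=1..n), BC, WP over (F0, F1..Fn, C, P).
// [[Rcpp::export]]
NumericVector mest_brackets_cpp(NumericVector y, NumericVector pack) {
  Pack k = unpack(pack);
  int n = k.n;
  const double *F = REAL(y);
  double C = y[n + 1], P = y[n + 2];
  const double *th = REAL(y) + n + 3;
  NumericVector out(n + 3);
  double Ssp = 0.0, Sth = 0.0;
  for (int i = 0; i <= n; ++i) Ssp += F[i];
  for (int j = 0; j <= n; ++j) Sth += th[j];
  double thC = 1.0 - Sth;
  double comp0;
  if (k.beta_mat) {
    comp0 = 0.0;
    for (int i = 1; i <= n; ++i) comp0 += k.beta_ji(i, 0) * F[i];
  } else comp0 = k.beta * (Ssp - F[0]);
  out[0] = k.r0 - k.alpha0 * F[0] - comp0 - k.aC * C - th[0] * k.u0 * P - k.d0;
  double F0c = F[0] > EPS_CAP ? F[0] : EPS_CAP;
  double invK = k.q / F0c;
  for (int i = 1; i <= n; ++i) {
    double comp;
    if (k.beta_mat) {
      comp = 0.0;
      for (int j = 0; j <= n; ++j) if (j != i) comp += k.beta_ji(j, i) * F[j];
    } else comp = k.beta * (Ssp - F[i]);
    double Bi = k.ri[i - 1] * (1.0 - F[i] * invK) - comp -
                th[i] * k.ui[i - 1] * P - k.di[i - 1];
    out[i] = Bi < -BRACKET_CAP ? -BRACKET_CAP : Bi;
  }
  out[n + 1] = k.eC * k.aC * F[0] - thC * k.uC * P - k.dC - k.alphaC * C;
  double gain = 0.0;
  for (int j = 0; j <= n; ++j) gain += th[j] * u_of(k, j) * F[j];
  out[n + 2] = k.eP * gain + k.eP * thC * k.uC * C - k.dP - k.alphaP * P;
  return out;
}

// Augmented field for tangent-space (Benettin) propagation: y is the full
// state followed by a d_alive x m tangent matrix restricted to the alive
// coordinates given in idx (0-based).
// [[Rcpp::export]]
NumericVector mest_rhs_tangent_cpp(NumericVector y, NumericVector pack,
                                   IntegerVector idx, int m) {
  Pack k = unpack(pack);
  int d = 2 * k.n + 4, da = idx.size();
  NumericVector dy(y.size());
  derivs(k, REAL(y), REAL(dy));
  std::vector<double> J(d * d);
  jac(k, REAL(y), J.data());
  const double *Phi = REAL(y) + d;
  double *dPhi = REAL(dy) + d;
  for (int c = 0; c < m; ++c)
    for (int a = 0; a < da; ++a) {
      double s = 0.0;
      for (int b = 0; b < da; ++b)
        s += J[idx[a] + d * idx[b]] * Phi[b + da * c];
      dPhi[a + da * c] = s;
    }
  return dy;
}
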