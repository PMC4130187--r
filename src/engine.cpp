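// Explicit-Euler co-simulation engine for the coupled tissue / lymph-node
// immune model.  Mirrors the R reference right-hand sides exactly:
// synchronous (pre-step) evaluation, 7-point Neumann Laplacian with
// clamped (mirrored) boundary indices, clamp-to-zero with counting.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

struct Grid {
  int nx, ny, nz;
  double ix2, iy2, iz2; // 1/dx^2 etc.
  inline int at(int i, int j, int k) const { return i + nx * (j + ny * k); }
};

inline double lap(const std::vector<double>& f, const Grid& g,
                  int i, int j, int k) {
  const double c = f[g.at(i, j, k)];
  const int im = i > 0 ? i - 1 : 0, ip = i < g.nx - 1 ? i + 1 : g.nx - 1;
  const int jm = j > 0 ? j - 1 : 0, jp = j < g.ny - 1 ? j + 1 : g.ny - 1;
  const int km = k > 0 ? k - 1 : 0, kp = k < g.nz - 1 ? k + 1 : g.nz - 1;
  return (f[g.at(im, j, k)] - 2.0 * c + f[g.at(ip, j, k)]) * g.ix2 +
         (f[g.at(i, jm, k)] - 2.0 * c + f[g.at(i, jp, k)]) * g.iy2 +
         (f[g.at(i, j, km)] - 2.0 * c + f[g.at(i, j, kp)]) * g.iz2;
}

std::vector<double> as_vec(const NumericVector& x) {
  return std::vector<double>(x.begin(), x.end());
}

} // namespace

// [[Rcpp::export]]
List run_engine(NumericVector A_in, NumericVector MR_in, NumericVector MA_in,
                NumericVector F_in, NumericVector lymph_in,
                NumericVector theta_bv, NumericVector theta_lv,
                IntegerVector dims, NumericVector spacing, double voxel_volume,
                List params, double dt, int iter_per_day, int num_days,
                double tol, bool stop_on_tol, int record_stride,
                IntegerVector snapshot_days) {
  Grid g;
  g.nx = dims[0]; g.ny = dims[1]; g.nz = dims[2];
  g.ix2 = 1.0 / (spacing[0] * spacing[0]);
  g.iy2 = 1.0 / (spacing[1] * spacing[1]);
  g.iz2 = 1.0 / (spacing[2] * spacing[2]);
  const int n = g.nx * g.ny * g.nz;
  const double dV = voxel_volume;

  // parameters
  const double beta_A = params["beta_A"], k_A = params["k_A"],
    mu_A = params["mu_A"], lambda_MR = params["lambda_MR"],
    lambda_MA = params["lambda_MA"], lambda_AF_MR = params["lambda_AF_MR"],
    lambda_AF_MA = params["lambda_AF_MA"], D_A = params["D_A"],
    mu_MR = params["mu_MR"], gamma_MA = params["gamma_MA"],
    alpha_MR = params["alpha_MR"], D_MR = params["D_MR"],
    MR_star = params["MR_star"], mu_MA = params["mu_MA"],
    alpha_MA = params["alpha_MA"], D_MA = params["D_MA"],
    D_F = params["D_F"], alpha_F = params["alpha_F"], V_LN = params["V_LN"],
    b_T = params["b_T"], rho_T = params["rho_T"], b_p = params["b_p"],
    alpha_T = params["alpha_T"], T_star = params["T_star"],
    b_p_b = params["b_p_b"], rho_B = params["rho_B"],
    alpha_B = params["alpha_B"], B_star = params["B_star"],
    b_p_p = params["b_p_p"], rho_P = params["rho_P"],
    alpha_P = params["alpha_P"], P_star = params["P_star"],
    rho_F = params["rho_F"];

  std::vector<double> A = as_vec(A_in), MR = as_vec(MR_in),
    MA = as_vec(MA_in), Fb = as_vec(F_in);
  std::vector<double> A2(n), MR2(n), MA2(n), F2(n);
  std::vector<double> tBV = as_vec(theta_bv), tLV = as_vec(theta_lv);

  std::vector<int> bv_idx, lv_idx;
  for (int p = 0; p < n; ++p) {
    if (tBV[p] > 0) bv_idx.push_back(p);
    if (tLV[p] > 0) lv_idx.push_back(p);
  }
  const double V_BV = bv_idx.size() * dV, V_LV = lv_idx.size() * dV;

  double MAL = lymph_in[0], Tc = lymph_in[1], Bc = lymph_in[2],
    Pc = lymph_in[3], FL = lymph_in[4];

  double clamp_count = 0.0;
  const int n_rec_max = num_days / std::max(record_stride, 1) + 2;
  NumericVector rec_day(n_rec_max);
  NumericMatrix rec(n_rec_max, 10); // A MR MA F MAL T B P FL total_A
  int n_rec = 0;

  std::vector<bool> want_snap(num_days + 1, false);
  for (int s = 0; s < snapshot_days.size(); ++s) {
    int d = snapshot_days[s];
    if (d >= 0 && d <= num_days) want_snap[d] = true;
  }
  List snaps;
  CharacterVector snap_names;

  auto field_mean = [&](const std::vector<double>& f) {
    double s = 0.0;
    for (int p = 0; p < n; ++p) s += f[p];
    return s / n;
  };
  auto total_antigen = [&]() {
    double s = 0.0;
    for (int p = 0; p < n; ++p) s += A[p];
    return s * dV;
  };
  auto record = [&](int day) {
    rec_day[n_rec] = day;
    rec(n_rec, 0) = field_mean(A);
    rec(n_rec, 1) = field_mean(MR);
    rec(n_rec, 2) = field_mean(MA);
    rec(n_rec, 3) = field_mean(Fb);
    rec(n_rec, 4) = MAL; rec(n_rec, 5) = Tc; rec(n_rec, 6) = Bc;
    rec(n_rec, 7) = Pc; rec(n_rec, 8) = FL;
    rec(n_rec, 9) = total_antigen();
    ++n_rec;
  };
  auto take_snapshot = [&](int day) {
    IntegerVector d3 = IntegerVector::create(g.nx, g.ny, g.nz);
    NumericVector a(A.begin(), A.end()), mr(MR.begin(), MR.end()),
      ma(MA.begin(), MA.end()), f(Fb.begin(), Fb.end());
    a.attr("dim") = d3; mr.attr("dim") = d3; ma.attr("dim") = d3;
    f.attr("dim") = d3;
    snaps.push_back(List::create(_["A"] = a, _["M_R"] = mr, _["M_A"] = ma,
                                 _["F"] = f));
    snap_names.push_back(std::to_string(day));
  };
  auto check_finite = [&](int day) {
    const char* nm[4] = {"A", "M_R", "M_A", "F"};
    const std::vector<double>* fl[4] = {&A, &MR, &MA, &Fb};
    for (int v = 0; v < 4; ++v)
      for (int p = 0; p < n; ++p)
        if (!std::isfinite((*fl[v])[p])) {
          int i = p % g.nx, j = (p / g.nx) % g.ny, k = p / (g.nx * g.ny);
          stop("non-finite value in field %s at voxel (%d, %d, %d), day %d",
               nm[v], i + 1, j + 1, k + 1, day);
        }
    const char* lm[5] = {"M_A_L", "T", "B", "P", "F_L"};
    double lv[5] = {MAL, Tc, Bc, Pc, FL};
    for (int v = 0; v < 5; ++v)
      if (!std::isfinite(lv[v]))
        stop("non-finite value in lymph variable %s, day %d", lm[v], day);
  };

  record(0);
  if (want_snap[0]) take_snapshot(0);

  int elim_day = -1;
  bool stopped_on_tol = false;
  if (stop_on_tol && total_antigen() <= tol) { // degenerate start
    elim_day = 0;
    stopped_on_tol = true;
  }

  int day = 0;
  while (day < num_days && !stopped_on_tol) {
    for (int it = 0; it < iter_per_day; ++it) {
      // coupling summary at the pre-step state
      double MAT = 0.0, FT = 0.0;
      if (!lv_idx.empty()) {
        for (size_t q = 0; q < lv_idx.size(); ++q) MAT += MA[lv_idx[q]];
        MAT = MAT * dV / V_LV;
      }
      if (!bv_idx.empty()) {
        for (size_t q = 0; q < bv_idx.size(); ++q) FT += Fb[bv_idx[q]];
        FT = FT * dV / V_BV;
      }
      // lymph derivatives (pre-step state)
      const double dMAL = V_LV > 0 ? alpha_MA * (MAT - MAL) * V_LV / V_LN : 0.0;
      const double dT = b_T * (rho_T - 1.0) * Tc * MAL -
        b_p * MAL * Tc * Bc + alpha_T * (T_star - Tc);
      const double dB = b_p_b * (rho_B * Tc * MAL - Tc * MAL * Bc) +
        alpha_B * (B_star - Bc);
      const double dP = b_p_p * rho_P * Tc * MAL * Bc + alpha_P * (P_star - Pc);
      const double dFL = rho_F * Pc -
        (V_BV > 0 ? alpha_F * (FL - FT) * V_BV / V_LN : 0.0);

      // tissue fields, synchronous update
      for (int k = 0; k < g.nz; ++k)
        for (int j = 0; j < g.ny; ++j)
          for (int i = 0; i < g.nx; ++i) {
            const int p = g.at(i, j, k);
            const double a = A[p], mr = MR[p], ma = MA[p], f = Fb[p];
            const double rA = beta_A * a * (1.0 - a / k_A) - mu_A * a -
              lambda_MR * mr * a - lambda_MA * a * ma -
              lambda_AF_MR * a * f * mr - lambda_AF_MA * a * f * ma +
              D_A * lap(A, g, i, j, k);
            const double rMR = -mu_MR * mr - gamma_MA * mr * a +
              alpha_MR * tBV[p] * (MR_star - mr) + D_MR * lap(MR, g, i, j, k);
            const double rMA = -mu_MA * ma + gamma_MA * mr * a +
              D_MA * lap(MA, g, i, j, k) - alpha_MA * tLV[p] * (ma - MAL);
            const double rF = -lambda_AF_MR * f * a * mr -
              lambda_AF_MA * f * a * ma + D_F * lap(Fb, g, i, j, k) +
              alpha_F * tBV[p] * (FL - f);
            double na = a + dt * rA, nmr = mr + dt * rMR,
              nma = ma + dt * rMA, nf = f + dt * rF;
            if (na < 0) { na = 0; clamp_count += 1; }
            if (nmr < 0) { nmr = 0; clamp_count += 1; }
            if (nma < 0) { nma = 0; clamp_count += 1; }
            if (nf < 0) { nf = 0; clamp_count += 1; }
            A2[p] = na; MR2[p] = nmr; MA2[p] = nma; F2[p] = nf;
          }
      A.swap(A2); MR.swap(MR2); MA.swap(MA2); Fb.swap(F2);

      MAL += dt * dMAL; Tc += dt * dT; Bc += dt * dB; Pc += dt * dP;
      FL += dt * dFL;
      if (MAL < 0) { MAL = 0; clamp_count += 1; }
      if (Tc < 0) { Tc = 0; clamp_count += 1; }
      if (Bc < 0) { Bc = 0; clamp_count += 1; }
      if (Pc < 0) { Pc = 0; clamp_count += 1; }
      if (FL < 0) { FL = 0; clamp_count += 1; }
    }
    ++day;
    check_finite(day);
    const double tot = total_antigen();
    if (elim_day < 0 && tot <= tol) elim_day = day;
    const bool due = (day % std::max(record_stride, 1) == 0) ||
      day == num_days || (stop_on_tol && tot <= tol);
    if (due) record(day);
    if (want_snap[day]) take_snapshot(day);
    if (stop_on_tol && tot <= tol) { stopped_on_tol = true; break; }
    Rcpp::checkUserInterrupt();
  }

  if (snaps.size() > 0) snaps.attr("names") = snap_names;
  return List::create(
    _["day"] = rec_day[Range(0, n_rec - 1)],
    _["series"] = rec(Range(0, n_rec - 1), _),
    _["elimination_day"] = elim_day,
    _["clamp_count"] = clamp_count,
    _["stopped_on_tol"] = stopped_on_tol,
    _["snapshots"] = snaps,
    _["final"] = List::create(
      _["lymph"] = NumericVector::create(
        _["M_A_L"] = MAL, _["T"] = Tc, _["B"] = Bc, _["P"] = Pc,
        _["F_L"] = FL))
  );
}
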