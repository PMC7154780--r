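// Compiled translation of the monthly stage chain in R/simulate.R.
// Expression order mirrors the R code so both engines agree to float
// round-off; tests pin the two trajectories to 1e-10 relative.
#include <Rcpp.h>
using namespace Rcpp;

namespace {

// parameter indices: must match PARAM_NAMES in R/parameters.R
enum P {
  ALPHA_C, Y, K, FULL_CAN_AGE,
  T_MIN, T_OPT, T_MAX, K_FROST,
  COEFF_COND, SW_CONST, SW_POWER, MAX_COND, MIN_COND, LAI_GCX,
  BL_COND, MAX_INTCPTN, LAI_MAX_INTCPTN, SOIL_COND,
  FN0, FNN, M0,
  MAX_AGE, N_AGE, R_AGE,
  F_CALPHA700, F_CG700,
  PFS2, PFS20, P_RX, P_RN,
  GAMMA_F0, GAMMA_F1, T_GAMMA_F, GAMMA_R,
  W_SX1000, THIN_POWER, M_F, M_R, M_S,
  A_WS, N_WS, A_H, N_HB, A_V, N_VB, SLA0, SLA1, T_SLA,
  LEAF_GROW, LEAF_FALL, NPAR
};

const double MOLP = 4.6, GCMOL = 12.0, CFRAC = 0.5;
const double PM_E20 = 2.2, PM_RHO = 1.2, PM_LAMBDA = 2460000.0,
             PM_VPDC = 0.000622, PM_QA = -90.0, PM_QB = 0.8;

inline double esat(double t) {
  return 0.61078 * std::exp(17.269 * t / (237.3 + t));
}

inline double clamp01(double x) {
  return std::min(std::max(x, 0.0), 1.0);
}

inline int days_in_month(int year, int month) {
  static const int base[12] = {31, 28, 31, 30, 31, 30, 31, 31, 30, 31, 30, 31};
  int d = base[month - 1];
  bool leap = (year % 4 == 0 && year % 100 != 0) || (year % 400 == 0);
  if (month == 2 && leap) d = 29;
  return d;
}

inline double day_length(double latitude, int month) {
  static const int mid[12] = {15, 46, 74, 105, 135, 166, 196, 227, 258, 288,
                              319, 349};
  double doy = mid[month - 1];
  double decl = -23.45 * M_PI / 180.0 * std::cos(2 * M_PI * (doy + 10) / 365);
  double cosh0 = -std::tan(latitude * M_PI / 180.0) * std::tan(decl);
  cosh0 = std::min(std::max(cosh0, -1.0), 1.0);
  return 2 * std::acos(cosh0) / (2 * M_PI) * 86400.0;
}

inline double penman_monteith(double srad, double vpd, double h, double gc,
                              double bl) {
  if (gc <= 0) return 0.0;
  double net_rad = PM_QA + PM_QB * (srad * 1e6 / h);
  double def_term = PM_RHO * PM_LAMBDA * PM_VPDC * (vpd * 10) * bl;
  double div = gc * (1 + PM_E20) + bl;
  double e = gc * (PM_E20 * net_rad + def_term) / div;
  return std::max(e / PM_LAMBDA * h, 0.0);
}

inline double litterfall_rate(double age, double g0, double g1, double tg) {
  if (g1 == g0) return g1;
  double kg = std::log(1 + g1 / g0) / tg;
  return g1 * g0 / (g0 + (g1 - g0) * std::exp(-kg * age));
}

inline double sla_at(double age, double sla0, double sla1, double tsla) {
  return sla1 + (sla0 - sla1) * std::exp(-std::log(2.0) *
                                         (age / tsla) * (age / tsla));
}

// Self-thinning removal: bracketed Newton on the log-space constraint.
// Mirrors solve_thinning() in R/mortality.R expression for expression.
inline double solve_thinning(double n, double ws, double w_sx1000,
                             double thin_power, double m_s) {
  const double c0 = std::log(1000 * ws) - std::log(w_sx1000) -
    thin_power * std::log(1000.0);
  auto phi = [&](double x) {
    return std::log((1 - m_s) + m_s * x / n) +
           (thin_power - 1) * std::log(x) + c0;
  };
  auto dphi = [&](double x) {
    return (m_s / n) / ((1 - m_s) + m_s * x / n) + (thin_power - 1) / x;
  };
  if (phi(n) <= 0) return 0.0;
  double lo = 0.05 * n, hi = n;
  if (phi(lo) > 0) stop("mortality solver did not bracket a solution");
  double x = n;
  for (int i = 0; i < 100; ++i) {
    double step = phi(x) / dphi(x);
    double x_new = x - step;
    if (!(x_new > lo && x_new < hi)) x_new = (lo + hi) / 2;
    if (phi(x_new) > 0) hi = x_new; else lo = x_new;
    if (std::fabs(x_new - x) < 1e-11 || (hi - lo) < 1e-11) {
      x = x_new;
      break;
    }
    x = x_new;
  }
  return n - x;
}

} // namespace

// [[Rcpp::export]]
NumericMatrix run3pg_cpp(NumericMatrix climate, NumericVector site,
                         NumericVector params, NumericVector init,
                         NumericMatrix events) {
  const int n = climate.nrow();
  const double lat = site[0], asw_max = site[1], fr = site[2];
  const double *p = params.begin();
  if (params.size() != NPAR) stop("parameter vector has wrong length");

  double age = init[0], n_trees = init[1], ws = init[2], wf = init[3],
         wr = init[4], asw = init[5], wf_debt = init[6];

  NumericMatrix out(n, 21);
  int ev_i = 0, nev = events.nrow();

  // per-run constants
  double h_month[12];
  for (int m = 0; m < 12; ++m) h_month[m] = day_length(lat, m + 1);
  const double f_nutr = 1 - (1 - p[FN0]) * std::pow(1 - fr, p[FNN]);
  const double fax = p[F_CALPHA700] / (2 - p[F_CALPHA700]);
  const double fg0 = p[F_CG700] / (2 * p[F_CG700] - 1);
  const double n_p = std::log(p[PFS20] / p[PFS2]) / std::log(10.0);
  const double a_p = p[PFS2] / std::pow(2.0, n_p);

  // caches: permitted stand stem mass at the current stocking (updated only
  // when n_trees changes) and end-of-month SLA/DBH reused next month
  double thr_ws = n_trees > 0 ?
    p[W_SX1000] * std::pow(1000 / n_trees, p[THIN_POWER]) * n_trees / 1000 :
    R_PosInf;
  double sla_cache = NA_REAL, dbh_cache = NA_REAL;

  for (int i = 0; i < n; ++i) {
    int year = (int)climate(i, 0), month = (int)climate(i, 1);
    double tmin = climate(i, 2), tmax = climate(i, 3), prcp = climate(i, 4),
           srad = climate(i, 5), frost = climate(i, 6), co2 = climate(i, 7);
    if (ISNAN(co2)) co2 = 380.0;
    int ndays = days_in_month(year, month);

    // 1. phenology
    if (p[LEAF_GROW] > 0) {
      if (month == (int)p[LEAF_GROW]) { wf += wf_debt; wf_debt = 0.0; }
      if (month == (int)p[LEAF_FALL]) { wf_debt += wf; wf = 0.0; }
    }

    // 2. modifiers
    double t_av = (tmin + tmax) / 2;
    double vpd = 0.5 * (esat(tmax) - esat(tmin));
    double f_t;
    if (t_av <= p[T_MIN] || t_av >= p[T_MAX]) {
      f_t = 0.0;
    } else {
      f_t = ((t_av - p[T_MIN]) / (p[T_OPT] - p[T_MIN])) *
            std::pow((p[T_MAX] - t_av) / (p[T_MAX] - p[T_OPT]),
                     (p[T_MAX] - p[T_OPT]) / (p[T_OPT] - p[T_MIN]));
      f_t = clamp01(f_t);
    }
    double f_frost = clamp01(1 - p[K_FROST] * (frost / ndays));
    double f_vpd = std::exp(-p[COEFF_COND] * vpd * 10);
    double r_sw = clamp01(asw / asw_max);
    double f_sw = 1.0 / (1.0 + std::pow((1 - r_sw) / p[SW_CONST],
                                        p[SW_POWER]));
    double f_age = 1.0 / (1.0 + std::pow((age / p[MAX_AGE]) / p[R_AGE],
                                         p[N_AGE]));
    double f_calpha = fax * co2 / (350 * (fax - 1) + co2);
    double f_cg = fg0 / (1 + (fg0 - 1) * co2 / 350);
    double phys_mod = f_age * std::min(f_vpd, f_sw);

    // 3. production
    double sla = ISNAN(sla_cache) ? sla_at(age, p[SLA0], p[SLA1], p[T_SLA])
                                  : sla_cache;
    double lai = wf * sla * 0.1;
    double cover = p[FULL_CAN_AGE] > 0 ?
      std::min(age / p[FULL_CAN_AGE], 1.0) : 1.0;
    double par = 0.5 * srad * ndays;
    double apar = par * (1 - std::exp(-p[K] * lai)) * cover;
    double alpha_eff = p[ALPHA_C] * f_t * f_frost * f_nutr * f_calpha *
      phys_mod;
    double gpp = alpha_eff * apar * MOLP * GCMOL / CFRAC * 0.01;
    double npp = p[Y] * gpp;

    // 4. allocation + turnover, 5. mortality
    double n_died = 0.0;
    if (n_trees > 0) {
      double dbh = ISNAN(dbh_cache) ?
        std::pow(ws * 1000 / n_trees / p[A_WS], 1.0 / p[N_WS]) : dbh_cache;
      double m = p[M0] + (1 - p[M0]) * fr;
      double p_r = p[P_RX] * p[P_RN] /
        (p[P_RN] + (p[P_RX] - p[P_RN]) * phys_mod * m);
      double p_fs = a_p * std::pow(dbh, n_p);
      double p_s = (1 - p_r) / (1 + p_fs);
      double p_f = 1 - p_r - p_s;
      double gamma_f = litterfall_rate(age, p[GAMMA_F0], p[GAMMA_F1],
                                       p[T_GAMMA_F]);
      double litter = gamma_f * wf;
      double root_to = p[GAMMA_R] * wr;
      wf = std::max(wf + (npp * p_f - litter), 0.0);
      wr = std::max(wr + (npp * p_r - root_to), 0.0);
      ws = std::max(ws + npp * p_s, 0.0);

      // self-thinning mortality (bracketed Newton, same algorithm as R);
      // the cached threshold makes the common understocked case free
      if (ws > thr_ws) {
        double n0 = n_trees, ws0 = ws;
        n_died = solve_thinning(n0, ws0, p[W_SX1000], p[THIN_POWER], p[M_S]);
        if (n_died > 0) {
          double fracd = n_died / n0;
          n_trees = n0 - n_died;
          ws = ws0 * (1 - p[M_S] * fracd);
          wf = wf * (1 - p[M_F] * fracd);
          wr = wr * (1 - p[M_R] * fracd);
          thr_ws = p[W_SX1000] * std::pow(1000 / n_trees, p[THIN_POWER]) *
            n_trees / 1000;
        }
      }
    }

    // 6. water balance
    double gc = p[MAX_COND] * std::min(f_vpd, f_sw) * f_age * f_cg *
      std::min(lai / p[LAI_GCX], 1.0);
    gc = std::max(gc, p[MIN_COND]);
    double h = h_month[month - 1];
    double interception = p[MAX_INTCPTN] *
      std::min(lai / p[LAI_MAX_INTCPTN], 1.0) * prcp;
    double transp = gc > 0 ?
      penman_monteith(srad, vpd, h, gc, p[BL_COND]) * ndays : 0.0;
    double avail = std::max(asw + prcp - interception, 0.0);
    transp = std::min(transp, avail);
    double g_soil = p[SOIL_COND] * std::exp(-p[K] * lai);
    double soil_evap = penman_monteith(srad, vpd, h, g_soil, p[BL_COND]) *
      ndays;
    soil_evap = std::min(soil_evap, std::max(avail - transp, 0.0));
    double raw = asw + prcp - interception - transp - soil_evap;
    double clip = std::max(-raw, 0.0);
    double runoff = std::max(raw - asw_max, 0.0);
    asw = std::min(std::max(raw, 0.0), asw_max);

    // 7. management due this month
    double age_end = age + 1.0 / 12;
    while (ev_i < nev && events(ev_i, 0) <= age_end + 1e-9) {
      double residual = events(ev_i, 1);
      if (residual <= n_trees) {
        double removed = n_trees - residual;
        if (removed > 0) {
          double fracr = removed / n_trees;
          ws = std::max(ws * (1 - events(ev_i, 4) * fracr), 0.0);
          wf = std::max(wf * (1 - events(ev_i, 2) * fracr), 0.0);
          wr = std::max(wr * (1 - events(ev_i, 3) * fracr), 0.0);
          n_trees = residual;
          thr_ws = n_trees > 0 ?
            p[W_SX1000] * std::pow(1000 / n_trees, p[THIN_POWER]) *
              n_trees / 1000 : R_PosInf;
        }
      }
      ++ev_i;
    }

    // 8. age and derived attributes
    age = age + 1.0 / 12;
    double sla1m = sla_at(age, p[SLA0], p[SLA1], p[T_SLA]);
    sla_cache = sla1m;
    double lai1 = wf * sla1m * 0.1;
    double dbh1 = 0, height1 = 0, ba1 = 0, vol1 = 0;
    if (n_trees > 0) {
      double wst = ws * 1000 / n_trees;
      dbh1 = std::pow(wst / p[A_WS], 1.0 / p[N_WS]);
      height1 = p[A_H] * std::pow(dbh1, p[N_HB]);
      ba1 = M_PI * (dbh1 / 200) * (dbh1 / 200) * n_trees;
      vol1 = p[A_V] * std::pow(dbh1, p[N_VB]) * n_trees;
      dbh_cache = dbh1;
    } else {
      dbh_cache = NA_REAL;
    }

    out(i, 0) = year; out(i, 1) = month; out(i, 2) = age;
    out(i, 3) = n_trees; out(i, 4) = ws; out(i, 5) = wf; out(i, 6) = wr;
    out(i, 7) = asw; out(i, 8) = lai1; out(i, 9) = dbh1; out(i, 10) = height1;
    out(i, 11) = ba1; out(i, 12) = vol1; out(i, 13) = gpp; out(i, 14) = npp;
    out(i, 15) = transp; out(i, 16) = soil_evap; out(i, 17) = interception;
    out(i, 18) = runoff; out(i, 19) = clip; out(i, 20) = n_died;
  }
  return out;
}
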