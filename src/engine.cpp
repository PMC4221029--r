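// Closed-loop engine: plant integration, PD pathway, mossy/climbing-fiber
// encoding, AER hemisphere updates and plasticity, all at the 10 ms control
// period. Mirrors the R reference operations exactly (same arithmetic order)
// so the two routes can be cross-checked on small problems.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

namespace {

struct Plant {
  double m_eff, m_tot, L, delta, J, s_inertia, alpha, r, g, k_tau;
  double c_s, asym, c_th, fall_threshold;
};

Plant as_plant(const List& q) {
  Plant p;
  p.m_eff = q["m_eff"]; p.m_tot = q["m_tot"]; p.L = q["L"];
  p.delta = q["delta"]; p.J = q["J"]; p.s_inertia = q["s_inertia"];
  p.alpha = q["alpha"]; p.r = q["r"]; p.g = q["g"]; p.k_tau = q["k_tau"];
  p.c_s = q["c_s"]; p.asym = q["asym"]; p.c_th = q["c_th"];
  p.fall_threshold = q["fall_threshold"];
  return p;
}

inline double clip(double x, double lo, double hi) {
  return x < lo ? lo : (x > hi ? hi : x);
}
inline double sgn(double x) { return (x > 0) - (x < 0); }

// y = (s, th, s_dot, th_dot)
inline void deriv(const Plant& q, const double y[4], double tau, double dy[4]) {
  double cs = std::cos(y[1] + q.delta + q.alpha);
  double mlc = q.m_eff * q.L * cs;
  double fric = q.c_s * (1 + q.asym * sgn(y[2])) * y[2];
  double b1 = q.m_eff * q.L * std::sin(y[1] + q.delta + q.alpha) * y[3] * y[3] +
              tau / q.r - fric - q.m_tot * q.g * std::sin(q.alpha);
  double b2 = q.m_eff * q.g * q.L * std::sin(y[1] + q.delta) - tau -
              q.c_th * y[3];
  double det = q.s_inertia * q.J - mlc * mlc;
  dy[0] = y[2];
  dy[1] = y[3];
  dy[2] = (q.J * b1 - mlc * b2) / det;
  dy[3] = (q.s_inertia * b2 - mlc * b1) / det;
}

void rk4(const Plant& q, double y[4], double tau, double dt, int n_sub) {
  double h = dt / n_sub;
  double k1[4], k2[4], k3[4], k4[4], tmp[4];
  for (int i = 0; i < n_sub; ++i) {
    deriv(q, y, tau, k1);
    for (int j = 0; j < 4; ++j) tmp[j] = y[j] + h / 2 * k1[j];
    deriv(q, tmp, tau, k2);
    for (int j = 0; j < 4; ++j) tmp[j] = y[j] + h / 2 * k2[j];
    deriv(q, tmp, tau, k3);
    for (int j = 0; j < 4; ++j) tmp[j] = y[j] + h * k3[j];
    deriv(q, tmp, tau, k4);
    for (int j = 0; j < 4; ++j)
      y[j] += h / 6 * (k1[j] + 2 * k2[j] + 2 * k3[j] + k4[j]);
  }
}

struct Hemi {
  IntegerVector ptr, P, pfpk_idx;     // ptr length N+1; P, idx 0-based
  NumericVector W, W_PkVn;
  int mf_lo, mf_hi;                    // 0-based inclusive ranges
  std::vector<std::pair<int, int>> pop_ranges;  // gr, Go, ba, Pk order
  int pk_lo, pk_hi, n_pk;
  double w_max, cf_spont;
  std::vector<double> rates;
  bool active = false;
};

Hemi as_hemi(const List& h) {
  Hemi o;
  o.ptr = h["ptr"]; o.P = h["P"]; o.W = clone(as<NumericVector>(h["W"]));
  o.pfpk_idx = h["pfpk_idx"];
  o.W_PkVn = clone(as<NumericVector>(h["W_PkVn"]));
  o.mf_lo = h["mf_lo"]; o.mf_hi = h["mf_hi"];
  IntegerVector lo = h["pop_lo"], hi = h["pop_hi"];
  for (int i = 0; i < lo.size(); ++i)
    o.pop_ranges.push_back({lo[i], hi[i]});
  o.pk_lo = lo[lo.size() - 1]; o.pk_hi = hi[hi.size() - 1];
  o.n_pk = o.pk_hi - o.pk_lo + 1;
  o.w_max = h["w_max"]; o.cf_spont = h["cf_spont"];
  o.rates.assign(o.ptr.size() - 1, 0.5);
  o.active = true;
  return o;
}

// one staged update; mf rates already written into o.rates. relax is the
// first-order rate-relaxation factor (1 = memoryless saturated-affine unit)
void hemi_step(Hemi& o, double relax) {
  for (auto& pr : o.pop_ranges) {
    for (int id = pr.first; id <= pr.second; ++id) {
      double s = 0.0;
      for (int k = o.ptr[id]; k < o.ptr[id + 1]; ++k)
        s += o.W[k] * (o.rates[o.P[k]] - 0.5);
      double target = clip(0.5 + s, 0.0, 1.0);
      o.rates[id] = o.rates[id] + relax * (target - o.rates[id]);
    }
  }
}

void pfpk_update(Hemi& o, double cf, double gltd, double gltp) {
  int n = o.pfpk_idx.size();
  if (cf > o.cf_spont) {
    double g = gltd * cf;
    for (int i = 0; i < n; ++i) {
      int k = o.pfpk_idx[i];
      o.W[k] = clip(o.W[k] + g * o.rates[o.P[k]], 0.0, o.w_max);
    }
  } else if (cf < o.cf_spont) {
    for (int i = 0; i < n; ++i) {
      int k = o.pfpk_idx[i];
      o.W[k] = clip(o.W[k] + gltp * o.rates[o.P[k]], 0.0, o.w_max);
    }
  }
}

void pkvn_update(Hemi& o, double vn, double gvn) {
  double wcap = 2.0 / o.n_pk;
  for (int j = 0; j < o.n_pk; ++j)
    o.W_PkVn[j] = clip(o.W_PkVn[j] + gvn * vn * (o.rates[o.pk_lo + j] - 0.5),
                       0.0, wcap);
}

double pk_weighted(const Hemi& o) {
  double s = 0.0;
  for (int j = 0; j < o.n_pk; ++j) s += o.W_PkVn[j] * o.rates[o.pk_lo + j];
  return s;
}

} // namespace

// [[Rcpp::export(name = ".run_trial_cpp")]]
List run_trial_cpp(List ctrl, List plant_base, List plant_pert, List pd,
                   List cfp, List plast, NumericVector mf_ranges,
                   Nullable<List> left_, Nullable<List> right_,
                   Nullable<NumericMatrix> noise_) {
  const int controller = ctrl["controller"];   // 0 pd, 1 uni, 2 bicnn
  const int n_steps = ctrl["n_steps"];
  const double dt = ctrl["dt"];
  const int n_sub = ctrl["n_substeps"];
  const double freq = ctrl["freq"], amp = ctrl["amplitude"];
  const int onset = ctrl["onset_step"];        // -1 = never
  const double quant = ctrl["encoder_quant"];
  const double relax = ctrl["rate_relax"];

  Plant base = as_plant(plant_base), pert = as_plant(plant_pert);
  const double kp_th = pd["kp_th"], kd_th = pd["kd_th"];
  const double kp_ph = pd["kp_ph"], kd_ph = pd["kd_ph"];
  const double gain = cfp["error_gain"], wp = cfp["w_p"], wv = cfp["w_v"];
  const double gltd = plast["gamma_LTD"], gltp = plast["gamma_LTP"],
               gvn = plast["gamma_PkVn"];

  Hemi L, R;
  if (left_.isNotNull()) L = as_hemi(List(left_));
  if (right_.isNotNull()) R = as_hemi(List(right_));
  bool has_noise = noise_.isNotNull();
  NumericMatrix noise = has_noise ? NumericMatrix(noise_) :
                        NumericMatrix(1, 2);

  const int NC = 13;
  NumericMatrix log(n_steps, NC);
  double y[4] = {0, 0, 0, 0};  // s, th, s_dot, th_dot
  y[1] = as<double>(ctrl["theta0"]);
  bool fallen = false;
  int fall_step = -1;
  double eff_copy = 0.0;
  const double w = 2 * M_PI * freq;

  for (int i = 0; i < n_steps; ++i) {
    const Plant& q = (onset >= 0 && i >= onset) ? pert : base;
    double t = i * dt;
    double phi_ref = amp * std::sin(w * t);
    double phi_dot_ref = amp * w * std::cos(w * t);
    double theta = y[1], theta_dot = y[3];
    double phi = y[0] / q.r, phi_dot = y[2] / q.r;

    // sensors (optional gyro noise / encoder quantization)
    double th_m = theta, thd_m = theta_dot, ph_m = phi, phd_m = phi_dot;
    if (has_noise && i < noise.nrow()) {
      th_m += noise(i, 0); thd_m += noise(i, 1);
    }
    if (quant > 0) {
      ph_m = std::round(ph_m / quant) * quant;
      phd_m = std::round(phd_m / quant) * quant;
    }
    double theta_e = -th_m, theta_dot_e = -thd_m;
    double phi_e = phi_ref - ph_m, phi_dot_e = phi_dot_ref - phd_m;

    // climbing fibers
    double raw = gain * (wp * phi_e + wv * phi_dot_e);
    double cf_l = 0, cf_r = 0;
    if (controller == 2) {
      cf_l = clip(L.cf_spont + raw, 0.0, 1.0);
      cf_r = clip(R.cf_spont - raw, 0.0, 1.0);
    } else if (controller == 1) {
      cf_l = clip(L.cf_spont + std::fabs(raw), 0.0, 1.0);
    }

    double bic = 0.0;
    if (controller != 0 && !fallen) {
      // mossy encoding: 7 signals -> round-robin channels
      double sig[7] = {phi_ref, phi_dot_ref, theta_e, theta_dot_e,
                       phi_e, phi_dot_e, eff_copy};
      double r7[7];
      for (int k = 0; k < 7; ++k)
        r7[k] = clip(0.5 + 0.5 * sig[k] / mf_ranges[k], 0.0, 1.0);
      for (int k = L.mf_lo; k <= L.mf_hi; ++k)
        L.rates[k] = r7[(k - L.mf_lo) % 7];
      hemi_step(L, relax);
      if (controller == 2) {
        for (int k = R.mf_lo; k <= R.mf_hi; ++k)
          R.rates[k] = r7[(k - R.mf_lo) % 7];
        hemi_step(R, relax);
        bic = clip(pk_weighted(R) - pk_weighted(L), -1.0, 1.0);
      } else {
        bic = clip(pk_weighted(L) - 0.5, -1.0, 1.0);
      }
    }

    double pd_out = clip(kp_th * theta_e + kd_th * theta_dot_e +
                         kp_ph * phi_e + kd_ph * phi_dot_e, -1.0, 1.0);
    double vn = fallen ? 0.0 : clip(pd_out - bic, -1.0, 1.0);

    log(i, 0) = t; log(i, 1) = phi_ref; log(i, 2) = phi_dot_ref;
    log(i, 3) = theta; log(i, 4) = theta_dot;
    log(i, 5) = phi; log(i, 6) = phi_dot;
    log(i, 7) = pd_out; log(i, 8) = bic; log(i, 9) = vn;
    log(i, 10) = cf_l; log(i, 11) = cf_r; log(i, 12) = fallen ? 1.0 : 0.0;

    if (!fallen) {
      // plasticity (this step's cf, fresh pf rates, this step's vn)
      if (controller >= 1) {
        pfpk_update(L, cf_l, gltd, gltp);
        pkvn_update(L, vn, gvn);
      }
      if (controller == 2) {
        pfpk_update(R, cf_r, gltd, gltp);
        pkvn_update(R, vn, gvn);
      }
      rk4(q, y, q.k_tau * vn, dt, n_sub);
      for (int j = 0; j < 4; ++j)
        if (!std::isfinite(y[j]))
          stop("plant integration produced non-finite state at step %d", i);
      if (std::fabs(y[1]) > q.fall_threshold) {
        fallen = true;
        fall_step = i;
      }
      eff_copy = vn;
    }
  }

  List out = List::create(
      _["log"] = log, _["fall_step"] = fall_step,
      _["W_left"] = L.active ? (SEXP)L.W : R_NilValue,
      _["W_right"] = R.active ? (SEXP)R.W : R_NilValue,
      _["W_PkVn_left"] = L.active ? (SEXP)L.W_PkVn : R_NilValue,
      _["W_PkVn_right"] = R.active ? (SEXP)R.W_PkVn : R_NilValue);
  return out;
}

// single hemisphere update, for cross-checking against the R implementation
// [[Rcpp::export(name = ".aer_step_cpp")]]
NumericVector aer_step_cpp(IntegerVector ptr, IntegerVector P, NumericVector W,
                           IntegerVector pop_lo, IntegerVector pop_hi,
                           int mf_lo, int mf_hi, NumericVector rates,
                           NumericVector mf, double relax) {
  Hemi o;
  o.ptr = ptr; o.P = P; o.W = W;
  for (int i = 0; i < pop_lo.size(); ++i)
    o.pop_ranges.push_back({pop_lo[i], pop_hi[i]});
  o.rates.assign(rates.begin(), rates.end());
  for (int k = mf_lo; k <= mf_hi; ++k)
    o.rates[k] = clip(mf[k - mf_lo], 0.0, 1.0);
  hemi_step(o, relax);
  return NumericVector(o.rates.begin(), o.rates.end());
}
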