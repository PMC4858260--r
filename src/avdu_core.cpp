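// Compiled engine: AVDU array stepping, corridor ray-casting and the
// closed-loop flight trial. Step semantics are defined by the R reference
// implementations (step_array / run_avdu_array_ref); this file must stay
// exactly step-equivalent to them and is held to that by the test suite.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

namespace {

struct Params {
  bool dynamic;
  double tau1, tau2;
  int k1, k2;                 // fixed-delay buffer lengths in steps
  double f_reg, tau_b, tau_r, tau_s, tau_pr, tau_alpha, denom_floor;
  int rect;                   // 0 none, 1 onset, 2 offset, 3 full
  bool adaptive, divide_first, tau_divisor;

  double lam(double tau, double dt) const {
    return tau_divisor ? dt / tau : dt * tau;
  }
};

Params parse_params(const List& p) {
  Params q;
  q.dynamic = as<bool>(p["dynamic"]);
  q.tau1 = as<double>(p["tau1"]);
  q.tau2 = as<double>(p["tau2"]);
  q.k1 = as<int>(p["k1"]);
  q.k2 = as<int>(p["k2"]);
  q.f_reg = as<double>(p["f_reg"]);
  q.tau_b = as<double>(p["tau_b"]);
  q.tau_r = as<double>(p["tau_r"]);
  q.tau_s = as<double>(p["tau_s"]);
  q.tau_pr = as<double>(p["tau_pr"]);
  q.tau_alpha = as<double>(p["tau_alpha"]);
  q.denom_floor = as<double>(p["denom_floor"]);
  q.rect = as<int>(p["rect"]);
  q.adaptive = as<bool>(p["adaptive"]);
  q.divide_first = as<bool>(p["divide_first"]);
  q.tau_divisor = as<bool>(p["tau_divisor"]);
  return q;
}

inline double rectify1(double a, int mode) {
  switch (mode) {
    case 1: return a > 0 ? a : 0.0;
    case 2: return a < 0 ? -a : 0.0;
    case 3: return std::fabs(a);
    default: return a;
  }
}

// One AVDU array: shared per-location channel states, per-pair subunit LINs,
// one smoothing stage. Mirrors R's array_state/step_array field for field.
struct ArrayState {
  Params par;
  double dt;
  int n_loc, n_det;
  std::vector<int> from, to;
  std::vector<double> a_pr, alpha, dir, del1, del2, r1, r2;
  std::vector<double> buf1, buf2;  // k x n_loc, row-major by buffer slot
  int pos1, pos2;
  double s, s_fast, s_slow;
  double sum_fast, sum_slow, ratio, s_out;
  double lp, la, lb, l1, l2, lr, ls;

  void init(const Params& p, int nloc, const IntegerVector& f0,
            const IntegerVector& t0, double dt_) {
    par = p; dt = dt_; n_loc = nloc; n_det = f0.size();
    from.assign(f0.begin(), f0.end());
    to.assign(t0.begin(), t0.end());
    a_pr.assign(n_loc, 0.0); alpha.assign(n_loc, 0.0);
    dir.assign(n_loc, 0.0); del1.assign(n_loc, 0.0); del2.assign(n_loc, 0.0);
    r1.assign(n_det, 0.0); r2.assign(n_det, 0.0);
    if (!par.dynamic) {
      buf1.assign((size_t)std::max(par.k1, 1) * n_loc, 0.0);
      buf2.assign((size_t)std::max(par.k2, 1) * n_loc, 0.0);
    }
    pos1 = pos2 = 0;
    s = s_fast = s_slow = 0.0;
    sum_fast = sum_slow = ratio = s_out = 0.0;
    lp = par.lam(par.tau_pr, dt); la = par.lam(par.tau_alpha, dt);
    lb = par.lam(par.tau_b, dt); l1 = par.lam(par.tau1, dt);
    l2 = par.lam(par.tau2, dt); lr = par.lam(par.tau_r, dt);
    ls = par.lam(par.tau_s, dt);
  }

  void step(const double* frame) {
    for (int i = 0; i < n_loc; ++i) {
      double x = frame[i], sig;
      if (par.adaptive) {
        double ap = a_pr[i] + lp * (-a_pr[i] - alpha[i] + x);
        alpha[i] += la * (-alpha[i] + x);
        a_pr[i] = ap;
        sig = ap;
      } else {
        sig = x;
      }
      double rp = rectify1(sig, par.rect);
      dir[i] += lb * (-dir[i] + rp);
      if (par.dynamic) {
        del1[i] += l1 * (-del1[i] + rp);
        del2[i] += l2 * (-del2[i] + rp);
      } else {
        double o1 = rp, o2 = rp;
        if (par.k1 > 0) {
          double* slot = &buf1[(size_t)pos1 * n_loc];
          o1 = slot[i]; slot[i] = rp;
        }
        if (par.k2 > 0) {
          double* slot = &buf2[(size_t)pos2 * n_loc];
          o2 = slot[i]; slot[i] = rp;
        }
        del1[i] += lb * (-del1[i] + o1);
        del2[i] += lb * (-del2[i] + o2);
      }
    }
    if (!par.dynamic) {
      if (par.k1 > 0) pos1 = (pos1 + 1) % par.k1;
      if (par.k2 > 0) pos2 = (pos2 + 1) % par.k2;
    }
    sum_fast = 0.0; sum_slow = 0.0;
    for (int j = 0; j < n_det; ++j) {
      int a = from[j], b = to[j];
      double prog1 = del1[a] * dir[b], reg1 = dir[a] * del1[b];
      double prog2 = del2[a] * dir[b], reg2 = dir[a] * del2[b];
      r1[j] += lr * (-r1[j] + prog1 - par.f_reg * reg1);
      r2[j] += lr * (-r2[j] + prog2 - par.f_reg * reg2);
      sum_fast += r1[j];
      sum_slow += r2[j];
    }
    if (par.divide_first) {
      ratio = sum_fast / std::max(sum_slow, par.denom_floor);
      s += ls * (-s + ratio);
      s_out = s;
    } else {
      s_fast += ls * (-s_fast + sum_fast);
      s_slow += ls * (-s_slow + sum_slow);
      ratio = s_fast / std::max(s_slow, par.denom_floor);
      s_out = ratio;
    }
  }

  double mean_fast() const {
    if (n_det == 0) return 0.0;
    double t = 0; for (double v : r1) t += v; return t / n_det;
  }
  double mean_slow() const {
    if (n_det == 0) return 0.0;
    double t = 0; for (double v : r2) t += v; return t / n_det;
  }
};

// --- corridor world -------------------------------------------------------

struct Surface {
  int waveform;      // 0 square, 1 sine, 2 uniform
  double freq_cm, contrast, mean, phase_cm;
};

struct World {
  double halfw, height;
  Surface left, right, floor_s;
  double ceil_lum, end_lum;
};

Surface parse_surface(const List& s) {
  Surface w;
  w.waveform = as<int>(s["waveform"]);
  w.freq_cm = as<double>(s["freq_cm"]);
  w.contrast = as<double>(s["contrast"]);
  w.mean = as<double>(s["mean"]);
  w.phase_cm = as<double>(s["phase_cm"]);
  return w;
}

World parse_world(const List& wl) {
  World w;
  w.halfw = as<double>(wl["width"]) / 2.0;
  w.height = as<double>(wl["height"]);
  w.left = parse_surface(wl["left"]);
  w.right = parse_surface(wl["right"]);
  w.floor_s = parse_surface(wl["floor"]);
  w.ceil_lum = as<double>(wl["ceiling_luminance"]);
  w.end_lum = as<double>(wl["end_luminance"]);
  return w;
}

inline double surf_lum(const Surface& w, double s_cm) {
  if (w.waveform == 2) return w.mean;
  double phi = 2.0 * M_PI * (s_cm - w.phase_cm) * w.freq_cm;
  double wv = (w.waveform == 1) ? std::sin(phi)
                                : (std::sin(phi) >= 0 ? 1.0 : -1.0);
  return w.mean * (1.0 + w.contrast * wv);
}

// First-hit luminance for a ray from (x, y, z); +x toward the right wall,
// +y along the corridor, +z up. The corridor is unbounded in y (patterns
// repeat), so every ray with a lateral or vertical component hits a wall,
// the floor or the ceiling; a purely axial ray sees the end luminance.
inline double ray_lum(const World& w, double x, double y, double z,
                      double dx, double dy, double dz) {
  double tbest = R_PosInf;
  int surf = -1;
  if (dx < 0) {
    double t = (-w.halfw - x) / dx;
    if (t < tbest) { tbest = t; surf = 0; }
  } else if (dx > 0) {
    double t = (w.halfw - x) / dx;
    if (t < tbest) { tbest = t; surf = 1; }
  }
  if (dz < 0) {
    double t = -z / dz;
    if (t < tbest) { tbest = t; surf = 2; }
  } else if (dz > 0) {
    double t = (w.height - z) / dz;
    if (t < tbest) { tbest = t; surf = 3; }
  }
  if (surf < 0) return w.end_lum;
  double yh = y + tbest * dy;
  switch (surf) {
    case 0: return surf_lum(w.left, yh);
    case 1: return surf_lum(w.right, yh);
    case 2: return surf_lum(w.floor_s, yh);
    default: return w.ceil_lum;
  }
}

}  // namespace

// [[Rcpp::export]]
List cpp_run_array(NumericMatrix lum, IntegerVector from0, IntegerVector to0,
                   List par, double dt) {
  Params p = parse_params(par);
  int n = lum.nrow(), n_loc = lum.ncol();
  ArrayState st;
  st.init(p, n_loc, from0, to0, dt);
  NumericVector sum_fast(n), sum_slow(n), ratio(n), S(n), mean_fast(n),
      mean_slow(n);
  std::vector<double> frame(n_loc);
  for (int t = 0; t < n; ++t) {
    for (int i = 0; i < n_loc; ++i) frame[i] = lum(t, i);
    st.step(frame.data());
    sum_fast[t] = st.sum_fast; sum_slow[t] = st.sum_slow;
    ratio[t] = st.ratio; S[t] = st.s_out;
    mean_fast[t] = st.mean_fast(); mean_slow[t] = st.mean_slow();
  }
  return List::create(_["sum_fast"] = sum_fast, _["sum_slow"] = sum_slow,
                      _["ratio"] = ratio, _["S"] = S,
                      _["mean_fast"] = mean_fast, _["mean_slow"] = mean_slow);
}

// [[Rcpp::export]]
NumericVector cpp_render(NumericMatrix dirs, NumericVector pose, List world) {
  World w = parse_world(world);
  int n = dirs.nrow();
  NumericVector out(n);
  double x = pose[0], y = pose[1], z = pose[2];
  for (int i = 0; i < n; ++i)
    out[i] = ray_lum(w, x, y, z, dirs(i, 0), dirs(i, 1), dirs(i, 2));
  return out;
}

// Closed-loop corridor trial: render -> step three AVDU arrays -> apply the
// lateral/height/speed controller every control interval. Returns one row
// per control step (plus the initial state): t, x, z, y, v, S_L, S_R, S_C.
// [[Rcpp::export]]
NumericMatrix cpp_run_trial(List world, List par, List subregions,
                            List controller, double duration_s,
                            double warmup_s, NumericVector start, double dt) {
  World w = parse_world(world);
  Params p = parse_params(par);

  std::vector<ArrayState> arrs(3);
  std::vector<NumericMatrix> dirs;
  for (int a = 0; a < 3; ++a) {
    List sub = subregions[a];
    NumericMatrix d = sub["dirs"];
    dirs.push_back(d);
    arrs[a].init(p, d.nrow(), sub["from0"], sub["to0"], dt);
  }

  double t_x = as<double>(controller["t_x"]);
  double t_z = as<double>(controller["t_z"]);
  double t_v = as<double>(controller["t_v"]);
  double div_x = as<double>(controller["div_x"]);
  double div_z = as<double>(controller["div_z"]);
  double div_v = as<double>(controller["div_v"]);
  int csteps = as<int>(controller["control_steps"]);
  double margin = as<double>(controller["clamp_margin"]);

  double x = start[0], y = start[1], z = start[2], v = start[3];

  // Open-loop warm-up: the detector states charge up (the smoothing stage
  // alone has a 100 ms time constant) while the bee coasts; the controller
  // engages only at t = 0 with the detectors at their steady response.
  int warm_steps = (int)std::lround(warmup_s * 1000.0 / dt);
  std::vector<double> frame;
  for (int step = 0; step < warm_steps; ++step) {
    for (int a = 0; a < 3; ++a) {
      const NumericMatrix& d = dirs[a];
      int nl = d.nrow();
      frame.resize(nl);
      for (int i = 0; i < nl; ++i)
        frame[i] = ray_lum(w, x, y, z, d(i, 0), d(i, 1), d(i, 2));
      arrs[a].step(frame.data());
    }
    y += v * dt / 1000.0;
  }

  int n_steps = (int)std::lround(duration_s * 1000.0 / dt);
  int n_rec = n_steps / csteps + 1;
  NumericMatrix out(n_rec, 8);
  int rec = 0;
  out(rec, 0) = 0; out(rec, 1) = x; out(rec, 2) = z; out(rec, 3) = y;
  out(rec, 4) = v;
  out(rec, 5) = arrs[0].s_out; out(rec, 6) = arrs[1].s_out;
  out(rec, 7) = arrs[2].s_out;
  ++rec;

  for (int step = 0; step < n_steps; ++step) {
    for (int a = 0; a < 3; ++a) {
      const NumericMatrix& d = dirs[a];
      int nl = d.nrow();
      frame.resize(nl);
      for (int i = 0; i < nl; ++i)
        frame[i] = ray_lum(w, x, y, z, d(i, 0), d(i, 1), d(i, 2));
      arrs[a].step(frame.data());
    }
    y += v * dt / 1000.0;
    if ((step + 1) % csteps == 0) {
      double sl = arrs[0].s_out, sr = arrs[1].s_out, sc = arrs[2].s_out;
      if (!std::isfinite(sl) || !std::isfinite(sr) || !std::isfinite(sc))
        stop("detector output became non-finite at t = %f s",
             (step + 1) * dt / 1000.0);
      // tie rule with a tolerance: exact FP equality would let last-bit
      // noise from the two arrays' summation order pick a lunge direction
      // in a perfectly symmetric world
      double sgn = (sl - sr > 1e-9) ? 1.0 : ((sr - sl > 1e-9) ? -1.0 : 0.0);
      x += sgn * (std::max(sl, sr) - t_x) / div_x;
      z += (sc - t_z) / div_z;
      v += -(sl + sr - t_v) / div_v;
      double xmax = w.halfw - margin;
      if (x > xmax) x = xmax; else if (x < -xmax) x = -xmax;
      if (z > w.height - margin) z = w.height - margin;
      else if (z < margin) z = margin;
      if (v < 0) v = 0;
      out(rec, 0) = (step + 1) * dt / 1000.0;
      out(rec, 1) = x; out(rec, 2) = z; out(rec, 3) = y; out(rec, 4) = v;
      out(rec, 5) = sl; out(rec, 6) = sr; out(rec, 7) = sc;
      ++rec;
    }
  }
  return out;
}
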