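#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Fixed-step RK4 integration of a planar point-mass arm driven by a PD servo
// tracking a minimum-jerk reference, a state-gated resting bias field, a
// gated hold controller (leaky reference adaptation that absorbs static loads
// while holding), and an optional pulse or ramp-hold-release perturbation.
//
// Units: positions cm, forces N, mass kg, damping N.s/cm, time s.
// Acceleration (cm/s^2) = 100 * F(N) / mass(kg).
//
// Gating g(t): 0 = off; 1 = hold_only (0 during movement, 1 - exp(-dt/tau)
// after online-detected movement end); 2 = always_on (1 throughout).
// The hold adaptation (reference offset ro) integrates position error with
// rate adapt_rate and leaks with time constant adapt_leak_tau; it is active
// only after movement end (it models the engaged holding controller).
//
// Noise is a 2 x n_steps matrix of zero-mean forces (N), held constant over
// each integration step so that results are reproducible from the R RNG.

struct SimPars {
  double t_go, T_reach, mass, damping, kp, kd;
  double sx, sy, tx, ty;
  double cx, cy, base_gain, dist_gain, bias_scale, boff_x, boff_y;
  int gating; double ramp_tau;
  double adapt_rate, adapt_leak_tau, hold_kp_frac;
  int pert; // 0 none, 1 pulse, 2 release
  double pulse_sign, pulse_peak, pulse_dur, pulse_trigger;
  double rel_dir_rad, rel_ramp, rel_hold, rel_force;
  double end_radius, end_speed, settle_delay, end_deadline;
  double latx, laty;
};

struct SimState { double x, y, vx, vy, rox, roy; };

struct Events {
  bool ended, pulsed;
  double t_end, t_pulse, t_ramp, t_release;
};

// participant force (pf) excludes the robot perturbation and damping;
// total accelerating force (ft) includes them
static inline void eval_forces(double t, const SimState& s, double nfx,
                               double nfy, const SimPars& p, const Events& ev,
                               double* pfx, double* pfy, double* ftx,
                               double* fty) {
  double rx, ry, rvx, rvy;
  {
    double tau = (t - p.t_go) / p.T_reach;
    if (tau <= 0.0) { rx = p.sx; ry = p.sy; rvx = rvy = 0.0; }
    else if (tau >= 1.0) { rx = p.tx; ry = p.ty; rvx = rvy = 0.0; }
    else {
      double sj = tau * tau * tau * (10.0 + tau * (-15.0 + 6.0 * tau));
      double sd = 30.0 * tau * tau * (1.0 - tau) * (1.0 - tau) / p.T_reach;
      rx = p.sx + (p.tx - p.sx) * sj; ry = p.sy + (p.ty - p.sy) * sj;
      rvx = (p.tx - p.sx) * sd; rvy = (p.ty - p.sy) * sd;
    }
  }
  double kpe = (ev.ended && t >= ev.t_end) ? p.kp * p.hold_kp_frac : p.kp;
  double ux = kpe * (rx + s.rox - s.x) + p.kd * (rvx - s.vx);
  double uy = kpe * (ry + s.roy - s.y) + p.kd * (rvy - s.vy);

  double g = 0.0;
  if (p.gating == 2) g = 1.0;
  else if (p.gating == 1 && ev.ended && t >= ev.t_end)
    g = 1.0 - std::exp(-(t - ev.t_end) / p.ramp_tau);
  double bx = 0.0, by = 0.0;
  if (g > 0.0 && p.bias_scale != 0.0) {
    double dx = p.cx - s.x, dy = p.cy - s.y;
    double d = std::sqrt(dx * dx + dy * dy);
    if (d > 1e-12) {
      double mag = (p.base_gain + p.dist_gain * d) * p.bias_scale;
      bx = mag * dx / d; by = mag * dy / d;
    }
    bx = g * (bx + p.boff_x); by = g * (by + p.boff_y);
  }

  double px = 0.0, py = 0.0;
  if (p.pert == 1 && ev.pulsed && t >= ev.t_pulse &&
      t <= ev.t_pulse + p.pulse_dur) {
    double w = 0.5 * p.pulse_peak *
      (1.0 - std::cos(2.0 * M_PI * (t - ev.t_pulse) / p.pulse_dur));
    px = p.pulse_sign * w * p.latx; py = p.pulse_sign * w * p.laty;
  } else if (p.pert == 2 && !ISNA(ev.t_ramp) && t >= ev.t_ramp &&
             t < ev.t_release) {
    double amp = (t < ev.t_ramp + p.rel_ramp) ?
      p.rel_force * (t - ev.t_ramp) / p.rel_ramp : p.rel_force;
    px = amp * std::cos(p.rel_dir_rad); py = amp * std::sin(p.rel_dir_rad);
  }

  *pfx = ux + bx + nfx; *pfy = uy + by + nfy;
  *ftx = *pfx + px - p.damping * s.vx;
  *fty = *pfy + py - p.damping * s.vy;
}

static inline SimState deriv(double t, const SimState& s, double nfx,
                             double nfy, const SimPars& p, const Events& ev) {
  double pfx, pfy, ftx, fty;
  eval_forces(t, s, nfx, nfy, p, ev, &pfx, &pfy, &ftx, &fty);
  double am = 100.0 / p.mass;
  SimState d;
  d.x = s.vx; d.y = s.vy; d.vx = am * ftx; d.vy = am * fty;
  bool hold_active = ev.ended && t >= ev.t_end;
  if (hold_active) {
    d.rox = p.adapt_rate * (p.tx - s.x) - s.rox / p.adapt_leak_tau;
    d.roy = p.adapt_rate * (p.ty - s.y) - s.roy / p.adapt_leak_tau;
  } else {
    d.rox = 0.0; d.roy = 0.0;
  }
  return d;
}

// [[Rcpp::export(name = ".reach_sim_cpp")]]
List reach_sim_cpp(double dt, int n_steps, NumericVector start,
                   NumericVector target, double t_go, double T_reach,
                   double mass, double damping, double kp, double kd,
                   double adapt_rate, double adapt_leak_tau,
                   double hold_kp_frac,
                   NumericVector conv_point, double base_gain,
                   double dist_gain, double bias_scale,
                   NumericVector bias_offset, int gating,
                   double ramp_tau, int pert, double pulse_sign,
                   double pulse_peak, double pulse_dur, double pulse_trigger,
                   double rel_dir_rad, double rel_ramp, double rel_hold,
                   double rel_force, NumericMatrix noise, double end_radius,
                   double end_speed, double settle_delay,
                   double end_deadline) {
  SimPars p;
  p.t_go = t_go; p.T_reach = T_reach; p.mass = mass; p.damping = damping;
  p.kp = kp; p.kd = kd;
  p.adapt_rate = adapt_rate; p.adapt_leak_tau = adapt_leak_tau;
  p.hold_kp_frac = hold_kp_frac;
  p.sx = start[0]; p.sy = start[1]; p.tx = target[0]; p.ty = target[1];
  p.cx = conv_point[0]; p.cy = conv_point[1];
  p.base_gain = base_gain; p.dist_gain = dist_gain; p.bias_scale = bias_scale;
  p.boff_x = bias_offset[0]; p.boff_y = bias_offset[1];
  p.gating = gating; p.ramp_tau = ramp_tau;
  p.pert = pert; p.pulse_sign = pulse_sign; p.pulse_peak = pulse_peak;
  p.pulse_dur = pulse_dur; p.pulse_trigger = pulse_trigger;
  p.rel_dir_rad = rel_dir_rad; p.rel_ramp = rel_ramp; p.rel_hold = rel_hold;
  p.rel_force = rel_force;
  p.end_radius = end_radius; p.end_speed = end_speed;
  p.settle_delay = settle_delay; p.end_deadline = end_deadline;
  {
    double mdx = (p.tx - p.sx), mdy = (p.ty - p.sy);
    double mlen = std::sqrt(mdx * mdx + mdy * mdy);
    p.latx = -mdy / mlen; p.laty = mdx / mlen;
  }

  Events ev;
  ev.ended = false; ev.pulsed = (pert != 1);
  ev.t_end = NA_REAL; ev.t_pulse = NA_REAL; ev.t_ramp = NA_REAL;
  ev.t_release = NA_REAL;

  int n_out = n_steps + 1;
  NumericMatrix out(n_out, 5); // t, x, y, vx, vy
  NumericMatrix uf(n_out, 2);  // participant-exerted force

  SimState s; s.x = p.sx; s.y = p.sy; s.vx = s.vy = 0.0; s.rox = s.roy = 0.0;

  out(0, 0) = 0.0; out(0, 1) = s.x; out(0, 2) = s.y;
  out(0, 3) = s.vx; out(0, 4) = s.vy;
  {
    double pfx, pfy, ftx, fty;
    eval_forces(0.0, s, noise(0, 0), noise(1, 0), p, ev,
                &pfx, &pfy, &ftx, &fty);
    uf(0, 0) = pfx; uf(0, 1) = pfy;
  }

  for (int i = 0; i < n_steps; ++i) {
    double t = i * dt;
    double nfx = noise(0, i), nfy = noise(1, i);

    // event triggers evaluated at step boundaries (sample resolution)
    if (!ev.pulsed && t >= p.t_go) {
      double ddx = s.x - p.sx, ddy = s.y - p.sy;
      if (std::sqrt(ddx * ddx + ddy * ddy) >= p.pulse_trigger) {
        ev.t_pulse = t; ev.pulsed = true;
      }
    }
    if (!ev.ended && t > p.t_go) {
      double ddx = s.x - p.tx, ddy = s.y - p.ty;
      double sp = std::sqrt(s.vx * s.vx + s.vy * s.vy);
      bool reached = std::sqrt(ddx * ddx + ddy * ddy) <= p.end_radius &&
                     sp < p.end_speed;
      if (reached || t >= p.end_deadline) {
        ev.ended = true; ev.t_end = t;
        if (p.pert == 2) {
          ev.t_ramp = ev.t_end + p.settle_delay;
          ev.t_release = ev.t_ramp + p.rel_ramp + p.rel_hold;
        }
      }
    }

    SimState k1 = deriv(t, s, nfx, nfy, p, ev);
    SimState s2 = s;
    s2.x += dt / 2 * k1.x; s2.y += dt / 2 * k1.y;
    s2.vx += dt / 2 * k1.vx; s2.vy += dt / 2 * k1.vy;
    s2.rox += dt / 2 * k1.rox; s2.roy += dt / 2 * k1.roy;
    SimState k2 = deriv(t + dt / 2, s2, nfx, nfy, p, ev);
    SimState s3 = s;
    s3.x += dt / 2 * k2.x; s3.y += dt / 2 * k2.y;
    s3.vx += dt / 2 * k2.vx; s3.vy += dt / 2 * k2.vy;
    s3.rox += dt / 2 * k2.rox; s3.roy += dt / 2 * k2.roy;
    SimState k3 = deriv(t + dt / 2, s3, nfx, nfy, p, ev);
    SimState s4 = s;
    s4.x += dt * k3.x; s4.y += dt * k3.y;
    s4.vx += dt * k3.vx; s4.vy += dt * k3.vy;
    s4.rox += dt * k3.rox; s4.roy += dt * k3.roy;
    SimState k4 = deriv(t + dt, s4, nfx, nfy, p, ev);

    s.x += dt / 6.0 * (k1.x + 2 * k2.x + 2 * k3.x + k4.x);
    s.y += dt / 6.0 * (k1.y + 2 * k2.y + 2 * k3.y + k4.y);
    s.vx += dt / 6.0 * (k1.vx + 2 * k2.vx + 2 * k3.vx + k4.vx);
    s.vy += dt / 6.0 * (k1.vy + 2 * k2.vy + 2 * k3.vy + k4.vy);
    s.rox += dt / 6.0 * (k1.rox + 2 * k2.rox + 2 * k3.rox + k4.rox);
    s.roy += dt / 6.0 * (k1.roy + 2 * k2.roy + 2 * k3.roy + k4.roy);

    double tn = (i + 1) * dt;
    double pfx, pfy, ftx, fty;
    eval_forces(tn, s, nfx, nfy, p, ev, &pfx, &pfy, &ftx, &fty);
    out(i + 1, 0) = tn; out(i + 1, 1) = s.x; out(i + 1, 2) = s.y;
    out(i + 1, 3) = s.vx; out(i + 1, 4) = s.vy;
    uf(i + 1, 0) = pfx; uf(i + 1, 1) = pfy;
  }

  return List::create(_["state"] = out, _["force"] = uf,
                      _["t_end"] = ev.t_end, _["t_pulse"] = ev.t_pulse,
                      _["t_release"] = ev.t_release);
}
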