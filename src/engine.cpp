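// Overdamped Langevin propagation of a point ligand on analytic binding
// landscapes, with the harmonic steering force of constant-velocity SMD
// computed in-loop. Uses R's RNG (norm_rand) so that a checkpoint is fully
// described by (.Random.seed, r, t). Time is accumulated as t += dt so the
// float-op sequence is identical whether a run is executed in one segment
// or split at checkpoints (bit-exact chunk transparency).

#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

// Packed landscape layout (see .land_pack in R):
//   funnel: [0]=0, [1:3]=center, [4]=depth, [5]=sigma_w, [6]=rho_b,
//           [7]=rim, [8]=k_bg, [9]=R_env, [10]=eps, [11]=wall_height,
//           [12]=wall_radius, [13]=wall_lambda, [14]=tube_radius,
//           [15]=n_channels, then per channel: dir(3), barrier, width
//   harmonic: [0]=1, [1:3]=center, [4]=kappa, [9]=R_env
struct Channel {
  double ex, ey, ez;   // unit direction
  double dB;           // barrier - rim
  double w2;           // angular width^2 (rad^2)
};

struct Land {
  int kind;
  double cx, cy, cz;
  double depth, sigma_w, rho_b, rim, k_bg, R_env, eps;
  double wall_h, wall_r2, inv_2wl4, rt2;
  double inv_2sw2, inv_rb2, eps2;
  double kappa;  // harmonic
  std::vector<Channel> ch;
};

static Land unpack_land(const NumericVector& p) {
  Land L;
  L.kind = (int)p[0];
  L.cx = p[1]; L.cy = p[2]; L.cz = p[3];
  if (L.kind == 1) {
    L.kappa = p[4];
    L.R_env = p[9];
    return L;
  }
  L.depth = p[4]; L.sigma_w = p[5]; L.rho_b = p[6];
  L.rim = p[7]; L.k_bg = p[8]; L.R_env = p[9]; L.eps = p[10];
  L.wall_h = p[11];
  L.wall_r2 = p[12] * p[12];
  double wl = p[13];
  L.inv_2wl4 = (wl > 0) ? 1.0 / (2.0 * wl * wl * wl * wl) : 0.0;
  L.rt2 = p[14] * p[14];
  L.inv_2sw2 = 1.0 / (2.0 * L.sigma_w * L.sigma_w);
  L.inv_rb2 = 1.0 / (L.rho_b * L.rho_b);
  L.eps2 = L.eps * L.eps;
  int nch = (int)p[15];
  L.ch.resize(nch);
  for (int c = 0; c < nch; ++c) {
    int o = 16 + 5 * c;
    L.ch[c].ex = p[o]; L.ch[c].ey = p[o + 1]; L.ch[c].ez = p[o + 2];
    L.ch[c].dB = p[o + 3] - L.rim;
    L.ch[c].w2 = p[o + 4] * p[o + 4];
  }
  // deepen the well by the wall's value at the center so that
  // energy(center) - energy(far field) = -depth stays exact; with a
  // tube-like pocket (tube_radius > 0) the channels converge at the center,
  // the openness there is ~1 and the correction is ~0
  if (L.wall_h > 0.0) {
    double W0 = 1.0;
    for (int c = 0; c < nch; ++c) {
      double invw2 = 1.0 / (L.ch[c].w2 + L.rt2 / L.eps2);
      W0 *= (1.0 - std::exp(-invw2));
    }
    L.depth += L.wall_h * std::exp(-L.wall_r2 * L.wall_r2 * L.inv_2wl4) * W0;
  }
  return L;
}

// energy and gradient at r; gradient written to g[3]
static double land_eval(const Land& L, const double* r, double* g) {
  double dx = r[0] - L.cx, dy = r[1] - L.cy, dz = r[2] - L.cz;
  double rho2 = dx * dx + dy * dy + dz * dz;

  if (L.kind == 1) {  // isotropic harmonic reference well
    g[0] = L.kappa * dx; g[1] = L.kappa * dy; g[2] = L.kappa * dz;
    return 0.5 * L.kappa * rho2;
  }

  // Gaussian well
  double ew = std::exp(-rho2 * L.inv_2sw2);
  double Uw = -L.depth * ew;
  double cw = L.depth * ew * 2.0 * L.inv_2sw2;  // d(-D e)/d(d) = cw * d
  g[0] = cw * dx; g[1] = cw * dy; g[2] = cw * dz;

  // radial shell s(rho) = x exp(1-x), x = rho^2/rho_b^2 (max 1 at rho_b)
  double x = rho2 * L.inv_rb2;
  double es = std::exp(1.0 - x);
  double s = x * es;
  double dsdx = es * (1.0 - x);
  double cs = dsdx * L.inv_rb2 * 2.0;  // ds/d(d) = cs * d

  // angular modulation A(u), u = d / sqrt(rho^2 + eps^2), and channel
  // "openness" P = prod_c (1 - g_c) for the pocket wall. Channels are
  // tube-like: the effective squared angular width is
  // w_eff^2 = w^2 + rt^2 / q^2, so cones widen toward the pocket bottom
  // (all exits converge at the center) and tend to the angular width w in
  // the far field.
  double q2 = rho2 + L.eps2;
  double q = std::sqrt(q2);
  double iq = 1.0 / q;
  double ux = dx * iq, uy = dy * iq, uz = dz * iq;
  double A = L.rim;
  double gAx = 0.0, gAy = 0.0, gAz = 0.0;
  int nch = (int)L.ch.size();
  double gv[8], dgx[8], dgy[8], dgz[8];  // per-channel g_c and gradient
  for (int c = 0; c < nch; ++c) {
    const Channel& C = L.ch[c];
    double dot = ux * C.ex + uy * C.ey + uz * C.ez;
    double Wc = 1.0 / (C.w2 + L.rt2 / q2);   // 1 / w_eff^2
    double gfac = std::exp(-(1.0 - dot) * Wc);
    // d(dot)/d(d) = e/q - dot * d / q^2
    double ddx = C.ex * iq - dot * dx * iq * iq;
    double ddy = C.ey * iq - dot * dy * iq * iq;
    double ddz = C.ez * iq - dot * dz * iq * iq;
    // dW/d(d) = W^2 * rt^2 / q^4 * 2 d
    double cW = Wc * Wc * L.rt2 / (q2 * q2) * 2.0;
    gv[c] = gfac;
    dgx[c] = gfac * (Wc * ddx - (1.0 - dot) * cW * dx);
    dgy[c] = gfac * (Wc * ddy - (1.0 - dot) * cW * dy);
    dgz[c] = gfac * (Wc * ddz - (1.0 - dot) * cW * dz);
    A += C.dB * gfac;
    gAx += C.dB * dgx[c];
    gAy += C.dB * dgy[c];
    gAz += C.dB * dgz[c];
  }

  double U = Uw + A * s;
  g[0] += A * cs * dx + s * gAx;
  g[1] += A * cs * dy + s * gAy;
  g[2] += A * cs * dz + s * gAz;

  if (L.wall_h > 0.0) {
    // pocket wall: wall_h * s_w(rho) * P, with the radial profile
    // s_w = exp(-(rho^2 - wall_r^2)^2 / (2 lambda^4)) a smooth function of
    // rho^2 (zero gradient at the well center), and P the product openness
    double a = rho2 - L.wall_r2;
    double sw = std::exp(-a * a * L.inv_2wl4);
    double csw = -4.0 * a * sw * L.inv_2wl4;  // d(sw)/d(d) = csw * d
    double P = 1.0;
    for (int c = 0; c < nch; ++c) P *= (1.0 - gv[c]);
    double dPx = 0.0, dPy = 0.0, dPz = 0.0;
    for (int c = 0; c < nch; ++c) {
      double prod_others = 1.0;
      for (int c2 = 0; c2 < nch; ++c2)
        if (c2 != c) prod_others *= (1.0 - gv[c2]);
      dPx -= dgx[c] * prod_others;
      dPy -= dgy[c] * prod_others;
      dPz -= dgz[c] * prod_others;
    }
    U += L.wall_h * sw * P;
    g[0] += L.wall_h * (csw * dx * P + sw * dPx);
    g[1] += L.wall_h * (csw * dy * P + sw * dPy);
    g[2] += L.wall_h * (csw * dz * P + sw * dPz);
  }

  if (L.k_bg > 0.0) {  // optional weak confinement
    U += 0.5 * L.k_bg * rho2;
    g[0] += L.k_bg * dx; g[1] += L.k_bg * dy; g[2] += L.k_bg * dz;
  }
  return U;
}

// [[Rcpp::export]]
NumericVector cpp_energy(NumericVector land, NumericMatrix pts) {
  Land L = unpack_land(land);
  int n = pts.nrow();
  NumericVector out(n);
  double g[3], r[3];
  for (int i = 0; i < n; ++i) {
    r[0] = pts(i, 0); r[1] = pts(i, 1); r[2] = pts(i, 2);
    out[i] = land_eval(L, r, g);
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_grad(NumericVector land, NumericMatrix pts) {
  Land L = unpack_land(land);
  int n = pts.nrow();
  NumericMatrix out(n, 3);
  double g[3], r[3];
  for (int i = 0; i < n; ++i) {
    r[0] = pts(i, 0); r[1] = pts(i, 1); r[2] = pts(i, 2);
    land_eval(L, r, g);
    out(i, 0) = g[0]; out(i, 1) = g[1]; out(i, 2) = g[2];
  }
  return out;
}

// Single Euler-Maruyama step with an arbitrary constant external force.
// [[Rcpp::export]]
List cpp_step(NumericVector land, NumericVector r0, double t0,
              NumericVector f_ext, double dt, double friction,
              double temperature) {
  Land L = unpack_land(land);
  const double kB = 0.0083144621;  // kJ/mol/K
  double g[3];
  double r[3] = { r0[0], r0[1], r0[2] };
  land_eval(L, r, g);
  double idt = dt / friction;
  double sig = (temperature > 0.0)
                 ? std::sqrt(2.0 * kB * temperature * dt / friction)
                 : 0.0;
  for (int a = 0; a < 3; ++a) {
    double f = f_ext[a] - g[a];
    double xi = (temperature > 0.0) ? norm_rand() : 0.0;
    r[a] += f * idt + sig * xi;
  }
  return List::create(_["r"] = NumericVector::create(r[0], r[1], r[2]),
                      _["t"] = t0 + dt);
}

// Propagate under landscape + harmonic steering (k, v, n, r_ref, t_start,
// x_offset). Records the signed scalar pulling force k*x (projection on n,
// evaluated at the pre-step state) each step. Early-exit reasons:
//   0 = max_steps reached, 1 = separation >= cutoff, 2 = optimization trigger
// Trigger: (t - t_last_opt) > trig_t0 AND mean of last W force samples > trig_f0.
// [[Rcpp::export]]
List cpp_run_segment(NumericVector land, NumericVector r0, double t_begin,
                     NumericVector pull,  // k, v, n(3), r_ref(3), t_start, x_offset
                     double dt, double friction, double temperature,
                     int max_steps, double cutoff_sep, bool trigger_enabled,
                     double t_last_opt, double trig_t0, double trig_f0,
                     int window_w, int traj_stride) {
  Land L = unpack_land(land);
  const double kB = 0.0083144621;
  double k = pull[0], v = pull[1];
  double nx = pull[2], ny = pull[3], nz = pull[4];
  double rx0 = pull[5], ry0 = pull[6], rz0 = pull[7];
  double t_start = pull[8], x_off = pull[9];

  double r[3] = { r0[0], r0[1], r0[2] };
  double t = t_begin;
  double g[3];
  double idt = dt / friction;
  double sig = (temperature > 0.0)
                 ? std::sqrt(2.0 * kB * temperature * dt / friction)
                 : 0.0;
  bool noise = temperature > 0.0;

  NumericVector forces(max_steps);
  int n_traj = (traj_stride > 0) ? (max_steps / traj_stride) : 0;
  NumericMatrix traj(n_traj > 0 ? n_traj : 1, 3);
  NumericVector traj_t(n_traj > 0 ? n_traj : 1);
  int traj_i = 0;

  // trailing-window ring buffer for the trigger
  double wsum = 0.0;

  int exit_code = 0;
  int i = 0;
  for (i = 0; i < max_steps; ++i) {
    // steering force at pre-step state
    double ddx = r[0] - rx0, ddy = r[1] - ry0, ddz = r[2] - rz0;
    double x = v * (t - t_start) + x_off - (ddx * nx + ddy * ny + ddz * nz);
    double fs = k * x;
    forces[i] = fs;

    land_eval(L, r, g);
    double fx = fs * nx - g[0], fy = fs * ny - g[1], fz = fs * nz - g[2];
    if (noise) {
      r[0] += fx * idt + sig * norm_rand();
      r[1] += fy * idt + sig * norm_rand();
      r[2] += fz * idt + sig * norm_rand();
    } else {
      r[0] += fx * idt; r[1] += fy * idt; r[2] += fz * idt;
    }
    t += dt;

    if (traj_stride > 0 && ((i + 1) % traj_stride == 0) && traj_i < n_traj) {
      traj(traj_i, 0) = r[0]; traj(traj_i, 1) = r[1]; traj(traj_i, 2) = r[2];
      traj_t[traj_i] = t;
      ++traj_i;
    }

    if (cutoff_sep >= 0.0) {
      double dx = r[0] - L.cx, dy = r[1] - L.cy, dz = r[2] - L.cz;
      double sep = std::sqrt(dx * dx + dy * dy + dz * dz) - L.R_env;
      if (sep >= cutoff_sep) { exit_code = 1; ++i; break; }
    }

    if (trigger_enabled) {
      wsum += forces[i];
      if (i >= window_w) wsum -= forces[i - window_w];
      if (i + 1 >= window_w && (t - t_last_opt) > trig_t0 &&
          (wsum / window_w) > trig_f0) {
        exit_code = 2; ++i; break;
      }
    }
  }
  int n_done = (exit_code == 0) ? i : i;

  List out = List::create(
      _["r"] = NumericVector::create(r[0], r[1], r[2]), _["t"] = t,
      _["n_steps"] = n_done,
      _["forces"] = (n_done == max_steps) ? forces
                                          : NumericVector(forces.begin(), forces.begin() + n_done),
      _["exit"] = exit_code);
  if (traj_stride > 0) {
    out["traj"] = traj(Range(0, std::max(traj_i - 1, 0)), _);
    out["traj_t"] = (traj_i > 0) ? NumericVector(traj_t.begin(), traj_t.begin() + traj_i)
                                 : NumericVector(0);
  }
  return out;
}
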