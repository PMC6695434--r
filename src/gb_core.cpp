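// Gay-Berne soft-ellipsoid core: pair energy/force/torque with the
// Berne-Pechukas overlap matrix H = A_i + A_j (A = R diag(l^2) R^T, which
// reduces to the uniaxial 2*l_perp^2*I + (l_par^2 - l_perp^2)(ee+ee) form
// for spheroids), and a Brownian / Langevin integrator in a cubic periodic
// box with a cell list, box ramping, and collision-onset recording.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

static inline void cross3(const double* a, const double* b, double* out) {
  out[0] = a[1] * b[2] - a[2] * b[1];
  out[1] = a[2] * b[0] - a[0] * b[2];
  out[2] = a[0] * b[1] - a[1] * b[0];
}

// A = R diag(l^2) R^T for a row-major 3x3 rotation R (columns = body axes)
static inline void shape_matrix(const double* R, const double* l2,
                                double* A) {
  // R stored row-major: R[3*r + c]; column c is body axis c
  for (int i = 0; i < 3; ++i)
    for (int j = 0; j < 3; ++j) {
      double s = 0.0;
      for (int k = 0; k < 3; ++k) s += R[3 * i + k] * l2[k] * R[3 * j + k];
      A[3 * i + j] = s;
    }
}

static inline bool solve3(const double* M, const double* b, double* x) {
  double a = M[0], bb = M[1], c = M[2], d = M[3], e = M[4], f = M[5],
         g = M[6], h = M[7], i = M[8];
  double A0 = e * i - f * h, A1 = c * h - bb * i, A2 = bb * f - c * e;
  double det = a * A0 + d * A1 + g * A2;
  if (std::fabs(det) < 1e-300) return false;
  double B0 = f * g - d * i, B1 = a * i - c * g, B2 = c * d - a * f;
  double C0 = d * h - e * g, C1 = bb * g - a * h, C2 = a * e - bb * d;
  x[0] = (A0 * b[0] + A1 * b[1] + A2 * b[2]) / det;
  x[1] = (B0 * b[0] + B1 * b[1] + B2 * b[2]) / det;
  x[2] = (C0 * b[0] + C1 * b[1] + C2 * b[2]) / det;
  return true;
}

struct PairOut {
  double energy, zeta, sigma;
  double force_j[3];   // force on particle j (r = r_j - r_i)
  double torque_i[3], torque_j[3];
  bool within_cut;
  bool capped;
};

// zeta is clamped from below at zeta_floor for integration safety when
// particles are driven into deep overlap
static void gb_pair(const double* rvec, const double* Ri, const double* Rj,
                    const double* l2, double sig_min, double eps,
                    double zeta_cut, double zeta_floor, PairOut& out) {
  double r = std::sqrt(rvec[0] * rvec[0] + rvec[1] * rvec[1] +
                       rvec[2] * rvec[2]);
  double rhat[3] = {rvec[0] / r, rvec[1] / r, rvec[2] / r};
  double Ai[9], Aj[9], H[9];
  shape_matrix(Ri, l2, Ai);
  shape_matrix(Rj, l2, Aj);
  for (int k = 0; k < 9; ++k) H[k] = Ai[k] + Aj[k];
  double w[3];
  solve3(H, rhat, w);
  double u = 0.5 * (rhat[0] * w[0] + rhat[1] * w[1] + rhat[2] * w[2]);
  double sigma = 1.0 / std::sqrt(u);
  double zeta = (r - sigma + sig_min) / sig_min;
  out.sigma = sigma;
  out.zeta = zeta;
  out.capped = false;
  if (zeta >= zeta_cut) {
    out.energy = 0.0;
    out.within_cut = false;
    for (int k = 0; k < 3; ++k)
      out.force_j[k] = out.torque_i[k] = out.torque_j[k] = 0.0;
    return;
  }
  out.within_cut = true;
  double zeff = zeta;
  if (zeff < zeta_floor) { zeff = zeta_floor; out.capped = true; }
  double zi = 1.0 / zeff, zi2 = zi * zi;
  double z6 = zi2 * zi2 * zi2;
  out.energy = 4.0 * eps * (z6 * z6 - z6);
  double dVdz = 4.0 * eps * (-12.0 * z6 * z6 + 6.0 * z6) / zeff;
  double s3 = sigma * sigma * sigma;
  // grad_r V = dVdz/sig_min * (rhat + 0.5*s3*(w - (rhat.w) rhat)/r)
  double rw = rhat[0] * w[0] + rhat[1] * w[1] + rhat[2] * w[2];
  for (int k = 0; k < 3; ++k) {
    double g = dVdz / sig_min *
      (rhat[k] + 0.5 * s3 * (w[k] - rw * rhat[k]) / r);
    out.force_j[k] = -g;
  }
  // torque_i = (dV/du) * (A_i w) x w ; dV/du = dVdz * s3 / (2 sig_min)
  double dVdu = dVdz * s3 / (2.0 * sig_min);
  double Aw[3], tq[3];
  for (int i = 0; i < 3; ++i)
    Aw[i] = Ai[3 * i] * w[0] + Ai[3 * i + 1] * w[1] + Ai[3 * i + 2] * w[2];
  cross3(Aw, w, tq);
  for (int k = 0; k < 3; ++k) out.torque_i[k] = dVdu * tq[k];
  for (int i = 0; i < 3; ++i)
    Aw[i] = Aj[3 * i] * w[0] + Aj[3 * i + 1] * w[1] + Aj[3 * i + 2] * w[2];
  cross3(Aw, w, tq);
  for (int k = 0; k < 3; ++k) out.torque_j[k] = dVdu * tq[k];
}

// [[Rcpp::export]]
List gb_pair_cpp(NumericVector rvec, NumericMatrix Ri, NumericMatrix Rj,
                 NumericVector ell, double eps, double zeta_cut,
                 double zeta_floor = 0.2) {
  double l2[3] = {ell[0] * ell[0], ell[1] * ell[1], ell[2] * ell[2]};
  double sig_min = std::min(ell[0], std::min(ell[1], ell[2]));
  double Ria[9], Rja[9];
  for (int i = 0; i < 3; ++i)
    for (int j = 0; j < 3; ++j) {
      Ria[3 * i + j] = Ri(i, j);
      Rja[3 * i + j] = Rj(i, j);
    }
  double rv[3] = {rvec[0], rvec[1], rvec[2]};
  PairOut o;
  gb_pair(rv, Ria, Rja, l2, sig_min, eps, zeta_cut, zeta_floor, o);
  return List::create(
    _["energy"] = o.energy, _["zeta"] = o.zeta, _["sigma"] = o.sigma,
    _["force_j"] = NumericVector::create(o.force_j[0], o.force_j[1],
                                         o.force_j[2]),
    _["torque_i"] = NumericVector::create(o.torque_i[0], o.torque_i[1],
                                          o.torque_i[2]),
    _["torque_j"] = NumericVector::create(o.torque_j[0], o.torque_j[1],
                                          o.torque_j[2]),
    _["capped"] = o.capped);
}

static inline void rotate_orientation(double* R, const double* omega) {
  double angle = std::sqrt(omega[0] * omega[0] + omega[1] * omega[1] +
                           omega[2] * omega[2]);
  if (angle < 1e-14) return;
  double ax[3] = {omega[0] / angle, omega[1] / angle, omega[2] / angle};
  double ca = std::cos(angle), sa = std::sin(angle), oc = 1.0 - ca;
  double Q[9] = {
    ca + ax[0] * ax[0] * oc, ax[0] * ax[1] * oc - ax[2] * sa,
    ax[0] * ax[2] * oc + ax[1] * sa,
    ax[1] * ax[0] * oc + ax[2] * sa, ca + ax[1] * ax[1] * oc,
    ax[1] * ax[2] * oc - ax[0] * sa,
    ax[2] * ax[0] * oc - ax[1] * sa, ax[2] * ax[1] * oc + ax[0] * sa,
    ca + ax[2] * ax[2] * oc};
  double out[9];
  for (int i = 0; i < 3; ++i)
    for (int j = 0; j < 3; ++j) {
      double s = 0.0;
      for (int k = 0; k < 3; ++k) s += Q[3 * i + k] * R[3 * k + j];
      out[3 * i + j] = s;
    }
  for (int k = 0; k < 9; ++k) R[k] = out[k];
}

static inline void orthonormalize(double* R) {
  // Gram-Schmidt on columns
  double c0[3], c1[3], c2[3];
  for (int i = 0; i < 3; ++i) {
    c0[i] = R[3 * i];
    c1[i] = R[3 * i + 1];
  }
  double n0 = std::sqrt(c0[0] * c0[0] + c0[1] * c0[1] + c0[2] * c0[2]);
  for (int i = 0; i < 3; ++i) c0[i] /= n0;
  double d = c0[0] * c1[0] + c0[1] * c1[1] + c0[2] * c1[2];
  for (int i = 0; i < 3; ++i) c1[i] -= d * c0[i];
  double n1 = std::sqrt(c1[0] * c1[0] + c1[1] * c1[1] + c1[2] * c1[2]);
  for (int i = 0; i < 3; ++i) c1[i] /= n1;
  cross3(c0, c1, c2);
  for (int i = 0; i < 3; ++i) {
    R[3 * i] = c0[i];
    R[3 * i + 1] = c1[i];
    R[3 * i + 2] = c2[i];
  }
}

struct CellList {
  int m;
  double cell;
  std::vector<int> head, nxt;   // linked-list cells, no per-step allocs
  std::vector<int> ccx, ccy, ccz;
  void build(const std::vector<double>& pos, int n, double L,
             double rcut) {
    m = std::max(1, (int)std::floor(L / rcut));
    if (m > 40) m = 40;
    cell = L / m;
    head.assign((size_t)m * m * m, -1);
    nxt.resize(n);
    ccx.resize(n); ccy.resize(n); ccz.resize(n);
    for (int i = 0; i < n; ++i) {
      int cx = (int)std::floor(pos[3 * i] / cell) % m;
      int cy = (int)std::floor(pos[3 * i + 1] / cell) % m;
      int cz = (int)std::floor(pos[3 * i + 2] / cell) % m;
      if (cx < 0) cx += m;
      if (cy < 0) cy += m;
      if (cz < 0) cz += m;
      ccx[i] = cx; ccy[i] = cy; ccz[i] = cz;
      size_t c = (size_t)(cx * m + cy) * m + cz;
      nxt[i] = head[c];
      head[c] = i;
    }
  }
};

// [[Rcpp::export]]
List run_gb_cpp(NumericMatrix pos0, NumericMatrix ornt0, NumericVector ell,
                double eps, double zeta_cut, double kT, double gamma_t,
                double gamma_r, double dt, double box0, double box_target,
                int ramp_steps, int equil_steps, int prod_steps,
                int sample_every, bool langevin, bool track_collisions,
                double collision_zeta = 1.0, double zeta_floor = 0.2) {
  const int n = pos0.nrow();
  double l2[3] = {ell[0] * ell[0], ell[1] * ell[1], ell[2] * ell[2]};
  double sig_min = std::min(ell[0], std::min(ell[1], ell[2]));
  double lmax = std::max(ell[0], std::max(ell[1], ell[2]));
  double rcut = 2.0 * lmax + sig_min * (zeta_cut - 1.0) + 1e-9;

  std::vector<double> pos(3 * n), unwrapped(3 * n), R(9 * n), vel(3 * n, 0.0);
  for (int i = 0; i < n; ++i) {
    for (int k = 0; k < 3; ++k) {
      pos[3 * i + k] = pos0(i, k);
      unwrapped[3 * i + k] = pos0(i, k);
    }
    for (int k = 0; k < 9; ++k) R[9 * i + k] = ornt0(i, k);
  }
  double L = box0;
  const double ramp_factor =
    ramp_steps > 0 ? std::pow(box_target / box0, 1.0 / ramp_steps) : 1.0;

  std::vector<double> force(3 * n), torque(3 * n);
  std::vector<uint8_t> in_contact((size_t)n * n, 0);
  std::vector<double> collisions;  // i, j, time, thi, phii, thj, phij
  CellList cl;
  PairOut po;
  long n_capped = 0;

  const int total_steps = ramp_steps + equil_steps + prod_steps;
  const int n_frames = prod_steps / sample_every + 1;
  NumericMatrix frames_w(n_frames, 3 * n), frames_u(n_frames, 3 * n);
  NumericVector frame_times(n_frames);
  std::vector<double> epot_trace;
  int frame = 0;

  const double deg = 180.0 / M_PI;
  double sq2kTdt_t = std::sqrt(2.0 * kT * dt / gamma_t);
  double sq2kTdt_r = std::sqrt(2.0 * kT * dt / gamma_r);

  for (int step = 0; step <= total_steps; ++step) {
    bool production = step >= ramp_steps + equil_steps;
    // forces
    std::fill(force.begin(), force.end(), 0.0);
    std::fill(torque.begin(), torque.end(), 0.0);
    double epot = 0.0;
    bool use_cells = L / rcut >= 3.0 && n > 32;
    if (use_cells) cl.build(pos, n, L, rcut);

    auto interact = [&](int i, int j) {
      double rv[3];
      for (int k = 0; k < 3; ++k) {
        double d = pos[3 * j + k] - pos[3 * i + k];
        d -= L * std::nearbyint(d / L);
        rv[k] = d;
      }
      double r2 = rv[0] * rv[0] + rv[1] * rv[1] + rv[2] * rv[2];
      if (r2 >= rcut * rcut) {
        if (track_collisions) in_contact[(size_t)i * n + j] = 0;
        return;
      }
      gb_pair(rv, &R[9 * i], &R[9 * j], l2, sig_min, eps, zeta_cut,
              zeta_floor, po);
      if (po.capped) ++n_capped;
      epot += po.energy;
      for (int k = 0; k < 3; ++k) {
        force[3 * j + k] += po.force_j[k];
        force[3 * i + k] -= po.force_j[k];
        torque[3 * i + k] += po.torque_i[k];
        torque[3 * j + k] += po.torque_j[k];
      }
      if (track_collisions) {
        uint8_t& st = in_contact[(size_t)i * n + j];
        bool now = po.zeta < collision_zeta;
        if (now && !st && production) {
          // body-frame contact direction: towards the partner
          double r = std::sqrt(r2);
          double d_i[3], d_j[3];
          // body = R^T lab (columns of R are body axes in lab frame)
          for (int a = 0; a < 3; ++a) {
            d_i[a] = (R[9 * i + 0 * 3 + a] * rv[0] +
                      R[9 * i + 1 * 3 + a] * rv[1] +
                      R[9 * i + 2 * 3 + a] * rv[2]) / r;
            d_j[a] = -(R[9 * j + 0 * 3 + a] * rv[0] +
                       R[9 * j + 1 * 3 + a] * rv[1] +
                       R[9 * j + 2 * 3 + a] * rv[2]) / r;
          }
          double thi = std::acos(std::max(-1.0, std::min(1.0, d_i[0]))) * deg;
          double phi_i = std::atan2(d_i[2], d_i[1]) * deg;
          if (phi_i < 0) phi_i += 360.0;
          double thj = std::acos(std::max(-1.0, std::min(1.0, d_j[0]))) * deg;
          double phi_j = std::atan2(d_j[2], d_j[1]) * deg;
          if (phi_j < 0) phi_j += 360.0;
          double t_now = (step - ramp_steps - equil_steps) * dt;
          collisions.insert(collisions.end(),
                            {(double)(i + 1), (double)(j + 1), t_now,
                             thi, phi_i, thj, phi_j});
        }
        st = now ? 1 : 0;
      }
    };

    if (use_cells) {
      int m = cl.m;
      for (int i = 0; i < n; ++i) {
        for (int dx = -1; dx <= 1; ++dx)
          for (int dy = -1; dy <= 1; ++dy)
            for (int dz = -1; dz <= 1; ++dz) {
              int ox = (cl.ccx[i] + dx + m) % m,
                  oy = (cl.ccy[i] + dy + m) % m,
                  oz = (cl.ccz[i] + dz + m) % m;
              size_t oc = (size_t)(ox * m + oy) * m + oz;
              for (int j = cl.head[oc]; j >= 0; j = cl.nxt[j])
                if (j > i) interact(i, j);
            }
      }
    } else {
      for (int i = 0; i < n - 1; ++i)
        for (int j = i + 1; j < n; ++j) interact(i, j);
    }

    if (production && step % sample_every == 0 && frame < n_frames) {
      for (int i = 0; i < n; ++i)
        for (int k = 0; k < 3; ++k) {
          frames_w(frame, 3 * i + k) = pos[3 * i + k];
          frames_u(frame, 3 * i + k) = unwrapped[3 * i + k];
        }
      frame_times[frame] = (step - ramp_steps - equil_steps) * dt;
      epot_trace.push_back(epot);
      ++frame;
    }
    if (step == total_steps) break;

    // integrate; the deterministic drift is capped at a fraction of the
    // particle size per step so that deep-overlap forces relax overlaps
    // instead of ejecting particles
    const double max_drift = 0.25 * sig_min;
    for (int i = 0; i < n; ++i) {
      double drift[3];
      double fmag = 0.0;
      for (int k = 0; k < 3; ++k) {
        drift[k] = force[3 * i + k] / gamma_t * dt;
        fmag += drift[k] * drift[k];
      }
      fmag = std::sqrt(fmag);
      if (fmag > max_drift)
        for (int k = 0; k < 3; ++k) drift[k] *= max_drift / fmag;
      for (int k = 0; k < 3; ++k) {
        double dx;
        if (langevin) {
          double& v = vel[3 * i + k];
          v += (force[3 * i + k] - gamma_t * v) * dt +
            std::sqrt(2.0 * gamma_t * kT * dt) * R::norm_rand();
          double vcap = max_drift / dt;
          if (v > vcap) v = vcap;
          if (v < -vcap) v = -vcap;
          dx = v * dt;
        } else {
          dx = drift[k] + sq2kTdt_t * R::norm_rand();
        }
        pos[3 * i + k] += dx;
        unwrapped[3 * i + k] += dx;
        pos[3 * i + k] -= L * std::floor(pos[3 * i + k] / L);
      }
      double omega[3];
      double tmag = 0.0;
      for (int k = 0; k < 3; ++k) {
        omega[k] = torque[3 * i + k] / gamma_r * dt;
        tmag += omega[k] * omega[k];
      }
      tmag = std::sqrt(tmag);
      if (tmag > 0.25)
        for (int k = 0; k < 3; ++k) omega[k] *= 0.25 / tmag;
      for (int k = 0; k < 3; ++k)
        omega[k] += sq2kTdt_r * R::norm_rand();
      rotate_orientation(&R[9 * i], omega);
    }
    if (step % 500 == 0)
      for (int i = 0; i < n; ++i) orthonormalize(&R[9 * i]);

    // box ramp with affine rescale
    if (step < ramp_steps) {
      L *= ramp_factor;
      for (int i = 0; i < n; ++i)
        for (int k = 0; k < 3; ++k) {
          pos[3 * i + k] *= ramp_factor;
          unwrapped[3 * i + k] = pos[3 * i + k];
        }
    }
    if (!std::isfinite(epot) || std::fabs(epot) > 1e12 * (n + 1))
      stop("dynamics instability: potential energy blow-up at step %d",
           step);
  }

  NumericMatrix coll(collisions.size() / 7, 7);
  for (size_t e = 0; e < collisions.size() / 7; ++e)
    for (int k = 0; k < 7; ++k) coll(e, k) = collisions[7 * e + k];
  NumericMatrix orn_out(n, 9);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < 9; ++k) orn_out(i, k) = R[9 * i + k];
  return List::create(
    _["wrapped"] = frames_w, _["unwrapped"] = frames_u,
    _["times"] = frame_times, _["box"] = L,
    _["epot"] = NumericVector(epot_trace.begin(), epot_trace.end()),
    _["collisions"] = coll, _["orientations"] = orn_out,
    _["n_capped"] = (double)n_capped);
}
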