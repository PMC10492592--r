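// Polarization-tracking Monte Carlo photon transport in a rectangular
// suspension slab, with backscatter detection through co/cross linear and
// circular analyzer channels and per-pixel scattering-event bookkeeping.
//
// Conventions (shared with the R-level packet operations):
//  * Right-handed local triad (e1, e2, v); the Stokes vector (I,Q,U,V) is
//    referenced to e1 ("parallel") / e2 ("perpendicular"); V > 0 is
//    right-circular in the receiver-frame optics convention.
//  * A scattering event rotates the frame about v by phi (Mueller rotation
//    R(phi)), deflects v by theta in the (e1', v) plane, applies the sphere
//    Mueller matrix M(theta), and renormalizes I to the packet weight.
//  * (theta, phi) are sampled by rejection from
//    P(theta, phi) ~ M11 I + M12 (Q cos 2phi + U sin 2phi)
//    with envelope M11 (1 + sqrt(Q^2 + U^2)) and theta proposals from the
//    tabulated M11 sin(theta) marginal.
#include <Rcpp.h>
#include <cstdint>
#include <cmath>
using namespace Rcpp;

namespace {

// ---- RNG: xoshiro256++ seeded via a splitmix64 chain; one independent
// stream per packet derived from the master seed and packet index, so
// results do not depend on execution order.
struct Xoshiro {
  uint64_t s[4];
  static uint64_t splitmix(uint64_t &x) {
    x += 0x9E3779B97F4A7C15ULL;
    uint64_t z = x;
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }
  void seed(uint64_t master, uint64_t idx) {
    uint64_t x = master ^ (0x9E3779B97F4A7C15ULL * (idx + 1));
    for (int i = 0; i < 4; ++i) s[i] = splitmix(x);
  }
  static uint64_t rotl(uint64_t x, int k) { return (x << k) | (x >> (64 - k)); }
  uint64_t next() {
    uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return result;
  }
  // uniform in (0, 1)
  double u01() { return ((next() >> 11) + 0.5) * (1.0 / 9007199254740992.0); }
};

struct Vec3 {
  double x, y, z;
};
inline Vec3 operator+(Vec3 a, Vec3 b) { return {a.x + b.x, a.y + b.y, a.z + b.z}; }
inline Vec3 operator*(double c, Vec3 a) { return {c * a.x, c * a.y, c * a.z}; }
inline double dot(Vec3 a, Vec3 b) { return a.x * b.x + a.y * b.y + a.z * b.z; }
inline Vec3 cross(Vec3 a, Vec3 b) {
  return {a.y * b.z - a.z * b.y, a.z * b.x - a.x * b.z, a.x * b.y - a.y * b.x};
}
inline Vec3 normalize(Vec3 a) {
  double n = std::sqrt(dot(a, a));
  return {a.x / n, a.y / n, a.z / n};
}

}  // namespace

// [[Rcpp::export]]
List mc_backscatter_cpp(NumericVector theta_deg, NumericVector m11,
                        NumericVector m12, NumericVector m33,
                        NumericVector m34, double mus, double mua, double Lx,
                        double Ly, double Lz, double beam_radius_cm,
                        int incident_code, int nx, int ny, double field_cm,
                        double acceptance_deg, double n_packets_d,
                        double seed_d, double max_events_d, int n_record) {
  const int nt = theta_deg.size();
  const double dtheta = (theta_deg[nt - 1] - theta_deg[0]) / (nt - 1);
  const double deg2rad = M_PI / 180.0;

  // cumulative trapezoid masses of M11(theta) sin(theta) per grid segment
  std::vector<double> w(nt), cum(nt, 0.0);
  for (int i = 0; i < nt; ++i) w[i] = m11[i] * std::sin(theta_deg[i] * deg2rad);
  for (int i = 1; i < nt; ++i) cum[i] = cum[i - 1] + 0.5 * (w[i - 1] + w[i]) * dtheta;
  const double wtot = cum[nt - 1];

  const double mut = mus + mua;
  const double albedo = mut > 0 ? mus / mut : 1.0;
  const double cos_accept = std::cos(acceptance_deg * deg2rad);
  const double half_field = field_cm / 2.0;
  const double px = field_cm / nx, py = field_cm / ny;
  const uint64_t n_packets = (uint64_t)n_packets_d;
  const uint64_t master_seed = (uint64_t)seed_d;
  const uint64_t max_events = (uint64_t)max_events_d;

  // incident Stokes (I = 1) and analyzer signs
  double S0Q = 0, S0U = 0, S0V = 0;
  switch (incident_code) {
    case 0: S0U = -1; break;  // linear -45 deg
    case 1: S0U = 1; break;   // linear +45 deg
    case 2: S0V = 1; break;   // right circular
    case 3: S0V = -1; break;  // left circular
    default: stop("unknown incident_code");
  }
  const double s_lin = (incident_code == 1) ? 1.0 : -1.0;
  const double s_circ = (incident_code == 3) ? -1.0 : 1.0;

  const int npix = nx * ny;
  NumericVector co_lin(npix), cross_lin(npix), co_circ(npix), cross_circ(npix),
      counts(npix), nscat_sum(npix), path_sum(npix), nscat_co_lin(npix),
      nscat_cross_lin(npix), nscat_co_circ(npix), nscat_cross_circ(npix);
  double n_detected = 0, n_out_of_grid = 0, n_top_exits = 0, n_capped = 0,
         n_rejection_failures = 0;

  NumericMatrix rec(n_record > 0 ? n_record : 1, 11);
  int recorded = 0;

  for (uint64_t ip = 0; ip < n_packets; ++ip) {
    Xoshiro rng;
    rng.seed(master_seed, ip);

    // launch: uniform on beam disc at the top face, heading +z into medium
    double r = beam_radius_cm * std::sqrt(rng.u01());
    double a0 = 2.0 * M_PI * rng.u01();
    Vec3 pos = {r * std::cos(a0), r * std::sin(a0), 0.0};
    Vec3 v = {0, 0, 1}, e1 = {1, 0, 0}, e2 = {0, 1, 0};
    double Q = S0Q, U = S0U, V = S0V;
    double weight = 1.0, path = 0.0;
    uint64_t nscat = 0;
    bool alive = true;

    while (alive) {
      double step = -std::log(rng.u01()) / mut;
      // distance to the nearest boundary along v
      double t_exit = INFINITY;
      int face = -1;  // 0 top(z=0), 1 bottom, 2..5 sides
      if (v.z < 0) { double t = -pos.z / v.z; if (t < t_exit) { t_exit = t; face = 0; } }
      if (v.z > 0) { double t = (Lz - pos.z) / v.z; if (t < t_exit) { t_exit = t; face = 1; } }
      if (v.x > 0) { double t = (Lx / 2 - pos.x) / v.x; if (t < t_exit) { t_exit = t; face = 2; } }
      if (v.x < 0) { double t = (-Lx / 2 - pos.x) / v.x; if (t < t_exit) { t_exit = t; face = 3; } }
      if (v.y > 0) { double t = (Ly / 2 - pos.y) / v.y; if (t < t_exit) { t_exit = t; face = 4; } }
      if (v.y < 0) { double t = (-Ly / 2 - pos.y) / v.y; if (t < t_exit) { t_exit = t; face = 5; } }

      if (step >= t_exit) {
        // move to the boundary and leave (index-matched boundaries)
        pos = pos + t_exit * v;
        path += t_exit;
        alive = false;
        if (face == 0) {
          n_top_exits += 1;
          double ce = -v.z;
          if (ce >= cos_accept) {
            // detection-frame rotation: d1 = x-hat projected off v, d2 = v x d1
            Vec3 d1 = {1 - v.x * v.x, -v.x * v.y, -v.x * v.z};
            d1 = normalize(d1);
            // rotation angle from (e1,e2) to the detection basis
            // (d1, v x d1) about v: d1 = cos(psi) e1 + sin(psi) e2
            double cpsi = dot(e1, d1), spsi = dot(e2, d1);
            double c2 = cpsi * cpsi - spsi * spsi, s2 = 2.0 * spsi * cpsi;
            double Qd = Q * c2 + U * s2;
            double Ud = -Q * s2 + U * c2;
            double i_co_l = 0.5 * (1.0 - s_lin * Ud) * weight;
            double i_cx_l = 0.5 * (1.0 + s_lin * Ud) * weight;
            double i_co_c = 0.5 * (1.0 + s_circ * V) * weight;
            double i_cx_c = 0.5 * (1.0 - s_circ * V) * weight;
            n_detected += 1;
            int ix = (int)std::floor((pos.x + half_field) / px);
            int iy = (int)std::floor((pos.y + half_field) / py);
            if (ix >= 0 && ix < nx && iy >= 0 && iy < ny) {
              int k = iy * nx + ix;
              co_lin[k] += i_co_l; cross_lin[k] += i_cx_l;
              co_circ[k] += i_co_c; cross_circ[k] += i_cx_c;
              counts[k] += weight;
              nscat_sum[k] += weight * (double)nscat;
              path_sum[k] += weight * path;
              nscat_co_lin[k] += i_co_l * (double)nscat;
              nscat_cross_lin[k] += i_cx_l * (double)nscat;
              nscat_co_circ[k] += i_co_c * (double)nscat;
              nscat_cross_circ[k] += i_cx_c * (double)nscat;
            } else {
              n_out_of_grid += 1;
            }
            if (recorded < n_record) {
              rec(recorded, 0) = pos.x; rec(recorded, 1) = pos.y;
              rec(recorded, 2) = v.x; rec(recorded, 3) = v.y; rec(recorded, 4) = v.z;
              rec(recorded, 5) = weight; rec(recorded, 6) = Qd;
              rec(recorded, 7) = Ud; rec(recorded, 8) = V;
              rec(recorded, 9) = (double)nscat; rec(recorded, 10) = path;
              ++recorded;
            }
          }
        }
        break;
      }

      // interior scattering event
      pos = pos + step * v;
      path += step;
      weight *= albedo;

      double pdop = std::sqrt(Q * Q + U * U);
      double theta = 0, phi = 0, c2p = 1, s2p = 0;
      bool accepted = false;
      for (int it = 0; it < 10000; ++it) {
        // theta proposal from the tabulated M11 sin(theta) marginal
        double uu = rng.u01() * wtot;
        int lo = 0, hi = nt - 1;
        while (hi - lo > 1) {
          int mid = (lo + hi) / 2;
          if (cum[mid] <= uu) lo = mid; else hi = mid;
        }
        double seg = cum[hi] - cum[lo];
        double frac = seg > 0 ? (uu - cum[lo]) / seg : 0.5;
        theta = (theta_deg[lo] + frac * dtheta) * deg2rad;
        phi = 2.0 * M_PI * rng.u01();
        c2p = std::cos(2.0 * phi);
        s2p = std::sin(2.0 * phi);
        double g = theta / (dtheta * deg2rad);
        int i0 = (int)g; if (i0 >= nt - 1) i0 = nt - 2;
        double f = g - i0;
        double m11t = m11[i0] + f * (m11[i0 + 1] - m11[i0]);
        double m12t = m12[i0] + f * (m12[i0 + 1] - m12[i0]);
        double ratio = (1.0 + (m12t / m11t) * (Q * c2p + U * s2p)) / (1.0 + pdop);
        if (rng.u01() <= ratio) { accepted = true; break; }
      }
      if (!accepted) { n_rejection_failures += 1; break; }

      // frame rotation about v by phi
      double cp = std::cos(phi), sp = std::sin(phi);
      Vec3 e1r = cp * e1 + sp * e2;
      Vec3 e2r = -1.0 * sp * e1 + cp * e2;
      double Qr = Q * c2p + U * s2p;
      double Ur = -Q * s2p + U * c2p;

      // deflect v by theta in the (e1r, v) plane
      double ct = std::cos(theta), st = std::sin(theta);
      Vec3 vn = st * e1r + ct * v;
      Vec3 e1n = ct * e1r + (-st) * v;

      // Mueller matrix at theta (linear interpolation), then renormalize I
      double g = theta / (dtheta * deg2rad);
      int i0 = (int)g; if (i0 >= nt - 1) i0 = nt - 2;
      double f = g - i0;
      double m11t = m11[i0] + f * (m11[i0 + 1] - m11[i0]);
      double m12t = m12[i0] + f * (m12[i0 + 1] - m12[i0]);
      double m33t = m33[i0] + f * (m33[i0 + 1] - m33[i0]);
      double m34t = m34[i0] + f * (m34[i0 + 1] - m34[i0]);
      double Iout = m11t + m12t * Qr;
      if (Iout < 1e-300) { break; }  // fully extinguished state (P = 0)
      Q = (m12t + m11t * Qr) / Iout;
      U = (m33t * Ur + m34t * V) / Iout;
      V = (-m34t * Ur + m33t * V) / Iout;

      v = vn; e1 = e1n; e2 = e2r;
      ++nscat;
      if (nscat % 64 == 0) {
        // guard against orthonormality drift
        v = normalize(v);
        e1 = normalize(e1 + (-dot(e1, v)) * v);
        e2 = cross(v, e1);
      }
      if (nscat >= max_events) { n_capped += 1; break; }
    }
  }

  List images = List::create(
      _["co_linear"] = co_lin, _["cross_linear"] = cross_lin,
      _["co_circular"] = co_circ, _["cross_circular"] = cross_circ,
      _["counts"] = counts, _["nscat_sum"] = nscat_sum,
      _["path_sum"] = path_sum, _["nscat_co_linear"] = nscat_co_lin,
      _["nscat_cross_linear"] = nscat_cross_lin,
      _["nscat_co_circular"] = nscat_co_circ,
      _["nscat_cross_circular"] = nscat_cross_circ);
  return List::create(
      _["images"] = images,
      _["n_detected"] = n_detected, _["n_out_of_grid"] = n_out_of_grid,
      _["n_top_exits"] = n_top_exits, _["n_capped"] = n_capped,
      _["n_rejection_failures"] = n_rejection_failures,
      _["exits"] = rec, _["n_recorded"] = recorded);
}
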