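// Force field and MD core.
//
// Unit system: length nm, energy kcal/mol, mass g/mol (amu), time ps
// (user-facing time steps are in fs; callers convert).  Because
// 1 kcal/mol = 4.184 amu nm^2/ps^2, accelerations from forces in
// kcal/mol/nm need the factor KCAL below, and kinetic energies in
// amu nm^2/ps^2 are divided by it to land back in kcal/mol.

#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

static const double KCAL = 4.184;       // amu nm^2/ps^2 per kcal/mol
static const double KB = 1.9872e-3;     // kcal/mol/K

struct FF {
  double l0, kd, th0, kth, kphi, sigma, epsh, Rc;
  double eps[3][3];
  double lam[3][3];
  double ushift[3][3];  // pair potential value at Rc (subtracted when shifting)
  bool shift;
};

static FF unpack_ff(const List& ffl) {
  FF ff;
  ff.l0 = as<double>(ffl["l0"]);
  ff.kd = as<double>(ffl["kd"]);
  ff.th0 = as<double>(ffl["theta0"]);
  ff.kth = as<double>(ffl["ktheta"]);
  ff.kphi = as<double>(ffl["kphi"]);
  ff.sigma = as<double>(ffl["sigma"]);
  ff.epsh = as<double>(ffl["eps_h"]);
  ff.Rc = as<double>(ffl["Rc"]);
  ff.shift = as<bool>(ffl["shift_at_cutoff"]);
  NumericMatrix em = ffl["epsilon_matrix"];
  NumericMatrix lm = ffl["lambda_matrix"];
  double sr = ff.sigma / ff.Rc;
  double sr6 = std::pow(sr, 6);
  for (int a = 0; a < 3; ++a)
    for (int b = 0; b < 3; ++b) {
      ff.eps[a][b] = em(a, b);
      ff.lam[a][b] = lm(a, b);
      ff.ushift[a][b] = ff.shift
        ? 4.0 * ff.eps[a][b] * (sr6 * sr6 - ff.lam[a][b] * sr6)
        : 0.0;
    }
  return ff;
}

struct V3 {
  double x, y, z;
  V3() : x(0), y(0), z(0) {}
  V3(double x_, double y_, double z_) : x(x_), y(y_), z(z_) {}
};
static inline V3 operator-(const V3& a, const V3& b) { return V3(a.x-b.x, a.y-b.y, a.z-b.z); }
static inline V3 operator+(const V3& a, const V3& b) { return V3(a.x+b.x, a.y+b.y, a.z+b.z); }
static inline V3 operator*(double s, const V3& a) { return V3(s*a.x, s*a.y, s*a.z); }
static inline double dot(const V3& a, const V3& b) { return a.x*b.x + a.y*b.y + a.z*b.z; }
static inline V3 cross(const V3& a, const V3& b) {
  return V3(a.y*b.z - a.z*b.y, a.z*b.x - a.x*b.z, a.x*b.y - a.y*b.x);
}
static inline double norm(const V3& a) { return std::sqrt(dot(a, a)); }

struct Energies {
  double stretch, bend, torsion, nonbonded;
  double total() const { return stretch + bend + torsion + nonbonded; }
};

// Evaluate all four terms and accumulate analytic forces (negative gradients).
static Energies eval_forces(const std::vector<V3>& r, const std::vector<int>& cls,
                            const FF& ff, std::vector<V3>& f) {
  const int n = (int) r.size();
  Energies e = {0, 0, 0, 0};
  for (int i = 0; i < n; ++i) f[i] = V3();

  // stretch: bonds (i, i+1)
  for (int i = 0; i + 1 < n; ++i) {
    V3 d = r[i + 1] - r[i];
    double l = norm(d);
    double dl = l - ff.l0;
    e.stretch += 0.5 * ff.kd * dl * dl;
    double c = ff.kd * dl / l;
    V3 g = c * d;                 // dE/dr_{i+1}
    f[i + 1] = f[i + 1] - g;
    f[i] = f[i] + g;
  }

  // bend: deflection angle between consecutive bond vectors at bead i
  // (theta = 0 for a straight chain; theta0 = 1.231 rad is the tetrahedral
  // supplement, i.e. a valence angle of 109.5 deg)
  for (int i = 1; i + 1 < n; ++i) {
    V3 u = r[i] - r[i - 1];
    V3 v = r[i + 1] - r[i];
    double lu = norm(u), lv = norm(v);
    double ct = dot(u, v) / (lu * lv);
    if (ct > 1.0) ct = 1.0;
    if (ct < -1.0) ct = -1.0;
    double th = std::acos(ct);
    double dth = th - ff.th0;
    e.bend += 0.5 * ff.kth * dth * dth;
    double st = std::sqrt(1.0 - ct * ct);
    if (st < 1e-8) st = 1e-8;      // collinear: clamped, force capped
    double pref = ff.kth * dth / st;
    // Gu = dcos/du, Gv = dcos/dv with u = r_i - r_{i-1}, v = r_{i+1} - r_i
    V3 Gu = (1.0 / (lu * lv)) * v - (ct / (lu * lu)) * u;
    V3 Gv = (1.0 / (lu * lv)) * u - (ct / (lv * lv)) * v;
    V3 ga = (-pref) * Gu;          // force on bead i-1
    V3 gc = pref * Gv;             // force on bead i+1
    f[i - 1] = f[i - 1] + ga;
    f[i + 1] = f[i + 1] + gc;
    f[i] = f[i] - (ga + gc);
  }

  // torsion: quadruplets (i, i+1, i+2, i+3); phi measured from trans (phi=0)
  for (int i = 0; i + 3 < n; ++i) {
    V3 b1 = r[i + 1] - r[i];
    V3 b2 = r[i + 2] - r[i + 1];
    V3 b3 = r[i + 3] - r[i + 2];
    V3 n1 = cross(b1, b2);
    V3 n2 = cross(b2, b3);
    double n1sq = dot(n1, n1), n2sq = dot(n2, n2);
    double b2n = norm(b2);
    if (n1sq < 1e-18 || n2sq < 1e-18) continue; // collinear: phi := 0 (trans), no force
    double x = dot(n1, n2);
    double y = dot(cross(n1, n2), b2) / b2n;
    double phi_std = std::atan2(y, x);          // cis = 0 convention
    double phi = phi_std > 0 ? phi_std - M_PI : phi_std + M_PI; // trans = 0
    e.torsion += 0.5 * ff.kphi * (1.0 - std::cos(3.0 * phi));
    double dEdphi = 1.5 * ff.kphi * std::sin(3.0 * phi);
    // gradients of phi_std (== gradients of phi, constant offset)
    V3 dphi1 = (-b2n / n1sq) * n1;
    V3 dphi4 = (b2n / n2sq) * n2;
    double c12 = dot(b1, b2) / (b2n * b2n);
    double c32 = dot(b3, b2) / (b2n * b2n);
    V3 dphi2 = (-1.0 - c12) * dphi1 + c32 * dphi4;
    V3 dphi3 = c12 * dphi1 + (-1.0 - c32) * dphi4;
    f[i]     = f[i]     - dEdphi * dphi1;
    f[i + 1] = f[i + 1] - dEdphi * dphi2;
    f[i + 2] = f[i + 2] - dEdphi * dphi3;
    f[i + 3] = f[i + 3] - dEdphi * dphi4;
  }

  // nonbonded: |j - i| >= 4, truncated (and optionally shifted) 12-6 LJ
  double Rc2 = ff.Rc * ff.Rc;
  for (int i = 0; i < n; ++i) {
    for (int j = i + 4; j < n; ++j) {
      V3 d = r[j] - r[i];
      double r2 = dot(d, d);
      if (r2 > Rc2) continue;
      int a = cls[i], b = cls[j];
      double s2 = ff.sigma * ff.sigma / r2;
      double s6 = s2 * s2 * s2;
      double s12 = s6 * s6;
      e.nonbonded += 4.0 * ff.eps[a][b] * (s12 - ff.lam[a][b] * s6) - ff.ushift[a][b];
      double fmag = 24.0 * ff.eps[a][b] * (2.0 * s12 - ff.lam[a][b] * s6) / r2;
      V3 g = fmag * d;            // force on j
      f[j] = f[j] + g;
      f[i] = f[i] - g;
    }
  }
  return e;
}

static void mat_to_vec(const NumericMatrix& m, std::vector<V3>& v) {
  int n = m.nrow();
  v.resize(n);
  for (int i = 0; i < n; ++i) v[i] = V3(m(i, 0), m(i, 1), m(i, 2));
}

// [[Rcpp::export]]
List cpp_energy_forces(NumericMatrix positions, IntegerVector classes, List ff_list) {
  FF ff = unpack_ff(ff_list);
  std::vector<V3> r, f;
  mat_to_vec(positions, r);
  int n = (int) r.size();
  std::vector<int> cls(classes.begin(), classes.end());
  f.resize(n);
  Energies e = eval_forces(r, cls, ff, f);
  NumericMatrix fm(n, 3);
  for (int i = 0; i < n; ++i) { fm(i, 0) = f[i].x; fm(i, 1) = f[i].y; fm(i, 2) = f[i].z; }
  return List::create(
    _["stretch"] = e.stretch, _["bend"] = e.bend, _["torsion"] = e.torsion,
    _["nonbonded"] = e.nonbonded, _["total"] = e.total(), _["forces"] = fm);
}

// Velocity-Verlet MD with optional single Nose-Hoover thermostat
// (Martyna-Tuckerman-Klein splitting, one thermostat, no chains).
// T_target in Kelvin; T_target < 0 runs NVE.  dt and tau in ps.
// Samples (energies + instantaneous T + xi) every sample_stride steps,
// frames (positions) every frame_stride steps; step 0 is always sampled.
// [[Rcpp::export]]
List cpp_run_md(NumericMatrix positions, NumericMatrix velocities,
                NumericVector masses, IntegerVector classes, List ff_list,
                double dt, int n_steps, double T_target, double tau,
                int frame_stride, int sample_stride, double xi0) {
  FF ff = unpack_ff(ff_list);
  std::vector<V3> r, v, f;
  mat_to_vec(positions, r);
  mat_to_vec(velocities, v);
  int n = (int) r.size();
  std::vector<int> cls(classes.begin(), classes.end());
  std::vector<double> m(masses.begin(), masses.end());
  f.resize(n);

  bool nvt = T_target > 0;
  int nfree = 3 * n - 6;          // net translation and rotation removed
  double G = nfree * KB * T_target;          // kcal/mol
  double Q = nvt ? G * tau * tau : 1.0;      // kcal/mol ps^2
  double xi = xi0;

  Energies e = eval_forces(r, cls, ff, f);

  auto kinetic = [&]() {
    double k = 0;
    for (int i = 0; i < n; ++i) k += m[i] * dot(v[i], v[i]);
    return 0.5 * k / KCAL;        // kcal/mol
  };

  int n_samples = n_steps / sample_stride + 1;
  int n_frames = n_steps / frame_stride + 1;
  NumericMatrix samples(n_samples, 9); // step, stretch, bend, torsion, nonbonded, pot, kin, Tinst, xi
  NumericVector frames(Dimension(n_frames, n, 3));
  IntegerVector frame_steps(n_frames);
  int si = 0, fi = 0;

  auto record = [&](int step) {
    if (step % sample_stride == 0 && si < n_samples) {
      double K = kinetic();
      samples(si, 0) = step;
      samples(si, 1) = e.stretch; samples(si, 2) = e.bend;
      samples(si, 3) = e.torsion; samples(si, 4) = e.nonbonded;
      samples(si, 5) = e.total(); samples(si, 6) = K;
      samples(si, 7) = 2.0 * K / (nfree * KB);
      samples(si, 8) = xi;
      ++si;
    }
    if (step % frame_stride == 0 && fi < n_frames) {
      for (int i = 0; i < n; ++i) {
        frames[fi + (size_t) n_frames * (0 * n + i)] = r[i].x;
        frames[fi + (size_t) n_frames * (1 * n + i)] = r[i].y;
        frames[fi + (size_t) n_frames * (2 * n + i)] = r[i].z;
      }
      frame_steps[fi] = step;
      ++fi;
    }
  };

  record(0);

  for (int step = 1; step <= n_steps; ++step) {
    if (nvt) {                    // half-step thermostat
      double K = kinetic();
      xi += 0.25 * dt * (2.0 * K - G) / Q;
      double s = std::exp(-0.5 * dt * xi);
      for (int i = 0; i < n; ++i) v[i] = s * v[i];
      K *= s * s;
      xi += 0.25 * dt * (2.0 * K - G) / Q;
    }
    for (int i = 0; i < n; ++i)   // kick
      v[i] = v[i] + (0.5 * dt * KCAL / m[i]) * f[i];
    for (int i = 0; i < n; ++i)   // drift
      r[i] = r[i] + dt * v[i];
    e = eval_forces(r, cls, ff, f);
    if (!std::isfinite(e.total()))
      stop("non-finite energy at step %d (bead overlap or blow-up)", step);
    for (int i = 0; i < n; ++i)   // kick
      v[i] = v[i] + (0.5 * dt * KCAL / m[i]) * f[i];
    if (nvt) {
      double K = kinetic();
      xi += 0.25 * dt * (2.0 * K - G) / Q;
      double s = std::exp(-0.5 * dt * xi);
      for (int i = 0; i < n; ++i) v[i] = s * v[i];
      K *= s * s;
      xi += 0.25 * dt * (2.0 * K - G) / Q;
    }
    record(step);
  }

  NumericMatrix rp(n, 3), vp(n, 3);
  for (int i = 0; i < n; ++i) {
    rp(i, 0) = r[i].x; rp(i, 1) = r[i].y; rp(i, 2) = r[i].z;
    vp(i, 0) = v[i].x; vp(i, 1) = v[i].y; vp(i, 2) = v[i].z;
  }
  colnames(samples) = CharacterVector::create(
    "step", "stretch", "bend", "torsion", "nonbonded", "potential",
    "kinetic", "T_inst", "xi");
  return List::create(
    _["positions"] = rp, _["velocities"] = vp, _["xi"] = xi,
    _["samples"] = samples, _["frames"] = frames, _["frame_steps"] = frame_steps);
}

// Contact count: unordered pairs with |i - j| > lcut and r_ij <= Rcut.
// [[Rcpp::export]]
int cpp_contact_count(NumericMatrix positions, double Rcut, int lcut) {
  int n = positions.nrow();
  double R2 = Rcut * Rcut;
  int count = 0;
  for (int i = 0; i < n; ++i)
    for (int j = i + lcut + 1; j < n; ++j) {
      double dx = positions(j, 0) - positions(i, 0);
      double dy = positions(j, 1) - positions(i, 1);
      double dz = positions(j, 2) - positions(i, 2);
      if (dx * dx + dy * dy + dz * dz <= R2) ++count;
    }
  return count;
}
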