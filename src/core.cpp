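// Langevin-dynamics core for a coarse-grained bead-spring DNA chain packaged
// into / ejected from a spherical capsid through a narrow portal channel.
//
// Reduced units throughout: sigma (length), k_BT (energy), m (mass),
// tau = sqrt(m sigma^2 / k_BT) (time).  The chain is a Kremer-Grest FENE+WCA
// polymer with a two-block bending potential K(1 + cos theta), theta the
// interior bond angle (straight chain => zero energy).  The capsid shell is a
// set of fixed WCA particles on a Fibonacci sphere; the portal is a square
// channel of four WCA wall planes; the removable blockage is one WCA plane
// across the channel's inner mouth.  Integration is BAOAB velocity-Verlet
// Langevin; with friction 0 and the thermostat off it reduces exactly to NVE
// velocity Verlet.

#ifdef __GNUC__
#pragma GCC optimize("O3")
#endif

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>
#include <string>
#include <sstream>

using namespace Rcpp;

// ---------------------------------------------------------------- RNG -----
// xoshiro256++ seeded through splitmix64; deterministic and platform-stable.

struct RNG {
  uint64_t s[4];
  explicit RNG(uint64_t seed) {
    uint64_t x = seed;
    for (int i = 0; i < 4; ++i) {
      x += 0x9e3779b97f4a7c15ULL;
      uint64_t z = x;
      z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
      z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
      s[i] = z ^ (z >> 31);
    }
    have_spare = false;
  }
  static uint64_t rotl(uint64_t x, int k) { return (x << k) | (x >> (64 - k)); }
  uint64_t next() {
    uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t;    s[3] = rotl(s[3], 45);
    return result;
  }
  double unif() {  // in (0,1)
    return ((next() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
  bool have_spare; double spare;
  double norm();   // ziggurat, defined after the tables
};

// Marsaglia-Tsang ziggurat for standard normals (the thermostat draws 3n
// normals per step, so the sampler speed sets the overall step cost)
struct ZigguratTables {
  uint32_t kn[128];
  double wn[128], fn[128];
  ZigguratTables() {
    const double m1 = 2147483648.0;
    double dn = 3.442619855899, tn = dn;
    const double vn = 9.91256303526217e-3;
    double q = vn / std::exp(-0.5 * dn * dn);
    kn[0] = (uint32_t)((dn / q) * m1);
    kn[1] = 0;
    wn[0] = q / m1;
    wn[127] = dn / m1;
    fn[0] = 1.0;
    fn[127] = std::exp(-0.5 * dn * dn);
    for (int i = 126; i >= 1; --i) {
      dn = std::sqrt(-2.0 * std::log(vn / dn + std::exp(-0.5 * dn * dn)));
      kn[i + 1] = (uint32_t)((dn / tn) * m1);
      tn = dn;
      fn[i] = std::exp(-0.5 * dn * dn);
      wn[i] = dn / m1;
    }
  }
};
static const ZigguratTables ZIG;

inline double RNG::norm() {
  const double r_tail = 3.442619855899;
  for (;;) {
    int32_t hz = (int32_t)(uint32_t)next();
    uint32_t iz = (uint32_t)hz & 127u;
    uint32_t ahz = hz < 0 ? (uint32_t)(-(int64_t)hz) : (uint32_t)hz;
    if (ahz < ZIG.kn[iz]) return hz * ZIG.wn[iz];
    if (iz == 0) {            // tail
      double x, y;
      do {
        x = -std::log(unif()) / r_tail;
        y = -std::log(unif());
      } while (y + y < x * x);
      return hz > 0 ? r_tail + x : -(r_tail + x);
    }
    double x = hz * ZIG.wn[iz];
    if (ZIG.fn[iz] + unif() * (ZIG.fn[iz - 1] - ZIG.fn[iz]) <
        std::exp(-0.5 * x * x))
      return x;
  }
}

// ---------------------------------------------------------- parameters ----

struct Params {
  int n;
  double K, R0, eps, sigma, mass, dt, gamma, temp;
  double KF, KL;
  double fp, fr, tau_stall;
  int stall_every;
  Params(const List& p) {
    n = as<int>(p["n_monomers"]);
    K = as<double>(p["K"]); R0 = as<double>(p["R0"]);
    eps = as<double>(p["epsilon"]); sigma = as<double>(p["sigma_reduced"]);
    mass = as<double>(p["mass"]); dt = as<double>(p["dt"]);
    gamma = as<double>(p["friction"]); temp = as<double>(p["temperature"]);
    KF = as<double>(p["K_F"]); KL = as<double>(p["K_L"]);
    fp = as<double>(p["f_p"]); fr = as<double>(p["f_r"]);
    tau_stall = as<double>(p["tau_stall"]);
    stall_every = as<int>(p["stall_every"]);
  }
};

struct Geom {
  bool active;
  double Rc, Rs, hw, z_base, z_out, wall_sigma, aperture;
  std::vector<double> shell;    // 3*m shell particle coordinates
  int n_shell;
  // static cell grid over shell particles
  double grid_lo, grid_cell; int grid_dim;
  std::vector<std::vector<int>> grid;
  Geom() : active(false), n_shell(0) {}
  Geom(const List& g) {
    active = as<bool>(g["active"]);
    if (!active) { n_shell = 0; return; }
    Rc = as<double>(g["interior_radius"]);
    Rs = as<double>(g["shell_radius"]);
    hw = as<double>(g["channel_half_width"]);
    z_base = as<double>(g["z_base"]);
    z_out = as<double>(g["z_out"]);
    wall_sigma = as<double>(g["wall_sigma"]);
    aperture = as<double>(g["aperture_radius"]);
    NumericMatrix sp = g["shell"];
    n_shell = sp.nrow();
    shell.resize(3 * n_shell);
    for (int i = 0; i < n_shell; ++i) {
      shell[3*i] = sp(i,0); shell[3*i+1] = sp(i,1); shell[3*i+2] = sp(i,2);
    }
    grid_cell = 1.6;
    grid_lo = -(Rs + 2.0);
    grid_dim = (int)std::ceil(2.0 * (Rs + 2.0) / grid_cell);
    grid.assign((size_t)grid_dim * grid_dim * grid_dim, {});
    for (int i = 0; i < n_shell; ++i) {
      int cx = cell_of(shell[3*i]), cy = cell_of(shell[3*i+1]), cz = cell_of(shell[3*i+2]);
      grid[(size_t)(cx * grid_dim + cy) * grid_dim + cz].push_back(i);
    }
  }
  int cell_of(double x) const {
    int c = (int)std::floor((x - grid_lo) / grid_cell);
    if (c < 0) c = 0; if (c >= grid_dim) c = grid_dim - 1;
    return c;
  }
};

static const double WCA_CUT = 1.1224620483093730;  // 2^(1/6)

// monomer status codes
enum Status { OUTSIDE = 0, IN_PORTAL = 1, IN_CAPSID = 2 };

// ------------------------------------------------------------- engine -----

struct Engine {
  Params par;
  Geom geom;
  RNG rng;
  int n;
  std::vector<double> x, v, f;
  std::vector<int> frozen;
  // Verlet pair list (monomer-monomer) and shell neighbour lists
  double skin, list_cut2, cut2;
  std::vector<int> pairs;                 // flattened (i,j)
  std::vector<int> shell_nb;              // flattened, offsets below
  std::vector<int> shell_off;
  std::vector<double> x_ref;              // positions at last list build
  bool blockage_on, fp_on, fr_on;
  long step_count;

  Engine(const Params& p, const Geom& g, NumericMatrix pos, NumericMatrix vel,
         uint64_t seed)
    : par(p), geom(g), rng(seed), n(p.n),
      x(3*p.n), v(3*p.n), f(3*p.n, 0.0), frozen(p.n, 0),
      blockage_on(false), fp_on(false), fr_on(false), step_count(0) {
    for (int i = 0; i < n; ++i)
      for (int d = 0; d < 3; ++d) {
        x[3*i+d] = pos(i,d);
        v[3*i+d] = vel(i,d);
      }
    skin = 0.4;
    double rc = WCA_CUT * par.sigma;
    cut2 = rc * rc;
    double rl = rc + skin;
    list_cut2 = rl * rl;
    x_ref.assign(x.begin(), x.end());
    build_lists();
    compute_forces();
  }

  bool in_channel(int i) const {
    if (!geom.active) return false;
    double zx = x[3*i+2];
    return zx >= geom.z_base && zx <= geom.z_out &&
           std::fabs(x[3*i]) < geom.hw && std::fabs(x[3*i+1]) < geom.hw;
  }
  int status_of(int i) const {
    if (!geom.active) return OUTSIDE;
    if (in_channel(i)) return IN_PORTAL;
    double r2 = x[3*i]*x[3*i] + x[3*i+1]*x[3*i+1] + x[3*i+2]*x[3*i+2];
    if (r2 < geom.Rs * geom.Rs) return IN_CAPSID;
    return OUTSIDE;
  }
  int count_in_capsid() const {
    int c = 0;
    for (int i = 0; i < n; ++i) if (status_of(i) == IN_CAPSID) ++c;
    return c;
  }
  int count_ejected() const {  // outside both the capsid and the portal
    int c = 0;
    for (int i = 0; i < n; ++i) if (status_of(i) == OUTSIDE) ++c;
    return c;
  }

  void build_lists() {
    pairs.clear();
    for (int i = 0; i < n; ++i)
      for (int j = i + 2; j < n; ++j) {   // bonded neighbours handled by FENE
        double dx = x[3*i]-x[3*j], dy = x[3*i+1]-x[3*j+1], dz = x[3*i+2]-x[3*j+2];
        double r2 = dx*dx + dy*dy + dz*dz;
        if (r2 < list_cut2) { pairs.push_back(i); pairs.push_back(j); }
      }
    shell_off.assign(n + 1, 0);
    shell_nb.clear();
    if (geom.active) {
      double rl = std::sqrt(list_cut2);
      for (int i = 0; i < n; ++i) {
        shell_off[i] = (int)shell_nb.size();
        double r = std::sqrt(x[3*i]*x[3*i] + x[3*i+1]*x[3*i+1] + x[3*i+2]*x[3*i+2]);
        if (r > geom.Rs - rl - 0.1 && r < geom.Rs + rl + 0.1) {
          int cx = geom.cell_of(x[3*i]), cy = geom.cell_of(x[3*i+1]), cz = geom.cell_of(x[3*i+2]);
          for (int ax = cx-1; ax <= cx+1; ++ax) {
            if (ax < 0 || ax >= geom.grid_dim) continue;
            for (int ay = cy-1; ay <= cy+1; ++ay) {
              if (ay < 0 || ay >= geom.grid_dim) continue;
              for (int az = cz-1; az <= cz+1; ++az) {
                if (az < 0 || az >= geom.grid_dim) continue;
                const std::vector<int>& cell =
                  geom.grid[(size_t)(ax * geom.grid_dim + ay) * geom.grid_dim + az];
                for (int k : cell) {
                  double dx = x[3*i]-geom.shell[3*k], dy = x[3*i+1]-geom.shell[3*k+1],
                         dz = x[3*i+2]-geom.shell[3*k+2];
                  if (dx*dx + dy*dy + dz*dz < list_cut2) shell_nb.push_back(k);
                }
              }
            }
          }
        }
      }
    }
    shell_off[n] = (int)shell_nb.size();
    if (!geom.active) std::fill(shell_off.begin(), shell_off.end(), 0);
    x_ref.assign(x.begin(), x.end());
  }

  void maybe_rebuild() {
    double half = 0.5 * skin, half2 = half * half, maxd2 = 0.0;
    for (int i = 0; i < n; ++i) {
      double dx = x[3*i]-x_ref[3*i], dy = x[3*i+1]-x_ref[3*i+1], dz = x[3*i+2]-x_ref[3*i+2];
      double d2 = dx*dx + dy*dy + dz*dz;
      if (d2 > maxd2) maxd2 = d2;
      if (maxd2 > half2) break;
    }
    if (maxd2 > half2) build_lists();
  }

  // WCA pair force magnitude over r (i.e. F = fac * dr_vec); 0 beyond cutoff
  static inline double wca_fac(double r2, double sg, double eps) {
    double s2 = sg * sg / r2;
    double s6 = s2 * s2 * s2;
    return 24.0 * eps * s6 * (2.0 * s6 - 1.0) / r2;
  }
  static inline double wca_en(double r2, double sg, double eps) {
    double s2 = sg * sg / r2;
    double s6 = s2 * s2 * s2;
    return 4.0 * eps * s6 * (s6 - 1.0) + eps;
  }

  void abort_with(const char* what, int i, double val) {
    std::ostringstream os;
    os << "simulation aborted: " << what << " (monomer " << (i + 1)
       << ", value " << val << ", step " << step_count << ")";
    stop(os.str());
  }

  // WCA repulsion from the nearest point of a finite wall element (rectangle
  // or disc).  Using the true distance-to-surface keeps the field continuous
  // across edges, so monomers cannot step into the divergent core.
  // j < 0: force on site i at (px,py,pz); j >= 0: the site is a bond
  // midpoint and the force is split between monomers i and j (keeping the
  // chain itself, not just monomer centres, from crossing thin walls)
  inline void surface_force2(double px, double py, double pz,
                             double qx, double qy, double qz,
                             int i, int j, double* fout, double* u) {
    double dx = px - qx, dy = py - qy, dz = pz - qz;
    double d2 = dx*dx + dy*dy + dz*dz;
    double cut = WCA_CUT * geom.wall_sigma;
    if (d2 >= cut * cut) return;
    if (d2 < 1e-6) d2 = 1e-6;
    double fac = wca_fac(d2, geom.wall_sigma, par.eps);
    double fmag = fac * std::sqrt(d2);
    if (fmag > 500.0) fac *= 500.0 / fmag;   // bounded kick, stable at dt
    if (j < 0) {
      fout[3*i]   += fac * dx;
      fout[3*i+1] += fac * dy;
      fout[3*i+2] += fac * dz;
    } else {
      fout[3*i]   += 0.5 * fac * dx;
      fout[3*i+1] += 0.5 * fac * dy;
      fout[3*i+2] += 0.5 * fac * dz;
      fout[3*j]   += 0.5 * fac * dx;
      fout[3*j+1] += 0.5 * fac * dy;
      fout[3*j+2] += 0.5 * fac * dz;
    }
    if (u) *u += wca_en(d2, geom.wall_sigma, par.eps);
  }
  inline void surface_force(int i, double qx, double qy, double qz,
                            double* fout, double* u) {
    surface_force2(x[3*i], x[3*i+1], x[3*i+2], qx, qy, qz, i, -1, fout, u);
  }
  // walls + blockage for one site (monomer i, or bond midpoint of i and j)
  inline void channel_site_forces(double px, double py, double pz,
                                  int i, int j, double* fout, double* u) {
    double wcut = WCA_CUT * geom.wall_sigma;
    if (pz >= geom.z_base - wcut && pz <= geom.z_out + wcut &&
        std::fabs(px) <= geom.hw + wcut && std::fabs(py) <= geom.hw + wcut) {
      double cz = clampd(pz, geom.z_base, geom.z_out);
      double cy = clampd(py, -geom.hw, geom.hw);
      double cx = clampd(px, -geom.hw, geom.hw);
      surface_force2(px, py, pz,  geom.hw, cy, cz, i, j, fout, u);
      surface_force2(px, py, pz, -geom.hw, cy, cz, i, j, fout, u);
      surface_force2(px, py, pz, cx,  geom.hw, cz, i, j, fout, u);
      surface_force2(px, py, pz, cx, -geom.hw, cz, i, j, fout, u);
    }
    if (blockage_on && std::fabs(pz - geom.z_base) <= wcut) {
      double rb = geom.aperture + 0.3;
      double lat = std::sqrt(px*px + py*py);
      if (lat <= rb) surface_force2(px, py, pz, px, py, geom.z_base, i, j, fout, u);
      else {
        double s = rb / lat;
        surface_force2(px, py, pz, px * s, py * s, geom.z_base, i, j, fout, u);
      }
    }
  }
  static inline double clampd(double v, double lo, double hi) {
    return v < lo ? lo : (v > hi ? hi : v);
  }

  // all conservative forces; returns potential energy if u != nullptr
  double forces_into(double* fo, bool want_u) {
    double u = 0.0;
    std::fill(fo, fo + 3*n, 0.0);
    const double sg = par.sigma, eps = par.eps;
    // FENE + WCA bonds
    double R02 = par.R0 * par.R0;
    for (int i = 0; i < n - 1; ++i) {
      double dx = x[3*i]-x[3*i+3], dy = x[3*i+1]-x[3*i+4], dz = x[3*i+2]-x[3*i+5];
      double r2 = dx*dx + dy*dy + dz*dz;
      if (r2 >= R02) abort_with("FENE bond overextended", i, std::sqrt(r2));
      if (r2 < 1e-12) abort_with("coincident bonded monomers", i, std::sqrt(r2));
      double fac = -par.K * R02 / (R02 - r2);          // FENE, attractive
      if (r2 < cut2) fac += wca_fac(r2, sg, eps);       // WCA, repulsive
      fo[3*i]   += fac * dx; fo[3*i+1] += fac * dy; fo[3*i+2] += fac * dz;
      fo[3*i+3] -= fac * dx; fo[3*i+4] -= fac * dy; fo[3*i+5] -= fac * dz;
      if (want_u) {
        u += -0.5 * par.K * R02 * std::log(1.0 - r2 / R02);
        if (r2 < cut2) u += wca_en(r2, sg, eps);
      }
    }
    // bending: U = Ka (1 - cos phi), phi angle between consecutive bond vectors
    int half = n / 2;
    for (int c = 1; c < n - 1; ++c) {
      double Ka = (c + 1 <= half) ? par.KF : par.KL;  // centre monomer, 1-based
      double b1x = x[3*c]-x[3*c-3],   b1y = x[3*c+1]-x[3*c-2],   b1z = x[3*c+2]-x[3*c-1];
      double b2x = x[3*c+3]-x[3*c],   b2y = x[3*c+4]-x[3*c+1],   b2z = x[3*c+5]-x[3*c+2];
      double n1sq = b1x*b1x + b1y*b1y + b1z*b1z;
      double n2sq = b2x*b2x + b2y*b2y + b2z*b2z;
      if (n1sq < 1e-18 || n2sq < 1e-18) abort_with("undefined bond angle", c, 0.0);
      double i1 = 1.0 / std::sqrt(n1sq), i2 = 1.0 / std::sqrt(n2sq);
      double e1x = b1x*i1, e1y = b1y*i1, e1z = b1z*i1;
      double e2x = b2x*i2, e2y = b2y*i2, e2z = b2z*i2;
      double cph = e1x*e2x + e1y*e2y + e1z*e2z;
      if (want_u) u += Ka * (1.0 - cph);
      // F_k = Ka * d(cos phi)/d r_k
      double g1x = (e2x - cph*e1x)*i1, g1y = (e2y - cph*e1y)*i1, g1z = (e2z - cph*e1z)*i1;
      double g3x = (e1x - cph*e2x)*i2, g3y = (e1y - cph*e2y)*i2, g3z = (e1z - cph*e2z)*i2;
      fo[3*(c-1)]   += Ka * (-g1x); fo[3*(c-1)+1] += Ka * (-g1y); fo[3*(c-1)+2] += Ka * (-g1z);
      fo[3*(c+1)]   += Ka * ( g3x); fo[3*(c+1)+1] += Ka * ( g3y); fo[3*(c+1)+2] += Ka * ( g3z);
      fo[3*c]       += Ka * ( g1x - g3x);
      fo[3*c+1]     += Ka * ( g1y - g3y);
      fo[3*c+2]     += Ka * ( g1z - g3z);
    }
    // non-bonded WCA
    for (size_t k = 0; k < pairs.size(); k += 2) {
      int i = pairs[k], j = pairs[k+1];
      double dx = x[3*i]-x[3*j], dy = x[3*i+1]-x[3*j+1], dz = x[3*i+2]-x[3*j+2];
      double r2 = dx*dx + dy*dy + dz*dz;
      if (r2 < cut2) {
        if (r2 < 1e-12) abort_with("coincident monomers", i, 0.0);
        double fac = wca_fac(r2, sg, eps);
        fo[3*i]   += fac * dx; fo[3*i+1] += fac * dy; fo[3*i+2] += fac * dz;
        fo[3*j]   -= fac * dx; fo[3*j+1] -= fac * dy; fo[3*j+2] -= fac * dz;
        if (want_u) u += wca_en(r2, sg, eps);
      }
    }
    if (geom.active) {
      // shell particles
      for (int i = 0; i < n; ++i)
        for (int kk = shell_off[i]; kk < shell_off[i+1]; ++kk) {
          int k = shell_nb[kk];
          double dx = x[3*i]-geom.shell[3*k], dy = x[3*i+1]-geom.shell[3*k+1],
                 dz = x[3*i+2]-geom.shell[3*k+2];
          double r2 = dx*dx + dy*dy + dz*dz;
          if (r2 < cut2) {
            double fac = wca_fac(r2, sg, eps);
            fo[3*i] += fac*dx; fo[3*i+1] += fac*dy; fo[3*i+2] += fac*dz;
            if (want_u) u += wca_en(r2, sg, eps);
          }
        }
      // portal channel walls (four rectangles spanning z in [z_base, z_out])
      // and, when present, the blockage disc across the inner mouth; both act
      // on monomer centres and on bond midpoints, so neither monomers nor
      // bonds can cross the thin walls
      double* uptr = want_u ? &u : nullptr;
      for (int i = 0; i < n; ++i)
        channel_site_forces(x[3*i], x[3*i+1], x[3*i+2], i, -1, fo, uptr);
      for (int i = 0; i < n - 1; ++i)
        channel_site_forces(0.5 * (x[3*i] + x[3*i+3]),
                            0.5 * (x[3*i+1] + x[3*i+4]),
                            0.5 * (x[3*i+2] + x[3*i+5]), i, i + 1, fo, uptr);
    }
    // external protocol forces (non-conservative; not part of reported U)
    if (fp_on) {
      for (int i = 0; i < n; ++i)
        if (in_channel(i)) fo[3*i+2] -= par.fp;   // toward the capsid
    }
    if (fr_on) {
      for (int i = 0; i < n; ++i) {
        double zx = x[3*i+2];
        if (zx > geom.z_out - 2.0 && zx <= geom.z_out &&
            std::fabs(x[3*i]) < geom.hw && std::fabs(x[3*i+1]) < geom.hw)
          fo[3*i+2] -= par.fr;                    // into the capsid
      }
    }
    return u;
  }

  void compute_forces() { forces_into(f.data(), false); }

  double potential_energy() {
    std::vector<double> tmp(3*n);
    bool sp = fp_on, sr = fr_on;
    fp_on = fr_on = false;      // external forces carry no potential here
    double u = forces_into(tmp.data(), true);
    fp_on = sp; fr_on = sr;
    return u;
  }
  double kinetic_energy() const {
    double ke = 0.0;
    for (int i = 0; i < n; ++i)
      ke += v[3*i]*v[3*i] + v[3*i+1]*v[3*i+1] + v[3*i+2]*v[3*i+2];
    return 0.5 * par.mass * ke;
  }

  bool thermostat = true;
  void step() {
    double h = par.dt, hm = 0.5 * h / par.mass;
    double c1 = 1.0, c2 = 0.0;
    if (thermostat && par.gamma > 0) {
      c1 = std::exp(-par.gamma * h);
      c2 = std::sqrt((1.0 - c1 * c1) * par.temp / par.mass);
    }
    for (int i = 0; i < n; ++i) {
      if (frozen[i]) { v[3*i] = v[3*i+1] = v[3*i+2] = 0.0; continue; }
      for (int d = 0; d < 3; ++d) {
        int k = 3*i + d;
        v[k] += hm * f[k];
        x[k] += 0.5 * h * v[k];
      }
    }
    if (thermostat && par.gamma > 0) {
      for (int i = 0; i < n; ++i) {
        if (frozen[i]) continue;
        for (int d = 0; d < 3; ++d) {
          int k = 3*i + d;
          v[k] = c1 * v[k] + c2 * rng.norm();
        }
      }
    }
    for (int i = 0; i < n; ++i) {
      if (frozen[i]) continue;
      for (int d = 0; d < 3; ++d) {
        int k = 3*i + d;
        x[k] += 0.5 * h * v[k];
      }
    }
    maybe_rebuild();
    compute_forces();
    for (int i = 0; i < n; ++i) {
      if (frozen[i]) continue;
      for (int d = 0; d < 3; ++d) {
        int k = 3*i + d;
        v[k] += hm * f[k];
      }
    }
    ++step_count;
  }

  NumericMatrix pos_matrix() const {
    NumericMatrix m(n, 3);
    for (int i = 0; i < n; ++i)
      for (int d = 0; d < 3; ++d) m(i,d) = x[3*i+d];
    return m;
  }
  NumericMatrix vel_matrix() const {
    NumericMatrix m(n, 3);
    for (int i = 0; i < n; ++i)
      for (int d = 0; d < 3; ++d) m(i,d) = v[3*i+d];
    return m;
  }
};

// ------------------------------------------------------- exported API -----

// standard-normal draws from the engine's own sampler (for statistical tests)
// [[Rcpp::export]]
NumericVector cg_rnorm(int n, double seed) {
  RNG rng((uint64_t)seed);
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = rng.norm();
  return out;
}

// [[Rcpp::export]]
NumericMatrix cg_fibonacci_sphere(int m, double radius) {
  NumericMatrix out(m, 3);
  double ga = M_PI * (3.0 - std::sqrt(5.0));
  for (int i = 0; i < m; ++i) {
    double z = 1.0 - 2.0 * (i + 0.5) / m;
    double r = std::sqrt(std::max(0.0, 1.0 - z * z));
    double th = ga * i;
    out(i,0) = radius * r * std::cos(th);
    out(i,1) = radius * r * std::sin(th);
    out(i,2) = radius * z;
  }
  return out;
}

// Grow the initial configuration: first 10 monomers collinear inside the
// portal channel, the remainder a self-avoiding random walk outside.
// [[Rcpp::export]]
List cg_grow_chain(List params, List geom_list, double seed) {
  Params par(params);
  Geom geom(geom_list);
  if (!geom.active) stop("initial growth requires an active capsid geometry");
  RNG rng((uint64_t)seed);
  int n = par.n;
  int n_seed = 10;
  double b0 = 0.97;
  std::vector<double> x(3*n, 0.0);
  // monomer n_seed sits near the channel's outer end; monomer 1 deepest
  double z_top = geom.z_out - 0.35;
  for (int i = 0; i < n_seed; ++i) {
    x[3*i] = 0.0; x[3*i+1] = 0.0;
    x[3*i+2] = z_top - (n_seed - 1 - i) * b0;
  }
  // distance from a point to the nearest channel wall rectangle
  auto wall_dist = [&](double px, double py, double pz) {
    double best = 1e18;
    double cz = pz < geom.z_base ? geom.z_base : (pz > geom.z_out ? geom.z_out : pz);
    double chw = geom.hw;
    double cx = px < -chw ? -chw : (px > chw ? chw : px);
    double cy = py < -chw ? -chw : (py > chw ? chw : py);
    double q[4][3] = {{ chw, cy, cz}, {-chw, cy, cz},
                      {cx,  chw, cz}, {cx, -chw, cz}};
    for (int w = 0; w < 4; ++w) {
      double dx = px - q[w][0], dy = py - q[w][1], dz = pz - q[w][2];
      double d = std::sqrt(dx*dx + dy*dy + dz*dz);
      if (d < best) best = d;
    }
    return best;
  };
  int max_restart = 200;
  for (int attempt = 0; attempt < max_restart; ++attempt) {
    bool ok = true;
    for (int i = n_seed; i < n; ++i) {
      bool placed = false;
      for (int t = 0; t < 400; ++t) {
        // uniform direction
        double ux, uy, uz, nn;
        do {
          ux = 2.0*rng.unif()-1.0; uy = 2.0*rng.unif()-1.0; uz = 2.0*rng.unif()-1.0;
          nn = ux*ux + uy*uy + uz*uz;
        } while (nn > 1.0 || nn < 1e-6);
        nn = std::sqrt(nn);
        double cx = x[3*(i-1)]   + b0 * ux / nn;
        double cy = x[3*(i-1)+1] + b0 * uy / nn;
        double cz = x[3*(i-1)+2] + b0 * uz / nn;
        // must clear every shell particle (all lie on the sphere of radius
        // Rs, so radius > Rs + 0.95 clears them) and the channel box
        double r2 = cx*cx + cy*cy + cz*cz;
        if (r2 < (geom.Rs + 0.95)*(geom.Rs + 0.95)) continue;
        // clear the channel walls, both for the monomer and for the bond
        // midpoint with its predecessor (bond midpoints feel the walls too)
        if (wall_dist(cx, cy, cz) < 0.62) continue;
        if (wall_dist(0.5 * (cx + x[3*(i-1)]), 0.5 * (cy + x[3*(i-1)+1]),
                      0.5 * (cz + x[3*(i-1)+2])) < 0.62) continue;
        bool in_bore = cz >= geom.z_base - 0.5 && cz <= geom.z_out + 0.3 &&
                       std::fabs(cx) < geom.hw && std::fabs(cy) < geom.hw;
        if (in_bore) continue;
        // overlap check against all previously placed monomers
        bool clash = false;
        for (int j = 0; j < i - 1; ++j) {
          double dx = cx-x[3*j], dy = cy-x[3*j+1], dz = cz-x[3*j+2];
          if (dx*dx + dy*dy + dz*dz < 0.9025) { clash = true; break; } // 0.95^2
        }
        if (clash) continue;
        x[3*i] = cx; x[3*i+1] = cy; x[3*i+2] = cz;
        placed = true;
        break;
      }
      if (!placed) { ok = false; break; }
    }
    if (ok) break;
    if (attempt == max_restart - 1) stop("initial chain growth failed after retries");
  }
  // thermal velocities
  NumericMatrix pos(n, 3), vel(n, 3);
  double sd = std::sqrt(par.temp / par.mass);
  for (int i = 0; i < n; ++i)
    for (int d = 0; d < 3; ++d) {
      pos(i,d) = x[3*i+d];
      vel(i,d) = sd * rng.norm();
    }
  return List::create(_["positions"] = pos, _["velocities"] = vel);
}

// classify every monomer: 0 outside, 1 in portal channel, 2 in capsid
// [[Rcpp::export]]
IntegerVector cg_status(NumericMatrix pos, List params, List geom_list) {
  Params par(params);
  Geom geom(geom_list);
  NumericMatrix vel(pos.nrow(), 3);
  Engine eng(par, geom, pos, vel, 1);
  IntegerVector out(par.n);
  for (int i = 0; i < par.n; ++i) out[i] = eng.status_of(i);
  return out;
}

// conservative energies of a configuration (external forces excluded)
// [[Rcpp::export]]
List cg_energy(NumericMatrix pos, NumericMatrix vel, List params, List geom_list) {
  Params par(params);
  Geom geom(geom_list);
  Engine eng(par, geom, pos, vel, 1);
  double u = eng.potential_energy();
  double k = eng.kinetic_energy();
  return List::create(_["potential"] = u, _["kinetic"] = k, _["total"] = u + k);
}

// One protocol phase.  phase: "free" | "package" | "rest" | "eject".
// Returns final state plus per-phase records.
// [[Rcpp::export]]
List cg_run_phase(NumericMatrix pos, NumericMatrix vel, List params,
                  List geom_list, std::string phase, double duration_tau,
                  double seed, List opts) {
  Params par(params);
  Geom geom(geom_list);
  Engine eng(par, geom, pos, vel, (uint64_t)seed);
  bool thermostat = opts.containsElementNamed("thermostat") ?
                      as<bool>(opts["thermostat"]) : true;
  double sample_every = opts.containsElementNamed("sample_every") ?
                      as<double>(opts["sample_every"]) : 1.0;
  bool record_frames = opts.containsElementNamed("record_frames") ?
                      as<bool>(opts["record_frames"]) : false;
  bool record_energy = opts.containsElementNamed("record_energy") ?
                      as<bool>(opts["record_energy"]) : false;
  eng.thermostat = thermostat;
  long steps_per_sample = std::max(1L, (long)std::llround(sample_every / par.dt));
  long n_steps = (long)std::llround(duration_tau / par.dt);

  std::vector<double> e_tot, e_kin, e_pot, t_ser;
  std::vector<NumericMatrix> frames;

  if (phase == "free" || phase == "rest") {
    eng.blockage_on = (phase == "rest") && geom.active;
    eng.compute_forces();
    for (long s = 0; s < n_steps; ++s) {
      eng.step();
      if ((s + 1) % steps_per_sample == 0) {
        if (record_energy) {
          double u = eng.potential_energy(), k = eng.kinetic_energy();
          e_pot.push_back(u); e_kin.push_back(k); e_tot.push_back(u + k);
          t_ser.push_back((s + 1) * par.dt);
        }
        if (record_frames) frames.push_back(eng.pos_matrix());
        if (((s + 1) / steps_per_sample) % 256 == 0) Rcpp::checkUserInterrupt();
      }
    }
    if (phase == "rest" && geom.active) {
      for (int i = 0; i < eng.n; ++i)
        if (eng.status_of(i) == OUTSIDE)
          stop("geometry leak: monomer escaped the capsid during resting");
    }
    List out = List::create(
      _["positions"] = eng.pos_matrix(), _["velocities"] = eng.vel_matrix(),
      _["time_tau"] = n_steps * par.dt,
      _["energy_time"] = wrap(t_ser), _["energy_total"] = wrap(e_tot),
      _["energy_kinetic"] = wrap(e_kin), _["energy_potential"] = wrap(e_pot));
    if (record_frames) {
      List fl(frames.size());
      for (size_t i = 0; i < frames.size(); ++i) fl[i] = frames[i];
      out["frames"] = fl;
    }
    return out;
  }

  if (phase == "package") {
    if (!geom.active) stop("packaging requires an active capsid geometry");
    eng.fp_on = true;
    eng.compute_forces();
    long max_steps = n_steps;           // duration_tau acts as the budget
    long stall_steps = (long)std::llround(par.tau_stall / par.dt);
    int next_threshold = par.stall_every;
    int n_stalls = 0;
    std::vector<double> nin_ser, tser;
    long s = 0;
    bool done = false;
    while (s < max_steps) {
      eng.step(); ++s;
      if (s % steps_per_sample == 0) {
        int nin = eng.count_in_capsid();
        nin_ser.push_back(nin); tser.push_back(s * par.dt);
        if (nin >= par.n) { done = true; break; }
        if (nin >= next_threshold && next_threshold < par.n) {
          // stall: packaging force off, monomers in the portal frozen
          eng.fp_on = false;
          int n_frozen = 0;
          for (int i = 0; i < eng.n; ++i)
            if (eng.in_channel(i)) { eng.frozen[i] = 1; ++n_frozen; }
          eng.compute_forces();
          for (long q = 0; q < stall_steps; ++q) {
            eng.step();
            if (q % 51200 == 0) Rcpp::checkUserInterrupt();
          }
          for (int i = 0; i < eng.n; ++i) eng.frozen[i] = 0;
          eng.fp_on = true;
          eng.compute_forces();
          ++n_stalls;
          next_threshold += par.stall_every;
          (void)n_frozen;
        }
        if ((s / steps_per_sample) % 256 == 0) Rcpp::checkUserInterrupt();
      }
    }
    return List::create(
      _["positions"] = eng.pos_matrix(), _["velocities"] = eng.vel_matrix(),
      _["success"] = done, _["n_stalls"] = n_stalls,
      _["time_tau"] = s * par.dt + n_stalls * par.tau_stall,
      _["n_in_series"] = wrap(nin_ser), _["n_in_time"] = wrap(tser),
      _["n_in"] = eng.count_in_capsid());
  }

  if (phase == "eject") {
    if (!geom.active) stop("ejection requires an active capsid geometry");
    eng.blockage_on = false;
    eng.fr_on = true;
    eng.compute_forces();
    double conv_window = opts.containsElementNamed("conv_window_tau") ?
                           as<double>(opts["conv_window_tau"]) : 250.0;
    double conv_tol = opts.containsElementNamed("conv_tol") ?
                           as<double>(opts["conv_tol"]) : 0.01;
    // duration_tau budgets the wait for the first exit; once ejection has
    // begun, every trajectory gets the same post-onset window so plateau
    // values are compared at matched ejection age
    double post_exit_tau = opts.containsElementNamed("post_exit_tau") ?
                           as<double>(opts["post_exit_tau"]) : 4000.0;
    long post_steps = (long)std::llround(post_exit_tau / par.dt);
    long wsteps = std::max(1L, (long)std::llround(conv_window / sample_every));
    std::vector<double> phi_ser, e_ser, tser;
    int i_exit = -1;
    double t_exit = NA_REAL;
    long exit_step = -1;
    long s = 0;
    bool converged = false;
    while (true) {
      if (i_exit < 0 && s >= n_steps) break;
      if (i_exit > 0 && s >= exit_step + post_steps) break;
      eng.step(); ++s;
      if (i_exit < 0) {
        // detect the first monomer past the channel's outer plane
        double zmax = -1e18; int arg = -1;
        for (int i = 0; i < eng.n; ++i)
          if (eng.x[3*i+2] > geom.z_out && eng.x[3*i+2] > zmax) {
            zmax = eng.x[3*i+2]; arg = i;
          }
        if (arg >= 0) { i_exit = arg + 1; t_exit = s * par.dt; exit_step = s; }
      }
      if (s % steps_per_sample == 0) {
        double phi = (double)eng.count_ejected() / eng.n;
        phi_ser.push_back(phi);
        double u = eng.potential_energy(), k = eng.kinetic_energy();
        e_ser.push_back(u + k);
        tser.push_back(s * par.dt);
        long m = (long)phi_ser.size();
        if (i_exit > 0 && m >= 4 * wsteps && m % wsteps == 0) {
          double m1 = 0, m2 = 0;
          for (long q = m - 2*wsteps; q < m - wsteps; ++q) m1 += phi_ser[q];
          for (long q = m - wsteps; q < m; ++q) m2 += phi_ser[q];
          m1 /= wsteps; m2 /= wsteps;
          if (std::fabs(m1 - m2) < conv_tol) { converged = true; break; }
        }
        if (m % 256 == 0) Rcpp::checkUserInterrupt();
      }
    }
    return List::create(
      _["positions"] = eng.pos_matrix(), _["velocities"] = eng.vel_matrix(),
      _["i_exit"] = i_exit, _["t_exit"] = t_exit,
      _["converged"] = converged,
      _["time_tau"] = s * par.dt,
      _["phi_time"] = wrap(tser), _["phi_series"] = wrap(phi_ser),
      _["energy_series"] = wrap(e_ser));
  }

  stop("unknown phase: " + phase);
}
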