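// Monte Carlo random-walk engine for restricted diffusion in a labelled
// substrate: immune spheres (3D), resident-cell hexagonal prisms and
// syncytiotrophoblast tube walls (both extruded through the slab),
// extracellular space elsewhere. Membranes are impermeable; walkers keep
// their compartment for the whole walk. PGSE phase encoding is reduced to
// two per-walker position integrals (one per gradient lobe), so the signal
// for every measurement is formed afterwards in R from S1, S2.
//
// RNG: xoshiro256++ seeded by splitmix64, Box-Muller normals. Fully
// self-contained so identical seeds give bit-identical trajectories on
// any platform.

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <vector>

using namespace Rcpp;

namespace {

struct Rng {
  uint64_t s[4];
  explicit Rng(uint64_t seed) {
    // splitmix64 expansion of the seed
    uint64_t x = seed;
    for (int i = 0; i < 4; ++i) {
      x += 0x9e3779b97f4a7c15ULL;
      uint64_t z = x;
      z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
      z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
      s[i] = z ^ (z >> 31);
    }
  }
  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  inline uint64_t next() {
    uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return result;
  }
  inline double unif() {  // (0,1)
    return ((next() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
  bool have_spare = false;
  double spare = 0.0;
  inline double norm() {
    if (have_spare) { have_spare = false; return spare; }
    double u1 = unif(), u2 = unif();
    double r = std::sqrt(-2.0 * std::log(u1));
    double a = 6.283185307179586476925286766559 * u2;
    spare = r * std::sin(a);
    have_spare = true;
    return r * std::cos(a);
  }
};

struct Geom {
  double Lx, Ly, Lz;
  // spheres: cx, cy, cz, r
  const double* sph; int n_sph;
  // prisms: cx, cy, circumradius, theta (hexagon apothem = R*sqrt(3)/2)
  const double* pri; int n_pri;
  // tubes: cx, cy, r_out, wall
  const double* tub; int n_tub;

  // xy cell lists (bin size >= largest sphere radius works; villi are few)
  double bin;
  int nbx, nby;
  std::vector<std::vector<int> > bins_sph, bins_pri, bins_tub;

  inline int bin_of(double x, double y) const {
    int ix = (int)(x / bin); if (ix < 0) ix = 0; if (ix >= nbx) ix = nbx - 1;
    int iy = (int)(y / bin); if (iy < 0) iy = 0; if (iy >= nby) iy = nby - 1;
    return iy * nbx + ix;
  }

  void build_bins() {
    bin = 25.0;
    nbx = std::max(1, (int)std::ceil(Lx / bin));
    nby = std::max(1, (int)std::ceil(Ly / bin));
    int nb = nbx * nby;
    bins_sph.assign(nb, std::vector<int>());
    bins_pri.assign(nb, std::vector<int>());
    bins_tub.assign(nb, std::vector<int>());
    for (int ib = 0; ib < nb; ++ib) {
      int ix = ib % nbx, iy = ib / nbx;
      double x0 = ix * bin, x1 = x0 + bin, y0 = iy * bin, y1 = y0 + bin;
      for (int i = 0; i < n_sph; ++i)
        if (circle_hits_rect(sph[4*i], sph[4*i+1], sph[4*i+3], x0, x1, y0, y1))
          bins_sph[ib].push_back(i);
      for (int i = 0; i < n_pri; ++i)
        if (circle_hits_rect(pri[4*i], pri[4*i+1], pri[4*i+2], x0, x1, y0, y1))
          bins_pri[ib].push_back(i);
      for (int i = 0; i < n_tub; ++i)
        if (circle_hits_rect(tub[4*i], tub[4*i+1], tub[4*i+2], x0, x1, y0, y1))
          bins_tub[ib].push_back(i);
    }
  }

  static bool circle_hits_rect(double cx, double cy, double r,
                               double x0, double x1, double y0, double y1) {
    double dx = cx < x0 ? x0 - cx : (cx > x1 ? cx - x1 : 0.0);
    double dy = cy < y0 ? y0 - cy : (cy > y1 ? cy - y1 : 0.0);
    return dx * dx + dy * dy <= r * r;
  }

  inline bool in_sphere(int i, double x, double y, double z) const {
    double dx = x - sph[4*i], dy = y - sph[4*i+1], dz = z - sph[4*i+2];
    double r = sph[4*i+3];
    return dx*dx + dy*dy + dz*dz <= r*r;
  }
  inline bool in_prism(int i, double x, double y) const {
    double dx = x - pri[4*i], dy = y - pri[4*i+1];
    double R = pri[4*i+2], th = pri[4*i+3];
    double a = R * 0.86602540378443864676;  // apothem
    double rr = dx*dx + dy*dy;
    if (rr > R*R) return false;
    for (int k = 0; k < 6; ++k) {
      double al = th + k * 1.0471975511965977462;  // pi/3
      if (dx * std::cos(al) + dy * std::sin(al) > a) return false;
    }
    return true;
  }
  inline bool in_tube_wall(int i, double x, double y) const {
    double dx = x - tub[4*i], dy = y - tub[4*i+1];
    double ro = tub[4*i+2], ri = ro - tub[4*i+3];
    double rr = dx*dx + dy*dy;
    return rr <= ro*ro && rr >= ri*ri;
  }

  // classify a point: 0 extracellular, 1 sphere, 2 prism, 3 tube wall;
  // idx receives the primitive index (-1 for extracellular)
  inline int classify(double x, double y, double z, int& idx) const {
    int ib = bin_of(x, y);
    const std::vector<int>& bs = bins_sph[ib];
    for (size_t k = 0; k < bs.size(); ++k)
      if (in_sphere(bs[k], x, y, z)) { idx = bs[k]; return 1; }
    const std::vector<int>& bp = bins_pri[ib];
    for (size_t k = 0; k < bp.size(); ++k)
      if (in_prism(bp[k], x, y)) { idx = bp[k]; return 2; }
    const std::vector<int>& bt = bins_tub[ib];
    for (size_t k = 0; k < bt.size(); ++k)
      if (in_tube_wall(bt[k], x, y)) { idx = bt[k]; return 3; }
    idx = -1;
    return 0;
  }
};

inline void reflect_box(double L, double& v) {
  // specular reflection at [0, L]; steps are far smaller than L
  if (v < 0) v = -v;
  if (v > L) v = 2 * L - v;
  if (v < 0) v = 0;  // pathological double bounce
}

}  // namespace

// [[Rcpp::export(name = ".walk_engine")]]
List walk_engine(NumericVector field_size,
                 NumericMatrix spheres, NumericMatrix prisms,
                 NumericMatrix tubes,
                 int n_walkers, int n_steps, double dt, double D0,
                 double seed,
                 double small_delta, double big_delta, bool have_timing,
                 bool record_traj) {
  Geom G;
  G.Lx = field_size[0]; G.Ly = field_size[1]; G.Lz = field_size[2];
  // R matrices are column-major; repack row-major quadruples
  auto repack = [](const NumericMatrix& m) {
    std::vector<double> out(m.nrow() * 4);
    for (int i = 0; i < m.nrow(); ++i)
      for (int j = 0; j < 4; ++j) out[4*i + j] = m(i, j);
    return out;
  };
  std::vector<double> sph = repack(spheres);
  std::vector<double> pri = repack(prisms);
  std::vector<double> tub = repack(tubes);
  G.sph = sph.data(); G.n_sph = spheres.nrow();
  G.pri = pri.data(); G.n_pri = prisms.nrow();
  G.tub = tub.data(); G.n_tub = tubes.nrow();
  G.build_bins();

  const double sigma = std::sqrt(2.0 * D0 * dt);
  // lobe membership per step: end-of-step position is the integrand
  // sample. Both lobes get exactly the same number of steps so that the
  // constant part of the position cancels in the phase difference.
  std::vector<int> lobe(n_steps, 0);
  if (have_timing) {
    int n1 = (int)std::lround(small_delta / dt);
    int sD = (int)std::lround(big_delta / dt);
    if (n1 < 1 || sD + n1 > n_steps)
      stop("walk too short for the PGSE timing (need Delta + delta)");
    for (int i = 0; i < n1; ++i) lobe[i] = 1;
    for (int i = sD; i < sD + n1; ++i) lobe[i] = 2;
  }

  NumericMatrix S1(n_walkers, 3), S2(n_walkers, 3);
  IntegerVector labels(n_walkers), prim_idx(n_walkers);
  NumericMatrix start(n_walkers, 3), finish(n_walkers, 3);
  NumericVector traj;
  if (record_traj) {
    traj = NumericVector(Dimension(3, n_steps + 1, n_walkers));
  }

  Rng rng((uint64_t)seed);
  for (int w = 0; w < n_walkers; ++w) {
    double x = rng.unif() * G.Lx, y = rng.unif() * G.Ly,
           z = rng.unif() * G.Lz;
    int idx;
    int lab = G.classify(x, y, z, idx);
    labels[w] = lab; prim_idx[w] = idx;
    start(w, 0) = x; start(w, 1) = y; start(w, 2) = z;
    const double x0 = x, y0 = y, z0 = z;   // offset removed for precision;
    double s1x = 0, s1y = 0, s1z = 0, s2x = 0, s2y = 0, s2z = 0;
    if (record_traj) {
      traj[(R_xlen_t)w * 3 * (n_steps + 1) + 0] = x;
      traj[(R_xlen_t)w * 3 * (n_steps + 1) + 1] = y;
      traj[(R_xlen_t)w * 3 * (n_steps + 1) + 2] = z;
    }
    for (int i = 0; i < n_steps; ++i) {
      double nx = x + sigma * rng.norm();
      double ny = y + sigma * rng.norm();
      double nz = z + sigma * rng.norm();
      reflect_box(G.Lx, nx); reflect_box(G.Ly, ny); reflect_box(G.Lz, nz);
      bool ok = true;
      if (lab == 1) {                      // inside an immune sphere
        double cx = G.sph[4*idx], cy = G.sph[4*idx+1], cz = G.sph[4*idx+2],
               r = G.sph[4*idx+3];
        double dx = nx - cx, dy = ny - cy, dz = nz - cz;
        double d = std::sqrt(dx*dx + dy*dy + dz*dz);
        if (d > r) {
          double f = (2 * r - d) / d;      // specular radial reflection
          nx = cx + dx * f; ny = cy + dy * f; nz = cz + dz * f;
          if (!G.in_sphere(idx, nx, ny, nz)) ok = false;
        }
      } else if (lab == 2) {               // resident-cell hexagonal prism
        double cx = G.pri[4*idx], cy = G.pri[4*idx+1],
               R = G.pri[4*idx+2], th = G.pri[4*idx+3];
        double a = R * 0.86602540378443864676;
        for (int k = 0; k < 6; ++k) {
          double al = th + k * 1.0471975511965977462;
          double nxk = std::cos(al), nyk = std::sin(al);
          double d = (nx - cx) * nxk + (ny - cy) * nyk;
          if (d > a) { nx -= 2 * (d - a) * nxk; ny -= 2 * (d - a) * nyk; }
        }
        if (!G.in_prism(idx, nx, ny)) ok = false;
      } else if (lab == 3) {               // tube-wall annulus
        double cx = G.tub[4*idx], cy = G.tub[4*idx+1],
               ro = G.tub[4*idx+2], ri = ro - G.tub[4*idx+3];
        double dx = nx - cx, dy = ny - cy;
        double rho = std::sqrt(dx*dx + dy*dy);
        double target = rho;
        if (rho > ro) target = 2 * ro - rho;
        else if (rho < ri) target = 2 * ri - rho;
        if (target != rho) {
          if (rho < 1e-9 || target < ri || target > ro) ok = false;
          else { nx = cx + dx * target / rho; ny = cy + dy * target / rho; }
        }
      } else {                             // extracellular
        int hit_idx;
        int hit = G.classify(nx, ny, nz, hit_idx);
        if (hit == 1) {
          // bounce off the sphere surface from outside
          double cx = G.sph[4*hit_idx], cy = G.sph[4*hit_idx+1],
                 cz = G.sph[4*hit_idx+2], r = G.sph[4*hit_idx+3];
          double dx = nx - cx, dy = ny - cy, dz = nz - cz;
          double d = std::sqrt(dx*dx + dy*dy + dz*dz);
          if (d < 1e-9) ok = false;
          else {
            double f = (2 * r - d) / d;
            nx = cx + dx * f; ny = cy + dy * f; nz = cz + dz * f;
            int chk;
            if (G.classify(nx, ny, nz, chk) != 0) ok = false;
          }
        } else if (hit != 0) {
          ok = false;                      // equal-step rejection
        }
      }
      if (ok) { x = nx; y = ny; z = nz; }
      if (lobe[i] == 1) { s1x += x - x0; s1y += y - y0; s1z += z - z0; }
      else if (lobe[i] == 2) { s2x += x - x0; s2y += y - y0; s2z += z - z0; }
      if (record_traj) {
        R_xlen_t off = ((R_xlen_t)w * (n_steps + 1) + (i + 1)) * 3;
        traj[off] = x; traj[off + 1] = y; traj[off + 2] = z;
      }
    }
    S1(w, 0) = s1x * dt; S1(w, 1) = s1y * dt; S1(w, 2) = s1z * dt;
    S2(w, 0) = s2x * dt; S2(w, 1) = s2y * dt; S2(w, 2) = s2z * dt;
    finish(w, 0) = x; finish(w, 1) = y; finish(w, 2) = z;
  }

  List out = List::create(
    _["S1"] = S1, _["S2"] = S2,
    _["labels"] = labels, _["prim_idx"] = prim_idx,
    _["start"] = start, _["finish"] = finish);
  if (record_traj) out["traj"] = traj;
  return out;
}
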