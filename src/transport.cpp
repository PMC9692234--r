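// Condensed-history proton transport through an axial slab stack
// (range shifter / air / aperture-with-bore / air / voxelized water phantom).
//
// Physics per step: mean Bethe energy loss from tabulated stopping powers,
// Gaussian (Bohr) energy-loss straggling, Highland multiple-Coulomb
// scattering with correlated lateral displacement (paraxial slopes), and a
// simplified nuclear-removal model (exponential attenuation of primaries,
// depositing a configurable local fraction of the removed proton's energy).
// Each primary owns a counter-based RNG stream derived from (seed, index),
// so results are independent of execution order and bit-reproducible.

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <vector>
#include <algorithm>
using namespace Rcpp;

static const double MP = 938.27209;     // proton rest energy, MeV
static const double TWO_PI = 6.283185307179586;

// splitmix64-based per-primary stream
struct Rng {
  uint64_t state;
  bool have_cached;
  double cached;
  void init(uint64_t seed, uint64_t idx) {
    state = seed * 0x9E3779B97F4A7C15ULL ^ (idx * 0xD1B54A32D192ED03ULL + 0x8BB84B93962EACC9ULL);
    have_cached = false;
    next_u64(); next_u64();
  }
  uint64_t next_u64() {
    uint64_t z = (state += 0x9E3779B97F4A7C15ULL);
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }
  double unif() {  // (0, 1]
    return ((next_u64() >> 11) + 1.0) * (1.0 / 9007199254740993.0);
  }
  double norm() {  // Marsaglia polar method
    if (have_cached) { have_cached = false; return cached; }
    double u, v, s;
    do {
      u = 2.0 * unif() - 1.0;
      v = 2.0 * unif() - 1.0;
      s = u * u + v * v;
    } while (s >= 1.0 || s == 0.0);
    double f = std::sqrt(-2.0 * std::log(s) / s);
    cached = v * f;
    have_cached = true;
    return u * f;
  }
};

struct Mat {
  double density;     // g/cm^3
  double zova;        // effective Z/A
  double x0;          // radiation length, g/cm^2
  double lambda_mm;   // nuclear removal mean free path, mm (<=0: off)
  std::vector<double> logE, logS;
  double msp(double e) const {  // mass stopping power, MeV cm^2/g
    double le = std::log(e);
    if (le < logE.front()) le = logE.front();
    if (le > logE.back())  le = logE.back();
    size_t hi = std::upper_bound(logE.begin(), logE.end(), le) - logE.begin();
    if (hi == 0) hi = 1;
    if (hi >= logE.size()) hi = logE.size() - 1;
    double t = (le - logE[hi - 1]) / (logE[hi] - logE[hi - 1]);
    return std::exp(logS[hi - 1] * (1.0 - t) + logS[hi] * t);
  }
};

struct Slab {
  double z0, z1;
  int type;          // 0 homogeneous, 1 aperture (cylindrical bore)
  int mat;           // material index (wall material for type 1)
  int mat_in;        // bore material index (type 1 only)
  double f_ms, f_ms_in;   // Highland log-correction factor, slab-evaluated
  double max_step, max_step_in;  // mm
  int region;        // 0 air, 1 range shifter, 2 aperture, 3 phantom
  double bore_r, dx, dy;
};

// [[Rcpp::export]]
List cpp_transport(NumericMatrix states, double z_source,
                   List slabs_r, List mats_r, List grid_r, List params) {
  const int n = states.nrow();

  std::vector<Mat> mats(mats_r.size());
  for (int i = 0; i < (int)mats_r.size(); ++i) {
    List m = mats_r[i];
    mats[i].density = as<double>(m["density"]);
    mats[i].zova = as<double>(m["zova"]);
    mats[i].x0 = as<double>(m["x0"]);
    mats[i].lambda_mm = as<double>(m["lambda_mm"]);
    mats[i].logE = as<std::vector<double>>(m["log_e"]);
    mats[i].logS = as<std::vector<double>>(m["log_s"]);
  }

  std::vector<Slab> slabs(slabs_r.size());
  for (int i = 0; i < (int)slabs_r.size(); ++i) {
    List s = slabs_r[i];
    Slab& sl = slabs[i];
    sl.z0 = as<double>(s["z0"]); sl.z1 = as<double>(s["z1"]);
    sl.type = as<int>(s["type"]); sl.mat = as<int>(s["mat"]);
    sl.mat_in = as<int>(s["mat_in"]);
    sl.f_ms = as<double>(s["f_ms"]); sl.f_ms_in = as<double>(s["f_ms_in"]);
    sl.max_step = as<double>(s["max_step"]);
    sl.max_step_in = as<double>(s["max_step_in"]);
    sl.region = as<int>(s["region"]);
    sl.bore_r = as<double>(s["bore_r"]);
    sl.dx = as<double>(s["dx"]); sl.dy = as<double>(s["dy"]);
  }

  const int nx = as<int>(grid_r["nx"]), ny = as<int>(grid_r["ny"]),
            nz = as<int>(grid_r["nz"]);
  const double vox = as<double>(grid_r["voxel"]);
  const double gx0 = as<double>(grid_r["x0"]), gy0 = as<double>(grid_r["y0"]),
               gz0 = as<double>(grid_r["z0"]);
  const size_t nvox = (size_t)nx * ny * nz;

  const uint64_t seed = (uint64_t)as<double>(params["seed"]);
  const double cutoff = as<double>(params["cutoff"]);
  const bool nuclear = as<bool>(params["nuclear"]);
  const double local_frac = as<double>(params["local_frac"]);
  const double e_nuc_min = as<double>(params["e_nuc_min"]);
  const int record_slab = as<int>(params["record_slab"]);  // 0-based, -1 none
  const int max_steps = as<int>(params["max_steps"]);

  std::vector<double> dose(nvox, 0.0), let_num(nvox, 0.0), let_den(nvox, 0.0);
  // regions: 0 air, 1 range shifter, 2 aperture, 3 phantom, 4 escaped
  std::vector<double> edep(5, 0.0);
  double e_initial = 0.0;

  std::vector<double> rec;  // recorded exit states, 6 per proton
  rec.reserve(record_slab >= 0 ? (size_t)n * 6 : 0);

  Rng rng;
  for (int i = 0; i < n; ++i) {
    double x = states(i, 0), y = states(i, 1);
    double tx = states(i, 2), ty = states(i, 3);
    double E = states(i, 4), w = states(i, 5);
    double z = z_source;
    bool alive = true;
    rng.init(seed, (uint64_t)(i + 1));
    e_initial += w * E;
    int nstep = 0;

    for (int si = 0; si < (int)slabs.size() && alive; ++si) {
      const Slab& sl = slabs[si];
      if (sl.z1 <= z + 1e-9) continue;
      while (alive && z < sl.z1 - 1e-9) {
        if (++nstep > max_steps) { alive = false; edep[4] += w * E; E = 0; break; }
        bool inb = false;
        if (sl.type == 1) {
          double ddx = x - sl.dx, ddy = y - sl.dy;
          inb = (ddx * ddx + ddy * ddy < sl.bore_r * sl.bore_r);
        }
        const Mat& m = inb ? mats[sl.mat_in] : mats[sl.mat];
        const double fms = inb ? sl.f_ms_in : sl.f_ms;
        const double mstep = inb ? sl.max_step_in : sl.max_step;

        double cost = 1.0 / std::sqrt(1.0 + tx * tx + ty * ty);
        double dz = std::min(mstep, sl.z1 - z);
        double spath = dz / cost;
        double slin = m.density * m.msp(E) / 10.0;  // MeV/mm
        if (slin > 1e-12) {
          double smax = 0.05 * E / slin;
          if (spath > smax) {
            spath = std::max(smax, 0.005);
            dz = spath * cost;
          }
        }
        double gamma = 1.0 + E / MP;
        double b2 = 1.0 - 1.0 / (gamma * gamma);
        double om2 = 0.1569 * m.density * m.zova * (spath / 10.0) *
                     (1.0 - b2 / 2.0) / (1.0 - b2);
        double dE = slin * spath;
        // Gaussian straggling only where the Gaussian model is valid
        // (sigma <= mean loss); thin near-vacuum steps lose the mean
        if (om2 > 0.0 && om2 <= dE * dE) dE += std::sqrt(om2) * rng.norm();
        if (dE < 0.0) dE = 0.0;
        if (dE > E) dE = E;
        double Emid = std::max(E - 0.5 * dE, 1.0);

        double pv = Emid * (Emid + 2.0 * MP) / (Emid + MP);
        double tg = (spath / 10.0) * m.density;  // g/cm^2
        double th0 = (m.x0 > 0.0 && tg > 0.0)
          ? 14.1 / pv * std::sqrt(tg / m.x0) * fms : 0.0;
        double z2x = rng.norm(), z1x = rng.norm();
        double z2y = rng.norm(), z1y = rng.norm();

        double xm = x + tx * dz * 0.5, ym = y + ty * dz * 0.5;
        double zm = z + dz * 0.5;
        x += tx * dz + dz * th0 * (z1x * 0.28867513459481287 + z2x * 0.5);
        y += ty * dz + dz * th0 * (z1y * 0.28867513459481287 + z2y * 0.5);
        tx += th0 * z2x;
        ty += th0 * z2y;
        z += dz;

        double eps_dep = dE;
        E -= dE;
        double smid_lin = m.density * m.msp(Emid) / 10.0;

        double extra_local = 0.0, extra_escaped = 0.0;
        if (nuclear && alive && E > e_nuc_min && m.lambda_mm > 0.0) {
          double p = 1.0 - std::exp(-spath / m.lambda_mm);
          if (rng.unif() < p) {
            extra_local = local_frac * E;
            extra_escaped = (1.0 - local_frac) * E;
            E = 0.0;
            alive = false;
          }
        }
        if (alive && E < cutoff) {
          extra_local += E;
          E = 0.0;
          alive = false;
        }

        if (sl.region == 3) {
          int ix = (int)std::floor((xm - gx0) / vox);
          int iy = (int)std::floor((ym - gy0) / vox);
          int iz = (int)std::floor((zm - gz0) / vox);
          if (ix >= 0 && ix < nx && iy >= 0 && iy < ny && iz >= 0 && iz < nz) {
            size_t id = (size_t)ix + (size_t)nx * (iy + (size_t)ny * iz);
            dose[id] += w * (eps_dep + extra_local);
            let_num[id] += w * eps_dep * smid_lin;
            let_den[id] += w * eps_dep;
            edep[3] += w * (eps_dep + extra_local);
            edep[4] += w * extra_escaped;
          } else {
            // left the scoring volume laterally: terminate, book as escaped
            edep[4] += w * (eps_dep + extra_local + extra_escaped);
            if (alive) { edep[4] += w * E; E = 0.0; alive = false; }
          }
        } else {
          edep[sl.region] += w * (eps_dep + extra_local);
          edep[4] += w * extra_escaped;
        }
      }
      if (alive && si == record_slab) {
        rec.push_back(x); rec.push_back(y);
        rec.push_back(tx); rec.push_back(ty);
        rec.push_back(E); rec.push_back(w);
      }
    }
    if (alive) edep[4] += w * E;  // exited the stack downstream
  }

  IntegerVector dim = IntegerVector::create(nx, ny, nz);
  NumericVector dose_r(dose.begin(), dose.end());
  NumericVector ln_r(let_num.begin(), let_num.end());
  NumericVector ld_r(let_den.begin(), let_den.end());
  dose_r.attr("dim") = dim;
  ln_r.attr("dim") = dim;
  ld_r.attr("dim") = dim;

  int nrec = (int)(rec.size() / 6);
  NumericMatrix recm(nrec, 6);
  for (int i = 0; i < nrec; ++i)
    for (int j = 0; j < 6; ++j) recm(i, j) = rec[(size_t)i * 6 + j];

  return List::create(_["dose"] = dose_r, _["let_num"] = ln_r,
                      _["let_den"] = ld_r, _["exit_states"] = recm,
                      _["edep"] = NumericVector(edep.begin(), edep.end()),
                      _["e_initial"] = e_initial);
}
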