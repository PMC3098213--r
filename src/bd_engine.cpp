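// Brownian-dynamics engine for sedimentation in a sector-shaped AUC cell.
//
// Each particle k owns a counter-based random substream derived from
// (seed, k) only, so results are bitwise independent of execution order or
// worker partitioning. Stream consumption is fixed: one uniform for the
// initial position, then exactly two uniforms per BD step (Box-Muller pair
// for the Brownian increment).

#include <Rcpp.h>
#include <cstdint>
#include <cmath>

using namespace Rcpp;

namespace {

inline uint64_t mix64(uint64_t z) {
  // splitmix64 finalizer (bijective avalanche mix)
  z += 0x9E3779B97F4A7C15ULL;
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

struct ParticleStream {
  uint64_t state;
  ParticleStream(uint64_t seed, uint64_t k) {
    state = mix64(mix64(seed) ^ mix64(k ^ 0x5851F42D4C957F2DULL));
  }
  double uniform() {  // open interval (0, 1)
    state += 0x9E3779B97F4A7C15ULL;
    uint64_t z = state;
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    z ^= z >> 31;
    return (static_cast<double>(z >> 12) + 0.5) * (1.0 / 4503599627370496.0);
  }
  double normal() {  // Box-Muller, consumes two uniforms
    double u1 = uniform();
    double u2 = uniform();
    return std::sqrt(-2.0 * std::log(u1)) * std::cos(2.0 * M_PI * u2);
  }
};

inline double apply_bounds(double r, double rm, double rb) {
  // meniscus clamp, bottom bounce; iterate until inside the cell
  while (r < rm || r > rb) {
    if (r > rb) {
      r = 2.0 * rb - r;
    } else {
      r = rm;  // clamp is inside, terminates the loop
    }
  }
  return r;
}

}  // namespace

//' @noRd
// [[Rcpp::export(name = "cpp_stream_uniforms")]]
NumericVector cpp_stream_uniforms(int seed, int particle, int n) {
  ParticleStream st(static_cast<uint64_t>(seed),
                    static_cast<uint64_t>(particle));
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = st.uniform();
  return out;
}

//' @noRd
// [[Rcpp::export(name = "cpp_stream_normals")]]
NumericVector cpp_stream_normals(int seed, int particle, int n, int skip) {
  // skip: number of uniforms to discard first (e.g. 1 = the position draw)
  ParticleStream st(static_cast<uint64_t>(seed),
                    static_cast<uint64_t>(particle));
  for (int i = 0; i < skip; ++i) st.uniform();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = st.normal();
  return out;
}

// Count matrix n(i, j): particles per radial slice i at scan time t_j.
// Particles are k = k_offset .. k_offset + n_part - 1 under global `seed`.
//' @noRd
// [[Rcpp::export(name = "cpp_bd_counts")]]
IntegerMatrix cpp_bd_counts(int n_part, int k_offset, int seed,
                            double s, double D, double omega,
                            double rm, double rb, int n_r,
                            double dt, int n_steps, int steps_per_scan) {
  const int n_scans = n_steps / steps_per_scan;
  IntegerMatrix counts(n_r, n_scans);
  const double span2 = rb * rb - rm * rm;
  const double chi = (rb - rm) / n_r;
  const double growth = std::expm1(s * omega * omega * dt);
  const double sigma = std::sqrt(2.0 * D * dt);

  for (int k = 0; k < n_part; ++k) {
    ParticleStream st(static_cast<uint64_t>(seed),
                      static_cast<uint64_t>(k_offset + k));
    double r = std::sqrt(st.uniform() * span2 + rm * rm);
    int j = 0;
    for (int step = 1; step <= n_steps; ++step) {
      double z = st.normal();
      r = apply_bounds(r + r * growth + sigma * z, rm, rb);
      if (step % steps_per_scan == 0) {
        int i = static_cast<int>((r - rm) / chi);
        if (i >= n_r) i = n_r - 1;
        if (i < 0) i = 0;
        ++counts(i, j);
        ++j;
      }
    }
  }
  return counts;
}

// Scan-time radii for selected particles; row 0 is the initial position,
// rows 1..n_scans are the positions at t_j = j * tau.
//' @noRd
// [[Rcpp::export(name = "cpp_bd_trajectories")]]
NumericMatrix cpp_bd_trajectories(IntegerVector particles, int seed,
                                  double s, double D, double omega,
                                  double rm, double rb,
                                  double dt, int n_steps, int steps_per_scan) {
  const int n_scans = n_steps / steps_per_scan;
  const int n_part = particles.size();
  NumericMatrix rec(n_scans + 1, n_part);
  const double span2 = rb * rb - rm * rm;
  const double growth = std::expm1(s * omega * omega * dt);
  const double sigma = std::sqrt(2.0 * D * dt);

  for (int k = 0; k < n_part; ++k) {
    ParticleStream st(static_cast<uint64_t>(seed),
                      static_cast<uint64_t>(particles[k]));
    double r = std::sqrt(st.uniform() * span2 + rm * rm);
    rec(0, k) = r;
    int j = 1;
    for (int step = 1; step <= n_steps; ++step) {
      double z = st.normal();
      r = apply_bounds(r + r * growth + sigma * z, rm, rb);
      if (step % steps_per_scan == 0) rec(j++, k) = r;
    }
  }
  return rec;
}
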