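#include <Rcpp.h>
#include <cstdint>
#include <cmath>
using namespace Rcpp;

// Small dedicated counter-free RNG (splitmix64-seeded xoshiro256+) so that a
// single Gillespie trajectory costs tens of nanoseconds per event and is
// reproducible from one integer seed independently of R's RNG state.
namespace {

struct Xoshiro {
  uint64_t s[4];
  explicit Xoshiro(uint64_t seed) {
    // splitmix64 expansion of the seed
    uint64_t x = seed + 0x9E3779B97F4A7C15ULL;
    for (int i = 0; i < 4; ++i) {
      uint64_t z = (x += 0x9E3779B97F4A7C15ULL);
      z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
      z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
      s[i] = z ^ (z >> 31);
    }
  }
  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  inline uint64_t next() {
    uint64_t result = s[0] + s[3];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return result;
  }
  // uniform in (0, 1); never exactly 0 so -log(u) is finite
  inline double runif() {
    return ((next() >> 11) + 1.0) * (1.0 / 9007199254740994.0);
  }
};

}  // namespace

// Exact stochastic simulation (Gillespie) of the predator-prey Markov jump
// process with reactions
//   prey birth    (w1, w2) -> (w1+1, w2)   at rate theta1 * w1
//   predation     (w1, w2) -> (w1-1, w2+1) at rate theta2 * w1 * w2
//   predator death(w1, w2) -> (w1, w2-1)   at rate theta3 * w2
// States are recorded at the supplied grid times by carrying the current
// state forward.  A trajectory stops early (flagged `capped`) when the event
// or population cap is hit; the last state is then carried forward over the
// remaining grid, keeping samplers total on explosive prior draws.
// [[Rcpp::export]]
List lv_gillespie_cpp(double theta1, double theta2, double theta3,
                      int y1_0, int y2_0, NumericVector t_grid,
                      int seed, double event_cap, double pop_cap,
                      bool return_path) {
  Xoshiro rng(static_cast<uint64_t>(seed));
  const int G = t_grid.size();
  IntegerMatrix grid(2, G);
  double t = 0.0;
  long long w1 = y1_0, w2 = y2_0;
  long long n_events = 0;
  bool capped = false;
  int g = 0;
  std::vector<double> path_t;
  std::vector<int> path_w1, path_w2;
  if (return_path) {
    path_t.push_back(0.0); path_w1.push_back(w1); path_w2.push_back(w2);
  }
  const double t_end = G > 0 ? t_grid[G - 1] : 0.0;
  while (true) {
    double a1 = theta1 * static_cast<double>(w1);
    double a2 = theta2 * static_cast<double>(w1) * static_cast<double>(w2);
    double a3 = theta3 * static_cast<double>(w2);
    double gamma = a1 + a2 + a3;
    double t_next;
    if (gamma <= 0.0) {
      t_next = R_PosInf;  // absorbing state
    } else {
      t_next = t - std::log(rng.runif()) / gamma;
    }
    while (g < G && t_grid[g] < t_next) {
      grid(0, g) = static_cast<int>(w1);
      grid(1, g) = static_cast<int>(w2);
      ++g;
    }
    if (g >= G || t_next > t_end || !R_FINITE(t_next)) break;
    t = t_next;
    double u = rng.runif() * gamma;
    if (u < a1) {
      ++w1;
    } else if (u < a1 + a2) {
      --w1; ++w2;
    } else {
      --w2;
    }
    ++n_events;
    if (return_path) {
      path_t.push_back(t); path_w1.push_back(w1); path_w2.push_back(w2);
    }
    if (n_events >= static_cast<long long>(event_cap) ||
        w1 > static_cast<long long>(pop_cap) ||
        w2 > static_cast<long long>(pop_cap)) {
      capped = true;
      while (g < G) {  // carry the capped state forward
        grid(0, g) = static_cast<int>(std::min<long long>(w1, 2147483647LL));
        grid(1, g) = static_cast<int>(std::min<long long>(w2, 2147483647LL));
        ++g;
      }
      break;
    }
  }
  List out = List::create(_["grid"] = grid, _["capped"] = capped,
                          _["n_events"] = static_cast<double>(n_events));
  if (return_path) {
    out["path_t"] = wrap(path_t);
    out["path_y1"] = wrap(path_w1);
    out["path_y2"] = wrap(path_w2);
  }
  return out;
}

// Single-server queue recursion: given service times u and interarrival
// times w (and a starting state (x0, v0) of last departure and last arrival
// times), computes interdeparture times y_i = u_i + max(0, v_i - x_{i-1}),
// arrival times v, departure times x and waiting times omega = x - v.
// [[Rcpp::export]]
List mg1_recurse_cpp(NumericVector u, NumericVector w, double x0, double v0) {
  const int n = u.size();
  if (w.size() != n) stop("u and w must have equal length");
  NumericVector y(n), v(n), x(n), omega(n);
  double xp = x0, vp = v0;
  for (int i = 0; i < n; ++i) {
    vp += w[i];
    double start = std::max(xp, vp);  // service starts at arrival or when free
    xp = start + u[i];
    y[i] = xp - (i == 0 ? x0 : x[i - 1]);
    v[i] = vp;
    x[i] = xp;
    omega[i] = xp - vp;
  }
  return List::create(_["y"] = y, _["v"] = v, _["x"] = x, _["u"] = u,
                      _["omega"] = omega);
}
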