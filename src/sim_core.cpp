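// Stochastic time stepping of the metacommunity dynamics.
//
// Per step: Euler-forward drift (growth + interactions + dispersal), clipped
// at zero, then demographic noise as a Poisson draw around the Euler mean.
// The whole update is one fused pass over the abundance matrix. Randomness
// comes from an internal xoshiro256++ stream seeded from R's RNG at entry,
// so set.seed() on the R side gives bit-identical trajectories.
#include <RcppArmadillo.h>
#include <cstdint>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

namespace {

// ---- RNG: xoshiro256++, seeded via splitmix64 from R's uniform stream ----
struct Xoshiro {
  uint64_t s[4];
  static inline uint64_t rotl(const uint64_t x, const int k) {
    return (x << k) | (x >> (64 - k));
  }
  void seed_from_R() {
    uint64_t x = (uint64_t)(unif_rand() * 9007199254740992.0);
    x ^= ((uint64_t)(unif_rand() * 9007199254740992.0)) << 11;
    for (int i = 0; i < 4; ++i) {  // splitmix64 expansion
      x += 0x9E3779B97f4A7C15ULL;
      uint64_t z = x;
      z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
      z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
      s[i] = z ^ (z >> 31);
    }
  }
  inline uint64_t next() {
    const uint64_t r = rotl(s[0] + s[3], 23) + s[0];
    const uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return r;
  }
  inline double unif() { return (next() >> 11) * 0x1.0p-53; }
};

// ---- exact Poisson sampling ----
// Knuth inversion below mean 10; transformed rejection with squeeze
// (Hormann's PTRS) above, with the slow-path constants computed lazily.
inline double lgamma_kp1(const long k) {
  static std::vector<double> cache;
  if (cache.empty()) {
    cache.resize(4096);
    for (long i = 0; i < 4096; ++i) cache[i] = std::lgamma(i + 1.0);
  }
  return (k >= 0 && k < 4096) ? cache[k] : std::lgamma(k + 1.0);
}

inline double rpois_fast(const double mu, Xoshiro& rng) {
  if (mu < 10.0) {
    const double L = std::exp(-mu);
    double p = 1.0;
    long k = 0;
    do { ++k; p *= rng.unif(); } while (p > L);
    return (double)(k - 1);
  }
  const double smu = std::sqrt(mu);
  const double b = 0.931 + 2.53 * smu;
  const double a = -0.059 + 0.02483 * b;
  const double v_r = 0.9277 - 3.6224 / (b - 2.0);
  for (;;) {
    const double U = rng.unif() - 0.5;
    const double V = rng.unif();
    const double us = 0.5 - std::fabs(U);
    const long k = (long)std::floor((2.0 * a / us + b) * U + mu + 0.43);
    if (us >= 0.07 && V <= v_r) return (double)k;
    if (k < 0 || (us < 0.013 && V > us)) continue;
    const double inv_alpha = 1.1239 + 1.1328 / (b - 3.4);
    if (std::log(V) + std::log(inv_alpha) - std::log(a / (us * us) + b) <=
        -mu + k * std::log(mu) - lgamma_kp1(k)) {
      return (double)k;
    }
  }
}

inline double draw(const double M, const double dt, const double inv_dt,
                   const int scheme, Xoshiro& rng) {
  // scheme: 0 scaled Poisson, 1 unit Poisson, 2 deterministic
  if (scheme == 2) return M;
  if (M <= 0.0) return 0.0;
  return (scheme == 0) ? dt * rpois_fast(M * inv_dt, rng) : rpois_fast(M, rng);
}

// one fused Euler + noise step; returns the total abundance after the step
double do_step(arma::mat& N, const arma::vec& r, const double K,
               const int inter_mode, const double alpha, const arma::mat& A,
               const double lam, const double beta,
               const double dt, const int scheme, const double pinned_m,
               arma::vec& tot, arma::vec& colavg, arma::mat& inter,
               Xoshiro& rng) {
  const arma::uword P = N.n_rows, S = N.n_cols;
  const double inv_dt = 1.0 / dt, invK = 1.0 / K, invP = 1.0 / (double)P;

  tot = arma::sum(N, 1);  // patch totals, snapshot at time t
  if (inter_mode == 1) inter = N * A;  // A symmetric, zero diagonal

  if (beta == 0.0) {
    if (pinned_m >= 0.0) {
      colavg.fill(pinned_m);
    } else {
      colavg = arma::vectorise(arma::mean(N, 0));
    }
  } else {
    // emigration weights w_xi = (1 + beta (tot_x - N_xi)) N_xi
    for (arma::uword i = 0; i < S; ++i) {
      const double* col = N.colptr(i);
      double acc = 0.0;
      for (arma::uword x = 0; x < P; ++x) {
        acc += (1.0 + beta * (tot[x] - col[x])) * col[x];
      }
      colavg[i] = acc * invP;
    }
  }

  double total = 0.0;
  bool bad = false;
  for (arma::uword i = 0; i < S; ++i) {
    double* col = N.colptr(i);
    const double* icol = (inter_mode == 1) ? inter.colptr(i) : nullptr;
    const double ri = r[i], ci = colavg[i];
    for (arma::uword x = 0; x < P; ++x) {
      const double n = col[x];
      const double it = (inter_mode == 1) ? icol[x] : alpha * (tot[x] - n);
      double f = ri * n * (1.0 - (n - it) * invK);
      if (beta == 0.0) {
        f += lam * (ci - n);
      } else {
        f += lam * (ci - (1.0 + beta * (tot[x] - n)) * n);
      }
      double M = n + dt * f;
      if (M < 0.0) M = 0.0;
      if (!std::isfinite(M)) { bad = true; M = 0.0; }
      const double nn = draw(M, dt, inv_dt, scheme, rng);
      col[x] = nn;
      total += nn;
    }
  }
  if (bad) stop("non-finite abundances during stepping; reduce dt");
  return total;
}

}  // namespace

// raw access to the Poisson sampler for distributional tests
// [[Rcpp::export]]
NumericVector rpois_stream(const int n, const NumericVector& mu) {
  Xoshiro rng;
  rng.seed_from_R();
  NumericVector out(n);
  const int nm = mu.size();
  for (int i = 0; i < n; ++i) out[i] = rpois_fast(mu[i % nm], rng);
  return out;
}

// [[Rcpp::export]]
List sim_core(const arma::mat& N0, const arma::vec& r, const double K,
              const int inter_mode, const double alpha, const arma::mat& A,
              const double lam, const double beta,
              const double dt, const int steps, const int record_every,
              const int scheme, const double pinned_m,
              const double t0) {
  arma::mat N = N0;
  const arma::uword P = N.n_rows, S = N.n_cols;
  arma::vec tot(P), colavg(S);
  arma::mat inter;
  if (inter_mode == 1) inter.set_size(P, S);
  Xoshiro rng;
  rng.seed_from_R();

  const int n_rec = steps / record_every + 1;
  std::vector<double> times, means;
  times.reserve(n_rec); means.reserve(n_rec);
  times.push_back(t0);
  means.push_back(arma::accu(N) / N.n_elem);

  bool extinct = means.back() == 0.0;
  int done = 0;
  while (done < steps && !extinct) {
    const int chunk = std::min(record_every, steps - done);
    double total = 0.0;
    for (int s = 0; s < chunk; ++s) {
      total = do_step(N, r, K, inter_mode, alpha, A, lam, beta, dt, scheme,
                      pinned_m, tot, colavg, inter, rng);
      if (total == 0.0) break;  // absorbed mid-chunk; steps are now no-ops
    }
    done += chunk;
    times.push_back(t0 + done * dt);
    means.push_back(total / N.n_elem);
    if (total == 0.0) extinct = true;
    Rcpp::checkUserInterrupt();
  }

  return List::create(
      _["times"] = times, _["mean_series"] = means,
      _["final_state"] = N,
      _["species_means"] = arma::conv_to<std::vector<double>>::from(
          arma::vectorise(arma::mean(N, 0))),
      _["extinct"] = extinct,
      _["t_end"] = t0 + done * dt);
}

// Single population with the mean field pinned at m: drift
// f(N) = rg N - (r/K) N^2 + lam (m - N), stepped by the same Poisson scheme.
// Returns abundances sampled every `sample_every` steps after `burn` steps.
// [[Rcpp::export]]
NumericVector sim_pinned_samples(const double n0, const double rg,
                                 const double r_over_K, const double lam,
                                 const double m, const double dt,
                                 const int burn, const int n_samples,
                                 const int sample_every, const int scheme) {
  NumericVector out(n_samples);
  Xoshiro rng;
  rng.seed_from_R();
  double n = n0;
  const double inv_dt = 1.0 / dt;
  auto step1 = [&](double x) {
    const double f = rg * x - r_over_K * x * x + lam * (m - x);
    double M = x + dt * f;
    if (M < 0.0) M = 0.0;
    if (!std::isfinite(M)) stop("non-finite abundance; reduce dt");
    return draw(M, dt, inv_dt, scheme, rng);
  };
  for (int s = 0; s < burn; ++s) n = step1(n);
  for (int k = 0; k < n_samples; ++k) {
    for (int s = 0; s < sample_every; ++s) n = step1(n);
    out[k] = n;
    if ((k & 0xFFFF) == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}
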