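# Single-species metapopulation with an explicit strong Allee effect on
# every patch: drift f(N) = r N (N/A - 1) (1 - N/K) + lam (m - N). The same
# Fokker-Planck construction gives a stationary density with a cubic
# exponent,
#   P[N] propto N^(2 lam m - 1) exp(c1 N + c2 N^2 + c3 N^3),
#   c1 = -2 (r + lam), c2 = r (1/A + 1/K), c3 = -2 r / (3 A K).
# Despite per-patch bistability, the metapopulation-level transition at
# lambda_c is continuous: the deterministic threshold is smoothed out by
# demographic noise, the mirror image of the emergent bistability that weak
# mutualism produces.

allee_coefs <- function(r, K, A, lam) {
  c(-2 * (r + lam), r * (1 / A + 1 / K), -2 * r / (3 * A * K))
}

#' Deterministic drift with an explicit strong Allee effect
#'
#' `f(N) = r N (N/A - 1) (1 - N/K) + lam (m - N)`: negative per-capita
#' growth below the Allee threshold `A`, positive between `A` and the
#' carrying capacity `K`. With `lam = 0` the fixed points are `0`, `A`
#' (unstable) and `K` (stable).
#'
#' @param N Abundance(s).
#' @param r Growth-rate scale, `> 0`.
#' @param K Carrying capacity.
#' @param A Allee threshold, `0 < A < K`.
#' @param lam Dispersal rate.
#' @param m Mean field abundance.
#' @return Drift value(s).
#' @export
allee_drift <- function(N, r, K, A, lam = 0, m = 0) {
  stopifnot(A > 0, A < K)
  r * N * (N / A - 1) * (1 - N / K) + lam * (m - N)
}

allee_mean_fn <- function(r, K, A, lam) {
  coefs <- allee_coefs(r, K, A, lam)
  function(m) mf_moments(2 * lam * m, coefs)$mean
}

#' Bifurcation scan for the explicit-Allee metapopulation
#'
#' Self-consistent mean-field branches for a single species whose local
#' dynamics are bistable (strong Allee effect with threshold `A`). The
#' scan demonstrates the continuous onset of the positive branch at the
#' critical dispersal rate: demographic noise plus dispersal smooths the
#' deterministic threshold rather than sharpening it.
#'
#' @param growth A [growth_params()] object (`r`, `K`; single species).
#' @param A Allee threshold, `0 < A < K`.
#' @param lam_grid Dispersal rates to scan.
#' @param n_grid Trial points per root scan.
#' @return An `mc_bifurcation` object (its `lam_c` solves the
#'   marginal-slope condition for the Allee drift).
#' @export
allee_bifurcation_scan <- function(growth, A,
                                   lam_grid = 10^seq(-3, 0, length.out = 31),
                                   n_grid = 200) {
  stopifnot(inherits(growth, "mc_growth"))
  r <- unique(growth$r); K <- growth$K
  if (length(r) != 1L || r <= 0) stop("requires a single common r > 0")
  if (A >= K) stop("Allee threshold A must be below K")
  lam_grid <- sort(lam_grid)

  roots_at <- function(lam) {
    mean_fn <- allee_mean_fn(r, K, A, lam)
    slope0 <- 2 * lam * exp(mf_log_weight_integral(1, allee_coefs(r, K, A, lam)))
    rt <- mf_root_engine(mean_fn, slope0, m_lo = 1e-6 * K, m_max = 3 * K,
                         n_grid = n_grid)
    rt[rt$type == "positive", , drop = FALSE]
  }
  per_lam <- purrr::map(lam_grid, roots_at)
  branches <- purrr::map2_dfr(lam_grid, per_lam, function(lam, rt) {
    if (nrow(rt) == 0) return(tibble::tibble())
    tibble::tibble(lambda = lam,
                   branch = ifelse(rt$stable, "stable", "unstable"),
                   m = rt$m)
  })
  # stability of the extinct state can flip twice here: noise-activated
  # crossings of the local Allee barrier destabilize it at intermediate
  # dispersal, while strong emigration re-stabilizes it at large dispersal.
  # lambda_c is the upper flip, where the threshold (unstable) branch
  # detaches continuously from zero.
  gfun <- function(lam) {
    2 * lam * exp(mf_log_weight_integral(1, allee_coefs(r, K, A, lam))) - 1
  }
  probe <- 10^seq(log10(min(lam_grid)) - 2, log10(max(lam_grid)) + 2,
                  length.out = 80)
  gv <- vapply(probe, gfun, numeric(1))
  flips <- which(diff(sign(gv)) != 0)
  lam_c <- if (length(flips)) {
    i <- flips[length(flips)]
    stats::uniroot(gfun, c(probe[i], probe[i + 1]), tol = 1e-12)$root
  } else NA_real_

  has_stable <- vapply(per_lam, function(rt) any(rt$stable), logical(1))
  lam_t <- if (any(has_stable)) lam_grid[which(has_stable)[1]] else NA_real_
  flag <- if (!any(has_stable)) "none"
          else if (has_stable[1]) "at_grid_min"
          else if (lam_t < lam_c * (1 - 1e-3)) "window"
          else "no_subcritical_window"
  params <- mc_params(growth_params(r = r, K = K, S = 1, P = 1),
                      interaction_spec(alpha = 0),
                      dispersal_spec(lam = lam_grid[1]))
  structure(list(branches = branches, lam_grid = lam_grid, lam_c = lam_c,
                 lam_t = lam_t, lam_t_flag = flag, params = params,
                 allee_A = A),
            class = "mc_bifurcation")
}
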