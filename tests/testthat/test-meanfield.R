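# The stationary density under a pinned mean field and the self-consistent
# roots built on it.

test_that("pure immigration-death stationary density is the Gamma law", {
  p <- p_uniform(S = 1, P = 1, lam = 0.1, alpha = 0, r = 0)
  d <- stationary_density(5, p)
  Ns <- seq(0.01, 80, length.out = 400)
  expect_lt(max(abs(d$density(Ns) - stats::dgamma(Ns, shape = 1, rate = 0.2))),
            1e-10)
  expect_equal(mean_of_density(d), 5, tolerance = 1e-10)
  # shape < 1 branch (integrable singularity at the origin)
  d2 <- stationary_density(2, p)   # shape 0.4
  expect_lt(max(abs(d2$density(Ns) -
                      stats::dgamma(Ns, shape = 0.4, rate = 0.2))), 1e-10)
  expect_equal(mean_of_density(d2), 2, tolerance = 1e-8)
  expect_equal(d2$cdf(5), stats::pgamma(5, shape = 0.4, rate = 0.2),
               tolerance = 1e-8)
})

test_that("the extinct mean field gives a point mass at zero", {
  d <- stationary_density(0, p_uniform(S = 1, P = 1, lam = 0.1))
  expect_true(d$degenerate)
  expect_equal(mean_of_density(d), 0)
  expect_equal(d$cdf(c(0, 1)), c(1, 1))
  expect_error(stationary_density(1, p_uniform(S = 1, P = 1, lam = 0)),
               "stationary")
})

test_that("the density mode sits close to the deterministic fixed point", {
  p <- p_uniform(S = 100, P = 1, lam = 0.1, alpha = 0.005)
  m <- 19.8
  d <- stationary_density(m, p)
  # mode solves (s - 1)/N + a - 2 b N = 0
  s <- d$shape_exp; a <- d$lin_coef; b <- d$quad_coef
  mode_analytic <- (a + sqrt(a^2 + 8 * b * (s - 1))) / (4 * b)
  grid <- seq(5, 35, by = 1e-3)
  mode_numeric <- grid[which.max(d$density(grid))]
  expect_equal(mode_numeric, mode_analytic, tolerance = 1e-3)
  expect_equal(mode_analytic, 19.06, tolerance = 5e-3)
  expect_lt(abs(mode_analytic - deterministic_fixed_point(p)) /
              deterministic_fixed_point(p), 0.05)
})

test_that("normalization and the small-m immigration asymptotics hold", {
  p <- p_uniform(S = 1, P = 1, lam = 0.01, alpha = 0)
  d <- stationary_density(1e-4, p)
  expect_equal(d$cdf(1e4), 1, tolerance = 1e-8)
  # as m -> 0, <N> -> 2 lam m W with W = int exp(a N - b N^2) dN
  W <- stats::integrate(function(N) exp(d$lin_coef * N - d$quad_coef * N^2),
                        0, Inf, rel.tol = 1e-10)$value
  expect_equal(mean_of_density(d), 2 * 0.01 * 1e-4 * W, tolerance = 1e-3)
})

test_that("self-consistency finds the expected root structure", {
  # single species above threshold: one stable positive root
  r1 <- self_consistent_roots(p_uniform(S = 1, P = 1, lam = 0.1, alpha = 0))
  pos1 <- r1[r1$type == "positive", ]
  expect_equal(nrow(pos1), 1)
  expect_true(pos1$stable)
  expect_false(r1$stable[r1$type == "extinct"])  # lam > lam_c

  # neutral r = 0 case is flagged degenerate
  r0 <- self_consistent_roots(p_uniform(S = 1, P = 1, lam = 0.1, r = 0))
  expect_true(attr(r0, "degenerate"))

  # lam = 0: only the extinct root
  rz <- self_consistent_roots(p_uniform(S = 10, P = 1, lam = 0))
  expect_equal(rz$type, "extinct")
})

test_that("critical dispersal rate decreases with carrying capacity", {
  lc10 <- critical_dispersal(growth_params(r = 0.3, K = 10))
  lc100 <- critical_dispersal(growth_params(r = 0.3, K = 100))
  lc1000 <- critical_dispersal(growth_params(r = 0.3, K = 1000))
  expect_gt(lc10, lc100)
  expect_gt(lc100, lc1000)
  expect_error(critical_dispersal(growth_params(r = 0, K = 10)), "r > 0")
})

test_that("single-species bifurcation is continuous with no unstable branch", {
  p <- p_uniform(S = 1, P = 1, alpha = 0)
  sc <- bifurcation_scan(p, lam_grid = 10^seq(-3, -1, length.out = 9))
  expect_false(any(sc$branches$branch == "unstable"))
  expect_equal(sc$lam_t_flag, "no_subcritical_window")
  stable <- sc$branches[sc$branches$branch == "stable", ]
  expect_true(all(diff(stable$m[order(stable$lambda)]) > 0))
  expect_true(all(stable$lambda > sc$lam_c))
})

test_that("mutualistic community shows a bistable window below lambda_c", {
  p <- p_uniform(S = 100, P = 1, alpha = 0.005)
  sc <- bifurcation_scan(p, lam_grid = 10^seq(-3.6, -2.2, length.out = 8))
  expect_equal(sc$lam_t_flag, "at_grid_min")
  br <- sc$branches
  both <- intersect(br$lambda[br$branch == "stable"],
                    br$lambda[br$branch == "unstable"])
  expect_gt(length(both), 0)
  for (l in both) {
    expect_lt(max(br$m[br$lambda == l & br$branch == "unstable"]),
              min(br$m[br$lambda == l & br$branch == "stable"]))
  }
})

test_that("density-dependent dispersal reduces to the constant-rate case at beta = 0", {
  p0 <- p_uniform(S = 100, P = 1, lam = 1e-3, alpha = 0.005, beta = 0)
  a <- self_consistent_roots(p0)
  b <- density_dependent_roots(p0)
  expect_equal(a, b)
})

test_that("mean-field loses its positive branch between 50 and 100 species at low dispersal", {
  # collapse with species number: at lam = 1e-3 the S = 100 community has a
  # stable positive branch, the S = 50 community does not
  r100 <- self_consistent_roots(p_uniform(S = 100, P = 1, lam = 1e-3))
  r50 <- self_consistent_roots(p_uniform(S = 50, P = 1, lam = 1e-3))
  expect_true(any(r100$stable & r100$type == "positive"))
  expect_false(any(r50$stable & r50$type == "positive"))
})

test_that("simulated steady state matches the mean-field stable root", {
  # lam well above lambda_c, single species
  p <- p_uniform(S = 1, P = 500, lam = 0.1, alpha = 0)
  rt <- self_consistent_roots(p)
  m_star <- rt$m[rt$stable & rt$type == "positive"]
  tr <- simulate_metacommunity(p, make_initial_state(p, level = 5),
                               sim_config(T_total = 1500), seed = 31)
  expect_false(tr$extinct)
  expect_lt(abs(steady_mean(tr) - m_star) / m_star, 0.1)
})
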