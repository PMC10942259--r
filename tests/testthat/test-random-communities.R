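test_that("interaction sampling is symmetric, hollow and seeded", {
  A <- sample_interactions(40, alpha_hat = -0.01, sigma = 0.5, seed = 3)
  expect_identical(A, t(A))
  expect_equal(diag(A), rep(0, 40))
  expect_identical(A, sample_interactions(40, -0.01, 0.5, seed = 3))
  expect_false(identical(A, sample_interactions(40, -0.01, 0.5, seed = 4)))

  A0 <- sample_interactions(10, alpha_hat = 0.02, sigma = 0, seed = 1)
  off <- A0[upper.tri(A0)]
  expect_true(all(off == 0.02))
})

test_that("pairwise coefficients have mean alpha_hat and spread sigma/sqrt(S)", {
  vals <- unlist(lapply(1:4, function(s) {
    A <- sample_interactions(100, alpha_hat = -0.01, sigma = 0.5, seed = s)
    A[upper.tri(A)]
  }))
  n <- length(vals)          # 4 x 4950 pairs
  se <- 0.05 / sqrt(n)
  expect_lt(abs(mean(vals) + 0.01), 3 * se)
  expect_equal(stats::sd(vals), 0.05, tolerance = 0.05)
})

test_that("matrix files round-trip with their JSON header", {
  A <- sample_interactions(12, alpha_hat = -0.01, sigma = 0.5, seed = 21)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_interaction_matrix(A, path, alpha_hat = -0.01, sigma = 0.5, seed = 21)
  B <- read_interaction_matrix(path)
  expect_equal(unclass(B), unclass(A), tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(attr(B, "header")$seed, 21)
})

test_that("realized interactions at the uniform fixed point are alpha N*/K", {
  p <- p_uniform(S = 100, P = 5, lam = 1e-3, alpha = 0.005)
  # build a finished trajectory at the fixed point without noise
  tr <- simulate_metacommunity(
    p, make_initial_state(p, "near_fixed_point"),
    sim_config(dt = 0.1, T_total = 1, scheme = "deterministic"), seed = 1)
  # uniform matrix via an explicit random spec with sigma = 0
  pu <- mc_params(p$growth,
                  interaction_spec("random_symmetric", alpha_hat = 0.005,
                                   sigma = 0, seed = 1),
                  p$disp)
  s <- survivor_summary(tr, pu, eps = 0.01)
  expect_equal(s$S_surv, 100L)
  expect_equal(s$alpha_hat_surv, 0.005)
  expect_equal(unique(round(s$interactions$I, 6)),
               round(0.005 / 10 * deterministic_fixed_point(p), 6))
  expect_equal(s$interactions$I[1], 0.0099, tolerance = 1e-3)
})

test_that("an all-extinct run yields an empty survivor summary", {
  p <- p_random(S = 10, P = 5, lam = 1e-4, seed = 2)
  tr <- simulate_metacommunity(p, make_initial_state(p, level = 0.05),
                               sim_config(T_total = 2000), seed = 7)
  expect_true(tr$extinct)
  s <- survivor_summary(tr, p)
  expect_equal(s$S_surv, 0L)
  expect_true(is.na(s$alpha_hat_surv))
  expect_equal(nrow(tidy(s)), 0)
  expect_error(effective_tipping_point(s, p$growth, 1e-3), "two surviving")
})

test_that("raising the survival threshold never adds survivors", {
  p <- p_random(S = 30, P = 20, lam = 0.05, seed = 13)
  tr <- simulate_metacommunity(p, make_initial_state(p, level = 5),
                               sim_config(T_total = 400), seed = 3)
  eps_grid <- c(1e-3, 1e-2, 1e-1, 1)
  counts <- vapply(eps_grid,
                   function(e) survivor_summary(tr, p, eps = e)$S_surv,
                   integer(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("the random-community pipeline is a pure function of its seeds", {
  run <- function() {
    p <- p_random(S = 15, P = 10, lam = 0.02, seed = 5)
    tr <- simulate_metacommunity(p, make_initial_state(p, level = 5),
                                 sim_config(T_total = 200), seed = 17)
    survivor_summary(tr, p)
  }
  a <- run(); b <- run()
  expect_identical(a$surviving_ids, b$surviving_ids)
  expect_identical(a$interactions$I, b$interactions$I)
})

test_that("effective uniform community reproduces the original tipping scan", {
  # a uniform community mapped through the survivor pathway must return the
  # tipping point of its own bifurcation scan
  p <- p_uniform(S = 60, P = 5, lam = 1e-3, alpha = 0.005)
  tr <- simulate_metacommunity(
    p, make_initial_state(p, "near_fixed_point"),
    sim_config(dt = 0.1, T_total = 1, scheme = "deterministic"), seed = 1)
  pu <- mc_params(p$growth,
                  interaction_spec("random_symmetric", alpha_hat = 0.005,
                                   sigma = 0, seed = 1),
                  p$disp)
  s <- survivor_summary(tr, pu)
  expect_equal(s$S_surv, 60L)
  grid <- 10^seq(-4, -1, length.out = 13)
  eff <- effective_tipping_point(s, p$growth, lam_operating = 1e-3,
                                 lam_grid = grid)
  direct <- bifurcation_scan(p, lam_grid = grid)
  lam_t_direct <- if (direct$lam_t_flag == "no_subcritical_window")
    direct$lam_c else direct$lam_t
  expect_equal(eff$lam_t_star, lam_t_direct, tolerance = 1e-6)
})
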