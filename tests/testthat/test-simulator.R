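test_that("the all-zero state is absorbing under any seed", {
  p <- p_uniform(S = 4, P = 6, lam = 0.1)
  zero <- make_initial_state(p, level = 0)
  for (seed in c(1, 77)) {
    tr <- simulate_metacommunity(p, zero, sim_config(T_total = 20), seed = seed)
    expect_true(tr$extinct)
    expect_equal(max(abs(tr$final_state)), 0)
    expect_equal(utils::tail(tr$series$mean_abundance, 1), 0)
  }
  st <- with_seed(3, step_metacommunity(zero, p))
  expect_equal(max(abs(st)), 0)
})

test_that("one-step Poisson noise matches the demographic-noise moments", {
  # r = 0, lam = 0: the Euler mean is the current state, so the one-step
  # conditional distribution is dt * Pois(N / dt): mean N, variance dt * N
  dt <- 0.1
  for (N0 in c(1, 10, 100)) {
    p <- p_uniform(S = 100, P = 100, lam = 0, alpha = 0, r = 0)
    st <- make_initial_state(p, level = N0)
    out <- with_seed(42 + N0,
                     step_metacommunity(st, p, sim_config(dt = dt, T_total = 1)))
    x <- as.vector(out)
    n <- length(x)
    se_mean <- sqrt(dt * N0 / n)
    expect_lt(abs(mean(x) - N0), 3 * se_mean)
    se_var <- dt * N0 * sqrt(2 / (n - 1))
    expect_lt(abs(stats::var(x) - dt * N0), 3 * se_var)
  }
})

test_that("the deterministic scheme reproduces Euler forward exactly", {
  p <- p_random(S = 6, P = 5, lam = 0.05, seed = 8)
  st <- rand_state(5, 6, seed = 4)
  sim <- sim_config(dt = 0.1, T_total = 1, scheme = "deterministic",
                    record_every = 0.1)
  tr <- simulate_metacommunity(p, st, sim, seed = 1)
  N <- unclass(st)
  for (k in 1:10) {
    N <- pmax(N + 0.1 * deterministic_rhs(mc_state(N), p), 0)
  }
  expect_equal(unclass(tr$final_state), N, tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("trajectories are bit-identical for identical seeds", {
  p <- p_uniform(S = 10, P = 10, lam = 0.01)
  st <- make_initial_state(p, level = 2)
  sim <- sim_config(T_total = 50)
  a <- simulate_metacommunity(p, st, sim, seed = 123)
  b <- simulate_metacommunity(p, st, sim, seed = 123)
  expect_identical(a$series, b$series)
  expect_identical(unclass(a$final_state), unclass(b$final_state))
  c2 <- simulate_metacommunity(p, st, sim, seed = 124)
  expect_false(identical(a$series$mean_abundance, c2$series$mean_abundance))
})

test_that("an isolated small population goes extinct without dispersal", {
  p <- p_uniform(S = 1, P = 10, lam = 0, alpha = 0)
  st <- make_initial_state(p, level = 0.5)
  tr <- simulate_metacommunity(p, st, sim_config(T_total = 3000), seed = 5)
  expect_true(tr$extinct)
})

test_that("initial-state constructors hit their requested means", {
  p <- p_uniform(S = 100, P = 10, alpha = 0.005)
  low <- make_initial_state(p, "uniform_low", level = 0.1)
  expect_equal(patch_species_means(low)$grand_mean, 0.1)
  star <- make_initial_state(p, "near_fixed_point")
  expect_equal(unique(as.vector(star)), 10 / (1 - 0.005 * 99))
  M <- matrix(2, 10, 100)
  expect_equal(unclass(make_initial_state(p, "custom", N = M)), M,
               ignore_attr = TRUE)
})

test_that("unit-Poisson scheme requires unit time steps and runs", {
  expect_error(sim_config(dt = 0.1, scheme = "unit_poisson"), "dt = 1")
  p <- p_uniform(S = 2, P = 5, lam = 0.05)
  st <- make_initial_state(p, level = 5)
  tr <- simulate_metacommunity(
    p, st, sim_config(dt = 1, T_total = 20, scheme = "unit_poisson"),
    seed = 9)
  expect_true(all(tr$series$mean_abundance >= 0))
  # integer abundances under the unit scheme
  expect_true(all(unclass(tr$final_state) == round(unclass(tr$final_state))))
})

test_that("steady-state means stay bounded by the deterministic capacity", {
  p <- p_uniform(S = 20, P = 30, lam = 0.1, alpha = 0.005)
  st <- make_initial_state(p, "near_fixed_point")
  tr <- simulate_metacommunity(p, st, sim_config(T_total = 400), seed = 21)
  nstar <- deterministic_fixed_point(p)
  expect_false(tr$extinct)
  expect_lt(steady_mean(tr), nstar * 1.05)
  expect_gt(steady_mean(tr), 0)
})
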