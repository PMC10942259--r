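# Reproducible experiment drivers: bistability scans over dispersal rates,
# hysteresis loops under slow dispersal cycling, and stepwise species
# removal. Each driver derives all replicate seeds from a single base seed
# and echoes its configuration, so results are pure functions of
# (parameters, seeds).

derive_seeds <- function(base_seed, n) {
  with_seed(base_seed, sample.int(.Machine$integer.max - 1L, n))
}

survived <- function(traj, threshold) {
  !traj$extinct && steady_mean(traj) > threshold
}

#' Bistability scan over dispersal rates
#'
#' For each dispersal rate, runs replicate simulations from a small initial
#' abundance (`level_low` per population) and from the deterministic fixed
#' point `N*`, and records the outcome. In the bistable window the
#' high-start runs persist while the low-start runs go extinct; the
#' empirical boundaries bracket `[lambda_t, lambda_c]`.
#'
#' @param params An [mc_params()] object (its `lam` is replaced by the grid
#'   values).
#' @param lam_grid Dispersal rates to scan.
#' @param replicates Replicates per (rate, start).
#' @param base_seed Seed from which all run seeds are derived.
#' @param sim An [sim_config()] object.
#' @param level_low Small initial abundance per population.
#' @param level_high Initial abundance for the high start; default the
#'   deterministic fixed point.
#' @return A tibble (`lambda`, `init`, `replicate`, `seed`, `final_mean`,
#'   `steady_mean`, `extinct`) with attribute `estimates`: empirical
#'   `lam_t` (smallest rate where high starts mostly survive) and `lam_c`
#'   (smallest rate where low starts mostly survive).
#' @export
bistability_experiment <- function(params, lam_grid, replicates = 5,
                                   base_seed = 1L, sim = sim_config(),
                                   level_low = 0.1, level_high = NULL) {
  stopifnot(inherits(params, "mc_params"))
  lam_grid <- sort(lam_grid)
  if (is.null(level_high)) level_high <- deterministic_fixed_point(params)
  grid <- tidyr::expand_grid(lambda = lam_grid, init = c("low", "high"),
                             replicate = seq_len(replicates))
  grid$seed <- derive_seeds(base_seed, nrow(grid))

  run1 <- function(lambda, init, seed) {
    params$disp$lam <- lambda
    lvl <- if (init == "low") level_low else level_high
    st <- make_initial_state(params, "uniform_low", level = lvl)
    tr <- simulate_metacommunity(params, st, sim, seed = seed)
    tibble::tibble(final_mean = mean(tr$final_state),
                   steady_mean = steady_mean(tr), extinct = tr$extinct)
  }
  out <- dplyr::bind_cols(
    grid,
    purrr::pmap_dfr(grid[c("lambda", "init", "seed")],
                    function(lambda, init, seed) run1(lambda, init, seed))
  )

  majority_survive <- function(sub) mean(!sub$extinct) > 0.5
  emp_boundary <- function(which_init) {
    ok <- vapply(lam_grid, function(l) {
      majority_survive(out[out$lambda == l & out$init == which_init, ])
    }, logical(1))
    if (any(ok)) lam_grid[which(ok)[1]] else NA_real_
  }
  attr(out, "estimates") <- list(lam_t_emp = emp_boundary("high"),
                                 lam_c_emp = emp_boundary("low"))
  attr(out, "config") <- list(params = as_config(params), base_seed = base_seed,
                              replicates = replicates, sim = unclass(sim),
                              level_low = level_low, level_high = level_high)
  out
}

#' Hysteresis loop under dispersal cycling
#'
#' Steps the dispersal rate up through `lam_seq` and back down, carrying the
#' state across steps and dwelling `dwell` generations at each rate. The
#' upward pass starts from a small population; whenever the carried state is
#' completely extinct at the start of a dwell, a small colonization attempt
#' (`reseed_level` per population) is planted, so each rate is probed for
#' invasibility from rare. A hysteresis loop is an intermediate rate where
#' the downward pass (carrying a large population) survives while the
#' upward pass (from rare) dies: the signature of the bistable window. For
#' a single non-interacting species the passes coincide.
#'
#' @param params An [mc_params()] object.
#' @param lam_seq Increasing dispersal rates for the upward pass (the
#'   downward pass reverses it).
#' @param dwell Generations per step.
#' @param sim An [sim_config()] object (`T_total` is ignored).
#' @param seed Base seed.
#' @param reseed_level Abundance per population for colonization attempts.
#' @param alive_threshold Steady mean above which a dwell counts as
#'   surviving (default `5 * reseed_level`).
#' @return A tibble (`pass`, `lambda`, `steady_mean`, `extinct`,
#'   `survived`) with attributes `loop` (logical) and `loop_lambdas`.
#' @export
hysteresis_experiment <- function(params, lam_seq, dwell = 1500,
                                  sim = sim_config(), seed = 1L,
                                  reseed_level = 0.1,
                                  alive_threshold = 5 * reseed_level) {
  stopifnot(inherits(params, "mc_params"))
  lam_seq <- sort(lam_seq)
  plan <- tibble::tibble(
    pass = rep(c("up", "down"), c(length(lam_seq), length(lam_seq))),
    lambda = c(lam_seq, rev(lam_seq))
  )
  seeds <- derive_seeds(seed, nrow(plan))
  dwell_sim <- sim_config(dt = sim$dt, T_total = dwell, scheme = sim$scheme,
                          record_every = sim$record_every)

  state <- make_initial_state(params, "uniform_low", level = reseed_level)
  rows <- vector("list", nrow(plan))
  for (k in seq_len(nrow(plan))) {
    params$disp$lam <- plan$lambda[k]
    if (all(state == 0)) {
      state <- make_initial_state(params, "uniform_low", level = reseed_level)
    }
    tr <- simulate_metacommunity(params, state, dwell_sim, seed = seeds[k])
    state <- tr$final_state
    rows[[k]] <- tibble::tibble(
      pass = plan$pass[k], lambda = plan$lambda[k],
      steady_mean = steady_mean(tr), extinct = tr$extinct,
      survived = survived(tr, alive_threshold)
    )
  }
  out <- dplyr::bind_rows(rows)
  up <- out[out$pass == "up", ]; down <- out[out$pass == "down", ]
  loop_l <- lam_seq[vapply(lam_seq, function(l) {
    down$survived[down$lambda == l] && !up$survived[up$lambda == l]
  }, logical(1))]
  attr(out, "loop") <- length(loop_l) > 0
  attr(out, "loop_lambdas") <- loop_l
  attr(out, "config") <- list(params = as_config(params), dwell = dwell,
                              seed = seed, reseed_level = reseed_level,
                              alive_threshold = alive_threshold)
  out
}

#' Stepwise species removal
#'
#' Starts the full community at its deterministic fixed point, equilibrates,
#' then removes species one group at a time (re-equilibrating after each
#' removal, carrying the surviving populations over). Below the critical
#' dispersal rate the community eventually collapses once too few mutualists
#' remain: the collapse size `S_star` is the largest remaining species count
#' at which the metacommunity goes extinct. The mean-field counterpart
#' (`S_star_mf`) is the largest `S` in the sequence without a stable
#' positive self-consistency root at this dispersal rate.
#'
#' @param params An [mc_params()] object (uniform interactions); its `S`
#'   must equal `max(S_sequence)`.
#' @param S_sequence Decreasing species counts to step through.
#' @param dwell Re-equilibration time after each removal (generations).
#' @param sim An [sim_config()] object (`T_total` is ignored).
#' @param seed Base seed.
#' @return A tibble (`S`, `steady_mean`, `extinct`) with attributes
#'   `S_star` (simulation) and `S_star_mf` (mean-field; `NA` if the
#'   mean-field branch survives throughout).
#' @export
species_removal_experiment <- function(params, S_sequence, dwell = 2000,
                                       sim = sim_config(), seed = 1L) {
  stopifnot(inherits(params, "mc_params"))
  S_sequence <- sort(unique(as.integer(S_sequence)), decreasing = TRUE)
  g <- params$growth
  stopifnot(g$S == S_sequence[1])
  seeds <- derive_seeds(seed, length(S_sequence))
  dwell_sim <- sim_config(dt = sim$dt, T_total = dwell, scheme = sim$scheme,
                          record_every = sim$record_every)

  at_S <- function(S) {
    mc_params(growth_params(r = unique(g$r), K = g$K, S = S, P = g$P),
              params$inter, params$disp)
  }
  state <- make_initial_state(params, "near_fixed_point")
  rows <- vector("list", length(S_sequence))
  for (k in seq_along(S_sequence)) {
    S <- S_sequence[k]
    pk <- at_S(S)
    state <- mc_state(unclass(state)[, seq_len(S), drop = FALSE],
                      t = attr(state, "t"))
    tr <- simulate_metacommunity(pk, state, dwell_sim, seed = seeds[k])
    state <- tr$final_state
    rows[[k]] <- tibble::tibble(S = S, steady_mean = steady_mean(tr),
                                extinct = tr$extinct)
  }
  out <- dplyr::bind_rows(rows)
  S_star <- if (any(out$extinct)) max(out$S[out$extinct]) else NA_integer_

  mf_alive <- vapply(S_sequence, function(S) {
    rt <- self_consistent_roots(at_S(S))
    any(rt$stable & rt$type == "positive")
  }, logical(1))
  S_star_mf <- if (any(!mf_alive)) max(S_sequence[!mf_alive]) else NA_integer_

  attr(out, "S_star") <- S_star
  attr(out, "S_star_mf") <- S_star_mf
  attr(out, "config") <- list(params = as_config(params), dwell = dwell,
                              seed = seed, S_sequence = S_sequence)
  out
}
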