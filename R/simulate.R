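#' Simulation settings
#'
#' @param dt Time step in generations, `> 0`.
#' @param T_total Total simulated time in generations, `>= dt`.
#' @param scheme Noise discretization. `"scaled_poisson"` (default): the
#'   updated abundance is `dt * Poisson(M / dt)` around the Euler mean `M`,
#'   which has conditional mean `M` and conditional variance `dt * M` for
#'   any `dt`, matching the demographic-noise variance rate `N` per unit
#'   time. `"unit_poisson"`: literal Poisson draw of the Euler mean,
#'   requires `dt = 1`. `"deterministic"`: noise off (Euler forward).
#' @param record_every Recording interval in generations.
#' @return An object of class `mc_sim_config`.
#' @export
sim_config <- function(dt = 0.1, T_total = 1e4,
                       scheme = c("scaled_poisson", "unit_poisson", "deterministic"),
                       record_every = max(dt, 1)) {
  scheme <- match.arg(scheme)
  stopifnot(dt > 0, T_total >= dt, record_every >= dt)
  if (scheme == "unit_poisson" && dt != 1) {
    stop("unit_poisson requires dt = 1")
  }
  structure(list(dt = dt, T_total = T_total, scheme = scheme,
                 record_every = record_every),
            class = "mc_sim_config")
}

scheme_code <- function(scheme) {
  match(scheme, c("scaled_poisson", "unit_poisson", "deterministic")) - 1L
}

#' One stochastic update step
#'
#' Euler-forward drift clipped at zero, followed by the Poisson noise draw.
#' Zero abundance is absorbing per population. Uses the current R RNG
#' stream.
#'
#' @param state An `mc_state`.
#' @param params An [mc_params()] object.
#' @param sim An [sim_config()] object (only `dt` and `scheme` are used).
#' @return The state at `t + dt`.
#' @export
step_metacommunity <- function(state, params, sim = sim_config()) {
  M <- pmax(unclass(state) + sim$dt * deterministic_rhs(state, params), 0)
  if (any(!is.finite(M))) {
    stop("non-finite abundances during stepping; reduce dt")
  }
  Np <- switch(sim$scheme,
    scaled_poisson = sim$dt * stats::rpois(length(M), M / sim$dt),
    unit_poisson = stats::rpois(length(M), M),
    deterministic = M
  )
  mc_state(matrix(Np, nrow(M), ncol(M)), t = (attr(state, "t") %||% 0) + sim$dt)
}

#' Run the stochastic metacommunity simulation
#'
#' Iterates the Poisson update scheme to time `T_total`, recording the grand
#' mean abundance, and stops early once every population is extinct (the
#' all-zero state is absorbing). Identical `(params, init, sim, seed)` give
#' bit-identical trajectories.
#'
#' @param params An [mc_params()] object.
#' @param init An `mc_state` (see [make_initial_state()]).
#' @param sim An [sim_config()] object.
#' @param seed Integer seed for the run.
#' @return An object of class `mc_trajectory` with components `series`
#'   (tibble: `time`, `mean_abundance`), `species_means` (at final time),
#'   `final_state`, `extinct`, and echoes of the inputs.
#' @examples
#' p <- mc_params(growth_params(S = 1, P = 50),
#'                disp = dispersal_spec(lam = 0.1))
#' tr <- simulate_metacommunity(p, make_initial_state(p, level = 1),
#'                              sim_config(T_total = 100), seed = 1)
#' glance(tr)
#' @export
simulate_metacommunity <- function(params, init, sim = sim_config(), seed = 1L) {
  stopifnot(inherits(params, "mc_params"), inherits(sim, "mc_sim_config"))
  init <- mc_state(as.matrix(init), attr(init, "t") %||% 0)
  g <- params$growth
  stopifnot(nrow(init) == g$P, ncol(init) == g$S)
  r <- if (length(g$r) == 1L) rep(g$r, g$S) else g$r
  A <- if (params$inter$mode == "uniform") matrix(0, 1, 1) else
    interaction_matrix(params)
  steps <- round(sim$T_total / sim$dt)
  rec <- max(1L, round(sim$record_every / sim$dt))

  res <- with_seed(seed, sim_core(
    unclass(init), r, g$K,
    inter_mode = if (params$inter$mode == "uniform") 0L else 1L,
    alpha = params$inter$alpha %||% 0, A = A,
    lam = params$disp$lam, beta = params$disp$beta,
    dt = sim$dt, steps = steps, record_every = rec,
    scheme = scheme_code(sim$scheme), pinned_m = -1,
    t0 = attr(init, "t")
  ))

  structure(list(
    series = tibble::tibble(time = res$times, mean_abundance = res$mean_series),
    species_means = res$species_means,
    final_state = mc_state(res$final_state, t = res$t_end),
    extinct = res$extinct,
    params = params, sim = sim, seed = seed
  ), class = "mc_trajectory")
}

#' Sample a single population with the mean field pinned
#'
#' Simulates one population whose dispersal term is held at
#' `lam * (m - N)` for a fixed mean field `m` (self-consistency bypassed),
#' using the same Poisson update scheme as the full simulator, and returns
#' abundances sampled at regular intervals after a burn-in. This is the
#' direct stochastic counterpart of [stationary_density()]: the histogram
#' of the samples converges to the analytic stationary distribution.
#'
#' @param params An [mc_params()] object with uniform interactions (sets
#'   `r`, `K`, `alpha`, `S`, `lam`; the effective growth rate is
#'   `rg = r (1 + alpha (S-1) m / K)`).
#' @param m Pinned mean field.
#' @param n_samples Number of samples to return.
#' @param sim An [sim_config()] object (`dt`, `scheme`).
#' @param burn Burn-in time (generations).
#' @param sample_every Sampling interval (generations).
#' @param seed RNG seed.
#' @param init Initial abundance (default `m`).
#' @return Numeric vector of sampled abundances (multiples of `dt` under
#'   the scaled Poisson scheme).
#' @export
sample_pinned_population <- function(params, m, n_samples = 1e5,
                                     sim = sim_config(), burn = 200,
                                     sample_every = 1, seed = 1L,
                                     init = m) {
  stopifnot(inherits(params, "mc_params"), m >= 0)
  cf <- mf_coefs(params, m)
  with_seed(seed, sim_pinned_samples(
    n0 = init, rg = cf$rg, r_over_K = cf$b, lam = cf$lam_eff, m = m,
    dt = sim$dt, burn = round(burn / sim$dt), n_samples = as.integer(n_samples),
    sample_every = max(1L, round(sample_every / sim$dt)),
    scheme = scheme_code(sim$scheme)
  ))
}

#' @export
print.mc_trajectory <- function(x, ...) {
  cat(sprintf("<mc_trajectory> t in [%g, %g], %s, final <N> = %.4g\n",
              x$series$time[1], max(x$series$time),
              if (x$extinct) "extinct" else "surviving",
              mean(x$final_state)))
  invisible(x)
}

#' Tidy a simulated trajectory
#'
#' @param x An `mc_trajectory`.
#' @param ... Unused.
#' @return The recorded time series as a tibble (`time`, `mean_abundance`).
#' @export
tidy.mc_trajectory <- function(x, ...) x$series

#' One-row summary of a trajectory
#'
#' `steady_mean` is the time average of the grand mean over the final 20%
#' of the recorded series, the package's steady-state read-out.
#'
#' @param x An `mc_trajectory`.
#' @param ... Unused.
#' @return A one-row tibble.
#' @export
glance.mc_trajectory <- function(x, ...) {
  tibble::tibble(
    t_end = max(x$series$time),
    extinct = x$extinct,
    final_mean = mean(x$final_state),
    steady_mean = steady_mean(x),
    n_surviving = sum(x$species_means > 0),
    seed = x$seed
  )
}

#' Steady-state read-out of a trajectory
#'
#' Time average of the recorded grand mean over the final `frac` of the run.
#'
#' @param traj An `mc_trajectory`.
#' @param frac Fraction of the series to average over (from the end).
#' @return A scalar mean abundance.
#' @export
steady_mean <- function(traj, frac = 0.2) {
  s <- traj$series
  n <- nrow(s)
  mean(s$mean_abundance[s$time >= s$time[n] - frac * (s$time[n] - s$time[1])])
}

#' @importFrom ggplot2 autoplot
#' @export
autoplot.mc_trajectory <- function(object, ...) {
  ggplot2::ggplot(object$series,
                  ggplot2::aes(x = .data$time, y = .data$mean_abundance)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (generations)", y = "mean abundance <N>")
}

#' Export a trajectory
#'
#' Writes `<prefix>_series.csv` (columns `time`, `mean_abundance`),
#' `<prefix>_final_state.csv` (the `P x S` abundance table) and
#' `<prefix>_summary.json` (parameter echo, seed, extinction flag, final
#' species means).
#'
#' @param traj An `mc_trajectory`.
#' @param prefix Output path prefix.
#' @return Invisibly, the paths written.
#' @export
write_trajectory <- function(traj, prefix) {
  paths <- paste0(prefix, c("_series.csv", "_final_state.csv", "_summary.json"))
  utils::write.csv(traj$series, paths[1], row.names = FALSE)
  utils::write.csv(as.data.frame(unclass(traj$final_state)), paths[2],
                   row.names = FALSE)
  jsonlite::write_json(list(
    params = as_config(traj$params),
    sim = unclass(traj$sim), seed = traj$seed, extinct = traj$extinct,
    t_end = max(traj$series$time), species_means = traj$species_means
  ), paths[3], auto_unbox = TRUE, digits = NA, null = "null")
  invisible(paths)
}
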