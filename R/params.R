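#' Growth and community-size parameters
#'
#' Bundles the per-capita growth rate `r`, the local carrying capacity `K`,
#' the number of species `S` and the number of patches `P` of the
#' metacommunity. `r` may be a single rate shared by all species (the usual
#' case) or a length-`S` vector of species-specific rates.
#'
#' @param r Per-capita growth rate(s), per generation; all entries `> 0`.
#' @param K Carrying capacity of a local population (individuals), `> 0`.
#' @param S Number of species, integer `>= 1`.
#' @param P Number of patches, integer `>= 1`.
#' @return An object of class `mc_growth`.
#' @examples
#' growth_params(r = 0.3, K = 10, S = 100, P = 500)
#' @export
growth_params <- function(r = 0.3, K = 10, S = 1, P = 1) {
  # r = 0 is admitted as the degenerate immigration-death limit used by
  # closed-form checks of the stationary density
  stopifnot(is.numeric(r), all(r >= 0), length(r) %in% c(1L, as.integer(S)))
  stopifnot(is.numeric(K), length(K) == 1L, K > 0)
  S <- as.integer(S); P <- as.integer(P)
  stopifnot(S >= 1L, P >= 1L)
  structure(list(r = r, K = K, S = S, P = P), class = "mc_growth")
}

#' Interaction structure between species
#'
#' Either a uniform mutualistic coupling `alpha` between every ordered pair
#' of distinct species, or a random symmetric coefficient matrix with
#' pairwise values drawn from a Gaussian with mean `alpha_hat` and standard
#' deviation `sigma / S` (materialized once `S` is known, see
#' [mc_params()]). The diagonal is always zero: self-limitation is carried
#' by the `-N/K` term of the growth law.
#'
#' @param mode `"uniform"` or `"random_symmetric"`.
#' @param alpha Uniform interaction strength (dimensionless); positive for
#'   mutualism, negative for direct competition. Used when
#'   `mode = "uniform"`.
#' @param alpha_hat Mean interaction coefficient for the random mode.
#' @param sigma Spread parameter; the pairwise standard deviation is
#'   `sigma / sqrt(S)` (see [sample_interactions()]).
#' @param seed RNG seed used to sample the random matrix.
#' @return An object of class `mc_interaction`.
#' @examples
#' interaction_spec("uniform", alpha = 0.005)
#' interaction_spec("random_symmetric", alpha_hat = -0.01, sigma = 0.5, seed = 1)
#' @export
interaction_spec <- function(mode = c("uniform", "random_symmetric"),
                             alpha = 0, alpha_hat = NULL, sigma = NULL,
                             seed = NULL) {
  mode <- match.arg(mode)
  if (mode == "uniform") {
    stopifnot(is.numeric(alpha), length(alpha) == 1L, is.finite(alpha))
  } else {
    stopifnot(is.numeric(alpha_hat), length(alpha_hat) == 1L,
              is.numeric(sigma), length(sigma) == 1L, sigma >= 0,
              !is.null(seed))
  }
  structure(list(mode = mode, alpha = alpha, alpha_hat = alpha_hat,
                 sigma = sigma, seed = seed, matrix = NULL),
            class = "mc_interaction")
}

#' Dispersal parameters
#'
#' Global (all-to-all) dispersal at baseline rate `lam`. With `beta = 0`
#' each population exchanges migrants at the constant per-capita rate `lam`,
#' giving the dispersal term `lam * (Nbar_i - N_xi)`. With `beta > 0`
#' emigration increases linearly with the local abundance of *other*
#' species, modelling crowding-driven dispersal.
#'
#' @param lam Baseline dispersal rate, per generation, `>= 0`.
#' @param beta Density-dependence coefficient, per individual, `>= 0`.
#' @return An object of class `mc_dispersal`.
#' @examples
#' dispersal_spec(lam = 1e-3)
#' dispersal_spec(lam = 1e-3, beta = 0.02)
#' @export
dispersal_spec <- function(lam = 0, beta = 0) {
  stopifnot(is.numeric(lam), length(lam) == 1L, lam >= 0,
            is.numeric(beta), length(beta) == 1L, beta >= 0)
  structure(list(lam = lam, beta = beta), class = "mc_dispersal")
}

#' Bundle model parameters
#'
#' Combines growth, interaction and dispersal parameters into a single
#' model-parameter object. For `mode = "random_symmetric"` the symmetric
#' interaction matrix is sampled here (seeded) via [sample_interactions()].
#' For a uniform positive coupling, `alpha * (S - 1) < 1` is enforced so
#' that population sizes do not diverge.
#'
#' @param growth A [growth_params()] object.
#' @param inter An [interaction_spec()] object (default: no interactions).
#' @param disp A [dispersal_spec()] object (default: no dispersal).
#' @return An object of class `mc_params`.
#' @examples
#' mc_params(growth_params(S = 100, P = 500),
#'           interaction_spec(alpha = 0.005),
#'           dispersal_spec(lam = 1e-3))
#' @export
mc_params <- function(growth, inter = interaction_spec(), disp = dispersal_spec()) {
  stopifnot(inherits(growth, "mc_growth"), inherits(inter, "mc_interaction"),
            inherits(disp, "mc_dispersal"))
  if (inter$mode == "uniform" && inter$alpha > 0 &&
      inter$alpha * (growth$S - 1) >= 1) {
    stop("alpha * (S - 1) must be < 1: population sizes would diverge")
  }
  if (inter$mode == "random_symmetric" && is.null(inter$matrix)) {
    inter$matrix <- sample_interactions(growth$S, inter$alpha_hat,
                                        inter$sigma, inter$seed)
  }
  structure(list(growth = growth, inter = inter, disp = disp),
            class = "mc_params")
}

#' @export
print.mc_params <- function(x, ...) {
  g <- x$growth
  cat(sprintf("<mc_params> S = %d species, P = %d patches\n", g$S, g$P))
  cat(sprintf("  growth: r = %s, K = %g\n",
              paste(signif(unique(g$r), 4), collapse = "/"), g$K))
  if (x$inter$mode == "uniform") {
    cat(sprintf("  interactions: uniform alpha = %g\n", x$inter$alpha))
  } else {
    cat(sprintf("  interactions: random symmetric, alpha_hat = %g, sigma = %g, seed = %s\n",
                x$inter$alpha_hat, x$inter$sigma, format(x$inter$seed)))
  }
  cat(sprintf("  dispersal: lam = %g, beta = %g\n", x$disp$lam, x$disp$beta))
  invisible(x)
}

#' Interaction matrix of a parameter set
#'
#' The `S x S` symmetric coefficient matrix with zero diagonal. For the
#' uniform mode every off-diagonal entry equals `alpha`.
#'
#' @param params An [mc_params()] object.
#' @return A numeric `S x S` matrix.
#' @export
interaction_matrix <- function(params) {
  stopifnot(inherits(params, "mc_params"))
  S <- params$growth$S
  if (params$inter$mode == "uniform") {
    A <- matrix(params$inter$alpha, S, S)
    diag(A) <- 0
    A
  } else {
    params$inter$matrix
  }
}

#' Flat configuration serialization
#'
#' `as_config()` flattens a parameter set into a named list with keys
#' `r, K, S, P, mode, alpha, alpha_hat, sigma, lam, beta, seed`;
#' `mc_params_from_config()` rebuilds the parameter object (re-sampling the
#' random interaction matrix from its seed, so the round trip is exact).
#'
#' @param params An [mc_params()] object.
#' @return `as_config()`: a named list; `mc_params_from_config()`: an
#'   [mc_params()] object.
#' @export
as_config <- function(params) {
  stopifnot(inherits(params, "mc_params"))
  g <- params$growth; i <- params$inter; d <- params$disp
  list(r = g$r, K = g$K, S = g$S, P = g$P, mode = i$mode,
       alpha = i$alpha, alpha_hat = i$alpha_hat, sigma = i$sigma,
       lam = d$lam, beta = d$beta, seed = i$seed)
}

#' @param config A named list (or flat YAML contents) with the keys written
#'   by `as_config()`; missing keys fall back to defaults.
#' @rdname as_config
#' @export
mc_params_from_config <- function(config) {
  get0 <- function(k, default = NULL) {
    if (!is.null(config[[k]])) config[[k]] else default
  }
  mode <- get0("mode", "uniform")
  inter <- if (mode == "uniform") {
    interaction_spec("uniform", alpha = get0("alpha", 0))
  } else {
    interaction_spec("random_symmetric", alpha_hat = get0("alpha_hat"),
                     sigma = get0("sigma"), seed = get0("seed"))
  }
  mc_params(
    growth_params(r = get0("r", 0.3), K = get0("K", 10),
                  S = get0("S", 1), P = get0("P", 1)),
    inter,
    dispersal_spec(lam = get0("lam", 0), beta = get0("beta", 0))
  )
}

# internal: run code with the global RNG seeded, restoring the prior state
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}
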