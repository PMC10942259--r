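#' Metacommunity state
#'
#' A state is the `P x S` matrix of nonnegative abundances `N[x, i]` of
#' species `i` on patch `x`, plus the elapsed time in generations.
#' `mc_state()` wraps and validates a plain matrix; [make_initial_state()]
#' builds the standard initial conditions.
#'
#' @param N Numeric `P x S` matrix, all entries `>= 0`.
#' @param t Elapsed time (generations).
#' @return An object of class `mc_state` (a matrix with a `t` attribute).
#' @export
mc_state <- function(N, t = 0) {
  stopifnot(is.matrix(N), is.numeric(N))
  if (any(!is.finite(N)) || any(N < 0)) {
    stop("invalid state: abundances must be finite and nonnegative")
  }
  structure(N, t = t, class = c("mc_state", class(matrix())))
}

#' @export
print.mc_state <- function(x, ...) {
  cat(sprintf("<mc_state> %d patches x %d species, t = %g, <N> = %.4g\n",
              nrow(x), ncol(x), attr(x, "t"), mean(x)))
  invisible(x)
}

#' Tidy a metacommunity state
#'
#' One row per (patch, species) population.
#'
#' @param x An `mc_state`.
#' @param ... Unused.
#' @return A tibble with columns `patch`, `species`, `abundance`.
#' @export
tidy.mc_state <- function(x, ...) {
  tibble::tibble(
    patch = rep(seq_len(nrow(x)), times = ncol(x)),
    species = rep(seq_len(ncol(x)), each = nrow(x)),
    abundance = as.vector(unclass(x))
  )
}

#' Standard initial conditions
#'
#' @param params An [mc_params()] object (fixes `P` and `S`).
#' @param mode `"uniform_low"`: every population at `level`;
#'   `"near_fixed_point"`: every population at the deterministic fixed point
#'   `N*` (uniform interactions only); `"custom"`: pass the matrix `N`.
#' @param level Abundance per population for `"uniform_low"`.
#' @param N Custom `P x S` matrix for `"custom"`.
#' @return An `mc_state` at `t = 0`.
#' @examples
#' p <- mc_params(growth_params(S = 100, P = 20), interaction_spec(alpha = 0.005))
#' make_initial_state(p, "uniform_low", level = 0.1)
#' make_initial_state(p, "near_fixed_point")
#' @export
make_initial_state <- function(params,
                               mode = c("uniform_low", "near_fixed_point", "custom"),
                               level = 0.1, N = NULL) {
  stopifnot(inherits(params, "mc_params"))
  mode <- match.arg(mode)
  g <- params$growth
  if (mode == "uniform_low") {
    stopifnot(is.numeric(level), length(level) == 1L)
    if (level < 0) stop("level must be >= 0")
    mc_state(matrix(level, g$P, g$S))
  } else if (mode == "near_fixed_point") {
    mc_state(matrix(deterministic_fixed_point(params), g$P, g$S))
  } else {
    stopifnot(is.matrix(N), nrow(N) == g$P, ncol(N) == g$S)
    mc_state(N)
  }
}

#' Deterministic positive fixed point
#'
#' For uniform interactions the deterministic per-patch dynamics have a
#' single positive fixed point `N* = K / (1 - alpha (S - 1))`, the logistic
#' carrying capacity enhanced by mutualistic coupling. It requires
#' `alpha (S - 1) < 1`.
#'
#' @param params An [mc_params()] object with uniform interactions.
#' @return The abundance `N*`.
#' @examples
#' p <- mc_params(growth_params(K = 10, S = 100), interaction_spec(alpha = 0.005))
#' deterministic_fixed_point(p)  # 19.80198
#' @export
deterministic_fixed_point <- function(params) {
  stopifnot(inherits(params, "mc_params"))
  if (params$inter$mode != "uniform") {
    stop("deterministic_fixed_point() requires uniform interactions")
  }
  g <- params$growth
  denom <- 1 - params$inter$alpha * (g$S - 1)
  if (denom <= 0) {
    stop("alpha * (S - 1) >= 1: population sizes diverge, no fixed point")
  }
  g$K / denom
}

#' Deterministic rates of change
#'
#' The drift of the dynamics: logistic growth with interactions,
#' `r_i N (1 - N/K + sum_{j != i} alpha_ij N_j / K)`, plus global dispersal.
#' With `beta = 0` the dispersal term is `lam (Nbar_i - N_xi)`; with
#' `beta > 0` emigration is density dependent,
#' `lam (mean_y w_yi - w_xi)` with weights
#' `w_xi = (1 + beta sum_{j != i} N_xj) N_xi`. For every species the
#' dispersal contributions sum to exactly zero over patches.
#'
#' This is the reference R implementation; the simulator's compiled core
#' applies the same drift.
#'
#' @param state An `mc_state`.
#' @param params An [mc_params()] object.
#' @return A `P x S` matrix of rates.
#' @export
deterministic_rhs <- function(state, params) {
  stopifnot(inherits(params, "mc_params"))
  N <- unclass(mc_state(as.matrix(state), attr(state, "t") %||% 0))
  attr(N, "t") <- NULL
  g <- params$growth
  r <- if (length(g$r) == 1L) rep(g$r, g$S) else g$r
  tot <- rowSums(N)

  if (params$inter$mode == "uniform") {
    inter <- params$inter$alpha * (tot - N)
  } else {
    inter <- N %*% interaction_matrix(params)
  }
  growth <- sweep(N * (1 - N / g$K + inter / g$K), 2, r, `*`)

  lam <- params$disp$lam; beta <- params$disp$beta
  if (beta == 0) {
    nbar <- colMeans(N)
    disp <- lam * sweep(-N, 2, nbar, `+`)
  } else {
    w <- (1 + beta * (tot - N)) * N
    disp <- lam * sweep(-w, 2, colMeans(w), `+`)
  }
  growth + disp
}

#' Patch and species averages
#'
#' @param state An `mc_state` (or plain abundance matrix).
#' @return A list with `patch_means` (species-averaged abundance per patch),
#'   `species_means` (patch-averaged abundance per species) and
#'   `grand_mean`.
#' @export
patch_species_means <- function(state) {
  N <- unclass(mc_state(as.matrix(state), attr(state, "t") %||% 0))
  list(patch_means = rowMeans(N), species_means = colMeans(N),
       grand_mean = mean(N))
}
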