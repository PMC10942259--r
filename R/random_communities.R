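#' Sample a random symmetric interaction matrix
#'
#' Upper-triangle coefficients (`i < j`) are drawn independently from a
#' Gaussian with mean `alpha_hat` and standard deviation `sigma / sqrt(S)`
#' (the random-matrix scaling that keeps the net interaction felt by one
#' species of order one as `S` grows), then mirrored so that
#' `alpha[j, i] = alpha[i, j]` exactly; the diagonal is zero. With
#' `alpha_hat < 0` the pool is on average competitive while individual
#' pairs can still be mutualistic.
#'
#' @param S Number of species, `>= 2`.
#' @param alpha_hat Mean interaction coefficient.
#' @param sigma Spread parameter; pairwise standard deviation is
#'   `sigma / sqrt(S)`.
#' @param seed RNG seed (the sampler restores the caller's RNG state).
#' @return A symmetric `S x S` matrix with zero diagonal.
#' @examples
#' A <- sample_interactions(100, alpha_hat = -0.01, sigma = 0.5, seed = 1)
#' @export
sample_interactions <- function(S, alpha_hat, sigma, seed) {
  stopifnot(S >= 2, sigma >= 0)
  A <- matrix(0, S, S)
  up <- upper.tri(A)
  A[up] <- with_seed(seed,
                     stats::rnorm(sum(up), mean = alpha_hat,
                                  sd = sigma / sqrt(S)))
  A + t(A)
}

#' Write / read an interaction matrix
#'
#' Tab-delimited `S x S` table preceded by one `#`-prefixed JSON header
#' line carrying `alpha_hat`, `sigma` and `seed`, for fixture reuse.
#'
#' @param A Matrix from [sample_interactions()].
#' @param path File path.
#' @param alpha_hat,sigma,seed Header metadata.
#' @return `write_interaction_matrix()`: the path, invisibly.
#'   `read_interaction_matrix()`: the matrix with attribute `header`.
#' @export
write_interaction_matrix <- function(A, path, alpha_hat = NA, sigma = NA,
                                     seed = NA) {
  header <- jsonlite::toJSON(list(alpha_hat = alpha_hat, sigma = sigma,
                                  seed = seed, S = ncol(A)),
                             auto_unbox = TRUE, digits = NA, null = "null")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", header), con)
  utils::write.table(A, con, sep = "\t", row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_interaction_matrix
#' @export
read_interaction_matrix <- function(path) {
  first <- readLines(path, n = 1)
  header <- jsonlite::fromJSON(sub("^#\\s*", "", first))
  A <- as.matrix(utils::read.table(path, sep = "\t", skip = 1))
  dimnames(A) <- NULL
  attr(A, "header") <- header
  A
}

#' Survivor statistics of a random-interaction run
#'
#' Species surviving a simulation are those whose patch-averaged abundance
#' at the final time exceeds `eps`. For each survivor the mean realized
#' interaction is
#' `I_i = < (alpha[i, j] / K) N[x, j] >` averaged with equal weight over
#' all patches `x` and co-surviving partners `j != i`; below the critical
#' dispersal rate, surviving communities are enriched in mutualism and all
#' `I_i` are positive. `alpha_hat_surv` is the mean coefficient over
#' distinct surviving pairs.
#'
#' @param traj An `mc_trajectory` from [simulate_metacommunity()].
#' @param params The [mc_params()] object used for the run.
#' @param eps Survival threshold on the final patch-mean abundance
#'   (default 0.01).
#' @return An object of class `mc_survivors` with fields `surviving_ids`,
#'   `S_surv`, `alpha_hat_surv`, and tibble `interactions` (`species`,
#'   `I`, `species_mean`).
#' @export
survivor_summary <- function(traj, params, eps = 0.01) {
  stopifnot(inherits(traj, "mc_trajectory"), inherits(params, "mc_params"),
            eps > 0)
  K <- params$growth$K
  nbar <- traj$species_means
  ids <- which(nbar > eps)
  if (length(ids) == 0) {
    return(structure(list(surviving_ids = integer(0), S_surv = 0L,
                          alpha_hat_surv = NA_real_,
                          interactions = tibble::tibble(
                            species = integer(0), I = numeric(0),
                            species_mean = numeric(0)),
                          eps = eps, params = params),
                     class = "mc_survivors"))
  }
  A <- interaction_matrix(params)
  a_surv <- if (length(ids) >= 2) {
    sub <- A[ids, ids, drop = FALSE]
    mean(sub[upper.tri(sub)])
  } else NA_real_
  I <- if (length(ids) >= 2) {
    vapply(ids, function(i) {
      js <- setdiff(ids, i)
      # equal weight per (patch, partner): the patch average enters as Nbar_j
      sum(A[i, js] / K * nbar[js]) / length(js)
    }, numeric(1))
  } else rep(NA_real_, length(ids))
  structure(list(
    surviving_ids = ids, S_surv = length(ids), alpha_hat_surv = a_surv,
    interactions = tibble::tibble(species = ids, I = I,
                                  species_mean = nbar[ids]),
    eps = eps, params = params
  ), class = "mc_survivors")
}

#' @export
print.mc_survivors <- function(x, ...) {
  cat(sprintf("<mc_survivors> S_surv = %d (eps = %g), alpha_hat_surv = %.4g\n",
              x$S_surv, x$eps, x$alpha_hat_surv))
  invisible(x)
}

#' Tidy survivor statistics
#'
#' @param x An `mc_survivors`.
#' @param ... Unused.
#' @return Tibble with one row per survivor (`species`, `I`,
#'   `species_mean`).
#' @export
tidy.mc_survivors <- function(x, ...) x$interactions

#' Tipping point of the effective uniform community
#'
#' Maps a surviving random community onto the analytically tractable
#' uniform community with `S = S_surv` species and coupling
#' `alpha = alpha_hat_surv`, and locates its tipping-point dispersal rate
#' `lambda_t*`. The ratio `lambda_t* / lam_operating` measures how close
#' the assembled community sits to its own tipping point
#' (self-organization towards criticality when it is near 1). When the
#' effective community has no subcritical window (e.g. on-average
#' competitive survivors), the onset is at `lambda_c` and `lambda_t*` is
#' reported as `lambda_c` with the corresponding flag.
#'
#' @param summary An `mc_survivors` from [survivor_summary()].
#' @param growth A [growth_params()] object giving `r` and `K`.
#' @param lam_operating The dispersal rate the community was assembled at.
#' @param lam_grid Grid for the underlying [bifurcation_scan()].
#' @return A list with `lam_t_star`, `proximity`
#'   (`lam_t_star / lam_operating`), `flag`, and the scan.
#' @export
effective_tipping_point <- function(summary, growth, lam_operating,
                                    lam_grid = 10^seq(-4, -1, length.out = 25)) {
  stopifnot(inherits(summary, "mc_survivors"), inherits(growth, "mc_growth"))
  if (summary$S_surv < 2) {
    stop("effective tipping point requires at least two surviving species")
  }
  a <- summary$alpha_hat_surv
  if (a * (summary$S_surv - 1) >= 1) {
    stop("alpha_hat_surv * (S_surv - 1) >= 1: effective community diverges")
  }
  eff <- mc_params(
    growth_params(r = unique(growth$r), K = growth$K, S = summary$S_surv,
                  P = growth$P),
    interaction_spec(alpha = a),
    dispersal_spec(lam = lam_operating)
  )
  scan <- bifurcation_scan(eff, lam_grid = lam_grid)
  lam_t_star <- if (is.na(scan$lam_t) || scan$lam_t_flag == "no_subcritical_window") {
    scan$lam_c
  } else {
    scan$lam_t
  }
  list(lam_t_star = lam_t_star, proximity = lam_t_star / lam_operating,
       flag = scan$lam_t_flag, scan = scan)
}
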