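# Mean-field machinery.
#
# Pinning the patch- and species-averaged abundances at a mean field m
# reduces the metacommunity to a single population with drift
#   f(N) = rg N - (r/K) N^2 + lam (m - N),   rg = r (1 + alpha (S-1) m / K),
# and demographic noise sqrt(N) dW (Ito). The stationary zero-flux solution
# of the corresponding Fokker-Planck equation is
#   P[N]  propto  N^(2 lam m - 1) exp(a N - b N^2),
# with a = 2 (rg - lam), b = r / K. Self-consistency demands that the mean
# of P equals m. All integrals are one-dimensional quadratures with an
# explicit substitution u = N^s near the integrable singularity at N = 0.

# ---- quadrature over weights exp((sp-1) log N + c1 N + c2 N^2 + c3 N^3) ----

# log of int_0^Inf N^(sp-1) exp(c1 N + c2 N^2 + c3 N^3) dN, sp > 0.
# c2 < 0 or (c2 == 0 and c1 < 0) or c3 < 0 required for convergence.
mf_log_weight_integral <- function(sp, coefs, rel.tol = 1e-11) {
  stopifnot(sp > 0)
  c1 <- coefs[1]; c2 <- coefs[2]; c3 <- if (length(coefs) > 2) coefs[3] else 0
  poly <- function(N) c1 * N + c2 * N^2 + c3 * N^3
  li <- function(N) (sp - 1) * log(N) + poly(N)

  cut <- if (c2 < 0) min(1, 1 / (2 * abs(c2))) else 1
  # upper integration scale: double until the integrand has fallen 745 logs
  # below its bulk maximum
  grid <- function(hi) exp(seq(log(cut), log(hi), length.out = 200))
  N_hi <- max(4 * cut, 4)
  shift <- max(li(grid(N_hi)))
  while (li(N_hi) > shift - 745 && N_hi < 1e12) {
    N_hi <- N_hi * 4
    shift <- max(shift, max(li(grid(N_hi))))
  }

  bulk <- stats::integrate(function(N) exp(li(N) - shift), cut, Inf,
                           rel.tol = rel.tol, subdivisions = 400L)$value
  head <- if (sp >= 1) {
    stats::integrate(function(N) exp(li(N) - shift), 0, cut,
                     rel.tol = rel.tol, subdivisions = 400L)$value
  } else {
    # u = N^sp removes the endpoint singularity
    stats::integrate(function(u) exp(poly(u^(1 / sp)) - shift) / sp,
                     0, cut^sp, rel.tol = rel.tol, subdivisions = 400L)$value
  }
  val <- head + bulk
  if (!is.finite(val) || val <= 0) {
    stop("quadrature failed for stationary-density integral (sp = ", sp, ")")
  }
  shift + log(val)
}

# normalization, mean of the stationary density with shape exponent s
mf_moments <- function(s, coefs) {
  logZ0 <- mf_log_weight_integral(s, coefs)
  logZ1 <- mf_log_weight_integral(s + 1, coefs)
  list(logZ0 = logZ0, logZ1 = logZ1, mean = exp(logZ1 - logZ0))
}

# drift coefficients for a parameter set at mean field m (uniform mode);
# density-dependent dispersal replaces lam by lam_eff(m) = lam (1 + beta (S-1) m)
mf_coefs <- function(params, m) {
  g <- params$growth
  r <- unique(g$r)
  if (length(r) != 1L) {
    stop("the mean-field analysis requires a common growth rate r")
  }
  if (params$inter$mode != "uniform") {
    stop("mean-field analysis applies to uniform interactions; use the ",
         "effective uniform community for random interactions")
  }
  alpha <- params$inter$alpha
  lam <- params$disp$lam; beta <- params$disp$beta
  lam_eff <- lam * (1 + beta * (g$S - 1) * m)
  rg <- r * (1 + alpha * (g$S - 1) * m / g$K)
  list(s = 2 * lam_eff * m, a = 2 * (rg - lam_eff), b = r / g$K,
       lam_eff = lam_eff, rg = rg, r = r)
}

#' Stationary abundance distribution at a pinned mean field
#'
#' The stationary solution of the one-population Fokker-Planck equation for
#' drift `f(N) = rg N - (r/K) N^2 + lam (m - N)` with demographic noise
#' `sqrt(N) dW` (Ito):
#' `P[N] propto N^(2 lam m - 1) exp(a N - b N^2)` with
#' `a = 2 (rg - lam)`, `b = r/K` and effective growth
#' `rg = r (1 + alpha (S-1) m / K)`. For `r = 0` this is the Gamma density
#' with shape `2 lam m` and rate `2 lam`. With density-dependent dispersal
#' (`beta > 0`) the baseline rate is replaced by
#' `lam_eff = lam (1 + beta (S-1) m)`.
#'
#' @param m Mean field (mean abundance), `>= 0`. `m = 0` returns the
#'   degenerate extinct distribution (point mass at 0).
#' @param params An [mc_params()] object with uniform interactions.
#' @return An object of class `mc_density` with fields `m`, `shape_exp`,
#'   `lin_coef`, `quad_coef`, `log_norm`, and vectorized functions
#'   `density(N)` and `cdf(q)`.
#' @examples
#' p <- mc_params(growth_params(r = 0.3, K = 10, S = 100),
#'                interaction_spec(alpha = 0.005),
#'                dispersal_spec(lam = 0.1))
#' d <- stationary_density(19.8, p)
#' mean_of_density(d)
#' @export
stationary_density <- function(m, params) {
  stopifnot(inherits(params, "mc_params"), is.numeric(m), length(m) == 1L,
            m >= 0)
  if (m == 0) {
    return(structure(list(
      m = 0, degenerate = TRUE, shape_exp = 0, lin_coef = NA_real_,
      quad_coef = NA_real_, log_norm = NA_real_,
      density = function(N) ifelse(N == 0, Inf, 0),
      cdf = function(q) as.numeric(q >= 0),
      params = params
    ), class = "mc_density"))
  }
  if (params$disp$lam <= 0) {
    stop("lam = 0 with m > 0: no stationary immigration balance exists")
  }
  cf <- mf_coefs(params, m)
  logZ0 <- mf_log_weight_integral(cf$s, c(cf$a, -cf$b))
  dens <- function(N) {
    out <- numeric(length(N))
    pos <- N > 0
    out[pos] <- exp((cf$s - 1) * log(N[pos]) + cf$a * N[pos] -
                      cf$b * N[pos]^2 - logZ0)
    out[N == 0] <- if (cf$s >= 1) 0 else Inf
    out
  }
  cdf <- function(q) {
    vapply(q, function(qi) {
      if (qi <= 0) return(0)
      mf_partial_mass(cf$s, c(cf$a, -cf$b), logZ0, qi)
    }, numeric(1))
  }
  structure(list(
    m = m, degenerate = FALSE, shape_exp = cf$s, lin_coef = cf$a,
    quad_coef = cf$b, log_norm = logZ0, lam_eff = cf$lam_eff,
    density = dens, cdf = cdf, params = params
  ), class = "mc_density")
}

# P(N <= q) under the stationary density with log-normalization logZ0
mf_partial_mass <- function(s, coefs, logZ0, q) {
  c1 <- coefs[1]; c2 <- coefs[2]
  poly <- function(N) c1 * N + c2 * N^2
  cut <- min(q, if (c2 < 0) min(1, 1 / (2 * abs(c2))) else 1)
  head <- if (s >= 1) {
    stats::integrate(function(N) exp((s - 1) * log(N) + poly(N) - logZ0),
                     0, cut, rel.tol = 1e-10)$value
  } else {
    stats::integrate(function(u) exp(poly(u^(1 / s)) - logZ0) / s,
                     0, cut^s, rel.tol = 1e-10)$value
  }
  rest <- if (q > cut) {
    stats::integrate(function(N) exp((s - 1) * log(N) + poly(N) - logZ0),
                     cut, q, rel.tol = 1e-10)$value
  } else 0
  min(1, head + rest)
}

#' @export
print.mc_density <- function(x, ...) {
  if (x$degenerate) {
    cat("<mc_density> extinct state: point mass at N = 0\n")
  } else {
    cat(sprintf(
      "<mc_density> m = %.4g: P[N] ~ N^%.4g exp(%.4g N - %.4g N^2)\n",
      x$m, x$shape_exp - 1, x$lin_coef, x$quad_coef))
  }
  invisible(x)
}

#' Mean abundance of a stationary density
#'
#' `<N> = int N P[N] dN` by adaptive quadrature (relative error below
#' `1e-8`). For the Gamma limit (`r = 0`) this returns `m` exactly.
#'
#' @param d An `mc_density` from [stationary_density()].
#' @return The mean abundance.
#' @export
mean_of_density <- function(d) {
  stopifnot(inherits(d, "mc_density"))
  if (d$degenerate) return(0)
  mm <- mf_moments(d$shape_exp, c(d$lin_coef, -d$quad_coef))
  mm$mean
}

# internal engine: all self-consistency roots of mean_fn(m) = m on a
# log-spaced grid, with contraction-based stability
mf_root_engine <- function(mean_fn, slope0, m_lo, m_max, n_grid = 200) {
  scan <- function(grid) {
    Fv <- vapply(grid, function(m) mean_fn(m) - m, numeric(1))
    idx <- which(diff(sign(Fv)) != 0)
    vapply(idx, function(i) {
      stats::uniroot(function(m) mean_fn(m) - m, c(grid[i], grid[i + 1]),
                     tol = 1e-10 * max(1, grid[i + 1]))$root
    }, numeric(1))
  }
  grid <- exp(seq(log(m_lo), log(m_max), length.out = n_grid))
  roots <- scan(grid)
  if (length(roots) == 0 && slope0 >= 1) {
    # a positive branch must exist above the repelling origin; refine once
    roots <- scan(exp(seq(log(m_lo), log(m_max), length.out = 10 * n_grid)))
  }
  slope_at <- function(m) {
    h <- 1e-4 * max(m, 1e-3)
    (mean_fn(m + h) - mean_fn(max(m - h, m_lo / 10))) /
      (h + m - max(m - h, m_lo / 10))
  }
  tibble::tibble(
    m = c(0, roots),
    stable = c(slope0 < 1, vapply(roots, function(m) slope_at(m) < 1, logical(1))),
    type = c("extinct", rep("positive", length(roots)))
  )
}

#' Self-consistent mean-field roots
#'
#' Solves the self-consistency condition `<N>_m = m`, where `<N>_m` is the
#' mean of the stationary density parameterized by the mean field `m`. A
#' root is stable when the iteration `m -> <N>_m` contracts there
#' (`d<N>/dm < 1`); the extinct root `m = 0` is stable when the slope at
#' the origin, `2 lam int exp(2 (r - lam) N - (r/K) N^2) dN`, is below 1
#' (equivalently `lam < lambda_c`). Supports density-dependent dispersal
#' (`beta > 0`), in which case `lam` is replaced by
#' `lam_eff(m) = lam (1 + beta (S-1) m)` in the stationary density.
#'
#' @param params An [mc_params()] object with uniform interactions.
#' @param m_max Upper end of the search interval; default `3 N*` (or `3 K`
#'   when `alpha (S-1)` is close to 1).
#' @param n_grid Number of log-spaced trial points (at least 200).
#' @return A tibble with columns `m`, `stable`, `type` (one row is the
#'   extinct root `m = 0`). The attribute `degenerate` flags the neutral
#'   `r = 0` case where `<N>_m = m` identically.
#' @examples
#' p <- mc_params(growth_params(r = 0.3, K = 10, S = 100),
#'                interaction_spec(alpha = 0.005), dispersal_spec(lam = 1e-3))
#' self_consistent_roots(p)
#' @export
self_consistent_roots <- function(params, m_max = NULL, n_grid = 200) {
  stopifnot(inherits(params, "mc_params"))
  g <- params$growth
  cf0 <- mf_coefs(params, 0)
  if (cf0$r == 0) {
    out <- tibble::tibble(m = 0, stable = NA, type = "extinct")
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  if (params$disp$lam <= 0) {
    return(tibble::tibble(m = 0, stable = TRUE, type = "extinct"))
  }
  m_ref <- if (params$inter$alpha * (g$S - 1) < 0.9) {
    g$K / max(1 - params$inter$alpha * (g$S - 1), 1e-12)
  } else {
    g$K
  }
  if (is.null(m_max)) m_max <- 3 * m_ref
  mean_fn <- function(m) {
    cf <- mf_coefs(params, m)
    mf_moments(cf$s, c(cf$a, -cf$b))$mean
  }
  slope0 <- 2 * params$disp$lam *
    exp(mf_log_weight_integral(1, c(cf0$a, -cf0$b)))
  out <- mf_root_engine(mean_fn, slope0, m_lo = 1e-6 * m_ref,
                        m_max = m_max, n_grid = max(n_grid, 200))
  if (params$disp$beta > 0 && any(out$m > 0.98 * m_max)) {
    warning("self-consistency root at the m_max boundary; ",
            "density-dependent dispersal may push the mean field higher")
  }
  attr(out, "degenerate") <- FALSE
  out
}

#' Roots with density-dependent dispersal
#'
#' Self-consistency roots when interactions act on dispersal
#' (`beta > 0`, usually `alpha = 0`): the stationary density is evaluated
#' at the elevated rate `lam_eff(m) = lam (1 + beta (S-1) m)`. At `m = 0`
#' the rate reduces to the baseline `lam`, so the stability threshold of
#' the extinct state (`lambda_c`) is unchanged by `beta`. With `beta = 0`
#' this reduces exactly to [self_consistent_roots()].
#'
#' @inheritParams self_consistent_roots
#' @return A tibble as in [self_consistent_roots()].
#' @export
density_dependent_roots <- function(params, m_max = NULL, n_grid = 200) {
  self_consistent_roots(params, m_max = m_max, n_grid = n_grid)
}

#' Critical dispersal rate
#'
#' The dispersal rate at which the extinct state loses stability. At
#' vanishing density, species-to-species interactions are negligible, so
#' `lambda_c` solves the single-species marginal-slope condition
#' `2 lam int_0^Inf exp(2 (r - lam) N - (r/K) N^2) dN = 1`
#' and is identical for every `S` and `alpha`.
#'
#' @param growth A [growth_params()] object (only `r` and `K` are used;
#'   `r` must be common to all species).
#' @param tol Relative tolerance on `lambda_c`.
#' @return The critical rate `lambda_c`.
#' @examples
#' critical_dispersal(growth_params(r = 0.3, K = 10))  # ~10^-2.59
#' @export
critical_dispersal <- function(growth, tol = 1e-6) {
  stopifnot(inherits(growth, "mc_growth"))
  r <- unique(growth$r)
  if (length(r) != 1L) stop("critical_dispersal() requires a common r")
  if (r <= 0) stop("critical_dispersal() requires r > 0")
  K <- growth$K
  # marginal slope in log(lam): lambda_c shrinks exponentially with K, so
  # the bisection runs on the log scale (tol is then a relative tolerance)
  gfun <- function(x) {
    lam <- exp(x)
    2 * lam * exp(mf_log_weight_integral(1, c(2 * (r - lam), -r / K))) - 1
  }
  hi <- log(r)
  while (gfun(hi) < 0 && hi < log(100 * r)) hi <- hi + log(2)
  lo <- hi
  while (gfun(lo) > 0 && lo > -690) lo <- lo - 4
  exp(stats::uniroot(gfun, c(lo, hi), tol = tol / 4)$root)
}

#' Bifurcation diagram over a dispersal grid
#'
#' Assembles the stable and unstable positive self-consistency branches
#' over a grid of dispersal rates, together with the critical rate
#' `lambda_c` (stability boundary of the extinct state) and the
#' tipping-point rate `lambda_t`, the smallest dispersal rate at which a
#' stable positive branch exists. `lambda_t` is refined by bisection in
#' `log10(lam)` to `1e-3` dex. When the onset of the positive branch is
#' continuous (no subcritical window), `lambda_t` coincides with
#' `lambda_c` and the flag is `"no_subcritical_window"`; when the stable
#' branch persists at the lowest grid rate the flag is `"at_grid_min"`.
#'
#' @param params An [mc_params()] object; its `lam` is ignored in favor of
#'   `lam_grid`. Works for both constant (`beta = 0`) and density-dependent
#'   (`beta > 0`) dispersal.
#' @param lam_grid Dispersal rates to scan (default log-spaced
#'   `10^-4 .. 10^-1`).
#' @param n_grid Trial points per root scan.
#' @return An object of class `mc_bifurcation`.
#' @export
bifurcation_scan <- function(params,
                             lam_grid = 10^seq(-4, -1, length.out = 31),
                             n_grid = 200) {
  stopifnot(inherits(params, "mc_params"))
  lam_grid <- sort(lam_grid)
  with_lam <- function(lam) {
    params$disp$lam <- lam
    params
  }
  roots_at <- function(lam) {
    rt <- self_consistent_roots(with_lam(lam), n_grid = n_grid)
    rt[rt$type == "positive", , drop = FALSE]
  }
  per_lam <- purrr::map(lam_grid, roots_at)
  branches <- purrr::map2_dfr(lam_grid, per_lam, function(lam, rt) {
    if (nrow(rt) == 0) return(tibble::tibble())
    tibble::tibble(lambda = lam,
                   branch = ifelse(rt$stable, "stable", "unstable"),
                   m = rt$m)
  })
  lam_c <- critical_dispersal(params$growth)

  has_stable <- vapply(per_lam, function(rt) any(rt$stable), logical(1))
  if (!any(has_stable)) {
    lam_t <- NA_real_; flag <- "none"
  } else if (has_stable[1]) {
    lam_t <- lam_grid[1]; flag <- "at_grid_min"
  } else {
    i <- which(has_stable)[1]
    lo <- log10(lam_grid[i - 1]); hi <- log10(lam_grid[i])
    while (hi - lo > 1e-3) {
      mid <- (lo + hi) / 2
      rt <- roots_at(10^mid)
      if (any(rt$stable)) hi <- mid else lo <- mid
    }
    lam_t <- 10^hi
    flag <- if (lam_t < lam_c * (1 - 1e-3)) "window" else "no_subcritical_window"
  }
  structure(list(
    branches = branches, lam_grid = lam_grid, lam_c = lam_c,
    lam_t = lam_t, lam_t_flag = flag, params = params
  ), class = "mc_bifurcation")
}

#' @export
print.mc_bifurcation <- function(x, ...) {
  cat(sprintf(
    "<mc_bifurcation> %d dispersal rates; lambda_c = %.4g, lambda_t = %.4g (%s)\n",
    length(x$lam_grid), x$lam_c, x$lam_t, x$lam_t_flag))
  invisible(x)
}

#' Tidy a bifurcation diagram
#'
#' @param x An `mc_bifurcation`.
#' @param ... Unused.
#' @return Tibble with columns `lambda`, `branch`, `m`.
#' @export
tidy.mc_bifurcation <- function(x, ...) x$branches

#' One-row summary of a bifurcation diagram
#'
#' @param x An `mc_bifurcation`.
#' @param ... Unused.
#' @return A one-row tibble with `lam_c`, `lam_t`, the bistable window
#'   width in decades and the flag.
#' @export
glance.mc_bifurcation <- function(x, ...) {
  tibble::tibble(
    lam_c = x$lam_c, lam_t = x$lam_t,
    window_dex = ifelse(is.na(x$lam_t), NA_real_, log10(x$lam_c / x$lam_t)),
    lam_t_flag = x$lam_t_flag,
    n_lambda = length(x$lam_grid)
  )
}

#' @export
autoplot.mc_bifurcation <- function(object, ...) {
  ggplot2::ggplot(object$branches,
                  ggplot2::aes(x = .data$lambda, y = .data$m,
                               linetype = .data$branch)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$lam_c, linetype = "dotted") +
    ggplot2::scale_x_log10() +
    ggplot2::scale_linetype_manual(values = c(stable = "solid",
                                              unstable = "dashed")) +
    ggplot2::labs(x = "dispersal rate lambda", y = "mean abundance m*")
}

#' Export a bifurcation diagram
#'
#' Writes `<prefix>_branches.csv` (`lambda`, `branch`, `m`) and
#' `<prefix>_summary.json` (`lam_c`, `lam_t`, flag, parameter echo).
#'
#' @param bif An `mc_bifurcation`.
#' @param prefix Output path prefix.
#' @return Invisibly, the paths written.
#' @export
write_bifurcation <- function(bif, prefix) {
  paths <- paste0(prefix, c("_branches.csv", "_summary.json"))
  utils::write.csv(bif$branches, paths[1], row.names = FALSE)
  jsonlite::write_json(list(
    lam_c = bif$lam_c, lam_t = bif$lam_t, lam_t_flag = bif$lam_t_flag,
    params = as_config(bif$params)
  ), paths[2], auto_unbox = TRUE, digits = NA, null = "null")
  invisible(paths)
}
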