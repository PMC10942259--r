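# shared fixture builders (all inputs generated in code)

p_uniform <- function(S = 100, P = 20, lam = 1e-3, alpha = 0.005,
                      r = 0.3, K = 10, beta = 0) {
  mc_params(growth_params(r = r, K = K, S = S, P = P),
            interaction_spec(alpha = alpha),
            dispersal_spec(lam = lam, beta = beta))
}

p_random <- function(S = 20, P = 10, lam = 1e-2, alpha_hat = -0.01,
                     sigma = 0.5, seed = 11, r = 0.3, K = 10) {
  mc_params(growth_params(r = r, K = K, S = S, P = P),
            interaction_spec("random_symmetric", alpha_hat = alpha_hat,
                             sigma = sigma, seed = seed),
            dispersal_spec(lam = lam))
}

rand_state <- function(P, S, seed = 1, max_n = 20) {
  set.seed(seed)
  mc_state(matrix(stats::runif(P * S, 0, max_n), P, S))
}

paper_growth <- function(S = 100, P = 500) growth_params(r = 0.3, K = 10, S = S, P = P)
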