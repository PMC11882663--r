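# shared fixtures, built in code

quick_settings <- function(seed, iters = 1000L, chains = 3L) {
  mcmc_settings(n_chains = chains, min_iterations = iters,
                max_iterations = iters, seed = seed)
}

# a small two-factor model for cheap sampler tests
toy_model <- function() {
  lambda <- matrix(0, 6, 2)
  lambda[1:3, 1] <- c(0.7, 0.75, 0.8)
  lambda[4:6, 2] <- c(0.7, 0.75, 0.8)
  cfa_model_spec("toy", lambda, 0.4, 1 - rowSums(lambda^2))
}

# hand-built discrepancy series for index algebra checks
fake_series <- function(d_obs, d_rep = d_obs, p_star, pD, N,
                        m = length(d_obs)) {
  structure(list(d_obs = d_obs, d_rep = d_rep, p_star = p_star, pD = pD,
                 N = N, m = m, q_free = NA_integer_, converged = TRUE),
            class = "discrepancy_series")
}

# observation-wise -2 * log-likelihood-ratio oracle against the saturated
# normal model, computed from raw data rather than moments
neg2_loglik_ratio <- function(X, mu, sigma) {
  n <- nrow(X); p <- ncol(X)
  ll <- function(m, s) {
    ch <- chol(s)
    cent <- sweep(X, 2L, m)
    quad <- sum((cent %*% chol2inv(ch)) * cent)
    -0.5 * (n * p * log(2 * pi) + n * 2 * sum(log(diag(ch))) + quad)
  }
  xbar <- colMeans(X)
  S <- crossprod(sweep(X, 2L, xbar)) / n
  -2 * (ll(mu, sigma) - ll(xbar, S))
}
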