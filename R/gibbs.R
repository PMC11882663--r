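#' MCMC settings for the Bayesian CFA sampler
#'
#' @param n_chains Number of chains (>= 2; the study design uses 3).
#' @param min_iterations Iterations run before the first convergence check
#'   (study default 10,000; the scaled-down desk settings use 2,000).
#' @param max_iterations Hard cap (study default 500,000).
#' @param psr_threshold Potential scale reduction threshold (default 1.10).
#' @param check_interval Iterations added between convergence checks;
#'   `NULL` grows the chain geometrically by 10% of its current length.
#' @param seed Integer seed; chain streams are derived from it.
#' @return An `mcmc_settings` list.
#' @export
mcmc_settings <- function(n_chains = 3L, min_iterations = 10000L,
                          max_iterations = 500000L, psr_threshold = 1.10,
                          check_interval = NULL, seed = 1L) {
  stopifnot(n_chains >= 2L, min_iterations <= max_iterations,
            psr_threshold > 1, min_iterations >= 10L)
  structure(list(n_chains = as.integer(n_chains),
                 min_iterations = as.integer(min_iterations),
                 max_iterations = as.integer(max_iterations),
                 psr_threshold = psr_threshold,
                 check_interval = check_interval,
                 seed = as.integer(seed)),
            class = "mcmc_settings")
}

# one chain's persistent state: current parameter values plus its RNG stream
new_chain_state <- function(X, model, prior, chain_index) {
  p <- model$n_items; q <- model$n_factors
  mask <- model$free_mask
  lambda <- matrix(0, p, q)
  start_mean <- prior$loading_mean
  start_mean[is.na(start_mean)] <- 0
  # overdispersed deterministic starts: alternate offsets around the prior
  # mean so PSR between chains is meaningful
  offset <- c(0.25, -0.25, 0.5, -0.5, 0.75, -0.75)[
    ((chain_index - 1L) %% 6L) + 1L]
  lambda[mask] <- start_mean[mask] + offset
  list(lambda = lambda, phi = diag(q), psi = rep(1, p),
       tau = colMeans(X), xi = NULL, rng = NULL)
}

# Cholesky with a growing scale-aware ridge: posteriors piled near the
# correlation boundary (strong factor correlations, inaccurate informative
# priors, small n) can make conditionals numerically semidefinite; the
# ridge keeps the chain alive without materially changing the target
safe_chol <- function(M) {
  ch <- tryCatch(chol(M), error = function(e) NULL)
  if (!is.null(ch)) return(ch)
  scale <- mean(diag(M))
  for (eps in scale * 10^(-8:-4)) {
    ch <- tryCatch(chol(M + diag(eps, nrow(M))), error = function(e) NULL)
    if (!is.null(ch)) return(ch)
  }
  stop("conditional covariance is not positive definite")
}

# Wishart(df, scale) draw by Bartlett decomposition, tolerant of
# near-singular scale matrices (boundary-adjacent posteriors)
rwishart_bartlett <- function(df, scale) {
  q <- nrow(scale)
  L <- t(safe_chol((scale + t(scale)) / 2))
  A <- matrix(0, q, q)
  diag(A) <- sqrt(stats::rchisq(q, df - seq_len(q) + 1))
  if (q > 1) A[lower.tri(A)] <- stats::rnorm(q * (q - 1) / 2)
  LA <- L %*% A
  tcrossprod(LA)
}

# advance one chain by n_iter Gibbs sweeps, returning the draw block.
# Per sweep: (1) factor scores from their multivariate-normal conditional;
# (2) parameter-expanded factor-correlation update (inverse-Wishart on the
# unconstrained covariance, rescaled to a correlation matrix with the
# scales pushed into loadings and scores); (3) per item, conjugate
# inverse-gamma residual-variance and normal loading/intercept updates.
run_chain_block <- function(state, X, model, prior, n_iter) {
  p <- model$n_items; q <- model$n_factors; n <- nrow(X)
  mask <- model$free_mask
  free_idx <- which(mask)
  nl <- length(free_idx)
  low_tri <- which(lower.tri(diag(q)))
  nc <- length(low_tri)
  prior_prec <- matrix(0, p, q)
  prior_prec[free_idx] <- 1 / prior$loading_var[free_idx]
  prior_pm <- matrix(0, p, q)  # prior precision * prior mean
  prior_pm[free_idx] <- prior$loading_mean[free_idx] /
    prior$loading_var[free_idx]
  item_cols <- lapply(seq_len(p), function(j) which(mask[j, ]))
  yty <- colSums(X^2)
  iw_df <- n - q - 1L
  if (iw_df < q) stop("sample too small for the factor-covariance update")

  lambda <- state$lambda; phi <- state$phi
  psi <- state$psi; tau <- state$tau
  draws <- matrix(NA_real_, n_iter, nl + nc + 2L * p)

  for (it in seq_len(n_iter)) {
    # (1) factor scores
    phi_inv <- chol2inv(safe_chol(phi))
    lam_w <- lambda / psi
    M <- crossprod(lambda, lam_w) + phi_inv
    V <- chol2inv(safe_chol(M))
    xi <- (X %*% lam_w - rep(1, n) %*% (t(tau) %*% lam_w)) %*% V +
      matrix(stats::rnorm(n * q), n, q) %*% safe_chol(V)

    # (2) parameter-expanded correlation update
    S_xi <- crossprod(xi)
    W_inv <- rwishart_bartlett(iw_df, chol2inv(safe_chol(S_xi)))
    W <- chol2inv(safe_chol(W_inv))
    d <- sqrt(diag(W))
    phi <- W / tcrossprod(d)
    diag(phi) <- 1
    xi <- sweep(xi, 2L, d, "/")
    lambda <- sweep(lambda, 2L, d, "*")

    # (3) residual variances, loadings, intercepts
    Z1 <- cbind(1, xi)
    G <- crossprod(Z1)              # (q+1) x (q+1)
    Zty <- crossprod(Z1, X)         # (q+1) x p
    for (j in seq_len(p)) {
      K <- item_cols[[j]]
      sel <- c(1L, K + 1L)
      Gs <- G[sel, sel, drop = FALSE]
      bty <- Zty[sel, j]
      beta <- c(tau[j], lambda[j, K])
      ssr <- max(yty[j] - 2 * sum(beta * bty) +
                   drop(crossprod(beta, Gs %*% beta)), 1e-12)
      psi_j <- 1 / stats::rgamma(1L, shape = n / 2 - 1, rate = ssr / 2)
      cond <- item_conditional(Gs, bty, psi_j, prior_prec[j, K],
                               prior_pm[j, K])
      beta <- cond$mean + backsolve(cond$chol,
                                    stats::rnorm(length(cond$mean)))
      tau[j] <- beta[1L]
      if (length(K)) lambda[j, K] <- beta[-1L]
      psi[j] <- psi_j
    }
    draws[it, ] <- c(lambda[free_idx], phi[low_tri], psi, tau)
  }
  state$lambda <- lambda; state$phi <- phi
  state$psi <- psi; state$tau <- tau
  list(state = state, draws = draws)
}

# conditional posterior of one item's (intercept, loadings) given factor
# scores and residual variance: precision = Z'Z/psi + prior precision
# (zero for the flat intercept), mean = the precision-weighted blend of the
# least-squares fit and the prior mean
item_conditional <- function(Gs, bty, psi_j, prior_prec_j, prior_pm_j) {
  A <- Gs / psi_j
  diag(A) <- diag(A) + c(0, prior_prec_j)
  b <- bty / psi_j + c(0, prior_pm_j)
  cA <- chol(A)
  list(mean = backsolve(cA, forwardsolve(t(cA), b)), chol = cA)
}

# reflect factors whose mean primary loading is negative (sign/label
# switching is only an issue under the diffuse prior, whose loading prior
# is symmetric around zero); operates on a draw block of one chain
reflect_chain <- function(draws, model, nl, nc) {
  q <- model$n_factors
  free_idx <- which(model$free_mask)
  free_col <- ((free_idx - 1L) %/% model$n_items) + 1L
  free_row <- ((free_idx - 1L) %% model$n_items) + 1L
  primary <- model$primary_factor[free_row] == free_col
  low_tri <- which(lower.tri(diag(q)))
  lt_row <- ((low_tri - 1L) %% q) + 1L
  lt_col <- ((low_tri - 1L) %/% q) + 1L
  flip <- logical(q)
  for (k in seq_len(q)) {
    cols <- which(free_col == k & primary)
    if (length(cols) && mean(draws[, cols]) < 0) flip[k] <- TRUE
  }
  if (!any(flip)) return(draws)
  for (k in which(flip)) {
    draws[, which(free_col == k)] <- -draws[, which(free_col == k)]
    pc <- which(xor(lt_row == k, lt_col == k))
    if (length(pc)) draws[, nl + pc] <- -draws[, nl + pc]
  }
  draws
}

#' Gelman-Rubin potential scale reduction factor
#'
#' Classic PSR over aligned chain segments:
#' \eqn{\sqrt{(((L-1)/L) W + B/L) / W}} with W the mean within-chain
#' variance and B the between-chain variance of the segment means times L,
#' floored at 1 (so chains with no between-chain spread report exactly 1).
#' Returns 1 when both W and B vanish, and `Inf` when W vanishes with
#' spread between chains.
#'
#' @param chain_segments List (one element per chain) of equal-length
#'   numeric vectors, or a matrix with one column per chain.
#' @return PSR scalar.
#' @export
psr <- function(chain_segments) {
  if (is.matrix(chain_segments))
    chain_segments <- lapply(seq_len(ncol(chain_segments)),
                             function(j) chain_segments[, j])
  L <- length(chain_segments[[1L]])
  if (length(unique(vapply(chain_segments, length, 1L))) != 1L)
    stop("chain segments must have equal lengths")
  if (length(chain_segments) < 2L || L < 2L)
    stop("psr needs >= 2 chains with >= 2 draws each")
  W <- mean(vapply(chain_segments, stats::var, 1.0))
  B <- L * stats::var(vapply(chain_segments, mean, 1.0))
  if (W == 0) return(if (B == 0) 1 else Inf)
  max(1, sqrt((((L - 1) / L) * W + B / L) / W))
}

#' Draw from the Bayesian CFA posterior
#'
#' Runs `n_chains` Gibbs chains with overdispersed starts, checking
#' convergence with the potential scale reduction factor on the second half
#' of each chain (after per-chain sign reflection) at `min_iterations` and
#' on a geometric schedule thereafter, stopping when every monitored
#' parameter has PSR below the threshold or `max_iterations` is reached.
#' The first half of each chain is discarded as burn-in; the retained
#' second halves of all chains are pooled.
#'
#' @param data n x p data matrix (a `cfa_dataset` or plain matrix).
#' @param model Analysis-form `cfa_model_spec`.
#' @param prior A `prior_spec` from [make_prior()].
#' @param settings An [mcmc_settings()] object.
#' @return A `posterior_draws` object: matrices `lambda` (m x free
#'   loadings), `phi` (m x q(q-1)/2 lower-triangle correlations), `psi`,
#'   `tau`; `chain` index per draw; `m`, `converged`, `iterations_used`,
#'   `psr_final` (per monitored parameter), and the model/prior used.
#' @export
sample_posterior <- function(data, model, prior, settings = mcmc_settings()) {
  X <- unclass(data)
  if (ncol(X) != model$n_items)
    stop("data column count does not match the model item count")
  n <- nrow(X)
  p <- model$n_items; q <- model$n_factors
  nl <- sum(model$free_mask)
  nc <- q * (q - 1) / 2

  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, globalenv()), add = TRUE)

  nch <- settings$n_chains
  states <- vector("list", nch)
  chain_draws <- vector("list", nch)
  rng_states <- vector("list", nch)
  for (c in seq_len(nch)) {
    set.seed((settings$seed %% 1000000L) * 1000L + c)
    states[[c]] <- new_chain_state(X, model, prior, c)
    rng_states[[c]] <- get(".Random.seed", globalenv())
    chain_draws[[c]] <- matrix(numeric(0), 0L, nl + nc + 2L * p)
  }

  iters <- 0L
  target <- settings$min_iterations
  converged <- FALSE
  psr_final <- NULL
  repeat {
    add <- target - iters
    for (c in seq_len(nch)) {
      assign(".Random.seed", rng_states[[c]], globalenv())
      block <- run_chain_block(states[[c]], X, model, prior, add)
      states[[c]] <- block$state
      rng_states[[c]] <- get(".Random.seed", globalenv())
      chain_draws[[c]] <- rbind(chain_draws[[c]], block$draws)
    }
    iters <- target
    keep <- (floor(iters / 2) + 1L):iters
    halves <- lapply(chain_draws, function(d)
      reflect_chain(d[keep, , drop = FALSE], model, nl, nc))
    psr_final <- vapply(seq_len(ncol(halves[[1L]])), function(jj)
      psr(lapply(halves, function(h) h[, jj])), 1.0)
    if (all(psr_final < settings$psr_threshold)) {
      converged <- TRUE
      break
    }
    if (iters >= settings$max_iterations) break
    step <- if (is.null(settings$check_interval))
      max(1L, as.integer(ceiling(0.10 * iters))) else
        as.integer(settings$check_interval)
    target <- min(settings$max_iterations, iters + step)
  }

  pooled <- do.call(rbind, halves)
  m <- nrow(pooled)
  structure(list(
    lambda = pooled[, seq_len(nl), drop = FALSE],
    phi = pooled[, nl + seq_len(nc), drop = FALSE],
    psi = pooled[, nl + nc + seq_len(p), drop = FALSE],
    tau = pooled[, nl + nc + p + seq_len(p), drop = FALSE],
    chain = rep(seq_len(nch), each = length(keep)),
    m = m, n = n, converged = converged, iterations_used = iters,
    psr_final = psr_final, model = model, prior_label = prior$label),
    class = "posterior_draws")
}

#' @export
print.posterior_draws <- function(x, ...) {
  cat(sprintf(paste0("posterior_draws: %d retained draws (%d chains x %d),",
                     " %s, max PSR %.3f\n"),
              x$m, max(x$chain), x$iterations_used %/% 2,
              if (x$converged) "converged" else "NOT converged",
              max(x$psr_final)))
  invisible(x)
}

#' Posterior means of all free parameters
#'
#' Elementwise means over the pooled retained draws.
#'
#' @param draws A `posterior_draws` object.
#' @return List with `lambda` (p x q matrix, zeros on fixed paths), `phi`,
#'   `psi`, `tau`.
#' @export
point_estimates <- function(draws) {
  model <- draws$model
  p <- model$n_items; q <- model$n_factors
  lambda <- matrix(0, p, q)
  lambda[which(model$free_mask)] <- colMeans(draws$lambda)
  phi <- diag(q)
  phi[lower.tri(phi)] <- colMeans(draws$phi)
  phi <- phi + t(phi) - diag(q)
  list(lambda = lambda, phi = phi, psi = colMeans(draws$psi),
       tau = colMeans(draws$tau))
}

#' Persist posterior draws in long format
#'
#' Writes one row per (chain, draw, parameter) with columns `chain`,
#' `draw`, `parameter`, `value`. Loadings are labeled `lambda[i,k]`,
#' correlations `phi[k,l]`, residual variances `psi[j]`, intercepts
#' `tau[j]`.
#'
#' @param draws A `posterior_draws` object.
#' @param file Path of the CSV to write.
#' @return Invisibly, the file path.
#' @export
write_draws <- function(draws, file) {
  model <- draws$model
  free_idx <- which(model$free_mask)
  p <- model$n_items
  lam_names <- sprintf("lambda[%d,%d]", ((free_idx - 1L) %% p) + 1L,
                       ((free_idx - 1L) %/% p) + 1L)
  q <- model$n_factors
  lt <- which(lower.tri(diag(q)))
  phi_names <- sprintf("phi[%d,%d]", ((lt - 1L) %% q) + 1L,
                       ((lt - 1L) %/% q) + 1L)
  mat <- cbind(draws$lambda, draws$phi, draws$psi, draws$tau)
  colnames(mat) <- c(lam_names, phi_names, sprintf("psi[%d]", 1:p),
                     sprintf("tau[%d]", 1:p))
  per_chain <- tabulate(draws$chain)
  long <- data.frame(
    chain = rep(draws$chain, times = ncol(mat)),
    draw = rep(unlist(lapply(per_chain, seq_len)), times = ncol(mat)),
    parameter = rep(colnames(mat), each = nrow(mat)),
    value = as.vector(mat))
  utils::write.csv(long, file, row.names = FALSE)
  invisible(file)
}

# model-implied covariance for one draw
draw_sigma <- function(draws, i) {
  model <- draws$model
  p <- model$n_items; q <- model$n_factors
  lambda <- matrix(0, p, q)
  lambda[which(model$free_mask)] <- draws$lambda[i, ]
  phi <- diag(q)
  phi[lower.tri(phi)] <- draws$phi[i, ]
  phi <- phi + t(phi) - diag(q)
  sigma <- lambda %*% phi %*% t(lambda) + diag(draws$psi[i, ], p)
  (sigma + t(sigma)) / 2
}
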