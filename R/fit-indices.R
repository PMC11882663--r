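#' Chi-square discrepancy between sample statistics and a model point
#'
#' The deviance of the model point against the saturated model:
#' \deqn{D = N[\ln|\Sigma| + tr(S\Sigma^{-1}) - \ln|S| - p
#'   + (\bar{x}-\mu)'\Sigma^{-1}(\bar{x}-\mu)]}
#' with `S` the divisor-N sample covariance, equal to minus twice the
#' log-likelihood ratio against the saturated normal model.
#'
#' @param sample_mean Length-p sample mean vector.
#' @param sample_cov p x p divisor-N sample covariance.
#' @param model_mean Length-p model-implied mean.
#' @param model_cov p x p model-implied covariance (positive definite).
#' @param N Sample size.
#' @return Nonnegative scalar.
#' @export
chi_square_discrepancy <- function(sample_mean, sample_cov, model_mean,
                                   model_cov, N) {
  p <- length(sample_mean)
  ch_m <- chol(model_cov)
  ch_s <- chol(sample_cov)
  sigma_inv <- chol2inv(ch_m)
  diff <- sample_mean - model_mean
  d <- N * (2 * sum(log(diag(ch_m))) - 2 * sum(log(diag(ch_s))) +
              sum(sigma_inv * sample_cov) - p +
              drop(crossprod(diff, sigma_inv %*% diff)))
  max(d, 0)
}

# divisor-N sample moments
sample_moments <- function(X) {
  n <- nrow(X)
  xbar <- colMeans(X)
  S <- crossprod(sweep(X, 2L, xbar)) / n
  list(mean = xbar, cov = S, n = n)
}

#' Posterior discrepancy series for a fitted CFA model
#'
#' For each retained draw, computes the observed-data discrepancy
#' \eqn{D_i^{obs}} at that draw's parameters and the replicated-data
#' discrepancy \eqn{D_i^{rep}} from a fresh dataset of the same size
#' simulated at the same draw (standard per-draw posterior predictive
#' model checking). Also returns the effective number of parameters
#' \eqn{pD = \bar{D} - D(\bar\theta)} and the saturated-moment count
#' \eqn{p^* = p(p+1)/2}.
#'
#' The series measures the covariance structure: the mean structure is
#' saturated (the discrepancy's mean term is evaluated at the sample mean),
#' matching the moment count \eqn{p^* = p(p+1)/2}, which counts covariance
#' moments only. Under diffuse priors pD then approaches the number of free
#' covariance-structure parameters (loadings + factor correlations +
#' residual variances, intercepts excluded), which is the convention under
#' which the Bayesian indices line up with their frequentist population
#' counterparts.
#'
#' @param data The observed n x p data matrix the posterior was fit to.
#' @param draws A `posterior_draws` object.
#' @param seed Optional seed for the replicated datasets; the caller's RNG
#'   state is preserved when supplied.
#' @return A `discrepancy_series` object with fields `d_obs`, `d_rep`,
#'   `p_star`, `pD`, `N`, `q_free`, `m`, `converged`.
#' @export
discrepancy_series <- function(data, draws, seed = NULL) {
  X <- unclass(data)
  n <- nrow(X)
  p <- ncol(X)
  obs <- sample_moments(X)
  if (!is.null(seed)) {
    old_seed <- if (exists(".Random.seed", globalenv()))
      get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old_seed))
      assign(".Random.seed", old_seed, globalenv()), add = TRUE)
    set.seed(seed)
  }
  m <- draws$m
  d_obs <- numeric(m)
  d_rep <- numeric(m)
  for (i in seq_len(m)) {
    sigma <- draw_sigma(draws, i)
    tau_i <- draws$tau[i, ]
    ch <- chol(sigma)
    d_obs[i] <- chi_square_discrepancy(obs$mean, obs$cov, obs$mean,
                                       sigma, n)
    rep_x <- matrix(stats::rnorm(n * p), n, p) %*% ch
    rep_x <- sweep(rep_x, 2L, tau_i, "+")
    rep_m <- sample_moments(rep_x)
    d_rep[i] <- chi_square_discrepancy(rep_m$mean, rep_m$cov, rep_m$mean,
                                       sigma, n)
  }
  pe <- point_estimates(draws)
  sigma_bar <- pe$lambda %*% pe$phi %*% t(pe$lambda) + diag(pe$psi, p)
  d_at_mean <- chi_square_discrepancy(obs$mean, obs$cov, obs$mean,
                                      sigma_bar, n)
  structure(list(d_obs = d_obs, d_rep = d_rep,
                 p_star = p * (p + 1) / 2,
                 pD = mean(d_obs) - d_at_mean,
                 d_at_point = d_at_mean,
                 N = n, m = m,
                 q_free = count_free_parameters(draws$model),
                 converged = draws$converged),
            class = "discrepancy_series")
}

#' Effective number of parameters
#'
#' \eqn{pD = \bar{D} - D(\bar\theta)}: the mean posterior deviance minus
#' the deviance at the posterior mean. Approximately the number of freely
#' estimated parameters under diffuse priors, and smaller as the loading
#' priors grow informative.
#'
#' @param d_obs Vector of per-draw observed-data discrepancies.
#' @param point_est Point estimates (from [point_estimates()]).
#' @param data The observed data matrix.
#' @return Scalar pD.
#' @export
effective_params <- function(d_obs, point_est, data) {
  X <- unclass(data)
  obs <- sample_moments(X)
  p <- ncol(X)
  sigma_bar <- point_est$lambda %*% point_est$phi %*% t(point_est$lambda) +
    diag(point_est$psi, p)
  mean(d_obs) - chi_square_discrepancy(obs$mean, obs$cov, obs$mean,
                                       sigma_bar, nrow(X))
}

#' Bayesian fit of the independence (null) model
#'
#' The null model constrains all covariances to zero with means and
#' variances free. Under the flat intercept prior and the limiting
#' noninformative inverse-gamma residual prior the posterior factorizes per
#' variable into conjugate normal-inverse-gamma form, so draws are exact:
#' \eqn{\sigma_j^2 | y \sim IG((n-3)/2, SS_j/2)},
#' \eqn{\mu_j | \sigma_j^2, y \sim N(\bar{y}_j, \sigma_j^2/n)}.
#'
#' @param data n x p data matrix.
#' @param m Number of posterior draws (match the hypothesized model's
#'   retained length).
#' @param seed Optional seed (caller RNG preserved when supplied).
#' @param include_rep Also simulate per-draw replicated-data discrepancies
#'   (not needed by any index; off by default).
#' @return List with `d_obs` (length m), `pD`, `p_star`, `N`, and
#'   optionally `d_rep`.
#' @export
fit_null_model <- function(data, m, seed = NULL, include_rep = FALSE) {
  X <- unclass(data)
  n <- nrow(X); p <- ncol(X)
  if (n < 6L) stop("null-model posterior needs n >= 6")
  obs <- sample_moments(X)
  ss <- diag(obs$cov) * n
  if (!is.null(seed)) {
    old_seed <- if (exists(".Random.seed", globalenv()))
      get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old_seed))
      assign(".Random.seed", old_seed, globalenv()), add = TRUE)
    set.seed(seed)
  }
  sigma2 <- matrix(NA_real_, m, p)
  mu <- matrix(NA_real_, m, p)
  for (j in seq_len(p)) {
    sigma2[, j] <- 1 / stats::rgamma(m, shape = (n - 3) / 2,
                                     rate = ss[j] / 2)
    mu[, j] <- stats::rnorm(m, obs$mean[j], sqrt(sigma2[, j] / n))
  }
  # vectorized discrepancy for diagonal model covariance
  log_det_S <- 2 * sum(log(diag(chol(obs$cov))))
  d_obs <- n * (rowSums(log(sigma2)) - log_det_S +
                  rowSums(sweep(1 / sigma2, 2L, diag(obs$cov), "*")) - p)
  s2_bar <- colMeans(sigma2)
  d_at_mean <- chi_square_discrepancy(obs$mean, obs$cov, obs$mean,
                                      diag(s2_bar, p), n)
  out <- list(d_obs = d_obs, pD = mean(d_obs) - d_at_mean,
              p_star = p * (p + 1) / 2, N = n)
  if (include_rep) {
    d_rep <- numeric(m)
    for (i in seq_len(m)) {
      rep_x <- sweep(matrix(stats::rnorm(n * p), n, p) %*%
                       diag(sqrt(sigma2[i, ]), p), 2L, mu[i, ], "+")
      rm_ <- sample_moments(rep_x)
      d_rep[i] <- chi_square_discrepancy(rm_$mean, rm_$cov, rm_$mean,
                                         diag(sigma2[i, ], p), n)
    }
    out$d_rep <- d_rep
  }
  out
}

# equal-tailed 90% interval, linear-interpolation quantiles
ci90 <- function(x) unname(stats::quantile(x, c(0.05, 0.95), type = 7))

new_fit_index_result <- function(index, series_draws, ppp_value = NA_real_) {
  ok <- is.finite(series_draws)
  dr <- series_draws[ok]
  res <- structure(list(
    index = index, draws = series_draws,
    mean = mean(dr), sd = stats::sd(dr), ci90 = ci90(dr),
    ppp = ppp_value, n_invalid = sum(!ok)),
    class = "fit_index_result")
  dec <- decide(res, index)
  res$rejected <- dec$rejected
  res$ci_class <- dec$ci_class
  res
}

#' @export
print.fit_index_result <- function(x, ...) {
  cat(sprintf("%s: mean %.3f (sd %.3f), 90%% CI [%.3f, %.3f]%s -> %s, %s\n",
              x$index, x$mean, x$sd, x$ci90[1], x$ci90[2],
              if (!is.na(x$ppp)) sprintf(", PPp %.3f", x$ppp) else "",
              if (isTRUE(x$rejected)) "reject" else "retain",
              x$ci_class))
  invisible(x)
}

#' Posterior predictive p-value
#'
#' Proportion of retained draws whose replicated-data discrepancy exceeds
#' the observed-data discrepancy. Values near 0.5 indicate good fit;
#' values below 0.05 or above 0.95 flag misfit.
#'
#' @param series A `discrepancy_series` (hypothesized model).
#' @return A `fit_index_result` whose `ppp` field holds the scalar.
#' @export
ppp <- function(series) {
  if (series$m < 1L) stop("empty discrepancy series")
  ind <- as.numeric(series$d_obs < series$d_rep)
  new_fit_index_result("PPp", ind, ppp_value = mean(ind))
}

check_pd_gap <- function(series) {
  if (series$p_star <= series$pD)
    stop("p* <= pD: effective parameter count is pathological")
}

#' Bayesian RMSEA, posterior predictive model-checking form
#'
#' Per draw
#' \eqn{\sqrt{\max(0, ((D_i^{obs} - D_i^{rep}) - (p^* - pD)) /
#' ((p^* - pD) N)}}.
#'
#' @param series A `discrepancy_series`.
#' @return A `fit_index_result`.
#' @export
brmsea_ppmc <- function(series) {
  check_pd_gap(series)
  gap <- series$p_star - series$pD
  x <- sqrt(pmax(0, ((series$d_obs - series$d_rep) - gap) /
                   (gap * series$N)))
  new_fit_index_result("BRMSEA_ppmc", x)
}

#' Bayesian RMSEA, deviance form
#'
#' Per draw \eqn{\sqrt{\max(0, (D_i^{obs} - p^*) / ((p^* - pD) N))}}.
#'
#' @param series A `discrepancy_series`.
#' @return A `fit_index_result`.
#' @export
brmsea_devm <- function(series) {
  check_pd_gap(series)
  gap <- series$p_star - series$pD
  x <- sqrt(pmax(0, (series$d_obs - series$p_star) / (gap * series$N)))
  new_fit_index_result("BRMSEA_devm", x)
}

#' Bayesian comparative fit index
#'
#' Per draw \eqn{1 - (D_{H,i}^{obs} - p^*) / (D_{o,i}^{obs} - p^*)}
#' against the independence-model series; draws are clamped to [0, 1] for
#' summaries. Draws whose null discrepancy equals p* are flagged invalid.
#'
#' @param series Hypothesized-model `discrepancy_series`.
#' @param null_fit Output of [fit_null_model()] of matching length.
#' @return A `fit_index_result`.
#' @export
bcfi <- function(series, null_fit) {
  stopifnot(length(null_fit$d_obs) == series$m)
  den <- null_fit$d_obs - series$p_star
  x <- 1 - (series$d_obs - series$p_star) / den
  x[abs(den) < sqrt(.Machine$double.eps)] <- NA_real_
  new_fit_index_result("BCFI", pmin(1, pmax(0, x)))
}

#' Bayesian Tucker-Lewis index
#'
#' Per draw, with \eqn{R_o = (D_{o,i}^{obs} - pD_o)/(p^* - pD_o)} and
#' \eqn{R_H = (D_{H,i}^{obs} - pD_H)/(p^* - pD_H)}, BTLI is
#' \eqn{(R_o - R_H)/(R_o - 1)}. Unclamped; draws with \eqn{R_o = 1}
#' are flagged invalid.
#'
#' @inheritParams bcfi
#' @return A `fit_index_result`.
#' @export
btli <- function(series, null_fit) {
  stopifnot(length(null_fit$d_obs) == series$m)
  check_pd_gap(series)
  if (null_fit$p_star <= null_fit$pD)
    stop("p* <= pD for the null model")
  r_o <- (null_fit$d_obs - null_fit$pD) / (series$p_star - null_fit$pD)
  r_h <- (series$d_obs - series$pD) / (series$p_star - series$pD)
  x <- (r_o - r_h) / (r_o - 1)
  x[abs(r_o - 1) < sqrt(.Machine$double.eps)] <- NA_real_
  new_fit_index_result("BTLI", x)
}

#' Cutoff and credible-interval decisions for a fit index
#'
#' Rejection uses the posterior mean (the scalar value for PPp): BRMSEA
#' above 0.06, BCFI/BTLI below 0.95, PPp outside (0.05, 0.95). The 90%
#' credible-interval classification: BCFI/BTLI are good when the lower
#' bound is at least 0.95 and poor when the upper bound is below 0.95;
#' BRMSEA is good when the upper bound is below 0.06 and poor when the
#' lower bound is at least 0.06; anything else is inconclusive.
#'
#' @param result A `fit_index_result` (or list with `mean`, `ci90`, `ppp`).
#' @param index_name One of `"BRMSEA"`, `"BCFI"`, `"BTLI"`, `"PPp"`
#'   (BRMSEA variants may carry suffixes).
#' @return List with `rejected` (logical) and `ci_class`.
#' @export
decide <- function(result, index_name = result$index) {
  lo <- result$ci90[1]; hi <- result$ci90[2]
  if (grepl("^BRMSEA", index_name)) {
    list(rejected = result$mean > 0.06,
         ci_class = if (hi < 0.06) "good"
                    else if (lo >= 0.06) "poor" else "inconclusive")
  } else if (index_name %in% c("BCFI", "BTLI")) {
    list(rejected = result$mean < 0.95,
         ci_class = if (lo >= 0.95) "good"
                    else if (hi < 0.95) "poor" else "inconclusive")
  } else if (index_name == "PPp") {
    list(rejected = result$ppp < 0.05 || result$ppp > 0.95,
         ci_class = NA_character_)
  } else stop("unknown index: ", index_name)
}

#' Fit a Bayesian CFA and compute all fit indices
#'
#' Convenience wrapper: samples the posterior, fits the independence null
#' model with the same number of retained draws, builds the discrepancy
#' series, and returns every index with its decision.
#'
#' @param data n x p data matrix.
#' @param model Analysis-form `cfa_model_spec`.
#' @param prior A `prior_spec`.
#' @param settings An [mcmc_settings()].
#' @param seed Seed for the replicated-data and null-model draws (the
#'   sampler itself is seeded through `settings`).
#' @return List with `draws`, `series`, `null_fit`, and `indices` (named
#'   list: PPp, BRMSEA_ppmc, BRMSEA_devm, BCFI, BTLI), plus `converged`.
#' @export
bayes_fit_indices <- function(data, model, prior,
                              settings = mcmc_settings(), seed = NULL) {
  draws <- sample_posterior(data, model, prior, settings)
  series <- discrepancy_series(data, draws,
                               seed = if (is.null(seed)) NULL else seed + 1L)
  null_fit <- fit_null_model(data, m = draws$m,
                             seed = if (is.null(seed)) NULL else seed + 2L)
  indices <- list(
    PPp = ppp(series),
    BRMSEA_ppmc = brmsea_ppmc(series),
    BRMSEA_devm = brmsea_devm(series),
    BCFI = bcfi(series, null_fit),
    BTLI = btli(series, null_fit))
  list(draws = draws, series = series, null_fit = null_fit,
       indices = indices, converged = draws$converged)
}
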