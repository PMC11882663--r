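test_that("the chi-square discrepancy matches hand evaluation and the
           saturated point", {
  expect_equal(chi_square_discrepancy(c(0, 0), diag(2), c(0, 0),
                                      diag(2, 2), 100),
               100 * (log(4) - 1))
  s <- matrix(c(1, 0.3, 0.3, 1), 2, 2)
  expect_equal(chi_square_discrepancy(c(0.1, -0.2), s, c(0.1, -0.2), s,
                                      50), 0)
  set.seed(11)
  for (r in 1:10) {
    p <- sample(2:4, 1)
    a <- matrix(stats::rnorm(p * p), p)
    sc <- crossprod(a) / p + diag(p)
    mc <- crossprod(matrix(stats::rnorm(p * p), p)) / p + diag(p)
    expect_gte(chi_square_discrepancy(stats::rnorm(p), sc,
                                      stats::rnorm(p), mc, 30), 0)
  }
})

test_that("the discrepancy equals the observation-wise -2 log-likelihood
           ratio", {
  set.seed(23)
  for (r in 1:5) {
    p <- sample(2:4, 1); n <- 40
    X <- matrix(stats::rnorm(n * p), n, p)
    mu <- stats::rnorm(p, sd = 0.3)
    sigma <- crossprod(matrix(stats::rnorm(p * p), p)) / p + diag(p)
    mom <- bsemfit:::sample_moments(X)
    d <- chi_square_discrepancy(mom$mean, mom$cov, mu, sigma, n)
    expect_equal(d, neg2_loglik_ratio(X, mu, sigma), tolerance = 1e-8)
  }
})

test_that("ppp counts exceedances", {
  s <- fake_series(d_obs = c(1, 2, 3), d_rep = c(2, 3, 4),
                   p_star = 10, pD = 3, N = 100)
  expect_equal(ppp(s)$ppp, 1)
  s2 <- fake_series(d_obs = c(1, 4), d_rep = c(2, 3),
                    p_star = 10, pD = 3, N = 100)
  expect_equal(ppp(s2)$ppp, 0.5)
  expect_false(decide(ppp(s2), "PPp")$rejected)
})

test_that("BRMSEA forms obey their algebraic identities", {
  p_star <- 120; pD <- 30; N <- 200
  gap <- p_star - pD
  # DevM: zero at d_obs = p*, one at d_obs = p* + gap * N
  s <- fake_series(d_obs = c(p_star, p_star + gap * N, p_star - 50),
                   p_star = p_star, pD = pD, N = N)
  expect_equal(brmsea_devm(s)$draws, c(0, 1, 0))
  # PPMC floor and the 1/sqrt(N) point at d_obs - d_rep = 2 * gap
  s2 <- fake_series(d_obs = c(100, 100 + 2 * gap), d_rep = c(100, 100),
                    p_star = p_star, pD = pD, N = N)
  expect_equal(brmsea_ppmc(s2)$draws, c(0, 1 / sqrt(N)))
  # the two coincide draw-wise when d_rep = pD
  s3 <- fake_series(d_obs = c(150, 300, 90), d_rep = rep(pD, 3),
                    p_star = p_star, pD = pD, N = N)
  expect_equal(brmsea_ppmc(s3)$draws, brmsea_devm(s3)$draws)
  expect_true(all(brmsea_devm(s3)$draws >= 0))
  bad <- fake_series(d_obs = 1, p_star = 10, pD = 11, N = 10)
  expect_error(brmsea_devm(bad), "p\\*")
})

test_that("BCFI and BTLI follow their definitions at anchor points", {
  p_star <- 120; N <- 200
  null_fit <- list(d_obs = c(500, 400, 500), pD = 15, p_star = p_star,
                   N = N)
  s <- fake_series(d_obs = c(p_star, 400, 600), p_star = p_star, pD = 30,
                   N = N)
  b <- bcfi(s, null_fit)
  expect_equal(b$draws[1], 1)             # d_obs = p*
  expect_equal(b$draws[2], 0)             # d_obs = null d_obs
  expect_equal(b$draws[3], 0)             # clamped below zero
  expect_true(all(b$draws >= 0 & b$draws <= 1))

  # BTLI = 1 when R_H = 1, 0 when R_H = R_o
  gap_h <- p_star - 30
  d_obs_rh1 <- 30 + gap_h                 # R_H = 1
  r_o <- (500 - 15) / (p_star - 15)
  d_obs_req <- 30 + r_o * gap_h           # R_H = R_o
  s2 <- fake_series(d_obs = c(d_obs_rh1, d_obs_req), p_star = p_star,
                    pD = 30, N = N)
  nf2 <- list(d_obs = c(500, 500), pD = 15, p_star = p_star, N = N)
  expect_equal(btli(s2, nf2)$draws, c(1, 0))
  # R_o = 1 draws flagged invalid
  nf3 <- list(d_obs = c(15 + (p_star - 15), 500), pD = 15,
              p_star = p_star, N = N)
  expect_equal(btli(s2, nf3)$n_invalid, 1L)
})

test_that("cutoff and credible-interval decisions follow the standard
           rules", {
  mk <- function(mean, ci) list(mean = mean, ci90 = ci, ppp = NA)
  expect_equal(decide(mk(0.97, c(0.96, 0.99)), "BCFI")$ci_class, "good")
  expect_equal(decide(mk(0.90, c(0.85, 0.94)), "BCFI")$ci_class, "poor")
  expect_true(decide(mk(0.90, c(0.85, 0.94)), "BCFI")$rejected)
  expect_equal(decide(mk(0.05, c(0.02, 0.08)), "BRMSEA_devm")$ci_class,
               "inconclusive")
  expect_equal(decide(mk(0.03, c(0.01, 0.05)), "BRMSEA_devm")$ci_class,
               "good")
  expect_true(decide(mk(0.07, c(0.065, 0.09)), "BRMSEA_devm")$rejected)
  expect_equal(decide(mk(0.07, c(0.065, 0.09)), "BRMSEA_ppmc")$ci_class,
               "poor")
  expect_true(decide(list(mean = NA, ci90 = c(NA, NA), ppp = 0.97),
                     "PPp")$rejected)
  expect_error(decide(mk(1, c(0, 1)), "WRMR"), "unknown index")
})

test_that("the null-model fit is exact-conjugate, seeded, and has pD near
           the variance count", {
  gen <- toy_model()
  X <- generate_data(gen, 2000, seed = 17)
  nf1 <- fit_null_model(X, m = 4000, seed = 5)
  nf2 <- fit_null_model(X, m = 4000, seed = 5)
  expect_identical(nf1$d_obs, nf2$d_obs)
  p <- ncol(X)
  expect_lt(abs(nf1$pD - p) / p, 0.15)
  expect_true(all(nf1$d_obs >= 0))
  withrep <- fit_null_model(X, m = 50, seed = 6, include_rep = TRUE)
  expect_length(withrep$d_rep, 50)
  expect_true(all(withrep$d_rep >= 0))
})

test_that("the discrepancy series is seeded and internally consistent", {
  gen <- toy_model()
  analysis <- misspecify(gen)
  prior <- make_prior("Diffuse", gen, analysis)
  X <- generate_data(gen, 150, seed = 8)
  draws <- sample_posterior(X, analysis, prior, quick_settings(2, 200L))
  s1 <- discrepancy_series(X, draws, seed = 99)
  s2 <- discrepancy_series(X, draws, seed = 99)
  expect_identical(s1$d_rep, s2$d_rep)
  expect_identical(s1$d_obs, s2$d_obs)
  expect_equal(s1$p_star, 21)
  expect_equal(s1$m, draws$m)
  expect_true(all(s1$d_obs >= 0) && all(s1$d_rep >= 0))
  expect_gt(mean(s1$d_rep), 0)
  # pD identity against the exported helper
  pe <- point_estimates(draws)
  expect_equal(s1$pD, effective_params(s1$d_obs, pe, X), tolerance = 1e-10)
  pp <- ppp(s1)
  expect_gte(pp$ppp, 0)
  expect_lte(pp$ppp, 1)
})
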