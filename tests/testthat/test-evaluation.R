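make_result <- function(rejected_flags, ci_classes = NULL, index = "BCFI") {
  reps <- lapply(seq_along(rejected_flags), function(i)
    data.frame(index = index, mean = 0.9, sd = 0.01, ci_lo = 0.88,
               ci_hi = 0.92, ppp = NA_real_,
               rejected = rejected_flags[i],
               ci_class = if (is.null(ci_classes)) "inconclusive"
                          else ci_classes[i],
               replication = i, seed = i, pD = 30,
               stringsAsFactors = FALSE))
  structure(list(condition = data.frame(condition_id = "toy"),
                 replications = reps,
                 n_converged = length(reps),
                 n_attempted = length(reps)),
            class = "condition_result")
}

test_that("rejection rates count flagged replications", {
  expect_equal(rejection_rates(make_result(rep(TRUE, 4)))$rate, 1)
  expect_equal(rejection_rates(make_result(rep(FALSE, 4)))$rate, 0)
  mixed <- rejection_rates(make_result(c(TRUE, TRUE, TRUE, rep(FALSE, 7))),
                           is_correctly_specified = TRUE)
  expect_equal(mixed$rate, 0.3)
  expect_equal(mixed$rate_type, "false_positive")
  empty <- make_result(logical(0))
  empty$n_converged <- 0L
  expect_error(rejection_rates(empty), "no converged")
})

test_that("eta squared matches a brute-force sums-of-squares
           decomposition", {
  # all identical -> every effect zero
  same <- data.frame(value = rep(1, 8), a = rep(c("x", "y"), 4),
                     b = rep(c("u", "v"), each = 4))
  expect_true(all(eta_squared(same, c("a", "b"))$eta_squared == 0))

  # two-group toy with no within-group variance
  toy <- data.frame(value = c(0, 0, 1, 1), a = c("A", "A", "B", "B"))
  expect_equal(eta_squared(toy, "a", formula_rhs = "a")$eta_squared, 1)

  # balanced two-way layout vs direct SS computation
  set.seed(14)
  g <- expand.grid(a = c("a1", "a2"), b = c("b1", "b2", "b3"),
                   rep = 1:5, stringsAsFactors = FALSE)
  eff_a <- c(a1 = -0.5, a2 = 0.5)
  eff_b <- c(b1 = -1, b2 = 0, b3 = 1)
  g$value <- eff_a[g$a] + eff_b[g$b] +
    ifelse(g$a == "a2" & g$b == "b3", 0.7, 0) + stats::rnorm(nrow(g), 0, 0.3)
  res <- eta_squared(g, c("a", "b"))
  ss_total <- sum((g$value - mean(g$value))^2)
  cell_mean <- function(f) tapply(g$value, g[[f]], mean)
  n_per <- nrow(g) / 2
  ss_a <- sum(2 * 15 * (cell_mean("a") - mean(g$value))^2)
  ss_b <- sum(2 * 10 * (cell_mean("b") - mean(g$value))^2)
  # brute force: per-level counts
  ss_a <- sum(tapply(g$value, g$a, length) *
                (cell_mean("a") - mean(g$value))^2)
  ss_b <- sum(tapply(g$value, g$b, length) *
                (cell_mean("b") - mean(g$value))^2)
  ab_mean <- tapply(g$value, interaction(g$a, g$b), mean)
  ss_cells <- sum(5 * (ab_mean - mean(g$value))^2)
  ss_ab <- ss_cells - ss_a - ss_b
  expect_equal(res$eta_squared[res$effect == "a"], ss_a / ss_total,
               tolerance = 1e-12)
  expect_equal(res$eta_squared[res$effect == "b"], ss_b / ss_total,
               tolerance = 1e-12)
  expect_equal(res$eta_squared[res$effect == "a:b"], ss_ab / ss_total,
               tolerance = 1e-12)
  expect_true(all(res$moderate == (res$eta_squared > 0.0588)))
})

test_that("unbalanced cells are subsampled to balance deterministically", {
  g <- data.frame(value = stats::rnorm(30),
                  a = rep(c("x", "y"), c(10, 20)))
  r1 <- eta_squared(g, "a", formula_rhs = "a", balance_seed = 3)
  r2 <- eta_squared(g, "a", formula_rhs = "a", balance_seed = 3)
  expect_equal(r1, r2)
})

test_that("study summaries aggregate with the sample-SD convention", {
  r1 <- make_result(c(TRUE, FALSE))
  r1$replications[[1]]$mean <- 0.9
  r1$replications[[2]]$mean <- 1.0
  s <- summarize_study(list(r1))
  expect_equal(s$mean_sd$mean, 0.95)
  expect_equal(s$mean_sd$sd, stats::sd(c(0.9, 1.0)))
  expect_equal(s$mean_sd$sd, 0.0707, tolerance = 1e-3)
  expect_equal(s$rejection$rate, 0.5)
  ci <- summarize_study(list(make_result(rep(FALSE, 4),
                                         c("good", "good", "poor",
                                           "inconclusive"))))$ci_class
  expect_equal(ci$good + ci$poor + ci$inconclusive, 1)
  empty <- summarize_study(list())
  expect_equal(nrow(empty$mean_sd), 0L)
})

test_that("run_condition is deterministic and replaces non-converged
           replications", {
  grid <- build_condition_grid(1)
  cond <- grid[grid$family == "A" & grid$factor_corr == 0.85 &
                 grid$analysis == "correct" & grid$n == 75 &
                 grid$prior == "AlignedSV", ]
  # short initial run with headroom so the PSR controller can extend
  st <- mcmc_settings(n_chains = 3, min_iterations = 400L,
                      max_iterations = 2000L, seed = 1)
  r1 <- run_condition(cond, n_reps = 2, settings = st, base_seed = 5,
                      condition_index = 3L)
  r2 <- run_condition(cond, n_reps = 2, settings = st, base_seed = 5,
                      condition_index = 3L)
  expect_identical(summarize_study(list(r1))$mean_sd,
                   summarize_study(list(r2))$mean_sd)
  expect_equal(r1$n_converged, 2L)
  expect_gte(r1$n_attempted, r1$n_converged)
  tab <- do.call(rbind, r1$replications)
  expect_setequal(unique(tab$index),
                  c("PPp", "BRMSEA_ppmc", "BRMSEA_devm", "BCFI", "BTLI"))
  # summaries only use converged replications by construction
  expect_true(all(tab$pD > 0))
})

test_that("an inaccurate informative prior inflates false positives in
           small samples relative to the diffuse prior", {
  grid <- build_condition_grid(1)
  st <- mcmc_settings(3, 1000L, 4000L, seed = 1)
  pick <- function(prior) grid[grid$family == "A" &
                                 grid$factor_corr == 0.85 &
                                 grid$analysis == "correct" &
                                 grid$n == 75 & grid$prior == prior, ]
  r_dsv <- run_condition(pick("DivergentSV"), n_reps = 10, settings = st,
                         base_seed = 88, condition_index = 1L)
  r_dif <- run_condition(pick("Diffuse"), n_reps = 10, settings = st,
                         base_seed = 88, condition_index = 2L)
  fpr <- function(res, idx) {
    tab <- do.call(rbind, res$replications)
    mean(tab$rejected[tab$index == idx])
  }
  for (idx in c("BRMSEA_devm", "BCFI", "BTLI"))
    expect_gte(fpr(r_dsv, idx), fpr(r_dif, idx))
  expect_gt(mean(vapply(c("BRMSEA_devm", "BCFI", "BTLI"),
                        function(i) fpr(r_dsv, i), 1.0)),
            mean(vapply(c("BRMSEA_devm", "BCFI", "BTLI"),
                        function(i) fpr(r_dif, i), 1.0)))
})

test_that("power to flag small ignored cross-loadings is low at large n", {
  grid <- build_condition_grid(1)
  cond <- grid[grid$family == "B" & grid$cross_loading == 0.2 &
                 grid$analysis == "severe" & grid$n == 2000 &
                 grid$prior == "Diffuse", ]
  st <- mcmc_settings(3, 2000L, 2000L, seed = 1)
  res <- run_condition(cond, n_reps = 6, settings = st, base_seed = 91,
                       condition_index = 4L)
  tab <- do.call(rbind, res$replications)
  # population RMSEA 0.041 sits below the 0.06 cutoff, so the true
  # positive rate collapses once sampling error shrinks
  expect_lt(mean(tab$rejected[tab$index == "BRMSEA_devm"]), 0.5)
})

test_that("summary CSV writers emit the four tables", {
  dir <- withr::local_tempdir()
  s <- summarize_study(list(make_result(c(TRUE, FALSE))))
  paths <- write_study_summary(s, dir, format = c("csv", "json"))
  expect_true(all(file.exists(file.path(dir, c("mean_sd.csv",
                                               "rejection.csv",
                                               "ci_class.csv",
                                               "convergence.csv",
                                               "summary.json")))))
  parsed <- jsonlite::read_json(file.path(dir, "summary.json"))
  expect_equal(parsed$mean_sd[[1]]$mean, s$mean_sd$mean[1])
})
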