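test_that("generation models carry the printed loading patterns", {
  a <- build_generation_model("A", 0.85)
  expect_equal(dim(a$loadings), c(15L, 3L))
  block <- c(0.70, 0.70, 0.75, 0.80, 0.80)
  for (f in 1:3)
    expect_equal(a$loadings[(5 * f - 4):(5 * f), f], block)
  expect_equal(sum(a$loadings != 0), 15L)
  expect_true(all(a$factor_corr[lower.tri(a$factor_corr)] == 0.85))

  b <- build_generation_model("B", cross_loading = 0.5)
  expect_equal(b$factor_corr[2, 1], 0.5)
  expect_equal(b$loadings[5, 2], 0.5)
  expect_equal(b$loadings[9, 3], 0.5)
  expect_equal(b$loadings[15, 1], 0.5)
  expect_equal(sum(b$loadings != 0), 18L)

  d2 <- build_generation_model("D2")
  expect_equal(d2$n_factors, 6L)
  expect_equal(d2$n_items, 30L)
  expect_equal(nrow(d2$cross_loadings), 6L)
  expect_equal(sort(table(d2$cross_loadings$factor)), sort(table(1:6)))

  c3 <- build_generation_model("C3")
  expect_equal(c3$loadings[6:10, 1], block)  # ten-item factors repeat block
})

test_that("generation model arguments are validated", {
  expect_error(build_generation_model("Z", 0.5), "unknown")
  expect_error(build_generation_model("A", 1.2), "factor_corr")
  expect_error(build_generation_model("A"), "requires factor_corr")
  expect_error(build_generation_model("B", cross_loading = -0.1), ">= 0")
})

test_that("implied covariance matches direct arithmetic", {
  a <- build_generation_model("A", 0.85)
  sigma <- implied_covariance(a)
  expect_equal(diag(sigma), rep(1, 15))          # unit item variances
  expect_equal(sigma[1, 2], 0.49)                # same factor: 0.7 * 0.7
  expect_equal(sigma[1, 6], 0.7 * 0.7 * 0.85)    # across factors
  expect_equal(sigma, t(sigma))
})

test_that("every study generation model has a positive-definite implied
           covariance", {
  gens <- c(lapply(c(0.35, 0.5, 0.85), function(r)
              build_generation_model("A", r)),
            lapply(c(0.2, 0.5), function(cl)
              build_generation_model("B", cross_loading = cl)),
            lapply(c("C1", "C2", "C3", "D1", "D2", "D3"),
                   build_generation_model))
  for (g in gens) {
    ev <- eigen(implied_covariance(g), symmetric = TRUE,
                only.values = TRUE)$values
    expect_gt(min(ev), 0)
  }
})

test_that("dimensionality misspecification reassigns items as designed", {
  a <- build_generation_model("A", 0.85)
  one <- misspecify(a, misspecification_plan("dimensionality", 1))
  expect_equal(one$n_factors, 1L)
  expect_true(all(one$free_mask[, 1]))

  two <- misspecify(a, misspecification_plan("dimensionality", 2))
  expect_equal(which(two$free_mask[, 1]), 1:5)
  expect_equal(which(two$free_mask[, 2]), 6:15)

  c1 <- build_generation_model("C1")
  c12 <- misspecify(c1, misspecification_plan("dimensionality", 2))
  expect_equal(which(c12$free_mask[, 1]), 1:15)  # balanced 15/15 split
  c22 <- misspecify(build_generation_model("C2"),
                    misspecification_plan("dimensionality", 4))
  expect_equal(unname(colSums(c22$free_mask)), c(8, 8, 7, 7))

  expect_error(misspecify(a, misspecification_plan("dimensionality", 3)),
               "smaller")
  expect_error(
    misspecify(a, misspecification_plan("dimensionality", 2,
                                        merge_map = c(1L, 1L, 1L))),
    "merge_map")
})

test_that("cross-loading misspecification drops paths in interleaved
           order", {
  b <- build_generation_model("B", cross_loading = 0.5)
  none <- misspecify(b, misspecification_plan("cross_loading",
                                              retained_cross_loadings = 0))
  expect_equal(sum(none$free_mask), 15L)         # independent-cluster mask
  keep2 <- misspecify(b, misspecification_plan("cross_loading",
                                               retained_cross_loadings = 2))
  expect_equal(sum(keep2$free_mask), 17L)
  expect_false(keep2$free_mask[5, 2])            # head of list dropped

  d1 <- build_generation_model("D1")
  keep4 <- misspecify(d1, misspecification_plan("cross_loading",
                                                retained_cross_loadings = 4))
  dropped <- setdiff(seq_len(nrow(d1$cross_loadings)), 0)
  dropped_items <- d1$cross_loadings$item[1:2]
  expect_equal(dropped_items, c(9L, 19L))        # one per factor
  for (i in dropped_items)
    expect_equal(sum(keep4$free_mask[i, ]), 1L)

  expect_error(
    misspecify(b, misspecification_plan("cross_loading",
                                        retained_cross_loadings = 4)),
    "0..3")
})

test_that("free-parameter counts follow the covariance-structure
           convention", {
  a1 <- misspecify(build_generation_model("A", 0.85))
  expect_equal(count_free_parameters(a1), 33L)   # 15 + 3 + 15
  expect_equal(count_free_parameters(a1, include_intercepts = TRUE), 48L)
  a3 <- misspecify(build_generation_model("A", 0.85),
                   misspecification_plan("dimensionality", 1))
  expect_equal(count_free_parameters(a3), 30L)
})

test_that("model specs survive a YAML round trip", {
  b <- build_generation_model("B", cross_loading = 0.2)
  path <- withr::local_tempfile(fileext = ".yaml")
  model_spec_to_yaml(b, path)
  back <- model_spec_from_yaml(path)
  expect_equal(back$loadings, b$loadings)
  expect_equal(back$free_mask, b$free_mask)
  expect_equal(back$factor_corr, b$factor_corr)
  expect_equal(back$residual_variances, b$residual_variances)
  expect_equal(back$cross_loadings$item, b$cross_loadings$item)
})
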