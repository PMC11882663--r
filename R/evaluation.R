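#' Run all replications of one simulation condition
#'
#' For each replication: generate a dataset from the condition's population
#' model, fit the hypothesized (analysis) model by Gibbs sampling, fit the
#' independence null model, compute the discrepancy series and every fit
#' index with its decisions. Replications that fail PSR convergence are
#' recorded and replaced by moving to the next replication index, so the
#' summary is always over `n_reps` converged solutions (up to the attempt
#' cap). Fully deterministic given `base_seed`.
#'
#' @param condition One row of [build_condition_grid()] (or any data frame
#'   row with the same columns).
#' @param n_reps Number of converged replications required.
#' @param settings An [mcmc_settings()]; its `seed` field is ignored in
#'   favor of the per-replication stream.
#' @param base_seed Integer study-level seed.
#' @param condition_index Integer used in the seed stream (defaults to 1;
#'   pass the row number when running a grid).
#' @param max_attempts Abort after this many total attempts (default
#'   `5 * n_reps`).
#' @return A `condition_result`: list with `condition`, `replications`
#'   (per-replication index summaries), `n_converged`, `n_attempted`.
#' @export
run_condition <- function(condition, n_reps, settings = mcmc_settings(),
                          base_seed = 1L, condition_index = 1L,
                          max_attempts = 5L * n_reps) {
  models <- condition_models(condition)
  prior <- make_prior(as.character(condition$prior), models$generation,
                      models$analysis)
  reps <- list()
  attempt <- 0L
  n_attempted <- 0L
  while (length(reps) < n_reps && attempt < max_attempts) {
    attempt <- attempt + 1L
    seed <- replication_seed(base_seed, condition_index, attempt)
    X <- generate_data(models$generation, condition$n, seed = seed,
                       condition_id = condition$condition_id,
                       replication = attempt)
    fit_settings <- settings
    fit_settings$seed <- replication_seed(base_seed, condition_index,
                                          attempt + 1000000L)
    # numerical failures (non-positive-definite conditionals) abort the
    # replication and are treated like PSR non-convergence: replaced
    fit <- tryCatch(
      bayes_fit_indices(X, models$analysis, prior, fit_settings,
                        seed = replication_seed(base_seed, condition_index,
                                                attempt + 2000000L)),
      error = function(e) NULL)
    n_attempted <- n_attempted + 1L
    if (is.null(fit) || !fit$converged) next
    reps[[length(reps) + 1L]] <- summarize_replication(fit, attempt, seed)
  }
  if (length(reps) < n_reps)
    warning(sprintf("condition %s: only %d of %d replications converged",
                    condition$condition_id, length(reps), n_reps))
  structure(list(condition = condition, replications = reps,
                 n_converged = length(reps), n_attempted = n_attempted),
            class = "condition_result")
}

summarize_replication <- function(fit, replication, seed) {
  rows <- lapply(fit$indices, function(r)
    data.frame(index = r$index, mean = r$mean, sd = r$sd,
               ci_lo = r$ci90[1], ci_hi = r$ci90[2], ppp = r$ppp,
               rejected = r$rejected, ci_class = r$ci_class,
               stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  out$replication <- replication
  out$seed <- seed
  out$pD <- fit$series$pD
  rownames(out) <- NULL
  out
}

#' Per-index rejection rates of a condition
#'
#' Proportion of converged replications whose index flagged misfit: the
#' false positive rate when the model is correctly specified, the true
#' positive rate when it is misspecified.
#'
#' @param result A `condition_result`.
#' @param is_correctly_specified Labels the rate in the output.
#' @return Data frame with `index`, `rate`, `rate_type`, `n`.
#' @export
rejection_rates <- function(result, is_correctly_specified = NA) {
  if (result$n_converged < 1L) stop("no converged replications")
  tab <- do.call(rbind, result$replications)
  agg <- stats::aggregate(rejected ~ index, tab, mean)
  data.frame(index = agg$index, rate = agg$rejected,
             rate_type = if (isTRUE(is_correctly_specified))
               "false_positive" else if (isFALSE(is_correctly_specified))
                 "true_positive" else NA_character_,
             n = result$n_converged, stringsAsFactors = FALSE)
}

#' Eta-squared effect sizes from a factorial ANOVA
#'
#' Fits a fixed-effects factorial ANOVA to replication-level index values
#' and returns \eqn{\eta^2 = SS_{effect}/SS_{total}} per effect, flagged at
#' the moderate (0.0588) and large (0.1379) thresholds. Cells are balanced
#' by subsampling every cell to the minimum cell count with a fixed seed
#' (converged replications only), keeping the sums-of-squares decomposition
#' clean.
#'
#' @param values Data frame with a numeric `value` column and factor
#'   columns named in `design_factors`.
#' @param design_factors Character vector of factor column names.
#' @param formula_rhs Right-hand side of the model formula (default: all
#'   main effects plus all two-way interactions).
#' @param balance_seed Seed for the balancing subsample.
#' @return Data frame with `effect`, `eta_squared`, `moderate`, `large`.
#' @export
eta_squared <- function(values, design_factors,
                        formula_rhs = NULL, balance_seed = 1L) {
  stopifnot(all(design_factors %in% names(values)), "value" %in% names(values))
  df <- values
  for (f in design_factors) df[[f]] <- factor(df[[f]])
  cell <- interaction(df[design_factors], drop = TRUE)
  min_n <- min(table(cell))
  if (min_n < 1L) stop("empty design cell")
  if (length(unique(table(cell))) > 1L) {
    old_seed <- if (exists(".Random.seed", globalenv()))
      get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old_seed))
      assign(".Random.seed", old_seed, globalenv()), add = TRUE)
    set.seed(balance_seed)
    keep <- unlist(lapply(split(seq_len(nrow(df)), cell),
                          function(ix) sample(ix, min_n)))
    df <- df[keep, , drop = FALSE]
  }
  if (is.null(formula_rhs))
    formula_rhs <- paste0("(", paste(design_factors, collapse = " + "),
                          ")^2")
  form <- stats::as.formula(paste("value ~", formula_rhs))
  fit <- stats::aov(form, data = df)
  ss <- summary(fit)[[1]][["Sum Sq"]]
  effects <- trimws(rownames(summary(fit)[[1]]))
  ss_total <- sum((df$value - mean(df$value))^2)
  eta <- if (ss_total < .Machine$double.eps) rep(0, length(ss))
         else ss / ss_total
  keep <- effects != "Residuals"
  data.frame(effect = effects[keep], eta_squared = eta[keep],
             moderate = eta[keep] > 0.0588, large = eta[keep] > 0.1379,
             stringsAsFactors = FALSE)
}

#' Summarize a set of condition results
#'
#' Builds the study-level tables: mean/SD of every index across converged
#' replications per condition, rejection rates, 90% credible-interval
#' classification proportions, and convergence rates.
#'
#' @param results List of `condition_result` objects.
#' @return A `study_summary`: list of data frames `mean_sd`,
#'   `rejection`, `ci_class`, `convergence`, and the stacked
#'   replication-level table `replications`.
#' @export
summarize_study <- function(results) {
  if (length(results) == 0L)
    return(structure(list(mean_sd = data.frame(), rejection = data.frame(),
                          ci_class = data.frame(),
                          convergence = data.frame(),
                          replications = data.frame()),
                     class = "study_summary"))
  long <- do.call(rbind, lapply(results, function(res) {
    if (res$n_converged == 0L) return(NULL)
    tab <- do.call(rbind, res$replications)
    tab$condition_id <- res$condition$condition_id
    tab
  }))
  mean_sd <- do.call(rbind, lapply(split(long, long[c("condition_id",
                                                      "index")]),
    function(g) if (nrow(g)) data.frame(
      condition_id = g$condition_id[1], index = g$index[1],
      mean = mean(g$mean), sd = stats::sd(g$mean), n = nrow(g),
      stringsAsFactors = FALSE)))
  rejection <- do.call(rbind, lapply(split(long, long[c("condition_id",
                                                        "index")]),
    function(g) if (nrow(g)) data.frame(
      condition_id = g$condition_id[1], index = g$index[1],
      rate = mean(g$rejected), n = nrow(g), stringsAsFactors = FALSE)))
  with_ci <- long[!is.na(long$ci_class), ]
  ci_class <- do.call(rbind, lapply(split(with_ci,
                                          with_ci[c("condition_id",
                                                    "index")]),
    function(g) if (nrow(g)) data.frame(
      condition_id = g$condition_id[1], index = g$index[1],
      good = mean(g$ci_class == "good"),
      poor = mean(g$ci_class == "poor"),
      inconclusive = mean(g$ci_class == "inconclusive"),
      stringsAsFactors = FALSE)))
  convergence <- do.call(rbind, lapply(results, function(res)
    data.frame(condition_id = res$condition$condition_id,
               n_converged = res$n_converged,
               n_attempted = res$n_attempted,
               rate = res$n_converged / max(1L, res$n_attempted),
               stringsAsFactors = FALSE)))
  rownames(mean_sd) <- rownames(rejection) <- NULL
  if (!is.null(ci_class)) rownames(ci_class) <- NULL
  structure(list(mean_sd = mean_sd, rejection = rejection,
                 ci_class = ci_class, convergence = convergence,
                 replications = long),
            class = "study_summary")
}

#' Write the study summary tables as CSV files
#'
#' @param summary A `study_summary`.
#' @param dir Output directory (created if missing).
#' @param format `"csv"` (one file per table) and/or `"json"` (one file
#'   holding all tables).
#' @return Invisibly, the paths written.
#' @export
write_study_summary <- function(summary, dir, format = "csv") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tables <- c("mean_sd", "rejection", "ci_class", "convergence")
  paths <- c()
  if ("csv" %in% format) {
    for (nm in tables) {
      path <- file.path(dir, paste0(nm, ".csv"))
      utils::write.csv(summary[[nm]], path, row.names = FALSE)
      paths <- c(paths, path)
    }
  }
  if ("json" %in% format) {
    path <- file.path(dir, "summary.json")
    jsonlite::write_json(summary[tables], path, dataframe = "rows",
                         digits = NA)
    paths <- c(paths, path)
  }
  invisible(paths)
}
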