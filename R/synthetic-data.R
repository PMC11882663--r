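#' Generate a multivariate-normal replication dataset
#'
#' Draws `n` i.i.d. observations from the population model's implied
#' distribution: mean equal to the intercepts (zero in the study designs)
#' and covariance `implied_covariance(spec)`. The same seed yields
#' bit-identical output; the caller's RNG state is left untouched.
#'
#' @param spec Population `cfa_model_spec`.
#' @param n Sample size (>= 2).
#' @param seed Integer seed; `NULL` uses (and advances) the current RNG.
#' @param condition_id,replication Optional bookkeeping labels stored on
#'   the result.
#' @return A `cfa_dataset`: numeric n x p matrix with attributes
#'   `condition_id`, `replication`, `seed`.
#' @export
generate_data <- function(spec, n, seed = NULL, condition_id = NA_character_,
                          replication = NA_integer_) {
  stopifnot(n >= 2)
  sigma <- implied_covariance(spec)
  if (!is.null(seed)) {
    old_seed <- if (exists(".Random.seed", globalenv()))
      get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old_seed))
      assign(".Random.seed", old_seed, globalenv())
      else rm(".Random.seed", envir = globalenv()), add = TRUE)
    set.seed(seed)
  }
  p <- spec$n_items
  z <- matrix(stats::rnorm(n * p), n, p)
  x <- z %*% chol(sigma)
  x <- sweep(x, 2L, spec$intercepts, "+")
  colnames(x) <- paste0("x", seq_len(p))
  structure(x, class = c("cfa_dataset", "matrix", "array"),
            condition_id = condition_id, replication = replication,
            seed = if (is.null(seed)) NA_integer_ else as.integer(seed))
}

#' Per-replication seed stream
#'
#' Counter-based scheme keyed by (base seed, condition index, replication
#' index), so any single replication is reproducible in isolation and
#' non-converged replications can be replaced (by moving to the next
#' replication index) without perturbing the others. Values stay below
#' 2^31 - 1.
#'
#' @param base_seed Integer study-level seed.
#' @param condition Integer condition index (>= 1).
#' @param replication Integer replication index (>= 1).
#' @return Integer seed.
#' @export
replication_seed <- function(base_seed, condition, replication) {
  m <- 2147483647
  s <- (as.numeric(base_seed) %% m) * 1103515245 + condition * 65537 +
    replication * 9973 + 12345
  as.integer(s %% m)
}

#' Study condition grids
#'
#' Enumerates the analysis conditions of the two simulation studies.
#' Study 1: 16 data-generation conditions (model A at factor correlations
#' 0.35/0.85, model B at cross-loadings 0.2/0.5, each at n in
#' 75/200/500/2000) crossed with 3 analysis models and 5 priors, 240 in
#' all. Study 2: 6 generation models (C1--C3, D1--D3) x correct/most-severe
#' analysis x n in 200/500 x 3 priors (Diffuse, AlignedSV, DivergentSV),
#' 72 in all.
#'
#' @param study 1 or 2.
#' @return Data frame with one row per analysis condition: `condition_id`,
#'   `family`, `factor_corr`, `cross_loading`, `analysis` (label),
#'   `n`, `prior`, and list-columns are avoided: generation/analysis models
#'   are rebuilt from the row via [condition_models()].
#' @export
build_condition_grid <- function(study) {
  study <- as.integer(study)
  if (!study %in% c(1L, 2L)) stop("unknown study: ", study)
  if (study == 1L) {
    gen <- rbind(
      expand.grid(family = "A", value = c(0.35, 0.85),
                  stringsAsFactors = FALSE),
      expand.grid(family = "B", value = c(0.2, 0.5),
                  stringsAsFactors = FALSE))
    analyses <- c("correct", "mild", "severe")
    priors <- c("Diffuse", "AlignedSV", "AlignedLV",
                "DivergentSV", "DivergentLV")
    grid <- expand.grid(gi = seq_len(nrow(gen)),
                        n = c(75L, 200L, 500L, 2000L),
                        analysis = analyses, prior = priors,
                        stringsAsFactors = FALSE)
    out <- data.frame(study = 1L,
                      family = gen$family[grid$gi],
                      factor_corr = ifelse(gen$family[grid$gi] == "A",
                                           gen$value[grid$gi], 0.5),
                      cross_loading = ifelse(gen$family[grid$gi] == "B",
                                             gen$value[grid$gi], 0),
                      analysis = grid$analysis, n = grid$n,
                      prior = grid$prior, stringsAsFactors = FALSE)
  } else {
    grid <- expand.grid(family = c("C1", "C2", "C3", "D1", "D2", "D3"),
                        analysis = c("correct", "severe"),
                        n = c(200L, 500L),
                        prior = c("Diffuse", "AlignedSV", "DivergentSV"),
                        stringsAsFactors = FALSE)
    out <- data.frame(study = 2L, family = grid$family,
                      factor_corr = 0.85,
                      cross_loading = ifelse(grepl("^D", grid$family),
                                             0.5, 0),
                      analysis = grid$analysis, n = grid$n,
                      prior = grid$prior, stringsAsFactors = FALSE)
  }
  out$condition_id <- sprintf(
    "s%d_%s%s%s_%s_n%d_%s", out$study, out$family,
    ifelse(out$family == "A", sprintf("_cor%.2f", out$factor_corr), ""),
    ifelse(out$family == "B", sprintf("_cld%.1f", out$cross_loading), ""),
    out$analysis, out$n, out$prior)
  rownames(out) <- NULL
  out[, c("condition_id", "study", "family", "factor_corr",
          "cross_loading", "analysis", "n", "prior")]
}

#' Rebuild the generation and analysis models of a condition row
#'
#' @param condition One row of [build_condition_grid()].
#' @return List with `generation` and `analysis` model specs.
#' @export
condition_models <- function(condition) {
  fam <- as.character(condition$family)
  gen <- if (fam == "A") build_generation_model("A", condition$factor_corr)
    else if (fam == "B")
      build_generation_model("B", cross_loading = condition$cross_loading)
    else build_generation_model(fam)
  plan <- condition_plan(fam, as.character(condition$analysis), gen)
  list(generation = gen, analysis = misspecify(gen, plan))
}

condition_plan <- function(family, analysis, gen) {
  if (analysis == "correct") {
    if (nrow(gen$cross_loadings) > 0)
      return(misspecification_plan("cross_loading",
               retained_cross_loadings = nrow(gen$cross_loadings)))
    return(NULL)
  }
  severe <- analysis == "severe"
  if (nrow(gen$cross_loadings) > 0) {
    ncl <- nrow(gen$cross_loadings)
    keep <- if (severe) 0L else ncl - ncl / 3L
    return(misspecification_plan("cross_loading",
                                 retained_cross_loadings = keep))
  }
  q <- gen$n_factors
  target <- if (severe) max(1L, q / 3L) else if (q == 3L) 2L else 4L
  misspecification_plan("dimensionality", target_factors = target)
}

#' Write / read a replication dataset as headered CSV
#'
#' @param data A `cfa_dataset` (or plain matrix), one row per observation.
#' @param file Path.
#' @return `read_dataset` returns a numeric matrix.
#' @export
write_dataset <- function(data, file) {
  utils::write.csv(as.data.frame(unclass(data)), file, row.names = FALSE)
  invisible(file)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(file) {
  as.matrix(utils::read.csv(file))
}
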