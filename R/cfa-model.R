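#' Confirmatory factor analysis model specification
#'
#' Container for a CFA measurement model \eqn{x = \tau + \Lambda\xi + \delta}
#' with standardized latent factors: a p x q loading matrix, a q x q factor
#' correlation matrix (unit diagonal), strictly positive residual variances,
#' and item intercepts. The same structure describes both population
#' (data-generating) models, whose loadings carry numeric values, and
#' analysis models, where `free_mask` marks which loadings are estimated and
#' the remaining entries are fixed to zero. Identification fixes all factor
#' variances to 1; loadings and factor correlations are free.
#'
#' @param name Identifier for the model.
#' @param loadings p x q numeric matrix of population loadings (0 where no
#'   path). Entries may be `NA` for analysis models whose free values carry
#'   no population counterpart.
#' @param factor_corr q x q symmetric correlation matrix (unit diagonal,
#'   positive definite), or a single scalar giving the common correlation of
#'   an equicorrelated structure.
#' @param residual_variances Length-p vector of positive residual variances.
#' @param intercepts Length-p vector of item intercepts (default 0).
#' @param free_mask p x q logical matrix of estimated loadings; defaults to
#'   `loadings != 0`.
#' @param primary_factor Optional length-p integer vector giving each item's
#'   primary factor (used for aligned priors and sign identification);
#'   defaults to the column of the largest absolute loading per row.
#' @return An object of class `cfa_model_spec`.
#' @export
cfa_model_spec <- function(name, loadings, factor_corr, residual_variances,
                           intercepts = NULL, free_mask = NULL,
                           primary_factor = NULL) {
  loadings <- as.matrix(loadings)
  p <- nrow(loadings)
  q <- ncol(loadings)
  if (length(factor_corr) == 1L && q > 1L) {
    phi <- matrix(factor_corr, q, q)
    diag(phi) <- 1
  } else {
    phi <- as.matrix(factor_corr)
  }
  if (q == 1L) phi <- matrix(1, 1, 1)
  if (is.null(intercepts)) intercepts <- rep(0, p)
  if (is.null(free_mask)) {
    free_mask <- !is.na(loadings) & loadings != 0
    free_mask[is.na(loadings)] <- TRUE
  }
  free_mask <- matrix(as.logical(free_mask), p, q)
  if (is.null(primary_factor)) {
    primary_factor <- apply(abs(replace(loadings, is.na(loadings), 0)),
                            1L, which.max)
  }
  spec <- structure(
    list(name = name, n_factors = q, n_items = p,
         loadings = loadings, free_mask = free_mask,
         factor_corr = phi,
         residual_variances = as.numeric(residual_variances),
         intercepts = as.numeric(intercepts),
         factor_means = rep(0, q),
         primary_factor = as.integer(primary_factor),
         cross_loadings = empty_cross_table()),
    class = "cfa_model_spec")
  validate_cfa_model_spec(spec)
  spec
}

empty_cross_table <- function() {
  data.frame(item = integer(0), factor = integer(0), value = numeric(0))
}

validate_cfa_model_spec <- function(spec) {
  p <- spec$n_items; q <- spec$n_factors
  phi <- spec$factor_corr
  stopifnot(nrow(spec$loadings) == p, ncol(spec$loadings) == q,
            nrow(phi) == q, ncol(phi) == q,
            length(spec$residual_variances) == p,
            length(spec$intercepts) == p)
  if (max(abs(phi - t(phi))) > 1e-10 || max(abs(diag(phi) - 1)) > 1e-10)
    stop("factor_corr must be symmetric with unit diagonal")
  if (min(eigen(phi, symmetric = TRUE, only.values = TRUE)$values) <= 0)
    stop("factor_corr must be positive definite")
  if (any(spec$residual_variances <= 0))
    stop("residual variances must be strictly positive")
  if (!anyNA(spec$loadings)) {
    sigma <- spec$loadings %*% phi %*% t(spec$loadings) +
      diag(spec$residual_variances, p)
    if (min(eigen(sigma, symmetric = TRUE, only.values = TRUE)$values) <= 0)
      stop("implied covariance is not positive definite")
  }
  invisible(spec)
}

#' @export
print.cfa_model_spec <- function(x, ...) {
  cat(sprintf("CFA model '%s': %d items, %d factors, %d free loadings\n",
              x$name, x$n_items, x$n_factors, sum(x$free_mask)))
  if (nrow(x$cross_loadings) > 0)
    cat(sprintf("  cross-loadings: %s\n",
                paste(sprintf("item %d -> F%d", x$cross_loadings$item,
                              x$cross_loadings$factor), collapse = ", ")))
  invisible(x)
}

# loading values (.70 .70 .75 .80 .80) per five-item block; ten-item factors
# repeat the block so the marginal distribution of loadings is preserved
primary_block <- function(items_per_factor) {
  base <- c(0.70, 0.70, 0.75, 0.80, 0.80)
  if (items_per_factor == 5L) return(base)
  if (items_per_factor == 10L) return(rep(base, 2L))
  stop("items per factor must be 5 or 10")
}

family_table <- function() {
  data.frame(
    family = c("A", "B", "C1", "C2", "C3", "D1", "D2", "D3"),
    n_factors = c(3L, 3L, 3L, 6L, 6L, 3L, 6L, 6L),
    items_per_factor = c(5L, 5L, 10L, 5L, 10L, 10L, 5L, 10L),
    cross_per_factor = c(0L, 1L, 0L, 0L, 0L, 2L, 1L, 2L),
    fixed_corr = c(NA, 0.5, 0.85, 0.85, 0.85, 0.85, 0.85, 0.85),
    fixed_cross = c(NA, NA, NA, NA, NA, 0.5, 0.5, 0.5),
    stringsAsFactors = FALSE)
}

# cross-loading placement, in interleaved cyclic order (first cross-loading
# of each factor's block, then the second of each, ...); when a
# misspecified analysis model drops d cross-loadings they are removed from
# the head of this list, i.e. spread one per factor.
# Family B follows the printed pattern exactly: the last item of factor 1's
# block and of factor 3's block, but the fourth (not fifth) item of factor
# 2's block, each loading on the next factor. All other families place the
# k cross-loading items per factor on the last (highest-loading) items of
# the block, loading on the next factor cyclically.
cross_positions <- function(family, n_factors, items_per_factor, k) {
  if (k == 0L) return(data.frame(item = integer(0), factor = integer(0)))
  if (family == "B")
    return(data.frame(item = c(5L, 9L, 15L), factor = c(2L, 3L, 1L)))
  out <- lapply(seq_len(k), function(j) {
    data.frame(item = seq_len(n_factors) * items_per_factor - k + j,
               factor = (seq_len(n_factors) %% n_factors) + 1L)
  })
  do.call(rbind, out)
}

#' Build a population (data-generating) CFA model
#'
#' Constructs one of the study's data-generating models. Family A is a
#' three-factor independent-cluster model (five items per factor) with a
#' free equicorrelation; family B adds one cross-loading per factor at fixed
#' factor correlation 0.5; families C1--C3 are larger independent-cluster
#' models (3 or 6 factors, 5 or 10 items each) at correlation 0.85; families
#' D1--D3 add cross-loadings of 0.5 to the C-type structures. Primary
#' loadings follow the (.70, .70, .75, .80, .80) block; residual variances
#' are 1 minus the squared primary loading, held fixed when cross-loadings
#' are added.
#'
#' @param family One of `"A"`, `"B"`, `"C1"`, `"C2"`, `"C3"`, `"D1"`,
#'   `"D2"`, `"D3"`.
#' @param factor_corr Common factor correlation in (0, 1). Required for
#'   family A; fixed by design for the others (0.5 for B, 0.85 for C/D) and
#'   defaulted accordingly.
#' @param cross_loading Cross-loading magnitude (>= 0). Required for family
#'   B; fixed at 0.5 for D families; ignored for A and C.
#' @return A `cfa_model_spec` population model.
#' @export
build_generation_model <- function(family, factor_corr = NULL,
                                   cross_loading = NULL) {
  fams <- family_table()
  row <- fams[fams$family == family, ]
  if (nrow(row) != 1L) stop("unknown model family: ", family)
  if (is.null(factor_corr)) factor_corr <- row$fixed_corr
  if (is.na(factor_corr)) stop("family ", family, " requires factor_corr")
  if (factor_corr <= 0 || factor_corr >= 1)
    stop("factor_corr must lie in (0, 1)")
  if (row$cross_per_factor > 0L) {
    if (is.null(cross_loading)) cross_loading <- row$fixed_cross
    if (is.na(cross_loading) || is.null(cross_loading))
      stop("family ", family, " requires cross_loading")
    if (cross_loading < 0) stop("cross_loading must be >= 0")
  } else {
    cross_loading <- 0
  }

  q <- row$n_factors
  ipf <- row$items_per_factor
  p <- q * ipf
  block <- primary_block(ipf)
  lambda <- matrix(0, p, q)
  primary <- rep(seq_len(q), each = ipf)
  lambda[cbind(seq_len(p), primary)] <- rep(block, q)

  crosses <- cross_positions(family, q, ipf, row$cross_per_factor)
  if (nrow(crosses) > 0) {
    if (any(crosses$item > p)) stop("cross-loading placement infeasible")
    lambda[cbind(crosses$item, crosses$factor)] <- cross_loading
    crosses$value <- cross_loading
  } else {
    crosses <- empty_cross_table()
  }
  # residual variances standardize each item against the sum of its squared
  # loadings (primary and cross); the factor-covariance contribution of a
  # cross-loading is not subtracted, so cross-loading items have total
  # variance slightly above 1
  psi <- 1 - rowSums(lambda^2)
  if (any(psi <= 0)) stop("cross-loading magnitude leaves no residual variance")

  label <- if (family == "A") sprintf("A_cor%.2f", factor_corr)
           else if (family == "B") sprintf("B_cld%.1f", cross_loading)
           else family
  spec <- cfa_model_spec(label, lambda, factor_corr, psi,
                         primary_factor = primary)
  spec$cross_loadings <- crosses
  spec
}

#' Model-implied covariance matrix
#'
#' Computes \eqn{\Sigma = \Lambda\Phi\Lambda' + \Psi} for a fully valued
#' model specification.
#'
#' @param spec A `cfa_model_spec` with numeric (non-`NA`) loadings.
#' @return p x p symmetric positive-definite covariance matrix.
#' @export
implied_covariance <- function(spec) {
  if (anyNA(spec$loadings))
    stop("spec has unvalued free loadings; implied covariance undefined")
  sigma <- spec$loadings %*% spec$factor_corr %*% t(spec$loadings) +
    diag(spec$residual_variances, spec$n_items)
  sigma <- (sigma + t(sigma)) / 2
  if (min(eigen(sigma, symmetric = TRUE, only.values = TRUE)$values) <= 0)
    stop("implied covariance is not positive definite")
  sigma
}

#' Describe a misspecified analysis model
#'
#' @param kind `"dimensionality"` (fit fewer factors than the population
#'   model, merging factors) or `"cross_loading"` (ignore some or all
#'   population cross-loadings).
#' @param target_factors For dimensionality plans, the number of factors in
#'   the analysis model.
#' @param retained_cross_loadings For cross-loading plans, how many of the
#'   population cross-loadings the analysis model keeps (dropped in fixed
#'   order from the head of the cyclic placement list).
#' @param merge_map Optional integer vector mapping each population factor
#'   to an analysis factor (population blocks kept intact). The study-1
#'   model A convention is the order-preserving merge: 3 -> 2 keeps factor 1
#'   and merges factors 2 and 3 (items 1--5 / 6--15); 3 -> 1 merges all.
#' @param split_sizes Optional integer vector of contiguous item-block sizes
#'   (summing to p) reassigning items to `target_factors` analysis factors
#'   directly. The larger study-2 models reduce dimensionality this way,
#'   splitting items as evenly as possible (e.g. 30 items onto two
#'   15-item factors, or onto four factors as 8/8/7/7) rather than merging
#'   whole population blocks. Exactly one of `merge_map`/`split_sizes` is
#'   used; when both are `NULL` a dimensionality plan defaults to the
#'   balanced split except for the 3 -> 2 and 3 -> 1 five-item merges.
#' @return A `misspecification_plan` object.
#' @export
misspecification_plan <- function(kind = c("dimensionality", "cross_loading"),
                                  target_factors = NULL,
                                  retained_cross_loadings = NULL,
                                  merge_map = NULL, split_sizes = NULL) {
  kind <- match.arg(kind)
  if (kind == "dimensionality" && is.null(target_factors))
    stop("dimensionality plan requires target_factors")
  if (kind == "cross_loading" && is.null(retained_cross_loadings))
    stop("cross_loading plan requires retained_cross_loadings")
  if (!is.null(merge_map) && !is.null(split_sizes))
    stop("give at most one of merge_map and split_sizes")
  structure(list(kind = kind, target_factors = target_factors,
                 retained_cross_loadings = retained_cross_loadings,
                 merge_map = merge_map, split_sizes = split_sizes),
            class = "misspecification_plan")
}

default_a_merge <- function(to) {
  if (to == 2L) c(1L, 2L, 2L)
  else if (to == 1L) c(1L, 1L, 1L)
  else stop("no default merge from 3 factors to ", to)
}

# as-even-as-possible contiguous split of p items into `to` blocks,
# larger blocks first
balanced_split_sizes <- function(p, to) {
  base <- p %/% to
  extra <- p %% to
  c(rep(base + 1L, extra), rep(base, to - extra))
}

#' Derive a (possibly misspecified) analysis model
#'
#' Applies a misspecification plan to a population model and returns the
#' analysis model actually fitted to data: the free-loading mask is set, and
#' loading values are retained only as reference population values (aligned
#' priors and correctness checks); estimation treats all masked loadings,
#' factor correlations, residual variances, and intercepts as free, with
#' factor variances fixed to 1. A `NULL` plan returns the correctly
#' specified analysis form of `spec`.
#'
#' @param spec Population `cfa_model_spec`.
#' @param plan A `misspecification_plan`, or `NULL` for the correct model.
#' @return An analysis-form `cfa_model_spec`.
#' @export
misspecify <- function(spec, plan = NULL) {
  p <- spec$n_items
  if (is.null(plan)) {
    out <- spec
    out$free_mask <- !is.na(spec$loadings) & spec$loadings != 0
    out$name <- paste0(spec$name, "_correct")
    return(out)
  }
  stopifnot(inherits(plan, "misspecification_plan"))
  if (plan$kind == "dimensionality") {
    qt <- plan$target_factors
    if (qt >= spec$n_factors)
      stop("target_factors must be smaller than the population n_factors")
    if (!is.null(plan$merge_map)) {
      mm <- plan$merge_map
      if (length(mm) != spec$n_factors || !setequal(unique(mm), seq_len(qt)))
        stop("merge_map must map every population factor onto 1..target_factors")
      new_primary <- mm[spec$primary_factor]
    } else {
      sizes <- plan$split_sizes
      if (is.null(sizes)) {
        # model A's 15 items cannot split evenly over 2 factors; the study
        # keeps whole blocks there (items 1-5 / 6-15). All other defaults
        # split items contiguously, as evenly as possible.
        if (spec$n_factors == 3L && spec$n_items == 15L)
          new_primary <- default_a_merge(qt)[spec$primary_factor]
        else sizes <- balanced_split_sizes(p, qt)
      }
      if (!is.null(sizes)) {
        if (sum(sizes) != p || length(sizes) != qt)
          stop("split_sizes must have length target_factors and sum to p")
        new_primary <- rep(seq_len(qt), sizes)
      }
    }
    lambda <- matrix(0, p, qt)
    mask <- matrix(FALSE, p, qt)
    # carry the population primary value as the reference value of the
    # reassigned path; secondary (cross) paths map to their merged factor
    # under a merge_map, and are simply absorbed under an item split
    for (i in seq_len(p)) {
      mask[i, new_primary[i]] <- TRUE
      lambda[i, new_primary[i]] <-
        spec$loadings[i, spec$primary_factor[i]]
    }
    if (!is.null(plan$merge_map) && nrow(spec$cross_loadings) > 0) {
      for (r in seq_len(nrow(spec$cross_loadings))) {
        f <- plan$merge_map[spec$cross_loadings$factor[r]]
        i <- spec$cross_loadings$item[r]
        if (!mask[i, f]) {
          mask[i, f] <- TRUE
          lambda[i, f] <- spec$cross_loadings$value[r]
        }
      }
    }
    out <- cfa_model_spec(sprintf("%s_as%df", spec$name, qt), lambda,
                          if (qt > 1) 0 else 1, spec$residual_variances,
                          free_mask = mask, primary_factor = new_primary)
    out
  } else {
    k <- plan$retained_cross_loadings
    ncl <- nrow(spec$cross_loadings)
    if (k < 0 || k > ncl)
      stop("retained_cross_loadings must lie in 0..", ncl)
    keep <- if (k > 0) spec$cross_loadings[(ncl - k + 1L):ncl, , drop = FALSE]
            else empty_cross_table()
    lambda <- matrix(0, p, spec$n_factors)
    idx <- cbind(seq_len(p), spec$primary_factor)
    lambda[idx] <- spec$loadings[idx]
    mask <- matrix(FALSE, p, spec$n_factors)
    mask[idx] <- TRUE
    if (nrow(keep) > 0) {
      lambda[cbind(keep$item, keep$factor)] <- keep$value
      mask[cbind(keep$item, keep$factor)] <- TRUE
    }
    out <- cfa_model_spec(sprintf("%s_keep%d", spec$name, k), lambda, 0,
                          spec$residual_variances, free_mask = mask,
                          primary_factor = spec$primary_factor)
    out$cross_loadings <- keep
    out
  }
}

#' Count free parameters of an analysis model
#'
#' Free loadings plus factor correlations plus residual variances; item
#' intercepts are counted only when `include_intercepts = TRUE`. The
#' covariance-structure count (`include_intercepts = FALSE`) is the `q` of
#' the frequentist degrees of freedom `df = p* - q` with
#' `p* = p(p + 1)/2`; the full count including intercepts is the number of
#' freely estimated parameters of the Bayesian fit, which the effective
#' number of parameters pD approaches under diffuse priors.
#'
#' @param spec Analysis-form `cfa_model_spec`.
#' @param include_intercepts Count the p intercepts as well.
#' @return Integer parameter count.
#' @export
count_free_parameters <- function(spec, include_intercepts = FALSE) {
  q <- spec$n_factors
  n <- sum(spec$free_mask) + q * (q - 1) / 2 + spec$n_items
  if (include_intercepts) n <- n + spec$n_items
  as.integer(n)
}

#' Serialize a model specification to YAML
#'
#' @param spec A `cfa_model_spec`.
#' @param file Optional path; when `NULL` the YAML string is returned.
#' @return The YAML string, invisibly when written to a file.
#' @export
model_spec_to_yaml <- function(spec, file = NULL) {
  obj <- list(name = spec$name,
              loadings = apply(spec$loadings, 1L, as.numeric,
                               simplify = FALSE),
              free_mask = apply(spec$free_mask, 1L, as.logical,
                                simplify = FALSE),
              factor_corr = apply(spec$factor_corr, 1L, as.numeric,
                                  simplify = FALSE),
              residual_variances = as.numeric(spec$residual_variances),
              intercepts = as.numeric(spec$intercepts),
              primary_factor = as.integer(spec$primary_factor),
              cross_loadings = as.list(spec$cross_loadings))
  txt <- yaml::as.yaml(obj)
  if (is.null(file)) return(txt)
  writeLines(txt, file)
  invisible(txt)
}

#' Read a model specification from YAML
#'
#' @param file Path to a YAML file written by [model_spec_to_yaml()].
#' @return A `cfa_model_spec`.
#' @export
model_spec_from_yaml <- function(file) {
  obj <- yaml::read_yaml(file)
  spec <- cfa_model_spec(obj$name,
                         do.call(rbind, obj$loadings),
                         do.call(rbind, obj$factor_corr),
                         obj$residual_variances,
                         intercepts = obj$intercepts,
                         free_mask = do.call(rbind, obj$free_mask),
                         primary_factor = obj$primary_factor)
  if (length(obj$cross_loadings$item) > 0)
    spec$cross_loadings <- data.frame(item = obj$cross_loadings$item,
                                      factor = obj$cross_loadings$factor,
                                      value = obj$cross_loadings$value)
  spec
}
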