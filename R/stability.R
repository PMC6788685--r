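#' Configuration for Stability-Selection ranking
#'
#' Per iteration, 10% of the samples and 30% of the features are left
#' out of the bag, LASSO is run on the remaining block over a 20-point
#' log-spaced penalty grid from the per-subsample `lambda_max` down to
#' `lambda_min_ratio * lambda_max`, and a feature counts as selected
#' when its coefficient is nonzero anywhere on the grid (the
#' selection-over-a-penalty-region formulation).  The default grid
#' floor of `0.5 * lambda_max` keeps per-iteration selection sparse
#' (about 10 of ~100 candidate features at the reference cohort
#' geometry), which is what makes selection frequencies discriminative;
#' a much deeper grid approaches the OLS support and saturates the
#' frequencies.  The reference analysis uses 100,000 iterations; 10,000
#' is the default here and already gives Monte-Carlo-stable
#' frequencies.
#'
#' @param iterations jackknife iterations.
#' @param frac_samples_out,frac_features_out out-of-bag fractions.
#' @param n_lambda,lambda_min_ratio penalty-grid geometry.
#' @param decision_rule `"any_lambda"` (default) or `"fixed_index"`.
#' @param fixed_index grid position used when `decision_rule` is
#'   `"fixed_index"`.
#' @param seed integer seed for the jackknife masks.
#' @return A list of class `stability_config`.
#' @export
stability_config <- function(iterations = 10000,
                             frac_samples_out = 0.10,
                             frac_features_out = 0.30,
                             n_lambda = 20, lambda_min_ratio = 0.5,
                             decision_rule = c("any_lambda", "fixed_index"),
                             fixed_index = 1L, seed = 1) {
  decision_rule <- match.arg(decision_rule)
  if (iterations < 1) stop("iterations must be >= 1")
  for (f in c(frac_samples_out, frac_features_out))
    if (!(f >= 0 && f < 1)) stop("out-of-bag fractions must lie in [0, 1)")
  if (n_lambda < 1) stop("n_lambda must be >= 1")
  if (!(lambda_min_ratio > 0 && lambda_min_ratio <= 1))
    stop("lambda_min_ratio must lie in (0, 1]")
  structure(list(iterations = as.integer(iterations),
                 frac_samples_out = frac_samples_out,
                 frac_features_out = frac_features_out,
                 n_lambda = as.integer(n_lambda),
                 lambda_min_ratio = lambda_min_ratio,
                 decision_rule = decision_rule,
                 fixed_index = as.integer(fixed_index),
                 seed = seed),
            class = "stability_config")
}

#' Jackknife masks for the double subsampling
#'
#' Each iteration removes `round(frac * n)` samples and features,
#' uniformly without replacement and independently across iterations.
#'
#' @param n_samples,n_features axis sizes.
#' @param config a [stability_config()].
#' @param iterations optional override of `config$iterations`.
#' @return A list with integer matrices `samples` and `features`
#'   (iterations x kept count, 1-based sorted kept indices).
#' @export
jackknife_masks <- function(n_samples, n_features, config,
                            iterations = NULL) {
  stopifnot(inherits(config, "stability_config"))
  iterations <- iterations %||% config$iterations
  ns_keep <- n_samples - round(config$frac_samples_out * n_samples)
  nf_keep <- n_features - round(config$frac_features_out * n_features)
  if (ns_keep < 1) stop("no samples retained in bag; lower frac_samples_out")
  if (nf_keep < 1) stop("no features retained in bag; lower frac_features_out")
  draw <- function(n, k) {
    m <- vapply(seq_len(iterations),
                function(i) sort(sample.int(n, k)), integer(k))
    if (k == 1) matrix(m, ncol = 1) else t(m)   # vapply drops to vector
  }
  with_seed(child_seed(config$seed, "masks"), {
    list(samples = draw(n_samples, ns_keep),
         features = draw(n_features, nf_keep))
  })
}

#' LASSO feature selection on one (sub)sample
#'
#' Coordinate-descent solution of
#' `0.5 * ||y - X b||^2 + lambda * ||b||_1` over a decreasing penalty
#' grid with warm starts.  `X` is expected standardized and `y`
#' centered.  Under the default `any_lambda` rule a feature is selected
#' when its coefficient is nonzero at any grid value.
#'
#' @param X numeric matrix (standardized columns).
#' @param y centered numeric response.
#' @param lambda decreasing positive penalty grid.
#' @param decision_rule `"any_lambda"` or `"fixed_index"`.
#' @param fixed_index grid position for the `fixed_index` rule.
#' @param tol,maxit coordinate-descent convergence controls.
#' @return Integer vector of selected column indices, with the full
#'   coefficient path (`p x length(lambda)`) as attribute `path`.
#' @export
lasso_select <- function(X, y, lambda, decision_rule = "any_lambda",
                         fixed_index = 1L, tol = 1e-7, maxit = 10000L) {
  X <- as.matrix(X)
  if (length(y) != nrow(X)) stop("length(y) must equal nrow(X)")
  if (any(diff(lambda) > 0)) stop("lambda grid must be decreasing")
  if (any(lambda < 0)) stop("penalties must be nonnegative")
  B <- lasso_cd_path_cpp(X, as.numeric(y), as.numeric(lambda), tol, maxit)
  if (!all(attr(B, "converged")))
    warning("coordinate descent did not converge at some penalties")
  nz <- abs(B) > 1e-9
  sel <- if (decision_rule == "any_lambda") which(rowSums(nz) > 0)
         else which(nz[, fixed_index])
  attr(sel, "path") <- B
  sel
}

#' Rank candidate proteins by Stability Selection
#'
#' Repeatedly subsamples samples and features ([jackknife_masks()]),
#' standardizes the in-bag block, runs the LASSO over the penalty grid,
#' and records, per protein, the proportion of in-bag iterations in
#' which a nonzero coefficient was reported.  Proteins are ranked by
#' descending selection frequency; ties are broken by mean absolute
#' coefficient across selected iterations, then by protein id.
#'
#' @param mat log10-scale [protein_matrix()].
#' @param labels group labels aligned with the matrix samples (factor or
#'   character with two classes; PD is coded 1, the other class 0).
#' @param candidate_ids proteins to rank (the nominated candidates).
#' @param config a [stability_config()].
#' @return A data.frame of class `stability_ranking`: `protein_id`,
#'   `frequency` (selected / eligible), `eligible`, `selected`,
#'   `mean_abs_coef`, `rank`; the configuration (and skipped-iteration
#'   count) travel as attributes.
#' @examples
#' cohort <- generate_cohort(sim_config(n_pd = 40, n_nc = 40,
#'                                      n_proteins = 30, n_planted = 2,
#'                                      delta = 0.3, seed = 5))
#' lmat <- log10_transform(cohort$matrix)
#' rk <- stability_rank(lmat, cohort$meta$group, protein_ids(lmat),
#'                      stability_config(iterations = 200, seed = 5))
#' head(rk)
#' @export
stability_rank <- function(mat, labels, candidate_ids, config) {
  stopifnot(inherits(mat, "protein_matrix"),
            inherits(config, "stability_config"))
  if (mat$scale != "log10") stop("stability ranking expects log10 values")
  absent <- setdiff(candidate_ids, protein_ids(mat))
  if (length(absent) > 0)
    stop("candidate(s) absent from matrix: ", paste(absent, collapse = ", "))
  labels <- as.character(labels)
  if (length(labels) != nrow(mat$values))
    stop("labels must align with matrix samples")
  classes <- unique(labels)
  if (length(classes) != 2)
    stop("need exactly 2 label classes, got ", length(classes))
  pos <- if ("PD" %in% classes) "PD" else sort(classes)[2]
  y <- as.numeric(labels == pos)
  y <- y - mean(y)

  X <- mat$values[, candidate_ids, drop = FALSE]
  masks <- jackknife_masks(nrow(X), ncol(X), config)
  acc <- stability_accumulate_cpp(
    X, y, masks$samples, masks$features,
    config$n_lambda, config$lambda_min_ratio,
    if (config$decision_rule == "any_lambda") 1L else 2L,
    config$fixed_index, 1e-7, 10000L)
  if (acc$skipped > 0)
    warning(acc$skipped, " iteration(s) skipped for non-convergence")
  eligible <- acc$eligible
  selected <- acc$selected
  freq <- ifelse(eligible > 0, selected / eligible, 0)
  mac <- ifelse(selected > 0, acc$coefsum / selected, 0)
  ord <- order(-freq, -mac, candidate_ids)
  rank <- integer(length(candidate_ids))
  rank[ord] <- seq_along(ord)
  out <- data.frame(protein_id = candidate_ids,
                    frequency = freq, eligible = eligible,
                    selected = selected, mean_abs_coef = mac,
                    rank = rank, row.names = NULL,
                    stringsAsFactors = FALSE)
  out <- out[ord, ]
  rownames(out) <- NULL
  attr(out, "config") <- config
  attr(out, "skipped") <- acc$skipped
  class(out) <- c("stability_ranking", "data.frame")
  out
}

#' @export
print.stability_ranking <- function(x, n = 10, ...) {
  cfg <- attr(x, "config")
  cat(sprintf("<stability_ranking> %d candidates, %d iterations (%.0f%% samples / %.0f%% features out)\n",
              nrow(x), cfg$iterations, 100 * cfg$frac_samples_out,
              100 * cfg$frac_features_out))
  print.data.frame(head(x, n), digits = 3)
  invisible(x)
}

#' @export
plot.stability_ranking <- function(x, n = 10, ...) {
  top <- head(x, n)
  graphics::barplot(rev(top$frequency), names.arg = rev(top$protein_id),
                    horiz = TRUE, las = 1, xlab = "selection frequency",
                    main = sprintf("Stability Selection (top %d)", n), ...)
  invisible(x)
}

#' Extract the top-k ranked proteins
#'
#' @param ranking a `stability_ranking`.
#' @param k how many proteins (default 10, the workflow's shortlist).
#' @return Character vector of the top-k protein ids, best first.
#' @export
top_k <- function(ranking, k = 10) {
  stopifnot(inherits(ranking, "stability_ranking"))
  head(ranking$protein_id[order(ranking$rank)], k)
}
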