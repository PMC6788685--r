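# Multisite replication of the discovery model, disease specificity
# against ALS, and the treated versus never-treated comparison.

#' Replication-cohort association models
#'
#' Mirrors the discovery estimator for the top-ranked proteins with the
#' multisite design `log10(RFU) ~ group + age + sex + site + batch`
#' (site and batch reference-coded; LEDD deliberately not part of this
#' design).  BH correction is applied over the tested k-protein family
#' only.
#'
#' @param mat log10-scale [protein_matrix()] of the replication cohort.
#' @param meta replication sample metadata.
#' @param top_ids protein ids advanced from discovery.  Proteins absent
#'   from the replication panel are reported as untestable (NA rows),
#'   not failures.
#' @param covariates replication covariates.
#' @return An `association_table` with one row per testable protein and
#'   attribute `untestable` listing absent ids.
#' @export
run_replication <- function(mat, meta, top_ids,
                            covariates = c("age", "sex", "site", "batch")) {
  covariates <- intersect(covariates, names(meta))
  testable <- intersect(top_ids, protein_ids(mat))
  untestable <- setdiff(top_ids, testable)
  if (length(untestable) > 0)
    message(length(untestable), " protein(s) absent from replication panel: ",
            paste(untestable, collapse = ", "))
  if (length(testable) == 0) stop("no testable proteins in replication panel")
  out <- assoc_engine(mat, meta, covariates, proteins = testable)
  attr(out, "untestable") <- untestable
  out
}

#' Declare replication
#'
#' A protein replicates when its FDR-adjusted p-value is below `alpha`
#' in both cohorts *and* the direction of the group effect agrees.
#'
#' @param discovery,replication `association_table` rows (must share
#'   `protein_id`, `q`, `direction` columns).
#' @param alpha FDR threshold (default 0.05).
#' @return Character vector of replicated protein ids (sorted).
#' @export
check_replication <- function(discovery, replication, alpha = 0.05) {
  common <- intersect(discovery$protein_id, replication$protein_id)
  d <- discovery[match(common, discovery$protein_id), ]
  r <- replication[match(common, replication$protein_id), ]
  ok <- d$q < alpha & r$q < alpha & d$direction == r$direction &
    d$direction != 0
  sort(common[which(ok)])
}

#' Three-group disease-specificity models
#'
#' Models each validated protein as
#' `log10(RFU) ~ group + age + sex + site` with a reference-coded
#' NC/PD/ALS group factor; both disease coefficients (PD vs NC, ALS vs
#' NC) are extracted, and BH adjustment is applied across all extracted
#' coefficients.
#'
#' @param mat log10-scale [protein_matrix()].
#' @param meta metadata containing NC, PD and ALS samples.
#' @param ids proteins to test.
#' @param covariates adjustment covariates.
#' @return A data.frame with one row per protein and disease contrast:
#'   `protein_id`, `term` (`groupPD` / `groupALS`), `beta`, `se`, `t`,
#'   `p`, `q`, `direction`, `n_used`.
#' @export
multigroup_specificity <- function(mat, meta, ids,
                                   covariates = c("age", "sex", "site")) {
  meta <- validate_sample_meta(meta)
  for (g in c("NC", "PD", "ALS"))
    if (!g %in% meta$group)
      stop("group level `", g, "` missing from metadata")
  covariates <- intersect(covariates, names(meta))
  des <- build_design(meta, covariates, group_coding = "multigroup")
  common <- intersect(des$sample_id, sample_ids(mat))
  X <- des$X[match(common, des$sample_id), , drop = FALSE]
  absent <- setdiff(ids, protein_ids(mat))
  if (length(absent) > 0)
    stop("protein(s) absent from matrix: ", paste(absent, collapse = ", "))
  Y <- mat$values[common, ids, drop = FALSE]
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) stop("rank-deficient multigroup design")
  B <- qr.coef(qrX, Y)
  res <- Y - X %*% B
  df_res <- nrow(X) - ncol(X)
  sigma2 <- colSums(res^2) / df_res
  XtXinv <- chol2inv(qr.R(qrX))
  dimnames(XtXinv) <- list(colnames(X), colnames(X))
  terms <- c("groupPD", "groupALS")
  out <- do.call(rbind, lapply(terms, function(cn) {
    beta <- B[cn, ]
    se <- sqrt(sigma2 * XtXinv[cn, cn])
    tt <- beta / se
    data.frame(protein_id = ids, term = cn, beta = as.numeric(beta),
               se = as.numeric(se), t = as.numeric(tt),
               p = 2 * pt(-abs(tt), df_res),
               direction = sign(as.numeric(beta)), n_used = nrow(X),
               row.names = NULL, stringsAsFactors = FALSE)
  }))
  out$q <- bh_adjust(out$p)  # one family across both contrasts
  out
}

#' Treated versus never-treated comparison
#'
#' Wilcoxon rank-sum comparison of one protein's log10 levels between
#' PD participants treated versus never treated with dopaminergic
#' medication: exact two-sided p for combined n <= `exact_max` without
#' ties, normal approximation with tie correction otherwise.
#'
#' @param values numeric log10 levels for PD participants.
#' @param treated logical flags aligned with `values`.
#' @param exact_max largest combined n for the exact null distribution.
#' @return A list with `statistic` (rank-sum W of the treated group),
#'   `p_value`, and `exact` (whether the exact null was used).
#' @export
never_treated_comparison <- function(values, treated, exact_max = 20) {
  if (length(values) != length(treated))
    stop("`values` and `treated` must have equal length")
  x <- values[treated]
  y <- values[!treated]
  if (length(x) == 0 || length(y) == 0)
    stop("both treated and never-treated subgroups must be nonempty")
  n <- length(x) + length(y)
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- n <= exact_max && !ties
  wt <- suppressWarnings(
    wilcox.test(x, y, exact = exact, correct = !exact,
                alternative = "two.sided"))
  list(statistic = unname(wt$statistic), p_value = wt$p.value,
       exact = exact)
}
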