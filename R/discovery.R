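# Per-protein covariate-adjusted linear models, candidate nomination,
# BH false-discovery control, and hierarchical clustering of candidates.

# Build the common design matrix for the association models.
# covariates may include "age", "sex", "ledd", "site", "batch";
# categorical terms are reference-coded.  Returns list(X, rows, meta).
build_design <- function(meta, covariates, group_coding = "pd_nc") {
  meta <- validate_sample_meta(meta)
  if (group_coding == "pd_nc") {
    keep <- meta$group %in% c("PD", "NC")
    meta <- meta[keep, , drop = FALSE]
    grp <- as.numeric(meta$group == "PD")
    df <- data.frame(group = grp)
  } else {  # multigroup: NC reference factor
    df <- data.frame(group = factor(as.character(meta$group),
                                    levels = c("NC", "PD", "ALS")))
  }
  for (cv in covariates) {
    if (!cv %in% names(meta))
      stop("covariate `", cv, "` absent from sample metadata")
    v <- meta[[cv]]
    if (cv %in% c("site", "batch")) {
      v <- factor(v)
      if (nlevels(v) < 2) {  # single-site / single-plate cohort
        message("covariate `", cv, "` has a single level; dropped")
        next
      }
    }
    if (cv == "ledd") v[is.na(v) & meta$group == "NC"] <- 0  # untreated NC
    df[[cv]] <- v
  }
  ok <- complete.cases(df)
  n_dropped <- sum(!ok)
  if (n_dropped > 0)
    message(n_dropped, " sample(s) dropped for missing covariate values")
  df <- df[ok, , drop = FALSE]
  X <- model.matrix(~ ., data = df)
  list(X = X, sample_id = meta$sample_id[ok], n_dropped = n_dropped,
       frame = df)
}

# Shared OLS engine: one QR for all proteins (same design for every
# response).  Returns an association_table for the requested terms.
assoc_engine <- function(mat, meta, covariates, proteins = NULL,
                         terms = "group") {
  stopifnot(inherits(mat, "protein_matrix"))
  if (mat$scale != "log10")
    stop("association models require log10-scale values; run QC first")
  des <- build_design(meta, covariates)
  proteins <- proteins %||% protein_ids(mat)
  absent <- setdiff(proteins, protein_ids(mat))
  if (length(absent) > 0)
    stop("protein(s) absent from matrix: ", paste(absent, collapse = ", "))
  common <- intersect(des$sample_id, sample_ids(mat))
  if (length(common) < ncol(des$X) + 1)
    stop("too few samples (", length(common), ") for the design (",
         ncol(des$X), " columns)")
  X <- des$X[match(common, des$sample_id), , drop = FALSE]
  Y <- mat$values[common, proteins, drop = FALSE]

  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    aliased <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("rank-deficient design; collinear term(s): ",
         paste(aliased, collapse = ", "))
  }
  B <- qr.coef(qrX, Y)
  res <- Y - X %*% B
  df_res <- nrow(X) - ncol(X)
  sigma2 <- colSums(res^2) / df_res
  if (any(sigma2 <= 0))
    stop("zero residual variance for protein(s): ",
         paste(head(proteins[sigma2 <= 0], 5), collapse = ", "))
  XtXinv <- chol2inv(qr.R(qrX))
  dimnames(XtXinv) <- list(colnames(X), colnames(X))

  rows <- lapply(terms, function(tm) {
    idx <- grep(paste0("^", tm), colnames(X), value = TRUE)
    if (length(idx) == 0) stop("term `", tm, "` not in design")
    do.call(rbind, lapply(idx, function(cn) {
      beta <- B[cn, ]
      se <- sqrt(sigma2 * XtXinv[cn, cn])
      tt <- beta / se
      data.frame(protein_id = proteins, term = cn,
                 beta = as.numeric(beta), se = as.numeric(se),
                 t = as.numeric(tt),
                 p = 2 * pt(-abs(tt), df_res),
                 direction = sign(as.numeric(beta)),
                 n_used = nrow(X),
                 row.names = NULL, stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, rows)
  out$q <- bh_adjust(out$p)
  attr(out, "n_dropped") <- des$n_dropped
  class(out) <- c("association_table", "data.frame")
  out
}

#' Fit the association model for a single protein
#'
#' Ordinary least squares of one protein's log10 level on the group
#' indicator (PD = 1, NC = 0) and covariates; the group coefficient, its
#' standard error, the t statistic on residual degrees of freedom, and
#' the two-sided p-value from the t reference distribution are returned.
#'
#' @param y numeric vector of log10 levels (one per sample, aligned with
#'   `design` rows).
#' @param design data.frame holding `group` (0/1 or PD/NC factor) and
#'   any covariate columns; all columns are entered as predictors.
#' @return One-row data.frame: `beta`, `se`, `t`, `df`, `p`, `direction`,
#'   `n_used`.
#' @examples
#' d <- data.frame(group = c(0, 0, 0, 1, 1, 1))
#' fit_protein_lm(c(1, 2, 3, 3, 4, 5), d)  # beta 2, p ~ 0.070
#' @export
fit_protein_lm <- function(y, design) {
  if (!is.data.frame(design) || !"group" %in% names(design))
    stop("`design` must be a data.frame containing a `group` column")
  if (length(y) != nrow(design))
    stop("length(y) must equal nrow(design)")
  df <- design
  if (!is.numeric(df$group))
    df$group <- as.numeric(as.character(df$group) == "PD")
  ok <- complete.cases(df) & !is.na(y)
  df <- df[ok, , drop = FALSE]
  y <- y[ok]
  X <- model.matrix(~ ., data = df)
  if (nrow(X) <= ncol(X))
    stop("too few samples (", nrow(X), ") for the design (", ncol(X),
         " columns)")
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    aliased <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("rank-deficient design; collinear term(s): ",
         paste(aliased, collapse = ", "))
  }
  fit <- lm(y ~ ., data = df)
  sm <- suppressWarnings(summary(fit))
  if (sm$sigma < 1e-10) stop("zero residual variance")
  co <- sm$coefficients["group", ]
  data.frame(beta = co[["Estimate"]], se = co[["Std. Error"]],
             t = co[["t value"]], df = fit$df.residual,
             p = co[["Pr(>|t|)"]],
             direction = sign(co[["Estimate"]]), n_used = nrow(X),
             row.names = NULL)
}

#' Discovery-cohort association scan
#'
#' Fits, for every retained protein, the linear model
#' `log10(RFU) ~ group + age + sex + LEDD` (PD = 1, NC = 0; LEDD taken
#' as 0 for controls) and collects the group effect with BH-adjusted
#' p-values across the whole tested family.
#'
#' @param mat log10-scale [protein_matrix()] that passed QC.
#' @param meta sample metadata (see [validate_sample_meta()]).
#' @param covariates covariate names; defaults to the discovery design.
#'   If `ledd` is requested but absent from `meta`, it is dropped with a
#'   warning.
#' @return An `association_table`: one row per protein with `beta`
#'   (log10 PD-NC difference), `se`, `t`, `p`, `q`, `direction`,
#'   `n_used`.
#' @examples
#' cohort <- generate_cohort(sim_config(n_pd = 30, n_nc = 30,
#'                                      n_proteins = 40, n_planted = 4,
#'                                      delta = 0.2, seed = 11))
#' tab <- run_discovery(log10_transform(cohort$matrix), cohort$meta)
#' head(tab[order(tab$p), ])
#' @export
run_discovery <- function(mat, meta, covariates = c("age", "sex", "ledd")) {
  if ("ledd" %in% covariates && !"ledd" %in% names(meta)) {
    warning("`ledd` not in metadata; excluded from the design")
    covariates <- setdiff(covariates, "ledd")
  }
  assoc_engine(mat, meta, covariates)
}

#' @export
print.association_table <- function(x, n = 6, ...) {
  cat(sprintf("<association_table> %d tests, %d with q < 0.05\n",
              nrow(x), sum(x$q < 0.05)))
  print.data.frame(head(x[order(x$p), ], n), digits = 3)
  invisible(x)
}

#' Nominate candidate biomarkers
#'
#' Proteins whose group-effect p-value is strictly below the nomination
#' threshold (default 0.005), sorted by ascending p with ties broken by
#' protein id.
#'
#' @param table an `association_table` from [run_discovery()].
#' @param p_threshold nomination threshold (strict).
#' @return Character vector of candidate protein ids.
#' @export
nominate_candidates <- function(table, p_threshold = 0.005) {
  stopifnot(is.data.frame(table), all(c("protein_id", "p") %in% names(table)))
  hit <- table[table$p < p_threshold, , drop = FALSE]
  hit <- hit[order(hit$p, hit$protein_id), , drop = FALSE]
  hit$protein_id
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment with monotone enforcement; the result is
#' returned in the input order.
#'
#' @param pvals numeric p-values in [0, 1].
#' @return Adjusted q-values, same order as the input.
#' @export
bh_adjust <- function(pvals) {
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  p.adjust(pvals, method = "BH")
}

#' Hierarchical clustering of candidate proteins
#'
#' Per-protein values are centered and scaled across samples, then both
#' proteins and samples are clustered agglomeratively with euclidean
#' distance and average linkage (the heatmap layout of the workflow).
#'
#' @param mat log10-scale [protein_matrix()].
#' @param candidate_ids at least two protein ids to cluster.
#' @return A list of class `candidate_clustering`: `protein_hclust`,
#'   `sample_hclust` (both `hclust` objects), and `heatmap_table` (the
#'   scaled matrix with rows/columns in dendrogram leaf order).
#' @export
cluster_candidates <- function(mat, candidate_ids) {
  stopifnot(inherits(mat, "protein_matrix"))
  if (length(candidate_ids) < 2) stop("need >= 2 candidates to cluster")
  absent <- setdiff(candidate_ids, protein_ids(mat))
  if (length(absent) > 0)
    stop("candidate(s) absent from matrix: ", paste(absent, collapse = ", "))
  v <- mat$values[, candidate_ids, drop = FALSE]
  sds <- apply(v, 2, sd)
  if (any(sds == 0))
    stop("constant protein(s) cannot be scaled: ",
         paste(candidate_ids[sds == 0], collapse = ", "))
  z <- scale(v)
  ph <- hclust(dist(t(z)), method = "average")
  sh <- hclust(dist(z), method = "average")
  structure(list(protein_hclust = ph, sample_hclust = sh,
                 heatmap_table = z[sh$order, ph$order, drop = FALSE]),
            class = "candidate_clustering")
}

#' @export
print.candidate_clustering <- function(x, ...) {
  cat(sprintf("<candidate_clustering> %d proteins x %d samples (euclidean, average linkage)\n",
              ncol(x$heatmap_table), nrow(x$heatmap_table)))
  invisible(x)
}
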