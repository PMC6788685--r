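#' Hybridization normalization
#'
#' Removes per-sample hybridization artifacts using spiked-in control
#' aptamers: each sample is rescaled by
#' `factor_i = median over controls of (reference_c / observed_ic)`.
#' When no external reference levels are supplied, the across-sample
#' median of each control is used (self-contained default in place of
#' vendor calibrator files).
#'
#' @param mat a raw-scale [protein_matrix()].
#' @param control_ids protein ids of the hybridization controls.
#' @param reference_levels optional named positive reference levels for
#'   the controls (raw RFU).
#' @return A list with `matrix` (normalized raw-scale matrix) and
#'   `factors` (named per-sample scale factors).
#' @export
hybridization_normalize <- function(mat, control_ids,
                                    reference_levels = NULL) {
  stopifnot(inherits(mat, "protein_matrix"))
  if (mat$scale != "raw") stop("hybridization normalization needs raw RFU")
  missing <- setdiff(control_ids, protein_ids(mat))
  if (length(missing) > 0)
    stop("control protein(s) absent from matrix: ",
         paste(missing, collapse = ", "))
  obs <- mat$values[, control_ids, drop = FALSE]
  if (any(obs <= 0))
    stop("nonpositive observed control values; cannot form ratios")
  if (is.null(reference_levels)) {
    reference_levels <- apply(obs, 2, median)
  } else {
    missing_ref <- setdiff(control_ids, names(reference_levels))
    if (length(missing_ref) > 0)
      stop("reference levels missing for control(s): ",
           paste(missing_ref, collapse = ", "))
    reference_levels <- reference_levels[control_ids]
    if (any(reference_levels <= 0)) stop("reference levels must be positive")
  }
  ratios <- sweep(1 / obs, 2, reference_levels, "*")
  factors <- apply(ratios, 1, median)
  out <- mat
  out$values <- mat$values * factors
  list(matrix = out, factors = factors)
}

#' Median normalization
#'
#' Removes remaining per-sample (intraplate) biases.  With `r_j` the
#' across-sample median of protein `j`, each sample is rescaled by
#' `factor_i = median over j of (r_j / x_ij)`; afterwards the median
#' ratio to the original reference is exactly 1 for every sample.
#'
#' @param mat a raw-scale [protein_matrix()] with at least 2 samples.
#' @return A list with `matrix` and per-sample `factors`.
#' @export
median_normalize <- function(mat) {
  stopifnot(inherits(mat, "protein_matrix"))
  if (mat$scale != "raw") stop("median normalization needs raw RFU")
  if (nrow(mat$values) < 2) stop("median normalization needs >= 2 samples")
  r <- apply(mat$values, 2, median)
  if (any(r == 0))
    stop("zero-valued protein median(s): ",
         paste(head(names(r)[r == 0], 5), collapse = ", "))
  ratios <- sweep(1 / mat$values, 2, r, "*")
  factors <- apply(ratios, 1, median)
  out <- mat
  out$values <- mat$values * factors
  list(matrix = out, factors = factors)
}

#' Scale-factor gate
#'
#' Flags samples whose hybridization or median scale factors fall
#' outside the assay's acceptance range (default 0.4-2.5; boundary
#' values pass).
#'
#' @param factors positive per-sample scale factors (named).
#' @param low,high acceptance bounds (inclusive).
#' @return A data.frame `(sample_id, factor, pass)`.
#' @export
gate_scale_factors <- function(factors, low = 0.4, high = 2.5) {
  if (any(factors <= 0)) stop("scale factors must be positive")
  data.frame(sample_id = names(factors) %||% seq_along(factors),
             factor = as.numeric(factors),
             pass = factors >= low & factors <= high,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Triplicate CV filter
#'
#' Per reference pool and protein, the coefficient of variation of the
#' three replicate raw RFUs is computed as sample (n-1) standard
#' deviation divided by mean.  A protein is excluded when *any* pool's
#' CV exceeds the threshold (strictly).
#'
#' @param qc_runs long table `(pool, replicate, protein_id, rfu)` with
#'   exactly 3 replicates per pool and protein.
#' @param threshold CV exclusion threshold (default 0.2).
#' @return A list with `cv_table` (`protein_id`, `pool`, `cv`),
#'   `excluded` (protein ids), and `threshold`.
#' @export
triplicate_cv_filter <- function(qc_runs, threshold = 0.2) {
  need <- c("pool", "replicate", "protein_id", "rfu")
  miss <- setdiff(need, names(qc_runs))
  if (length(miss) > 0)
    stop("qc_runs lacks column(s): ", paste(miss, collapse = ", "))
  cnt <- table(qc_runs$protein_id, qc_runs$pool)
  if (any(cnt != 3))
    stop("each (protein, pool) set must have exactly 3 replicates")
  agg_m <- tapply(qc_runs$rfu, list(qc_runs$protein_id, qc_runs$pool), mean)
  if (any(agg_m <= 0)) stop("nonpositive triplicate mean; CV undefined")
  agg_s <- tapply(qc_runs$rfu, list(qc_runs$protein_id, qc_runs$pool), sd)
  cv <- agg_s / agg_m
  cv_table <- data.frame(
    protein_id = rep(rownames(cv), ncol(cv)),
    pool = rep(colnames(cv), each = nrow(cv)),
    cv = as.vector(cv),
    row.names = NULL, stringsAsFactors = FALSE)
  excluded <- sort(rownames(cv)[apply(cv > threshold, 1, any)])
  list(cv_table = cv_table, excluded = excluded, threshold = threshold)
}

#' Limit-of-detection filter
#'
#' Excludes proteins for which more than `max_frac` of measurements lie
#' outside the detection limits (strictly below the LLOD or strictly
#' above the ULOD).  Proteins without annotated limits are retained with
#' a warning, mirroring panels for which limits are unavailable.
#'
#' @param mat a raw-scale [protein_matrix()] carrying `llod`/`ulod`.
#' @param max_frac maximal tolerated out-of-detection fraction (strict;
#'   default 0.25).
#' @return A list with `fractions` (named out-of-detection fraction per
#'   assessable protein), `excluded`, and `skipped` (proteins lacking
#'   limits).
#' @export
lod_filter <- function(mat, max_frac = 0.25) {
  stopifnot(inherits(mat, "protein_matrix"))
  if (mat$scale != "raw") stop("LOD filtering operates on raw RFU")
  prot <- protein_ids(mat)
  have <- prot[prot %in% names(mat$llod) & prot %in% names(mat$ulod)]
  skipped <- setdiff(prot, have)
  if (length(skipped) > 0)
    warning(length(skipped),
            " protein(s) lack detection limits; retained unfiltered")
  if (length(have) == 0)
    return(list(fractions = setNames(numeric(0), character(0)),
                excluded = character(0), skipped = skipped))
  v <- mat$values[, have, drop = FALSE]
  below <- sweep(v, 2, mat$llod[have], "<")
  above <- sweep(v, 2, mat$ulod[have], ">")
  frac <- colMeans(below | above)
  list(fractions = frac,
       excluded = sort(names(frac)[frac > max_frac]),
       skipped = skipped)
}

#' Log10 transform
#'
#' @param mat a raw-scale [protein_matrix()] with strictly positive
#'   values.
#' @return The matrix on the log10 scale.
#' @export
log10_transform <- function(mat) {
  stopifnot(inherits(mat, "protein_matrix"))
  if (mat$scale != "raw") stop("matrix is already log10-transformed")
  if (any(mat$values <= 0))
    stop("log10 transform requires strictly positive values")
  out <- mat
  out$values <- log10(mat$values)
  out$scale <- "log10"
  out
}

#' Run the full preprocessing and QC chain
#'
#' Applies, in order: hybridization normalization (when control ids are
#' given), median normalization, the scale-factor gate on both factor
#' sets (failing samples are dropped), the triplicate-CV filter and the
#' detection-limit filter (their exclusions are unioned; the two act on
#' disjoint evidence, so order is immaterial), and the log10 transform.
#'
#' @param mat raw-scale [protein_matrix()].
#' @param qc_runs optional triplicate table for [triplicate_cv_filter()].
#' @param control_ids optional hybridization-control protein ids (these
#'   are removed from the analyte panel after normalization).
#' @param reference_levels optional control reference levels.
#' @param cv_threshold,lod_max_frac,gate_low,gate_high stage thresholds.
#' @param apply_lod apply the detection-limit filter (set `FALSE` for
#'   panels without annotated limits).
#' @return A list of class `qc_result`: `matrix` (log10 scale, retained
#'   samples and proteins) and `report` (a `qc_report`).
#' @examples
#' cohort <- generate_cohort(sim_config(n_pd = 12, n_nc = 12,
#'                                      n_proteins = 60, seed = 3))
#' qc <- run_qc(cohort$matrix,
#'              qc_runs = generate_qc_triplicates(cohort$config,
#'                                                n_high_cv = 4))
#' qc$report
#' @export
run_qc <- function(mat, qc_runs = NULL, control_ids = NULL,
                   reference_levels = NULL,
                   cv_threshold = 0.2, lod_max_frac = 0.25,
                   gate_low = 0.4, gate_high = 2.5,
                   apply_lod = TRUE) {
  stopifnot(inherits(mat, "protein_matrix"))
  n_assayed <- ncol(mat$values)
  hyb_factors <- NULL
  if (!is.null(control_ids)) {
    hn <- hybridization_normalize(mat, control_ids, reference_levels)
    mat <- hn$matrix
    hyb_factors <- hn$factors
    keep <- setdiff(protein_ids(mat), control_ids)
    mat <- subset_proteins(mat, keep)
    n_assayed <- length(keep)
  }
  mn <- median_normalize(mat)
  mat <- mn$matrix
  med_factors <- mn$factors

  gates <- gate_scale_factors(med_factors, gate_low, gate_high)
  if (!is.null(hyb_factors)) {
    hyb_gates <- gate_scale_factors(hyb_factors, gate_low, gate_high)
    gates$pass <- gates$pass & hyb_gates$pass[match(gates$sample_id,
                                                    hyb_gates$sample_id)]
  }
  dropped_samples <- gates$sample_id[!gates$pass]
  if (length(dropped_samples) > 0)
    mat <- subset_samples(mat, setdiff(sample_ids(mat), dropped_samples))

  cv_excl <- character(0); cv_table <- NULL
  if (!is.null(qc_runs)) {
    cvf <- triplicate_cv_filter(qc_runs, threshold = cv_threshold)
    cv_excl <- intersect(cvf$excluded, protein_ids(mat))
    cv_table <- cvf$cv_table
  }
  lod_excl <- character(0); lod_skipped <- character(0)
  if (apply_lod) {
    lf <- lod_filter(mat, max_frac = lod_max_frac)
    lod_excl <- lf$excluded
    lod_skipped <- lf$skipped
  }
  excluded <- sort(union(cv_excl, lod_excl))
  retained <- setdiff(protein_ids(mat), excluded)
  mat <- subset_proteins(mat, retained)
  mat <- log10_transform(mat)

  reasons <- rbind(
    if (length(cv_excl)) data.frame(id = cv_excl, unit = "protein",
                                    reason = "cv", stringsAsFactors = FALSE),
    if (length(lod_excl)) data.frame(id = lod_excl, unit = "protein",
                                     reason = "lod", stringsAsFactors = FALSE),
    if (length(dropped_samples)) data.frame(id = dropped_samples,
                                            unit = "sample",
                                            reason = "scale_factor",
                                            stringsAsFactors = FALSE))
  report <- structure(list(
    hybridization_factors = hyb_factors,
    median_factors = med_factors,
    gates = gates,
    cv_table = cv_table,
    exclusions = reasons,
    lod_skipped = lod_skipped,
    n_assayed = n_assayed,
    n_retained = length(retained),
    n_excluded_cv = length(cv_excl),
    n_excluded_lod = length(lod_excl),
    n_samples_dropped = length(dropped_samples),
    thresholds = list(cv = cv_threshold, lod_max_frac = lod_max_frac,
                      gate = c(gate_low, gate_high))
  ), class = "qc_report")
  structure(list(matrix = mat, report = report), class = "qc_result")
}

#' @export
print.qc_report <- function(x, ...) {
  cat("<qc_report>\n")
  cat(sprintf("  proteins assayed:  %d\n", x$n_assayed))
  cat(sprintf("  excluded, CV > %.2g:        %d\n", x$thresholds$cv,
              x$n_excluded_cv))
  cat(sprintf("  excluded, >%.0f%% outside LOD: %d\n",
              100 * x$thresholds$lod_max_frac, x$n_excluded_lod))
  cat(sprintf("  proteins retained: %d\n", x$n_retained))
  cat(sprintf("  samples dropped (scale factor outside %.2g-%.2g): %d\n",
              x$thresholds$gate[1], x$thresholds$gate[2],
              x$n_samples_dropped))
  invisible(x)
}
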