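# Preanalytical and medication-state robustness: paired on/off tests
# and handling-induced percent change.

#' Paired t test per protein
#'
#' Classic paired t on the ON-OFF differences, `df = n - 1`.  When all
#' differences are zero the statistic is undefined; such proteins are
#' reported with p = 1 and flagged `degenerate` (documented convention
#' for a literally unchanged protein).
#'
#' @param on,off numeric vectors (one protein) or matrices
#'   (subjects x proteins) of log10 levels, rows paired by subject.
#' @return A data.frame `(protein_id, mean_diff, t, df, p, degenerate)`.
#' @examples
#' paired_ttest(c(2, 3, 4), c(1, 1, 1))  # diffs 1,2,3: t = 3.464
#' @export
paired_ttest <- function(on, off) {
  on <- as.matrix(on); off <- as.matrix(off)
  if (!all(dim(on) == dim(off)))
    stop("`on` and `off` must have identical dimensions")
  if (nrow(on) < 2) stop("paired t test needs n >= 2 pairs")
  d <- on - off
  n <- nrow(d)
  m <- colMeans(d)
  s <- apply(d, 2, sd)
  degen <- s == 0
  tt <- ifelse(degen, NA_real_, m / (s / sqrt(n)))
  p <- ifelse(degen, ifelse(m == 0, 1, 0), 2 * pt(-abs(tt), n - 1))
  data.frame(protein_id = colnames(d) %||% as.character(seq_along(m)),
             mean_diff = m, t = tt, df = n - 1, p = p,
             degenerate = degen, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Paired sign-flip permutation test per protein
#'
#' Statistic: |mean ON-OFF difference|.  For n <= `max_exact_n` pairs
#' the null is the full set of 2^n sign flips, enumerated exactly, and
#' p is the proportion of the null at least as extreme as observed (the
#' identity flip makes p >= 2^-n automatically).  Larger n uses
#' Monte-Carlo sign flips with the add-one convention
#' `p = (1 + #{null >= obs}) / (n_mc + 1)`.
#'
#' @param on,off paired vectors or subject-by-protein matrices.
#' @param max_exact_n largest n for exact enumeration (default 12).
#' @param n_mc Monte-Carlo flips beyond that.
#' @param seed seed for the Monte-Carlo path.
#' @return A data.frame `(protein_id, mean_diff, p, exact)`.
#' @examples
#' paired_permutation(c(2, 3, 4), c(1, 1, 1))  # diffs 1,2,3: p = 0.25
#' @export
paired_permutation <- function(on, off, max_exact_n = 12, n_mc = 10000,
                               seed = 1) {
  on <- as.matrix(on); off <- as.matrix(off)
  if (!all(dim(on) == dim(off)))
    stop("`on` and `off` must have identical dimensions")
  d <- on - off
  n <- nrow(d)
  if (n < 2) stop("paired permutation test needs n >= 2 pairs")
  obs <- abs(colMeans(d))
  exact <- n <= max_exact_n
  eps <- 1e-12
  if (exact) {
    signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
    null_means <- abs(signs %*% d) / n          # 2^n x p
    p <- colMeans(sweep(null_means, 2, obs - eps, ">="))
  } else {
    p <- with_seed(child_seed(seed, "permutation"), {
      hits <- numeric(ncol(d))
      for (b in seq_len(n_mc)) {
        s <- sample(c(-1, 1), n, replace = TRUE)
        hits <- hits + (abs(colMeans(s * d)) >= obs - eps)
      }
      (1 + hits) / (n_mc + 1)
    })
  }
  data.frame(protein_id = colnames(d) %||% as.character(seq_along(obs)),
             mean_diff = colMeans(d), p = p, exact = exact,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Handling-induced percent change
#'
#' Relative change of each protein between a baseline reference-pool
#' aliquot and a handling-perturbed aliquot, computed on raw RFU:
#' `change = (perturbed - baseline) / baseline`.  Proteins whose
#' absolute change exceeds the threshold (default 30%) are flagged.
#'
#' @param baseline_pool,perturbed_pool named raw-RFU vectors over the
#'   same protein panel.
#' @param flag_threshold absolute relative-change threshold (strict).
#' @return A data.frame `(protein_id, change, percent, flagged)`.
#' @export
handling_percent_change <- function(baseline_pool, perturbed_pool,
                                    flag_threshold = 0.30) {
  if (is.null(names(baseline_pool)) || is.null(names(perturbed_pool)))
    stop("pool vectors must be named by protein id")
  if (!setequal(names(baseline_pool), names(perturbed_pool)))
    stop("pool panels do not match")
  perturbed_pool <- perturbed_pool[names(baseline_pool)]
  if (any(baseline_pool <= 0)) stop("baseline pool values must be positive")
  change <- (perturbed_pool - baseline_pool) / baseline_pool
  data.frame(protein_id = names(baseline_pool),
             change = as.numeric(change),
             percent = 100 * as.numeric(change),
             flagged = abs(change) > flag_threshold,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Long-format interface for the paired medication analysis
#'
#' Convenience converter from a long table
#' `(subject_id, state, protein_id, rfu)` to the paired matrices used
#' by [paired_ttest()] and [paired_permutation()]; values are log10
#' transformed.
#'
#' @param onoff long-format data.frame with states `"ON"`/`"OFF"`.
#' @return A list with matrices `on` and `off` (subjects x proteins).
#' @export
onoff_matrices <- function(onoff) {
  need <- c("subject_id", "state", "protein_id", "rfu")
  miss <- setdiff(need, names(onoff))
  if (length(miss) > 0)
    stop("onoff table lacks column(s): ", paste(miss, collapse = ", "))
  if (!all(onoff$state %in% c("ON", "OFF")))
    stop("state must be ON or OFF")
  mk <- function(st) {
    d <- onoff[onoff$state == st, ]
    tab <- tapply(d$rfu, list(d$subject_id, d$protein_id), mean)
    if (anyNA(tab)) stop("incomplete ", st, " measurements")
    log10(tab)
  }
  on <- mk("ON"); off <- mk("OFF")
  off <- off[rownames(on), colnames(on), drop = FALSE]
  list(on = on, off = off)
}
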