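#' Protein measurement matrix
#'
#' The analysis substrate: a samples-by-proteins table of aptamer
#' measurements, either raw relative-fluorescence units (RFU) or their
#' log10 transform, with optional per-protein detection limits (raw RFU).
#'
#' @param values numeric matrix, samples in rows, proteins in columns;
#'   both dimensions must carry unique names.
#' @param scale `"raw"` or `"log10"`.  Raw values must be nonnegative.
#' @param llod,ulod optional named numeric vectors of lower/upper limits
#'   of detection, in raw RFU, named by protein id.
#' @return An object of class `protein_matrix`: a list with elements
#'   `values`, `scale`, `llod`, `ulod`.
#' @examples
#' m <- matrix(c(1000, 2000, 1500, 2500), 2, 2,
#'             dimnames = list(c("s1", "s2"), c("p1", "p2")))
#' pm <- protein_matrix(m, scale = "raw")
#' pm
#' @export
protein_matrix <- function(values, scale = c("raw", "log10"),
                           llod = NULL, ulod = NULL) {
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must have sample (row) and protein (column) names")
  if (anyDuplicated(rownames(values)))
    stop("duplicate sample ids: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]),
               collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop("duplicate protein ids: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]),
               collapse = ", "))
  if (scale == "raw" && any(values < 0, na.rm = TRUE))
    stop("raw RFU values must be nonnegative")
  for (lim in list(llod = llod, ulod = ulod)) {
    if (!is.null(lim) && is.null(names(lim)))
      stop("detection limits must be named by protein id")
  }
  structure(list(values = values, scale = scale, llod = llod, ulod = ulod),
            class = "protein_matrix")
}

#' @export
print.protein_matrix <- function(x, ...) {
  cat(sprintf("<protein_matrix> %d samples x %d proteins [%s scale]\n",
              nrow(x$values), ncol(x$values), x$scale))
  n_lim <- sum(colnames(x$values) %in% names(x$llod))
  if (n_lim > 0)
    cat(sprintf("  detection limits for %d proteins\n", n_lim))
  invisible(x)
}

#' @export
dim.protein_matrix <- function(x) dim(x$values)

#' Sample and protein identifiers of a matrix
#'
#' @param x a [protein_matrix()].
#' @return Character vector of ids.
#' @export
sample_ids <- function(x) rownames(x$values)

#' @rdname sample_ids
#' @export
protein_ids <- function(x) colnames(x$values)

# Subset a protein_matrix, keeping limit annotations aligned.
subset_proteins <- function(x, ids) {
  missing <- setdiff(ids, protein_ids(x))
  if (length(missing) > 0)
    stop("proteins absent from matrix: ", paste(missing, collapse = ", "))
  protein_matrix(x$values[, ids, drop = FALSE], scale = x$scale,
                 llod = x$llod[intersect(ids, names(x$llod))],
                 ulod = x$ulod[intersect(ids, names(x$ulod))])
}

subset_samples <- function(x, ids) {
  missing <- setdiff(ids, sample_ids(x))
  if (length(missing) > 0)
    stop("samples absent from matrix: ", paste(missing, collapse = ", "))
  protein_matrix(x$values[ids, , drop = FALSE], scale = x$scale,
                 llod = x$llod, ulod = x$ulod)
}

#' Validate a sample metadata table
#'
#' Checks the per-sample phenotype/covariate table used throughout the
#' workflow.  Required columns: `sample_id`, `group` (levels among NC,
#' PD, ALS), `age` (years), `sex` (`"F"`/`"M"` or 1/0 with female = 1).
#' Optional: `site`, `batch`, `ledd` (mg/day), `treated` (logical),
#' `disease_duration` (years), `education` (years).
#'
#' @param meta a data.frame.
#' @return `meta`, with `group` as a factor with reference level NC, and
#'   `sex` coerced to a 0/1 numeric indicator (female = 1).
#' @export
validate_sample_meta <- function(meta) {
  required <- c("sample_id", "group", "age", "sex")
  miss <- setdiff(required, names(meta))
  if (length(miss) > 0)
    stop("sample metadata lacks required columns: ",
         paste(miss, collapse = ", "))
  allowed <- c("NC", "PD", "ALS")
  bad <- setdiff(unique(as.character(meta$group)), allowed)
  if (length(bad) > 0)
    stop("unknown group level(s) ", paste(bad, collapse = ", "),
         "; allowed: ", paste(allowed, collapse = ", "))
  # level order NC, PD, ALS puts NC as the reference where present
  meta$group <- factor(as.character(meta$group),
                       levels = intersect(allowed, unique(as.character(meta$group))))
  if (anyDuplicated(meta$sample_id))
    stop("duplicate sample ids in metadata")
  meta$sex <- code_sex(meta$sex)
  if (!is.numeric(meta$age)) stop("`age` must be numeric (years)")
  meta
}

# Female = 1, male = 0 (so coefficient signs read as the female contrast).
code_sex <- function(sex) {
  if (is.numeric(sex)) {
    if (!all(sex %in% c(0, 1))) stop("numeric `sex` must be 0/1 (female = 1)")
    return(as.numeric(sex))
  }
  s <- toupper(as.character(sex))
  out <- ifelse(s %in% c("F", "FEMALE"), 1,
                ifelse(s %in% c("M", "MALE"), 0, NA_real_))
  if (anyNA(out)) stop("unrecognized sex codes: ",
                       paste(unique(s[is.na(out)]), collapse = ", "))
  out
}
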