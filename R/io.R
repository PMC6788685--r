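# Readers and writers for the tabular interchange formats, the newick
# dendrogram export, and packaged cohort demographics.

#' Read a protein matrix from TSV
#'
#' Expects a rectangular tab-separated table: first column `sample_id`,
#' remaining columns one protein each.  A leading directive line
#' `# scale: raw` or `# scale: log10` sets the scale; otherwise pass
#' `scale`.  An optional annotation sidecar (`protein_id`, `llod`,
#' `ulod`) attaches detection limits.
#'
#' @param path TSV file path.
#' @param scale `"raw"` or `"log10"`; overridden by a file directive.
#' @param annotations optional path of the detection-limit sidecar.
#' @return A [protein_matrix()].
#' @export
read_protein_matrix <- function(path, scale = "raw", annotations = NULL) {
  if (!file.exists(path)) stop("input file not found: ", path)
  first <- readLines(path, n = 1)
  if (grepl("^#\\s*scale:", first)) {
    scale <- trimws(sub("^#\\s*scale:", "", first))
  }
  d <- read.delim(path, comment.char = "#", check.names = FALSE,
                  stringsAsFactors = FALSE)
  if (ncol(d) < 2) stop("matrix file needs a sample column plus proteins")
  ids <- as.character(d[[1]])
  prot <- colnames(d)[-1]
  if (anyDuplicated(prot))
    stop("duplicate protein column(s): ",
         paste(unique(prot[duplicated(prot)]), collapse = ", "))
  if (anyDuplicated(ids))
    stop("duplicate sample id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  vals <- as.matrix(d[, -1, drop = FALSE])
  if (!is.numeric(vals)) {
    bad <- which(!vapply(d[-1], is.numeric, logical(1)))
    stop("non-numeric cells in column(s): ",
         paste(prot[bad], collapse = ", "))
  }
  rownames(vals) <- ids
  llod <- ulod <- NULL
  if (!is.null(annotations)) {
    ann <- read.delim(annotations, stringsAsFactors = FALSE)
    need <- c("protein_id", "llod", "ulod")
    miss <- setdiff(need, names(ann))
    if (length(miss) > 0)
      stop("annotation sidecar lacks column(s): ",
           paste(miss, collapse = ", "))
    llod <- setNames(ann$llod, ann$protein_id)
    ulod <- setNames(ann$ulod, ann$protein_id)
  }
  protein_matrix(vals, scale = scale, llod = llod, ulod = ulod)
}

#' Write a protein matrix to TSV
#'
#' @param mat a [protein_matrix()].
#' @param path output TSV path (a `# scale:` directive is written).
#' @export
write_protein_matrix <- function(mat, path) {
  stopifnot(inherits(mat, "protein_matrix"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# scale: ", mat$scale), con)
  d <- data.frame(sample_id = rownames(mat$values),
                  mat$values, check.names = FALSE,
                  stringsAsFactors = FALSE)
  write.table(d, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read sample metadata from TSV
#'
#' Required columns: `sample_id`, `group`, `age`, `sex`; optional
#' columns (`site`, `batch`, `ledd`, `treated`, `disease_duration`,
#' `education`) are tolerated when missing, with a notice.
#'
#' @param path TSV path.
#' @return A validated metadata data.frame.
#' @export
read_sample_meta <- function(path) {
  if (!file.exists(path)) stop("input file not found: ", path)
  d <- read.delim(path, stringsAsFactors = FALSE)
  optional <- c("site", "batch", "ledd", "treated", "disease_duration",
                "education")
  absent <- setdiff(optional, names(d))
  if (length(absent) > 0)
    message("optional metadata column(s) absent: ",
            paste(absent, collapse = ", "))
  validate_sample_meta(d)
}

#' Export a dendrogram in newick format
#'
#' @param hc an `hclust` object (e.g. from [cluster_candidates()]).
#' @param path output file.
#' @export
export_newick <- function(hc, path) {
  stopifnot(inherits(hc, "hclust"))
  ape::write.tree(ape::as.phylo(hc), file = path)
  invisible(path)
}

#' Write an association table as tidy TSV
#'
#' @param table an `association_table`.
#' @param path output file.
#' @export
write_association_table <- function(table, path) {
  cols <- intersect(c("protein_id", "term", "beta", "se", "t", "p", "q",
                      "direction", "n_used"), names(table))
  write.table(table[, cols], path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Demographic summary of the emulated cohorts
#'
#' Group sizes and age distributions of the discovery, replication
#' (including ALS) and paired-medication cohorts that the synthetic
#' generator emulates, as packaged reference data.
#'
#' @return A data.frame with one row per cohort and group: `cohort`,
#'   `group`, `n`, `n_female`, `n_male`, `age_mean`, `age_sd`.
#' @export
cohort_demographics <- function() {
  read.delim(system.file("extdata", "cohort_demographics.tsv",
                         package = "proteodiscover"),
             stringsAsFactors = FALSE)
}

#' Pooled mean age of a cohort
#'
#' Sample-size-weighted mean age over the requested groups.
#'
#' @param cohort cohort name in [cohort_demographics()].
#' @param groups groups to pool (default PD + NC).
#' @return Pooled mean age in years.
#' @export
cohort_mean_age <- function(cohort, groups = c("PD", "NC")) {
  d <- cohort_demographics()
  d <- d[d$cohort == cohort & d$group %in% groups, ]
  if (nrow(d) == 0) stop("unknown cohort: ", cohort)
  sum(d$n * d$age_mean) / sum(d$n)
}

#' Cohort size over groups
#'
#' @param cohort cohort name in [cohort_demographics()].
#' @param groups groups to count.
#' @return Total participants.
#' @export
cohort_group_size <- function(cohort, groups = c("PD", "NC")) {
  d <- cohort_demographics()
  d <- d[d$cohort == cohort & d$group %in% groups, ]
  if (nrow(d) == 0) stop("unknown cohort: ", cohort)
  sum(d$n)
}

#' Load a measured supplementary cohort table, when available
#'
#' The measured cohort data (wide protein matrix plus demographics) are
#' distributed as journal supplementary spreadsheets and are not
#' packaged here.  If a TSV export is placed at the given path (first
#' column `sample_id`, protein columns, plus metadata columns), this
#' reads it into the workflow's containers; otherwise it stops with an
#' informative error.
#'
#' @param path TSV export of the supplementary table.
#' @param meta_cols column names to split off into sample metadata.
#' @param scale measurement scale of the protein columns.
#' @return A list with `matrix` ([protein_matrix()]) and `meta`.
#' @export
read_supplementary_cohort <- function(path,
                                      meta_cols = c("group", "age", "sex",
                                                    "ledd"),
                                      scale = "log10") {
  if (!file.exists(path))
    stop("supplementary cohort table not available at `", path,
         "`; export the published spreadsheet to TSV and pass its path")
  d <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  meta_cols <- intersect(meta_cols, names(d))
  meta <- data.frame(sample_id = as.character(d[[1]]),
                     d[, meta_cols, drop = FALSE],
                     stringsAsFactors = FALSE)
  vals <- as.matrix(d[, setdiff(names(d)[-1], meta_cols), drop = FALSE])
  rownames(vals) <- meta$sample_id
  list(matrix = protein_matrix(vals, scale = scale),
       meta = validate_sample_meta(meta))
}
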