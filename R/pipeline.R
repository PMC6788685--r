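# End-to-end orchestration of the synthetic discovery -> replication ->
# progression workflow, with a machine-readable run manifest.

#' Workflow run configuration
#'
#' Collects every stage threshold (at its reference default), the
#' synthetic-study design, the output directory, and the global seed
#' from which all stage seeds fan out.
#'
#' @param seed global seed.
#' @param out_dir output directory for report tables (`NULL` = none).
#' @param discovery,replication [sim_config()]s for the two cohorts.
#' @param stability a [stability_config()].
#' @param p_nomination nomination threshold on the group-effect p.
#' @param fdr_alpha FDR threshold for replication calls.
#' @param cv_threshold,lod_max_frac,gate_low,gate_high QC thresholds.
#' @param top_k_size shortlist size advanced to replication.
#' @param handling_threshold |relative change| flag level.
#' @return A list of class `run_config`.
#' @export
run_config <- function(seed = 1, out_dir = NULL,
                       discovery = sim_config(seed = seed),
                       replication = sim_config(
                         n_pd = 215, n_nc = 102, n_proteins = 1305,
                         n_sites = 2, n_batches = 5,
                         censor_frac_target = 0, seed = seed + 1),
                       stability = stability_config(seed = seed),
                       p_nomination = 0.005, fdr_alpha = 0.05,
                       cv_threshold = 0.2, lod_max_frac = 0.25,
                       gate_low = 0.4, gate_high = 2.5,
                       top_k_size = 10, handling_threshold = 0.30) {
  structure(list(seed = seed, out_dir = out_dir,
                 discovery = discovery, replication = replication,
                 stability = stability,
                 p_nomination = p_nomination, fdr_alpha = fdr_alpha,
                 cv_threshold = cv_threshold, lod_max_frac = lod_max_frac,
                 gate_low = gate_low, gate_high = gate_high,
                 top_k_size = top_k_size,
                 handling_threshold = handling_threshold),
            class = "run_config")
}

#' Provenance hash of a run configuration
#'
#' FNV-1a hash over the deparsed configuration; any threshold or design
#' change changes the hash, which is stamped into every report.
#'
#' @param config a [run_config()].
#' @return 8-character hex string.
#' @export
config_hash <- function(config) {
  fnv1a_hash(paste(deparse(unclass(config)), collapse = ""))
}

#' Run the full synthetic biomarker workflow
#'
#' Simulates a discovery and a replication cohort sharing planted
#' effects, runs QC, the discovery association scan, candidate
#' nomination, Stability-Selection ranking, replication with direction
#' concordance, the medication and handling robustness stages, and the
#' progression models (mixed-effects interaction and tertile Cox), and
#' returns all stage outputs plus a provenance manifest.  With
#' `out_dir` set, tidy TSV reports and a JSON manifest are written.
#'
#' Each stage is equally runnable on its own through the exported stage
#' functions ([generate_cohort()], [run_qc()], [run_discovery()],
#' [stability_rank()], [run_replication()], [paired_ttest()],
#' [fit_lmm()], [fit_cox()], ...); this orchestrator fixes their order
#' and provenance.
#'
#' @param config a [run_config()].
#' @return A list of class `pipeline_result` with elements `discovery`,
#'   `qc`, `associations`, `candidates`, `ranking`, `top`,
#'   `replication`, `replicated`, `robustness`, `progression`,
#'   `manifest`.
#' @examples
#' \donttest{
#' cfg <- run_config(seed = 42,
#'                   discovery = sim_config(n_pd = 24, n_nc = 24,
#'                                          n_proteins = 60, n_planted = 3,
#'                                          delta = 0.25, seed = 42),
#'                   replication = sim_config(n_pd = 40, n_nc = 30,
#'                                            n_proteins = 60, n_sites = 2,
#'                                            n_batches = 2,
#'                                            censor_frac_target = 0,
#'                                            seed = 43),
#'                   stability = stability_config(iterations = 300,
#'                                                seed = 42))
#' res <- run_pipeline(cfg)
#' res$manifest$counts
#' }
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  counts <- list()

  # --- simulate ------------------------------------------------------
  disc <- generate_cohort(config$discovery, group_prefix = "D")
  qc_runs <- generate_qc_triplicates(config$discovery)
  repl <- generate_cohort(config$replication,
                          planted_ids = intersect(
                            disc$truth$planted_ids,
                            sprintf("P%04d", seq_len(config$replication$n_proteins))),
                          delta_per_protein = disc$truth$delta_per_protein[
                            intersect(disc$truth$planted_ids,
                                      sprintf("P%04d",
                                              seq_len(config$replication$n_proteins)))],
                          group_prefix = "R")
  counts$discovery_samples <- nrow(disc$matrix$values)
  counts$replication_samples <- nrow(repl$matrix$values)

  # --- qc ------------------------------------------------------------
  qc <- run_qc(disc$matrix, qc_runs = qc_runs,
               cv_threshold = config$cv_threshold,
               lod_max_frac = config$lod_max_frac,
               gate_low = config$gate_low, gate_high = config$gate_high)
  counts$proteins_retained <- qc$report$n_retained
  repl_log <- log10_transform(repl$matrix)

  # --- discover ------------------------------------------------------
  assoc <- run_discovery(qc$matrix, disc$meta)
  candidates <- nominate_candidates(assoc, config$p_nomination)
  counts$candidates <- length(candidates)
  clustering <- if (length(candidates) >= 2)
    cluster_candidates(qc$matrix, candidates) else NULL

  # --- rank ----------------------------------------------------------
  ranking <- NULL; top <- character(0)
  if (length(candidates) >= 2) {
    meta_d <- disc$meta[match(sample_ids(qc$matrix), disc$meta$sample_id), ]
    ranking <- stability_rank(qc$matrix, meta_d$group, candidates,
                              config$stability)
    top <- top_k(ranking, config$top_k_size)
  }
  counts$top_k <- length(top)

  # --- replicate -----------------------------------------------------
  repl_assoc <- NULL; replicated <- character(0)
  if (length(top) > 0) {
    repl_assoc <- run_replication(repl_log, repl$meta, top)
    replicated <- check_replication(assoc[assoc$protein_id %in% top, ],
                                    repl_assoc, alpha = config$fdr_alpha)
  }
  counts$replicated <- length(replicated)

  # --- robustness ----------------------------------------------------
  onoff <- generate_paired_onoff(config$discovery)
  om <- list(on = log10(onoff$matrix$values[onoff$meta$state == "ON", ,
                                            drop = FALSE]),
             off = log10(onoff$matrix$values[onoff$meta$state == "OFF", ,
                                             drop = FALSE]))
  tt <- paired_ttest(om$on, om$off)
  perm <- paired_permutation(om$on, om$off, seed = config$seed)
  pools <- generate_handling_pools(config$discovery)
  handling <- handling_percent_change(pools$baseline, pools$perturbed,
                                      config$handling_threshold)
  counts$onoff_p01 <- sum(tt$p < 0.01, na.rm = TRUE)
  counts$handling_flagged <- sum(handling$flagged)

  # --- progression ---------------------------------------------------
  longit <- generate_longitudinal(disc)
  x <- setNames(log10(disc$matrix$values[, disc$truth$lmm_protein]),
                rownames(disc$matrix$values))
  lmm <- fit_lmm(longit, x, disc$meta)
  surv <- generate_conversion_times(disc)
  cox <- fit_cox(surv)
  counts$conversion_events <- sum(surv$event)

  manifest <- list(
    config_hash = config_hash(config),
    seed = config$seed,
    counts = counts,
    thresholds = list(p_nomination = config$p_nomination,
                      fdr_alpha = config$fdr_alpha,
                      cv = config$cv_threshold,
                      lod_max_frac = config$lod_max_frac,
                      gate = c(config$gate_low, config$gate_high)))

  result <- structure(list(
    discovery = disc, qc = qc, associations = assoc,
    candidates = candidates, clustering = clustering,
    ranking = ranking, top = top,
    replication = repl_assoc, replicated = replicated,
    robustness = list(paired_t = tt, paired_permutation = perm,
                      handling = handling),
    progression = list(lmm = lmm, cox = cox, survival = surv),
    manifest = manifest), class = "pipeline_result")

  if (!is.null(config$out_dir)) write_pipeline_reports(result, config)
  result
}

write_pipeline_reports <- function(result, config) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  outp <- function(f) file.path(config$out_dir, f)
  write_association_table(result$associations, outp("discovery_associations.tsv"))
  if (!is.null(result$replication))
    write_association_table(result$replication, outp("replication_associations.tsv"))
  if (!is.null(result$ranking)) {
    con <- file(outp("stability_ranking.tsv"), "w")
    cfg <- attr(result$ranking, "config")
    writeLines(sprintf("# iterations: %d; out-of-bag: %.2f samples, %.2f features; config: %s",
                       cfg$iterations, cfg$frac_samples_out,
                       cfg$frac_features_out,
                       result$manifest$config_hash), con)
    write.table(as.data.frame(result$ranking), con, sep = "\t",
                quote = FALSE, row.names = FALSE)
    close(con)
  }
  if (!is.null(result$clustering)) {
    export_newick(result$clustering$protein_hclust,
                  outp("candidate_proteins.nwk"))
    export_newick(result$clustering$sample_hclust,
                  outp("candidate_samples.nwk"))
  }
  write.table(result$robustness$paired_t, outp("onoff_paired_t.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(result$robustness$handling, outp("handling_change.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(result$manifest, outp("manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(config$out_dir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  utils::str(x$manifest$counts, give.head = FALSE)
  invisible(x)
}
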