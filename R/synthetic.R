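#' Configuration for the synthetic cohort generator
#'
#' Defaults emulate the single-site discovery design: 96 PD and 45 NC
#' participants, 1,129 assayed proteins, planted group effects on the
#' log10-RFU scale, demographically matched groups, and a fraction of
#' proteins pushed against the lower limit of detection so the
#' detection-limit filter has work to do.
#'
#' @param n_pd,n_nc participants per group.
#' @param n_proteins proteins assayed.
#' @param n_planted proteins carrying a true group effect.
#' @param delta magnitude of the planted PD-NC effect (log10 RFU);
#'   planted signs alternate so both directions occur.
#' @param age_slope log10-RFU change per year of age.
#' @param sex_offset log10-RFU offset for female participants.
#' @param n_sites,site_sd number of clinical sites and the SD of the
#'   per-site multiplicative shift (log10 scale).
#' @param n_batches,batch_sd number of assay plates and the SD of the
#'   per-plate multiplicative shift (log10 scale).
#' @param block_size,block_rho proteins per correlated block and the
#'   within-block correlation (shared latent factor construction).
#' @param noise_sd residual log10-RFU SD.
#' @param llod,ulod assay detection limits, raw RFU.
#' @param censor_frac_target fraction of proteins whose baseline is set
#'   low enough that the >25% out-of-detection rule should catch them
#'   (default 125/1129, the study's discovery-panel censoring load).
#' @param seed integer seed; identical configs give identical cohorts.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_pd = 96, n_nc = 45, n_proteins = 1129,
                       n_planted = 20, delta = 0.1,
                       age_slope = 0.002, sex_offset = 0.02,
                       n_sites = 1, site_sd = 0.1,
                       n_batches = 1, batch_sd = 0.1,
                       block_size = 10, block_rho = 0.3,
                       noise_sd = 0.15,
                       llod = 200, ulod = 60000,
                       censor_frac_target = 125 / 1129,
                       seed = 1) {
  cfg <- list(n_pd = n_pd, n_nc = n_nc, n_proteins = n_proteins,
              n_planted = n_planted, delta = delta,
              age_slope = age_slope, sex_offset = sex_offset,
              n_sites = n_sites, site_sd = site_sd,
              n_batches = n_batches, batch_sd = batch_sd,
              block_size = block_size, block_rho = block_rho,
              noise_sd = noise_sd, llod = llod, ulod = ulod,
              censor_frac_target = censor_frac_target, seed = seed)
  counts <- c("n_pd", "n_nc", "n_proteins", "n_planted", "n_sites",
              "n_batches", "block_size")
  for (f in counts) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v) || v < 0 ||
        v != round(v))
      stop("invalid config field `", f, "`: must be a nonnegative integer")
  }
  if (cfg$n_pd + cfg$n_nc < 2) stop("invalid config field `n_pd`/`n_nc`: need >= 2 samples")
  if (cfg$n_proteins < 1) stop("invalid config field `n_proteins`: need >= 1")
  if (cfg$n_planted > cfg$n_proteins)
    stop("invalid config field `n_planted`: exceeds n_proteins")
  if (cfg$n_sites < 1) stop("invalid config field `n_sites`: need >= 1")
  if (cfg$n_batches < 1) stop("invalid config field `n_batches`: need >= 1")
  if (cfg$block_size < 1) stop("invalid config field `block_size`: need >= 1")
  if (!is.finite(cfg$block_rho) || cfg$block_rho < 0 || cfg$block_rho >= 1)
    stop("invalid config field `block_rho`: must lie in [0, 1)")
  for (f in c("delta", "age_slope", "sex_offset", "site_sd", "batch_sd",
              "noise_sd", "censor_frac_target")) {
    if (!is.numeric(cfg[[f]]) || !is.finite(cfg[[f]]))
      stop("invalid config field `", f, "`: must be finite numeric")
  }
  if (cfg$noise_sd < 0) stop("invalid config field `noise_sd`: must be >= 0")
  if (cfg$censor_frac_target < 0 || cfg$censor_frac_target > 1)
    stop("invalid config field `censor_frac_target`: must lie in [0, 1]")
  if (!(cfg$llod < cfg$ulod))
    stop("invalid config field `llod`: llod must be below ulod")
  structure(cfg, class = "sim_config")
}

#' Generate a synthetic discovery-style cohort
#'
#' Raw RFU values are built as `10^(baseline_j + delta_j * group +
#' age_slope * (age - mean age) + sex_offset * female + site shift +
#' batch shift + block factor + noise)`.  Ages and sexes are drawn from
#' the same distribution in both groups (normal(70, 8) truncated to
#' 45-95 years; Bernoulli(1/2) female), so the groups are matched in
#' expectation.  Baseline log10 abundances are uniform on [2.5, 4.5]; a
#' `censor_frac_target` fraction of (never planted) proteins is instead
#' anchored just below the lower detection limit.  Block correlation is
#' induced by a shared latent factor: the noise term is
#' `noise_sd * (sqrt(rho) * F_block + sqrt(1 - rho) * Z)`.
#'
#' @param config a [sim_config()].
#' @param planted_ids,delta_per_protein optionally force which proteins
#'   carry effects and their signed sizes (used to share ground truth
#'   between a discovery and a replication cohort).
#' @param n_als number of additional ALS participants (group "ALS").
#' @param als_delta named vector of log10 effects applied to ALS samples
#'   (e.g. a shared-with-PD marker); defaults to none.
#' @param group_prefix prefix for generated sample ids.
#' @return A list of class `synthetic_cohort` with elements `matrix`
#'   (raw-scale [protein_matrix()] with detection limits), `meta`
#'   (sample metadata), and `truth` (ground-truth record: planted ids,
#'   signed effects, censored ids, designated longitudinal/survival
#'   proteins with their planted parameters, medication-effect ids).
#' @examples
#' cohort <- generate_cohort(sim_config(n_pd = 20, n_nc = 20,
#'                                      n_proteins = 50, seed = 7))
#' cohort$matrix
#' head(cohort$truth$planted_ids)
#' @export
generate_cohort <- function(config, planted_ids = NULL,
                            delta_per_protein = NULL,
                            n_als = 0, als_delta = NULL,
                            group_prefix = "S") {
  stopifnot(inherits(config, "sim_config"))
  with_seed(child_seed(config$seed, "cohort"), {
    n <- config$n_pd + config$n_nc + n_als
    prot <- sprintf("P%04d", seq_len(config$n_proteins))
    samp <- sprintf("%s%04d", group_prefix, seq_len(n))
    group <- c(rep("PD", config$n_pd), rep("NC", config$n_nc),
               rep("ALS", n_als))

    # demographics: identical distributions across groups
    age <- rnorm_trunc(n, 70, 8, 45, 95)
    sex <- rbinom(n, 1, 0.5)
    site <- factor(sprintf("site%d", sample.int(config$n_sites, n, replace = TRUE)))
    batch <- factor(sprintf("plate%d", sample.int(config$n_batches, n, replace = TRUE)))
    ledd <- ifelse(group == "PD", pmax(0, rnorm(n, 600, 250)), 0)
    treated <- ifelse(group == "PD", runif(n) > 18 / 215, FALSE)
    disease_duration <- ifelse(group == "PD", rgamma(n, shape = 4, scale = 1.5), 0)
    education <- round(rnorm_trunc(n, 15, 3, 8, 22))

    # protein-level structure
    baseline <- runif(config$n_proteins, 2.5, 4.5)
    n_cens <- round(config$censor_frac_target * config$n_proteins)
    if (is.null(planted_ids)) {
      planted_ids <- if (config$n_planted > 0)
        sort(sample(prot, config$n_planted)) else character(0)
    } else {
      if (!all(planted_ids %in% prot))
        stop("planted_ids not all present in generated panel")
      planted_ids <- sort(planted_ids)
    }
    if (is.null(delta_per_protein)) {
      delta_per_protein <- setNames(
        config$delta * rep_len(c(1, -1), length(planted_ids)), planted_ids)
    } else {
      if (!setequal(names(delta_per_protein), planted_ids))
        stop("delta_per_protein names must match planted_ids")
      delta_per_protein <- delta_per_protein[planted_ids]
    }
    censorable <- setdiff(prot, planted_ids)
    censored_ids <- if (n_cens > 0)
      sort(sample(censorable, min(n_cens, length(censorable)))) else character(0)
    names(baseline) <- prot
    # anchor censored proteins just under the LLOD so ~60% of their
    # measurements fall below it (comfortably past the 25% rule)
    baseline[censored_ids] <- log10(config$llod) - 0.5 * config$noise_sd

    delta_full <- setNames(numeric(config$n_proteins), prot)
    delta_full[planted_ids] <- delta_per_protein
    als_full <- setNames(numeric(config$n_proteins), prot)
    if (!is.null(als_delta)) {
      if (!all(names(als_delta) %in% prot))
        stop("als_delta names not all present in generated panel")
      als_full[names(als_delta)] <- als_delta
    }

    site_shift <- setNames(rnorm(config$n_sites, 0, config$site_sd),
                           sprintf("site%d", seq_len(config$n_sites)))
    batch_shift <- setNames(rnorm(config$n_batches, 0, config$batch_sd),
                            sprintf("plate%d", seq_len(config$n_batches)))
    if (config$n_sites == 1) site_shift[] <- 0
    if (config$n_batches == 1) batch_shift[] <- 0

    blocks <- ceiling(seq_len(config$n_proteins) / config$block_size)
    n_blocks <- max(blocks)
    factor_mat <- matrix(rnorm(n * n_blocks), n, n_blocks)
    idio <- matrix(rnorm(n * config$n_proteins), n, config$n_proteins)
    noise <- config$noise_sd *
      (sqrt(config$block_rho) * factor_mat[, blocks, drop = FALSE] +
         sqrt(1 - config$block_rho) * idio)

    is_pd <- as.numeric(group == "PD")
    is_als <- as.numeric(group == "ALS")
    logval <- matrix(baseline, n, config$n_proteins, byrow = TRUE) +
      outer(is_pd, delta_full) +
      outer(is_als, als_full) +
      config$age_slope * (age - mean(age)) +
      config$sex_offset * sex +
      site_shift[as.character(site)] +
      batch_shift[as.character(batch)] +
      noise
    dimnames(logval) <- list(samp, prot)

    mat <- protein_matrix(10^logval, scale = "raw",
                          llod = setNames(rep(config$llod, config$n_proteins), prot),
                          ulod = setNames(rep(config$ulod, config$n_proteins), prot))
    meta <- data.frame(
      sample_id = samp, group = group, age = age,
      sex = ifelse(sex == 1, "F", "M"),
      site = as.character(site), batch = as.character(batch),
      ledd = ledd, treated = treated,
      disease_duration = disease_duration, education = education,
      stringsAsFactors = FALSE)

    nonplanted <- setdiff(prot, c(planted_ids, censored_ids))
    truth <- list(
      planted_ids = planted_ids,
      delta_per_protein = delta_per_protein,
      censored_ids = censored_ids,
      lmm_protein = if (length(planted_ids)) planted_ids[1] else prot[1],
      lmm_gamma = 0.0905,
      cox_protein = if (length(planted_ids)) planted_ids[1] else prot[1],
      cox_loghr = log(2.27),
      medication_effect_ids = head(nonplanted, 2),
      medication_delta = 0.05
    )
    structure(list(matrix = mat, meta = meta, truth = truth,
                   config = config),
              class = "synthetic_cohort")
  })
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  tab <- table(x$meta$group)
  cat("<synthetic_cohort>",
      paste(sprintf("%s=%d", names(tab), as.integer(tab)), collapse = ", "),
      sprintf("| %d proteins (%d planted, %d near-LLOD)\n",
              ncol(x$matrix$values), length(x$truth$planted_ids),
              length(x$truth$censored_ids)))
  invisible(x)
}

#' Generate QC reference-pool triplicates
#'
#' Emulates the assay's intraplate QC design: `n_pools` reference pools,
#' each run in triplicate.  A configurable subset of proteins is given a
#' high true coefficient of variation so the CV filter has true
#' positives.  Replicate noise is multiplicative lognormal with
#' `sigma_log = sqrt(log(1 + cv^2))`, which makes the target CV exact on
#' the raw scale.
#'
#' @param config a [sim_config()].
#' @param n_pools number of reference pools (the study design uses 3).
#' @param n_high_cv number of proteins with true CV `cv_high`; the
#'   default scales the discovery panel's CV-filter load (36 of 1,129)
#'   to the configured panel size.
#' @param cv_high,cv_low true raw-scale CVs for the noisy/stable subsets.
#' @return A long data.frame `(pool, replicate, protein_id, rfu)` with
#'   attribute `high_cv_ids` naming the planted high-CV proteins.
#' @export
generate_qc_triplicates <- function(config, n_pools = 3,
                                    n_high_cv = round(36 / 1129 *
                                                        config$n_proteins),
                                    cv_high = 0.5, cv_low = 0.05) {
  stopifnot(inherits(config, "sim_config"))
  if (n_pools < 1) stop("n_pools must be >= 1")
  if (n_high_cv > config$n_proteins)
    stop("n_high_cv exceeds n_proteins")
  with_seed(child_seed(config$seed, "qc"), {
    prot <- sprintf("P%04d", seq_len(config$n_proteins))
    baseline <- runif(config$n_proteins, 2.5, 4.5)
    high_ids <- if (n_high_cv > 0) sort(sample(prot, n_high_cv)) else character(0)
    cv <- setNames(rep(cv_low, config$n_proteins), prot)
    cv[high_ids] <- cv_high
    sdlog <- sqrt(log(1 + cv^2))

    out <- expand.grid(replicate = 1:3, pool = seq_len(n_pools),
                       protein_id = prot, KEEP.OUT.ATTRS = FALSE,
                       stringsAsFactors = FALSE)
    out <- out[, c("pool", "replicate", "protein_id")]
    mu <- 10^baseline[match(out$protein_id, prot)]
    s <- sdlog[out$protein_id]
    # lognormal with mean exactly mu and raw-scale CV as targeted
    out$rfu <- exp(log(mu) - s^2 / 2 + rnorm(nrow(out), 0, s))
    attr(out, "high_cv_ids") <- high_ids
    out
  })
}

#' Generate longitudinal cognitive trajectories
#'
#' For each PD participant, cognitive scores follow
#' `score_it = intercept_i + (base_slope + gamma * x_i) * t + e_it`
#' where `x_i` is the participant's baseline log10 level of the
#' designated protein, `intercept_i` is a participant-level random
#' intercept, and `t` is years since baseline.  Defaults emulate the
#' Mattis Dementia Rating Scale-2 (DRS, 0-144, higher is better), with
#' baseline scores near 137 and a mild mean decline.
#'
#' @param cohort a [generate_cohort()] result.
#' @param n_visits visits per participant (including baseline at t = 0).
#' @param visit_gap_yr years between visits.
#' @param gamma time-by-protein interaction (score units per year per
#'   log10 RFU); defaults to the cohort's planted `lmm_gamma`.
#' @param protein designated protein id; defaults to the cohort truth.
#' @param base_slope mean score change per year at x = 0.
#' @param intercept_mean,intercept_sd distribution of participant
#'   baseline ability (truncated to keep scores on-scale).
#' @param resid_sd visit-level measurement noise SD.
#' @param seed optional override of the stage seed.
#' @return A data.frame `(participant_id, visit_time, score, scale)`
#'   with `n_visits` rows per PD participant.
#' @export
generate_longitudinal <- function(cohort, n_visits = 4, visit_gap_yr = 1,
                                  gamma = NULL, protein = NULL,
                                  base_slope = -1.5,
                                  intercept_mean = 135, intercept_sd = 5,
                                  resid_sd = 2, seed = NULL) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  if (n_visits < 2) stop("n_visits must be >= 2")
  gamma <- gamma %||% cohort$truth$lmm_gamma
  protein <- protein %||% cohort$truth$lmm_protein
  seed <- seed %||% child_seed(cohort$config$seed, "longitudinal")
  pd <- cohort$meta$sample_id[cohort$meta$group == "PD"]
  x <- log10(cohort$matrix$values[pd, protein])
  with_seed(seed, {
    intercept <- rnorm_trunc(length(pd), intercept_mean, intercept_sd,
                             100, 142)
    slope <- base_slope + gamma * x
    tt <- (seq_len(n_visits) - 1) * visit_gap_yr
    rec <- expand.grid(participant_id = pd, visit = seq_len(n_visits),
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    rec <- rec[order(rec$participant_id, rec$visit), ]
    i <- match(rec$participant_id, pd)
    rec$visit_time <- tt[rec$visit]
    rec$score <- intercept[i] + slope[i] * rec$visit_time +
      if (resid_sd > 0) rnorm(nrow(rec), 0, resid_sd) else 0
    rec$scale <- "DRS"
    rownames(rec) <- NULL
    rec[, c("participant_id", "visit_time", "score", "scale")]
  })
}

#' Generate paired on/off-medication samples
#'
#' Each subject contributes one ON- and one OFF-medication sample
#' sharing the subject's protein baselines; a medication effect is added
#' (on the log10 scale) to the ON sample only, for the designated
#' medication-affected proteins.
#'
#' @param config a [sim_config()] (protein panel and seed).
#' @param n_subjects number of paired subjects (the study design uses 10).
#' @param effect_ids protein ids carrying a medication effect (default:
#'   two proteins chosen from the panel).
#' @param effect log10-RFU shift in the ON state.
#' @param repeat_sd technical repeatability noise SD (log10 scale)
#'   between the two draws of one subject.
#' @return A list with `matrix` (a raw-scale [protein_matrix()] of
#'   `2 * n_subjects` samples), `meta` (`sample_id`, `subject_id`,
#'   `state`), and `effect_ids`.
#' @export
generate_paired_onoff <- function(config, n_subjects = 10,
                                  effect_ids = NULL, effect = 0.05,
                                  repeat_sd = 0.02) {
  stopifnot(inherits(config, "sim_config"))
  if (n_subjects < 2) stop("n_subjects must be >= 2")
  with_seed(child_seed(config$seed, "onoff"), {
    prot <- sprintf("P%04d", seq_len(config$n_proteins))
    if (is.null(effect_ids)) effect_ids <- head(prot, 2)
    if (!all(effect_ids %in% prot))
      stop("effect_ids not all present in generated panel")
    baseline <- runif(config$n_proteins, 2.5, 4.5)
    subj_level <- matrix(baseline, n_subjects, config$n_proteins, byrow = TRUE) +
      matrix(rnorm(n_subjects * config$n_proteins, 0, config$noise_sd),
             n_subjects, config$n_proteins)
    med <- setNames(numeric(config$n_proteins), prot)
    med[effect_ids] <- effect
    on_log <- subj_level + matrix(med, n_subjects, config$n_proteins,
                                  byrow = TRUE) +
      if (repeat_sd > 0) matrix(rnorm(n_subjects * config$n_proteins, 0, repeat_sd),
                                n_subjects, config$n_proteins) else 0
    off_log <- subj_level +
      if (repeat_sd > 0) matrix(rnorm(n_subjects * config$n_proteins, 0, repeat_sd),
                                n_subjects, config$n_proteins) else 0
    subj <- sprintf("B%03d", seq_len(n_subjects))
    vals <- rbind(10^on_log, 10^off_log)
    rownames(vals) <- c(paste0(subj, "_ON"), paste0(subj, "_OFF"))
    colnames(vals) <- prot
    meta <- data.frame(
      sample_id = rownames(vals),
      subject_id = rep(subj, 2),
      state = rep(c("ON", "OFF"), each = n_subjects),
      stringsAsFactors = FALSE)
    list(matrix = protein_matrix(vals, scale = "raw"),
         meta = meta, effect_ids = effect_ids)
  })
}

#' Generate time-to-conversion records from a cohort
#'
#' Event times are exponential with log hazard
#' `cox_loghr * 1[lowest tertile] + beta_age * (age - mean) +
#' beta_duration * (duration - mean)`, administratively censored at
#' `follow_up_yr`.  Tertiles come from the designated protein's baseline
#' log10 level via [assign_tertiles()].
#'
#' @param cohort a [generate_cohort()] result.
#' @param loghr planted log hazard ratio for the lowest tertile
#'   (default: cohort truth, log(2.27)).
#' @param protein tertile-defining protein id (default: cohort truth).
#' @param follow_up_yr administrative censoring time, years.
#' @param base_rate baseline hazard (events per year).
#' @param beta_age,beta_duration covariate log-hazard slopes.
#' @param seed optional override of the stage seed.
#' @return A data.frame of survival records: `participant_id`, `time`
#'   (years), `event` (logical), `tertile`, `age`, `sex`,
#'   `disease_duration`, `education`.
#' @export
generate_conversion_times <- function(cohort, loghr = NULL, protein = NULL,
                                      follow_up_yr = 5, base_rate = 0.15,
                                      beta_age = 0.02, beta_duration = 0.03,
                                      seed = NULL) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  loghr <- loghr %||% cohort$truth$cox_loghr
  protein <- protein %||% cohort$truth$cox_protein
  if (!protein %in% colnames(cohort$matrix$values))
    stop("tertile-defining protein ", protein, " absent from cohort matrix")
  seed <- seed %||% child_seed(cohort$config$seed, "survival")
  meta <- cohort$meta
  pd <- meta[meta$group == "PD", , drop = FALSE]
  x <- log10(cohort$matrix$values[pd$sample_id, protein])
  tert <- assign_tertiles(x)
  with_seed(seed, {
    lp <- loghr * (tert == "low") +
      beta_age * (pd$age - mean(pd$age)) +
      beta_duration * (pd$disease_duration - mean(pd$disease_duration))
    t_event <- rexp(nrow(pd), rate = base_rate * exp(lp))
    event <- t_event <= follow_up_yr
    data.frame(
      participant_id = pd$sample_id,
      time = pmin(t_event, follow_up_yr),
      event = event,
      tertile = tert,
      age = pd$age,
      sex = pd$sex,
      disease_duration = pd$disease_duration,
      education = pd$education,
      stringsAsFactors = FALSE)
  })
}

#' Generate a pair of handling-perturbed reference pools
#'
#' Builds one baseline reference-pool measurement per protein and a
#' perturbed aliquot in which a chosen subset of proteins changes by
#' more than the flagging threshold (emulating room-temperature
#' incubation plus an extra freeze-thaw), the rest by small amounts.
#'
#' @param config a [sim_config()].
#' @param n_perturbed number of proteins pushed beyond +/-30%.
#' @param big_change range of |relative change| for perturbed proteins.
#' @param small_change range of |relative change| for the rest.
#' @return A list with numeric vectors `baseline` and `perturbed` (raw
#'   RFU, named by protein) and `perturbed_ids`.
#' @export
generate_handling_pools <- function(config, n_perturbed = 25,
                                    big_change = c(0.35, 0.8),
                                    small_change = c(0, 0.1)) {
  stopifnot(inherits(config, "sim_config"))
  if (n_perturbed > config$n_proteins)
    stop("n_perturbed exceeds n_proteins")
  with_seed(child_seed(config$seed, "handling"), {
    prot <- sprintf("P%04d", seq_len(config$n_proteins))
    baseline <- setNames(10^runif(config$n_proteins, 2.5, 4.5), prot)
    ids <- if (n_perturbed > 0) sort(sample(prot, n_perturbed)) else character(0)
    chg <- runif(config$n_proteins, small_change[1], small_change[2]) *
      sample(c(-1, 1), config$n_proteins, replace = TRUE)
    names(chg) <- prot
    chg[ids] <- runif(length(ids), big_change[1], big_change[2]) *
      sample(c(-1, 1), length(ids), replace = TRUE)
    list(baseline = baseline, perturbed = baseline * (1 + chg),
         perturbed_ids = ids)
  })
}
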