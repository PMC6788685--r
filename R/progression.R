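# Baseline and longitudinal cognition: Spearman correlation, linear
# mixed-effects time-by-protein models, cognitive-state norms, event
# derivation, tertile assignment, and Cox proportional hazards.

#' Spearman correlation of biomarkers with baseline cognition
#'
#' Rank-order correlation (average ranks for ties) of each biomarker's
#' baseline log10 level with the baseline cognitive score, two-sided p,
#' BH adjustment across the biomarker family.
#'
#' @param biomarkers numeric vector (one biomarker) or matrix
#'   (participants x biomarkers) of log10 levels.
#' @param baseline_scores numeric scores aligned with the rows.
#' @return A data.frame `(biomarker, rho, p, q, n_used)`.
#' @export
spearman_baseline <- function(biomarkers, baseline_scores) {
  b <- as.matrix(biomarkers)
  if (nrow(b) != length(baseline_scores))
    stop("biomarkers and scores must align")
  res <- lapply(seq_len(ncol(b)), function(j) {
    ok <- !is.na(b[, j]) & !is.na(baseline_scores)
    if (sum(ok) < 3) stop("need >= 3 complete pairs")
    ct <- suppressWarnings(
      cor.test(b[ok, j], baseline_scores[ok], method = "spearman"))
    data.frame(biomarker = colnames(b)[j] %||% as.character(j),
               rho = unname(ct$estimate), p = ct$p.value,
               n_used = sum(ok), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$q <- bh_adjust(out$p)
  out[, c("biomarker", "rho", "p", "q", "n_used")]
}

#' Linear mixed-effects model of cognitive decline
#'
#' Fits `score ~ age + sex + disease_duration + baseline_score + time +
#' time:protein` with a participant random intercept (REML by default),
#' and returns the time-by-protein interaction: score units per year
#' per log10 RFU.  The baseline (t = 0) score enters as a covariate, so
#' the response rows are the follow-up visits only; the time main
#' effect accompanies the interaction.  A singular or failed
#' mixed-model fit falls back to the fixed-effects model with a
#' warning.
#'
#' @param records longitudinal table `(participant_id, visit_time,
#'   score, ...)`; `visit_time` in years with baseline at 0.
#' @param baseline_protein named vector of baseline log10 protein
#'   levels, one per participant.
#' @param meta participant covariates (`sample_id`, `age`, `sex`,
#'   `disease_duration`, optionally `education`).
#' @param include_education add years of education as a fixed effect.
#' @param method `"REML"` (default) or `"ML"`.
#' @return A list of class `lmm_fit`: `gamma` (interaction estimate),
#'   `se`, `df`, `p`, `ci` (95% Wald), `fallback`, and the fitted
#'   `model`.
#' @export
fit_lmm <- function(records, baseline_protein, meta,
                    include_education = FALSE, method = "REML") {
  need <- c("participant_id", "visit_time", "score")
  miss <- setdiff(need, names(records))
  if (length(miss) > 0)
    stop("records lack column(s): ", paste(miss, collapse = ", "))
  base <- records[records$visit_time == 0, c("participant_id", "score")]
  names(base)[2] <- "baseline_score"
  fup <- records[records$visit_time > 0, , drop = FALSE]
  if (nrow(fup) == 0) stop("no follow-up visits (visit_time > 0)")
  d <- merge(fup, base, by = "participant_id")
  d$protein <- baseline_protein[d$participant_id]
  if (anyNA(d$protein))
    stop("baseline protein level missing for some participants")
  mcols <- c("sample_id", "age", "sex", "disease_duration",
             if (include_education) "education")
  miss <- setdiff(mcols, names(meta))
  if (length(miss) > 0)
    stop("meta lacks column(s): ", paste(miss, collapse = ", "))
  mm <- meta[, mcols]
  names(mm)[1] <- "participant_id"
  d <- merge(d, mm, by = "participant_id")
  d$sex <- code_sex(d$sex)
  d$time <- d$visit_time

  fixed <- score ~ age + sex + disease_duration + baseline_score +
    time + time:protein
  if (include_education)
    fixed <- stats::update(fixed, . ~ . + education)

  fit <- tryCatch(
    nlme::lme(fixed, random = ~ 1 | participant_id, data = d,
              method = method),
    error = function(e) e)
  fallback <- inherits(fit, "error")
  if (fallback) {
    warning("mixed-effects fit failed (", conditionMessage(fit),
            "); falling back to fixed-effects model")
    lmfit <- lm(fixed, data = d)
    sm <- suppressWarnings(summary(lmfit))$coefficients
    row <- sm["time:protein", ]
    gamma <- row[["Estimate"]]; se <- row[["Std. Error"]]
    df <- lmfit$df.residual; p <- row[["Pr(>|t|)"]]
    model <- lmfit
  } else {
    tt <- summary(fit)$tTable
    row <- tt["time:protein", ]
    gamma <- row[["Value"]]; se <- row[["Std.Error"]]
    df <- row[["DF"]]; p <- row[["p-value"]]
    model <- fit
  }
  ci <- gamma + c(-1, 1) * qt(0.975, df) * se
  structure(list(gamma = gamma, se = se, df = df, p = p, ci = ci,
                 fallback = fallback, model = model,
                 n_participants = length(unique(d$participant_id)),
                 n_obs = nrow(d)),
            class = "lmm_fit")
}

#' @export
print.lmm_fit <- function(x, ...) {
  cat(sprintf("<lmm_fit> time-by-protein interaction: %.4f (se %.4f), 95%% CI [%.4f, %.4f], p = %.3g%s\n",
              x$gamma, x$se, x$ci[1], x$ci[2], x$p,
              if (x$fallback) " [fixed-effects fallback]" else ""))
  invisible(x)
}

#' Classify cognitive state from MoCA norms
#'
#' MoCA 26-30 is normal, 21-25 mild cognitive impairment, 20 or less
#' dementia.  DRS-based states come from consensus diagnosis and are
#' supplied externally, not computed.
#'
#' @param score numeric MoCA scores (0-30).
#' @param scale only `"MoCA"` is computable.
#' @return Character vector in `{"normal", "MCI", "dementia"}`.
#' @export
classify_cognitive_state <- function(score, scale = c("MoCA", "DRS")) {
  scale <- match.arg(scale)
  if (scale == "DRS")
    stop("DRS cognitive states come from consensus diagnosis; supply them as data")
  if (any(score < 0 | score > 30, na.rm = TRUE))
    stop("MoCA scores must lie in [0, 30]")
  ifelse(score >= 26, "normal", ifelse(score >= 21, "MCI", "dementia"))
}

#' Derive conversion events from cognitive-state sequences
#'
#' Events are conversions normal->MCI, normal->dementia, or
#' MCI->dementia (between consecutive visits).  Participants with
#' dementia at baseline, or with any normal state following a baseline
#' MCI, are excluded.  Event time is the visit time of the first
#' qualifying transition; otherwise the participant is censored at the
#' last visit.
#'
#' @param states data.frame `(participant_id, visit_time, state)` with
#'   states in `{"normal", "MCI", "dementia"}`.
#' @return A list with `events` (`participant_id`, `time`, `event`) and
#'   `exclusions` (`participant_id`, `reason`).
#' @export
derive_events <- function(states) {
  need <- c("participant_id", "visit_time", "state")
  miss <- setdiff(need, names(states))
  if (length(miss) > 0)
    stop("states lack column(s): ", paste(miss, collapse = ", "))
  bad <- setdiff(unique(states$state), c("normal", "MCI", "dementia"))
  if (length(bad) > 0)
    stop("unknown state(s): ", paste(bad, collapse = ", "))
  sev <- c(normal = 1, MCI = 2, dementia = 3)
  res <- lapply(split(states, states$participant_id), function(s) {
    s <- s[order(s$visit_time), ]
    base <- s$state[1]
    if (base == "dementia")
      return(list(excl = "dementia at baseline"))
    if (base == "MCI" && any(s$state[-1] == "normal"))
      return(list(excl = "normal following baseline MCI"))
    worse <- which(diff(sev[s$state]) > 0) + 1L
    if (length(worse) > 0)
      list(time = s$visit_time[worse[1]], event = TRUE)
    else
      list(time = s$visit_time[nrow(s)], event = FALSE)
  })
  ids <- names(res)
  is_excl <- vapply(res, function(r) !is.null(r$excl), logical(1))
  exclusions <- data.frame(
    participant_id = ids[is_excl],
    reason = vapply(res[is_excl], `[[`, character(1), "excl"),
    row.names = NULL, stringsAsFactors = FALSE)
  kept <- res[!is_excl]
  events <- data.frame(
    participant_id = ids[!is_excl],
    time = vapply(kept, `[[`, numeric(1), "time"),
    event = vapply(kept, `[[`, logical(1), "event"),
    row.names = NULL, stringsAsFactors = FALSE)
  list(events = events, exclusions = exclusions)
}

#' Assign biomarker tertiles
#'
#' Cuts baseline log10 biomarker levels at the 1/3 and 2/3 sample
#' quantiles (linear-interpolation quantiles, R type 7); boundary ties
#' go to the lower tertile.
#'
#' @param x numeric baseline levels (>= 3 values, not all equal).
#' @return Factor with levels `low`, `medium`, `high`, named like `x`.
#' @export
assign_tertiles <- function(x) {
  if (length(x) < 3) stop("need >= 3 participants for tertiles")
  qs <- quantile(x, c(1 / 3, 2 / 3), names = FALSE, type = 7)
  if (qs[1] == qs[2]) stop("degenerate tertile cuts (values too concentrated)")
  lab <- ifelse(x <= qs[1], "low", ifelse(x <= qs[2], "medium", "high"))
  out <- factor(lab, levels = c("low", "medium", "high"))
  names(out) <- names(x)
  out
}

#' Assemble survival records
#'
#' Joins derived events with tertile assignments and participant
#' covariates into the record format consumed by [fit_cox()].
#'
#' @param events `events` element from [derive_events()].
#' @param tertiles factor from [assign_tertiles()], named by
#'   participant.
#' @param meta covariates (`sample_id`, `age`, `sex`,
#'   `disease_duration`, optionally `education`).
#' @return A data.frame of survival records.
#' @export
build_survival_records <- function(events, tertiles, meta) {
  d <- events
  d$tertile <- tertiles[d$participant_id]
  if (anyNA(d$tertile)) stop("tertile missing for some participants")
  mcols <- intersect(c("sample_id", "age", "sex", "disease_duration",
                       "education"), names(meta))
  mm <- meta[, mcols]
  names(mm)[1] <- "participant_id"
  merge(d, mm, by = "participant_id")
}

#' Cox proportional hazards for conversion to MCI/dementia
#'
#' Partial-likelihood fit (Efron ties) of
#' `Surv(time, event) ~ tertile + age + sex + disease_duration`
#' (optionally + education).  The tertile enters as a categorical term;
#' by default the highest tertile is the reference, so the reported
#' hazard ratio for `low` is lowest-versus-highest.  A
#' lowest-versus-rest contrast is available via `contrast`.
#'
#' @param records survival records from [build_survival_records()] or
#'   [generate_conversion_times()].
#' @param include_education add education as a covariate.
#' @param contrast `"lowest_vs_highest"` (categorical tertile, highest
#'   as reference) or `"lowest_vs_rest"` (binary indicator).
#' @param covariates adjustment covariates (default age, sex and
#'   disease duration, the workflow's standard adjustment set).
#' @return A list of class `cox_fit`: `hr` table (term, hr, lo, hi, p),
#'   the `survival::coxph` `model`, and `n_events`.
#' @export
fit_cox <- function(records, include_education = FALSE,
                    contrast = c("lowest_vs_highest", "lowest_vs_rest"),
                    covariates = c("age", "sex", "disease_duration")) {
  contrast <- match.arg(contrast)
  need <- c("time", "event", "tertile", covariates)
  miss <- setdiff(need, names(records))
  if (length(miss) > 0)
    stop("records lack column(s): ", paste(miss, collapse = ", "))
  if (sum(records$event) < 1) stop("need at least one event")
  if (any(records$time <= 0 & records$event))
    stop("event at nonpositive time")
  d <- records
  if ("sex" %in% covariates) d$sex <- code_sex(d$sex)
  rhs <- function(first)
    as.formula(paste("survival::Surv(time, event) ~", first,
                     if (length(covariates))
                       paste("+", paste(covariates, collapse = " + "))
                     else ""))
  if (contrast == "lowest_vs_highest") {
    d$tertile <- stats::relevel(factor(as.character(d$tertile),
                                       levels = c("low", "medium", "high")),
                                ref = "high")
    fml <- rhs("tertile")
  } else {
    d$lowest <- as.numeric(d$tertile == "low")
    fml <- rhs("lowest")
  }
  if (include_education) {
    if (!"education" %in% names(d)) stop("records lack `education`")
    fml <- stats::update(fml, . ~ . + education)
  }
  fit <- survival::coxph(fml, data = d, ties = "efron")
  if (any(!is.finite(coef(fit))) || any(!is.finite(sqrt(diag(fit$var)))))
    stop("monotone likelihood / complete separation in Cox fit")
  sm <- summary(fit)
  hr <- data.frame(term = rownames(sm$coefficients),
                   hr = sm$conf.int[, "exp(coef)"],
                   lo = sm$conf.int[, "lower .95"],
                   hi = sm$conf.int[, "upper .95"],
                   p = sm$coefficients[, "Pr(>|z|)"],
                   row.names = NULL, stringsAsFactors = FALSE)
  structure(list(hr = hr, model = fit, n_events = sum(records$event),
                 n = nrow(d), contrast = contrast),
            class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  cat(sprintf("<cox_fit> %d events / %d participants (%s)\n",
              x$n_events, x$n, x$contrast))
  print.data.frame(x$hr, digits = 3)
  invisible(x)
}

#' Likelihood-ratio comparison of nested Cox models
#'
#' Compares a model without education (model 1) against one with it
#' (model 2) by the partial-likelihood ratio test.
#'
#' @param fit1,fit2 `cox_fit` objects (fit2 nests fit1).
#' @return A list with `chisq`, `df`, `p`.
#' @export
compare_cox_models <- function(fit1, fit2) {
  stopifnot(inherits(fit1, "cox_fit"), inherits(fit2, "cox_fit"))
  a <- anova(fit1$model, fit2$model)
  list(chisq = a$Chisq[2], df = a$Df[2], p = a[["Pr(>|Chi|)"]][2])
}
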