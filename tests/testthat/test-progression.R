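# Cognition: Spearman baseline association, mixed-effects interaction,
# state norms, event derivation, tertiles, Cox models.

test_that("Spearman correlation matches the rank closed form", {
  expect_equal(spearman_baseline(1:6, (1:6)^2)$rho, 1)
  expect_equal(spearman_baseline(1:6, -(1:6)^3)$rho, -1)
  # 1 - 6 * sum(d^2) / (n (n^2 - 1)) with d^2 = (1,1,0)
  expect_equal(spearman_baseline(c(1, 2, 3), c(2, 1, 3))$rho, 0.5)
  m <- cbind(a = c(1, 2, 3, 4), b = c(4, 3, 2, 1))
  res <- spearman_baseline(m, c(10, 20, 30, 40))
  expect_equal(res$rho, c(1, -1))
  expect_equal(res$q, bh_oracle(res$p))
  expect_error(spearman_baseline(1:2, 1:2), ">= 3")
})

test_that("noiseless trajectories identify the interaction exactly", {
  co <- generate_cohort(sim_config(n_pd = 40, n_nc = 5, n_proteins = 8,
                                   n_planted = 1, censor_frac_target = 0,
                                   seed = 19))
  rec <- generate_longitudinal(co, n_visits = 4, gamma = 0.09,
                               intercept_sd = 0, resid_sd = 0)
  x <- setNames(log10(co$matrix$values[, co$truth$lmm_protein]),
                rownames(co$matrix$values))
  expect_warning(fit <- fit_lmm(rec, x, co$meta), "falling back")
  expect_true(fit$fallback)
  expect_equal(fit$gamma, 0.09, tolerance = 1e-6)
})

test_that("the mixed model recovers a planted interaction with noise", {
  co <- generate_cohort(sim_config(n_pd = 90, n_nc = 5, n_proteins = 8,
                                   n_planted = 1, censor_frac_target = 0,
                                   seed = 27))
  rec <- generate_longitudinal(co, n_visits = 4, gamma = 0.0905)
  x <- setNames(log10(co$matrix$values[, co$truth$lmm_protein]),
                rownames(co$matrix$values))
  fit <- fit_lmm(rec, x, co$meta)
  expect_false(fit$fallback)
  expect_lt(abs(fit$gamma - 0.0905), 3 * fit$se)
  # education enters as an additional fixed effect without upheaval
  fit_edu <- fit_lmm(rec, x, co$meta, include_education = TRUE)
  expect_lt(abs(fit_edu$gamma - fit$gamma), fit$se)
})

test_that("permuting the protein across participants nulls the interaction", {
  co <- generate_cohort(sim_config(n_pd = 60, n_nc = 5, n_proteins = 8,
                                   n_planted = 1, censor_frac_target = 0,
                                   seed = 37))
  rec <- generate_longitudinal(co, n_visits = 4, gamma = 0.2)
  x <- setNames(log10(co$matrix$values[, co$truth$lmm_protein]),
                rownames(co$matrix$values))
  set.seed(5)
  pd_ids <- co$meta$sample_id[co$meta$group == "PD"]
  pvals <- vapply(1:30, function(i) {
    xp <- x
    xp[pd_ids] <- x[sample(pd_ids)]
    fit_lmm(rec, xp, co$meta)$p
  }, numeric(1))
  expect_lte(sum(pvals < 0.1), qbinom(0.995, 30, 0.1))
  expect_gte(sum(pvals < 0.9), qbinom(0.005, 30, 0.9))
})

test_that("MoCA norms classify cognitive state exactly at the boundaries", {
  expect_equal(classify_cognitive_state(c(30, 26, 25, 21, 20, 0)),
               c("normal", "normal", "MCI", "MCI", "dementia", "dementia"))
  expect_error(classify_cognitive_state(31), "\\[0, 30\\]")
  expect_error(classify_cognitive_state(25, scale = "DRS"), "consensus")
})

test_that("event derivation applies conversion and exclusion rules", {
  st <- rbind(
    data.frame(participant_id = "a", visit_time = c(0, 1, 2),
               state = c("normal", "normal", "MCI")),
    data.frame(participant_id = "b", visit_time = c(0, 1),
               state = c("MCI", "normal")),
    data.frame(participant_id = "c", visit_time = c(0, 1),
               state = c("dementia", "dementia")),
    data.frame(participant_id = "d", visit_time = c(0, 1, 2),
               state = c("MCI", "MCI", "dementia")),
    data.frame(participant_id = "e", visit_time = c(0, 1, 2),
               state = c("normal", "normal", "normal")))
  ev <- derive_events(st)
  expect_setequal(ev$exclusions$participant_id, c("b", "c"))
  expect_equal(ev$exclusions$reason[ev$exclusions$participant_id == "b"],
               "normal following baseline MCI")
  get <- function(id) ev$events[ev$events$participant_id == id, ]
  expect_equal(get("a")$time, 2); expect_true(get("a")$event)
  expect_equal(get("d")$time, 2); expect_true(get("d")$event)
  expect_equal(get("e")$time, 2); expect_false(get("e")$event)
  # order-stability and idempotence
  ev2 <- derive_events(st[sample(nrow(st)), ])
  expect_equal(ev2$events[order(ev2$events$participant_id), ],
               ev$events[order(ev$events$participant_id), ])
  expect_false(any(ev$exclusions$participant_id %in%
                     ev$events$participant_id))
})

test_that("tertile assignment follows the documented quantile convention", {
  t9 <- assign_tertiles(setNames(1:9, letters[1:9]))
  expect_equal(as.character(t9[c("a", "e", "i")]),
               c("low", "medium", "high"))
  expect_equal(unname(table(t9)), rep(3L, 3), ignore_attr = TRUE)
  t10 <- assign_tertiles(1:10)
  expect_lte(diff(range(table(t10))), 1)
  # boundary ties go to the lower tertile
  tt <- assign_tertiles(c(1, 1, 1, 5, 5, 9, 9, 9, 2))
  expect_equal(as.character(tt[4]), as.character(tt[5]))
  expect_error(assign_tertiles(rep(3, 6)), "degenerate")
  expect_error(assign_tertiles(1:2), ">= 3")
})

test_that("the Cox fit matches a brute-force partial-likelihood search", {
  set.seed(50)
  n <- 24
  x <- rbinom(n, 1, 0.5)
  time <- rexp(n, rate = 0.2 * exp(0.9 * x))
  event <- rep(TRUE, n)
  fit <- survival::coxph(survival::Surv(time, event) ~ x, ties = "efron")
  grid <- seq(-2, 3, by = 1e-4)
  ll <- vapply(grid, cox_partial_loglik, numeric(1),
               time = time, event = event, x = x)
  expect_equal(unname(coef(fit)), grid[which.max(ll)], tolerance = 2e-4)
  # the package surface reproduces the same estimate via lowest_vs_rest
  rec <- data.frame(participant_id = as.character(1:n), time = time,
                    event = event,
                    tertile = ifelse(x == 1, "low", "high"),
                    age = 70, sex = rep(c("F", "M"), n / 2),
                    disease_duration = 5)
  cf <- fit_cox(rec, contrast = "lowest_vs_rest",
                covariates = character(0))
  expect_equal(log(cf$hr$hr[cf$hr$term == "lowest"]), unname(coef(fit)),
               tolerance = 1e-6)
})

test_that("Cox hazard ratios are invariant to time rescaling and centering", {
  co <- generate_cohort(sim_config(n_pd = 80, n_nc = 5, n_proteins = 8,
                                   n_planted = 1, censor_frac_target = 0,
                                   seed = 63))
  sv <- generate_conversion_times(co, follow_up_yr = 6)
  f1 <- fit_cox(sv)
  sv_m <- sv; sv_m$time <- sv$time * 12           # years -> months
  f2 <- fit_cox(sv_m)
  expect_equal(f1$hr$hr[1], f2$hr$hr[1], tolerance = 1e-8)
  sv_c <- sv; sv_c$age <- sv$age - mean(sv$age)   # covariate centering
  f3 <- fit_cox(sv_c)
  expect_equal(f1$hr$hr[1], f3$hr$hr[1], tolerance = 1e-8)
})

test_that("education adjustment leaves an independent hazard untouched", {
  co <- generate_cohort(sim_config(n_pd = 120, n_nc = 5, n_proteins = 8,
                                   n_planted = 1, censor_frac_target = 0,
                                   seed = 70))
  sv <- generate_conversion_times(co, follow_up_yr = 6)
  f1 <- fit_cox(sv)
  f2 <- fit_cox(sv, include_education = TRUE)
  lhr1 <- log(f1$hr$hr[f1$hr$term == "tertilelow"])
  lhr2 <- log(f2$hr$hr[f2$hr$term == "tertilelow"])
  se1 <- (log(f1$hr$hi[1]) - log(f1$hr$lo[1])) / (2 * 1.96)
  expect_lt(abs(lhr1 - lhr2), se1)
  cmp <- compare_cox_models(f1, f2)
  expect_gt(cmp$p, 0.01)
  expect_equal(cmp$df, 1)
})
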