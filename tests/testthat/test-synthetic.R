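# Synthetic cohort generator: determinism, null behavior, effect
# injection, and the auxiliary study designs.

test_that("identical configs reproduce bit-identical cohorts", {
  cfg <- sim_config(n_pd = 15, n_nc = 15, n_proteins = 25, seed = 42)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$matrix$values, b$matrix$values)
  expect_identical(a$meta, b$meta)
  expect_identical(a$truth, b$truth)
  # different seed differs
  c <- generate_cohort(sim_config(n_pd = 15, n_nc = 15, n_proteins = 25,
                                  seed = 43))
  expect_false(identical(a$matrix$values, c$matrix$values))
})

test_that("invalid configurations are rejected naming the field", {
  expect_error(sim_config(n_planted = 30, n_proteins = 20), "n_planted")
  expect_error(sim_config(block_rho = 1), "block_rho")
  expect_error(sim_config(block_rho = -0.1), "block_rho")
  expect_error(sim_config(llod = 100, ulod = 50), "llod")
  expect_error(sim_config(noise_sd = -1), "noise_sd")
  expect_error(sim_config(n_pd = 2.5), "n_pd")
})

test_that("null configuration shows no group separation", {
  cfg <- sim_config(n_pd = 100, n_nc = 100, n_proteins = 200,
                    n_planted = 0, delta = 0, censor_frac_target = 0,
                    seed = 7)
  co <- generate_cohort(cfg)
  lv <- log10(co$matrix$values)
  pd <- co$meta$group == "PD"
  diff <- colMeans(lv[pd, ]) - colMeans(lv[!pd, ])
  sp <- sqrt((apply(lv[pd, ], 2, var) * 99 + apply(lv[!pd, ], 2, var) * 99) / 198)
  z <- diff / (sp * sqrt(1 / 100 + 1 / 100))
  expect_lt(max(abs(z)), 5)  # 200 null z-scores
})

test_that("planted effects are recovered by the mean-difference oracle", {
  cfg <- sim_config(n_pd = 100, n_nc = 100, n_proteins = 200,
                    n_planted = 20, delta = 0.1, censor_frac_target = 0,
                    seed = 11)
  co <- generate_cohort(cfg)
  lv <- log10(co$matrix$values)
  pd <- co$meta$group == "PD"
  planted <- co$truth$planted_ids
  signs <- sign(co$truth$delta_per_protein[planted])
  diff <- (colMeans(lv[pd, planted, drop = FALSE]) -
             colMeans(lv[!pd, planted, drop = FALSE])) * signs
  # analytic SE of a two-sample mean difference, averaged over 20 proteins
  sp <- sqrt((apply(lv[pd, planted], 2, var) + apply(lv[!pd, planted], 2, var)) / 2)
  se_mean <- mean(sp) * sqrt(1 / 100 + 1 / 100) / sqrt(length(planted))
  expect_lt(abs(mean(diff) - 0.1), 3 * se_mean)
})

test_that("within-block correlation matches the latent-factor target", {
  cfg <- sim_config(n_pd = 300, n_nc = 300, n_proteins = 40, n_planted = 0,
                    delta = 0, block_size = 10, block_rho = 0.4,
                    censor_frac_target = 0, seed = 5)
  co <- generate_cohort(cfg)
  lv <- log10(co$matrix$values)
  r_in <- cor(lv[, 1], lv[, 2])     # same block
  r_out <- cor(lv[, 1], lv[, 11])   # different block
  expect_equal(r_in, 0.4, tolerance = 0.12)
  expect_lt(abs(r_out), 0.12)
})

test_that("QC triplicates have the designed shape and CV structure", {
  cfg <- sim_config(n_proteins = 30, seed = 2)
  qr3 <- generate_qc_triplicates(cfg, n_pools = 3, n_high_cv = 5)
  expect_equal(nrow(qr3), 30 * 3 * 3)
  expect_true(all(table(qr3$protein_id) == 9))
  # zero replicate noise -> all CVs identically zero
  qr0 <- generate_qc_triplicates(cfg, n_pools = 2, n_high_cv = 0,
                                 cv_low = 0, cv_high = 0)
  cv0 <- triplicate_cv_filter(qr0)
  expect_true(all(cv0$cv_table$cv == 0))
  expect_length(cv0$excluded, 0)
})

test_that("planted high-CV proteins are flagged in nearly all seeds", {
  # Monte-Carlo oracle over 200 seeds: with a true raw-scale CV of 0.5
  # the per-protein flag rate (any of three pools above 0.2) is ~99%;
  # a sample CV from 3 replicates is noisy enough that it occasionally
  # lands under the threshold in all three pools.
  rate <- vapply(1:200, function(s) {
    cfg <- sim_config(n_proteins = 30, seed = s)
    qr3 <- generate_qc_triplicates(cfg, n_pools = 3, n_high_cv = 10,
                                   cv_high = 0.5)
    flt <- triplicate_cv_filter(qr3, threshold = 0.2)
    mean(attr(qr3, "high_cv_ids") %in% flt$excluded)
  }, numeric(1))
  expect_gte(mean(rate), 0.95)
})

test_that("longitudinal records have the designed shape and slopes", {
  co <- tiny_cohort(seed = 3)
  rec <- generate_longitudinal(co, n_visits = 4)
  expect_equal(nrow(rec), 4 * sum(co$meta$group == "PD"))
  expect_true(all(table(rec$participant_id) == 4))
  # flat trajectories when every slope and noise source is off
  flat <- generate_longitudinal(co, n_visits = 3, gamma = 0,
                                base_slope = 0, resid_sd = 0)
  spread <- tapply(flat$score, flat$participant_id,
                   function(s) diff(range(s)))
  expect_true(all(spread == 0))
  expect_error(generate_longitudinal(co, n_visits = 1), "n_visits")
})

test_that("paired on/off design plants recoverable medication effects", {
  cfg <- sim_config(n_proteins = 100, seed = 8)
  oo <- generate_paired_onoff(cfg, n_subjects = 10, effect = 0.05)
  expect_equal(nrow(oo$matrix$values), 20)
  d <- log10(oo$matrix$values[oo$meta$state == "ON", ]) -
    log10(oo$matrix$values[oo$meta$state == "OFF", ])
  top2 <- names(sort(abs(colMeans(d)), decreasing = TRUE))[1:2]
  expect_setequal(top2, oo$effect_ids)
  # zero effect, zero repeat noise -> exactly paired
  oo0 <- generate_paired_onoff(cfg, n_subjects = 5, effect = 0,
                               repeat_sd = 0)
  d0 <- log10(oo0$matrix$values[oo0$meta$state == "ON", ]) -
    log10(oo0$matrix$values[oo0$meta$state == "OFF", ])
  expect_true(all(abs(d0) < 1e-12))
})

test_that("conversion-time generator respects null and censoring limits", {
  co <- generate_cohort(sim_config(n_pd = 96, n_nc = 10, n_proteins = 10,
                                   n_planted = 1, censor_frac_target = 0,
                                   seed = 21))
  # censoring horizon zero -> no events
  s0 <- generate_conversion_times(co, follow_up_yr = 0)
  expect_equal(sum(s0$event), 0)
  # under a null hazard ratio the log-rank test stays calibrated
  pvals <- vapply(1:40, function(s) {
    sv <- generate_conversion_times(co, loghr = 0, seed = s,
                                    follow_up_yr = 5)
    sd <- survival::survdiff(survival::Surv(time, event) ~ tertile,
                             data = sv)
    1 - pchisq(sd$chisq, length(sd$n) - 1)
  }, numeric(1))
  expect_lte(sum(pvals < 0.1), qbinom(0.995, 40, 0.1))
  expect_gte(sum(pvals < 0.9), qbinom(0.005, 40, 0.9))
})
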