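# Replication with multisite covariates, direction concordance,
# disease specificity, and the treated/never-treated comparison.

# delta large enough to clear the q<0.05 bar in the *discovery* model,
# where adjusting for LEDD (near-collinear with the PD indicator)
# roughly doubles the group-effect standard error.
make_pair <- function(seed = 61, delta = 0.25) {
  disc <- generate_cohort(sim_config(n_pd = 96, n_nc = 45, n_proteins = 60,
                                     n_planted = 4, delta = delta,
                                     censor_frac_target = 0, seed = seed))
  repl <- generate_cohort(sim_config(n_pd = 215, n_nc = 102, n_proteins = 60,
                                     n_sites = 2, n_batches = 5,
                                     censor_frac_target = 0, seed = seed + 1),
                          planted_ids = disc$truth$planted_ids,
                          delta_per_protein = disc$truth$delta_per_protein,
                          group_prefix = "R")
  list(disc = disc, repl = repl)
}

test_that("planted effects replicate across cohorts with matching direction", {
  pair <- make_pair()
  dmat <- log10_transform(pair$disc$matrix)
  rmat <- log10_transform(pair$repl$matrix)
  dtab <- run_discovery(dmat, pair$disc$meta)
  top <- c(pair$disc$truth$planted_ids,
           setdiff(protein_ids(rmat), pair$disc$truth$planted_ids)[1:6])
  rtab <- run_replication(rmat, pair$repl$meta, top)
  expect_equal(nrow(rtab), 10)
  planted <- pair$disc$truth$planted_ids
  expect_true(all(rtab$q[rtab$protein_id %in% planted] < 0.05))
  rep_ids <- check_replication(dtab[dtab$protein_id %in% top, ], rtab)
  expect_setequal(rep_ids, planted)
  # direction concordance with the planted signs
  est <- setNames(rtab$direction, rtab$protein_id)[planted]
  expect_equal(unname(est),
               unname(sign(pair$disc$truth$delta_per_protein[planted])))
})

test_that("batch structure without group effects yields no calls", {
  null <- generate_cohort(sim_config(n_pd = 120, n_nc = 80, n_proteins = 30,
                                     n_planted = 0, delta = 0,
                                     n_sites = 2, n_batches = 5,
                                     site_sd = 0.3, batch_sd = 0.3,
                                     censor_frac_target = 0, seed = 77))
  rmat <- log10_transform(null$matrix)
  rtab <- run_replication(rmat, null$meta, protein_ids(rmat)[1:10])
  expect_true(all(rtab$q >= 0.05))
})

test_that("replication without site/batch columns nests the discovery model", {
  pair <- make_pair(seed = 71)
  rmat <- log10_transform(pair$repl$matrix)
  ids <- protein_ids(rmat)[1:5]
  a <- run_replication(rmat, pair$repl$meta, ids,
                       covariates = c("age", "sex"))
  b <- run_discovery(rmat, pair$repl$meta, covariates = c("age", "sex"))
  b <- b[match(ids, b$protein_id), ]
  expect_equal(a$beta, b$beta, tolerance = 1e-12)
  expect_equal(a$p, b$p, tolerance = 1e-12)
})

test_that("replication declarations follow the q-and-direction rule", {
  d <- data.frame(protein_id = c("a", "b", "c"),
                  q = c(0.04, 0.04, 0.04), direction = c(1, 1, 1))
  r1 <- data.frame(protein_id = c("a", "b", "c"),
                   q = c(0.04, 0.04, 0.06), direction = c(1, -1, 1))
  expect_equal(check_replication(d, r1), "a")   # b flips sign, c misses q
  # symmetry in the two inputs
  expect_equal(check_replication(r1, d), check_replication(d, r1))
  # untestable proteins are reported, not failed
  pair <- make_pair(seed = 81)
  rmat <- log10_transform(pair$repl$matrix)
  expect_message(rt <- run_replication(rmat, pair$repl$meta,
                                       c("P0001", "ABSENT1")),
                 "ABSENT1")
  expect_equal(attr(rt, "untestable"), "ABSENT1")
})

test_that("three-group models separate PD-specific from shared effects", {
  shared <- "P0050"; pd_only <- "P0010"
  co <- generate_cohort(sim_config(n_pd = 150, n_nc = 100, n_proteins = 60,
                                   n_planted = 1, delta = 0.2,
                                   n_sites = 2, censor_frac_target = 0,
                                   seed = 91),
                        planted_ids = c(pd_only, shared),
                        delta_per_protein = c(0.2, 0.2) |>
                          setNames(c(pd_only, shared)),
                        n_als = 59,
                        als_delta = setNames(0.2, shared))
  lmat <- log10_transform(co$matrix)
  ms <- multigroup_specificity(lmat, co$meta, c(pd_only, shared))
  q <- function(id, term) ms$q[ms$protein_id == id & ms$term == term]
  expect_lt(q(pd_only, "groupPD"), 0.05)
  expect_gte(q(pd_only, "groupALS"), 0.05)
  expect_lt(q(shared, "groupPD"), 0.05)
  expect_lt(q(shared, "groupALS"), 0.05)
  # missing ALS level is a clean error
  noals <- co$meta[co$meta$group != "ALS", ]
  expect_error(multigroup_specificity(lmat, noals, pd_only), "ALS")
})

test_that("rank-sum comparison matches full enumeration for small n", {
  res <- never_treated_comparison(c(1, 2, 3, 4),
                                  c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(res$p_value, 2 / 6, tolerance = 1e-12)
  expect_true(res$exact)
  set.seed(14)
  for (i in 1:15) {
    nx <- sample(2:4, 1); ny <- sample(2:4, 1)
    v <- sample(seq(1, 40), nx + ny)  # distinct values, no ties
    treated <- rep(c(TRUE, FALSE), c(nx, ny))
    res <- never_treated_comparison(v, treated)
    expect_equal(res$p_value, ranksum_oracle(v[treated], v[!treated]),
                 tolerance = 1e-12)
  }
  # identical tied subgroups: p = 1 under the correction convention
  res_tie <- never_treated_comparison(c(1, 2, 1, 2),
                                      c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(res_tie$p_value, 1)
  expect_error(never_treated_comparison(1:3, rep(TRUE, 3)), "nonempty")
})
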