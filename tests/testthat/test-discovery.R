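# Per-protein linear models, nomination, BH adjustment, clustering.

test_that("single-protein model equals the pooled two-sample t oracle", {
  y <- c(1, 2, 3, 3, 4, 5)
  d <- data.frame(group = c(0, 0, 0, 1, 1, 1))
  fit <- fit_protein_lm(y, d)
  tt <- t.test(y[4:6], y[1:3], var.equal = TRUE)
  expect_equal(fit$beta, unname(tt$estimate[1] - tt$estimate[2]))  # 2.0
  expect_equal(fit$beta, 2.0)
  expect_equal(fit$t, unname(tt$statistic), tolerance = 1e-10)
  expect_equal(fit$p, tt$p.value, tolerance = 1e-10)
  expect_equal(fit$df, 4)
  expect_equal(fit$se, 0.8165, tolerance = 1e-4)
})

test_that("OLS agrees with the normal-equations oracle on a random battery", {
  set.seed(99)
  for (i in 1:30) {
    n <- sample(6:10, 1)
    k <- sample(0:2, 1)
    df <- data.frame(group = rbinom(n, 1, 0.5))
    if (sum(df$group) %in% c(0, n)) df$group[1:2] <- c(0, 1)
    if (k >= 1) df$age <- rnorm(n, 70, 8)
    if (k >= 2) df$ledd <- runif(n, 0, 900)
    y <- rnorm(n)
    fit <- fit_protein_lm(y, df)
    X <- model.matrix(~ ., data = df)
    or <- ols_oracle(X, y)
    expect_equal(fit$beta, unname(or$beta["group"]), tolerance = 1e-10)
    expect_equal(fit$se, unname(or$se["group"]), tolerance = 1e-10)
    expect_equal(fit$df, or$df)
  }
})

test_that("a covariate orthogonal to group leaves its coefficient unchanged", {
  set.seed(12)
  g <- rep(c(0, 1), each = 5)
  z <- rnorm(10); z <- residuals(lm(z ~ g))   # orthogonal by construction
  y <- rnorm(10) + 0.8 * g
  f1 <- fit_protein_lm(y, data.frame(group = g))
  f2 <- fit_protein_lm(y, data.frame(group = g, z = z))
  expect_equal(f1$beta, f2$beta, tolerance = 1e-10)
})

test_that("rank deficiency and degenerate responses are rejected", {
  g <- rep(c(0, 1), each = 4)
  expect_error(fit_protein_lm(rnorm(8),
                              data.frame(group = g, twin = g)),
               "collinear")
  expect_error(fit_protein_lm(g * 1.0, data.frame(group = g)),
               "residual variance")
})

test_that("the cohort scan reproduces the single-protein fits", {
  co <- tiny_cohort(seed = 17)
  lmat <- log10_transform(co$matrix)
  tab <- run_discovery(lmat, co$meta)
  expect_s3_class(tab, "association_table")
  expect_equal(nrow(tab), 30)
  expect_true(all(tab$q >= tab$p))
  meta <- co$meta
  for (pid in c("P0003", "P0017")) {
    d <- data.frame(group = as.numeric(meta$group == "PD"),
                    age = meta$age,
                    sex = as.numeric(meta$sex == "F"),
                    ledd = meta$ledd)
    single <- fit_protein_lm(lmat$values[, pid], d)
    row <- tab[tab$protein_id == pid, ]
    expect_equal(row$beta, single$beta, tolerance = 1e-10)
    expect_equal(row$se, single$se, tolerance = 1e-10)
    expect_equal(row$p, single$p, tolerance = 1e-10)
  }
})

test_that("missing LEDD degrades the design with a warning", {
  co <- tiny_cohort(seed = 23)
  lmat <- log10_transform(co$matrix)
  meta <- co$meta[, setdiff(names(co$meta), "ledd")]
  expect_warning(tab <- run_discovery(lmat, meta), "ledd")
  expect_equal(nrow(tab), 30)
})

test_that("nomination applies a strict, deterministically sorted cut", {
  tab <- data.frame(protein_id = c("b", "a", "c"),
                    p = c(0.004, 0.005, 0.006))
  expect_equal(nominate_candidates(tab), "b")
  expect_equal(nominate_candidates(tab[0, ]), character(0))
  expect_equal(nominate_candidates(tab, 1.0), c("b", "a", "c"))
  # ties broken by protein id
  tie <- data.frame(protein_id = c("z", "y"), p = c(0.001, 0.001))
  expect_equal(nominate_candidates(tie), c("y", "z"))
})

test_that("BH adjustment matches the hand step-up oracle", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), rep(0.03, 3))
  expect_equal(bh_adjust(c(0.005, 0.5)), c(0.01, 0.5))
  set.seed(8)
  for (i in 1:20) {
    p <- runif(sample(1:40, 1))
    q <- bh_adjust(p)
    expect_equal(q, bh_oracle(p), tolerance = 1e-12)
    expect_true(all(q >= p - 1e-15))
    expect_true(all(q[order(p)] == cummax(q[order(p)])))  # monotone in p
  }
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("clustering reproduces hand-computed average-linkage heights", {
  # exact sample correlations chosen so scaled euclidean distances form
  # a 3-4-5 triangle: merge {1,2} at 3, then average linkage joins the
  # third protein at (5 + 4) / 2 = 4.5
  n <- 10
  dd <- c(d12 = 3, d13 = 5, d23 = 4)
  R <- diag(3)
  R[1, 2] <- R[2, 1] <- 1 - dd["d12"]^2 / (2 * (n - 1))
  R[1, 3] <- R[3, 1] <- 1 - dd["d13"]^2 / (2 * (n - 1))
  R[2, 3] <- R[3, 2] <- 1 - dd["d23"]^2 / (2 * (n - 1))
  X <- exact_corr_matrix(n, R, seed = 2)
  rownames(X) <- paste0("s", 1:n)
  cl <- cluster_candidates(protein_matrix(X, scale = "log10"),
                           c("p1", "p2", "p3"))
  expect_equal(cl$protein_hclust$height, c(3, 4.5), tolerance = 1e-9)
  # identical proteins merge first at height zero
  Y <- cbind(p1 = rnorm(5), p3 = rnorm(5))
  Y <- cbind(Y, p2 = Y[, "p1"])
  rownames(Y) <- paste0("s", 1:5)
  cl2 <- cluster_candidates(protein_matrix(Y, scale = "log10"),
                            c("p1", "p2", "p3"))
  expect_equal(cl2$protein_hclust$height[1], 0)
  first_pair <- cl2$protein_hclust$labels[
    -cl2$protein_hclust$merge[1, ]]
  expect_setequal(first_pair, c("p1", "p2"))
})

test_that("clustering is invariant to input order and rejects constants", {
  co <- tiny_cohort(seed = 29)
  lmat <- log10_transform(co$matrix)
  ids <- protein_ids(lmat)[1:8]
  cl <- cluster_candidates(lmat, ids)
  cl_shuf <- cluster_candidates(lmat, rev(ids))
  expect_equal(sort(cl$protein_hclust$height),
               sort(cl_shuf$protein_hclust$height), tolerance = 1e-12)
  v <- lmat$values[, 1:3]; v[, 2] <- 5
  colnames(v) <- c("a", "const", "c")
  expect_error(cluster_candidates(protein_matrix(v, scale = "log10"),
                                  colnames(v)), "const")
  expect_error(cluster_candidates(lmat, ids[1]), ">= 2")
})
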