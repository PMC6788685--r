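# Independent oracles used across the suite.  These deliberately take
# the brute-force route (normal equations, full enumeration, closed
# forms) so they share no code with the implementation they check.

# OLS via normal equations, with classical standard errors.
ols_oracle <- function(X, y) {
  XtX <- t(X) %*% X
  beta <- solve(XtX, t(X) %*% y)
  res <- y - X %*% beta
  df <- nrow(X) - ncol(X)
  sigma2 <- sum(res^2) / df
  se <- sqrt(sigma2 * diag(solve(XtX)))
  list(beta = drop(beta), se = se, df = df)
}

# Benjamini-Hochberg step-up by hand.
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  ranked <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(ranked)))
  adj <- pmin(adj, 1)
  out <- numeric(n)
  out[o] <- adj
  out
}

# Exact sign-flip permutation p for |mean difference|, enumerating the
# 2^n flips through bit arithmetic (different machinery from the
# implementation's expand.grid).
signflip_oracle <- function(d) {
  n <- length(d)
  obs <- abs(mean(d))
  total <- 2^n
  hits <- 0L
  for (m in 0:(total - 1)) {
    s <- ifelse(bitwAnd(m, 2^(0:(n - 1))) > 0, 1, -1)
    if (abs(mean(s * d)) >= obs - 1e-12) hits <- hits + 1L
  }
  hits / total
}

# Exact two-sided rank-sum p by full enumeration of the
# choose(n, nx) group assignments (no ties assumed), matching the
# two-sided doubling convention of the exact Mann-Whitney test.
ranksum_oracle <- function(x, y) {
  nx <- length(x); ny <- length(y)
  r <- rank(c(x, y))
  u_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  combos <- utils::combn(nx + ny, nx)
  u_null <- apply(combos, 2, function(idx) {
    sum(rank(c(x, y))[idx]) - nx * (nx + 1) / 2
  })
  mu <- nx * ny / 2
  p <- if (u_obs > mu) 2 * mean(u_null >= u_obs) else 2 * mean(u_null <= u_obs)
  min(1, p)
}

soft_threshold <- function(z, g) sign(z) * pmax(abs(z) - g, 0)

# Cox partial log-likelihood for one numeric covariate (Breslow form;
# equals Efron when event times are untied).
cox_partial_loglik <- function(beta, time, event, x) {
  ll <- 0
  for (i in which(event)) {
    risk <- time >= time[i]
    ll <- ll + beta * x[i] - log(sum(exp(beta * x[risk])))
  }
  ll
}

# Construct an n x 3 data matrix whose columns have *exact* sample
# correlations R (via an orthonormalized latent basis), so that scaled
# euclidean distances are known in closed form.
exact_corr_matrix <- function(n, R, seed = 1) {
  set.seed(seed)
  Z <- matrix(rnorm(n * ncol(R)), n, ncol(R))
  Z <- scale(Z, center = TRUE, scale = FALSE)
  Z <- qr.Q(qr(Z)) * sqrt(n - 1)       # exact identity sample covariance
  X <- Z %*% chol(R)
  colnames(X) <- paste0("p", seq_len(ncol(R)))
  X
}

# Small synthetic cohort shared by several tests.
tiny_cohort <- function(seed = 1, ...) {
  generate_cohort(sim_config(n_pd = 20, n_nc = 20, n_proteins = 30,
                             n_planted = 2, delta = 0.3,
                             censor_frac_target = 0, seed = seed, ...))
}
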