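# Internal helpers: deterministic seed fan-out and RNG hygiene.

# One global seed fans out to per-stage child seeds.  Stages are named so a
# stage re-run in isolation sees the same stream as inside the full
# pipeline.  Values stay below 2^31 - 1 (R integers are 32-bit).
.stage_offsets <- c(
  cohort = 1L, qc = 2L, longitudinal = 3L, onoff = 4L,
  survival = 5L, masks = 6L, handling = 7L, replication = 8L,
  permutation = 9L
)

child_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  off <- .stage_offsets[[stage]]
  if (is.null(off)) stop("unknown seed stage: ", stage)
  as.integer((as.double(seed) * 101L + off * 9973L) %% 2147483629)
}

# Evaluate expr under a fixed seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Truncated normal via inverse-CDF (exact, vectorized).
rnorm_trunc <- function(n, mean, sd, lower, upper) {
  plo <- pnorm(lower, mean, sd)
  phi <- pnorm(upper, mean, sd)
  qnorm(runif(n, plo, phi), mean, sd)
}

# FNV-1a hash of a character scalar, for config provenance stamps.
fnv1a_hash <- function(x) {
  bytes <- utf8ToInt(paste(x, collapse = "\n"))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), as.integer(b))
    h <- (h * 16777619) %% 2^32
  }
  sprintf("%08x", as.integer(h %% 2^31))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
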