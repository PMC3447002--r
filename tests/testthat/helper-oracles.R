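# Independent oracles used by the tests. These re-derive expected values
# by brute force / closed form, independent of the implementation paths
# they check.

# Brute-force chemotaxis-only probabilities over an explicit enumeration
# of the Moore directions (independent of jump_vectors()).
oracle_chemo_3d <- function(v) {
  v <- v / sqrt(sum(v^2))
  w <- c()
  dirs <- list()
  for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
    if (dx == 0 && dy == 0 && dz == 0) next
    u <- c(dx, dy, dz)
    lu <- sqrt(sum(u^2))
    ca <- sum(u * v) / lu
    dirs[[length(dirs) + 1L]] <- u
    w <- c(w, if (ca >= 0) ca^2 / lu else 0)
  }
  list(p = w / sum(w), dirs = do.call(rbind, dirs))
}

# Closed-form directional CI at |C| = 1: expectation ratio over the
# pure-chemotaxis jump distribution (no sampling).
oracle_ci_ceiling <- function() {
  o <- oracle_chemo_3d(c(1, 0, 0))
  len <- sqrt(rowSums(o$dirs^2))
  sum(o$p * o$dirs[, 1]) / sum(o$p * len)
}

# Base-walk weights by direct normalisation (isotropic case).
oracle_isotropic_axis_prob <- function(p0 = 0) {
  lens <- c(rep(1, 6), rep(sqrt(2), 12), rep(sqrt(3), 8))
  (1 - p0) * (1 / 1) / sum(1 / lens)
}

# Reference single-step sampler built from the R module surface, for
# goodness-of-fit checks against the C++ engine's sampling.
sample_steps_reference <- function(n, p) {
  tabulate(sample.int(length(p), n, replace = TRUE, prob = p), length(p))
}

# Cached heavyweight computations shared across acceptance blocks.
.acc_cache <- new.env(parent = emptyenv())
acc_cached <- function(key, expr) {
  if (!exists(key, envir = .acc_cache)) {
    assign(key, force(expr), envir = .acc_cache)
  }
  get(key, envir = .acc_cache)
}
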