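test_that("2D worked example: chemotaxis-only probabilities at 30 degrees", {
  pc <- chemo_only_probabilities(c(0.866, 0.5))
  # exact normalisation of cos^2/|u| with counter-directed jumps zeroed
  expect_equal(as.numeric(pc),
               c(0.43933, 0.38648, 0.14644, 0, 0, 0, 0, 0.02775),
               tolerance = 2e-4)
  expect_equal(sum(pc), 1, tolerance = 1e-12)
})

test_that("3D chemotaxis-only probabilities match the brute-force oracle", {
  for (v in list(c(1, 0, 0), c(0.3, -0.8, 0.52), c(0, 0, 1))) {
    o <- oracle_chemo_3d(v)
    pc <- chemo_only_probabilities(v / sqrt(sum(v^2)))
    dirs <- attr(pc, "dirs")
    key_o <- paste(o$dirs[, 1], o$dirs[, 2], o$dirs[, 3])
    key_i <- paste(dirs[, 1], dirs[, 2], dirs[, 3])
    expect_equal(as.numeric(pc), o$p[match(key_i, key_o)], tolerance = 1e-12)
  }
  pc <- chemo_only_probabilities(c(1, 0, 0))
  dirs <- attr(pc, "dirs")
  expect_equal(pc[dirs[, 1] == 1 & dirs[, 2] == 0 & dirs[, 3] == 0],
               1 / (1 + 4 * (0.5 / sqrt(2)) + 4 * ((1 / 3) / sqrt(3))),
               tolerance = 1e-9)
  expect_equal(sum(pc > 0), 9L)  # only jumps with positive x-component
})

test_that("jumps counter to the attraction always get zero probability", {
  set.seed(401)
  for (k in 1:20) {
    v <- stats::rnorm(3); v <- v / sqrt(sum(v^2))
    pc <- chemo_only_probabilities(v)
    dirs <- attr(pc, "dirs")
    expect_true(all(pc[as.numeric(dirs %*% v) < 0] == 0))
  }
  expect_error(chemo_only_probabilities(c(0, 0, 0)), "zero vector")
})

test_that("portal attraction is a capped inverse-square vector sum", {
  a <- portal_attraction(c(0, 0, 0), rbind(c(2, 0, 0)), K_E = 1)
  expect_equal(a$strength, 0.25)
  expect_equal(a$direction, c(1, 0, 0))
  # capped at 1
  expect_equal(portal_attraction(c(0, 0, 0), rbind(c(1, 0, 0)), 3)$strength, 1)
  # opposite equidistant portals cancel
  z <- portal_attraction(c(0, 0, 0), rbind(c(3, 0, 0), c(-3, 0, 0)), 2)
  expect_equal(z$strength, 0)
  expect_null(z$direction)
  # a portal at the cell's own site contributes zero
  expect_equal(portal_attraction(c(1, 1, 1), rbind(c(1, 1, 1)), 5)$strength, 0)
  # influence cutoff: K_E / r^2 below 0.01 is ignored
  expect_equal(portal_attraction(c(0, 0, 0), rbind(c(20, 0, 0)), 1)$strength, 0)
  # M identical-direction sources scale linearly until the cap
  one <- portal_attraction(c(0, 0, 0), rbind(c(3, 0, 0)), 1)$strength
  three <- portal_attraction(c(0, 0, 0),
                             rbind(c(3, 0, 0), c(3, 0, 0), c(3, 0, 0)),
                             1)$strength
  expect_equal(three, 3 * one)
  expect_equal(portal_attraction(c(0, 0, 0),
                                 matrix(rep(c(2, 0, 0), 9), ncol = 3,
                                        byrow = TRUE), 1)$alpha, 1)
})

test_that("combined distribution mixes, blocks and conserves mass", {
  mp <- motility_params(p0 = 0.4, kappa = 0.8)
  p <- base_jump_probabilities(c(0, 1, 0), mp)
  pc <- chemo_only_probabilities(c(1, 0, 0))
  # alpha = 0: base walk unchanged
  expect_equal(combined_jump_probabilities(p, pc, 0), as.numeric(p))
  # alpha = 1: pure chemotaxis, no no-jump mass
  full <- combined_jump_probabilities(p, pc, 1)
  expect_equal(full[1], 0)
  expect_equal(full[-1], as.numeric(pc))
  # all directions blocked: everything collapses to no-jump
  allb <- combined_jump_probabilities(p, pc, 1, blocked = 1:26)
  expect_equal(allb, c(1, rep(0, 26)))
  expect_error(combined_jump_probabilities(p, pc, 1.5), "alpha")
  expect_error(combined_jump_probabilities(p, pc, 0.5, blocked = 27L), "blocked")
})

test_that("normalisation holds for random alpha and blocked sets", {
  set.seed(402)
  mp <- motility_params(p0 = 0.35, kappa = 1.1)
  for (k in 1:50) {
    prev <- stats::rnorm(3); prev <- prev / sqrt(sum(prev^2))
    v <- stats::rnorm(3); v <- v / sqrt(sum(v^2))
    p <- base_jump_probabilities(prev, mp)
    pc <- chemo_only_probabilities(v)
    alpha <- stats::runif(1)
    blocked <- sample(1:26, stats::rpois(1, 5))
    ps <- combined_jump_probabilities(p, pc, alpha, blocked)
    expect_equal(sum(ps), 1, tolerance = 1e-12)
    expect_true(all(ps >= 0))
    expect_true(all(ps[blocked + 1L] == 0))
  }
})

test_that("engine move sampling matches the combined distribution", {
  # one free-space step under uniform attraction, no previous direction
  mp <- motility_params(p0 = 0.4, kappa = 0.9)
  C <- c(0.6, 0, 0)
  set.seed(403)
  res <- paracortex:::cpp_free_walk(30000L, 1L, mp$p0, mp$kappa, C, TRUE)
  one <- res$step == 1L
  p <- base_jump_probabilities(NULL, mp)
  pc <- chemo_only_probabilities(c(1, 0, 0))
  expected <- combined_jump_probabilities(p, pc, alpha = 0.6)
  dirs <- attr(p, "dirs")
  key <- paste(res$x[one], res$y[one], res$z[one])
  counts <- as.numeric(table(factor(key, levels = paste(dirs[, 1], dirs[, 2],
                                                        dirs[, 3]))))
  gof <- suppressWarnings(stats::chisq.test(counts, p = expected))
  expect_gt(gof$p.value, 0.001)
})

test_that("directional CI rises monotonically with strength and is walk-independent at the ceiling", {
  set.seed(404)
  ci <- vapply(c(0, 0.25, 0.5, 0.75, 1), function(s)
    as.numeric(chemotaxis_index(s, 10, 1000)), numeric(1))
  expect_true(all(diff(ci) > -0.02))
  expect_lt(abs(ci[1]), 0.03)
  # alpha = 1 erases the base walk
  set.seed(405)
  a <- as.numeric(chemotaxis_index(1, 10, 2000,
                                   params = motility_params(0.1, 0)))
  set.seed(406)
  b <- as.numeric(chemotaxis_index(1, 10, 2000,
                                   params = motility_params(0.9, 2)))
  expect_equal(a, b, tolerance = 0.02)
  expect_equal(a, oracle_ci_ceiling(), tolerance = 0.02)
  expect_error(chemotaxis_index(1, 0), "n_steps")
})

test_that("ci_sweep returns a tidy table", {
  set.seed(407)
  sw <- ci_sweep(c(0, 1), n_steps = 5, n_traj = 200)
  expect_s3_class(sw, "ci_sweep")
  expect_named(sw, c("strength", "mode", "n_steps", "CI", "sd"))
  expect_equal(nrow(sw), 2L)
  expect_true(all(diff(sw$CI) > 0))
})
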