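test_that("exit-candidate predicate enforces boundary layer and cap", {
  b <- build_blob(4000)   # R ~ 9.8
  # centre of a large blob: second shell nowhere near the outside
  expect_false(is_exit_candidate(c(0L, 0L, 0L), b))
  # a site ~two layers inside the boundary on the -x side qualifies
  xs <- -(floor(b$R) - 1L)
  expect_true(is_exit_candidate(c(xs, 0L, 0L), b))
  # the same layer site on +x is excluded by the cap (x/R ~ 0.8 > 0.6)
  expect_false(is_exit_candidate(c(-xs, 0L, 0L), b))
  cand <- exit_candidates(b)
  expect_gt(nrow(cand), 0)
  expect_true(all(cand[, 1] / b$R <= 0.6))
  r <- sqrt(rowSums(cand^2))
  expect_true(all(r > b$R - 3.5 & r < b$R))
})

test_that("required exit count follows the power law with beta and P_E scaling", {
  tp <- trafficking_params()
  expect_equal(beta_exit_reduction(0), 0.9997)
  expect_equal(beta_exit_reduction(5), 0.5)   # clamped
  expect_lt(beta_exit_reduction(2), beta_exit_reduction(0))
  n1 <- required_exit_count(1e5, tp, round_count = FALSE)
  n2 <- required_exit_count(1e5, trafficking_params(P_E = 0.01),
                            round_count = FALSE)
  expect_equal(n2 / n1, 2, tolerance = 1e-9)  # halving P_E doubles exits
  # near-linear: doubling N roughly doubles the count
  expect_equal(required_exit_count(2e5, tp, round_count = FALSE) / n1, 2,
               tolerance = 0.03)
  bad <- tp; bad$power_a <- NA_real_
  expect_error(required_exit_count(1e4, bad), "calibrate_exit_constants")
})

test_that("portal placement is valid, separated and reproducible", {
  b <- build_blob(6000)
  tp <- trafficking_params()
  set.seed(501)
  ps <- place_portals(b, 4, tp)
  expect_s3_class(ps, "portal_set")
  expect_equal(nrow(ps$sites), 4L)
  for (j in 1:4) expect_true(is_exit_candidate(ps$sites[j, ], b))
  d <- as.matrix(stats::dist(ps$sites))
  expect_true(all(d[upper.tri(d)] >= tp$min_separation - 1e-9) ||
                ps$relaxed > 0)
  set.seed(501)
  ps2 <- place_portals(b, 4, tp)
  expect_identical(ps$sites, ps2$sites)
  expect_equal(nrow(place_portals(b, 0, tp)$sites), 0L)
  expect_error(place_portals(b, 1e6, tp), "infeasible")
})

test_that("portal update relocates invalid portals and re-matches the count", {
  b <- build_blob(6000)
  tp <- trafficking_params()
  set.seed(502)
  ps <- place_portals(b, required_exit_count(6000, tp), tp)
  # contract the blob by a whole shell: old portals fall outside the layer
  b2 <- b
  for (i in seq_len(900)) {
    idx <- which(b2$avail)
    far <- idx[which.max(b2$r2[idx])]
    b2$occ[far] <- 0L
    b2 <- remove_boundary_site(b2)
  }
  ps2 <- update_portals(b2, ps, sum(b2$avail), tp)
  for (j in seq_len(nrow(ps2$sites))) {
    expect_true(is_exit_candidate(ps2$sites[j, ], b2))
  }
  expect_equal(nrow(ps2$sites), required_exit_count(sum(b2$avail), tp))
  # unchanged N: portal count unchanged
  ps3 <- update_portals(b, ps, 6000, tp)
  expect_equal(nrow(ps3$sites), nrow(ps$sites))
})

test_that("ingress places Poisson arrivals inside the entry sphere", {
  b <- build_blob(3000)
  cells <- blob_cells(b)
  # F_in = 0: nothing happens
  out0 <- ingress_step(0, b, cells)
  expect_identical(out0$cells, cells)
  set.seed(503)
  tot <- 0L
  out <- list(blob = b, cells = cells)
  for (k in 1:40) {
    out <- ingress_step(138.9, out$blob, out$cells, t_min = k * 0.25)
    tot <- tot + (nrow(out$cells) - 3000L - tot)
  }
  n_new <- nrow(out$cells) - 3000L
  # mean 34.7 per step; 40 steps ~ 1389 +- sampling noise
  expect_gt(n_new, 1389 - 4 * sqrt(1389))
  expect_lt(n_new, 1389 + 4 * sqrt(1389))
  new <- dplyr::filter(out$cells, entry_min > 0)
  r <- sqrt(new$x^2 + new$y^2 + new$z^2)
  expect_true(all(r <= 0.7 * out$blob$R + 1e-9))
  # accounting: one boundary site added per placed arrival
  expect_equal(sum(out$blob$avail), nrow(out$cells))
})

test_that("egress removes only portal-neighbourhood cells at rate P_E", {
  b <- build_blob(3000)
  cells <- blob_cells(b)
  set.seed(504)
  ps <- place_portals(b, 1, trafficking_params())
  # P_E = 0: no egress
  out0 <- egress_step(b, cells, ps, params = trafficking_params(P_E = 1e-12))
  expect_equal(nrow(out0$departed), 0L)
  # P_E = 1: every cell in the neighbourhood leaves, none outside does
  out1 <- egress_step(b, cells, ps, t_min = 10,
                      params = trafficking_params(P_E = 1))
  expect_gt(nrow(out1$departed), 0L)
  expect_true(all(abs(out1$departed$x - ps$sites[1, 1]) <= 1))
  expect_true(all(out1$departed$exit_min == 10))
  left <- out1$cells
  in_nb <- abs(left$x - ps$sites[1, 1]) <= 1 &
    abs(left$y - ps$sites[1, 2]) <= 1 & abs(left$z - ps$sites[1, 3]) <= 1
  expect_false(any(in_nb))
  expect_equal(sum(out1$blob$avail), nrow(out1$cells) + out1$deferred_removals)
  # expected departures: 27 occupied sites x P_E = 0.54 per step
  set.seed(505)
  deps <- replicate(300, nrow(egress_step(b, cells, ps,
                                          params = trafficking_params())$departed))
  expect_equal(mean(deps), 27 * 0.02, tolerance = 0.15)
})

test_that("flux-matching calibration matches the mean-field oracle scale", {
  set.seed(506)
  cal <- calibrate_exit_count(2500, run_days = 0.75, n_iter = 2)
  # mean-field: N * dt / (T_res * 27 * P_E)
  mf <- 2500 * 0.25 / (720 * 27 * 0.02)
  expect_equal(cal$N_E, mf, tolerance = 0.25)
  expect_equal(cal$portal_occ, 1, tolerance = 0.15)
})
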