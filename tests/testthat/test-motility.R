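test_that("isotropic base-walk probabilities normalise the 1/|u| weights", {
  p <- base_jump_probabilities(NULL, motility_params(p0 = 0, kappa = 0))
  expect_equal(sum(p), 1, tolerance = 1e-12)
  expect_equal(p[1], 0)
  dirs <- attr(p, "dirs")
  axis_idx <- which(rowSums(abs(dirs)) == 1)
  # axis jumps: 1/sum over the 26 weights 1/|u| (brute-force oracle)
  expect_equal(unname(p[axis_idx[1]]), oracle_isotropic_axis_prob(),
               tolerance = 1e-12)
  expect_equal(length(unique(round(p[axis_idx], 12))), 1L)
})

test_that("degenerate and limiting motility parameters behave", {
  p <- base_jump_probabilities(NULL, motility_params(p0 = 1 - 1e-12, kappa = 0))
  expect_equal(unname(p[1]), 1, tolerance = 1e-9)
  # large kappa concentrates mass on the most aligned jump
  prev <- c(1, 0, 0)
  p2 <- base_jump_probabilities(prev, motility_params(p0 = 0, kappa = 25))
  dirs <- attr(p2, "dirs")
  best <- which.max(p2)
  expect_equal(unname(dirs[best, ]), c(1L, 0L, 0L))
  expect_gt(p2[best], 0.95)
  expect_error(motility_params(p0 = 1.2), "p0")
  expect_error(motility_params(kappa = -1), "kappa")
})

test_that("engine sampling matches the R jump distribution (chi-square)", {
  # one-step trajectories: first step has no previous direction
  mp <- motility_params(p0 = 0.3, kappa = 1.2)
  set.seed(301)
  res <- paracortex:::cpp_free_walk(30000L, 1L, mp$p0, mp$kappa, c(0, 0, 0),
                                    TRUE)
  one <- res$step == 1L
  key <- paste(res$x[one], res$y[one], res$z[one])
  p <- base_jump_probabilities(NULL, mp)
  dirs <- attr(p, "dirs")
  expected <- as.numeric(p)
  counts <- as.numeric(table(factor(key, levels = paste(dirs[, 1], dirs[, 2],
                                                        dirs[, 3]))))
  gof <- suppressWarnings(stats::chisq.test(counts, p = expected))
  expect_gt(gof$p.value, 0.001)
})

test_that("measured speed and Cm have the right trivial limits", {
  # straight-line mover at one axis grid per step: 6.3 um / 0.25 min
  tr <- tibble::tibble(traj = 1, step = 0:60, t_min = (0:60) * 0.25,
                       x = 0:60, y = 0, z = 0)
  mm <- measure_motility(tr)
  expect_equal(mm$speed_um_min, 25.2, tolerance = 1e-9)
  # immobile cells
  tr0 <- tibble::tibble(traj = rep(1:3, each = 61), step = rep(0:60, 3),
                        t_min = rep((0:60) * 0.25, 3), x = 0, y = 0, z = 0)
  mm0 <- measure_motility(tr0)
  expect_equal(mm0$speed_um_min, 0)
  expect_equal(mm0$Cm_um2_min, 0, tolerance = 1e-9)
  expect_error(measure_motility(tr[1:3, ]), "insufficient")
})

test_that("kappa = 0 walk matches unbiased random-walk statistics", {
  set.seed(321)
  tr <- simulate_walk(600, 240, motility_params(p0 = 0.5, kappa = 0))
  last <- dplyr::filter(tr, step == max(step))
  # zero-mean displacement
  expect_lt(abs(mean(last$x)), 3 * stats::sd(last$x) / sqrt(nrow(last)))
  expect_lt(abs(mean(last$y)), 3 * stats::sd(last$y) / sqrt(nrow(last)))
  # MSD linear in t at large t: slope over 3rd quarter vs 4th quarter agree
  g <- dplyr::summarise(dplyr::group_by(tr, step),
                        msd = mean(x^2 + y^2 + z^2))
  n <- nrow(g)
  s1 <- stats::coef(stats::lm(msd ~ step, data = g[(n %/% 2):(3 * n %/% 4), ]))[2]
  s2 <- stats::coef(stats::lm(msd ~ step, data = g[(3 * n %/% 4):n, ]))[2]
  expect_equal(unname(s1 / s2), 1, tolerance = 0.2)
})

test_that("speed falls with p0 and Cm rises with kappa at fixed speed", {
  set.seed(331)
  m_lo <- measure_motility(simulate_walk(300, 240, motility_params(p0 = 0.3, kappa = 0.5)))
  m_hi <- measure_motility(simulate_walk(300, 240, motility_params(p0 = 0.7, kappa = 0.5)))
  expect_gt(m_lo$speed_um_min, m_hi$speed_um_min)
  # fixed speed: raise kappa, adjust p0 via the exact speed relation
  p0a <- 1 - 15 * 0.25 / (6.3 * paracortex:::.mean_jump_length(0.2))
  p0b <- 1 - 15 * 0.25 / (6.3 * paracortex:::.mean_jump_length(1.6))
  ma <- measure_motility(simulate_walk(300, 360, motility_params(p0a, 0.2)))
  mb <- measure_motility(simulate_walk(300, 360, motility_params(p0b, 1.6)))
  expect_equal(ma$speed_um_min, mb$speed_um_min, tolerance = 0.1)
  expect_gt(mb$Cm_um2_min, ma$Cm_um2_min)
})

test_that("calibration reproduces reachable targets and rejects others", {
  set.seed(341)
  mp <- calibrate_motility(15, 30, n_traj = 300, n_steps = 360)
  meas <- attr(mp, "measured")
  expect_lt(abs(meas$speed_um_min - 15) / 15, 0.05)
  expect_lt(abs(meas$Cm_um2_min - 30) / 30, 0.15)
  # zero speed is the degenerate stay distribution
  expect_equal(calibrate_motility(0, 0)$p0, 1, tolerance = 1e-9)
  # a Cm beyond the ballistic limit is unreachable
  expect_error(calibrate_motility(10, 1e6), "ballistic")
  expect_error(suppressWarnings(calibrate_motility(15, 500,
                                                   n_traj = 100,
                                                   n_steps = 120)),
               "calibration failure")
})
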