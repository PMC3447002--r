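# Persistent random walk of T cells on the lattice, calibrated to the
# speed and motility-coefficient ranges measured by intravital microscopy.

#' Base-walk jump probabilities
#'
#' Probability vector over the 27 outcomes of one 15 s step: index 1 is
#' "no jump" (probability `p0`); indices 2..27 map to the 26 Moore jumps
#' (see [jump_vectors()]) with probability proportional to
#' `exp(kappa * cos(phi)) / |u|`, where `phi` is the angle between the
#' candidate jump `u` and the previous jump direction. With no previous
#' direction (or `kappa = 0`) the walk is isotropic up to the `1/|u|`
#' jump-length correction.
#'
#' @param prev_dir Unit 3-vector of the previous jump, or `NULL`.
#' @param params A [motility_params()] object.
#' @return A numeric vector of length 27 summing to 1, with attribute
#'   `"dirs"` holding the jump vectors.
#' @examples
#' p <- base_jump_probabilities(NULL, motility_params(p0 = 0, kappa = 0))
#' p[2]  # axis jumps ~0.0568 each
#' @export
base_jump_probabilities <- function(prev_dir = NULL, params = motility_params()) {
  stopifnot(inherits(params, "motility_params"))
  dirs <- jump_vectors(3)
  len <- jump_lengths(3)
  if (is.null(prev_dir) || params$kappa == 0) {
    w <- 1 / len
  } else {
    prev_dir <- as.numeric(prev_dir)
    if (length(prev_dir) != 3L || abs(sqrt(sum(prev_dir^2)) - 1) > 1e-6) {
      stop("`prev_dir` must be a unit 3-vector or NULL", call. = FALSE)
    }
    cosphi <- as.numeric(dirs %*% prev_dir) / len
    w <- exp(params$kappa * cosphi) / len
  }
  p <- c(params$p0, (1 - params$p0) * w / sum(w))
  structure(p, dirs = rbind(c(0L, 0L, 0L), dirs))
}

#' Simulate free-space walk trajectories
#'
#' Simulates `n_traj` independent cells walking on an unbounded lattice
#' (no crowding, no blob boundary), optionally under a spatially uniform
#' chemotactic attraction `C`. Used for motility calibration and for the
#' chemotaxis-index estimator.
#'
#' @param n_traj Number of trajectories.
#' @param n_steps Number of 15 s steps per trajectory.
#' @param params A [motility_params()] object.
#' @param attraction Uniform chemotactic attraction vector `C` (length 3);
#'   `c(0, 0, 0)` for the pure base walk. The fractional chemotactic
#'   influence is `alpha = min(1, |C|)`.
#' @return A tibble with columns `traj`, `step`, `t_min`, `x`, `y`, `z`
#'   (positions in lattice units, starting at the origin).
#' @examples
#' tr <- simulate_walk(5, 20)
#' dplyr::count(tr, traj)
#' @export
simulate_walk <- function(n_traj, n_steps, params = motility_params(),
                          attraction = c(0, 0, 0)) {
  stopifnot(n_traj >= 1, n_steps >= 1, length(attraction) == 3L)
  res <- cpp_free_walk(as.integer(n_traj), as.integer(n_steps),
                       params$p0, params$kappa, as.numeric(attraction), TRUE)
  tibble::tibble(
    traj = res$traj, step = res$step, t_min = res$step * params$dt_min,
    x = res$x, y = res$y, z = res$z
  )
}

#' Measure speed and motility coefficient from trajectories
#'
#' Speed is the mean over cells of (path length) / (duration). The motility
#' coefficient `Cm` (the diffusion-like coefficient of the walk) is the
#' asymptotic slope of the ensemble mean squared displacement against time,
#' divided by 6 (3D), estimated by a linear fit over the tail half of the
#' lag range where the walk has decorrelated.
#'
#' @param trajectories A tibble as returned by [simulate_walk()]: columns
#'   `traj`, `t_min`, `x`, `y`, `z` in lattice units.
#' @param grid_um Grid spacing, micrometres.
#' @return A list with `speed_um_min` and `Cm_um2_min`.
#' @export
measure_motility <- function(trajectories, grid_um = 6.3) {
  tr <- dplyr::arrange(trajectories, .data$traj, .data$t_min)
  ntraj <- dplyr::n_distinct(tr$traj)
  steps_per <- nrow(tr) / ntraj - 1
  dur_min <- max(tr$t_min) - min(tr$t_min)
  if (ntraj < 1 || dur_min <= 0 || steps_per < 4) {
    stop("insufficient trajectory data", call. = FALSE)
  }
  g <- dplyr::group_by(tr, .data$traj)
  path <- dplyr::summarise(
    g,
    path = sum(sqrt(diff(.data$x)^2 + diff(.data$y)^2 + diff(.data$z)^2)),
    dur = max(.data$t_min) - min(.data$t_min)
  )
  speed <- mean(path$path / path$dur) * grid_um

  # ensemble MSD from each trajectory's start
  t0 <- dplyr::slice_min(g, .data$t_min, n = 1, with_ties = FALSE)
  t0 <- dplyr::select(dplyr::ungroup(t0), "traj", x0 = "x", y0 = "y", z0 = "z")
  tr2 <- dplyr::left_join(dplyr::ungroup(g), t0, by = "traj")
  tr2$lag <- tr2$t_min - min(tr2$t_min)
  tr2$sq <- (tr2$x - tr2$x0)^2 + (tr2$y - tr2$y0)^2 + (tr2$z - tr2$z0)^2
  msd <- dplyr::summarise(dplyr::group_by(tr2, .data$lag),
                          msd = mean(.data$sq), .groups = "drop")
  tail_half <- msd[msd$lag >= max(msd$lag) / 2, ]
  fit <- stats::lm(msd ~ lag, data = tail_half)
  slope <- stats::coef(fit)[["lag"]]  # lattice^2 per min
  list(speed_um_min = speed, Cm_um2_min = slope * grid_um^2 / 6)
}

# Exact stationary mean jump length of the persistent kernel, via the
# 26-state Markov chain over previous-jump directions (no-jump steps do
# not change the previous direction, so p0 drops out).
.mean_jump_length <- function(kappa) {
  dirs <- jump_vectors(3)
  len <- jump_lengths(3)
  u <- dirs / len
  W <- matrix(0, 26, 26)
  for (i in 1:26) W[i, ] <- exp(kappa * as.numeric(u %*% u[i, ])) / len
  P <- W / rowSums(W)
  e <- Re(eigen(t(P))$vectors[, 1])
  pi_st <- e / sum(e)
  sum(pi_st * (P %*% len))
}

#' Calibrate the persistent random walk to motion targets
#'
#' Finds `(p0, kappa)` so that free-space trajectories reproduce a target
#' mean speed and motility coefficient. The mean executed jump length per
#' jump depends only on `kappa` and is computed exactly from the
#' stationary distribution of the 26-state direction chain, which pins
#' `p0` analytically for any `kappa`:
#' `speed = (1 - p0) * m(kappa) * grid / dt`. The remaining 1D search on
#' `kappa` matches `Cm` using simulated trajectories (Cm increases with
#' persistence at fixed speed).
#'
#' @param target_speed Target mean speed, um/min.
#' @param target_Cm Target motility coefficient, um^2/min.
#' @param dt_min,grid_um Step length (min) and grid spacing (um).
#' @param n_traj,n_steps Simulation size per candidate evaluation.
#' @param kappa_max Upper bound of the persistence search range.
#' @return A [motility_params()] object, with attribute `"measured"`
#'   holding the re-measured speed and Cm.
#' @examples
#' \donttest{
#' set.seed(1)
#' mp <- calibrate_motility(15, 55)
#' }
#' @export
calibrate_motility <- function(target_speed, target_Cm, dt_min = 0.25,
                               grid_um = 6.3, n_traj = 400, n_steps = 480,
                               kappa_max = 2.5) {
  if (target_speed == 0) {
    return(motility_params(p0 = 1 - 1e-12, kappa = 0, dt_min = dt_min,
                           grid_um = grid_um))
  }
  if (target_speed < 0 || target_Cm < 0) {
    stop("targets must be non-negative", call. = FALSE)
  }
  # crude ballistic bound: Cm cannot exceed speed^2 * T_obs / 6
  if (target_Cm > target_speed^2 * (n_steps * dt_min) / 6) {
    stop("calibration failure: target_Cm exceeds the ballistic limit ",
         "for the observation window", call. = FALSE)
  }
  p0_for <- function(kappa) {
    p0 <- 1 - target_speed * dt_min / (grid_um * .mean_jump_length(kappa))
    if (p0 < 0 || p0 >= 1) NA_real_ else p0
  }
  cm_at <- function(kappa) {
    p0 <- p0_for(kappa)
    if (is.na(p0)) return(NA_real_)
    tr <- simulate_walk(n_traj, n_steps,
                        motility_params(p0, kappa, dt_min, grid_um))
    measure_motility(tr, grid_um)$Cm_um2_min
  }
  kgrid <- seq(0, kappa_max, length.out = 9)
  cms <- vapply(kgrid, cm_at, numeric(1))
  ok <- !is.na(cms)
  if (!any(ok)) stop("calibration failure: speed target unreachable", call. = FALSE)
  kgrid <- kgrid[ok]; cms <- cms[ok]
  if (target_Cm < min(cms) - 5 || target_Cm > max(cms) + 5) {
    stop(sprintf(
      "calibration failure: reachable Cm range at speed %.3g um/min is [%.3g, %.3g] um^2/min",
      target_speed, min(cms), max(cms)), call. = FALSE)
  }
  kappa <- stats::approx(cms, kgrid, xout = target_Cm, rule = 2)$y
  # one refinement pass on a finer local grid
  kloc <- seq(max(0, kappa - 0.3), min(kappa_max, kappa + 0.3), length.out = 5)
  cml <- vapply(kloc, cm_at, numeric(1))
  keep <- !is.na(cml)
  if (sum(keep) >= 2) {
    kappa <- stats::approx(cml[keep], kloc[keep], xout = target_Cm, rule = 2)$y
  }
  out <- motility_params(p0_for(kappa), kappa, dt_min, grid_um)
  check <- measure_motility(simulate_walk(1000, n_steps, out), grid_um)
  if (abs(check$speed_um_min - target_speed) > 0.05 * target_speed ||
      abs(check$Cm_um2_min - target_Cm) > 0.15 * target_Cm) {
    stop(sprintf(
      "calibration failure: achieved speed %.3g um/min, Cm %.3g um^2/min for targets (%.3g, %.3g)",
      check$speed_um_min, check$Cm_um2_min, target_speed, target_Cm),
      call. = FALSE)
  }
  attr(out, "measured") <- check
  out
}
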