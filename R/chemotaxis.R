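# Probabilistic chemotaxis on the lattice: a chemotaxis-only jump
# distribution built from the attraction direction, mixed into the base
# walk according to the attraction strength.

#' Chemotaxis-only jump probabilities
#'
#' The directional effect of chemotaxis alone, without reference to its
#' strength: for each jump direction the weight is the squared cosine of
#' the angle between the jump vector and the attraction unit vector `v`,
#' divided by the jump distance (necessary because neighbours lie at three
#' different distances); jumps directed counter to the attraction
#' (negative cosine) get probability zero. Weights are normalised to sum
#' to 1 over the jump directions (there is no no-jump entry).
#'
#' In 2D with `v` at 30 degrees from the x-axis this reproduces the worked
#' example: probabilities 0.439, 0.386, 0.147, 0.028 for directions 1, 2,
#' 3, 8 and zero for the counter-directed jumps.
#'
#' @param v Attraction unit vector (length 2 or 3). A non-unit vector is
#'   normalised; a zero vector is an error (undefined direction).
#' @param dim Lattice dimension (2 or 3); defaults to `length(v)`.
#' @return Numeric vector over jump directions 1..N_J summing to 1, with
#'   attribute `"dirs"`.
#' @examples
#' round(chemo_only_probabilities(c(0.866, 0.5)), 3)
#' chemo_only_probabilities(c(1, 0, 0))[1]  # ~0.314
#' @export
chemo_only_probabilities <- function(v, dim = length(v)) {
  v <- as.numeric(v)
  if (length(v) != dim || !dim %in% c(2L, 3L)) {
    stop("`v` must have length 2 or 3 matching `dim`", call. = FALSE)
  }
  nv <- sqrt(sum(v^2))
  if (nv < 1e-12) stop("attraction direction undefined for a zero vector",
                       call. = FALSE)
  v <- v / nv
  dirs <- jump_vectors(dim)
  len <- sqrt(rowSums(dirs^2))
  cosang <- as.numeric(dirs %*% v) / len
  w <- ifelse(cosang >= 0, cosang^2 / len, 0)
  structure(w / sum(w), dirs = dirs)
}

#' Net chemotactic attraction from exit portals
#'
#' The attraction exerted on a cell by a set of exit portals is a bounded
#' inverse-square function of distance: each portal at distance `r`
#' (lattice units) contributes `g(r) = min(1, K_E / r^2)` along the unit
#' vector toward it, where `K_E` is the cell's chemotactic susceptibility.
#' Contributions combine by vector addition. Portals with
#' `K_E / r^2 < cutoff` are out of influence range and skipped; a portal
#' exactly at the cell's position has undefined direction and contributes
#' zero.
#'
#' @param pos Cell position, integer coordinates (length 3).
#' @param portals Portal coordinates: a matrix with 3 columns (one row per
#'   portal) or a [place_portals()] result.
#' @param K_E Chemotactic susceptibility, `>= 0`.
#' @param cutoff Influence cutoff on `K_E / r^2` (default 0.01, below
#'   which chemotaxis is under 1% and indistinguishable from noise).
#' @return A list of class `"chemo_attraction"`: `C` (3-vector),
#'   `strength` = |C|, `direction` (unit vector or `NULL` if |C| = 0) and
#'   `alpha = min(1, |C|)`, the fractional chemotactic influence.
#' @examples
#' portal_attraction(c(0, 0, 0), rbind(c(2, 0, 0)), K_E = 1)$strength  # 0.25
#' @export
portal_attraction <- function(pos, portals, K_E, cutoff = 0.01) {
  if (K_E < 0) stop("`K_E` must be >= 0", call. = FALSE)
  portals <- portal_matrix(portals)
  C <- c(0, 0, 0)
  if (K_E > 0 && nrow(portals) > 0L) {
    for (j in seq_len(nrow(portals))) {
      d <- as.numeric(portals[j, ]) - as.numeric(pos)
      r2 <- sum(d^2)
      if (r2 == 0) next                 # undefined direction: contributes 0
      if (K_E / r2 < cutoff) next       # out of influence range
      C <- C + min(1, K_E / r2) * d / sqrt(r2)
    }
  }
  s <- sqrt(sum(C^2))
  structure(list(C = C, strength = s,
                 direction = if (s > 0) C / s else NULL,
                 alpha = min(1, s)),
            class = "chemo_attraction")
}

#' Combine base-walk and chemotaxis-only jump probabilities
#'
#' The modified jump distribution `p*` mixes the base walk `p` and the
#' chemotaxis-only distribution `p_c` with weight `alpha` (the fractional
#' chemotactic influence), and accounts for jump directions prevented by
#' cell crowding: a blocked direction's probability mass is transferred to
#' the no-jump outcome (a blocked attempt is a failed move), so the
#' distribution always sums to 1.
#'
#' For unblocked `i >= 1`: `p*(i) = (1 - alpha) p(i) + alpha p_c(i)`;
#' for blocked `i`: `p*(i) = 0`; and
#' `p*(0) = (1 - alpha) p(0) + sum over blocked of the mixed mass`.
#'
#' @param p Base-walk distribution of length `N_J + 1` (index 1 = no jump),
#'   e.g. from [base_jump_probabilities()].
#' @param p_c Chemotaxis-only distribution of length `N_J`, e.g. from
#'   [chemo_only_probabilities()].
#' @param alpha Fractional chemotactic influence in `[0, 1]`.
#' @param blocked Integer vector of blocked jump indices (in `1..N_J`).
#' @return Numeric vector of length `N_J + 1` summing to 1.
#' @examples
#' p <- base_jump_probabilities(NULL, motility_params())
#' pc <- chemo_only_probabilities(c(1, 0, 0))
#' pstar <- combined_jump_probabilities(p, pc, alpha = 1)
#' pstar[1]  # 0: full chemotaxis leaves no no-jump mass
#' @export
combined_jump_probabilities <- function(p, p_c, alpha, blocked = integer()) {
  p <- as.numeric(p); p_c <- as.numeric(p_c)
  nj <- length(p_c)
  if (length(p) != nj + 1L) {
    stop("`p` must have length one more than `p_c`", call. = FALSE)
  }
  if (!is.numeric(alpha) || length(alpha) != 1L || is.na(alpha) ||
      alpha < 0 || alpha > 1) {
    stop("`alpha` must be a number in [0, 1]", call. = FALSE)
  }
  if (abs(sum(p) - 1) > 1e-8 || abs(sum(p_c) - 1) > 1e-8 ||
      any(p < 0) || any(p_c < 0)) {
    stop("`p` and `p_c` must be probability vectors", call. = FALSE)
  }
  blocked <- as.integer(blocked)
  if (any(blocked < 1L | blocked > nj)) {
    stop("`blocked` indices must lie in 1..N_J", call. = FALSE)
  }
  mixed <- (1 - alpha) * p[-1L] + alpha * p_c
  out <- numeric(nj + 1L)
  out[1L] <- (1 - alpha) * p[1L] + sum(mixed[blocked])
  mixed[blocked] <- 0
  out[-1L] <- mixed
  out
}

#' Chemotaxis index of the simulated walk
#'
#' Estimates the chemotaxis index (CI) for the artificial situation of a
#' spatially invariant attraction of given strength along a fixed axis, in
#' free space. The standard (McCutcheon) index is straight-line distance
#' over path length; it does not go to zero without chemotaxis, so the
#' directional variant divides the displacement *along the attraction
#' axis* by the path length instead. The mean is taken over a large number
#' of independent trajectories; trajectories that never jump (zero path
#' length) have an undefined ratio and are excluded.
#'
#' @param strength Attraction strength |C| in `[0, 1]` (1 = fully
#'   chemotactic motion).
#' @param n_steps Steps per trajectory (default 10).
#' @param n_traj Number of trajectories (default 1000).
#' @param mode `"directional"` (default) or `"standard"`.
#' @param params A [motility_params()] object for the base walk.
#' @return The mean CI (dimensionless), with attribute `"sd"` (between-
#'   trajectory standard deviation) and `"n"` (trajectories used).
#' @examples
#' set.seed(1)
#' chemotaxis_index(1, n_traj = 200)    # ~0.74
#' @export
chemotaxis_index <- function(strength, n_steps = 10, n_traj = 1000,
                             mode = c("directional", "standard"),
                             params = motility_params()) {
  mode <- match.arg(mode)
  if (n_steps < 1) stop("`n_steps` must be >= 1", call. = FALSE)
  if (strength < 0) stop("`strength` must be >= 0", call. = FALSE)
  res <- cpp_free_walk(as.integer(n_traj), as.integer(n_steps),
                       params$p0, params$kappa,
                       c(strength, 0, 0), FALSE)
  path <- res$path
  keep <- path > 0
  ci_each <- if (mode == "directional") {
    res$dx[keep] / path[keep]
  } else {
    sqrt(res$dx[keep]^2 + res$dy[keep]^2 + res$dz[keep]^2) / path[keep]
  }
  structure(mean(ci_each), sd = stats::sd(ci_each), n = sum(keep))
}

#' Sweep the chemotaxis index over attraction strengths
#'
#' @param strengths Vector of |C| values.
#' @inheritParams chemotaxis_index
#' @return A tibble with columns `strength`, `mode`, `n_steps`, `CI`, `sd`.
#' @examples
#' set.seed(1)
#' ci_sweep(c(0, 0.5, 1), n_traj = 200)
#' @export
ci_sweep <- function(strengths, n_steps = 10, n_traj = 1000,
                     mode = "directional", params = motility_params()) {
  rows <- lapply(strengths, function(s) {
    ci <- chemotaxis_index(s, n_steps, n_traj, mode, params)
    tibble::tibble(strength = s, mode = mode, n_steps = n_steps,
                   CI = as.numeric(ci), sd = attr(ci, "sd"))
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("ci_sweep", class(out))
  out
}
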