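# Ingress into the entry sphere, discrete exit portals near the boundary,
# and the exit-count scaling law that keeps trafficking in steady state.

# Accept either a plain matrix of portal coordinates or a portal_set.
portal_matrix <- function(portals) {
  if (inherits(portals, "portal_set")) portals <- portals$sites
  if (is.null(portals)) return(matrix(integer(), 0L, 3L))
  portals <- as.matrix(portals)
  if (length(portals) == 0L) return(matrix(integer(), 0L, 3L))
  if (ncol(portals) != 3L) stop("portals must have 3 columns", call. = FALSE)
  storage.mode(portals) <- "integer"
  portals
}

#' Exit-candidate predicate
#'
#' A site can host an exit portal iff (i) all 27 sites of its Moore
#' neighbourhood are inside the blob, (ii) at least one of those sites has
#' a neighbour outside the blob (so the portal sits just inside the
#' boundary), and (iii) it is not in the follicle-interface cap, i.e.
#' `x / R <= cap_threshold`.
#'
#' @param site Integer coordinates (length 3).
#' @param blob A `"lattice_blob"`.
#' @param cap_threshold Cap exclusion threshold on x/R (default 0.6).
#' @return Logical flag.
#' @export
is_exit_candidate <- function(site, blob, cap_threshold = 0.6) {
  if (site[1L] / blob$R > cap_threshold) return(FALSE)
  nbhd <- moore_neighborhood(site)
  inside <- apply(nbhd, 1L, function(s) blob_contains(blob, s))
  if (!all(inside)) return(FALSE)
  for (k in seq_len(nrow(nbhd))) {
    nb2 <- moore_neighborhood(nbhd[k, ])[-1L, ]
    if (!all(apply(nb2, 1L, function(s) blob_contains(blob, s)))) return(TRUE)
  }
  FALSE
}

#' Chemotactic exit-count reduction factor
#'
#' When every cell is attracted to the portals they crowd the portal
#' neighbourhoods and the egress rate per portal rises, so fewer portals
#' are needed for the same flux. The reduction factor is the fitted
#' quadratic `beta(K) = c0 + c1 K + c2 K^2`, clamped below at 0.5: at high
#' chemotaxis the portal neighbourhoods are constantly fully occupied (two
#' cells per site) and further attraction has no effect.
#'
#' @param K_E Chemotactic susceptibility (vectorised).
#' @param coeffs Quadratic coefficients `(c0, c1, c2)`.
#' @return beta values in `[0.5, ~1]`.
#' @examples
#' beta_exit_reduction(0)   # ~1
#' beta_exit_reduction(5)   # clamped to 0.5
#' @export
beta_exit_reduction <- function(K_E, coeffs = .default_beta_coeffs) {
  pmax(coeffs[1L] + coeffs[2L] * K_E + coeffs[3L] * K_E^2, 0.5)
}

#' Number of exit portals required for steady state
#'
#' The calibrated power law gives the portal count that balances influx
#' `N / T_res` at egress probability 0.02; it is scaled inversely with
#' `P_E` and reduced by `beta(K_E)` when all cells are chemotactic:
#' `N_E = round( beta(K_E) * (0.02 / P_E) * a * N^b / T_res )`
#' with `T_res` in minutes.
#'
#' @param N T cell population.
#' @param params A [trafficking_params()] object (carries `P_E`,
#'   `T_res_min`, the power-law constants and the beta coefficients).
#' @param K_E Chemotactic susceptibility of the bulk population (0 when
#'   only a small subset is chemotactic).
#' @param round_count Return an integer count (default) or the continuous
#'   requirement.
#' @return Portal count.
#' @examples
#' required_exit_count(1e5, trafficking_params())
#' @export
required_exit_count <- function(N, params = trafficking_params(), K_E = 0,
                                round_count = TRUE) {
  if (N < 1) stop("`N` must be >= 1", call. = FALSE)
  if (!is.finite(params$power_a) || !is.finite(params$power_b)) {
    stop("power-law constants missing; run calibrate_exit_constants()",
         call. = FALSE)
  }
  ne <- beta_exit_reduction(K_E, params$beta_coeffs) * (0.02 / params$P_E) *
    params$power_a * N^params$power_b / params$T_res_min
  if (round_count) as.integer(round(ne)) else ne
}

#' Place exit portals on the blob
#'
#' Samples `n_portals` exit-candidate sites uniformly at random, subject
#' to a minimum pairwise separation (dart throwing with up to 100 retries
#' per portal; if separation cannot be honoured the nearest feasible
#' candidate is accepted and the relaxation is counted). Deterministic
#' under a fixed RNG seed.
#'
#' @param blob A `"lattice_blob"`.
#' @param n_portals Number of portals (0 gives a closed node).
#' @param params A [trafficking_params()] object (`cap_threshold`,
#'   `min_separation`).
#' @return An object of class `"portal_set"`: list with `sites` (matrix),
#'   `min_separation`, `relaxed` (count of separation relaxations).
#' @export
place_portals <- function(blob, n_portals, params = trafficking_params()) {
  stopifnot(n_portals >= 0)
  cand <- exit_candidates(blob, params$cap_threshold)
  if (n_portals > nrow(cand)) {
    stop(sprintf("infeasible portal count: only %d candidate sites exist",
                 nrow(cand)), call. = FALSE)
  }
  chosen <- matrix(integer(), 0L, 3L)
  relaxed <- 0L
  for (k in seq_len(n_portals)) {
    placed <- FALSE
    for (try in seq_len(100L)) {
      s <- cand[sample.int(nrow(cand), 1L), , drop = TRUE]
      if (nrow(chosen) == 0L ||
          min(sqrt(rowSums(sweep(chosen, 2L, s)^2))) >= params$min_separation) {
        chosen <- rbind(chosen, s)
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      # accept the candidate farthest from existing portals
      d <- apply(cand, 1L, function(s)
        min(sqrt(rowSums(sweep(chosen, 2L, s)^2))))
      chosen <- rbind(chosen, cand[which.max(d), , drop = TRUE])
      relaxed <- relaxed + 1L
    }
  }
  rownames(chosen) <- NULL
  structure(list(sites = chosen, min_separation = params$min_separation,
                 relaxed = relaxed),
            class = "portal_set")
}

#' Enumerate exit-candidate sites
#'
#' @inheritParams is_exit_candidate
#' @return Integer matrix of candidate coordinates (possibly 0 rows).
#' @export
exit_candidates <- function(blob, cap_threshold = 0.6) {
  shell <- which(blob$avail & blob$r2 >= (max(0, blob$R - 3.5))^2)
  keep <- vapply(shell, function(i) {
    is_exit_candidate(c(blob$x[i], blob$y[i], blob$z[i]), blob, cap_threshold)
  }, logical(1))
  m <- cbind(x = blob$x[shell[keep]], y = blob$y[shell[keep]],
             z = blob$z[shell[keep]])
  storage.mode(m) <- "integer"
  m
}

#' Re-match portals to a changed blob
#'
#' Portals that no longer satisfy the exit-candidate predicate (because
#' the blob grew or contracted) are relocated to the nearest valid
#' candidate; the portal count is then re-matched to
#' [required_exit_count()] by adding portals at random candidates or
#' removing the most recently added ones.
#'
#' @param blob A `"lattice_blob"`.
#' @param portals A `"portal_set"`.
#' @param N Current population.
#' @param params A [trafficking_params()] object.
#' @param K_E Bulk chemotactic susceptibility.
#' @return The updated `"portal_set"`.
#' @export
update_portals <- function(blob, portals, N, params = trafficking_params(),
                           K_E = 0) {
  sites <- portal_matrix(portals)
  cand <- exit_candidates(blob, params$cap_threshold)
  if (nrow(sites) > 0L) {
    for (j in seq_len(nrow(sites))) {
      if (!is_exit_candidate(sites[j, ], blob, params$cap_threshold)) {
        if (nrow(cand) == 0L) stop("no exit candidates available", call. = FALSE)
        d <- sqrt(rowSums(sweep(cand, 2L, sites[j, ])^2))
        sites[j, ] <- cand[which.min(d), ]
      }
    }
  }
  target <- required_exit_count(N, params, K_E)
  while (nrow(sites) > target) sites <- sites[-nrow(sites), , drop = FALSE]
  if (nrow(sites) < target) {
    extra <- place_portals(blob, target - nrow(sites), params)
    sites <- rbind(sites, extra$sites)
  }
  structure(list(sites = sites,
                 min_separation = params$min_separation,
                 relaxed = if (inherits(portals, "portal_set")) portals$relaxed else 0L),
            class = "portal_set")
}

#' One ingress step (reference implementation)
#'
#' Draws `Poisson(F_in * dt)` arrivals and places each at a uniformly
#' sampled available site with occupancy < 2 inside the entry sphere of
#' radius `entry_fraction * R` (up to 50 resamples; arrivals that cannot
#' be placed are deferred and reported). Each placed arrival makes one
#' more boundary site available, preserving sites == cells.
#'
#' @param F_in Influx rate, cells/min.
#' @param blob A `"lattice_blob"`.
#' @param cells Cell tibble.
#' @param t_min Current time (stamped on entries).
#' @param params A [trafficking_params()] object.
#' @param dt_min Step, minutes.
#' @param K_E Susceptibility given to the new cells.
#' @return List with updated `blob`, `cells`, and `deferred` count.
#' @export
ingress_step <- function(F_in, blob, cells, t_min = 0,
                         params = trafficking_params(), dt_min = 0.25,
                         K_E = 0) {
  stopifnot(F_in >= 0)
  n_new <- stats::rpois(1L, F_in * dt_min)
  deferred <- 0L
  if (n_new == 0L) return(list(blob = blob, cells = cells, deferred = 0L))
  entry_r2 <- (params$entry_fraction * blob$R)^2
  entry_idx <- which(blob$avail & blob$r2 <= entry_r2)
  next_id <- if (nrow(cells)) max(cells$id) + 1L else 1L
  for (k in seq_len(n_new)) {
    placed <- FALSE
    for (try in seq_len(50L)) {
      i <- entry_idx[sample.int(length(entry_idx), 1L)]
      if (blob$occ[i] < 2L) {
        blob$occ[i] <- blob$occ[i] + 1L
        cells <- dplyr::bind_rows(cells, tibble::tibble(
          id = next_id, x = blob$x[i], y = blob$y[i], z = blob$z[i],
          prev_dir = NA_integer_, K_E = K_E, tagged = FALSE,
          entry_min = t_min))
        next_id <- next_id + 1L
        blob <- add_boundary_site(blob)
        placed <- TRUE
        break
      }
    }
    if (!placed) deferred <- deferred + 1L
  }
  list(blob = blob, cells = cells, deferred = deferred)
}

#' One egress step (reference implementation)
#'
#' Every cell located in at least one portal Moore neighbourhood departs
#' with probability `P_E`, applied once per cell per step regardless of
#' how many neighbourhoods overlap it. Departed cells are removed, one
#' boundary site is retired per departure (deferred if all boundary sites
#' are occupied), and exit times are recorded.
#'
#' @param blob A `"lattice_blob"`.
#' @param cells Cell tibble.
#' @param portals A `"portal_set"` or coordinate matrix.
#' @param t_min Current time (stamped on exits).
#' @param params A [trafficking_params()] object.
#' @return List with `blob`, `cells`, `departed` (tibble of departures),
#'   `deferred_removals`.
#' @export
egress_step <- function(blob, cells, portals, t_min = 0,
                        params = trafficking_params()) {
  sites <- portal_matrix(portals)
  if (nrow(sites) == 0L || nrow(cells) == 0L) {
    return(list(blob = blob, cells = cells,
                departed = cells[0, ], deferred_removals = 0L))
  }
  in_nbhd <- rep(FALSE, nrow(cells))
  for (j in seq_len(nrow(sites))) {
    in_nbhd <- in_nbhd |
      (abs(cells$x - sites[j, 1L]) <= 1L &
       abs(cells$y - sites[j, 2L]) <= 1L &
       abs(cells$z - sites[j, 3L]) <= 1L)
  }
  leaving <- which(in_nbhd & stats::runif(nrow(cells)) < params$P_E)
  deferred <- 0L
  if (length(leaving)) {
    for (i in leaving) {
      r <- .blob_rank(blob, c(cells$x[i], cells$y[i], cells$z[i]))
      blob$occ[r] <- blob$occ[r] - 1L
      blob <- tryCatch(remove_boundary_site(blob), paracortex_retry = function(e) {
        deferred <<- deferred + 1L
        blob$n_cells <- blob$n_cells - 1L
        blob
      })
    }
  }
  departed <- cells[leaving, , drop = FALSE]
  if (nrow(departed)) departed$exit_min <- t_min
  list(blob = blob,
       cells = if (length(leaving)) cells[-leaving, , drop = FALSE] else cells,
       departed = departed, deferred_removals = deferred)
}
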