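# The "blob": a roughly spherical region of available sites on a cubic
# lattice representing the paracortical T zone. The number of available
# sites always equals the number of cells; a site may transiently hold two
# cells (for one step) so that cells can pass each other.

#' Lattice grid spacing from cell volume occupancy
#'
#' The lattice grid spacing follows from the fraction of tissue volume
#' occupied by the cells: each cell of volume `cell_volume` claims a cube
#' of volume `cell_volume / volume_fraction`, the rest being other cell
#' types, fibres and fluid. At the default 60% occupancy and a T cell
#' volume of 150 um^3 this gives the 6.3 um spacing used throughout.
#'
#' @param volume_fraction Fraction of volume occupied by cells, in (0, 1].
#' @param cell_volume Single-cell volume in cubic micrometres.
#' @return Grid spacing in micrometres.
#' @examples
#' grid_spacing_from_occupancy(0.6, 150)   # ~6.3 um
#' @export
grid_spacing_from_occupancy <- function(volume_fraction, cell_volume) {
  if (!is.numeric(volume_fraction) || length(volume_fraction) != 1L ||
      !is.finite(volume_fraction) || volume_fraction <= 0 ||
      volume_fraction > 1) {
    stop("`volume_fraction` must be a number in (0, 1]", call. = FALSE)
  }
  if (!is.numeric(cell_volume) || length(cell_volume) != 1L ||
      !is.finite(cell_volume) || cell_volume <= 0) {
    stop("`cell_volume` must be a positive number", call. = FALSE)
  }
  (cell_volume / volume_fraction)^(1 / 3)
}

#' Nominal blob radius for a cell count
#'
#' Radius (lattice units) of the sphere whose volume holds `n_cells` unit
#' cells: `(3 n / (4 pi))^(1/3)`.
#'
#' @param n_cells Number of cells (= available sites).
#' @return Radius in lattice units.
#' @examples
#' blob_radius(10000)  # ~13.4
#' @export
blob_radius <- function(n_cells) (3 * n_cells / (4 * pi))^(1 / 3)

# Site ordering used for all blob bookkeeping: by squared distance from the
# centre (origin), ties broken lexicographically by (x, y, z). The blob of
# n cells is built from the first n sites of this ordering, and growth /
# contraction add or remove sites so as to keep the region as close to a
# sphere as the ordering allows.
.site_order <- function(half) {
  ax <- -half:half
  g <- expand.grid(x = ax, y = ax, z = ax)
  r2 <- g$x^2 + g$y^2 + g$z^2
  o <- order(r2, g$x, g$y, g$z)
  list(x = as.integer(g$x[o]), y = as.integer(g$y[o]), z = as.integer(g$z[o]),
       r2 = r2[o], half = as.integer(half))
}

.site_key <- function(x, y, z, half) {
  L <- 2L * half + 1L
  (x + half) + L * ((y + half) + L * (z + half)) + 1L
}

#' Build a spherical lattice blob
#'
#' Creates the blob with exactly `n_cells` available sites: the `n_cells`
#' lattice sites nearest the origin, ties broken by a fixed lexicographic
#' ordering so the construction is deterministic. Every available site
#' starts with occupancy 1 (the blob is densely packed).
#'
#' @param n_cells Number of cells / available sites (`>= 1`).
#' @param grid_um Grid spacing in micrometres.
#' @param headroom Multiplicative allowance for later growth; the enclosing
#'   cube is sized for `headroom * n_cells` sites.
#' @return An object of class `"lattice_blob"`.
#' @examples
#' b <- build_blob(1000)
#' b$R
#' @export
build_blob <- function(n_cells, grid_um = 6.3, headroom = 2) {
  stopifnot(is.numeric(n_cells), length(n_cells) == 1L, n_cells >= 1)
  n_cells <- as.integer(n_cells)
  half <- as.integer(ceiling(blob_radius(headroom * n_cells)) + 3L)
  ord <- .site_order(half)
  n_sites <- length(ord$x)
  if (n_cells > n_sites) stop("cube too small for `n_cells`", call. = FALSE)
  rank_of <- integer((2L * half + 1L)^3)
  rank_of[.site_key(ord$x, ord$y, ord$z, half)] <- seq_len(n_sites)
  avail <- logical(n_sites)
  avail[seq_len(n_cells)] <- TRUE
  occ <- integer(n_sites)
  occ[seq_len(n_cells)] <- 1L
  structure(list(
    x = ord$x, y = ord$y, z = ord$z, r2 = ord$r2, half = half,
    rank_of = rank_of, avail = avail, occ = occ,
    n_cells = n_cells, R = blob_radius(n_cells), grid_um = grid_um
  ), class = "lattice_blob")
}

#' @export
print.lattice_blob <- function(x, ...) {
  cat(sprintf("<lattice_blob> %d available sites, R = %.2f lattice units (%.1f um), %d cells on sites\n",
              sum(x$avail), x$R, x$R * x$grid_um, sum(x$occ)))
  invisible(x)
}

# Rank (position in the canonical ordering) of a site; 0 if outside cube.
.blob_rank <- function(blob, site) {
  if (any(abs(site) > blob$half)) return(0L)
  blob$rank_of[.site_key(site[1L], site[2L], site[3L], blob$half)]
}

#' Query whether a site is inside the blob
#'
#' @param blob A `"lattice_blob"`.
#' @param site Integer coordinates (length 3), origin at the blob centre.
#' @return `TRUE` if the site is AVAILABLE (part of the blob).
#' @export
blob_contains <- function(blob, site) {
  r <- .blob_rank(blob, site)
  r > 0L && blob$avail[r]
}

#' Site occupancy
#' @inheritParams blob_contains
#' @return Occupancy count 0, 1 or 2 (0 for sites outside the blob).
#' @export
blob_occupancy <- function(blob, site) {
  r <- .blob_rank(blob, site)
  if (r == 0L) 0L else blob$occ[r]
}

#' Grow or shrink the blob by one boundary site
#'
#' `add_boundary_site()` makes available the outside site nearest the
#' nominal spherical surface (lowest-ranked unavailable site, ties broken
#' lexicographically); it is called when a cell enters or divides.
#' `remove_boundary_site()` makes unavailable the *unoccupied* available
#' site farthest from the centre; it is called when a cell leaves or dies.
#' If every boundary site is occupied the removal cannot be honoured this
#' step and an error of class `"paracortex_retry"` is signalled so the
#' caller can defer it.
#'
#' @param blob A `"lattice_blob"`.
#' @return The modified blob.
#' @examples
#' b <- build_blob(100)
#' b2 <- add_boundary_site(b)
#' sum(b2$avail) - sum(b$avail)  # 1
#' @export
add_boundary_site <- function(blob) {
  i <- which(!blob$avail)
  if (length(i) == 0L) stop("enclosing cube exhausted; rebuild with more headroom",
                            call. = FALSE)
  i <- i[1L]
  blob$avail[i] <- TRUE
  blob$n_cells <- blob$n_cells + 1L
  blob$R <- blob_radius(sum(blob$avail))
  blob
}

#' @rdname add_boundary_site
#' @export
remove_boundary_site <- function(blob) {
  cand <- which(blob$avail & blob$occ == 0L)
  if (length(cand) == 0L) {
    cond <- structure(
      class = c("paracortex_retry", "error", "condition"),
      list(message = "all boundary sites occupied; defer removal one step",
           call = sys.call(-1)))
    stop(cond)
  }
  i <- cand[length(cand)]  # ranks are sorted by distance: farthest last
  blob$avail[i] <- FALSE
  blob$n_cells <- blob$n_cells - 1L
  blob$R <- blob_radius(sum(blob$avail))
  blob
}

#' Export the blob as a site table
#'
#' @param blob A `"lattice_blob"`.
#' @param all_sites If `FALSE` (default) only AVAILABLE sites are returned.
#' @return A tibble with columns `x`, `y`, `z`, `state`
#'   (`"AVAILABLE"`/`"OUTSIDE"`), `occupancy`.
#' @export
blob_sites <- function(blob, all_sites = FALSE) {
  keep <- if (all_sites) rep(TRUE, length(blob$avail)) else blob$avail
  tibble::tibble(
    x = blob$x[keep], y = blob$y[keep], z = blob$z[keep],
    state = ifelse(blob$avail[keep], "AVAILABLE", "OUTSIDE"),
    occupancy = blob$occ[keep]
  )
}

#' Create a cell table for a blob
#'
#' One T cell per available site, the dense initial packing of a freshly
#' built blob. Cells are rows of a tibble: position, previous jump
#' direction (`NA` before the first jump), chemotactic susceptibility
#' `K_E`, tag flag and entry time.
#'
#' @param blob A `"lattice_blob"`.
#' @param K_E Chemotactic susceptibility assigned to every cell.
#' @return A tibble with one row per cell.
#' @export
blob_cells <- function(blob, K_E = 0) {
  idx <- which(blob$avail & blob$occ > 0L)
  idx <- rep(idx, blob$occ[idx])
  tibble::tibble(
    id = seq_along(idx),
    x = blob$x[idx], y = blob$y[idx], z = blob$z[idx],
    prev_dir = NA_integer_,
    K_E = K_E, tagged = FALSE, entry_min = 0
  )
}

#' Resolve doubly occupied sites
#'
#' Two cells may share a site for a single step (this is what lets cells
#' pass each other on the packed lattice). At the end of each step every
#' cell on a doubly occupied site attempts a forced move: its jump
#' distribution is renormalised over admissible destinations (inside the
#' blob, occupancy < 2) with the no-jump option excluded. If no admissible
#' destination exists the cell stays and the event is counted as a
#' crowding exception.
#'
#' @param blob A `"lattice_blob"` whose `occ` reflects the cells' positions.
#' @param cells A cell tibble (see [blob_cells()]).
#' @param params A [motility_params()] object.
#' @return A list with elements `blob`, `cells` and `exceptions` (count of
#'   cells that could not move).
#' @export
resolve_double_occupancy <- function(blob, cells, params = motility_params()) {
  dirs <- jump_vectors(3)
  flagged <- which(vapply(seq_len(nrow(cells)), function(i) {
    blob_occupancy(blob, c(cells$x[i], cells$y[i], cells$z[i])) == 2L
  }, logical(1)))
  exceptions <- 0L
  for (i in flagged) {
    pos <- c(cells$x[i], cells$y[i], cells$z[i])
    if (blob_occupancy(blob, pos) < 2L) next  # partner already moved away
    prev <- if (is.na(cells$prev_dir[i])) NULL else dirs[cells$prev_dir[i], ] /
      jump_lengths(3)[cells$prev_dir[i]]
    p <- base_jump_probabilities(prev, params)[-1L]  # drop no-jump
    dest_ok <- vapply(seq_len(26L), function(j) {
      s <- pos + dirs[j, ]
      r <- .blob_rank(blob, s)
      r > 0L && blob$avail[r] && blob$occ[r] < 2L
    }, logical(1))
    p[!dest_ok] <- 0
    if (sum(p) <= 0) {
      exceptions <- exceptions + 1L
      next
    }
    j <- sample.int(26L, 1L, prob = p)
    from <- .blob_rank(blob, pos)
    to <- .blob_rank(blob, pos + dirs[j, ])
    blob$occ[from] <- blob$occ[from] - 1L
    blob$occ[to] <- blob$occ[to] + 1L
    cells$x[i] <- cells$x[i] + dirs[j, 1L]
    cells$y[i] <- cells$y[i] + dirs[j, 2L]
    cells$z[i] <- cells$z[i] + dirs[j, 3L]
    cells$prev_dir[i] <- j
  }
  list(blob = blob, cells = cells, exceptions = exceptions)
}
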