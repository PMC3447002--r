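#' Lattice jump vectors
#'
#' The possible single-step jumps on the cubic (3D) or square (2D) lattice.
#' In 3D these are the 26 Moore-neighbourhood offsets, ordered
#' lexicographically by (dx, dy, dz) with dx varying fastest. In 2D they are
#' the 8 neighbour offsets ordered counter-clockwise starting from the +x
#' axis, i.e. direction 1 = (1, 0), direction 2 = (1, 1), ..., direction
#' 8 = (1, -1); this is the conventional numbering used in the worked
#' chemotaxis example (see [chemo_only_probabilities()]).
#'
#' All distances are in lattice grid units, so neighbours lie at distance 1,
#' sqrt(2) or sqrt(3).
#'
#' @param dim Lattice dimension, 2 or 3.
#' @return An integer matrix with one row per jump direction and `dim`
#'   columns.
#' @examples
#' jump_vectors(3)          # 26 rows
#' sqrt(rowSums(jump_vectors(2)^2))
#' @export
jump_vectors <- function(dim = 3) {
  if (dim == 3) {
    g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
    g <- g[rowSums(abs(g)) > 0, , drop = FALSE]
    rownames(g) <- NULL
    storage.mode(g) <- "integer"
    g
  } else if (dim == 2) {
    m <- rbind(
      c(1L, 0L), c(1L, 1L), c(0L, 1L), c(-1L, 1L),
      c(-1L, 0L), c(-1L, -1L), c(0L, -1L), c(1L, -1L)
    )
    colnames(m) <- c("dx", "dy")
    m
  } else {
    stop("`dim` must be 2 or 3", call. = FALSE)
  }
}

#' @return For `jump_lengths()`, a numeric vector of Euclidean jump
#'   distances in lattice units.
#' @rdname jump_vectors
#' @export
jump_lengths <- function(dim = 3) {
  sqrt(rowSums(jump_vectors(dim)^2))
}

#' Moore neighbourhood of a lattice site
#'
#' The block of 27 sites (9 in 2D) centred on a site: the site itself plus
#' its 26 (8) nearest lattice neighbours.
#'
#' @param site Integer coordinate vector of length 3 (or 2).
#' @return An integer matrix with 27 (or 9) rows, including `site` itself.
#' @examples
#' nbhd <- moore_neighborhood(c(0L, 0L, 0L))
#' nrow(nbhd)  # 27
#' @export
moore_neighborhood <- function(site) {
  dim <- length(site)
  if (!dim %in% c(2L, 3L)) stop("`site` must have length 2 or 3", call. = FALSE)
  offs <- rbind(matrix(0L, 1L, dim), jump_vectors(dim))
  out <- sweep(offs, 2L, as.integer(site), "+")
  storage.mode(out) <- "integer"
  colnames(out) <- c("x", "y", "z")[seq_len(dim)]
  out
}
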