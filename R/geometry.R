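# Distance machinery shared by the shell builder and the hydration
# counters. The workhorse is a cell-list (neighbor-grid) search: reference
# points are binned into cubic cells of edge >= cutoff, so all neighbors
# of a query point within the cutoff lie in its 27 surrounding cells.
# Periodic systems use a vectorized minimum-image search instead (desk-
# scale frames are small; the grid stays the open-boundary fast path).

as_coord_matrix <- function(p) {
  if (is.matrix(p)) {
    stopifnot(ncol(p) == 3L)
    return(unname(p))
  }
  unname(as.matrix(p[, c("x", "y", "z")]))
}

cell_key <- function(idx) {
  paste(idx[, 1], idx[, 2], idx[, 3], sep = ",")
}

#' Minimum distance from each query point to a reference set
#'
#' Returns, for each query point, the distance to the nearest reference
#' point, computed with a neighbor grid of cell edge `cutoff`: distances
#' beyond `cutoff` are reported as `Inf` (they never matter to the
#' callers, which only test membership against `cutoff`). With a periodic
#' `box`, the minimum-image convention is applied and the search is exact
#' for all distances up to half the smallest box edge.
#'
#' @param query,ref Matrices or data frames with `x`, `y`, `z` in nm.
#' @param cutoff Search radius, nm.
#' @param box Optional periodic box: numeric length-3 edge vector (or a
#'   scalar for a cubic box).
#' @return Numeric vector, one value per query row.
#' @export
min_dist_within <- function(query, ref, cutoff, box = NULL) {
  q <- as_coord_matrix(query)
  r <- as_coord_matrix(ref)
  if (nrow(r) == 0L || nrow(q) == 0L) {
    return(rep(Inf, nrow(q)))
  }
  if (!is.null(box)) {
    return(min_dist_pbc(q, r, box))
  }
  min_dist_grid(q, r, cutoff)
}

min_dist_grid <- function(q, r, cutoff) {
  stopifnot(cutoff > 0)
  origin <- apply(rbind(q, r), 2L, min)
  rc <- floor(sweep(r, 2L, origin) / cutoff)
  qc <- floor(sweep(q, 2L, origin) / cutoff)
  bins <- split(seq_len(nrow(r)), cell_key(rc))
  offsets <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  out <- rep(Inf, nrow(q))
  for (i in seq_len(nrow(q))) {
    cells <- cell_key(sweep(offsets, 2L, -qc[i, ]))
    cand <- unlist(bins[cells], use.names = FALSE)
    if (is.null(cand) || length(cand) == 0L) next
    d2 <- rowSums(sweep(r[cand, , drop = FALSE], 2L, q[i, ])^2)
    out[i] <- sqrt(min(d2))
  }
  out
}

min_dist_pbc <- function(q, r, box) {
  box <- rep_len(as.numeric(box), 3L)
  out <- numeric(nrow(q))
  for (i in seq_len(nrow(q))) {
    d <- sweep(r, 2L, q[i, ])
    d <- d - sweep(round(sweep(d, 2L, box, "/")), 2L, box, "*")
    out[i] <- sqrt(min(rowSums(d^2)))
  }
  out
}

#' Reference points within a cutoff of each query point
#'
#' For each query row, the integer indices of the reference rows at
#' distance `<= cutoff` (inclusive boundary — the counting convention of
#' the whole package). Open boundaries use the neighbor grid; a periodic
#' `box` switches to an exact minimum-image search.
#'
#' @inheritParams min_dist_within
#' @return A list of integer vectors, one per query row.
#' @export
neighbors_within <- function(query, ref, cutoff, box = NULL) {
  q <- as_coord_matrix(query)
  r <- as_coord_matrix(ref)
  if (nrow(q) == 0L) return(list())
  if (nrow(r) == 0L) {
    return(rep(list(integer(0)), nrow(q)))
  }
  c2 <- cutoff^2
  if (!is.null(box)) {
    box <- rep_len(as.numeric(box), 3L)
    return(lapply(seq_len(nrow(q)), function(i) {
      d <- sweep(r, 2L, q[i, ])
      d <- d - sweep(round(sweep(d, 2L, box, "/")), 2L, box, "*")
      which(rowSums(d^2) <= c2)
    }))
  }
  origin <- apply(rbind(q, r), 2L, min)
  rc <- floor(sweep(r, 2L, origin) / cutoff)
  qc <- floor(sweep(q, 2L, origin) / cutoff)
  bins <- split(seq_len(nrow(r)), cell_key(rc))
  offsets <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  lapply(seq_len(nrow(q)), function(i) {
    cells <- cell_key(sweep(offsets, 2L, -qc[i, ]))
    cand <- unlist(bins[cells], use.names = FALSE)
    if (is.null(cand) || length(cand) == 0L) {
      return(integer(0))
    }
    d2 <- rowSums(sweep(r[cand, , drop = FALSE], 2L, q[i, ])^2)
    cand[d2 <= c2]
  })
}

# random rotation matrix from the current RNG stream (uniform over SO(3),
# via a normalized random quaternion)
random_rotation <- function() {
  qv <- stats::rnorm(4L)
  qv <- qv / sqrt(sum(qv^2))
  w <- qv[1]; x <- qv[2]; y <- qv[3]; z <- qv[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), nrow = 3L, byrow = TRUE)
}
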