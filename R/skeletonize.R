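# Two-subiteration parallel thinning, branch-point detection with the
# cross kernel, and spur pruning.
#
# Neighbour numbering: x1..x8 are the 8 neighbours of p starting from the
# east neighbour and numbered counter-clockwise (east, north-east, north,
# north-west, west, south-west, south, south-east, with row index
# increasing downwards). Indices are cyclic, x9 == x1. Border pixels read
# their out-of-image neighbours as 0.

# Shift a padded logical matrix to expose neighbour (dy, dx) of each pixel.
shift_mask <- function(pad, ny, nx, dy, dx) {
  pad[(2L + dy):(ny + 1L + dy), (2L + dx):(nx + 1L + dx)]
}

# All eight neighbour fields of a binary matrix as logical matrices,
# in the x1..x8 order described above.
neighbor_fields <- function(mask) {
  b <- mask > 0
  ny <- nrow(b); nx <- ncol(b)
  pad <- matrix(FALSE, ny + 2L, nx + 2L)
  pad[2:(ny + 1L), 2:(nx + 1L)] <- b
  list(
    x1 = shift_mask(pad, ny, nx, 0L, 1L),   # E
    x2 = shift_mask(pad, ny, nx, -1L, 1L),  # NE
    x3 = shift_mask(pad, ny, nx, -1L, 0L),  # N
    x4 = shift_mask(pad, ny, nx, -1L, -1L), # NW
    x5 = shift_mask(pad, ny, nx, 0L, -1L),  # W
    x6 = shift_mask(pad, ny, nx, 1L, -1L),  # SW
    x7 = shift_mask(pad, ny, nx, 1L, 0L),   # S
    x8 = shift_mask(pad, ny, nx, 1L, 1L)    # SE
  )
}

#' Crossing number of a neighbourhood code
#'
#' `X_H(p) = sum(b_i, i = 1..4)` where `b_i = 1` iff `x_{2i-1} = 0` and
#' (`x_{2i} = 1` or `x_{2i+1} = 1`), indices cyclic. It counts the
#' distinct 0-to-1 transitions around p; a value of 1 means deleting p
#' cannot disconnect its neighbourhood.
#'
#' @param code Numeric/logical vector of length 8, the neighbours x1..x8.
#' @return Integer in 0..4.
#' @export
crossing_number <- function(code) {
  stopifnot(length(code) == 8L)
  x <- as.logical(code)
  x9 <- x[1L]
  b <- vapply(1:4, function(i) {
    !x[2L * i - 1L] && (x[2L * i] || if (i < 4L) x[2L * i + 1L] else x9)
  }, logical(1))
  sum(b)
}

#' Weighted neighbour counts of a neighbourhood code
#'
#' `n1 = sum over k of (x_{2k-1} | x_{2k})` and
#' `n2 = sum over k of (x_{2k} | x_{2k+1})`, `x9 == x1`. The minimum of
#' the two measures the local stroke width seen from p.
#'
#' @param code Numeric/logical vector of length 8, the neighbours x1..x8.
#' @return Integer vector `c(n1, n2)`.
#' @export
neighbor_counts <- function(code) {
  stopifnot(length(code) == 8L)
  x <- as.logical(code)
  n1 <- sum(vapply(1:4, function(k) x[2L * k - 1L] || x[2L * k], logical(1)))
  n2 <- sum(vapply(1:4, function(k) {
    x[2L * k] || if (k < 4L) x[2L * k + 1L] else x[1L]
  }, logical(1)))
  c(n1 = n1, n2 = n2)
}

# Deletion masks for one sub-iteration, evaluated in parallel on the
# current image state.
thin_deletable <- function(mask, subiter) {
  f <- neighbor_fields(mask)
  b1 <- !f$x1 & (f$x2 | f$x3)
  b2 <- !f$x3 & (f$x4 | f$x5)
  b3 <- !f$x5 & (f$x6 | f$x7)
  b4 <- !f$x7 & (f$x8 | f$x1)
  xh <- b1 + b2 + b3 + b4
  n1 <- (f$x1 | f$x2) + (f$x3 | f$x4) + (f$x5 | f$x6) + (f$x7 | f$x8)
  n2 <- (f$x2 | f$x3) + (f$x4 | f$x5) + (f$x6 | f$x7) + (f$x8 | f$x1)
  nmin <- pmin(n1, n2)
  cond_ab <- (mask > 0) & xh == 1L & nmin >= 2L & nmin <= 3L
  if (subiter == 1L) {
    cond_ab & !((f$x2 | f$x3 | !f$x8) & f$x1)
  } else {
    cond_ab & !((f$x6 | f$x7 | !f$x4) & f$x5)
  }
}

#' Thin a binary mask to a one-pixel skeleton
#'
#' Two-subiteration parallel thinning: within one iteration, the first
#' sub-iteration deletes every pixel satisfying conditions (a) crossing
#' number `X_H(p) = 1`, (b) `2 <= min(n1, n2) <= 3`, and (c)
#' `(x2 | x3 | !x8) & x1 == 0`; the second sub-iteration replaces (c) with
#' (d) `(x6 | x7 | !x4) & x5 == 0`. Deletions inside one sub-iteration are
#' simultaneous (all conditions read the image state at its start).
#' Iterations repeat until the image stops changing, so the result is a
#' fixed point of the operator.
#'
#' @param mask Logical/binary matrix.
#' @return Logical matrix, the skeleton.
#' @export
thin <- function(mask) {
  stopifnot(is.matrix(mask))
  cur <- mask > 0
  repeat {
    d1 <- thin_deletable(cur, 1L)
    cur1 <- cur & !d1
    d2 <- thin_deletable(cur1, 2L)
    nxt <- cur1 & !d2
    if (!any(d1) && !any(d2)) break
    cur <- nxt
  }
  cur
}

#' Branch points of a skeleton
#'
#' Convolves the skeleton with the 3x3 cross kernel (0 at the four
#' corners, 1 elsewhere) and returns skeleton pixels whose convolution
#' value is at least 4, i.e. skeleton pixels with three or more skeleton
#' 4-neighbours - the bifurcations.
#'
#' @param mask Logical/binary skeleton matrix.
#' @return Integer matrix with columns `y`, `x` in scan order.
#' @export
find_branch_points <- function(mask) {
  b <- mask > 0
  ny <- nrow(b); nx <- ncol(b)
  pad <- matrix(FALSE, ny + 2L, nx + 2L)
  pad[2:(ny + 1L), 2:(nx + 1L)] <- b
  conv <- b +
    shift_mask(pad, ny, nx, 0L, 1L) + shift_mask(pad, ny, nx, 0L, -1L) +
    shift_mask(pad, ny, nx, 1L, 0L) + shift_mask(pad, ny, nx, -1L, 0L)
  hit <- which(b & conv >= 4L)
  cbind(y = (hit - 1L) %% ny + 1L, x = (hit - 1L) %/% ny + 1L)
}

#' Skeleton bifurcations by crossing number
#'
#' A skeleton pixel is a bifurcation when its crossing number
#' `X_H(p) >= 3`, i.e. at least three distinct branches leave it. This is
#' a superset of [find_branch_points()]: one-pixel-wide thinned skeletons
#' are 8-connected, so a T-junction is often realized with its side
#' branch attached diagonally, which the 4-neighbour cross kernel cannot
#' see but the crossing number does.
#'
#' @param mask Logical/binary skeleton matrix.
#' @return Integer matrix with columns `y`, `x` in scan order.
#' @export
find_bifurcations <- function(mask) {
  b <- mask > 0
  f <- neighbor_fields(b)
  b1 <- !f$x1 & (f$x2 | f$x3)
  b2 <- !f$x3 & (f$x4 | f$x5)
  b3 <- !f$x5 & (f$x6 | f$x7)
  b4 <- !f$x7 & (f$x8 | f$x1)
  xh <- b1 + b2 + b3 + b4
  hit <- which(b & xh >= 3L)
  cbind(y = (hit - 1L) %% nrow(b) + 1L, x = (hit - 1L) %/% nrow(b) + 1L)
}

#' Remove spur pixels from a skeleton
#'
#' Iteratively deletes endpoint pixels (skeleton pixels with exactly one
#' 8-neighbour), all endpoints of a round simultaneously, for at most
#' `max_spur_length` rounds. The removed pixels are the putative locations
#' of dendritic spines. Closed loops have no endpoints and are unchanged;
#' isolated single pixels have zero neighbours and are kept.
#'
#' @param mask Logical/binary skeleton matrix.
#' @param max_spur_length Maximum pruning rounds, `>= 1`.
#' @return List with `pruned` (logical matrix) and `removed` (integer
#'   matrix of removed pixels, columns `y`, `x`).
#' @export
remove_spurs <- function(mask, max_spur_length = 4L) {
  stopifnot(is.matrix(mask), max_spur_length >= 1L)
  cur <- mask > 0
  removed <- matrix(integer(0), 0, 2, dimnames = list(NULL, c("y", "x")))
  for (i in seq_len(max_spur_length)) {
    ends <- cur & neighbor_count8(cur) == 1L
    if (!any(ends)) break
    hit <- which(ends)
    removed <- rbind(removed,
                     cbind(y = (hit - 1L) %% nrow(cur) + 1L,
                           x = (hit - 1L) %/% nrow(cur) + 1L))
    cur <- cur & !ends
  }
  list(pruned = cur, removed = removed)
}
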