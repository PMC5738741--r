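# Internal numerics shared across modules: separable convolution with
# reflective borders, sampled Gaussian-derivative kernels, connected-component
# labelling, and second-moment region statistics.

#' @importFrom stats mad median rnorm rpois runif setNames
#' @importFrom utils read.csv write.csv
NULL

# Symmetric (half-sample) reflective index vector for padding length n by r.
reflect_idx <- function(n, r) {
  if (r == 0L) return(seq_len(n))
  idx <- c(seq(r, 1L), seq_len(n), seq(n, n - r + 1L))
  pmin(pmax(idx, 1L), n)
}

# Correlate a matrix with a 1-D kernel along columns (x) or rows (y),
# reflective boundary. Kernel length must be odd.
conv1d <- function(m, k, along = c("x", "y")) {
  along <- match.arg(along)
  r <- (length(k) - 1L) %/% 2L
  if (along == "x") {
    p <- m[, reflect_idx(ncol(m), r), drop = FALSE]
    out <- matrix(0, nrow(m), ncol(m))
    for (j in seq_along(k)) {
      out <- out + k[j] * p[, j:(j + ncol(m) - 1L), drop = FALSE]
    }
  } else {
    p <- m[reflect_idx(nrow(m), r), , drop = FALSE]
    out <- matrix(0, nrow(m), ncol(m))
    for (j in seq_along(k)) {
      out <- out + k[j] * p[j:(j + nrow(m) - 1L), , drop = FALSE]
    }
  }
  out
}

# Sampled Gaussian kernel and its first/second derivatives, truncated at
# 4 standard deviations. Discrete moment conditions are enforced so that the
# kernels are exact on polynomials up to degree 2: order 0 sums to 1,
# order 1 has unit first moment, order 2 has zero sum and second moment 2.
gaussian_kernel <- function(sigma, order = 0L) {
  stopifnot(sigma > 0)
  r <- max(1L, ceiling(4 * sigma))
  x <- seq(-r, r)
  g <- exp(-x^2 / (2 * sigma^2))
  k <- switch(as.character(order),
    "0" = g,
    "1" = -x / sigma^2 * g,
    "2" = (x^2 / sigma^4 - 1 / sigma^2) * g,
    stop("order must be 0, 1 or 2")
  )
  if (order == 0L) {
    k / sum(k)
  } else if (order == 1L) {
    -k / sum(x * k) # correlation with result differentiates once
  } else {
    k <- k - sum(k) / length(k)
    k * 2 / sum(x^2 * k)
  }
}

# Label connected components of a binary matrix (8- or 4-connectivity).
# Returns an integer matrix, 0 = background, components numbered from 1 in
# scan order of their first pixel.
label_components <- function(mask, connectivity = 8L) {
  stopifnot(is.matrix(mask), connectivity %in% c(4L, 8L))
  fg <- which(mask > 0)
  lab <- matrix(0L, nrow(mask), ncol(mask))
  if (length(fg) == 0L) return(lab)
  ny <- nrow(mask)
  nx <- ncol(mask)
  id <- matrix(0L, ny, nx)
  id[fg] <- seq_along(fg)
  yy <- (fg - 1L) %% ny + 1L
  xx <- (fg - 1L) %/% ny + 1L
  shifts <- list(c(0L, 1L), c(1L, 0L))
  if (connectivity == 8L) shifts <- c(shifts, list(c(1L, 1L), c(1L, -1L)))
  edges <- integer(0)
  for (s in shifts) {
    y2 <- yy + s[1]
    x2 <- xx + s[2]
    ok <- y2 >= 1L & y2 <= ny & x2 >= 1L & x2 <= nx
    j <- id[cbind(y2[ok], x2[ok])]
    keep <- j > 0L
    edges <- c(edges, rbind(id[cbind(yy[ok], xx[ok])][keep], j[keep]))
  }
  g <- igraph::make_graph(edges = edges, n = length(fg), directed = FALSE)
  memb <- igraph::components(g)$membership
  # renumber in scan order of first occurrence
  first <- match(unique(memb), memb)
  rank <- order(fg[first])
  remap <- integer(max(memb))
  remap[unique(memb)[rank]] <- seq_along(rank)
  lab[fg] <- remap[memb]
  lab
}

# Second-moment shape statistics of a pixel set given as cbind(y, x).
# Axis lengths follow the usual image-moment convention (4 * sqrt of the
# covariance eigenvalues), so a filled disk of radius r has major axis ~ 2r.
region_moments <- function(px) {
  n <- nrow(px)
  cy <- mean(px[, 1])
  cx <- mean(px[, 2])
  if (n == 1L) {
    return(list(centroid = c(y = cy, x = cx), eccentricity = 0,
                major_axis = 0, minor_axis = 0, area = 1L))
  }
  dy <- px[, 1] - cy
  dx <- px[, 2] - cx
  cyy <- mean(dy^2); cxx <- mean(dx^2); cxy <- mean(dx * dy)
  tr <- cxx + cyy
  disc <- sqrt(max((cxx - cyy)^2 + 4 * cxy^2, 0))
  l1 <- (tr + disc) / 2
  l2 <- max((tr - disc) / 2, 0)
  ecc <- if (l1 <= 0) 0 else sqrt(max(1 - l2 / l1, 0))
  list(centroid = c(y = cy, x = cx), eccentricity = ecc,
       major_axis = 4 * sqrt(l1), minor_axis = 4 * sqrt(l2), area = n)
}

# Count of foreground 8-neighbours at every pixel (zero padding).
neighbor_count8 <- function(mask) {
  b <- mask > 0
  ny <- nrow(b); nx <- ncol(b)
  p <- matrix(FALSE, ny + 2L, nx + 2L)
  p[2:(ny + 1L), 2:(nx + 1L)] <- b
  cnt <- matrix(0L, ny, nx)
  for (dy in -1:1) for (dx in -1:1) {
    if (dy == 0 && dx == 0) next
    cnt <- cnt + p[(2 + dy):(ny + 1 + dy), (2 + dx):(nx + 1 + dx)]
  }
  cnt
}

# Affine rescale by a fixed range (stack-level normalization), clipped to
# [0, 1]; degenerate range maps to zeros.
scale_to_range <- function(img, rng) {
  lo <- rng[1]; hi <- rng[2]
  if (hi <= lo) return(matrix(0, nrow(img), ncol(img)))
  pmin(pmax((img - lo) / (hi - lo), 0), 1)
}

# Otsu threshold of a numeric vector (wrapper over EBImage's histogram
# implementation; values are scaled into [0, 1] first).
otsu_threshold <- function(v, levels = 256L) {
  v <- v[is.finite(v)]
  if (length(v) == 0L) return(NA_real_)
  lo <- min(v); hi <- max(v)
  if (hi <= lo) return(lo)
  img <- EBImage::Image((v - lo) / (hi - lo), dim = c(length(v), 1))
  th <- EBImage::otsu(img, range = c(0, 1), levels = levels)
  lo + th * (hi - lo)
}
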