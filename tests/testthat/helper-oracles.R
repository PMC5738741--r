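# Independent oracles used across the suite.

# Closed-form Hessian eigenvalues of Gaussian models probed with
# derivative-of-Gaussian kernels of scale s. Convolving a Gaussian of
# scale t with a Gaussian of scale s yields a Gaussian of scale
# sqrt(t^2 + s^2); the amplitude scales by t^2/(t^2+s^2) for the 2D
# surface and by t/sqrt(t^2+s^2) for the 1D cross-section. The measured
# Hessian at the structure centre is therefore the analytic model
# eigenvalue evaluated at those effective parameters.
eff_blob_center_lambda <- function(C, delta, s) {
  C_eff <- C * delta^2 / (delta^2 + s^2)
  delta_eff2 <- delta^2 + s^2
  -C_eff / delta_eff2 # both eigenvalues coincide at the centre
}

eff_ridge_center_lambda <- function(C, sigma, s) {
  C_eff <- C * sigma / sqrt(sigma^2 + s^2)
  sigma_eff2 <- sigma^2 + s^2
  -C_eff / sigma_eff2
}

# Sample the blob / ridge models on an n x n grid centred at (c0, c0).
sample_blob <- function(n, delta, C = 1) {
  c0 <- (n + 1) / 2
  yy <- matrix(seq_len(n), n, n)
  xx <- t(yy)
  blob_model(xx, yy, C = C, x0 = c0, y0 = c0, delta = delta)
}

sample_ridge <- function(n, sigma, theta = 0, C = 1) {
  c0 <- (n + 1) / 2
  yy <- matrix(seq_len(n) - c0, n, n)
  xx <- t(yy)
  ridge_model(xx, yy, C_den = C, sigma = sigma, theta = theta)
}

# Brute-force strict local maxima by explicit window scan.
brute_local_maxima <- function(p, window, floor) {
  r <- (window - 1L) %/% 2L
  out <- NULL
  for (y in seq_len(nrow(p))) for (x in seq_len(ncol(p))) {
    v <- p[y, x]
    if (v <= floor) next
    win <- p[max(1, y - r):min(nrow(p), y + r),
             max(1, x - r):min(ncol(p), x + r)]
    if (sum(win >= v) == 1L) out <- rbind(out, c(y = y, x = x))
  }
  if (is.null(out)) matrix(integer(0), 0, 2) else out
}

# Brute-force branch points: skeleton pixel whose cross-kernel sum
# (itself plus its 4-neighbours) reaches 4.
brute_branch_points <- function(mask) {
  b <- mask > 0
  out <- NULL
  for (y in seq_len(nrow(b))) for (x in seq_len(ncol(b))) {
    if (!b[y, x]) next
    s <- 1L
    if (y > 1 && b[y - 1, x]) s <- s + 1L
    if (y < nrow(b) && b[y + 1, x]) s <- s + 1L
    if (x > 1 && b[y, x - 1]) s <- s + 1L
    if (x < ncol(b) && b[y, x + 1]) s <- s + 1L
    if (s >= 4L) out <- rbind(out, c(y = y, x = x))
  }
  if (is.null(out)) matrix(integer(0), 0, 2) else out
}

# Random binary masks made of discs and thick bars (the shapes thinning
# must handle), reproducible from a seed.
random_mask <- function(seed, n = 48L) {
  set.seed(seed)
  m <- matrix(FALSE, n, n)
  yy <- matrix(seq_len(n), n, n)
  xx <- t(yy)
  for (i in seq_len(sample(2:4, 1))) {
    cy <- sample(8:(n - 8), 1); cx <- sample(8:(n - 8), 1)
    r <- sample(3:6, 1)
    m <- m | ((yy - cy)^2 + (xx - cx)^2 <= r^2)
  }
  for (i in seq_len(sample(1:3, 1))) {
    y0 <- sample(5:(n - 5), 1)
    w <- sample(2:4, 1)
    x0 <- sample(2:(n %/% 2), 1); x1 <- sample((n %/% 2):(n - 2), 1)
    if (runif(1) < 0.5) {
      m[max(1, y0 - w %/% 2):min(n, y0 + w %/% 2), x0:x1] <- TRUE
    } else {
      m[x0:x1, max(1, y0 - w %/% 2):min(n, y0 + w %/% 2)] <- TRUE
    }
  }
  m
}

# 8-connected foreground / 4-connected background component counts via
# breadth-first flood fill (independent of the package's labelling).
count_components <- function(mask, connectivity) {
  b <- mask > 0
  ny <- nrow(b); nx <- ncol(b)
  seen <- matrix(FALSE, ny, nx)
  if (connectivity == 8L) {
    nb <- cbind(c(-1, -1, -1, 0, 0, 1, 1, 1), c(-1, 0, 1, -1, 1, -1, 0, 1))
  } else {
    nb <- cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1))
  }
  ncomp <- 0L
  for (y in seq_len(ny)) for (x in seq_len(nx)) {
    if (!b[y, x] || seen[y, x]) next
    ncomp <- ncomp + 1L
    queue <- matrix(c(y, x), 1)
    seen[y, x] <- TRUE
    while (nrow(queue)) {
      p <- queue[1, , drop = FALSE]; queue <- queue[-1, , drop = FALSE]
      for (k in seq_len(nrow(nb))) {
        y2 <- p[1] + nb[k, 1]; x2 <- p[2] + nb[k, 2]
        if (y2 >= 1 && y2 <= ny && x2 >= 1 && x2 <= nx &&
            b[y2, x2] && !seen[y2, x2]) {
          seen[y2, x2] <- TRUE
          queue <- rbind(queue, c(y2, x2))
        }
      }
    }
  }
  ncomp
}

# Background components are counted on a zero-padded complement so the
# outer background is a single component.
count_holes <- function(mask) {
  b <- mask > 0
  pad <- matrix(FALSE, nrow(b) + 2L, ncol(b) + 2L)
  pad[2:(nrow(b) + 1L), 2:(ncol(b) + 1L)] <- b
  count_components(!pad, 4L)
}

# Canonical point-set form for comparing (y, x) matrices regardless of
# row order and dimnames.
sort_points <- function(m) {
  m <- unname(as.matrix(m))
  if (nrow(m) == 0L) return(m)
  m[order(m[, 1], m[, 2]), , drop = FALSE]
}

# A single-layer axon scene: a thin shaft along a row with Gaussian
# boutons riding on it, on a dark background.
shaft_with_blobs <- function(n = 120, row = 60, shaft = 40,
                             peaks = numeric(0), cols = integer(0),
                             radius = 4, profile = c("gaussian", "flat")) {
  profile <- match.arg(profile)
  yy <- matrix(seq_len(n), n, n); xx <- t(yy)
  img <- if (profile == "gaussian") {
    shaft * exp(-(yy - row)^2 / (2 * (1.3 / sqrt(3))^2))
  } else {
    shaft * (abs(yy - row) <= 1) # uniform 3-px band
  }
  for (i in seq_along(cols)) {
    img <- img + blob_model(xx, yy, C = peaks[i], x0 = cols[i], y0 = row,
                            delta = scale_from_radius(radius))
  }
  img
}
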