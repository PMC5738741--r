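test_that("structure radii derive from physical sizes as printed", {
  expect_identical(radius_from_physical(1.0, 137), 4L)
  expect_identical(radius_from_physical(0.9, 137), 3L)
  expect_identical(radius_from_physical(2 * 137 / 1000, 137), 1L)
  expect_error(radius_from_physical(0, 137), "positive")
  expect_error(radius_from_physical(1, -1), "positive")
})

test_that("model scale is radius over sqrt(3)", {
  expect_equal(scale_from_radius(4), 4 / sqrt(3), tolerance = 1e-12)
  expect_equal(scale_from_radius(3), sqrt(3), tolerance = 1e-12)
  expect_equal(scale_from_radius(sqrt(3)), 1, tolerance = 1e-12)
  expect_error(scale_from_radius(0), "positive")
})

test_that("blob model evaluates the Gaussian surface", {
  expect_equal(blob_model(3, 5, C = 2, x0 = 3, y0 = 5, delta = 1.7), 2)
  d <- sqrt(2) * 1.7
  expect_equal(blob_model(3 + d, 5, C = 2, x0 = 3, y0 = 5, delta = 1.7),
               2 * exp(-1))
  expect_lt(blob_model(100, 100, C = 2, x0 = 3, y0 = 5, delta = 1.7), 1e-12)
})

test_that("analytic blob profile reproduces its three limit cases", {
  for (dl in c(1.5, 4 / sqrt(3), 3.5)) {
    expect_equal(blob_eigenvalue_profile(0, dl), 1 / dl^3,
                 tolerance = 1e-9)
    expect_equal(blob_eigenvalue_profile(2 * dl^2, dl),
                 -sqrt(3) / (dl^3 * exp(1)), tolerance = 1e-9)
    expect_lt(abs(blob_eigenvalue_profile(1e8 * dl^2, dl)), 1e-9)
  }
})

test_that("the blob profile's branch switch is a magnitude crossing", {
  # at m = 2 delta^2 the two Hessian eigenvalues have equal magnitude and
  # opposite sign, so the min-|lambda| profile flips sign there with the
  # magnitude the closed form prints
  dl <- 2.1
  m0 <- 2 * dl^2
  left <- blob_eigenvalue_profile(m0 - 1e-9, dl)
  right <- blob_eigenvalue_profile(m0 + 1e-9, dl)
  expect_equal(left, -sqrt(3) / (dl^3 * exp(1)), tolerance = 1e-6)
  expect_equal(right, -left, tolerance = 1e-6)
})

test_that("discrete Hessian eigenvalues match the closed forms at centres", {
  # the probe kernel blurs the model, so the closed form is evaluated at
  # the blurred model's effective amplitude and scale (helper-oracles.R)
  for (dl in c(1.5, 2.31, 3.5)) {
    n <- 2 * ceiling(6 * dl) + 41
    c0 <- (n + 1) %/% 2
    h <- hessian_eigenvalues(sample_blob(n, dl), dl)
    pred <- eff_blob_center_lambda(1, dl, dl)
    expect_lt(abs(h$low[c0, c0] - pred) / abs(pred), 0.05)
    expect_lt(abs(h$high[c0, c0] - pred) / abs(pred), 0.05)
  }
  for (sg in c(1.5, 2.31, 3.5)) for (th in c(0, pi / 6, pi / 4)) {
    n <- 101
    c0 <- 51
    h <- hessian_eigenvalues(sample_ridge(n, sg, th), sg)
    pred <- eff_ridge_center_lambda(1, sg, sg)
    expect_lt(abs(h$high[c0, c0] - pred) / abs(pred), 0.05)
  }
})

test_that("hessian_eigenvalues handles degenerate inputs", {
  h <- hessian_eigenvalues(matrix(5, 31, 31), 2)
  expect_lt(max(abs(h$low)), 1e-10)
  expect_lt(max(abs(h$high)), 1e-10)
  expect_error(hessian_eigenvalues(matrix(0, 4, 4), 2), "smaller")
})

test_that("blob enhancement peaks at blob centres", {
  dl <- 4 / sqrt(3)
  img <- sample_blob(61, dl)
  e <- enhance_blobs(img, dl)
  am <- which(e$pixels == max(e$pixels), arr.ind = TRUE)
  expect_equal(unname(am[1, ]), c(31, 31))
  expect_gt(e$pixels[31, 31], 0)
  expect_identical(e$mode, "blob")

  # two well-separated blobs give two local maxima at the two centres
  n <- 81
  yy <- matrix(seq_len(n), n, n); xx <- t(yy)
  two <- blob_model(xx, yy, x0 = 21, y0 = 21, delta = dl) +
    blob_model(xx, yy, x0 = 61, y0 = 61, delta = dl)
  e2 <- enhance_blobs(two, dl)
  mx <- find_local_maxima(e2, window = 9, floor = max(e2$pixels) / 2)
  expect_equal(nrow(mx), 2L)
  expect_true(all(apply(mx, 1, function(p) {
    min(sqrt((p[1] - c(21, 61))^2 + (p[2] - c(21, 61))^2)) <= 1
  })))

  flat <- enhance_blobs(matrix(3, 41, 41), dl)
  expect_lt(max(abs(flat$pixels)), 1e-10)
})

test_that("line enhancement responds with the cross-section amplitude", {
  sg <- sqrt(3)
  e <- enhance_lines(sample_ridge(81, sg, 0), sg)
  expect_true(all(e$pixels >= 0))
  expect_lt(abs(e$pixels[41, 41] - 1), 0.05)
  expect_identical(e$mode, "line")

  # orientation invariance on the centreline
  e45 <- enhance_lines(sample_ridge(81, sg, pi / 4), sg)
  expect_lt(abs(e45$pixels[41, 41] - e$pixels[41, 41]), 0.05)

  expect_true(all(enhance_lines(matrix(2, 41, 41), sg)$pixels == 0))
})

test_that("the Gaussian profile's third derivative flips sign at sqrt(3)*delta", {
  for (dl in c(1.5, 4 / sqrt(3), 3.1)) {
    h <- 0.01
    x <- seq(0, 5 * dl, by = h)
    r <- exp(-x^2 / (2 * dl^2))
    d3 <- diff(r, differences = 3) / h^3
    xm <- x[seq_along(d3)] + 1.5 * h # centred third difference
    inner <- xm > 0.5 * dl # skip the root at the centre
    flip <- which(inner[-1] & sign(d3[-1]) != sign(d3[-length(d3)]))[1] + 1L
    expect_lt(abs(xm[flip] - sqrt(3) * dl), h)
  }
})

test_that("enhancers are equivariant to whole-pixel translation", {
  set.seed(41)
  base <- matrix(0, 60, 60)
  yy <- matrix(seq_len(60), 60, 60); xx <- t(yy)
  base <- blob_model(xx, yy, x0 = 25, y0 = 28, delta = 2.3)
  shifted <- blob_model(xx, yy, x0 = 25 + 7, y0 = 28 + 5, delta = 2.3)
  eb <- enhance_blobs(base, 2.3)$pixels
  es <- enhance_blobs(shifted, 2.3)$pixels
  # compare away from borders where reflection padding differs
  expect_equal(es[16:50, 16:50], eb[(16:50) - 5, (16:50) - 7],
               tolerance = 1e-10)
  el <- enhance_lines(base, 2.3)$pixels
  el2 <- enhance_lines(shifted, 2.3)$pixels
  expect_equal(el2[16:50, 16:50], el[(16:50) - 5, (16:50) - 7],
               tolerance = 1e-10)
})

test_that("ridge eigenvalue profile matches the ridge Hessian centre value", {
  expect_equal(ridge_eigenvalue_profile(0, 2, C_den = 3), -3 / 4)
  # the eigenvalue vanishes at the model edge u = sigma
  expect_equal(ridge_eigenvalue_profile(2, 2), 0, tolerance = 1e-12)
})
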