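test_that("strict local maxima exclude plateaus and obey the floor", {
  dl <- 4 / sqrt(3)
  e <- enhance_blobs(sample_blob(41, dl), dl)
  mx <- find_local_maxima(e, window = 9)
  expect_equal(nrow(mx), 1L)
  expect_equal(unname(mx[1, ]), c(21, 21))

  expect_equal(nrow(find_local_maxima(matrix(5, 30, 30), window = 5)), 0L)
})

test_that("local maxima agree with the brute-force window scan", {
  set.seed(51)
  for (i in 1:5) {
    p <- matrix(rnorm(900), 30, 30)
    floor <- 3 * mad(p)
    got <- find_local_maxima(p, window = 5, floor = floor)
    want <- brute_local_maxima(p, 5L, floor)
    expect_equal(got[order(got[, 1], got[, 2]), , drop = FALSE],
                 want[order(want[, 1], want[, 2]), , drop = FALSE])
  }
})

test_that("segmentation thresholds the enhanced response", {
  dl <- 4 / sqrt(3)
  e <- enhance_lines(sample_ridge(41, dl), dl)
  expect_identical(segment_enhanced(e, 0), e$pixels > 0)
  expect_false(any(segment_enhanced(e, max(e$pixels))))

  eb <- enhance_blobs(sample_blob(41, dl), dl)
  mask <- segment_enhanced(eb, eb$pixels[21, 21] / 2)
  lab <- synapsedetect:::label_components(mask, 8L)
  expect_equal(max(lab), 1L)
  expect_equal(lab[21, 21], 1L)
  mom <- synapsedetect:::region_moments(which(mask, arr.ind = TRUE))
  expect_lt(mom$eccentricity, 0.1) # disk-like
})

test_that("region filtering enforces maxima and disk-likeness", {
  disk <- matrix(FALSE, 20, 20)
  yy <- matrix(seq_len(20), 20, 20); xx <- t(yy)
  disk[(yy - 10)^2 + (xx - 10)^2 <= 9] <- TRUE
  kept <- filter_regions(disk, cbind(y = 10L, x = 10L))
  expect_length(kept, 1L)
  expect_true(is.na(kept[[1]]$reject_reason))

  expect_length(filter_regions(disk, matrix(integer(0), 0, 2)), 0L)

  bar <- matrix(FALSE, 40, 10); bar[4:33, 4:5] <- TRUE # 30 x 2 bar
  mom <- synapsedetect:::region_moments(which(bar, arr.ind = TRUE))
  expect_gt(mom$eccentricity, 0.99)
  res <- filter_regions(bar, cbind(y = 18L, x = 4L), e_max = 0.95)
  expect_identical(res[[1]]$reject_reason, "eccentricity")
})

test_that("shaft intensity is the annulus median over shaft pixels", {
  img <- shaft_with_blobs(80, row = 40, shaft = 50, profile = "flat")
  region <- which((matrix(seq_len(80), 80, 80) - 40)^2 +
                  (t(matrix(seq_len(80), 80, 80)) - 40)^2 <= 9,
                  arr.ind = TRUE)
  est <- estimate_shaft_intensity(img, region)
  expect_gt(est, 40); expect_lte(est, 50)

  # region surrounded by exact zeros: no above-background sample
  blank <- matrix(0, 40, 40); blank[20, 20] <- 100
  expect_true(is.na(estimate_shaft_intensity(blank, cbind(20L, 20L))))

  img2 <- shaft_with_blobs(100, row = 50, shaft = 40, peaks = 200,
                           cols = 50, profile = "flat")
  region2 <- which((matrix(seq_len(100), 100, 100) - 50)^2 +
                   (t(matrix(seq_len(100), 100, 100)) - 50)^2 <= 16,
                   arr.ind = TRUE)
  est2 <- estimate_shaft_intensity(img2, region2)
  expect_gte(est2, 35); expect_lte(est2, 45)
})

test_that("detect_boutons recovers planted boutons and explains rejections", {
  cols <- c(15, 38, 61, 84, 107)
  img <- shaft_with_blobs(120, row = 60, shaft = 30,
                          peaks = rep(150, 5), cols = cols)
  det <- detect_boutons(img, radius = 4)
  acc <- det[det$accepted, ]
  expect_equal(nrow(acc), 5L)
  ord <- order(acc$x)
  expect_true(all(abs(acc$x[ord] - cols) <= 1))
  expect_true(all(abs(acc$y - 60) <= 1))

  # a swelling only twice as bright as its shaft fails the 3x criterion
  dim_img <- shaft_with_blobs(120, row = 60, shaft = 40, peaks = 40,
                              cols = 60, profile = "flat") # peak ~ 2x shaft
  det2 <- detect_boutons(dim_img, radius = 4)
  expect_equal(sum(det2$accepted), 0L)
  if (nrow(det2)) expect_true("brightness_ratio" %in% det2$reason)

  expect_equal(nrow(detect_boutons(matrix(0, 60, 60), radius = 4)), 0L)
})

test_that("every accepted bouton centre lies inside its region", {
  img <- shaft_with_blobs(120, row = 60, shaft = 30,
                          peaks = c(150, 180), cols = c(40, 80))
  det <- detect_boutons(img, radius = 4)
  regions <- attr(det, "regions")
  for (i in which(det$accepted)) {
    px <- regions[[i]]$pixels
    expect_true(any(px[, "y"] == det$y[i] & px[, "x"] == det$x[i]))
  }
})

test_that("raising the segmentation threshold never adds boutons", {
  img <- shaft_with_blobs(120, row = 60, shaft = 30,
                          peaks = c(150, 120, 90), cols = c(30, 60, 90))
  norm <- normalize_image(img)
  e <- enhance_blobs(norm, scale_from_radius(4))
  ths <- quantile(e$pixels[e$pixels > 0], c(0.1, 0.3, 0.5, 0.7, 0.9, 0.99))
  counts <- vapply(ths, function(th) {
    sum(detect_boutons(img, radius = 4, threshold = th)$accepted)
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
  expect_gt(counts[1], 0)
})

test_that("enhancement separates boutons a single raw threshold cannot", {
  # weak bouton on a bright shaft: any raw threshold either keeps the
  # shaft or loses the bouton, while the enhanced image isolates it
  img <- shaft_with_blobs(100, row = 50, shaft = 60, peaks = 80, cols = 50)
  peak_val <- max(img)
  shaft_val <- 60
  # raw thresholding: a threshold below the shaft keeps the whole shaft
  low <- img > shaft_val * 0.8
  expect_gt(sum(low), 100) # the full shaft centreline survives
  # a threshold above the shaft rim still clips most of the bouton
  high <- img > shaft_val * 1.2
  expect_lt(sum(high), 60)
  # enhanced pipeline recovers the bouton cleanly at its default threshold
  det <- detect_boutons(img, radius = 4, brightness_factor = 1)
  expect_equal(sum(det$accepted), 1L)
  expect_true(abs(det$y[det$accepted] - 50) <= 1 &&
              abs(det$x[det$accepted] - 50) <= 1)
})
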