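# A single-layer dendrite scene: one horizontal tube with perpendicular
# spine protrusions, rendered with the package's own tube model.
dendrite_layer <- function(n = 120, row = 60, spine_cols = integer(0),
                           spine_len = 6, up = TRUE, amp_dend = 120,
                           amp_spine = 110, bg = 10) {
  spec <- synthetic_spec(
    ny = n, nx = n, n_layers = 1L,
    dendrites = list(list(path = cbind(c(row, row), c(4, n - 3)),
                          amplitude = amp_dend, halfwidth = 3)),
    spines = if (length(spine_cols)) {
      data.frame(id = seq_along(spine_cols), attach_y = row,
                 attach_x = spine_cols,
                 angle = ifelse(rep(up, length(spine_cols)), -pi / 2, pi / 2),
                 length = spine_len, halfwidth = 1.6, amplitude = amp_spine,
                 z_start = 1L, z_end = 1L)
    } else NULL,
    background = bg, noise = list(type = "none"), seed = 1L
  )
  r <- render_stack(spec)
  list(layer = get_layer(subtract_channels(r$ch1, r$ch2), 1),
       truth = r$truth$spines_2d)
}

test_that("locate_spines finds the spur tip hanging off a junction", {
  # T-skeleton: bar plus a 3-px protrusion from its middle
  sk <- matrix(FALSE, 12, 16)
  sk[6, 3:14] <- TRUE
  sk[7:9, 8] <- TRUE
  pr <- remove_spurs(sk, 3)
  out <- locate_spines(sk, pr$pruned, pr$removed, search_radius = 5)
  # hand trace: the tip (9,8) and (8,8) are removed; the stub (7,8) keeps
  # its three bar neighbours and anchors the spur
  hit <- out[out$branch_y == 7 & out$branch_x == 8, ]
  expect_equal(nrow(hit), 1L)
  expect_equal(c(hit$y, hit$x), c(9, 8)) # the protrusion tip

  # straight skeleton: end erosion yields no candidates
  line <- matrix(FALSE, 8, 20); line[4, 3:18] <- TRUE
  prl <- remove_spurs(line, 3)
  expect_equal(nrow(locate_spines(line, prl$pruned, prl$removed)), 0L)

  # X-crossing with long arms: nothing is removed near the junction
  xx <- matrix(FALSE, 21, 21)
  for (i in 1:21) { xx[i, i] <- TRUE; xx[i, 22 - i] <- TRUE }
  prx <- remove_spurs(xx, 2)
  out_x <- locate_spines(xx, prx$pruned, prx$removed)
  expect_equal(nrow(out_x), 0L)
})

test_that("axon screening judges area/perimeter and intensity", {
  # 11 x 1 line: area 11, every pixel is a boundary pixel, ratio 1
  mask <- matrix(FALSE, 15, 15)
  mask[8, 3:13] <- TRUE
  img <- matrix(1, 15, 15)
  cands <- data.frame(layer = 1L, y = 8L, x = 8L, branch_y = 8L,
                      branch_x = 8L)
  out <- filter_axon_points(cands, mask, img, box = 15)
  expect_equal(out$ratio, 1)
  expect_false(out$accepted)
  expect_identical(out$reason, "axon_like")

  # filled 7x7 square: area 49, boundary 24, ratio ~ 2.04
  sq <- matrix(FALSE, 15, 15)
  sq[5:11, 5:11] <- TRUE
  out2 <- filter_axon_points(cands, sq, img, box = 15)
  expect_equal(out2$ratio, 49 / 24, tolerance = 1e-12)
  expect_true(out2$accepted)

  # empty window
  out3 <- filter_axon_points(cands, matrix(FALSE, 15, 15), img, box = 15)
  expect_false(out3$accepted)
  expect_identical(out3$reason, "empty_structure")
})

test_that("detect_spines recovers planted protrusions without noise", {
  sc <- dendrite_layer(140, row = 70, spine_cols = c(30, 60, 90, 120))
  det <- detect_spines(sc$layer)
  acc <- det[det$accepted, ]
  expect_equal(nrow(acc), 4L)
  for (i in seq_len(nrow(sc$truth))) {
    d <- sqrt((acc$y - sc$truth$y[i])^2 + (acc$x - sc$truth$x[i])^2)
    expect_lte(min(d), 2)
  }
})

test_that("an axon-only image yields no accepted spines", {
  # thin, dim line with a short twig: the twig is located as a candidate
  # but screened out as axon-like
  spec <- synthetic_spec(
    ny = 100, nx = 100, n_layers = 1L,
    yfp_axons = list(
      list(path = cbind(c(10, 90), c(50, 50)), amplitude = 45,
           halfwidth = 1.1),
      list(path = cbind(c(40, 40), c(50, 55)), amplitude = 45,
           halfwidth = 1.1)),
    background = 10, noise = list(type = "none"), seed = 2L
  )
  r <- render_stack(spec)
  layer <- get_layer(subtract_channels(r$ch1, r$ch2), 1)
  det <- detect_spines(layer)
  expect_equal(sum(det$accepted), 0L)
  expect_true(nrow(det) == 0L || all(det$reason == "axon_like"))

  expect_equal(nrow(detect_spines(matrix(0, 60, 60))), 0L)
})

test_that("accepted spines are a screened subset near their anchors", {
  sc <- dendrite_layer(140, row = 70, spine_cols = c(40, 100), up = FALSE)
  det <- detect_spines(sc$layer)
  st <- attr(det, "stages")
  cands <- locate_spines(st$skeleton, st$pruned, st$removed)
  expect_lte(sum(det$accepted), nrow(cands))
  acc <- det[det$accepted, ]
  expect_true(all(pmax(abs(acc$y - acc$branch_y),
                       abs(acc$x - acc$branch_x)) <= 8))
})

test_that("raising screening thresholds never adds spines", {
  sc <- dendrite_layer(140, row = 70, spine_cols = c(30, 60, 90, 120))
  for (par in c("ratio_min", "intensity_min")) {
    vals <- if (par == "ratio_min") c(0.5, 1, 1.5, 2, 3) else
      c(0.05, 0.2, 0.5, 0.8, 0.95)
    counts <- vapply(vals, function(v) {
      args <- list(layer = sc$layer)
      args[[par]] <- v
      sum(do.call(detect_spines, args)$accepted)
    }, numeric(1))
    expect_true(all(diff(counts) <= 0), label = par)
    expect_gt(counts[1], 0)
  }
})
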