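# Independently coded reference of the two-subiteration thinning scheme.
#
# This implementation shares no code with synapsedetect::thin(): deletion
# decisions are precomputed as 256-entry lookup tables by enumerating
# every neighbourhood code and evaluating the published conditions with
# scalar arithmetic, and the image update walks pixels with explicit
# loops. Neighbour order matches the package convention: x1 = east, then
# counter-clockwise.

ref_thin_luts <- local({
  del1 <- logical(256)
  del2 <- logical(256)
  for (code in 0:255) {
    x <- as.integer(intToBits(code))[1:8]
    xs <- function(i) x[((i - 1L) %% 8L) + 1L] # cyclic accessor
    xh <- 0L
    for (i in 1:4) {
      if (xs(2 * i - 1) == 0L && (xs(2 * i) == 1L || xs(2 * i + 1) == 1L)) {
        xh <- xh + 1L
      }
    }
    n1 <- 0L; n2 <- 0L
    for (k in 1:4) {
      if (xs(2 * k - 1) == 1L || xs(2 * k) == 1L) n1 <- n1 + 1L
      if (xs(2 * k) == 1L || xs(2 * k + 1) == 1L) n2 <- n2 + 1L
    }
    ab <- xh == 1L && min(n1, n2) >= 2L && min(n1, n2) <= 3L
    c_ok <- ((xs(2) | xs(3) | !xs(8)) & xs(1)) == 0L
    d_ok <- ((xs(6) | xs(7) | !xs(4)) & xs(5)) == 0L
    del1[code + 1L] <- ab && c_ok
    del2[code + 1L] <- ab && d_ok
  }
  list(del1 = del1, del2 = del2)
})

ref_neighbor_code <- function(pad, y, x) {
  # pad is zero-padded by 1; (y, x) indexes the padded matrix
  n <- c(pad[y, x + 1], pad[y - 1, x + 1], pad[y - 1, x], pad[y - 1, x - 1],
         pad[y, x - 1], pad[y + 1, x - 1], pad[y + 1, x], pad[y + 1, x + 1])
  sum(n * 2L^(0:7)) + 1L
}

ref_thin <- function(mask) {
  cur <- (mask > 0) * 1L
  ny <- nrow(cur); nx <- ncol(cur)
  repeat {
    changed <- FALSE
    for (lut in list(ref_thin_luts$del1, ref_thin_luts$del2)) {
      pad <- matrix(0L, ny + 2L, nx + 2L)
      pad[2:(ny + 1L), 2:(nx + 1L)] <- cur
      nxt <- cur
      for (y in seq_len(ny)) for (x in seq_len(nx)) {
        if (cur[y, x] == 1L && lut[ref_neighbor_code(pad, y + 1L, x + 1L)]) {
          nxt[y, x] <- 0L
          changed <- TRUE
        }
      }
      cur <- nxt
    }
    if (!changed) break
  }
  cur > 0
}
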