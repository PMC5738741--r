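# Dendritic spine detection: spines appear as short terminal branches of
# the dendrite skeleton. Removing spur pixels marks putative spine
# locations; a candidate is confirmed when its removed spur hangs off a
# bifurcation of the skeleton, and screened against axon-like structures
# by area/perimeter ratio and mean intensity of the local mask structure.

#' Locate spine candidates from skeleton geometry
#'
#' A component of removed-spur pixels marks a spine when it hangs off the
#' side of a surviving skeleton line: some pruned-skeleton pixel adjacent
#' to the component (its attachment anchor) still has two or more
#' skeleton neighbours, i.e. the line continues through the bifurcation
#' the spur left from. Components produced by eroding the free end of a
#' line attach to an endpoint (one neighbour) and yield no candidate.
#' Each qualifying component within the `(2*search_radius+1)^2` window of
#' its anchor yields one candidate at the spur's distal end, the removed
#' pixel farthest from the anchor. The anchor rule, rather than a lookup
#' of explicit branch-point pixels, is used because parallel thinning
#' often realizes a junction as a diagonal jog spread over two pixels
#' that neither the cross kernel nor the crossing number flags.
#'
#' @param skeleton Logical/binary skeleton matrix (before pruning).
#' @param pruned Logical matrix, the pruned skeleton from [remove_spurs()].
#' @param removed Integer matrix of removed pixels (columns `y`, `x`).
#' @param search_radius Chebyshev window radius in pixels (default 8,
#'   one more than the spur-pruning budget so a fully pruned spur always
#'   fits its window).
#' @param layer_index z index recorded in the output.
#' @return `data.frame` with columns `layer`, `y`, `x` (candidate), and
#'   `branch_y`, `branch_x` (the attachment anchor on the skeleton).
#' @export
locate_spines <- function(skeleton, pruned, removed, search_radius = 8L,
                          layer_index = 1L) {
  stopifnot(is.matrix(skeleton), is.matrix(pruned))
  empty <- data.frame(layer = integer(0), y = integer(0), x = integer(0),
                      branch_y = integer(0), branch_x = integer(0))
  if (nrow(removed) == 0L) return(empty)
  ny <- nrow(skeleton); nx <- ncol(skeleton)
  rmask <- matrix(FALSE, ny, nx)
  rmask[removed] <- TRUE
  rlab <- label_components(rmask, 8L)
  deg <- neighbor_count8(pruned) # pruned-skeleton neighbour counts
  out <- empty
  for (cid in seq_len(max(rlab))) {
    comp <- removed[rlab[removed] == cid, , drop = FALSE]
    # anchors: pruned pixels 8-adjacent to the component that continue a
    # line (>= 2 pruned neighbours)
    anchors <- NULL
    for (k in seq_len(nrow(comp))) {
      yy <- max(1L, comp[k, 1] - 1L):min(ny, comp[k, 1] + 1L)
      xx <- max(1L, comp[k, 2] - 1L):min(nx, comp[k, 2] + 1L)
      loc <- which(pruned[yy, xx, drop = FALSE] & deg[yy, xx, drop = FALSE] >= 2L,
                   arr.ind = TRUE)
      if (nrow(loc)) {
        anchors <- rbind(anchors, cbind(yy[loc[, 1]], xx[loc[, 2]]))
      }
    }
    if (is.null(anchors)) next
    anchors <- unique(anchors)
    # anchor: the adjacent line pixel closest to the component centroid
    cy <- mean(comp[, 1]); cx <- mean(comp[, 2])
    a <- anchors[which.min((anchors[, 1] - cy)^2 + (anchors[, 2] - cx)^2), ]
    cheb <- pmax(abs(comp[, 1] - a[1]), abs(comp[, 2] - a[2]))
    in_win <- cheb <= search_radius
    if (!any(in_win)) next
    d2 <- (comp[, 1] - a[1])^2 + (comp[, 2] - a[2])^2
    d2[!in_win] <- -Inf
    j <- which.max(d2)
    out <- rbind(out, data.frame(layer = layer_index, y = comp[j, 1],
                                 x = comp[j, 2], branch_y = a[1],
                                 branch_x = a[2]))
  }
  unique(out)
}

#' Screen spine candidates against axon-like structures
#'
#' The YFP channel contains axons as well as dendrites, and skeleton spurs
#' on axons masquerade as spines. For each candidate, the 8-connected
#' component of the dendrite mask supporting it is cropped to a `box x box`
#' window and judged by two criteria: the ratio of its area to its
#' perimeter (perimeter = count of foreground pixels with at least one
#' background 4-neighbour inside the window) and the mean original
#' intensity over its foreground. Thin, dim structures - axons - fail;
#' wide, bright dendrite shafts pass. A candidate is accepted iff
#' `ratio >= ratio_min` and `mean intensity >= intensity_min`.
#'
#' @param cands `data.frame` from [locate_spines()].
#' @param dendrite_mask Logical/binary segmentation mask of the layer.
#' @param original Numeric matrix, the (normalized) intensity image the
#'   mean-intensity criterion is applied to.
#' @param box Odd window width in pixels (default 15).
#' @param ratio_min Minimum area/perimeter ratio (default 1.2; a
#'   one-pixel-wide line scores exactly 1, a filled 7x7 square ~ 2).
#' @param intensity_min Minimum mean intensity over the structure
#'   (default 0.2 on normalized intensities).
#' @return `cands` with added columns `ratio`, `mean_intensity`,
#'   `accepted`, `reason` (`axon_like` or `empty_structure` when rejected).
#' @export
filter_axon_points <- function(cands, dendrite_mask, original, box = 15L,
                               ratio_min = 1.2, intensity_min = 0.2) {
  stopifnot(box %% 2L == 1L)
  n <- nrow(cands)
  cands$ratio <- numeric(n)
  cands$mean_intensity <- numeric(n)
  cands$accepted <- logical(n)
  cands$reason <- rep(NA_character_, n)
  if (n == 0L) return(cands)
  lab <- label_components(dendrite_mask, 8L)
  r <- (box - 1L) %/% 2L
  ny <- nrow(dendrite_mask); nx <- ncol(dendrite_mask)
  for (i in seq_len(n)) {
    cy <- cands$y[i]; cx <- cands$x[i]
    # component supporting the candidate: at the candidate pixel itself or
    # the nearest foreground pixel within 3 px
    cid <- lab[cy, cx]
    if (cid == 0L) {
      win <- lab[max(1L, cy - 3L):min(ny, cy + 3L),
                 max(1L, cx - 3L):min(nx, cx + 3L), drop = FALSE]
      ids <- win[win > 0L]
      cid <- if (length(ids)) ids[1L] else 0L
    }
    y0 <- max(1L, cy - r); y1 <- min(ny, cy + r)
    x0 <- max(1L, cx - r); x1 <- min(nx, cx + r)
    sub <- (lab[y0:y1, x0:x1, drop = FALSE] == cid) & cid > 0L
    area <- sum(sub)
    if (area == 0L) {
      cands$accepted[i] <- FALSE
      cands$reason[i] <- "empty_structure"
      next
    }
    # boundary pixels: foreground with a background 4-neighbour inside the
    # window; neighbours beyond the window are ignored, so a shaft crossing
    # the window is not charged for its cut ends
    pad <- matrix(TRUE, nrow(sub) + 2L, ncol(sub) + 2L)
    pad[2:(nrow(sub) + 1L), 2:(ncol(sub) + 1L)] <- sub
    nb4 <- shift_mask(pad, nrow(sub), ncol(sub), 0L, 1L) &
      shift_mask(pad, nrow(sub), ncol(sub), 0L, -1L) &
      shift_mask(pad, nrow(sub), ncol(sub), 1L, 0L) &
      shift_mask(pad, nrow(sub), ncol(sub), -1L, 0L)
    perim <- sum(sub & !nb4)
    ratio <- if (perim == 0L) Inf else area / perim
    mi <- mean(original[y0:y1, x0:x1, drop = FALSE][sub])
    cands$ratio[i] <- ratio
    cands$mean_intensity[i] <- mi
    if (ratio >= ratio_min && mi >= intensity_min) {
      cands$accepted[i] <- TRUE
    } else {
      cands$accepted[i] <- FALSE
      cands$reason[i] <- "axon_like"
    }
  }
  cands
}

#' Detect dendritic spines in one layer
#'
#' Composition: normalize, ridge-enhance at the scale matched to the
#' dendrite radius, Otsu segmentation of the enhanced image, thinning to a
#' skeleton, spur removal, candidate location at bifurcations, and axon
#' screening. Per-stage intermediates are attached for overlay writers.
#'
#' @param layer Numeric matrix, the original (un-normalized) layer.
#' @param radius Dendrite half-width in pixels (default 3, i.e. a 0.9 um
#'   structure at 137 nm/pixel).
#' @param threshold Segmentation threshold (`NULL` = Otsu on the positive
#'   enhanced response of this layer). When processing a stack, compute
#'   one threshold for the whole stack (as [run_full()] does) so blank or
#'   sparse layers do not get an over-adapted threshold.
#' @param max_spur_length Spur-pruning rounds (default 7: a spine protruding
#'   ~0.5 um beyond the shaft surface gives a skeleton spur of up to
#'   ~7 px at 137 nm/pixel once the shaft half-width and a pixel of
#'   skeleton-midline slack are included).
#' @param search_radius Spur-anchor window radius (default 8).
#' @param box,ratio_min,intensity_min Axon-screening parameters, see
#'   [filter_axon_points()].
#' @param norm_range Optional `c(lo, hi)` used instead of the layer's own
#'   min/max for normalization (stack-level normalization).
#' @param layer_index z index recorded in the output.
#' @return `data.frame` of candidates with screening columns (accepted and
#'   rejected, with reasons). Intermediates are attached as attribute
#'   `"stages"`: `normalized`, `enhanced`, `mask`, `skeleton`, `pruned`,
#'   `removed`.
#' @export
detect_spines <- function(layer, radius = 3L, threshold = NULL,
                          max_spur_length = 7L, search_radius = 8L,
                          box = 15L, ratio_min = 1.2,
                          intensity_min = 0.2, norm_range = NULL,
                          layer_index = 1L) {
  stopifnot(is.matrix(layer), radius > 0)
  norm <- if (is.null(norm_range)) {
    normalize_image(layer)
  } else {
    scale_to_range(layer, norm_range)
  }
  enh <- enhance_lines(norm, scale_from_radius(radius))
  mask <- segment_enhanced(enh, threshold = threshold)
  skel <- thin(mask)
  pr <- remove_spurs(skel, max_spur_length = max_spur_length)
  cands <- locate_spines(skel, pr$pruned, pr$removed,
                         search_radius = search_radius,
                         layer_index = layer_index)
  cands <- filter_axon_points(cands, mask, norm, box = box,
                              ratio_min = ratio_min,
                              intensity_min = intensity_min)
  attr(cands, "stages") <- list(normalized = norm, enhanced = enh,
                                mask = mask, skeleton = skel,
                                pruned = pr$pruned, removed = pr$removed)
  cands
}
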