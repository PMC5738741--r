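# Synapse assembly: per-layer distance pairing of boutons with spines,
# and mutual-nearest-neighbour linking of per-layer detections across
# consecutive z-layers into 3D objects. Distances are lateral (y, x) only;
# the ~5x axial anisotropy makes 3D Euclidean distances misleading, and
# linking compares adjacent layers only.

#' Pair boutons with spines within one layer
#'
#' Greedy one-to-one nearest pairing: all bouton-spine pairs with lateral
#' distance at most `d_max` are sorted by ascending distance and accepted
#' when both members are still unused, so each bouton and each spine
#' belongs to at most one synapse.
#'
#' @param boutons `data.frame` with columns `y`, `x` (accepted boutons of
#'   one layer).
#' @param spines `data.frame` with columns `y`, `x` (accepted spines of
#'   the same layer).
#' @param d_max Maximum pairing distance in pixels (default 6: bouton
#'   radius plus spine-search tolerance).
#' @param layer_index z index recorded in the output.
#' @return `data.frame` with columns `layer`, `bouton_id`, `spine_id`
#'   (row indices into the inputs), `bouton_y`, `bouton_x`, `spine_y`,
#'   `spine_x`, `y`, `x` (pair midpoint) and `distance`.
#' @export
pair_synapses_2d <- function(boutons, spines, d_max = 6, layer_index = 1L) {
  empty <- data.frame(layer = integer(0), bouton_id = integer(0),
                      spine_id = integer(0), bouton_y = numeric(0),
                      bouton_x = numeric(0), spine_y = numeric(0),
                      spine_x = numeric(0), y = numeric(0), x = numeric(0),
                      distance = numeric(0))
  nb <- nrow(boutons); ns <- nrow(spines)
  if (nb == 0L || ns == 0L) return(empty)
  d <- sqrt(outer(boutons$y, spines$y, "-")^2 +
            outer(boutons$x, spines$x, "-")^2)
  cand <- which(d <= d_max, arr.ind = TRUE)
  if (nrow(cand) == 0L) return(empty)
  dist <- d[cand]
  ord <- order(dist, cand[, 1], cand[, 2]) # deterministic under ties
  used_b <- logical(nb); used_s <- logical(ns)
  out <- empty
  for (k in ord) {
    bi <- cand[k, 1]; si <- cand[k, 2]
    if (used_b[bi] || used_s[si]) next
    used_b[bi] <- TRUE; used_s[si] <- TRUE
    out <- rbind(out, data.frame(
      layer = layer_index, bouton_id = bi, spine_id = si,
      bouton_y = boutons$y[bi], bouton_x = boutons$x[bi],
      spine_y = spines$y[si], spine_x = spines$x[si],
      y = (boutons$y[bi] + spines$y[si]) / 2,
      x = (boutons$x[bi] + spines$x[si]) / 2,
      distance = dist[k]))
  }
  out
}

#' Link per-layer detections across z into 3D objects
#'
#' For each pair of consecutive layers, a detection `a` in layer k links
#' to `b` in layer k+1 iff `b` is the nearest neighbour of `a`, `a` is the
#' nearest neighbour of `b`, and their lateral distance is at most
#' `d_link`. Chains of links become one 3D object; unlinked detections
#' become singletons. A detection missing in an intermediate layer breaks
#' the chain (no z-gap tolerance), which is surfaced so a proofreader can
#' merge; ties in nearest-neighbour distance are broken by (y, x) order so
#' the result does not depend on within-layer detection order.
#'
#' @param per_layer List of `data.frame`s ordered by z, each with columns
#'   `y`, `x` (and optionally others, carried through). Empty layers may
#'   be `NULL` or zero-row frames.
#' @param d_link Maximum link distance in pixels (default 4).
#' @return List of 3D objects; each is a list with `members`
#'   (`data.frame` with `layer`, `y`, `x`), `z_first`, `z_last`, and
#'   `representative` (`c(z, y, x)` of the member of the chain whose link
#'   distance is smallest, or the first member for singletons).
#' @export
link_across_layers <- function(per_layer, d_link = 4) {
  nz <- length(per_layer)
  pts <- lapply(seq_len(nz), function(z) {
    df <- per_layer[[z]]
    if (is.null(df) || nrow(df) == 0L) {
      return(data.frame(layer = integer(0), y = numeric(0), x = numeric(0)))
    }
    ord <- order(df$y, df$x) # canonical order: permutation invariance
    data.frame(layer = z, y = df$y[ord], x = df$x[ord])
  })
  counts <- vapply(pts, nrow, integer(1))
  total <- sum(counts)
  if (total == 0L) return(list())
  offset <- cumsum(c(0L, counts[-nz]))
  edges <- integer(0)
  edge_d <- numeric(0)
  for (z in seq_len(nz - 1L)) {
    a <- pts[[z]]; b <- pts[[z + 1L]]
    if (nrow(a) == 0L || nrow(b) == 0L) next
    d <- sqrt(outer(a$y, b$y, "-")^2 + outer(a$x, b$x, "-")^2)
    nn_ab <- apply(d, 1, which.min) # ties: first = smallest (y, x)
    nn_ba <- apply(d, 2, which.min)
    for (i in seq_len(nrow(a))) {
      j <- nn_ab[i]
      if (nn_ba[j] == i && d[i, j] <= d_link) {
        edges <- c(edges, offset[z] + i, offset[z + 1L] + j)
        edge_d <- c(edge_d, d[i, j])
      }
    }
  }
  g <- igraph::make_graph(edges = edges, n = total, directed = FALSE)
  memb <- igraph::components(g)$membership
  all_pts <- do.call(rbind, pts)
  all_pts$min_link <- Inf
  if (length(edges)) {
    ij <- matrix(edges, ncol = 2, byrow = TRUE)
    for (k in seq_len(nrow(ij))) {
      all_pts$min_link[ij[k, ]] <- pmin(all_pts$min_link[ij[k, ]], edge_d[k])
    }
  }
  objs <- lapply(sort(unique(memb)), function(cid) {
    mem <- all_pts[memb == cid, , drop = FALSE]
    mem <- mem[order(mem$layer), , drop = FALSE]
    rep_i <- which.min(mem$min_link)
    if (!is.finite(mem$min_link[rep_i])) rep_i <- 1L
    list(members = mem[, c("layer", "y", "x")],
         z_first = mem$layer[1L], z_last = mem$layer[nrow(mem)],
         representative = c(z = mem$layer[rep_i], y = mem$y[rep_i],
                            x = mem$x[rep_i]))
  })
  # stable order: by first layer then representative position
  ord <- order(vapply(objs, `[[`, numeric(1), "z_first"),
               vapply(objs, function(o) o$representative[["y"]], numeric(1)),
               vapply(objs, function(o) o$representative[["x"]], numeric(1)))
  objs[ord]
}

#' Count 3D objects
#'
#' @param objects List of 3D objects from [link_across_layers()].
#' @return Integer count of distinct 3D structures.
#' @export
count_3d <- function(objects) length(objects)

#' Summarize 3D objects as a table
#'
#' @param objects List from [link_across_layers()].
#' @return `data.frame` with one row per object: `id`, `z_first`,
#'   `z_last`, `n_layers`, `rep_z`, `rep_y`, `rep_x`.
#' @export
summarize_3d <- function(objects) {
  if (length(objects) == 0L) {
    return(data.frame(id = integer(0), z_first = integer(0),
                      z_last = integer(0), n_layers = integer(0),
                      rep_z = numeric(0), rep_y = numeric(0),
                      rep_x = numeric(0)))
  }
  do.call(rbind, lapply(seq_along(objects), function(i) {
    o <- objects[[i]]
    data.frame(id = i, z_first = o$z_first, z_last = o$z_last,
               n_layers = nrow(o$members), rep_z = o$representative[["z"]],
               rep_y = o$representative[["y"]], rep_x = o$representative[["x"]])
  }))
}
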