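# End-to-end orchestration: channel handling, per-layer bouton and spine
# detection, 2D synapse pairing, 3D linking, reporting, and evaluation
# against ground truth.

#' Default pipeline configuration
#'
#' Collects every tunable of the pipeline in one list so a run can be
#' reproduced from its serialized config. Physical defaults assume the
#' acquisition geometry of 137 nm/pixel lateral pitch: a 1.0 um bouton
#' (radius 4 px) and a 0.9 um dendrite (half-width 3 px).
#'
#' @param ... Named overrides of any default.
#' @return Named list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    pixel_size_nm = 137,
    pixel_size_z_nm = 700,
    bouton_diameter_um = 1.0,
    spine_shaft_diameter_um = 0.9,
    bouton = list(window = NULL, threshold = NULL, noise_k = 3,
                  e_max = 0.95, a_min = 2, a_max = NULL, b_min = 2,
                  brightness_factor = 3, annulus_inner = 1,
                  annulus_outer = 4),
    spine = list(threshold = NULL, max_spur_length = 7L, search_radius = 8L,
                 box = 15L, ratio_min = 1.2, intensity_min = 0.2),
    synapse = list(d_max = 6, d_link = 4),
    match_radius = list(bouton = 3, spine = 3, synapse = 4)
  )
  over <- list(...)
  for (nm in names(over)) {
    if (is.list(cfg[[nm]]) && is.list(over[[nm]])) {
      cfg[[nm]][names(over[[nm]])] <- over[[nm]]
    } else {
      cfg[[nm]] <- over[[nm]]
    }
  }
  structure(cfg, class = c("pipeline_config", "list"))
}

#' Run the full detection workflow on a two-channel stack
#'
#' Channel handling (YFP-only = channel 1 - channel 2), per-layer bouton
#' detection on the axon channel and spine detection on the YFP-only
#' channel, per-layer bouton-spine pairing, and mutual-nearest-neighbour
#' 3D linking of both synapses and boutons. Deterministic given config
#' and inputs.
#'
#' @param ch1 `image_stack`, the GFP+YFP channel.
#' @param ch2 `image_stack`, the GFP-only (axon) channel.
#' @param config A [pipeline_config()].
#' @return List of class `synapse_report`: `boutons`, `spines`,
#'   `synapses_2d` (per-layer tables, including rejected candidates with
#'   reasons), `synapses_3d`, `boutons_3d` (summary tables), `counts`,
#'   and the `config`. Coordinates are 1-based `(z, y, x)`.
#' @export
run_full <- function(ch1, ch2, config = pipeline_config()) {
  stopifnot(inherits(ch1, "image_stack"), inherits(ch2, "image_stack"))
  yfp <- subtract_channels(ch1, ch2)
  r_b <- radius_from_physical(config$bouton_diameter_um, config$pixel_size_nm)
  r_s <- radius_from_physical(config$spine_shaft_diameter_um,
                              config$pixel_size_nm)
  nz <- n_layers(ch2)
  # stack-level normalization and one segmentation threshold per stack and
  # branch: a single acquisition has one intensity scale, and per-layer
  # adaptive thresholds over-adapt on layers containing no structure
  rng_b <- range(ch2$voxels)
  rng_s <- range(yfp$voxels)
  th_b <- config$bouton$threshold
  if (is.null(th_b)) {
    pos <- unlist(lapply(seq_len(nz), function(z) {
      e <- enhance_blobs(scale_to_range(get_layer(ch2, z), rng_b),
                         scale_from_radius(r_b))
      e$pixels[e$pixels > 0]
    }))
    th_b <- if (length(pos) < 2L) 0 else otsu_threshold(pos)
  }
  th_s <- config$spine$threshold
  if (is.null(th_s)) {
    pos <- unlist(lapply(seq_len(nz), function(z) {
      e <- enhance_lines(scale_to_range(get_layer(yfp, z), rng_s),
                         scale_from_radius(r_s))
      e$pixels[e$pixels > 0]
    }))
    th_s <- if (length(pos) < 2L) 0 else otsu_threshold(pos)
  }
  cfg_b <- config$bouton; cfg_b$threshold <- th_b
  cfg_s <- config$spine; cfg_s$threshold <- th_s
  boutons <- list(); spines <- list(); synapses <- list()
  for (z in seq_len(nz)) {
    bz <- withCallingHandlers(
      do.call(detect_boutons, c(list(layer = get_layer(ch2, z),
                                     radius = r_b, norm_range = rng_b,
                                     layer_index = z),
                                cfg_b)),
      warning = function(w) invokeRestart("muffleWarning"))
    sz <- do.call(detect_spines, c(list(layer = get_layer(yfp, z),
                                        radius = r_s, norm_range = rng_s,
                                        layer_index = z),
                                   cfg_s))
    attr(sz, "stages") <- NULL
    attr(bz, "regions") <- NULL
    ba <- bz[bz$accepted, , drop = FALSE]
    sa <- sz[sz$accepted, , drop = FALSE]
    synapses[[z]] <- pair_synapses_2d(ba, sa, d_max = config$synapse$d_max,
                                      layer_index = z)
    boutons[[z]] <- bz
    spines[[z]] <- sz
  }
  boutons_df <- do.call(rbind, boutons)
  spines_df <- do.call(rbind, spines)
  synapses_df <- do.call(rbind, synapses)
  syn3d <- link_across_layers(synapses, d_link = config$synapse$d_link)
  bout_acc <- lapply(boutons, function(b) b[b$accepted, , drop = FALSE])
  bout3d <- link_across_layers(bout_acc, d_link = config$synapse$d_link)
  structure(list(
    boutons = boutons_df, spines = spines_df, synapses_2d = synapses_df,
    synapses_3d = summarize_3d(syn3d), boutons_3d = summarize_3d(bout3d),
    synapse_objects = syn3d, bouton_objects = bout3d,
    counts = c(boutons_2d = sum(boutons_df$accepted),
               spines_2d = sum(spines_df$accepted),
               synapses_2d = nrow(synapses_df),
               synapses_3d = count_3d(syn3d),
               boutons_3d = count_3d(bout3d)),
    config = config), class = "synapse_report")
}

#' @export
print.synapse_report <- function(x, ...) {
  cat("synapse_report:\n")
  print(x$counts)
  invisible(x)
}

#' Write a report to CSV and JSON
#'
#' One CSV per table plus a JSON file with counts and the full config
#' (coordinates 1-based `(z, y, x)`, distances in lateral pixels).
#'
#' @param report A `synapse_report`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in c("boutons", "spines", "synapses_2d", "synapses_3d",
               "boutons_3d")) {
    write.csv(report[[nm]], file.path(dir, paste0(nm, ".csv")),
              row.names = FALSE)
  }
  jsonlite::write_json(
    list(coordinates = "1-based (z, y, x); distances in lateral pixels",
         counts = as.list(report$counts), config = unclass(report$config)),
    file.path(dir, "report.json"), auto_unbox = TRUE, pretty = TRUE,
    digits = NA, null = "null")
  invisible(dir)
}

# Greedy one-to-one matching of detections to truths within match_radius.
match_points <- function(det, truth, radius) {
  nd <- nrow(det); nt <- nrow(truth)
  if (nd == 0L || nt == 0L) {
    return(list(matched = 0L, fp = nd, fn = nt))
  }
  d <- sqrt(outer(det$y, truth$y, "-")^2 + outer(det$x, truth$x, "-")^2)
  cand <- which(d <= radius, arr.ind = TRUE)
  if (nrow(cand) == 0L) return(list(matched = 0L, fp = nd, fn = nt))
  ord <- order(d[cand], cand[, 1], cand[, 2])
  used_d <- logical(nd); used_t <- logical(nt)
  m <- 0L
  for (k in ord) {
    i <- cand[k, 1]; j <- cand[k, 2]
    if (used_d[i] || used_t[j]) next
    used_d[i] <- TRUE; used_t[j] <- TRUE
    m <- m + 1L
  }
  list(matched = m, fp = nd - m, fn = nt - m)
}

#' Evaluate a report against synthetic ground truth
#'
#' Per structure class and layer, detections are matched one-to-one to
#' planted truths (greedy by distance within the class match radius);
#' unmatched detections are false positives, unmatched truths false
#' negatives.
#'
#' @param report A `synapse_report` from [run_full()].
#' @param truth A `synthetic_ground_truth`.
#' @param match_radius Named list/vector with elements `bouton`, `spine`,
#'   `synapse` (pixels); defaults from the report config.
#' @return `data.frame` with one row per class: `class`, `truth_n`,
#'   `detected_n`, `matched`, `false_positives`, `false_negatives`,
#'   `recall`, `precision`. Matched + FP = detected and matched + FN =
#'   truth, per class.
#' @export
evaluate_against_truth <- function(report, truth, match_radius = NULL) {
  if (is.null(match_radius)) match_radius <- report$config$match_radius
  det <- list(
    bouton = report$boutons[report$boutons$accepted, c("layer", "y", "x")],
    spine = report$spines[report$spines$accepted, c("layer", "y", "x")],
    synapse = report$synapses_2d[, c("layer", "y", "x")]
  )
  tru <- list(bouton = truth$boutons_2d, spine = truth$spines_2d,
              synapse = truth$synapses_2d)
  rows <- lapply(names(det), function(cl) {
    dd <- det[[cl]]; tt <- tru[[cl]]
    layers <- sort(unique(c(dd$layer, tt$z)))
    tot <- c(matched = 0L, fp = 0L, fn = 0L)
    for (z in layers) {
      r <- match_points(dd[dd$layer == z, , drop = FALSE],
                        tt[tt$z == z, , drop = FALSE],
                        match_radius[[cl]])
      tot <- tot + c(r$matched, r$fp, r$fn)
    }
    data.frame(class = cl, truth_n = nrow(tt), detected_n = nrow(dd),
               matched = tot[["matched"]], false_positives = tot[["fp"]],
               false_negatives = tot[["fn"]],
               recall = if (nrow(tt)) tot[["matched"]] / nrow(tt) else NA_real_,
               precision = if (nrow(dd)) tot[["matched"]] / nrow(dd) else NA_real_)
  })
  do.call(rbind, rows)
}

#' Mark detections on a stack for visual proofreading
#'
#' Burns a small cross at every accepted detection into a copy of the
#' stack and writes it as a 16-bit multi-page TIFF overlay.
#'
#' @param stack `image_stack` to draw on.
#' @param detections `data.frame` with `layer`, `y`, `x`.
#' @param path Output TIFF path.
#' @param arm Cross arm length in pixels.
#' @return `path`, invisibly.
#' @export
write_overlay <- function(stack, detections, path, arm = 3L) {
  v <- stack$voxels
  hi <- max(v)
  d <- dim(v)
  for (i in seq_len(nrow(detections))) {
    z <- detections$layer[i]
    y <- round(detections$y[i]); x <- round(detections$x[i])
    yy <- pmin(pmax(y + (-arm:arm), 1L), d[1])
    xx <- pmin(pmax(x + (-arm:arm), 1L), d[2])
    v[cbind(yy, x, z)] <- hi
    v[cbind(y, xx, z)] <- hi
  }
  write_stack(image_stack(v, stack$pixel_size_xy, stack$pixel_size_z,
                          paste0(stack$channel_label, "+overlay")), path)
  invisible(path)
}
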