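# Synthetic two-photon stack generator with exact ground truth.
#
# Emulates the geometry the detectors are built for: bright round boutons
# (2D Gaussian surfaces, persisting over a few z-layers with a cosine
# amplitude taper) riding on dimmer curvilinear axon shafts; dendrite
# tubes with Gaussian cross-sections carrying short spine protrusions;
# dim axon-like lines contaminating the dendrite channel; additive
# background plus Poisson-like and Gaussian noise. Channel 1 is the sum
# of the axon (GFP) and dendrite (YFP) scenes, channel 2 the axon scene
# alone, so channel subtraction recovers the dendrite scene as in the
# dual-colour labelling scheme.

#' Construct and validate a synthetic stack specification
#'
#' @param ny,nx Image height and width in pixels.
#' @param n_layers Number of z-layers.
#' @param boutons `data.frame` with columns `id`, `y`, `x`, `peak`,
#'   `radius`, `z_start`, `z_end`. Rendered into the axon channel as
#'   Gaussian surfaces of scale `radius/sqrt(3)` with a cosine axial
#'   amplitude taper (floor 0.6 of the peak) over `[z_start, z_end]`.
#' @param axons List of axon shafts: each `list(path = cbind(y, x),
#'   amplitude, halfwidth)`; rendered into the axon channel in all layers.
#' @param dendrites List of dendrite tubes (same structure as `axons`);
#'   rendered into the dendrite channel in all layers.
#' @param spines `data.frame` with columns `id`, `attach_y`, `attach_x`,
#'   `angle` (radians), `length`, `halfwidth`, `amplitude`, `z_start`,
#'   `z_end`; rendered into the dendrite channel as short tubes from the
#'   attachment point to the tip.
#' @param yfp_axons List of dim axon-like contaminants of the dendrite
#'   channel (same structure as `axons`).
#' @param synapses `data.frame` with columns `id`, `bouton_id`,
#'   `spine_id`; a synapse exists in the layers where both members exist.
#' @param background Additive background level (both channels).
#' @param noise `list(type, gain, sd)`: `type` one of `"none"`,
#'   `"gaussian"`, `"poisson"`, `"poisson+gaussian"`; `gain` is the
#'   photon-scaling of the Poisson component (`I -> gain * Pois(I/gain)`),
#'   `sd` the absolute Gaussian sigma.
#' @param seed Integer seed; rendering is bit-reproducible given the spec.
#' @return Object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(ny = 144L, nx = 144L, n_layers = 10L,
                           boutons = NULL, axons = list(),
                           dendrites = list(), spines = NULL,
                           yfp_axons = list(), synapses = NULL,
                           background = 10,
                           noise = list(type = "none", gain = 0.1, sd = 3),
                           seed = 1L) {
  if (is.null(boutons)) {
    boutons <- data.frame(id = integer(0), y = numeric(0), x = numeric(0),
                          peak = numeric(0), radius = numeric(0),
                          z_start = integer(0), z_end = integer(0))
  }
  if (is.null(spines)) {
    spines <- data.frame(id = integer(0), attach_y = numeric(0),
                         attach_x = numeric(0), angle = numeric(0),
                         length = numeric(0), halfwidth = numeric(0),
                         amplitude = numeric(0), z_start = integer(0),
                         z_end = integer(0))
  }
  if (is.null(synapses)) {
    synapses <- data.frame(id = integer(0), bouton_id = integer(0),
                           spine_id = integer(0))
  }
  spec <- structure(
    list(ny = as.integer(ny), nx = as.integer(nx),
         n_layers = as.integer(n_layers), boutons = boutons, axons = axons,
         dendrites = dendrites, spines = spines, yfp_axons = yfp_axons,
         synapses = synapses, background = background, noise = noise,
         seed = as.integer(seed)),
    class = "synthetic_spec"
  )
  validate_synthetic_spec(spec)
  spec
}

spine_tip <- function(sp) {
  c(y = sp$attach_y + sp$length * sin(sp$angle),
    x = sp$attach_x + sp$length * cos(sp$angle))
}

validate_synthetic_spec <- function(spec) {
  inb <- function(y, x) {
    all(y >= 1 & y <= spec$ny & x >= 1 & x <= spec$nx)
  }
  with(spec, {
    if (nrow(boutons) && !inb(boutons$y, boutons$x)) {
      stop("bouton centre out of bounds")
    }
    if (nrow(boutons) &&
        any(boutons$z_start < 1 | boutons$z_end > n_layers |
            boutons$z_start > boutons$z_end)) {
      stop("bouton z-range out of bounds")
    }
    for (s in c(axons, dendrites, yfp_axons)) {
      if (!inb(s$path[, 1], s$path[, 2])) stop("polyline out of bounds")
    }
    if (nrow(spines)) {
      tips <- t(vapply(seq_len(nrow(spines)),
                       function(i) spine_tip(spines[i, ]), numeric(2)))
      if (!inb(spines$attach_y, spines$attach_x) ||
          !inb(tips[, 1], tips[, 2])) {
        stop("spine out of bounds")
      }
      if (any(spines$z_start < 1 | spines$z_end > n_layers |
              spines$z_start > spines$z_end)) {
        stop("spine z-range out of bounds")
      }
    }
    if (nrow(synapses) &&
        (!all(synapses$bouton_id %in% boutons$id) ||
         !all(synapses$spine_id %in% spines$id))) {
      stop("synapse references unknown bouton or spine id")
    }
  })
  invisible(spec)
}

# Rasterize a polyline (vertex matrix cbind(y, x)) into a pixel mask by
# dense sampling along each segment.
rasterize_polyline <- function(path, ny, nx) {
  m <- matrix(FALSE, ny, nx)
  for (i in seq_len(nrow(path) - 1L)) {
    p0 <- path[i, ]; p1 <- path[i + 1L, ]
    len <- max(abs(p1 - p0))
    t <- seq(0, 1, length.out = max(2L, ceiling(len * 4) + 1L))
    yy <- pmin(pmax(round(p0[1] + t * (p1[1] - p0[1])), 1L), ny)
    xx <- pmin(pmax(round(p0[2] + t * (p1[2] - p0[2])), 1L), nx)
    m[cbind(yy, xx)] <- TRUE
  }
  m
}

# Gaussian tube around a polyline: amplitude * exp(-d^2 / (2 sigma^2))
# with sigma = halfwidth / sqrt(3) and d the distance to the rasterized
# centerline.
render_tube <- function(path, amplitude, halfwidth, ny, nx) {
  cl <- rasterize_polyline(path, ny, nx)
  if (!any(cl)) return(matrix(0, ny, nx))
  d <- EBImage::distmap(EBImage::Image(1 - cl))@.Data
  sg <- halfwidth / sqrt(3)
  amplitude * exp(-d^2 / (2 * sg^2))
}

# Gaussian surface for a bouton.
render_blob <- function(y0, x0, peak, radius, ny, nx) {
  dl <- radius / sqrt(3)
  yy <- matrix(seq_len(ny), ny, nx)
  xx <- matrix(seq_len(nx), ny, nx, byrow = TRUE)
  peak * exp(-((yy - y0)^2 + (xx - x0)^2) / (2 * dl^2))
}

# Cosine axial amplitude taper over [z_start, z_end], 1 at the centre and
# 0.6 at the range edges: boutons stay well above the shaft-brightness
# criterion throughout their axial extent, as they do within the depth of
# field of the acquisition.
bouton_taper <- function(z, z_start, z_end) {
  zc <- (z_start + z_end) / 2
  span <- z_end - z_start + 1
  0.6 + 0.4 * cos(pi * (z - zc) / span)
}

apply_noise <- function(img, noise) {
  type <- noise$type %||% "none"
  if (type %in% c("poisson", "poisson+gaussian")) {
    gain <- noise$gain %||% 0.1
    img[] <- gain * stats::rpois(length(img), pmax(img, 0) / gain)
  }
  if (type %in% c("gaussian", "poisson+gaussian")) {
    img <- img + stats::rnorm(length(img), 0, noise$sd %||% 3)
  }
  pmax(img, 0)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Render a synthetic stack and its ground truth
#'
#' Structures are rendered additively onto the background (so rendering
#' structures separately and summing equals rendering jointly, pre-noise);
#' noise is applied last, with the spec seed, making the output
#' bit-reproducible.
#'
#' @param spec A `synthetic_spec`.
#' @return List with `ch1` (GFP+YFP `image_stack`), `ch2` (GFP-only
#'   `image_stack`), and `truth`, a `synthetic_ground_truth`: per-layer
#'   tables `boutons_2d`, `spines_2d`, `synapses_2d` (columns `id`, `z`,
#'   `y`, `x`, plus member ids for synapses) and 3D tables `boutons_3d`,
#'   `synapses_3d` (one row per object with its z-range). Spine `y`, `x`
#'   is the protrusion tip.
#' @export
render_stack <- function(spec) {
  validate_synthetic_spec(spec)
  ny <- spec$ny; nx <- spec$nx; nz <- spec$n_layers
  axon_field <- matrix(0, ny, nx)
  for (s in spec$axons) {
    axon_field <- axon_field +
      render_tube(s$path, s$amplitude, s$halfwidth, ny, nx)
  }
  dend_field <- matrix(0, ny, nx)
  for (s in c(spec$dendrites, spec$yfp_axons)) {
    dend_field <- dend_field +
      render_tube(s$path, s$amplitude, s$halfwidth, ny, nx)
  }
  spine_fields <- list()
  if (nrow(spec$spines)) {
    for (i in seq_len(nrow(spec$spines))) {
      sp <- spec$spines[i, ]
      tip <- spine_tip(sp)
      path <- rbind(c(sp$attach_y, sp$attach_x), tip)
      spine_fields[[i]] <- render_tube(path, sp$amplitude, sp$halfwidth,
                                       ny, nx)
    }
  }
  ch1 <- array(0, dim = c(ny, nx, nz))
  ch2 <- array(0, dim = c(ny, nx, nz))
  for (z in seq_len(nz)) {
    ax <- axon_field
    if (nrow(spec$boutons)) {
      for (i in seq_len(nrow(spec$boutons))) {
        b <- spec$boutons[i, ]
        if (z < b$z_start || z > b$z_end) next
        ax <- ax + render_blob(b$y, b$x,
                               b$peak * bouton_taper(z, b$z_start, b$z_end),
                               b$radius, ny, nx)
      }
    }
    de <- dend_field
    if (length(spine_fields)) {
      for (i in seq_along(spine_fields)) {
        sp <- spec$spines[i, ]
        if (z >= sp$z_start && z <= sp$z_end) de <- de + spine_fields[[i]]
      }
    }
    ch2[, , z] <- spec$background + ax
    ch1[, , z] <- spec$background + ax + de
  }
  set.seed(spec$seed)
  if ((spec$noise$type %||% "none") != "none") {
    for (z in seq_len(nz)) {
      ch1[, , z] <- apply_noise(ch1[, , z], spec$noise)
      ch2[, , z] <- apply_noise(ch2[, , z], spec$noise)
    }
  }
  truth <- ground_truth_from_spec(spec)
  list(ch1 = image_stack(ch1, channel_label = "GFP+YFP"),
       ch2 = image_stack(ch2, channel_label = "GFP-only"),
       truth = truth)
}

ground_truth_from_spec <- function(spec) {
  b2 <- if (nrow(spec$boutons)) {
    do.call(rbind, lapply(seq_len(nrow(spec$boutons)), function(i) {
      b <- spec$boutons[i, ]
      data.frame(id = b$id, z = seq(b$z_start, b$z_end), y = b$y, x = b$x)
    }))
  } else data.frame(id = integer(0), z = integer(0), y = numeric(0),
                    x = numeric(0))
  s2 <- if (nrow(spec$spines)) {
    do.call(rbind, lapply(seq_len(nrow(spec$spines)), function(i) {
      sp <- spec$spines[i, ]
      tip <- spine_tip(sp)
      data.frame(id = sp$id, z = seq(sp$z_start, sp$z_end),
                 y = round(tip[["y"]]), x = round(tip[["x"]]))
    }))
  } else data.frame(id = integer(0), z = integer(0), y = numeric(0),
                    x = numeric(0))
  y2 <- if (nrow(spec$synapses)) {
    do.call(rbind, lapply(seq_len(nrow(spec$synapses)), function(i) {
      sy <- spec$synapses[i, ]
      b <- spec$boutons[spec$boutons$id == sy$bouton_id, ]
      sp <- spec$spines[spec$spines$id == sy$spine_id, ]
      zz <- seq(max(b$z_start, sp$z_start), min(b$z_end, sp$z_end))
      if (length(zz) == 0L) return(NULL)
      tip <- spine_tip(sp)
      data.frame(id = sy$id, z = zz, y = (b$y + tip[["y"]]) / 2,
                 x = (b$x + tip[["x"]]) / 2,
                 bouton_id = sy$bouton_id, spine_id = sy$spine_id)
    }))
  } else NULL
  if (is.null(y2)) {
    y2 <- data.frame(id = integer(0), z = integer(0), y = numeric(0),
                     x = numeric(0), bouton_id = integer(0),
                     spine_id = integer(0))
  }
  b3 <- unique(b2[, "id", drop = FALSE])
  y3 <- unique(y2[, "id", drop = FALSE])
  structure(list(boutons_2d = b2, spines_2d = s2, synapses_2d = y2,
                 boutons_3d = b3, synapses_3d = y3),
            class = "synthetic_ground_truth")
}

#' Write / read ground truth as CSV files
#'
#' Serializes the per-layer and 3D ground-truth tables losslessly.
#'
#' @param truth A `synthetic_ground_truth`.
#' @param dir Output directory (created if missing).
#' @return `dir` (write) or the reconstructed object (read).
#' @export
write_ground_truth <- function(truth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(truth)) {
    write.csv(truth[[nm]], file.path(dir, paste0(nm, ".csv")),
              row.names = FALSE)
  }
  invisible(dir)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(dir) {
  classes <- list(
    boutons_2d = c(id = "integer", z = "integer", y = "numeric",
                   x = "numeric"),
    spines_2d = c(id = "integer", z = "integer", y = "numeric",
                  x = "numeric"),
    synapses_2d = c(id = "integer", z = "integer", y = "numeric",
                    x = "numeric", bouton_id = "integer",
                    spine_id = "integer"),
    boutons_3d = c(id = "integer"),
    synapses_3d = c(id = "integer")
  )
  out <- lapply(names(classes), function(nm) {
    read.csv(file.path(dir, paste0(nm, ".csv")),
             colClasses = classes[[nm]])
  })
  structure(setNames(out, names(classes)),
            class = "synthetic_ground_truth")
}

# --- benchmark scenes -------------------------------------------------------

# A standard scene: horizontal dendrites with perpendicular spines, axons
# running past some spine tips carrying boutons (those bouton-spine pairs
# are the planted synapses), extra non-synaptic boutons, and a dim
# axon-like contaminant with a short side twig in the dendrite channel.
build_scene <- function(ny, nx, nz, dend_rows, spines_per_dend,
                        n_free_boutons, synapse_fraction = 1,
                        noise, seed, with_yfp_axon = TRUE,
                        spine_len = 6, spine_halfwidth = 1.6,
                        bouton_offset = 3) {
  set.seed(seed)
  dendrites <- lapply(dend_rows, function(r) {
    xs <- seq(6, nx - 5, length.out = 7)
    ys <- r + round(cumsum(stats::runif(7, -1.2, 1.2)))
    list(path = cbind(ys, xs), amplitude = 120, halfwidth = 3)
  })
  spines <- NULL
  sid <- 0L
  for (di in seq_along(dendrites)) {
    path <- dendrites[[di]]$path
    # attach on the rasterized centerline (the rendered tube axis), not the
    # interpolated polyline: rounding can offset the two by 1-2 px and the
    # skeleton spur length must track the rendered geometry
    cl <- rasterize_polyline(path, ny, nx)
    xs <- seq(22, nx - 22, length.out = spines_per_dend[di])
    for (k in seq_along(xs)) {
      sid <- sid + 1L
      up <- (k %% 2L == 0L)
      ay <- stats::median(which(cl[, round(xs[k])]))
      spines <- rbind(spines, data.frame(
        id = sid, attach_y = round(ay), attach_x = round(xs[k]),
        angle = if (up) -pi / 2 else pi / 2,
        length = spine_len, halfwidth = spine_halfwidth, amplitude = 110,
        z_start = 1L, z_end = nz))
    }
  }
  n_syn <- max(0L, round(synapse_fraction * sid))
  syn_spines <- if (n_syn > 0) seq_len(sid)[seq_len(n_syn)] else integer(0)
  boutons <- NULL
  axons <- list()
  synapses <- NULL
  bid <- 0L
  for (si in syn_spines) {
    sp <- spines[si, ]
    tip <- spine_tip(sp)
    bid <- bid + 1L
    by <- tip[["y"]] + bouton_offset * sin(sp$angle)
    bx <- tip[["x"]]
    zs <- sample(seq_len(max(1L, nz - 5L)), 1L)
    ze <- min(nz, zs + sample(3:5, 1L))
    boutons <- rbind(boutons, data.frame(
      id = bid, y = round(by), x = round(bx), peak = 150, radius = 4,
      z_start = zs, z_end = ze))
    axons[[length(axons) + 1L]] <- list(
      path = cbind(c(round(by), round(by)), c(max(1, bx - 16), min(nx, bx + 16))),
      amplitude = 28, halfwidth = 1.3)
    synapses <- rbind(synapses, data.frame(
      id = bid, bouton_id = bid, spine_id = si))
  }
  # free (non-synaptic) boutons on their own axon, well away from dendrites
  if (n_free_boutons > 0) {
    free_row <- round(ny / 2)
    axons[[length(axons) + 1L]] <- list(
      path = cbind(c(free_row, free_row), c(6, nx - 5)),
      amplitude = 28, halfwidth = 1.3)
    xs <- seq(25, nx - 25, length.out = n_free_boutons)
    for (k in seq_len(n_free_boutons)) {
      bid <- bid + 1L
      zs <- sample(seq_len(max(1L, nz - 5L)), 1L)
      ze <- min(nz, zs + sample(3:5, 1L))
      boutons <- rbind(boutons, data.frame(
        id = bid, y = free_row, x = round(xs[k]), peak = 150, radius = 4,
        z_start = zs, z_end = ze))
    }
  }
  yfp_axons <- list()
  if (with_yfp_axon) {
    # dim, thin axon in the dendrite channel with a short side twig: its
    # skeleton produces a spine-like candidate that the screening step
    # must reject
    col <- round(nx * 0.86)
    yfp_axons <- list(
      list(path = cbind(c(4, ny - 3), c(col, col)), amplitude = 45,
           halfwidth = 1.1),
      list(path = cbind(c(round(ny * 0.4), round(ny * 0.4)),
                        c(col, col + 5)), amplitude = 45, halfwidth = 1.1))
  }
  synthetic_spec(ny = ny, nx = nx, n_layers = nz, boutons = boutons,
                 axons = axons, dendrites = dendrites, spines = spines,
                 yfp_axons = yfp_axons, synapses = synapses,
                 background = 10, noise = noise, seed = seed)
}

#' Default benchmark suite of synthetic stacks
#'
#' A fixed small suite spanning structure densities and noise levels, used
#' by the end-to-end recovery tests: two noise-free stacks (sparse and
#' dense), two stacks at the default noise level (Poisson gain 0.1 plus
#' Gaussian sd 3 on peaks of ~160), one axon-contaminated stack, and one
#' noise-free 12-synapse stack whose 3D synapse count is known exactly.
#'
#' @param seed Integer; every stack derives its own sub-seed from it.
#' @return Named list of `synthetic_spec` objects: `clean_sparse`,
#'   `clean_dense`, `noisy_sparse`, `noisy_dense`, `axon_screen`,
#'   `synapse3d_12`.
#' @export
default_benchmark_suite <- function(seed = 7L) {
  noise_off <- list(type = "none")
  noise_on <- list(type = "poisson+gaussian", gain = 0.1, sd = 3)
  list(
    clean_sparse = build_scene(144L, 144L, 8L, dend_rows = c(40L, 104L),
                               spines_per_dend = c(2L, 2L),
                               n_free_boutons = 2L, noise = noise_off,
                               seed = seed + 1L),
    clean_dense = build_scene(144L, 144L, 8L, dend_rows = c(34L, 110L),
                              spines_per_dend = c(3L, 3L),
                              n_free_boutons = 3L, noise = noise_off,
                              seed = seed + 2L),
    noisy_sparse = build_scene(144L, 144L, 8L, dend_rows = c(40L, 104L),
                               spines_per_dend = c(2L, 2L),
                               n_free_boutons = 2L, noise = noise_on,
                               seed = seed + 3L),
    noisy_dense = build_scene(144L, 144L, 8L, dend_rows = c(34L, 110L),
                              spines_per_dend = c(3L, 3L),
                              n_free_boutons = 3L, noise = noise_on,
                              seed = seed + 4L),
    axon_screen = build_scene(144L, 144L, 6L, dend_rows = c(72L),
                              spines_per_dend = c(2L),
                              n_free_boutons = 0L, noise = noise_off,
                              seed = seed + 5L, with_yfp_axon = TRUE),
    synapse3d_12 = build_scene(216L, 216L, 12L,
                               dend_rows = c(40L, 108L, 176L),
                               spines_per_dend = c(4L, 4L, 4L),
                               n_free_boutons = 0L, noise = noise_off,
                               seed = seed + 6L)
  )
}
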