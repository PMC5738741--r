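# Stack I/O and channel arithmetic.
#
# Stacks are 3D arrays indexed [y, x, z] with lateral and axial pixel pitch
# metadata. Pitches are supplied by the caller (defaults 137 nm lateral,
# 700 nm axial, the acquisition geometry this pipeline was designed for);
# they are never read from TIFF tags.

#' Construct an image stack
#'
#' @param voxels 3D numeric array `[y, x, z]` (a matrix is promoted to a
#'   single-layer stack). Intensities must be non-negative.
#' @param pixel_size_xy Lateral pixel pitch in nm/pixel.
#' @param pixel_size_z Axial pitch in nm/layer.
#' @param channel_label Free-text channel description.
#' @return An object of class `image_stack`.
#' @export
image_stack <- function(voxels, pixel_size_xy = 137, pixel_size_z = 700,
                        channel_label = "") {
  if (is.matrix(voxels)) voxels <- array(voxels, dim = c(dim(voxels), 1L))
  stopifnot(is.array(voxels), length(dim(voxels)) == 3L)
  if (any(voxels < 0)) stop("stack intensities must be non-negative")
  if (pixel_size_xy <= 0 || pixel_size_z <= 0) {
    stop("pixel pitches must be positive")
  }
  structure(
    list(voxels = voxels, pixel_size_xy = pixel_size_xy,
         pixel_size_z = pixel_size_z, channel_label = channel_label),
    class = "image_stack"
  )
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf(
    "image_stack: %d x %d pixels, %d layer(s), %.0f nm/px lateral, %.0f nm axial%s\n",
    d[1], d[2], d[3], x$pixel_size_xy, x$pixel_size_z,
    if (nzchar(x$channel_label)) paste0(" [", x$channel_label, "]") else ""
  ))
  invisible(x)
}

#' Number of layers in a stack
#' @param stack An `image_stack`.
#' @return Integer layer count.
#' @export
n_layers <- function(stack) dim(stack$voxels)[3]

#' Extract one layer of a stack as a matrix
#' @param stack An `image_stack`.
#' @param z 1-based layer index.
#' @return Numeric matrix `[y, x]`.
#' @export
get_layer <- function(stack, z) {
  stopifnot(z >= 1, z <= n_layers(stack))
  stack$voxels[, , z]
}

#' Read a grayscale TIFF stack
#'
#' Reads a single- or multi-page grayscale TIFF; each page becomes one
#' z-layer. Integer TIFFs are returned at their native integer scale
#' (not rescaled to `[0, 1]`). Pixel pitches come from the arguments, never
#' from TIFF metadata.
#'
#' @param path Path to the TIFF file.
#' @inheritParams image_stack
#' @return An `image_stack` with one layer per page.
#' @export
read_stack <- function(path, pixel_size_xy = 137, pixel_size_z = 700,
                       channel_label = "") {
  if (!file.exists(path)) stop("no such file: ", path)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  for (p in pages) {
    if (length(dim(p)) == 3L && dim(p)[3] > 1L) {
      stop("non-grayscale TIFF page (", dim(p)[3], " samples per pixel)")
    }
  }
  pages <- lapply(pages, function(p) {
    if (length(dim(p)) == 3L) p <- p[, , 1]
    p
  })
  d1 <- dim(pages[[1]])
  if (!all(vapply(pages, function(p) identical(dim(p), d1), logical(1)))) {
    stop("TIFF pages have inconsistent dimensions")
  }
  vox <- array(unlist(pages), dim = c(d1, length(pages)))
  image_stack(vox, pixel_size_xy, pixel_size_z, channel_label)
}

#' Write a stack as a multi-page grayscale TIFF
#'
#' Integer-valued stacks in `[0, 65535]` are written as 16-bit pages and
#' round-trip bit-exactly through [read_stack()]. Other data are scaled to
#' the stack maximum and written as 16-bit (lossy; a warning is issued).
#'
#' @param stack An `image_stack`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  v <- stack$voxels
  is_int <- all(v == round(v)) && max(v) <= 65535
  if (!is_int) {
    warning("non-integer or out-of-range stack scaled to 16-bit")
    v <- round(v / max(v, 1e-12) * 65535)
  }
  pages <- lapply(seq_len(dim(v)[3]), function(z) v[, , z] / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}

#' Subtract the GFP channel from the dual channel
#'
#' Channel 1 carries GFP plus YFP, Channel 2 GFP only; the voxelwise
#' difference isolates the YFP signal. Negative differences are clamped to
#' zero: negative fluorescence is physically meaningless and arises only
#' from noise.
#'
#' @param ch1 `image_stack`, the GFP+YFP channel.
#' @param ch2 `image_stack`, the GFP-only channel; identical dimensions and
#'   pixel pitches.
#' @return An `image_stack` labelled `"YFP-only"`.
#' @export
subtract_channels <- function(ch1, ch2) {
  stopifnot(inherits(ch1, "image_stack"), inherits(ch2, "image_stack"))
  if (!identical(dim(ch1$voxels), dim(ch2$voxels))) {
    stop("channel stacks have different dimensions")
  }
  if (ch1$pixel_size_xy != ch2$pixel_size_xy ||
      ch1$pixel_size_z != ch2$pixel_size_z) {
    stop("channel stacks have different pixel pitches")
  }
  image_stack(pmax(ch1$voxels - ch2$voxels, 0),
              ch1$pixel_size_xy, ch1$pixel_size_z, "YFP-only")
}

#' Min-max normalize a 2D image
#'
#' Maps intensities affinely onto `[0, 1]`:
#' `(I - I_min) / (I_max - I_min)`. A constant image returns all zeros
#' rather than erroring, so batch pipelines survive blank layers.
#'
#' @param img Numeric matrix.
#' @return Numeric matrix with range `[0, 1]` (all zeros if constant).
#' @export
normalize_image <- function(img) {
  stopifnot(is.matrix(img), length(img) >= 1)
  lo <- min(img)
  hi <- max(img)
  if (hi <= lo) return(matrix(0, nrow(img), ncol(img)))
  (img - lo) / (hi - lo)
}
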