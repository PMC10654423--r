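# CT intensity conditioning and data handling: Hounsfield-unit windowing,
# global histogram equalization with min-max normalization, paired
# geometric augmentation, and deterministic train/test splitting.

#' Hounsfield-unit windowing
#'
#' Clips CT intensities to a diagnostic soft-tissue window; the default
#' `[-150, 250]` HU enhances the liver against the abdominal background.
#' Idempotent: windowing a windowed slice is a no-op.
#'
#' @param x numeric matrix/array of Hounsfield units.
#' @param lo,hi window bounds in HU.
#' @return clipped array of the same shape.
#' @examples
#' hu_window(matrix(c(-1000, 0, 3000), 1)) # -150 0 250
#' @export
hu_window <- function(x, lo = -150, hi = 250) {
  if (lo >= hi) stop("invalid window: lo (", lo, ") must be below hi (", hi, ")")
  if (any(!is.finite(x))) stop("non-finite intensities in input")
  pmin(pmax(x, lo), hi)
}

#' Histogram equalization and min-max normalization
#'
#' Global 256-bin histogram equalization (the value-to-CDF mapping over the
#' slice's own range) followed by min-max scaling to `[0, 1]`.  A constant
#' slice maps to all zeros.
#'
#' @param x numeric matrix (one slice).
#' @param levels number of histogram bins.
#' @return matrix with values in `[0, 1]`.
#' @export
equalize_normalize <- function(x, levels = 256L) {
  rng <- range(x)
  if (rng[1] == rng[2]) {
    return(array(0, dim = dim(x)))
  }
  bin <- pmin(floor((x - rng[1]) / (rng[2] - rng[1]) * levels), levels - 1L)
  cdf <- cumsum(tabulate(bin + 1L, nbins = levels)) / length(x)
  eq <- cdf[bin + 1L]
  out <- (eq - min(eq)) / (max(eq) - min(eq))
  dim(out) <- dim(x)
  out
}

#' Augmentation specification
#'
#' Random vertical flip plus a combined shift/scale/rotate warp, applied
#' identically to image and mask (bilinear vs nearest-neighbour sampling).
#' Limits follow common practice for CT slices: shifts and scalings within
#' 10 percent, rotations within 15 degrees, each transform applied with
#' probability one half.
#'
#' @param vflip_prob probability of a vertical flip.
#' @param shift_limit maximum shift, as a fraction of the extent.
#' @param scale_limit maximum relative scale change.
#' @param rotate_limit maximum rotation in degrees.
#' @param p probability of applying the shift/scale/rotate warp.
#' @export
augment_spec <- function(vflip_prob = 0.5, shift_limit = 0.1,
                         scale_limit = 0.1, rotate_limit = 15, p = 0.5) {
  stopifnot(
    vflip_prob >= 0, vflip_prob <= 1, p >= 0, p <= 1,
    shift_limit >= 0, scale_limit >= 0, rotate_limit >= 0
  )
  structure(
    list(
      vflip_prob = vflip_prob, shift_limit = shift_limit,
      scale_limit = scale_limit, rotate_limit = rotate_limit, p = p
    ),
    class = "augment_spec"
  )
}

#' Augment an image/mask pair
#'
#' Draws one random geometric transform from `spec` (using the current RNG
#' state, so a seeded caller gets reproducible sequences) and applies it to
#' both inputs: the image with bilinear interpolation, the mask with
#' nearest-neighbour so it stays strictly binary.
#'
#' @param image numeric matrix.
#' @param mask binary matrix of the same extent.
#' @param spec an [augment_spec()].
#' @return list with `image` and `mask`.
#' @export
augment_pair <- function(image, mask, spec = augment_spec()) {
  if (!all(dim(image) == dim(mask))) {
    stop("image and mask extents differ")
  }
  if (stats::runif(1) < spec$vflip_prob) {
    image <- image[rev(seq_len(nrow(image))), , drop = FALSE]
    mask <- mask[rev(seq_len(nrow(mask))), , drop = FALSE]
  }
  if (stats::runif(1) < spec$p) {
    ang <- stats::runif(1, -spec$rotate_limit, spec$rotate_limit) * pi / 180
    scl <- 1 + stats::runif(1, -spec$scale_limit, spec$scale_limit)
    dy <- stats::runif(1, -spec$shift_limit, spec$shift_limit) * nrow(image)
    dx <- stats::runif(1, -spec$shift_limit, spec$shift_limit) * ncol(image)
    cy <- (nrow(image) - 1) / 2
    cx <- (ncol(image) - 1) / 2
    # inverse map: output pixel -> source coordinates
    ca <- cos(ang) / scl
    sa <- sin(ang) / scl
    m <- c(
      ca, -sa, cy - ca * (cy + dy) + sa * (cx + dx),
      sa, ca, cx - sa * (cy + dy) - ca * (cx + dx)
    )
    image <- cpp_affine_warp(image, m, TRUE, 0)
    mask <- cpp_affine_warp(mask, m, FALSE, 0)
  }
  list(image = image, mask = mask)
}

#' Deterministic train/test split
#'
#' Randomly splits items at the given ratio.  In volume mode every slice of
#' a volume lands on the same side, so there is no cross-volume leakage by
#' construction.
#'
#' @param n number of items (slices), or a vector of item ids.
#' @param ratio two integers, train:test (default 4:1).
#' @param mode `"slice"` or `"volume"`.
#' @param volume_ids vector assigning each item to a volume (required in
#'   volume mode).
#' @param seed optional integer seed.
#' @return list with integer index vectors `train` and `test`.
#' @export
split_dataset <- function(n, ratio = c(4L, 1L), mode = c("slice", "volume"),
                          volume_ids = NULL, seed = NULL) {
  mode <- match.arg(mode)
  ids <- if (length(n) == 1L) seq_len(n) else seq_along(n)
  if (length(ids) < 5L) stop("need at least 5 items to split 4:1")
  if (!is.null(seed)) set.seed(seed)
  frac <- ratio[2] / sum(ratio)
  if (mode == "slice") {
    n_test <- max(1L, round(length(ids) * frac))
    test <- sort(sample(ids, n_test))
  } else {
    if (is.null(volume_ids)) stop("volume mode needs volume_ids")
    vols <- unique(volume_ids)
    if (length(vols) < 5L) stop("need at least 5 volumes to split 4:1")
    n_test <- max(1L, round(length(vols) * frac))
    test_vols <- sample(vols, n_test)
    test <- sort(ids[volume_ids %in% test_vols])
  }
  list(train = setdiff(ids, test), test = test)
}

#' Select slices carrying tumour annotations
#'
#' Keeps the slices whose mask has at least `min_pixels` foreground pixels,
#' the selection rule applied before training.
#'
#' @param masks array `(h, w, n)`.
#' @param min_pixels minimum tumour pixel count (default 1).
#' @return integer indices of the retained slices.
#' @export
select_tumor_slices <- function(masks, min_pixels = 1L) {
  which(apply(masks, 3L, sum) >= min_pixels)
}

#' Full preprocessing of a raw HU stack
#'
#' Windowing, equalization and normalization applied slice-wise.
#'
#' @param hu array `(h, w, n)` of raw Hounsfield units.
#' @param lo,hi window bounds.
#' @return array `(h, w, n)` with values in `[0, 1]`.
#' @export
preprocess_slices <- function(hu, lo = -150, hi = 250) {
  out <- array(0, dim = dim(hu))
  for (i in seq_len(dim(hu)[3])) {
    out[, , i] <- equalize_normalize(hu_window(hu[, , i], lo, hi))
  }
  out
}
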