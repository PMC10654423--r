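# Synthetic CT phantoms: an elliptical "liver" field on a darker abdominal
# background, containing a variable number of darker tumour blobs with
# blurred (fuzzy) boundaries and additive Gaussian noise.  The phantom
# emulates the intensity structure the segmentation method assumes; it does
# not attempt anatomical realism.

#' Phantom specification
#'
#' Defaults are chosen so that a small network can learn the task on CPU in
#' minutes while the signal survives the standard preprocessing chain:
#' background -100 HU, liver 60 HU, tumours at 60 minus `contrast` HU (all
#' inside the `[-150, 250]` HU window), boundary blur sigma 1.5 px, noise
#' sigma 10 HU, one to three tumours of radius 3-12 px on a 96 px slice.
#'
#' @param extent slice extent in pixels (square, at least 32).
#' @param background,liver_hu background and liver intensities in HU.
#' @param contrast tumour-to-liver contrast in HU (tumours are darker).
#' @param tumor_count integer range `c(min, max)` of tumours per slice.
#' @param tumor_radius radius range in pixels.
#' @param blur_sigma boundary blur (Gaussian sigma, pixels).
#' @param noise_sigma additive Gaussian noise (HU).
#' @param liver_axes semi-axis range as a fraction of the extent.
#' @param slices_per_volume volume length used by [phantom_dataset()].
#' @param spacing in-plane pixel spacing in mm (written to NIfTI headers).
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(extent = 96L, background = -100, liver_hu = 60,
                         contrast = 45, tumor_count = c(1L, 3L),
                         tumor_radius = c(3, 12), blur_sigma = 1.5,
                         noise_sigma = 10, liver_axes = c(0.28, 0.40),
                         slices_per_volume = 20L, spacing = c(0.7, 0.7)) {
  stopifnot(
    extent >= 32L, all(tumor_count >= 0L), tumor_count[1] <= tumor_count[2],
    all(tumor_radius > 0), tumor_radius[1] <= tumor_radius[2],
    blur_sigma >= 0, noise_sigma >= 0
  )
  structure(
    list(
      extent = as.integer(extent), background = background,
      liver_hu = liver_hu, contrast = contrast,
      tumor_count = as.integer(tumor_count), tumor_radius = tumor_radius,
      blur_sigma = blur_sigma, noise_sigma = noise_sigma,
      liver_axes = liver_axes, slices_per_volume = as.integer(slices_per_volume),
      spacing = spacing
    ),
    class = "phantom_spec"
  )
}

gaussian_blur <- function(m, sigma) {
  if (sigma <= 0) {
    return(m)
  }
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k <- k / sum(k)
  x <- array(m, dim = c(nrow(m), ncol(m), 1L, 1L))
  # separable blur via two 1-d convolutions with replicated-edge padding
  pad_conv <- function(x, kv, vertical) {
    kh <- if (vertical) length(kv) else 1L
    kw <- if (vertical) 1L else length(kv)
    w <- array(kv, dim = c(kh, kw, 1L, 1L))
    # replicate edges by reflecting the pad zone into the array first
    H <- dim(x)[1]
    W <- dim(x)[2]
    if (vertical) {
      xp <- array(0, dim = c(H + 2L * r, W, 1L, 1L))
      xp[r + seq_len(H), , 1L, 1L] <- x[, , 1L, 1L]
      xp[seq_len(r), , 1L, 1L] <- x[rep(1L, r), , 1L, 1L]
      xp[H + r + seq_len(r), , 1L, 1L] <- x[rep(H, r), , 1L, 1L]
    } else {
      xp <- array(0, dim = c(H, W + 2L * r, 1L, 1L))
      xp[, r + seq_len(W), 1L, 1L] <- x[, , 1L, 1L]
      xp[, seq_len(r), 1L, 1L] <- x[, rep(1L, r), 1L, 1L]
      xp[, W + r + seq_len(r), 1L, 1L] <- x[, rep(W, r), 1L, 1L]
    }
    cpp_conv_fwd(xp, w, numeric(0), 1L, 0L, FALSE)
  }
  x <- pad_conv(x, k, TRUE)
  x <- pad_conv(x, k, FALSE)
  matrix(x, nrow = nrow(m))
}

#' Generate one phantom slice
#'
#' @param spec a [phantom_spec()].
#' @param liver optional fixed liver ellipse (list with `cy`, `cx`, `ay`,
#'   `ax`, `theta`), e.g. shared across a volume's slices.
#' @param max_retries placement attempts per tumour before giving up.
#' @return list with `image` (HU matrix), `mask` (binary matrix, 1 exactly
#'   on the pre-blur tumour supports), `liver` (the ellipse used),
#'   `n_tumors` and `radii`.
#' @export
phantom_slice <- function(spec = phantom_spec(), liver = NULL,
                          max_retries = 100L) {
  E <- spec$extent
  if (is.null(liver)) {
    liver <- list(
      cy = E / 2 + runif(1, -0.05, 0.05) * E,
      cx = E / 2 + runif(1, -0.05, 0.05) * E,
      ay = runif(1, spec$liver_axes[1], spec$liver_axes[2]) * E,
      ax = runif(1, spec$liver_axes[1], spec$liver_axes[2]) * E,
      theta = runif(1, 0, pi)
    )
  }
  yy <- matrix(seq_len(E), E, E)
  xx <- t(yy)
  ct <- cos(liver$theta)
  st <- sin(liver$theta)
  u <- (yy - liver$cy) * ct + (xx - liver$cx) * st
  v <- -(yy - liver$cy) * st + (xx - liver$cx) * ct
  inside <- (u / liver$ay)^2 + (v / liver$ax)^2 <= 1
  # uniform over {min, ..., max}; sample.int avoids R's scalar-sample gotcha
  n_tum <- spec$tumor_count[1] +
    sample.int(spec$tumor_count[2] - spec$tumor_count[1] + 1L, 1L) - 1L
  mask <- matrix(0, E, E)
  radii <- numeric(n_tum)
  for (t in seq_len(n_tum)) {
    # the radius is drawn once so its distribution stays uniform; only the
    # position is re-sampled on rejection
    r <- runif(1, spec$tumor_radius[1], spec$tumor_radius[2])
    ay2 <- liver$ay - r
    ax2 <- liver$ax - r
    placed <- FALSE
    if (ay2 >= 1 && ax2 >= 1) {
      for (try in seq_len(max_retries)) {
        # centre inside the ellipse shrunk by r: the whole disc then fits
        ty <- runif(1, 1, E)
        tx <- runif(1, 1, E)
        uu <- (ty - liver$cy) * ct + (tx - liver$cx) * st
        vv <- -(ty - liver$cy) * st + (tx - liver$cx) * ct
        if ((uu / ay2)^2 + (vv / ax2)^2 <= 1) {
          mask[(yy - ty)^2 + (xx - tx)^2 <= r^2] <- 1
          radii[t] <- r
          placed <- TRUE
          break
        }
      }
    }
    if (!placed) {
      stop(
        "could not place a tumour of radius ", round(r, 1),
        " px inside the liver ellipse after ", max_retries, " attempts"
      )
    }
  }
  img <- matrix(spec$background, E, E)
  img[inside] <- spec$liver_hu
  img[mask > 0] <- spec$liver_hu - spec$contrast
  img <- gaussian_blur(img, spec$blur_sigma)
  if (spec$noise_sigma > 0) {
    img <- img + matrix(rnorm(E * E, 0, spec$noise_sigma), E, E)
  }
  list(image = img, mask = mask, liver = liver, n_tumors = n_tum, radii = radii)
}

#' Generate a phantom dataset
#'
#' Produces `n_volumes` volumes of `spec$slices_per_volume` slices each; the
#' liver ellipse is fixed within a volume, tumours vary per slice.  With an
#' output directory, image and mask volumes are written as NIfTI (with the
#' spec's pixel spacing in the header) together with a CSV manifest.
#'
#' @param spec a [phantom_spec()].
#' @param n_volumes number of volumes.
#' @param out_dir optional output directory for NIfTI files + manifest.
#' @param seed optional integer seed.
#' @return list with `images` and `masks` (arrays `(h, w, n)`),
#'   `volume_ids`, `slice_index` and `manifest` (data frame).
#' @export
phantom_dataset <- function(spec = phantom_spec(), n_volumes = 10L,
                            out_dir = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  E <- spec$extent
  S <- spec$slices_per_volume
  n <- n_volumes * S
  images <- array(0, dim = c(E, E, n))
  masks <- array(0, dim = c(E, E, n))
  volume_ids <- integer(n)
  slice_index <- integer(n)
  manifest <- vector("list", n_volumes)
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  for (v in seq_len(n_volumes)) {
    liver <- NULL
    tum_px <- integer(S)
    for (s in seq_len(S)) {
      sl <- phantom_slice(spec, liver = liver)
      liver <- sl$liver
      i <- (v - 1L) * S + s
      images[, , i] <- sl$image
      masks[, , i] <- sl$mask
      volume_ids[i] <- v
      slice_index[i] <- s
      tum_px[s] <- sum(sl$mask)
    }
    manifest[[v]] <- data.frame(
      volume = v, slices = S,
      tumor_slices = sum(tum_px > 0), mean_tumor_pixels = mean(tum_px)
    )
    if (!is.null(out_dir)) {
      idx <- (v - 1L) * S + seq_len(S)
      img_arr <- images[, , idx]
      attr(img_arr, "pixdim") <- c(spec$spacing, 5)
      img_nii <- RNifti::asNifti(img_arr)
      msk_arr <- masks[, , idx]
      attr(msk_arr, "pixdim") <- c(spec$spacing, 5)
      msk_nii <- RNifti::asNifti(msk_arr, datatype = "uint8")
      RNifti::writeNifti(img_nii, file.path(out_dir, sprintf("vol%03d_image.nii.gz", v)))
      RNifti::writeNifti(msk_nii, file.path(out_dir, sprintf("vol%03d_mask.nii.gz", v)))
    }
  }
  manifest <- do.call(rbind, manifest)
  if (!is.null(out_dir)) {
    write.csv(manifest, file.path(out_dir, "manifest.csv"), row.names = FALSE)
  }
  list(
    images = images, masks = masks, volume_ids = volume_ids,
    slice_index = slice_index, manifest = manifest
  )
}

#' Read a phantom (or any 2-D+slices) NIfTI dataset directory
#'
#' Expects the `volNNN_image.nii.gz` / `volNNN_mask.nii.gz` layout written
#' by [phantom_dataset()].
#'
#' @param dir dataset directory.
#' @return list as returned by [phantom_dataset()] (without a manifest).
#' @export
read_nifti_dataset <- function(dir) {
  imgs <- sort(list.files(dir, "_image\\.nii(\\.gz)?$", full.names = TRUE))
  if (length(imgs) == 0) stop("no *_image.nii[.gz] files in ", dir)
  images <- NULL
  masks <- NULL
  volume_ids <- integer(0)
  spacing <- NULL
  for (v in seq_along(imgs)) {
    im <- RNifti::readNifti(imgs[v])
    mk <- RNifti::readNifti(sub("_image\\.nii", "_mask.nii", imgs[v]))
    if (is.null(spacing)) spacing <- RNifti::pixdim(im)[1:2]
    a <- as.array(im)
    b <- as.array(mk)
    if (length(dim(a)) == 2L) {
      a <- array(a, dim = c(dim(a), 1L))
      b <- array(b, dim = c(dim(b), 1L))
    }
    images <- if (is.null(images)) a else {
      arr <- array(0, dim = c(dim(a)[1:2], dim(images)[3] + dim(a)[3]))
      arr[, , seq_len(dim(images)[3])] <- images
      arr[, , dim(images)[3] + seq_len(dim(a)[3])] <- a
      arr
    }
    masks <- if (is.null(masks)) b else {
      arr <- array(0, dim = c(dim(b)[1:2], dim(masks)[3] + dim(b)[3]))
      arr[, , seq_len(dim(masks)[3])] <- masks
      arr[, , dim(masks)[3] + seq_len(dim(b)[3])] <- b
      arr
    }
    volume_ids <- c(volume_ids, rep(v, dim(a)[3]))
  }
  list(
    images = images, masks = masks, volume_ids = volume_ids,
    spacing = spacing
  )
}
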