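# The phantom generator: determinism, geometric containment, sampling
# distributions and NIfTI round-trips.

test_that("a zero tumour-count range yields an empty mask", {
  set.seed(1)
  sl <- phantom_slice(phantom_spec(tumor_count = c(0L, 0L)))
  expect_equal(sum(sl$mask), 0)
})

test_that("generation is bit-reproducible under a fixed seed", {
  set.seed(99)
  a <- phantom_slice(phantom_spec())
  set.seed(99)
  b <- phantom_slice(phantom_spec())
  expect_identical(a$image, b$image)
  expect_identical(a$mask, b$mask)
})

test_that("tumour masks are contained in the liver ellipse", {
  set.seed(2)
  for (i in 1:10) {
    sl <- phantom_slice(phantom_spec())
    L <- sl$liver
    idx <- which(sl$mask > 0, arr.ind = TRUE)
    u <- (idx[, 1] - L$cy) * cos(L$theta) + (idx[, 2] - L$cx) * sin(L$theta)
    v <- -(idx[, 1] - L$cy) * sin(L$theta) + (idx[, 2] - L$cx) * cos(L$theta)
    expect_true(all((u / L$ay)^2 + (v / L$ax)^2 <= 1 + 1e-9))
  }
})

test_that("the tumour signal survives windowing and equalization", {
  set.seed(3)
  sl <- phantom_slice(phantom_spec())
  img <- equalize_normalize(hu_window(sl$image))
  inside <- sl$mask > 0
  liver_only <- !inside & ((sl$image > 30)) # bright liver region
  expect_gt(sum(inside), 0)
  # tumours are darker than surrounding liver after the full pipeline
  expect_lt(mean(img[inside]), mean(img[liver_only]) - 0.05)
})

test_that("mean tumour count matches the uniform-range mean", {
  set.seed(4)
  spec <- phantom_spec(tumor_count = c(1L, 5L), tumor_radius = c(2, 4))
  counts <- vapply(1:500, function(i) phantom_slice(spec)$n_tumors, numeric(1))
  expect_lt(abs(mean(counts) - 3), 0.2)
  expect_setequal(sort(unique(counts)), 1:5)
})

test_that("tumour radii are uniform over the stated range", {
  set.seed(6)
  spec <- phantom_spec(tumor_count = c(1L, 2L))
  radii <- unlist(lapply(1:500, function(i) phantom_slice(spec)$radii))
  expect_gt(length(radii), 500)
  expect_gte(min(radii), 3)
  expect_lte(max(radii), 12)
  ks <- suppressWarnings(stats::ks.test(radii, "punif", 3, 12))
  expect_gt(ks$p.value, 1e-4)
})

test_that("an impossible placement raises a generation error", {
  spec <- phantom_spec(
    extent = 32L, tumor_radius = c(30, 31),
    tumor_count = c(1L, 1L), liver_axes = c(0.2, 0.25)
  )
  set.seed(7)
  expect_error(phantom_slice(spec), "could not place")
})

test_that("datasets round-trip through NIfTI bit-identically", {
  dir <- tempfile("phantoms")
  ds <- phantom_dataset(phantom_spec(extent = 48L, slices_per_volume = 4L),
    n_volumes = 2L, out_dir = dir, seed = 8
  )
  expect_equal(dim(ds$images), c(48, 48, 8))
  expect_equal(nrow(ds$manifest), 2)
  expect_length(list.files(dir, "_image\\.nii\\.gz$"), 2)
  expect_length(list.files(dir, "_mask\\.nii\\.gz$"), 2)
  back <- read_nifti_dataset(dir)
  expect_identical(back$masks, ds$masks)
  expect_equal(back$images, ds$images, tolerance = 1e-6)
  expect_equal(back$volume_ids, ds$volume_ids)
  expect_equal(back$spacing, c(0.7, 0.7), tolerance = 1e-6)
  unlink(dir, recursive = TRUE)
})

test_that("downstream slice selection removes exactly the empty masks", {
  ds <- phantom_dataset(
    phantom_spec(
      extent = 48L, tumor_count = c(0L, 2L),
      slices_per_volume = 10L
    ),
    n_volumes = 2L, seed = 9
  )
  keep <- select_tumor_slices(ds$masks)
  sums <- apply(ds$masks, 3, sum)
  expect_equal(keep, which(sums > 0))
  expect_gt(length(keep), 0)
  expect_lt(length(keep), 20) # some slices drew zero tumours
})
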