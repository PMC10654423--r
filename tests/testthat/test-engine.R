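# Training orchestration: the Dice loss, the learning-rate schedule,
# checkpoint selection, short smoke training, evaluation plumbing,
# visualization, checkpoints and the command-line front end.

test_that("soft Dice loss reproduces closed-form toy values", {
  p <- array(0.5, dim = c(2, 2, 1, 1))
  t2 <- array(c(1, 1, 0, 0), dim = c(2, 2, 1, 1))
  expect_equal(dice_loss(p, t2), 1 - (2 * 1 + 1) / (2 + 2 + 1)) # 0.4
  tb <- array(c(1, 0, 1, 0), dim = c(2, 2, 1, 1))
  expect_equal(dice_loss(tb, tb), 0) # exact identity, any smooth
  set.seed(1)
  for (i in 1:10) {
    pr <- array(runif(32, 0.001, 0.999), dim = c(4, 4, 2, 1))
    tr <- array(rbinom(32, 1, 0.4), dim = c(4, 4, 2, 1))
    l <- dice_loss(pr, tr)
    expect_gte(l, 0)
    expect_lte(l, 1)
  }
  expect_error(dice_loss(p, array(0, dim = c(3, 3, 1, 1))), "shapes differ")
})

test_that("the step-decay schedule hits the protocol values", {
  expect_equal(lr_at_epoch(1), 1e-4)
  expect_equal(lr_at_epoch(29), 1e-4)
  expect_equal(lr_at_epoch(30), 1e-5)
  expect_equal(lr_at_epoch(59), 1e-5)
  expect_equal(lr_at_epoch(60), 1e-6)
  expect_equal(lr_at_epoch(80), 1e-6)
})

test_that("checkpoint selection takes the argmax of logged test Dice", {
  h <- data.frame(epoch = 1:6, test_dice = c(0.1, 0.5, 0.48, 0.62, 0.61, 0.3))
  expect_equal(select_best_epoch(h), 4)
})

test_that("short training runs reduce the loss in most seeded trials", {
  cfg <- manet_config(encoder_widths = c(4L, 8L), bridge_width = 16L)
  wins <- 0
  for (seed in 1:5) {
    set.seed(seed)
    ph <- phantom_dataset(
      phantom_spec(extent = 64L, tumor_radius = c(4, 10)),
      n_volumes = 1L, seed = seed
    )
    imgs <- preprocess_slices(ph$images[, , 1:16])
    # augmentation off: the check isolates the optimizer making progress on
    # a fixed sample rather than the augmentation resampling noise
    fit <- manet(imgs, ph$masks[, , 1:16],
      config = cfg, epochs = 2,
      seed = seed, augment = NULL, verbose = FALSE
    )
    if (fit$history$loss[2] < fit$history$loss[1]) wins <- wins + 1
  }
  expect_gte(wins, 4)
})

test_that("training is bit-reproducible under a fixed seed", {
  cfg <- manet_config(encoder_widths = c(4L, 8L), bridge_width = 16L)
  ph <- phantom_dataset(phantom_spec(extent = 64L), n_volumes = 1L, seed = 3)
  imgs <- preprocess_slices(ph$images[, , 1:8])
  f1 <- manet(imgs, ph$masks[, , 1:8],
    config = cfg, epochs = 1, seed = 11,
    verbose = FALSE
  )
  f2 <- manet(imgs, ph$masks[, , 1:8],
    config = cfg, epochs = 1, seed = 11,
    verbose = FALSE
  )
  expect_identical(f1$history$loss, f2$history$loss)
  expect_identical(f1$params, f2$params)
})

test_that("training aborts with a diagnostic on empty or bad input", {
  cfg <- manet_config(encoder_widths = c(4L, 8L), bridge_width = 16L)
  expect_error(
    manet(array(0, dim = c(16, 16)), NULL, config = cfg, epochs = 1),
    "array of slices"
  )
})

test_that("evaluation of a perfect and of an empty prediction behaves", {
  truth <- array(0, dim = c(16, 16, 3))
  truth[5:8, 5:8, ] <- 1
  perfect <- segmentation_report(truth, truth)
  expect_equal(perfect$aggregate$mean[perfect$aggregate$metric == "dice"], 1)
  expect_equal(perfect$aggregate$mean[perfect$aggregate$metric == "voe"], 0)
  none <- segmentation_report(array(0, dim = dim(truth)), truth)
  expect_equal(none$aggregate$mean[none$aggregate$metric == "dice"], 0)
  expect_equal(none$n_non_segmentation, 3)
})

test_that("evaluate_manet agrees with a manual predict + report pipeline", {
  cfg <- manet_config(encoder_widths = c(4L, 8L), bridge_width = 16L)
  ph <- phantom_dataset(phantom_spec(extent = 32L, slices_per_volume = 4L, tumor_radius = c(2, 5)),
    n_volumes = 2L, seed = 5
  )
  imgs <- preprocess_slices(ph$images)
  m <- manet(config = cfg, epochs = 0, seed = 2)
  r1 <- evaluate_manet(m, imgs, ph$masks,
    grouping = "volume",
    volume_ids = ph$volume_ids
  )
  pred <- predict(m, imgs, type = "mask")
  r2 <- segmentation_report(pred, ph$masks > 0.5,
    grouping = "volume",
    volume_ids = ph$volume_ids
  )
  expect_equal(r1$cases, r2$cases)
  expect_equal(nrow(r1$cases), 2)
})

test_that("feature visualization scales to [0,1] with mid-gray degeneracy", {
  ns <- asNamespace("manet")
  expect_equal(ns$minmax_scale(matrix(3, 4, 4)), matrix(0.5, 4, 4))
  cfg <- manet_config(encoder_widths = c(4L, 8L), bridge_width = 16L)
  m <- manet(config = cfg, epochs = 0, seed = 6)
  x <- matrix(runif(32 * 32), 32)
  dir <- tempfile("viz")
  maps <- visualize_features(m, x,
    layers = c("enc1", "bridge", "dec2", "dec2_sa_att", "output"), dir = dir
  )
  for (mm in maps) {
    expect_gte(min(mm), 0)
    expect_lte(max(mm), 1)
  }
  expect_length(list.files(dir, "\\.png$"), 5)
  expect_error(visualize_features(m, x, layers = "nope"), "unknown layer")
  unlink(dir, recursive = TRUE)
})

test_that("zero-initialized attention halves the gated map before scaling", {
  ns <- asNamespace("manet")
  cfg <- manet_config(encoder_widths = c(4L, 8L), bridge_width = 16L)
  m <- manet(config = cfg, epochs = 0, seed = 7)
  # zero the decoder-2 spatial-attention weights: gate becomes exactly 0.5
  m$params[["dec2.sa.conv.w"]][] <- 0
  m$params[["dec2.sa.conv.b"]][] <- 0
  x <- matrix(runif(32 * 32), 32)
  st <- ns$state_as_env(m$state)
  fw <- ns$nn_forward(cfg, m$params, st,
    ns$make_inputs(array(x, dim = c(32, 32, 1)), 1L, 3L),
    training = FALSE, capture = c("dec2_pre_sa", "dec2_sa_att")
  )
  expect_equal(fw$captures$dec2_sa_att,
    array(0.5, dim = dim(fw$captures$dec2_sa_att)),
    tolerance = 1e-12
  )
})

test_that("checkpoints round-trip with identical predictions", {
  cfg <- manet_config(encoder_widths = c(4L, 8L), bridge_width = 16L)
  ph <- phantom_dataset(phantom_spec(extent = 32L, slices_per_volume = 4L, tumor_radius = c(2, 5)),
    n_volumes = 1L, seed = 8
  )
  imgs <- preprocess_slices(ph$images)
  fit <- manet(imgs, ph$masks,
    config = cfg, epochs = 1, seed = 9,
    verbose = FALSE
  )
  path <- tempfile(fileext = ".rds")
  write_manet(fit, path)
  back <- read_manet(path)
  expect_identical(predict(back, imgs), predict(fit, imgs))
  expect_true(nzchar(back$config_yaml))
  unlink(path)
})

test_that("the ablation harness builds and scores requested variants", {
  tab <- run_ablation(
    variants = c("unet", "unet_rb", "manet"),
    data = phantom_dataset(phantom_spec(extent = 32L, slices_per_volume = 10L, tumor_radius = c(2, 5)),
      n_volumes = 2L, seed = 10
    ),
    epochs = 1L, seed = 10
  )
  expect_equal(tab$variant, c("unet", "unet_rb", "manet"))
  expect_true(all(c("dice", "assd", "voe", "sensitivity") %in% names(tab)))
  expect_lt(tab$parameters[1], tab$parameters[3])
  expect_error(run_ablation(variants = "bogus"), "unknown variant")
})

test_that("the summarize subcommand prints and writes the trace", {
  dir <- tempfile("cli")
  dir.create(dir)
  out <- capture.output(
    manet_cli(c("summarize", "--variant", "manet", "--input-size", "64", "--out", dir))
  )
  expect_true(any(grepl("Conv 15", out)))
  expect_true(any(grepl("7.82 M", out)))
  expect_true(file.exists(file.path(dir, "layer_trace.csv")))
  unlink(dir, recursive = TRUE)
})
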