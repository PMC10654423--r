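# Architecture assembly: parameter accounting against an independent tally,
# trace fidelity, forward-pass contracts and the variant factory.

test_that("parameter count equals the independent longhand tally on a toy net", {
  cfg <- manet_config(encoder_widths = c(4L, 8L, 16L), bridge_width = 32L)
  expect_equal(count_parameters(cfg), oracle_manet_params(c(4, 8, 16), 32))
  cfg2 <- manet_config(encoder_widths = c(17L, 34L, 68L), bridge_width = 136L)
  expect_equal(count_parameters(cfg2), oracle_manet_params(c(17, 34, 68), 136))
})

test_that("analytic parameter count equals the sum over initialized arrays", {
  for (v in c("manet", "unet", "unet_rb", "unet_all_attn")) {
    cfg <- manet_config(variant = v, encoder_widths = c(4L, 8L, 16L), bridge_width = 32L)
    m <- manet(config = cfg, epochs = 0, seed = 1)
    expect_equal(count_parameters(m), count_parameters(cfg), info = v)
  }
})

test_that("single-layer accounting identities hold", {
  tr <- trace_layers(manet_config())
  head_row <- tr[tr$operation == "Conv 15", ]
  expect_equal(head_row$params, 34 * 3 + 3) # bias-free part: 1x1, 34 -> 3
  conv14 <- tr[tr$operation == "Conv 14", ]
  expect_equal(conv14$macs, 9 * 68 * 34 * 512^2)
  # a 3x3 conv, 1 -> 1 channel, on a 4x4 output grid costs 9 x 16 MACs
  expect_equal(9 * 1 * 1 * 4^2, 144)
})

test_that("MAC total equals an independent per-layer enumeration on a toy net", {
  e <- c(4, 8, 16)
  B <- 32
  sz <- 64
  conv_macs <- function(k, a, b, out) k * k * a * b * out^2
  s <- conv_macs(3, 3, 4, 64) + conv_macs(3, 4, 4, 64) + conv_macs(1, 3, 4, 64) +
    2 * (4 * 2 + 2 * 4) +
    conv_macs(3, 4, 8, 32) + conv_macs(3, 8, 8, 32) + conv_macs(1, 4, 8, 32) +
    2 * (8 * 4 + 4 * 8) +
    conv_macs(3, 8, 16, 16) + conv_macs(3, 16, 16, 16) + conv_macs(1, 8, 16, 16) +
    2 * (16 * 8 + 8 * 16) +
    conv_macs(3, 16, 32, 8) + conv_macs(3, 32, 32, 8) + conv_macs(1, 16, 32, 8) +
    2 * (32 * 16 + 16 * 32) + conv_macs(7, 2, 1, 8) +
    # decoder 1: upconv 32 -> 16 at 16^2, SA, SCAG at 8^2, convs (16+16) -> 8 -> 8
    4 * 32 * 16 * 16^2 + conv_macs(7, 2, 1, 16) +
    (16 * 8 + 32 * 8 + 8) * 8^2 +
    conv_macs(3, 32, 8, 16) + conv_macs(3, 8, 8, 16) +
    # decoder 2: upconv 8 -> 8 at 32^2, SCAG gate at 16^2
    4 * 8 * 8 * 32^2 + conv_macs(7, 2, 1, 32) +
    (8 * 4 + 8 * 4 + 4) * 16^2 +
    conv_macs(3, 16, 4, 32) + conv_macs(3, 4, 4, 32) +
    # decoder 3: upconv 4 -> 2 at 64^2, gate at 32^2, convs (2+4) -> 4 -> 2
    4 * 4 * 2 * 64^2 + conv_macs(7, 2, 1, 64) +
    (4 * 2 + 4 * 2 + 2) * 32^2 +
    conv_macs(3, 6, 4, 64) + conv_macs(3, 4, 2, 64) +
    2 * 3 * 64^2
  cfg <- manet_config(encoder_widths = e, bridge_width = B)
  expect_equal(count_macs(cfg, sz), s)
})

test_that("the layer trace scales spatially but not in width at half input", {
  t1 <- trace_layers(manet_config(), 512)
  t2 <- trace_layers(manet_config(), 256)
  expect_equal(t1$filters, t2$filters)
  o1 <- as.integer(sub("x.*", "", t1$output[t1$op != "dense"]))
  o2 <- as.integer(sub("x.*", "", t2$output[t2$op != "dense"]))
  expect_equal(o1, 2L * o2)
})

test_that("forward pass honours the shape contract and the (0,1) range", {
  cfg <- manet_config(encoder_widths = c(4L, 8L, 16L), bridge_width = 32L)
  m <- manet(config = cfg, epochs = 0, seed = 3)
  x <- array(runif(64 * 64 * 3), dim = c(64, 64, 3, 1))
  p <- predict(m, x)
  expect_equal(dim(p), c(64, 64, 3, 1))
  expect_true(all(p > 0 & p < 1))
  # indivisible extent names the required divisor
  bad <- array(runif(60 * 60 * 3), dim = c(60, 60, 3, 1))
  expect_error(predict(m, bad), "divisible by 8")
  wrongc <- array(runif(64 * 64 * 2), dim = c(64, 64, 2, 1))
  expect_error(predict(m, wrongc), "expects 3")
})

test_that("evaluation-mode forward is deterministic", {
  cfg <- manet_config(encoder_widths = c(4L, 8L, 16L), bridge_width = 32L)
  m <- manet(config = cfg, epochs = 0, seed = 4)
  x <- array(runif(32 * 32 * 3), dim = c(32, 32, 3, 2))
  expect_identical(predict(m, x), predict(m, x))
})

test_that("all eight ablation variants build and parameters grow monotonically", {
  base <- function(v) {
    manet_config(
      variant = v, encoder_widths = c(4L, 8L, 16L),
      bridge_width = 32L
    )
  }
  counts <- vapply(manet_variants, function(v) count_parameters(base(v)), numeric(1))
  rb <- counts[["unet_rb"]]
  for (v in c("unet_rb_scag", "unet_rb_ca", "unet_rb_sa", "unet_rb_cbam")) {
    expect_gt(counts[[v]], rb)
    expect_lt(counts[[v]], counts[["manet"]])
  }
  expect_gt(counts[["manet"]], counts[["unet_all_attn"]])
  expect_lt(counts[["unet"]], counts[["unet_rb"]])
  expect_error(manet_config(variant = "nope"), "should be one of")
})

test_that("one optimization step moves every trainable parameter group", {
  cfg <- manet_config(encoder_widths = c(4L, 8L), bridge_width = 16L)
  set.seed(5)
  x <- array(runif(16 * 16 * 8), dim = c(16, 16, 8))
  y <- array((matrix(runif(16 * 16 * 8), 16) > 0.8) * 1, dim = c(16, 16, 8))
  m0 <- manet(config = cfg, epochs = 0, seed = 6)
  m1 <- manet(x, y,
    config = cfg, epochs = 1, batch_size = 8, seed = 6,
    augment = NULL, verbose = FALSE
  )
  moved <- vapply(names(m0$params), function(nm) {
    any(m0$params[[nm]] != m1$params[[nm]])
  }, logical(1))
  expect_true(all(moved), info = paste(names(moved)[!moved], collapse = ", "))
})
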