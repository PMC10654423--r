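# The seven evaluation metrics against set-arithmetic and all-pairs
# distance oracles, plus their algebraic invariants and aggregation modes.

test_that("confusion counts match brute-force set arithmetic", {
  a <- matrix(0, 8, 8)
  a[1:3, 1:3] <- 1
  b <- matrix(0, 8, 8)
  b[2:4, 2:4] <- 1
  cc <- confusion_counts(a, b)
  expect_equal(cc, list(TP = 4, TN = 50, FP = 5, FN = 5))
  expect_equal(cc$TP + cc$TN + cc$FP + cc$FN, 64)
  full <- matrix(1, 4, 4)
  expect_equal(confusion_counts(full, full), list(TP = 16, TN = 0, FP = 0, FN = 0))
  none <- matrix(0, 4, 4)
  expect_equal(confusion_counts(none, none)$TN, 16)
  expect_error(confusion_counts(matrix(2, 2, 2), matrix(0, 2, 2)), "binary")
})

test_that("overlap metrics follow the printed formulas", {
  om <- overlap_metrics(list(TP = 4, TN = 50, FP = 5, FN = 5))
  expect_equal(om$dice, 8 / 18)
  expect_equal(om$jaccard, 4 / 14)
  expect_equal(om$voe, 1 - 4 / 14)
  expect_equal(om$accuracy, 54 / 64)
  expect_equal(om$sensitivity, 4 / 9)
  expect_equal(om$specificity, 50 / 55)
  # identity and disjoint cases
  a <- matrix(rbinom(64, 1, 0.4), 8)
  id <- overlap_metrics(a, a)
  expect_equal(id$dice, 1)
  expect_equal(id$voe, 0)
  expect_equal(id$sensitivity, 1)
  d1 <- matrix(0, 4, 4)
  d1[1, 1] <- 1
  d2 <- matrix(0, 4, 4)
  d2[4, 4] <- 1
  dis <- overlap_metrics(d1, d2)
  expect_equal(dis$dice, 0)
  expect_equal(dis$voe, 1)
})

test_that("empty-mask policy: both empty scores 1, sensitivity is missing", {
  z <- matrix(0, 4, 4)
  om <- overlap_metrics(z, z)
  expect_equal(om$dice, 1)
  expect_equal(om$jaccard, 1)
  expect_true(is.na(om$sensitivity))
  b <- z
  b[2, 2] <- 1
  om2 <- overlap_metrics(z, b) # predicted-empty-only
  expect_equal(om2$dice, 0)
  expect_true(is.na(assd(z, b)))
})

test_that("ASSD reproduces hand cases and is symmetric", {
  a <- matrix(0, 8, 8)
  a[1, 1] <- 1
  b <- matrix(0, 8, 8)
  b[4, 5] <- 1
  expect_equal(assd(a, b), 5) # 3-4-5 triangle
  expect_equal(assd(b, a), 5)
  m <- matrix(rbinom(64, 1, 0.3), 8)
  if (sum(m) > 0) expect_equal(assd(m, m), 0)
})

test_that("ASSD equals the all-pairs oracle on random masks", {
  set.seed(10)
  n_checked <- 0
  for (i in 1:60) {
    a <- random_mask()
    b <- random_mask()
    if (sum(a) == 0 || sum(b) == 0) next
    expect_equal(assd(a, b), oracle_assd(a, b), tolerance = 1e-9)
    n_checked <- n_checked + 1
  }
  expect_gt(n_checked, 15)
})

test_that("millimetre spacing scales ASSD", {
  a <- matrix(0, 8, 8)
  a[2, 2] <- 1
  b <- matrix(0, 8, 8)
  b[2, 6] <- 1
  expect_equal(assd(a, b, spacing = c(0.5, 0.5)), 2) # 4 px x 0.5 mm
  expect_equal(assd(a, b, spacing = c(2, 1)), 4) # column distance unscaled by row spacing
})

test_that("algebraic identities: dice from jaccard, voe complement", {
  set.seed(11)
  for (i in 1:25) {
    a <- random_mask()
    b <- random_mask()
    om <- overlap_metrics(a, b)
    expect_equal(om$voe + om$jaccard, 1)
    expect_equal(om$dice, 2 * om$jaccard / (1 + om$jaccard), tolerance = 1e-12)
  }
})

test_that("translating a mask away never decreases ASSD", {
  b <- matrix(0, 24, 24)
  b[10:13, 10:13] <- 1
  prev <- 0
  for (shift in 0:6) {
    a <- matrix(0, 24, 24)
    a[10:13 + shift, 10:13] <- 1
    cur <- assd(a, b)
    expect_gte(cur, prev)
    prev <- cur
  }
})

test_that("volume aggregation pools counts; slice aggregation averages", {
  # two volumes of two slices with deliberately unbalanced per-slice dice
  pred <- array(0, dim = c(8, 8, 4))
  truth <- array(0, dim = c(8, 8, 4))
  truth[1:4, 1:4, 1] <- 1
  pred[1:4, 1:4, 1] <- 1 # slice 1: perfect (TP 16)
  truth[1:2, 1:2, 2] <- 1
  pred[5:6, 5:6, 2] <- 1 # slice 2: disjoint (TP 0, FP 4, FN 4)
  truth[1:3, 1:3, 3] <- 1
  pred[1:3, 1:3, 3] <- 1
  truth[1, 1, 4] <- 1
  pred[1, 1, 4] <- 1
  vols <- c(1, 1, 2, 2)
  rs <- segmentation_report(pred, truth, grouping = "slice")
  rv <- segmentation_report(pred, truth, grouping = "volume", volume_ids = vols)
  expect_equal(rs$aggregate$mean[rs$aggregate$metric == "dice"], mean(c(1, 0, 1, 1)))
  # volume 1 pooled: TP 16, FP 4, FN 4 -> dice 32/40
  expect_equal(rv$cases$dice, c(32 / 40, 1))
  expect_equal(rv$aggregate$mean[rv$aggregate$metric == "dice"], mean(c(0.8, 1)))
  # population standard deviation
  expect_equal(
    rs$aggregate$sd[rs$aggregate$metric == "dice"],
    sqrt(mean((c(1, 0, 1, 1) - 0.75)^2))
  )
  # single case: sd 0
  r1 <- segmentation_report(
    pred[, , 1, drop = FALSE],
    truth[, , 1, drop = FALSE]
  )
  expect_equal(r1$aggregate$sd[r1$aggregate$metric == "dice"], 0)
})

test_that("non-segmentation cases are flagged and report zero dice", {
  pred <- array(0, dim = c(8, 8, 2))
  truth <- array(0, dim = c(8, 8, 2))
  truth[2:3, 2:3, ] <- 1
  r <- segmentation_report(pred, truth)
  expect_equal(r$n_non_segmentation, 2)
  expect_equal(r$cases$dice, c(0, 0))
  expect_true(all(is.na(r$cases$assd)))
})
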