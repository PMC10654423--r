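# The four attention operators against scalar-loop oracles, their neutrality
# at zero parameters, and the shape contracts of the published topology.

test_that("zero-initialized attention gates scale inputs by exactly one half", {
  set.seed(1)
  x <- array(rnorm(5 * 5 * 4 * 2), dim = c(5, 5, 4, 2))
  ca <- channel_attention(x, ca_params(4, init = "zero"))
  expect_equal(ca$att, array(0.5, dim = c(1, 1, 4, 2)))
  expect_equal(ca$out, 0.5 * x)
  sa <- spatial_attention(x, sa_params(init = "zero"))
  expect_equal(sa$att, array(0.5, dim = c(5, 5, 1, 2)))
  expect_equal(sa$out, 0.5 * x)
  g <- array(rnorm(3 * 3 * 6 * 2), dim = c(3, 3, 6, 2))
  xs <- array(rnorm(6 * 6 * 4 * 2), dim = c(6, 6, 4, 2))
  sc <- scag(xs, g, scag_params(4, 6, init = "zero"))
  expect_equal(sc$out, 0.5 * xs)
  expect_equal(cbam(x, ca_params(4, init = "zero"), sa_params(init = "zero")), 0.25 * x)
})

test_that("attention maps stay strictly inside (0, 1)", {
  set.seed(2)
  x <- array(rnorm(6 * 6 * 4 * 2, sd = 3), dim = c(6, 6, 4, 2))
  capar <- ca_params(4)
  sapar <- sa_params()
  expect_true(all(channel_attention(x, capar)$att > 0 & channel_attention(x, capar)$att < 1))
  expect_true(all(spatial_attention(x, sapar)$att > 0 & spatial_attention(x, sapar)$att < 1))
})

test_that("operators preserve the published shapes at full width", {
  # encoder-1 width 68 at 512^2, bridge width 544 at 64^2, encoder-3 skip
  x <- array(0.1, dim = c(512, 512, 68, 1))
  r <- channel_attention(x, ca_params(68, init = "zero"))
  expect_equal(dim(r$att), c(1, 1, 68, 1))
  expect_equal(dim(r$out), dim(x))
  rm(x, r)
  xb <- array(0.1, dim = c(64, 64, 544, 1))
  expect_equal(dim(cbam(xb, ca_params(544, init = "zero"), sa_params(init = "zero"))), dim(xb))
  rm(xb)
  xs <- array(0.1, dim = c(128, 128, 272, 1))
  g <- array(0.1, dim = c(64, 64, 544, 1))
  rs <- scag(xs, g, scag_params(272, 544, init = "zero"))
  expect_equal(dim(rs$out), c(128, 128, 272, 1))
  expect_equal(dim(rs$att), c(128, 128, 1, 1))
})

test_that("channel attention matches the scalar-loop oracle", {
  for (seed in 1:4) {
    set.seed(seed)
    c_ <- sample(c(2, 4), 1)
    x <- array(sample(-4:4, 4 * 4 * c_ * 2, replace = TRUE) / 2,
      dim = c(4, 4, c_, 2)
    )
    p <- list(
      w1 = matrix(sample(-2:2, c_ * (c_ %/% 2), TRUE), c_, c_ %/% 2),
      w2 = matrix(sample(-2:2, (c_ %/% 2) * c_, TRUE), c_ %/% 2, c_)
    )
    got <- channel_attention(x, p)
    ref <- oracle_channel_attention(x, p$w1, p$w2)
    expect_equal(got$att, ref$att, tolerance = 1e-6)
    expect_equal(got$out, ref$out, tolerance = 1e-6)
  }
})

test_that("a zero channel yields the hand-computed descriptor pathway", {
  set.seed(9)
  x <- array(runif(3 * 3 * 4, 0.5, 2), dim = c(3, 3, 4, 1))
  x[, , 2, 1] <- 0
  p <- list(
    w1 = matrix(c(1, 0, -1, 2, 0, 1, 1, -1), 4, 2),
    w2 = matrix(c(1, -1, 0, 2, 2, 0, -1, 1), 2, 4)
  )
  got <- channel_attention(x, p)
  # both pooled descriptors carry 0 in channel 2; evaluate the MLP by hand
  mp <- apply(x[, , , 1], 3, max)
  ap <- apply(x[, , , 1], 3, mean)
  expect_equal(mp[2], 0)
  mlp <- function(v) as.vector(t(p$w2) %*% pmax(as.vector(t(p$w1) %*% v), 0))
  expect_equal(as.vector(got$att), sigmoid_ref(mlp(mp) + mlp(ap)), tolerance = 1e-6)
})

test_that("spatial attention matches the scalar-loop oracle", {
  for (seed in 1:4) {
    set.seed(seed)
    c_ <- sample(2:4, 1)
    x <- array(sample(-4:4, 4 * 4 * c_ * 2, TRUE) / 2, dim = c(4, 4, c_, 2))
    p <- list(
      w = array(sample(-1:1, 49 * 2, TRUE) / 2, dim = c(7, 7, 2, 1)),
      b = 0.25
    )
    got <- spatial_attention(x, p)
    ref <- oracle_spatial_attention(x, p$w, p$b)
    expect_equal(got$att, ref$att, tolerance = 1e-6)
    expect_equal(got$out, ref$out, tolerance = 1e-6)
  }
})

test_that("a centre-tap kernel reproduces sigmoid of twice the hot pixel", {
  x <- array(0, dim = c(4, 4, 1, 1))
  x[2, 3, 1, 1] <- 2
  w <- array(0, dim = c(7, 7, 2, 1))
  w[4, 4, 1, 1] <- 1 # centre weight on the max-pool descriptor
  w[4, 4, 2, 1] <- 1 # and on the average-pool descriptor
  got <- spatial_attention(x, list(w = w, b = numeric(1)))
  # with one channel, max and mean descriptors both equal x itself
  expect_equal(got$att[, , 1, 1], sigmoid_ref(2 * x[, , 1, 1]), tolerance = 1e-6)
})

test_that("constant fields give spatially constant interior attention", {
  # zero padding perturbs the 3-pixel frame the 7x7 kernel overlaps; away
  # from it a constant field must give a constant attention map
  x <- array(1.7, dim = c(12, 12, 3, 1))
  r <- spatial_attention(x, sa_params())
  expect_lt(diff(range(r$att[4:9, 4:9, 1, 1])), 1e-6)
})

test_that("the attention gate matches the scalar-loop oracle", {
  for (seed in 1:4) {
    set.seed(seed)
    cx <- sample(c(2, 4), 1)
    cg <- sample(2:4, 1)
    xs <- array(sample(-3:3, 4 * 4 * cx * 2, TRUE) / 2, dim = c(4, 4, cx, 2))
    g <- array(sample(-3:3, 2 * 2 * cg * 2, TRUE) / 2, dim = c(2, 2, cg, 2))
    half <- cx %/% 2
    p <- list(
      wx = array(sample(-2:2, cx * half, TRUE), dim = c(1, 1, cx, half)),
      wg = array(sample(-2:2, cg * half, TRUE), dim = c(1, 1, cg, half)),
      bg = sample(-1:1, half, TRUE) / 2,
      wphi = array(sample(-2:2, half, TRUE), dim = c(1, 1, half, 1)),
      bphi = 0.5
    )
    got <- scag(xs, g, p)
    ref <- oracle_scag(xs, g, p)
    expect_equal(got$att, ref$att, tolerance = 1e-6)
    expect_equal(got$out, ref$out, tolerance = 1e-6)
  }
})

test_that("the gate hand-evaluates on a 2x2 integer toy", {
  xs <- array(c(1, 2, 3, 4, -1, 0, 1, 2), dim = c(2, 2, 2, 1))
  g <- array(c(2, -1), dim = c(1, 1, 2, 1))
  p <- list(
    wx = array(c(1, -1), dim = c(1, 1, 2, 1)),
    wg = array(c(1, 2), dim = c(1, 1, 2, 1)), bg = 1,
    wphi = array(2, dim = c(1, 1, 1, 1)), bphi = -1
  )
  # projections: x-path picks xs[1,1,]= (1,-1) -> 1*1 + (-1)*(-1) = 2
  # g-path: 2*1 + (-1)*2 + 1 = 1; relu(2+1)=3; phi: 2*3-1 = 5
  got <- scag(xs, g, p)
  expect_equal(got$att[1, 1, 1, 1], sigmoid_ref(5), tolerance = 1e-6)
  expect_equal(got$out[1, 1, 1, 1], 1 * sigmoid_ref(5), tolerance = 1e-6)
})

test_that("gate rejects incompatible extents with both sizes in the message", {
  xs <- array(0, dim = c(6, 6, 4, 1))
  g <- array(0, dim = c(2, 2, 4, 1))
  expect_error(scag(xs, g, scag_params(4, 4)), "6x6.*2x2")
})

test_that("channel attention is permutation-equivariant", {
  set.seed(11)
  c_ <- 4
  x <- array(rnorm(5 * 5 * c_ * 2), dim = c(5, 5, c_, 2))
  p <- ca_params(c_)
  perm <- c(3, 1, 4, 2)
  xp <- x[, , perm, , drop = FALSE]
  pp <- list(w1 = p$w1[perm, , drop = FALSE], w2 = p$w2[, perm, drop = FALSE])
  a1 <- channel_attention(x, p)$att
  a2 <- channel_attention(xp, pp)$att
  expect_equal(a2[1, 1, , ], a1[1, 1, perm, ], tolerance = 1e-6)
})

test_that("cbam is bit-identical to explicit channel-then-spatial composition", {
  set.seed(12)
  x <- array(rnorm(6 * 6 * 4 * 2), dim = c(6, 6, 4, 2))
  capar <- ca_params(4)
  sapar <- sa_params()
  expect_identical(
    cbam(x, capar, sapar),
    spatial_attention(channel_attention(x, capar)$out, sapar)$out
  )
})

test_that("non-finite inputs are rejected", {
  x <- array(1, dim = c(4, 4, 4, 1))
  x[1] <- NA
  expect_error(channel_attention(x, ca_params(4)), "non-finite")
})
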