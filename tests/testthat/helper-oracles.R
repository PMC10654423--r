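# Independent scalar-loop oracles used to validate the vectorized
# implementations.  These are deliberately naive (nested loops, no shared
# code with the package internals).

oracle_conv2d <- function(x, w, b = NULL, stride = 1, pad = 0) {
  d <- dim(x)
  kh <- dim(w)[1]
  kw <- dim(w)[2]
  Co <- dim(w)[4]
  Ho <- (d[1] + 2 * pad - kh) %/% stride + 1
  Wo <- (d[2] + 2 * pad - kw) %/% stride + 1
  y <- array(0, dim = c(Ho, Wo, Co, d[4]))
  for (n in seq_len(d[4])) {
    for (o in seq_len(Co)) {
      for (oi in seq_len(Ho)) {
        for (oj in seq_len(Wo)) {
          s <- if (is.null(b)) 0 else b[o]
          for (c in seq_len(d[3])) {
            for (ki in seq_len(kh)) {
              for (kj in seq_len(kw)) {
                i <- (oi - 1) * stride + ki - pad
                j <- (oj - 1) * stride + kj - pad
                if (i >= 1 && i <= d[1] && j >= 1 && j <= d[2]) {
                  s <- s + x[i, j, c, n] * w[ki, kj, c, o]
                }
              }
            }
          }
          y[oi, oj, o, n] <- s
        }
      }
    }
  }
  y
}

sigmoid_ref <- function(z) 1 / (1 + exp(-z))

oracle_channel_attention <- function(x, w1, w2) {
  d <- dim(x)
  att <- array(0, dim = c(1, 1, d[3], d[4]))
  out <- array(0, dim = d)
  for (n in seq_len(d[4])) {
    mp <- ap <- numeric(d[3])
    for (c in seq_len(d[3])) {
      mp[c] <- max(x[, , c, n])
      ap[c] <- mean(x[, , c, n])
    }
    mlp <- function(v) {
      h <- pmax(as.vector(t(w1) %*% v), 0)
      as.vector(t(w2) %*% h)
    }
    a <- sigmoid_ref(mlp(mp) + mlp(ap))
    att[1, 1, , n] <- a
    for (c in seq_len(d[3])) out[, , c, n] <- x[, , c, n] * a[c]
  }
  list(att = att, out = out)
}

oracle_spatial_attention <- function(x, w, b) {
  d <- dim(x)
  att <- array(0, dim = c(d[1], d[2], 1, d[4]))
  out <- array(0, dim = d)
  for (n in seq_len(d[4])) {
    smp <- apply(x[, , , n, drop = FALSE], c(1, 2), max)
    sap <- apply(x[, , , n, drop = FALSE], c(1, 2), mean)
    desc <- array(0, dim = c(d[1], d[2], 2, 1))
    desc[, , 1, 1] <- smp
    desc[, , 2, 1] <- sap
    z <- oracle_conv2d(desc, w, b, stride = 1, pad = 3)
    att[, , 1, n] <- sigmoid_ref(z[, , 1, 1])
    for (c in seq_len(d[3])) out[, , c, n] <- x[, , c, n] * att[, , 1, n]
  }
  list(att = att, out = out)
}

# half-pixel-centre bilinear x2 upsampling of a matrix
oracle_upsample2 <- function(m) {
  H <- nrow(m)
  W <- ncol(m)
  out <- matrix(0, 2 * H, 2 * W)
  for (oi in seq_len(2 * H)) {
    for (oj in seq_len(2 * W)) {
      si <- min(max((oi - 0.5) / 2 - 0.5, 0), H - 1)
      sj <- min(max((oj - 0.5) / 2 - 0.5, 0), W - 1)
      i0 <- floor(si)
      j0 <- floor(sj)
      i1 <- min(i0 + 1, H - 1)
      j1 <- min(j0 + 1, W - 1)
      wi <- si - i0
      wj <- sj - j0
      out[oi, oj] <- (1 - wj) * ((1 - wi) * m[i0 + 1, j0 + 1] + wi * m[i1 + 1, j0 + 1]) +
        wj * ((1 - wi) * m[i0 + 1, j1 + 1] + wi * m[i1 + 1, j1 + 1])
    }
  }
  out
}

oracle_scag <- function(xsf, xdf, p) {
  dsf <- dim(xsf)
  ddf <- dim(xdf)
  stride <- if (dsf[1] == 2 * ddf[1]) 2 else 1
  xs <- oracle_conv2d(xsf, p$wx, NULL, stride = stride, pad = 0)
  xg <- oracle_conv2d(xdf, p$wg, p$bg, stride = 1, pad = 0)
  a <- pmax(xs + xg, 0)
  z <- oracle_conv2d(a, p$wphi, p$bphi, stride = 1, pad = 0)
  att <- sigmoid_ref(z)
  out <- array(0, dim = dsf)
  attf <- array(0, dim = c(dsf[1], dsf[2], 1, dsf[4]))
  for (n in seq_len(dsf[4])) {
    am <- att[, , 1, n]
    if (stride == 2) am <- oracle_upsample2(am)
    attf[, , 1, n] <- am
    for (c in seq_len(dsf[3])) out[, , c, n] <- xsf[, , c, n] * am
  }
  list(att = attf, out = out)
}

# all-pairs boundary-distance oracle for the ASSD
oracle_assd <- function(a, b, spacing = c(1, 1)) {
  bound <- function(m) {
    H <- nrow(m)
    W <- ncol(m)
    pts <- NULL
    for (i in seq_len(H)) {
      for (j in seq_len(W)) {
        if (m[i, j] > 0) {
          nb <- c(
            if (i > 1) m[i - 1, j] else 0, if (i < H) m[i + 1, j] else 0,
            if (j > 1) m[i, j - 1] else 0, if (j < W) m[i, j + 1] else 0
          )
          if (any(nb == 0) || i == 1 || i == H || j == 1 || j == W) {
            pts <- rbind(pts, c(i, j))
          }
        }
      }
    }
    pts
  }
  pa <- bound(a)
  pb <- bound(b)
  if (is.null(pa) || is.null(pb)) {
    return(NA_real_)
  }
  dmin <- function(p, q) {
    vapply(seq_len(nrow(p)), function(k) {
      min(sqrt(((p[k, 1] - q[, 1]) * spacing[1])^2 +
        ((p[k, 2] - q[, 2]) * spacing[2])^2))
    }, numeric(1))
  }
  da <- dmin(pa, pb) # from boundary of a to boundary of b
  db <- dmin(pb, pa)
  (sum(da) + sum(db)) / (length(da) + length(db))
}

# random binary mask with a few rectangular patches
random_mask <- function(extent = 16, n_patches = 2, min_patches = 0) {
  m <- matrix(0, extent, extent)
  for (k in seq_len(sample(min_patches:n_patches, 1))) {
    i <- sample(extent - 3, 1)
    j <- sample(extent - 3, 1)
    h <- sample(2:4, 1)
    w <- sample(2:4, 1)
    m[i:min(i + h, extent), j:min(j + w, extent)] <- 1
  }
  m
}

# independent per-layer parameter tally for the toy manet configuration
# (variant "manet", encoder widths e1/e2/e3, bridge B): written out longhand
oracle_manet_params <- function(e, B, cin = 3, cout = 3) {
  conv <- function(k, a, b) k * k * a * b + b
  bn <- function(b) 2 * b
  rb <- function(a, b) {
    conv(3, a, b) + bn(b) + conv(3, b, b) + bn(b) + conv(1, a, b) + bn(b)
  }
  ca <- function(c) c * (c %/% 2) * 2
  sa <- 7 * 7 * 2 * 1 + 1
  f <- max(e[1] %/% 2, 1)
  up <- c(e[3], e[2], f)
  dec_w1 <- c(e[2], e[1], e[1])
  dec_w2 <- c(e[2], e[1], f)
  skips <- c(e[3], e[2], e[1])
  gates <- c(B, e[2], e[1])
  total <- rb(cin, e[1]) + ca(e[1]) + rb(e[1], e[2]) + ca(e[2]) +
    rb(e[2], e[3]) + ca(e[3]) +
    rb(e[3], B) + ca(B) + sa # bridge + CBAM
  prev <- B
  for (i in 1:3) {
    total <- total + (2 * 2 * prev * up[i] + up[i]) + bn(up[i]) + sa
    half <- skips[i] %/% 2
    total <- total + skips[i] * half + gates[i] * half + half + half + 1
    total <- total + conv(3, up[i] + skips[i], dec_w1[i]) + bn(dec_w1[i])
    total <- total + conv(3, dec_w1[i], dec_w2[i]) + bn(dec_w2[i])
    prev <- dec_w2[i]
  }
  total + prev * cout + cout
}
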