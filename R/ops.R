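# Differentiable tensor operations used by the network forward pass.  All
# values are numeric arrays (h, w, c, b).  Each op_* takes the tape first,
# returns a node, and installs a backfn returning one gradient per parent
# (NULL where the parent needs none).

op_conv <- function(tape, x, w, b = NULL, stride = 1L, pad = 0L) {
  single <- is.null(tape) || tape$single
  bias <- if (is.null(b)) numeric(0) else b$value
  # when recording in single precision, keep the im2col buffer for backward
  keep <- !is.null(tape) && single
  y <- cpp_conv_fwd(x$value, w$value, bias, stride, pad, single, keep)
  col <- NULL
  if (keep) {
    col <- y$col
    y <- y$y
  }
  parents <- if (is.null(b)) list(x, w) else list(x, w, b)
  xv <- x$value
  wv <- w$value
  ndx <- needs_grad(x)
  nd(tape, y, parents, function(dy) {
    r <- cpp_conv_bwd(xv, wv, dy, stride, pad, ndx, single, col)
    if (is.null(b)) {
      list(if (ndx) r$dx, r$dw)
    } else {
      list(if (ndx) r$dx, r$dw, r$db)
    }
  })
}

op_convT <- function(tape, x, w, b = NULL, stride = 2L) {
  single <- is.null(tape) || tape$single
  bias <- if (is.null(b)) numeric(0) else b$value
  y <- cpp_convT_fwd(x$value, w$value, bias, stride, single)
  parents <- if (is.null(b)) list(x, w) else list(x, w, b)
  xv <- x$value
  wv <- w$value
  nd(tape, y, parents, function(dy) {
    r <- cpp_convT_bwd(xv, wv, dy, stride, single)
    if (is.null(b)) list(r$dx, r$dw) else list(r$dx, r$dw, r$db)
  })
}

op_relu <- function(tape, x) {
  y <- cpp_relu_fwd(x$value)
  nd(tape, y, list(x), function(dy) list(cpp_relu_bwd(dy, y)))
}

op_sigmoid <- function(tape, x) {
  y <- cpp_sigmoid_fwd(x$value)
  nd(tape, y, list(x), function(dy) list(cpp_sigmoid_bwd(dy, y)))
}

op_add <- function(tape, a, b) {
  nd(tape, a$value + b$value, list(a, b), function(dy) list(dy, dy))
}

# Batch normalization with running statistics kept in `state[[key]]`
# (a side-channel environment owned by the model, not the tape).
op_bn <- function(tape, x, gamma, beta, state, key, training, momentum = 0.1,
                  eps = 1e-5) {
  d <- dim(x$value)
  m <- prod(d[c(1L, 2L, 4L)])
  if (training) {
    mom <- cpp_chan_moments(x$value)
    mu <- mom$mean
    va <- mom$var
    st <- state[[key]]
    unb <- if (m > 1) va * m / (m - 1) else va
    state[[key]] <- list(
      mean = (1 - momentum) * st$mean + momentum * mu,
      var = (1 - momentum) * st$var + momentum * unb
    )
  } else {
    st <- state[[key]]
    mu <- st$mean
    va <- st$var
  }
  inv <- 1 / sqrt(va + eps)
  xhat <- cpp_chan_affine(x$value, inv, -mu * inv)
  y <- cpp_chan_affine(xhat, gamma$value, beta$value)
  gv <- gamma$value
  nd(tape, y, list(x, gamma, beta), function(dy) {
    dgamma <- cpp_chan_dot(dy, xhat)
    dbeta <- cpp_chan_sum(dy)
    if (training) {
      a <- gv * inv
      dx <- cpp_bn_dx(dy, xhat, a, -a * dbeta / m, -a * dgamma / m)
    } else {
      dx <- cpp_chan_affine(dy, gv * inv, rep(0, length(gv)))
    }
    list(dx, dgamma, dbeta)
  })
}

# Global spatial pooling: (h, w, c, b) -> (1, 1, c, b).
op_gap <- function(tape, x) {
  d <- dim(x$value)
  hw <- d[1] * d[2]
  M <- x$value
  dim(M) <- c(hw, d[3] * d[4])
  y <- array(.colMeans(M, hw, d[3] * d[4]), dim = c(1L, 1L, d[3], d[4]))
  nd(tape, y, list(x), function(dy) {
    g <- rep(as.vector(dy) / hw, each = hw)
    dim(g) <- d
    list(g)
  })
}

op_gmp <- function(tape, x) {
  d <- dim(x$value)
  hw <- d[1] * d[2]
  M <- x$value
  dim(M) <- c(hw, d[3] * d[4])
  mx <- apply(M, 2L, max)
  y <- array(mx, dim = c(1L, 1L, d[3], d[4]))
  nd(tape, y, list(x), function(dy) {
    # route gradient to the maxima; ties share equally
    mask <- M == rep(mx, each = hw)
    cnt <- .colSums(mask, hw, d[3] * d[4])
    g <- mask * rep(as.vector(dy) / cnt, each = hw)
    dim(g) <- d
    list(g)
  })
}

# Per-pixel pooling across channels: (h, w, c, b) -> (h, w, 1, b).
op_cmean <- function(tape, x) {
  d <- dim(x$value)
  y <- cpp_cmean_fwd(x$value)
  nd(tape, y, list(x), function(dy) list(cpp_cmean_bwd(dy, d[3])))
}

op_cmax <- function(tape, x) {
  xv <- x$value
  y <- cpp_cmax_fwd(xv)
  nd(tape, y, list(x), function(dy) list(cpp_cmax_bwd(dy, xv, y)))
}

# index vector replicating a (h, w, 1, b) field across c channels (memoized;
# the same shapes recur every batch)
.idx_cache <- new.env(parent = emptyenv())
rep_pix_idx <- function(d) {
  key <- paste(d, collapse = "x")
  v <- .idx_cache[[key]]
  if (!is.null(v)) {
    return(v)
  }
  hw <- d[1] * d[2]
  base <- rep(seq_len(hw), times = d[3])
  off <- rep((seq_len(d[4]) - 1L) * hw, each = hw * d[3])
  v <- rep.int(base, d[4]) + off
  .idx_cache[[key]] <- v
  v
}

# x * att with att of shape (1, 1, c, b): per-channel gating.
op_scale_channel <- function(tape, x, att) {
  xv <- x$value
  av <- att$value
  y <- cpp_scale_channel_fwd(xv, av)
  nd(tape, y, list(x, att), function(dy) {
    r <- cpp_scale_channel_bwd(dy, xv, av)
    list(r$dx, r$datt)
  })
}

# x * att with att of shape (h, w, 1, b): per-pixel gating.
op_scale_spatial <- function(tape, x, att) {
  xv <- x$value
  av <- att$value
  y <- cpp_scale_spatial_fwd(xv, av)
  nd(tape, y, list(x, att), function(dy) {
    r <- cpp_scale_spatial_bwd(dy, xv, av)
    list(r$dx, r$datt)
  })
}

op_concat_c <- function(tape, a, b) {
  ca <- dim(a$value)[3]
  y <- cpp_concat2(a$value, b$value)
  nd(tape, y, list(a, b), function(dy) {
    r <- cpp_split2(dy, ca)
    list(r$a, r$b)
  })
}

# Dense layer on channel descriptors (1, 1, c_in, b); w is (c_in, c_out).
op_dense <- function(tape, x, w) {
  d <- dim(x$value)
  M <- matrix(x$value, nrow = d[3], ncol = d[4])
  y <- crossprod(w$value, M) # (c_out, b)
  yo <- array(y, dim = c(1L, 1L, ncol(w$value), d[4]))
  wv <- w$value
  nd(tape, yo, list(x, w), function(dy) {
    dym <- matrix(dy, nrow = ncol(wv), ncol = d[4])
    dx <- array(wv %*% dym, dim = d)
    dw <- M %*% t(dym)
    list(dx, dw)
  })
}

op_upsample2 <- function(tape, x) {
  d <- dim(x$value)
  y <- cpp_upsample2_fwd(x$value)
  nd(tape, y, list(x), function(dy) list(cpp_upsample2_bwd(dy, d[1], d[2])))
}

# Soft Dice loss, averaged over batch and the selected (foreground) channels.
op_dice_loss <- function(tape, pred, target, smooth = 1, channels = NULL) {
  d <- dim(pred$value)
  if (is.null(channels)) channels <- seq_len(d[3])
  pv <- pred$value
  total <- 0
  grad_coef <- vector("list", length(channels) * d[4])
  k <- 0L
  denom_n <- length(channels) * d[4]
  for (n in seq_len(d[4])) {
    for (ch in channels) {
      p <- pv[, , ch, n]
      t <- target[, , ch, n]
      I <- sum(p * t)
      S <- sum(p) + sum(t)
      total <- total + (1 - (2 * I + smooth) / (S + smooth))
      k <- k + 1L
      grad_coef[[k]] <- list(ch = ch, n = n, t = t, I = I, S = S)
    }
  }
  loss <- total / denom_n
  nd(tape, loss, list(pred), function(dy) {
    g <- array(0, dim = d)
    for (e in grad_coef) {
      gd <- -(2 * e$t * (e$S + smooth) - (2 * e$I + smooth)) / (e$S + smooth)^2
      g[, , e$ch, e$n] <- gd / denom_n
    }
    list(dy * g)
  })
}
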