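# The four attention operators: channel attention (CA), spatial attention
# (SA), their sequential composition (CBAM), and the skip-connection
# attention gate (SCAG).  Node-level versions (attn_*) are used inside the
# network graph; the exported functions wrap plain arrays.

#' Channel-attention parameters
#'
#' Creates the shared two-layer perceptron of the channel-attention module.
#' The hidden width is half the channel count (integer division); both
#' layers are bias-free and shared between the max-pool and average-pool
#' branches.
#'
#' @param channels number of input channels.
#' @param init `"kaiming"` (default) or `"zero"`.
#' @return list with `w1` (`channels x hidden`) and `w2` (`hidden x channels`).
#' @export
ca_params <- function(channels, init = c("kaiming", "zero")) {
  init <- match.arg(init)
  if (channels < 2) stop("channel attention needs at least 2 channels, got ", channels)
  hidden <- channels %/% 2L
  list(
    w1 = init_weight(c(channels, hidden), fan_in = channels, init = init),
    w2 = init_weight(c(hidden, channels), fan_in = hidden, init = init)
  )
}

#' Spatial-attention parameters
#'
#' A single 7x7 convolution mapping the two pooled descriptor channels to a
#' one-channel attention logit map (padding 3 preserves the extent).
#'
#' @inheritParams ca_params
#' @return list with `w` (`7 x 7 x 2 x 1`) and `b` (length-1 bias).
#' @export
sa_params <- function(init = c("kaiming", "zero")) {
  init <- match.arg(init)
  list(
    w = init_weight(c(7L, 7L, 2L, 1L), fan_in = 7 * 7 * 2, init = init),
    b = numeric(1)
  )
}

#' Skip-connection attention-gate parameters
#'
#' Both inputs are projected to `channels_x %/% 2` channels by 1x1
#' convolutions; the shallow-feature path carries no bias, the gate and
#' output paths do.
#'
#' @param channels_x channels of the shallow (encoder) features.
#' @param channels_g channels of the deep gate signal.
#' @inheritParams ca_params
#' @return list with `wx`, `wg`, `bg`, `wphi`, `bphi`.
#' @export
scag_params <- function(channels_x, channels_g, init = c("kaiming", "zero")) {
  init <- match.arg(init)
  half <- channels_x %/% 2L
  if (half < 1) stop("shallow feature width must be at least 2, got ", channels_x)
  list(
    wx = init_weight(c(1L, 1L, channels_x, half), fan_in = channels_x, init = init),
    wg = init_weight(c(1L, 1L, channels_g, half), fan_in = channels_g, init = init),
    bg = numeric(half),
    wphi = init_weight(c(1L, 1L, half, 1L), fan_in = half, init = init),
    bphi = numeric(1)
  )
}

# ---- node-level implementations -------------------------------------------

attn_ca <- function(tape, x, w1, w2) {
  mlp <- function(d) op_dense(tape, op_relu(tape, op_dense(tape, d, w1)), w2)
  att <- op_sigmoid(tape, op_add(
    tape,
    mlp(op_gmp(tape, x)),
    mlp(op_gap(tape, x))
  ))
  list(att = att, out = op_scale_channel(tape, x, att))
}

attn_sa <- function(tape, x, w, b) {
  d <- op_concat_c(tape, op_cmax(tape, x), op_cmean(tape, x))
  att <- op_sigmoid(tape, op_conv(tape, d, w, b, stride = 1L, pad = 3L))
  list(att = att, out = op_scale_spatial(tape, x, att))
}

attn_scag <- function(tape, xsf, xdf, p) {
  dsf <- dim(xsf$value)
  ddf <- dim(xdf$value)
  if (dsf[1] == 2L * ddf[1] && dsf[2] == 2L * ddf[2]) {
    stride <- 2L
    up <- TRUE
  } else if (dsf[1] == ddf[1] && dsf[2] == ddf[2]) {
    stride <- 1L
    up <- FALSE
  } else {
    stop(
      "incompatible extents for attention gate: shallow ",
      dsf[1], "x", dsf[2], " vs gate ", ddf[1], "x", ddf[2]
    )
  }
  xs <- op_conv(tape, xsf, p$wx, NULL, stride = stride, pad = 0L)
  xg <- op_conv(tape, xdf, p$wg, p$bg, stride = 1L, pad = 0L)
  a <- op_relu(tape, op_add(tape, xs, xg))
  a <- op_sigmoid(tape, op_conv(tape, a, p$wphi, p$bphi, stride = 1L, pad = 0L))
  if (up) a <- op_upsample2(tape, a)
  list(att = a, out = op_scale_spatial(tape, xsf, a))
}

# ---- exported array-level operators ---------------------------------------

check_fmap <- function(x, name = "x") {
  if (!is.array(x) || length(dim(x)) != 4L) {
    stop(name, " must be a rank-4 array (h, w, c, b)")
  }
  if (any(!is.finite(x))) stop(name, " contains non-finite values")
  invisible(x)
}

wrap_params <- function(p) lapply(p, function(a) nd(NULL, a))

#' Channel attention
#'
#' Recalibrates channels from global max- and average-pooled descriptors
#' passed through a shared bias-free two-layer perceptron:
#' `att = sigmoid(MLP(maxpool(x)) + MLP(avgpool(x)))`, applied by broadcast
#' multiplication over all spatial positions.
#'
#' @param x feature map, array `(h, w, c, b)`.
#' @param params list from [ca_params()].
#' @return list with `att` (`1 x 1 x c x b` attention map, values in (0,1))
#'   and `out` (recalibrated map, same shape as `x`).
#' @examples
#' x <- array(rnorm(4 * 4 * 4), dim = c(4, 4, 4, 1))
#' z <- channel_attention(x, ca_params(4, init = "zero"))
#' all.equal(z$out, 0.5 * x) # zero weights gate everything by sigmoid(0)
#' @export
channel_attention <- function(x, params) {
  check_fmap(x)
  p <- wrap_params(params)
  r <- attn_ca(NULL, nd(NULL, x), p$w1, p$w2)
  list(att = r$att$value, out = r$out$value)
}

#' Spatial attention
#'
#' Per-pixel gating from channel-wise max and mean maps: the two descriptor
#' maps are concatenated and passed through a 7x7 convolution and a sigmoid;
#' the resulting `(h, w, 1, b)` map multiplies every channel.
#'
#' @param x feature map, array `(h, w, c, b)`.
#' @param params list from [sa_params()].
#' @return list with `att` and `out` as in [channel_attention()].
#' @export
spatial_attention <- function(x, params) {
  check_fmap(x)
  p <- wrap_params(params)
  r <- attn_sa(NULL, nd(NULL, x), p$w, p$b)
  list(att = r$att$value, out = r$out$value)
}

#' Convolutional block attention module
#'
#' Sequential channel-then-spatial attention; identical by construction to
#' `spatial_attention(channel_attention(x)$out)$out`.
#'
#' @param x feature map, array `(h, w, c, b)`.
#' @param ca list from [ca_params()].
#' @param sa list from [sa_params()].
#' @return recalibrated feature map, same shape as `x`.
#' @export
cbam <- function(x, ca, sa) {
  spatial_attention(channel_attention(x, ca)$out, sa)$out
}

#' Skip-connection attention gate
#'
#' Additive attention gate weighting shallow encoder features `x_sf` with a
#' deep gate signal `x_df`.  Both inputs are projected to half the shallow
#' width by 1x1 convolutions (the shallow path with stride 2 when the gate
#' lives at half resolution), summed, passed through ReLU, a 1x1 convolution
#' and a sigmoid; the attention map is bilinearly upsampled back to the
#' shallow resolution and multiplies `x_sf`.
#'
#' @param x_sf shallow features `(h, w, c_x, b)`.
#' @param x_df gate signal `(h/2, w/2, c_g, b)` or `(h, w, c_g, b)`.
#' @param params list from [scag_params()].
#' @return list with `att` (`h x w x 1 x b`) and `out` (gated `x_sf`).
#' @export
scag <- function(x_sf, x_df, params) {
  check_fmap(x_sf, "x_sf")
  check_fmap(x_df, "x_df")
  p <- wrap_params(params)
  r <- attn_scag(NULL, nd(NULL, x_sf), nd(NULL, x_df), p)
  list(att = r$att$value, out = r$out$value)
}
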