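# Network assembly: configuration, parameter initialization, forward graph,
# layer tracing and parameter/MAC accounting.

#' The eight architecture variants of the ablation study
#'
#' From the plain U-Net backbone through residual blocks (RB) and the three
#' attention mechanisms to the full model.
#' @export
manet_variants <- c(
  "unet", "unet_rb", "unet_rb_scag", "unet_rb_ca", "unet_rb_sa",
  "unet_rb_cbam", "unet_all_attn", "manet"
)

variant_flags <- function(variant) {
  f <- list(
    unet = character(0),
    unet_rb = "rb",
    unet_rb_scag = c("rb", "scag"),
    unet_rb_ca = c("rb", "ca"),
    unet_rb_sa = c("rb", "sa"),
    unet_rb_cbam = c("rb", "cbam"),
    unet_all_attn = c("scag", "ca", "sa", "cbam"),
    manet = c("rb", "scag", "ca", "sa", "cbam")
  )[[variant]]
  if (is.null(f)) stop("unknown variant: ", variant)
  list(
    rb = "rb" %in% f, ca = "ca" %in% f, sa = "sa" %in% f,
    scag = "scag" %in% f, cbam = "cbam" %in% f
  )
}

#' Architecture configuration
#'
#' Defines one buildable network.  The defaults reproduce the published
#' MANet topology exactly: encoder widths 68/136/272, bridge 544, decoder
#' convolution widths 136/68/68 with a final narrowing to 34, and a
#' three-channel sigmoid head at 512 x 512.  The transposed convolutions
#' (2x2, stride 2) emit the encoder widths shifted down one stage and end at
#' the final width — `c(272, 136, 34)` on defaults — the wiring that
#' reproduces the published parameter and multiply-accumulate totals (the
#' source table does not print these widths; see the methods vignette).
#'
#' @param variant one of `"unet"`, `"unet_rb"`, `"unet_rb_scag"`,
#'   `"unet_rb_ca"`, `"unet_rb_sa"`, `"unet_rb_cbam"`, `"unet_all_attn"`,
#'   `"manet"` — the eight ablation rows.
#' @param in_channels,out_channels input/output channel counts.
#' @param encoder_widths channel widths of the encoder stages.
#' @param bridge_width channel width of the bridge.
#' @param decoder_widths first-convolution widths of the decoder stages.
#' @param final_width width of the last decoder convolution.
#' @param upconv_widths output widths of the transposed convolutions.
#' @return object of class `manet_config`.
#' @export
manet_config <- function(variant = "manet",
                         in_channels = 3L, out_channels = 3L,
                         encoder_widths = c(68L, 136L, 272L),
                         bridge_width = 544L,
                         decoder_widths = NULL,
                         final_width = NULL,
                         upconv_widths = NULL) {
  variant <- match.arg(variant, manet_variants)
  D <- length(encoder_widths)
  if (D < 2) stop("need at least two encoder stages")
  if (any(encoder_widths < 2) || bridge_width < 2) {
    stop("channel widths must be at least 2")
  }
  if (is.null(decoder_widths)) {
    decoder_widths <- encoder_widths[pmax(D - seq_len(D), 1L)]
  }
  if (is.null(final_width)) final_width <- max(encoder_widths[1] %/% 2L, 1L)
  if (is.null(upconv_widths)) {
    upconv_widths <- c(encoder_widths[seq(D, 2L)], final_width)
  }
  stopifnot(length(decoder_widths) == D, length(upconv_widths) == D)
  structure(
    list(
      variant = variant, in_channels = as.integer(in_channels),
      out_channels = as.integer(out_channels),
      encoder_widths = as.integer(encoder_widths),
      bridge_width = as.integer(bridge_width),
      decoder_widths = as.integer(decoder_widths),
      final_width = as.integer(final_width),
      upconv_widths = as.integer(upconv_widths),
      depth = D, flags = variant_flags(variant)
    ),
    class = "manet_config"
  )
}

as_manet_config <- function(x) {
  if (inherits(x, "manet_config")) {
    return(x)
  }
  if (inherits(x, "manet")) {
    return(x$config)
  }
  stop("expected a manet_config or fitted manet object")
}

# ---- layer inventory -------------------------------------------------------
# One row per parameterized layer; the single source for initialization,
# parameter totals, MAC totals and the printed trace.  `macs` follows the
# declared convention: kernel_elements * c_in * c_out * output_positions for
# convolutions and transposed convolutions, c_in * c_out per pooled branch
# for the attention perceptrons; normalization and activations are free.

layer_table <- function(config, input_size = 512L) {
  cfg <- as_manet_config(config)
  fl <- cfg$flags
  D <- cfg$depth
  rows <- list()
  add <- function(name, block, op, kh, kw, cin, cout, stride, pad, bias,
                  out_hw, macs_mult = 1, table_row = NA_integer_) {
    params <- switch(op,
      conv = ,
      convT = kh * kw * cin * cout + if (bias) cout else 0,
      dense = cin * cout,
      bn = 2 * cout
    )
    macs <- switch(op,
      conv = ,
      convT = kh * kw * cin * cout * out_hw^2,
      dense = macs_mult * cin * cout,
      bn = 0
    )
    rows[[length(rows) + 1L]] <<- data.frame(
      name = name, block = block, op = op, kernel = kh, cin = cin,
      cout = cout, stride = stride, pad = pad, bias = bias, out = out_hw,
      params = params, macs = macs, table_row = table_row,
      stringsAsFactors = FALSE
    )
  }
  conv_bn <- function(name, block, kh, cin, cout, stride, out_hw, tr = NA_integer_) {
    add(paste0(name, ".conv"), block, "conv", kh, kh, cin, cout, stride,
      (kh - 1) %/% 2, TRUE, out_hw,
      table_row = tr
    )
    add(paste0(name, ".bn"), block, "bn", 0, 0, cout, cout, 1, 0, FALSE, out_hw)
  }
  ca_rows <- function(name, block, c, out_hw) {
    h <- c %/% 2L
    add(paste0(name, ".w1"), block, "dense", 1, 1, c, h, 1, 0, FALSE, 1, macs_mult = 2)
    add(paste0(name, ".w2"), block, "dense", 1, 1, h, c, 1, 0, FALSE, 1, macs_mult = 2)
  }
  sa_rows <- function(name, block, out_hw) {
    add(paste0(name, ".conv"), block, "conv", 7, 7, 2, 1, 1, 3, TRUE, out_hw)
  }
  sz <- input_size
  tr <- 0L
  # encoder
  cin <- cfg$in_channels
  for (k in seq_len(D)) {
    cout <- cfg$encoder_widths[k]
    stride <- if (k == 1L) 1L else 2L
    sz <- sz %/% stride
    blk <- paste0("Encoder ", k)
    nm <- paste0("enc", k)
    conv_bn(paste0(nm, ".c1"), blk, 3, cin, cout, stride, sz, tr = (tr <- tr + 1L))
    conv_bn(paste0(nm, ".c2"), blk, 3, cout, cout, 1, sz, tr = (tr <- tr + 1L))
    if (fl$rb) conv_bn(paste0(nm, ".proj"), blk, 1, cin, cout, stride, sz)
    if (fl$ca) ca_rows(paste0(nm, ".ca"), blk, cout, sz)
    cin <- cout
  }
  # bridge
  cout <- cfg$bridge_width
  sz <- sz %/% 2L
  conv_bn("bridge.c1", "Bridge", 3, cin, cout, 2, sz, tr = (tr <- tr + 1L))
  conv_bn("bridge.c2", "Bridge", 3, cout, cout, 1, sz, tr = (tr <- tr + 1L))
  if (fl$rb) conv_bn("bridge.proj", "Bridge", 1, cin, cout, 2, sz)
  if (fl$cbam) {
    ca_rows("bridge.cbam.ca", "Bridge", cout, sz)
    sa_rows("bridge.cbam.sa", "Bridge", sz)
  }
  # decoder
  prev <- cfg$bridge_width
  gate_c <- cfg$bridge_width
  for (k in seq_len(D)) {
    cx <- cfg$encoder_widths[D + 1L - k]
    w1 <- cfg$decoder_widths[k]
    w2 <- if (k == D) cfg$final_width else cfg$decoder_widths[k]
    cu <- cfg$upconv_widths[k]
    blk <- paste0("Decoder ", k)
    nm <- paste0("dec", k)
    gate_sz <- sz
    sz <- sz * 2L
    add(paste0(nm, ".up.conv"), blk, "convT", 2, 2, prev, cu, 2, 0, TRUE, sz)
    add(paste0(nm, ".up.bn"), blk, "bn", 0, 0, cu, cu, 1, 0, FALSE, sz)
    if (fl$sa) sa_rows(paste0(nm, ".sa"), blk, sz)
    if (fl$scag) {
      half <- cx %/% 2L
      add(paste0(nm, ".scag.wx"), blk, "conv", 1, 1, cx, half, 2, 0, FALSE, gate_sz)
      add(paste0(nm, ".scag.wg"), blk, "conv", 1, 1, gate_c, half, 1, 0, TRUE, gate_sz)
      add(paste0(nm, ".scag.wphi"), blk, "conv", 1, 1, half, 1, 1, 0, TRUE, gate_sz)
    }
    conv_bn(paste0(nm, ".c1"), blk, 3, cu + cx, w1, 1, sz, tr = (tr <- tr + 1L))
    conv_bn(paste0(nm, ".c2"), blk, 3, w1, w2, 1, sz, tr = (tr <- tr + 1L))
    prev <- w2
    gate_c <- w2
  }
  add("head.conv", "Output", "conv", 1, 1, prev, cfg$out_channels, 1, 0, TRUE,
    sz,
    table_row = (tr <- tr + 1L)
  )
  do.call(rbind, rows)
}

# ---- initialization --------------------------------------------------------

# Kaiming-uniform in the deep-learning framework's default flavor:
# U(-1/sqrt(fan_in), 1/sqrt(fan_in)); biases start at zero.
init_weight <- function(dims, fan_in, init = "kaiming") {
  if (identical(init, "zero")) {
    return(array(0, dim = dims))
  }
  bound <- 1 / sqrt(fan_in)
  array(runif(prod(dims), -bound, bound), dim = dims)
}

nn_init <- function(config) {
  cfg <- as_manet_config(config)
  lt <- layer_table(cfg)
  params <- list()
  state <- new.env(parent = emptyenv())
  for (i in seq_len(nrow(lt))) {
    r <- lt[i, ]
    if (r$op == "conv") {
      params[[paste0(r$name, ".w")]] <-
        init_weight(c(r$kernel, r$kernel, r$cin, r$cout), r$kernel^2 * r$cin)
      if (r$bias) params[[paste0(r$name, ".b")]] <- numeric(r$cout)
    } else if (r$op == "convT") {
      params[[paste0(r$name, ".w")]] <-
        init_weight(c(r$kernel, r$kernel, r$cout, r$cin), r$kernel^2 * r$cin)
      if (r$bias) params[[paste0(r$name, ".b")]] <- numeric(r$cout)
    } else if (r$op == "dense") {
      params[[paste0(r$name, ".w")]] <- init_weight(c(r$cin, r$cout), r$cin)
    } else if (r$op == "bn") {
      params[[paste0(r$name, ".g")]] <- rep(1, r$cout)
      params[[paste0(r$name, ".b")]] <- numeric(r$cout)
      state[[r$name]] <- list(mean = numeric(r$cout), var = rep(1, r$cout))
    }
  }
  list(params = params, state = state)
}

# ---- forward pass ----------------------------------------------------------

nn_forward <- function(config, params, state, x, training = FALSE,
                       tape = NULL, capture = character(0)) {
  cfg <- as_manet_config(config)
  fl <- cfg$flags
  D <- cfg$depth
  dm <- dim(x)
  div <- 2L^D
  if (dm[3] != cfg$in_channels) {
    stop("input has ", dm[3], " channels; the network expects ", cfg$in_channels)
  }
  if (dm[1] %% div != 0L || dm[2] %% div != 0L) {
    stop("spatial extent ", dm[1], "x", dm[2], " must be divisible by ", div)
  }
  caps <- list()
  keep <- function(name, node) {
    if (name %in% capture) caps[[name]] <<- node$value
  }
  P <- new.env(parent = emptyenv())
  pn <- function(name) {
    if (is.null(P[[name]])) {
      v <- params[[name]]
      if (is.null(v)) stop("missing parameter: ", name)
      P[[name]] <- nd_param(tape, v)
    }
    P[[name]]
  }
  conv_bn_relu <- function(h, nm, stride, pad = 1L, relu = TRUE) {
    h <- op_conv(tape, h, pn(paste0(nm, ".conv.w")), pn(paste0(nm, ".conv.b")),
      stride = stride, pad = pad
    )
    h <- op_bn(
      tape, h, pn(paste0(nm, ".bn.g")), pn(paste0(nm, ".bn.b")),
      state, paste0(nm, ".bn"), training
    )
    if (relu) op_relu(tape, h) else h
  }
  block <- function(h, nm, stride) {
    if (fl$rb) {
      main <- conv_bn_relu(h, paste0(nm, ".c1"), stride)
      main <- conv_bn_relu(main, paste0(nm, ".c2"), 1L, relu = FALSE)
      skip <- conv_bn_relu(h, paste0(nm, ".proj"), stride, pad = 0L, relu = FALSE)
      op_relu(tape, op_add(tape, main, skip))
    } else {
      h <- conv_bn_relu(h, paste0(nm, ".c1"), stride)
      conv_bn_relu(h, paste0(nm, ".c2"), 1L)
    }
  }
  h <- nd_input(tape, x)
  enc <- vector("list", D)
  for (k in seq_len(D)) {
    nm <- paste0("enc", k)
    h <- block(h, nm, if (k == 1L) 1L else 2L)
    keep(paste0(nm, "_pre_ca"), h)
    if (fl$ca) {
      r <- attn_ca(tape, h, pn(paste0(nm, ".ca.w1.w")), pn(paste0(nm, ".ca.w2.w")))
      h <- r$out
      keep(paste0(nm, "_ca_att"), r$att)
    }
    keep(nm, h)
    enc[[k]] <- h
  }
  h <- block(h, "bridge", 2L)
  keep("bridge_pre_cbam", h)
  if (fl$cbam) {
    r <- attn_ca(
      tape, h, pn("bridge.cbam.ca.w1.w"),
      pn("bridge.cbam.ca.w2.w")
    )
    r2 <- attn_sa(tape, r$out, pn("bridge.cbam.sa.conv.w"), pn("bridge.cbam.sa.conv.b"))
    h <- r2$out
  }
  keep("bridge", h)
  for (k in seq_len(D)) {
    nm <- paste0("dec", k)
    gate <- h
    up <- op_convT(tape, h, pn(paste0(nm, ".up.conv.w")), pn(paste0(nm, ".up.conv.b")),
      stride = 2L
    )
    up <- op_bn(
      tape, up, pn(paste0(nm, ".up.bn.g")), pn(paste0(nm, ".up.bn.b")),
      state, paste0(nm, ".up.bn"), training
    )
    up <- op_relu(tape, up)
    keep(paste0(nm, "_pre_sa"), up)
    if (fl$sa) {
      r <- attn_sa(tape, up, pn(paste0(nm, ".sa.conv.w")), pn(paste0(nm, ".sa.conv.b")))
      up <- r$out
      keep(paste0(nm, "_sa_att"), r$att)
    }
    skip <- enc[[D + 1L - k]]
    if (fl$scag) {
      p <- list(
        wx = pn(paste0(nm, ".scag.wx.w")),
        wg = pn(paste0(nm, ".scag.wg.w")), bg = pn(paste0(nm, ".scag.wg.b")),
        wphi = pn(paste0(nm, ".scag.wphi.w")), bphi = pn(paste0(nm, ".scag.wphi.b"))
      )
      r <- attn_scag(tape, skip, gate, p)
      skip <- r$out
      keep(paste0(nm, "_scag_att"), r$att)
    }
    h <- op_concat_c(tape, up, skip)
    h <- conv_bn_relu(h, paste0(nm, ".c1"), 1L)
    h <- conv_bn_relu(h, paste0(nm, ".c2"), 1L)
    keep(nm, h)
  }
  out <- op_sigmoid(tape, op_conv(tape, h, pn("head.conv.w"), pn("head.conv.b"),
    stride = 1L, pad = 0L
  ))
  keep("output", out)
  list(out = out, params = P, captures = caps)
}

# ---- public accounting functions ------------------------------------------

#' Count trainable parameters
#'
#' Exact integer sum of every trainable scalar: convolution and transposed
#' convolution weights and biases, attention weights and biases, and the
#' batch-normalization scale/shift pairs (running statistics are buffers,
#' not parameters).
#'
#' @param object a `manet_config` or fitted `manet` model.
#' @return parameter count (numeric scalar).
#' @examples
#' count_parameters(manet_config()) # the full-scale network
#' @export
count_parameters <- function(object) {
  if (inherits(object, "manet")) {
    return(sum(vapply(object$params, length, numeric(1))))
  }
  sum(layer_table(as_manet_config(object))$params)
}

#' Count multiply-accumulate operations
#'
#' Total MACs of one forward pass at the given square input extent, under
#' the profiler convention: `kernel_elements * c_in * c_out *
#' output_positions` per convolution or transposed convolution, both pooled
#' branches of each attention perceptron, and nothing for normalization,
#' activations or pooling.
#'
#' @inheritParams count_parameters
#' @param input_size square input extent in pixels (default 512).
#' @return MAC count (numeric scalar; divide by 1e9 for GMac).
#' @export
count_macs <- function(object, input_size = 512L) {
  cfg <- as_manet_config(object)
  div <- 2L^cfg$depth
  if (input_size %% div != 0L) {
    stop("input_size must be divisible by ", div)
  }
  sum(layer_table(cfg, input_size)$macs)
}

#' Layer-by-layer architecture trace
#'
#' Machine-checkable reproduction of the published topology table: one row
#' per layer with kernel, filter count, stride and output size.  The
#' numbered convolution rows (`conv_id` 1-15 on defaults) correspond to the
#' published table; auxiliary rows (projections, attention, normalization)
#' carry `conv_id = NA`.
#'
#' @inheritParams count_macs
#' @return data frame of class `manet_trace`.
#' @export
trace_layers <- function(object, input_size = 512L) {
  cfg <- as_manet_config(object)
  lt <- layer_table(cfg, input_size)
  out <- data.frame(
    block = lt$block,
    operation = ifelse(!is.na(lt$table_row), paste("Conv", lt$table_row),
      lt$name
    ),
    op = lt$op,
    kernel = ifelse(lt$op %in% c("conv", "convT"),
      paste0(lt$kernel, "x", lt$kernel), ""
    ),
    filters = lt$cout,
    stride = lt$stride,
    output = ifelse(lt$op == "dense", paste0("1x1x", lt$cout),
      paste0(lt$out, "x", lt$out, "x", lt$cout)
    ),
    conv_id = lt$table_row,
    params = lt$params,
    macs = lt$macs,
    stringsAsFactors = FALSE
  )
  class(out) <- c("manet_trace", "data.frame")
  out
}

#' @export
print.manet_trace <- function(x, ...) {
  df <- x[, c("block", "operation", "kernel", "filters", "stride", "output")]
  class(df) <- "data.frame"
  print(df, row.names = FALSE, ...)
  cat(sprintf(
    "total parameters: %s; total MACs: %.2f G\n",
    format(sum(x$params), big.mark = ","), sum(x$macs) / 1e9
  ))
  invisible(x)
}
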