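# The fitting front end: `manet()` trains a network with Dice loss and Adam
# and returns a classed model object with the usual methods.

state_as_list <- function(state) as.list(state)
state_as_env <- function(lst) list2env(lst, new.env(parent = emptyenv()))

# one-hot style target stack: channel 1 = background, last = tumour,
# middle channels (if any) stay empty unless extra label maps are supplied
make_targets <- function(masks, out_channels) {
  d <- dim(masks)
  t <- array(0, dim = c(d[1], d[2], out_channels, d[3]))
  if (out_channels == 1L) {
    t[, , 1L, ] <- masks
  } else {
    t[, , 1L, ] <- 1 - masks
    t[, , out_channels, ] <- masks
  }
  t
}

# replicate grayscale slices into the network's input channels
make_inputs <- function(imgs, idx, in_channels) {
  d <- dim(imgs)
  x <- array(0, dim = c(d[1], d[2], in_channels, length(idx)))
  for (j in seq_along(idx)) {
    for (c in seq_len(in_channels)) x[, , c, j] <- imgs[, , idx[j]]
  }
  x
}

adam_init <- function(params) {
  list(
    m = lapply(params, function(p) array(0, dim = dim(p) %||% length(p))),
    v = lapply(params, function(p) array(0, dim = dim(p) %||% length(p))),
    t = 0
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

adam_step <- function(params, grads, opt, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  opt$t <- opt$t + 1
  bc1 <- 1 - beta1^opt$t
  bc2 <- 1 - beta2^opt$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    opt$m[[nm]] <- beta1 * opt$m[[nm]] + (1 - beta1) * g
    opt$v[[nm]] <- beta2 * opt$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (opt$m[[nm]] / bc1) / (sqrt(opt$v[[nm]] / bc2) + eps)
  }
  list(params = params, opt = opt)
}

#' Learning-rate schedule
#'
#' Step decay: the initial rate is attenuated by `factor` every `every`
#' epochs, i.e. `lr * factor^(epoch %/% every)` — 1e-4 for epochs 1-29,
#' 1e-5 from epoch 30, 1e-6 from epoch 60 on the defaults.
#'
#' @param epoch epoch number (1-based).
#' @param lr initial learning rate.
#' @param factor decay factor.
#' @param every decay interval in epochs.
#' @export
lr_at_epoch <- function(epoch, lr = 1e-4, factor = 0.1, every = 30L) {
  lr * factor^(epoch %/% every)
}

#' Fit a multi-attention segmentation network
#'
#' Trains the network with the soft Dice loss and step-decayed Adam, doing
#' real-time augmentation on each batch, evaluating the held-out set after
#' every epoch and keeping the weights with the highest test Dice.  With
#' `epochs = 0` (or no data) the initialized, untrained network is returned,
#' which is what [trace_layers()], [count_parameters()] and [count_macs()]
#' operate on just as well.
#'
#' There is deliberately no validation split: checkpoint selection uses the
#' test set, mirroring the training protocol this implements — an
#' optimistic-selection choice, which evaluation reports inherit.
#'
#' @param x training images, array `(h, w, n)` with values in `[0, 1]`
#'   (grayscale slices are replicated into the network's input channels) or
#'   `(h, w, c, n)`.
#' @param y training masks, binary array `(h, w, n)`.
#' @param config a [manet_config()].
#' @param epochs training epochs (protocol default 80).
#' @param batch_size batch size (protocol default 4).
#' @param lr initial Adam learning rate (protocol default 1e-4).
#' @param lr_decay,lr_decay_every step-decay factor and interval.
#' @param smooth Dice-loss smoothing constant.
#' @param augment an [augment_spec()], or `NULL` to disable augmentation.
#' @param test optional held-out set, `list(x =, y =)`, used for per-epoch
#'   Dice logging and best-checkpoint selection.
#' @param seed integer seed making initialization, shuffling and
#'   augmentation reproducible.
#' @param precision `"single"` (default) or `"double"` compute precision.
#' @param verbose print one line per epoch.
#' @return object of class `manet` with elements `config`, `params`,
#'   `state`, `history` (epoch, loss, lr, test_dice), `best_epoch`.
#' @seealso [predict.manet()], [evaluate_manet()], [phantom_dataset()]
#' @export
manet <- function(x = NULL, y = NULL, config = manet_config(), epochs = 80L,
                  batch_size = 4L, lr = 1e-4, lr_decay = 0.1,
                  lr_decay_every = 30L, smooth = 1, augment = augment_spec(),
                  test = NULL, seed = NULL, precision = c("single", "double"),
                  verbose = TRUE) {
  cfg <- as_manet_config(config)
  precision <- match.arg(precision)
  if (!is.null(seed)) set.seed(seed)
  net <- nn_init(cfg)
  model <- structure(
    list(
      config = cfg, params = net$params, state = state_as_list(net$state),
      history = data.frame(), best_epoch = NA_integer_,
      precision = precision, smooth = smooth, call = match.call()
    ),
    class = "manet"
  )
  if (is.null(x) || epochs < 1L) {
    return(model)
  }
  if (length(dim(x)) != 3L) stop("x must be an (h, w, n) array of slices")
  if (!all(dim(y) == dim(x))) stop("y must match x in extent and count")
  n <- dim(x)[3]
  if (n < 1L) stop("empty training set")
  state <- net$state
  params <- net$params
  opt <- adam_init(params)
  fg <- if (cfg$out_channels == 1L) 1L else seq(2L, cfg$out_channels)
  hist <- vector("list", epochs)
  best <- list(dice = -Inf, params = params, state = state_as_list(state), epoch = NA)
  for (epoch in seq_len(epochs)) {
    lr_e <- lr_at_epoch(epoch, lr, lr_decay, lr_decay_every)
    ord <- sample.int(n)
    losses <- numeric(0)
    for (start in seq(1L, n, by = batch_size)) {
      idx <- ord[start:min(start + batch_size - 1L, n)]
      xb <- array(0, dim = c(dim(x)[1], dim(x)[2], 1L, length(idx)))
      yb <- array(0, dim = c(dim(x)[1], dim(x)[2], 1L, length(idx)))
      for (j in seq_along(idx)) {
        im <- x[, , idx[j]]
        mk <- y[, , idx[j]]
        if (!is.null(augment)) {
          a <- augment_pair(im, mk, augment)
          im <- a$image
          mk <- a$mask
        }
        xb[, , 1L, j] <- im
        yb[, , 1L, j] <- mk
      }
      xin <- array(xb[, , rep.int(1L, cfg$in_channels), , drop = FALSE],
        dim = c(dim(xb)[1], dim(xb)[2], cfg$in_channels, length(idx))
      )
      tgt <- make_targets(array(yb, dim = c(dim(yb)[1], dim(yb)[2], length(idx))),
        out_channels = cfg$out_channels
      )
      tape <- tape_new(precision)
      fw <- nn_forward(cfg, params, state, xin, training = TRUE, tape = tape)
      loss <- op_dice_loss(tape, fw$out, tgt, smooth = smooth, channels = fg)
      if (!is.finite(loss$value)) {
        stop("non-finite loss at epoch ", epoch, "; aborting training")
      }
      backward(tape, loss)
      grads <- lapply(as.list(fw$params), function(nd) nd$grad)
      st <- adam_step(params, grads, opt, lr_e)
      params <- st$params
      opt <- st$opt
      losses <- c(losses, loss$value)
    }
    td <- NA_real_
    if (!is.null(test)) {
      td <- mean_test_dice(cfg, params, state, test$x, test$y,
        precision = precision
      )
      if (td > best$dice) {
        best <- list(
          dice = td, params = params,
          state = state_as_list(state), epoch = epoch
        )
      }
    }
    hist[[epoch]] <- data.frame(
      epoch = epoch, loss = mean(losses),
      lr = lr_e, test_dice = td
    )
    if (verbose) {
      message(sprintf(
        "epoch %3d  loss %.4f  lr %.1e  test dice %s",
        epoch, mean(losses), lr_e,
        if (is.na(td)) "-" else sprintf("%.4f", td)
      ))
    }
  }
  if (is.null(test)) {
    best <- list(
      dice = NA_real_, params = params,
      state = state_as_list(state), epoch = epochs
    )
  }
  model$params <- best$params
  model$state <- best$state
  model$history <- do.call(rbind, hist)
  model$best_epoch <- best$epoch
  model
}

mean_test_dice <- function(cfg, params, state_env_or_list, x, y, precision) {
  pm <- predict_prob(cfg, params, state_env_or_list, x, precision)
  ch <- dim(pm)[3]
  d <- vapply(seq_len(dim(pm)[4]), function(i) {
    dice_pair(pm[, , ch, i] >= 0.5, y[, , i] > 0.5)
  }, numeric(1))
  mean(d)
}

# Dice with the empty-mask policy: both empty -> 1, one empty -> 0.
dice_pair <- function(a, b) {
  sa <- sum(a)
  sb <- sum(b)
  if (sa == 0 && sb == 0) {
    return(1)
  }
  2 * sum(a & b) / (sa + sb)
}

predict_prob <- function(cfg, params, state, x, precision, batch_size = 8L) {
  if (is.environment(state)) state <- state_as_list(state)
  if (is.matrix(x)) x <- array(x, dim = c(dim(x), 1L))
  if (length(dim(x)) == 3L) {
    n <- dim(x)[3]
    grab <- function(idx) make_inputs(x, idx, cfg$in_channels)
  } else {
    n <- dim(x)[4]
    grab <- function(idx) x[, , , idx, drop = FALSE]
  }
  out <- NULL
  st <- state_as_env(state) # eval mode: running stats are read, not written
  for (start in seq(1L, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, n)
    fw <- nn_forward(cfg, params, st, grab(idx),
      training = FALSE,
      tape = NULL
    )
    p <- fw$out$value
    if (is.null(out)) out <- array(0, dim = c(dim(p)[1:3], n))
    out[, , , idx] <- p
  }
  out
}

#' Predict segmentation maps
#'
#' @param object fitted (or initialized) `manet` model.
#' @param x slices `(h, w, n)`, a single matrix, or a ready input batch
#'   `(h, w, c, n)`.
#' @param type `"prob"` for the full sigmoid probability field
#'   `(h, w, c, n)`, `"mask"` for the tumour channel binarized at 0.5
#'   (`(h, w, n)` array).
#' @param threshold binarization threshold for `type = "mask"`.
#' @param ... unused.
#' @export
predict.manet <- function(object, x, type = c("prob", "mask"),
                          threshold = 0.5, ...) {
  type <- match.arg(type)
  p <- predict_prob(object$config, object$params, object$state, x,
    precision = object$precision
  )
  if (type == "prob") {
    return(p)
  }
  ch <- dim(p)[3]
  array((p[, , ch, , drop = FALSE] >= threshold) * 1, dim = dim(p)[c(1, 2, 4)])
}

#' @export
print.manet <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "Multi-attention segmentation network ('%s')\n", cfg$variant
  ))
  cat(sprintf(
    "  encoder %s | bridge %d | decoder %s -> %d | classes %d\n",
    paste(cfg$encoder_widths, collapse = "/"), cfg$bridge_width,
    paste(cfg$decoder_widths, collapse = "/"), cfg$final_width,
    cfg$out_channels
  ))
  cat(sprintf(
    "  trainable parameters: %s (%.2f M)\n",
    format(count_parameters(x), big.mark = ","), count_parameters(x) / 1e6
  ))
  if (nrow(x$history) > 0) {
    cat(sprintf(
      "  trained %d epochs; best test Dice %.4f at epoch %d\n",
      nrow(x$history), max(x$history$test_dice, na.rm = TRUE), x$best_epoch
    ))
  } else {
    cat("  untrained (initialized weights)\n")
  }
  invisible(x)
}

#' @export
summary.manet <- function(object, input_size = NULL, ...) {
  print(object)
  is <- input_size %||% 2L^object$config$depth * 8L
  cat("\nLayer trace at input", is, "x", is, ":\n")
  print(trace_layers(object$config, is))
  invisible(object)
}

#' @export
coef.manet <- function(object, ...) object$params

#' @export
plot.manet <- function(x, ...) {
  h <- x$history
  if (nrow(h) == 0) {
    stop("model has no training history")
  }
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  plot(h$epoch, h$loss,
    type = "l", xlab = "epoch", ylab = "Dice loss",
    main = "training loss", ...
  )
  if (any(!is.na(h$test_dice))) {
    plot(h$epoch, h$test_dice,
      type = "l", xlab = "epoch",
      ylab = "test Dice", main = "held-out Dice", ...
    )
    graphics::abline(v = x$best_epoch, lty = 2)
  }
  invisible(x)
}

#' Save / load a fitted model
#'
#' The checkpoint is an RDS container holding the weights, the
#' batch-normalization buffers, the training history and the architecture
#' configuration (also embedded as a YAML string for external tools).
#'
#' @param model fitted `manet` object.
#' @param path file path.
#' @export
write_manet <- function(model, path) {
  model$config_yaml <- yaml::as.yaml(unclass(model$config)[
    setdiff(names(model$config), "flags")
  ])
  saveRDS(model, path)
  invisible(path)
}

#' @rdname write_manet
#' @export
read_manet <- function(path) {
  m <- readRDS(path)
  stopifnot(inherits(m, "manet"))
  m
}
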