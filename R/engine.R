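# Training/evaluation orchestration helpers: the standalone Dice loss,
# model evaluation against the metric suite, the ablation harness and
# feature-map visualization.

#' Soft Dice loss
#'
#' `1 - (2 * sum(p*t) + s) / (sum(p) + sum(t) + s)`, computed per sample and
#' per selected channel, then averaged.  `pred` holds probabilities in
#' (0, 1); the smoothing constant `s` keeps the loss defined on empty masks.
#'
#' @param pred probability array `(h, w, c, b)` (or a plain matrix).
#' @param target binary array of the same shape.
#' @param smooth smoothing constant (default 1).
#' @param channels channel indices entering the average (default: all).
#' @return scalar loss in `[0, 1]`.
#' @examples
#' p <- array(0.5, dim = c(2, 2, 1, 1))
#' t <- array(c(1, 1, 0, 0), dim = c(2, 2, 1, 1))
#' dice_loss(p, t) # 1 - (2*1 + 1)/(2 + 2 + 1) = 0.4
#' @export
dice_loss <- function(pred, target, smooth = 1, channels = NULL) {
  if (is.matrix(pred)) pred <- array(pred, dim = c(dim(pred), 1L, 1L))
  if (is.matrix(target)) target <- array(target, dim = c(dim(target), 1L, 1L))
  if (!all(dim(pred) == dim(target))) stop("pred and target shapes differ")
  node <- op_dice_loss(NULL, nd(NULL, pred), target,
    smooth = smooth,
    channels = channels
  )
  node$value
}

#' Evaluate a fitted model on a slice set
#'
#' Binarizes the tumour probability channel at `threshold` and computes the
#' seven-metric report in slice or volume grouping.
#'
#' @param model fitted `manet`.
#' @param x slices `(h, w, n)` in `[0, 1]`.
#' @param y binary masks `(h, w, n)`.
#' @param grouping `"slice"` or `"volume"`.
#' @param volume_ids per-slice volume ids for volume grouping.
#' @param spacing optional pixel spacing (mm) for ASSD.
#' @param threshold binarization threshold.
#' @return a [segmentation_report()] object.
#' @export
evaluate_manet <- function(model, x, y, grouping = c("slice", "volume"),
                           volume_ids = NULL, spacing = NULL, threshold = 0.5) {
  grouping <- match.arg(grouping)
  pred <- predict(model, x, type = "mask", threshold = threshold)
  segmentation_report(pred, y > 0.5,
    grouping = grouping,
    volume_ids = volume_ids, spacing = spacing
  )
}

#' Ablation harness
#'
#' Builds every requested architecture variant at shared widths, trains each
#' for a (typically reduced) number of epochs on the same data and reports
#' the ablation table: variant, parameter count and the seven test metrics.
#'
#' @param variants subset of the eight variant names (default: all).
#' @param data list with `images`, `masks` (e.g. from [phantom_dataset()]);
#'   when `NULL`, a small phantom set is generated.
#' @param config_fn function(variant) returning the [manet_config()] to
#'   build; defaults to a reduced-width configuration.
#' @param epochs epochs per variant.
#' @param seed integer seed shared by all variants.
#' @param ... further arguments passed to [manet()].
#' @return data frame with one row per variant.
#' @export
run_ablation <- function(variants = manet_variants, data = NULL,
                         config_fn = NULL, epochs = 1L, seed = 1L, ...) {
  bad <- setdiff(variants, manet_variants)
  if (length(bad)) stop("unknown variant: ", paste(bad, collapse = ", "))
  if (is.null(config_fn)) {
    config_fn <- function(v) {
      manet_config(
        variant = v, encoder_widths = c(8L, 16L, 32L),
        bridge_width = 64L
      )
    }
  }
  if (is.null(data)) {
    data <- phantom_dataset(phantom_spec(extent = 64L),
      n_volumes = 2L,
      seed = seed
    )
  }
  n <- dim(data$images)[3]
  sp <- split_dataset(n, seed = seed)
  imgs <- preprocess_slices(data$images)
  rows <- lapply(variants, function(v) {
    cfg <- config_fn(v)
    fit <- manet(imgs[, , sp$train], data$masks[, , sp$train],
      config = cfg,
      epochs = epochs, seed = seed, verbose = FALSE,
      test = list(x = imgs[, , sp$test], y = data$masks[, , sp$test]), ...
    )
    rep <- evaluate_manet(fit, imgs[, , sp$test], data$masks[, , sp$test])
    a <- rep$aggregate
    stat <- function(m) a$mean[a$metric == m]
    data.frame(
      variant = v, parameters = count_parameters(cfg),
      dice = stat("dice"), assd = stat("assd"), jaccard = stat("jaccard"),
      voe = stat("voe"), accuracy = stat("accuracy"),
      sensitivity = stat("sensitivity"), specificity = stat("specificity"),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

#' Best checkpoint by held-out Dice
#'
#' @param history data frame with `epoch` and `test_dice` columns.
#' @return the epoch with the maximal test Dice.
#' @export
select_best_epoch <- function(history) {
  stopifnot(all(c("epoch", "test_dice") %in% names(history)))
  history$epoch[which.max(history$test_dice)]
}

# min-max scale a matrix to [0, 1]; a degenerate range maps to flat 0.5
minmax_scale <- function(m) {
  rng <- range(m)
  if (rng[1] == rng[2]) {
    return(matrix(0.5, nrow(m), ncol(m)))
  }
  (m - rng[1]) / (rng[2] - rng[1])
}

#' Visualize intermediate feature maps
#'
#' Runs one input through the network, captures the selected layers,
#' averages each over channels and min-max scales the result to `[0, 1]`
#' (a constant map renders mid-gray).  For attention layers both the map
#' before the operator and the one after are captured, so the PNG pairs
#' show what the gate suppressed.
#'
#' @param model fitted or initialized `manet`.
#' @param x a single slice (matrix) or input batch.
#' @param layers layer names; defaults to the encoder/bridge/decoder block
#'   outputs.  Valid names include `enc1..encD`, `bridge`, `dec1..decD`,
#'   `encK_pre_ca`, `decK_pre_sa`, `bridge_pre_cbam`, `decK_scag_att`,
#'   `decK_sa_att`, `encK_ca_att` and `output`.
#' @param dir optional directory; when given, each map is written as
#'   `<layer>.png`.
#' @return named list of `[0, 1]` matrices (invisibly when writing PNGs).
#' @export
visualize_features <- function(model, x, layers = NULL, dir = NULL) {
  cfg <- model$config
  D <- cfg$depth
  if (is.null(layers)) {
    layers <- c(paste0("enc", seq_len(D)), "bridge", paste0("dec", seq_len(D)))
  }
  if (is.matrix(x)) x <- array(x, dim = c(dim(x), 1L))
  if (length(dim(x)) == 3L) x <- make_inputs(x, seq_len(dim(x)[3]), cfg$in_channels)
  st <- state_as_env(model$state)
  fw <- nn_forward(cfg, model$params, st, x,
    training = FALSE, tape = NULL,
    capture = layers
  )
  missing <- setdiff(layers, names(fw$captures))
  if (length(missing)) {
    stop("unknown layer(s): ", paste(missing, collapse = ", "))
  }
  maps <- lapply(fw$captures, function(v) {
    d <- dim(v)
    hw <- d[1] * d[2]
    M <- v[, , , 1L, drop = FALSE]
    dim(M) <- c(hw, d[3])
    minmax_scale(matrix(.rowMeans(M, hw, d[3]), d[1], d[2]))
  })
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    for (nm in names(maps)) {
      png::writePNG(maps[[nm]], file.path(dir, paste0(nm, ".png")))
    }
    return(invisible(maps))
  }
  maps
}

#' Reduced-scale phantom benchmark
#'
#' The package's end-to-end reference experiment at desk scale: 200 phantom
#' slices at 96 x 96 (ten volumes), windowed/equalized, split 4:1, a reduced
#' network (encoder 17/34/68, bridge 136) trained for 15 epochs with batch
#' size 4 and learning rate 1e-4, best checkpoint selected by held-out Dice.
#' Everything derives from `seed`, so a run is fully reproducible.
#'
#' @param seed integer seed driving generation, splitting and training.
#' @param epochs training epochs.
#' @param n_volumes phantom volumes (20 slices each).
#' @param config network configuration; default is the reduced network.
#' @param spec phantom generator settings.
#' @param keep_model also return the fitted model.
#' @param verbose print per-epoch lines.
#' @return list with `best_dice`, `best_epoch`, `history` and optionally
#'   `model` plus the held-out data.
#' @export
phantom_benchmark <- function(seed, epochs = 15L, n_volumes = 10L,
                              config = manet_config(
                                encoder_widths = c(17L, 34L, 68L),
                                bridge_width = 136L
                              ),
                              spec = phantom_spec(), keep_model = FALSE,
                              verbose = FALSE) {
  ph <- phantom_dataset(spec, n_volumes = n_volumes, seed = seed)
  imgs <- preprocess_slices(ph$images)
  n <- dim(imgs)[3]
  sp <- split_dataset(n, seed = seed)
  test <- list(x = imgs[, , sp$test], y = ph$masks[, , sp$test])
  fit <- manet(imgs[, , sp$train], ph$masks[, , sp$train],
    config = config,
    epochs = epochs, batch_size = 4L, lr = 1e-4, seed = seed,
    test = test, verbose = verbose
  )
  out <- list(
    best_dice = max(fit$history$test_dice, na.rm = TRUE),
    best_epoch = fit$best_epoch, history = fit$history
  )
  if (keep_model) {
    out$model <- fit
    out$test <- test
  }
  out
}
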