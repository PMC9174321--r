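# U-net nuclei segmentation: Dice loss, model construction, training and
# heatmap prediction. Heatmaps stay soft throughout the pipeline -- they
# are never thresholded, because cytoplasm and cell-shape context around
# nuclei also carries signal for the downstream classifier.

#' Dice loss between a predicted heatmap and a binary mask
#'
#' \code{1 - 2 * (sum(p * y) + eps) / (sum(p) + sum(y) + eps)}, summed over
#' all pixels; \code{eps} keeps the denominator non-zero on empty scenes.
#'
#' @param pred Predicted probabilities in [0, 1] (matrix).
#' @param truth Binary ground-truth mask of the same shape.
#' @param epsilon Smoothing constant (default 1e-8).
#' @return Scalar loss in [0, 1].
#' @export
dice_loss <- function(pred, truth, epsilon = 1e-8) {
  if (!all(dim(pred) == dim(truth)))
    stop_param("pred and truth must have identical dimensions")
  check_number(epsilon, "epsilon", lower = 0, open_lower = TRUE)
  1 - 2 * (sum(pred * truth) + epsilon) /
    (sum(pred) + sum(truth) + epsilon)
}

#' Configuration for U-net segmentation training
#'
#' @param depth Number of encoder (pooling) levels (>= 2); input edge must
#'   be divisible by \code{2^depth}.
#' @param base_channels Channels of the first encoder level; doubled per
#'   level.
#' @param epochs Training epochs.
#' @param learning_rate Adam learning rate.
#' @param epsilon Dice smoothing constant.
#' @param val_fraction Held-out fraction for validation Dice (seeded
#'   shuffle split).
#' @param augment Apply random horizontal/vertical flips during training.
#' @param seed Integer seed (initialization, split, shuffling).
#' @return Object of class \code{seg_train_config}.
#' @export
seg_train_config <- function(depth = 4, base_channels = 16, epochs = 10,
                             learning_rate = 1e-3, epsilon = 1e-8,
                             val_fraction = 0.2, augment = TRUE, seed = 1L) {
  check_number(depth, "depth", lower = 2)
  check_number(base_channels, "base_channels", lower = 1)
  check_number(epochs, "epochs", lower = 0)
  check_number(learning_rate, "learning_rate", lower = 0, open_lower = TRUE)
  check_number(epsilon, "epsilon", lower = 0, open_lower = TRUE)
  check_number(val_fraction, "val_fraction", lower = 0, upper = 0.9)
  structure(list(depth = as.integer(depth),
                 base_channels = as.integer(base_channels),
                 epochs = as.integer(epochs),
                 learning_rate = learning_rate, epsilon = epsilon,
                 val_fraction = val_fraction, augment = isTRUE(augment),
                 seed = as.integer(seed)),
            class = "seg_train_config")
}

#' Build an untrained U-net segmentation model
#'
#' Encoder-decoder with skip connections at each level and a per-pixel
#' sigmoid output; 3 input channels, 1 output channel. Initialization is a
#' pure function of the config seed.
#'
#' @param config A \code{\link{seg_train_config}}.
#' @return Object of class \code{unet_model} (weights, config, empty
#'   history).
#' @export
build_unet <- function(config = seg_train_config()) {
  stopifnot(inherits(config, "seg_train_config"))
  ptr <- .unet_create(config$depth, config$base_channels, 3L,
                      derive_seed(config$seed, "unet-init"))
  structure(list(config = config, weights = .unet_get_weights(ptr),
                 history = data.frame(epoch = integer(0),
                                      train_loss = numeric(0),
                                      val_dice = numeric(0))),
            class = "unet_model")
}

unet_ptr <- function(model) {
  ptr <- .unet_create(model$config$depth, model$config$base_channels, 3L, 1)
  .unet_set_weights(ptr, model$weights)
  ptr
}

seg_pair_image <- function(p) {
  img <- if (inherits(p, "sim_tile")) p$image else p$image
  as_image255(img) / 255
}

flip_img <- function(a, h, v) {
  if (h) a <- if (length(dim(a)) == 3L) a[, rev(seq_len(ncol(a))), , drop = FALSE]
             else a[, rev(seq_len(ncol(a))), drop = FALSE]
  if (v) a <- if (length(dim(a)) == 3L) a[rev(seq_len(nrow(a))), , , drop = FALSE]
             else a[rev(seq_len(nrow(a))), , drop = FALSE]
  a
}

#' Train a U-net on image/mask pairs with Dice loss
#'
#' @param pairs List of pairs; each element needs an \code{image}
#'   (H x W x 3) and a binary \code{mask} (objects returned by
#'   \code{\link{generate_nuclei_tile}} work directly).
#' @param config A \code{\link{seg_train_config}}.
#' @return A \code{unet_model} with trained weights and a per-epoch
#'   history (mean training Dice loss, held-out soft Dice score).
#' @export
train_unet <- function(pairs, config = seg_train_config()) {
  stopifnot(inherits(config, "seg_train_config"))
  if (length(pairs) < 2) stop_param("need at least 2 training pairs")
  model <- build_unet(config)
  if (config$epochs == 0) return(model)
  ptr <- unet_ptr(model)
  n <- length(pairs)
  imgs <- lapply(pairs, seg_pair_image)
  masks <- lapply(pairs, function(p) {
    m <- p$mask
    if (!all(m %in% c(0, 1))) stop_param("masks must be binary")
    m
  })
  hist <- with_seed(derive_seed(config$seed, "unet-train"), {
    n_val <- if (config$val_fraction > 0)
      max(1L, round(config$val_fraction * n)) else 0L
    idx <- sample.int(n)
    val_idx <- if (n_val > 0) idx[seq_len(n_val)] else integer(0)
    tr_idx <- setdiff(idx, val_idx)
    if (length(tr_idx) == 0) stop_param("validation split left no training pairs")
    hist <- vector("list", config$epochs)
    for (ep in seq_len(config$epochs)) {
      losses <- numeric(length(tr_idx))
      ord <- sample(tr_idx)
      for (k in seq_along(ord)) {
        i <- ord[k]
        img <- imgs[[i]]; msk <- masks[[i]]
        if (config$augment) {
          h <- runif(1) < 0.5; v <- runif(1) < 0.5
          img <- flip_img(img, h, v); msk <- flip_img(msk, h, v)
        }
        losses[k] <- .unet_train_step(ptr, img, msk,
                                      config$learning_rate, config$epsilon)
      }
      vd <- if (length(val_idx)) {
        mean(vapply(val_idx, function(i) {
          1 - dice_loss(.unet_predict(ptr, imgs[[i]]), masks[[i]],
                        config$epsilon)
        }, numeric(1)))
      } else NA_real_
      hist[[ep]] <- data.frame(epoch = ep, train_loss = mean(losses),
                               val_dice = vd)
    }
    do.call(rbind, hist)
  })
  model$weights <- .unet_get_weights(ptr)
  model$history <- hist
  model
}

#' Predict a soft nuclei heatmap for a tile
#'
#' The output is a probability map and is deliberately not thresholded.
#'
#' @param model A \code{unet_model}.
#' @param tile Image array (H x W x 3; 0-255 or [0,1]), \code{tile_record}
#'   or \code{sim_tile}.
#' @return Matrix of per-pixel probabilities in [0, 1], same spatial size.
#' @export
predict_heatmap <- function(model, tile) {
  stopifnot(inherits(model, "unet_model"))
  px <- if (inherits(tile, "tile_record")) tile$pixels else
    if (inherits(tile, "sim_tile")) tile$image else as_image255(tile)
  d <- dim(px)
  if (d[1] %% 2^model$config$depth != 0 || d[2] %% 2^model$config$depth != 0)
    stop_param("tile dimensions must be divisible by 2^depth = ",
               2^model$config$depth)
  .unet_predict(unet_ptr(model), px / 255)
}

#' @export
predict.unet_model <- function(object, newdata, ...) {
  if (is.list(newdata) && !inherits(newdata, c("tile_record", "sim_tile")) &&
      !is.array(newdata))
    lapply(newdata, function(t) predict_heatmap(object, t))
  else predict_heatmap(object, newdata)
}

#' @export
print.unet_model <- function(x, ...) {
  cat(sprintf("<unet_model> depth %d, base %d channels, %s parameters\n",
              x$config$depth, x$config$base_channels,
              format(length(x$weights), big.mark = ",")))
  if (nrow(x$history)) {
    last <- x$history[nrow(x$history), ]
    cat(sprintf("  trained %d epochs; final train Dice loss %.4f, held-out Dice %.4f\n",
                nrow(x$history), last$train_loss, last$val_dice))
  } else cat("  untrained (initialization only)\n")
  invisible(x)
}

#' @export
plot.unet_model <- function(x, ...) {
  if (!nrow(x$history)) stop_param("no training history to plot")
  graphics::par(mfrow = c(1, 2))
  plot(x$history$epoch, x$history$train_loss, type = "b",
       xlab = "epoch", ylab = "mean Dice loss", main = "training loss", ...)
  plot(x$history$epoch, x$history$val_dice, type = "b",
       xlab = "epoch", ylab = "held-out Dice", main = "validation Dice", ...)
  graphics::par(mfrow = c(1, 1))
  invisible(x)
}
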