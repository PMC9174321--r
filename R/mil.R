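# Multiple-instance learning core: four-channel tile assembly, signed
# generalized-mean bag aggregation, threshold classification, the
# piecewise probability transform, the L2-regularized cross-entropy
# objective, the bag-level training loop over a MobileNetV2-style
# per-tile scorer, and high-predictability tile retrieval.
#
# Label convention (stated once, used everywhere): a bag label of 1 means
# GOOD outcome / LOW recurrence risk. The probability transform maps high
# activated bag scores to low p, so cross-entropy drives good-outcome bags
# toward low activated scores; the activated score itself is the reported
# risk score, and `predicted_class = 1` flags the high-score (high-risk)
# class.

#' MIL training configuration
#'
#' Defaults are the published operating point of the classifier:
#' aggregation exponent p = 3, decision threshold t = 0.4457, L2 factor
#' alpha = 0.02, Adam at an initial learning rate of 1e-4 halving every
#' 10 epochs, bag batch size 1.
#'
#' @param aggregation_exponent Generalized-mean exponent p (>= 1).
#' @param threshold Decision threshold t on the sigmoid-activated bag
#'   score, in (0, 1).
#' @param l2_alpha Weight of the L2 penalty on all trainable weights.
#' @param initial_lr Initial Adam learning rate.
#' @param lr_halving_epochs Epoch period after which the rate halves.
#' @param epochs Training epochs.
#' @param bag_batch_size Bags per optimizer step (only 1 is supported).
#' @param backbone_variant "tiny" (3 inverted-residual stages, for
#'   CPU-scale work) or "standard" (the published MobileNetV2 topology).
#' @param power_mean Use the normalized power mean
#'   \code{(mean(s^p))^(1/p)} instead of the plain p-norm.
#' @param log_clip Probabilities are clipped to
#'   \code{[log_clip, 1 - log_clip]} before logarithms.
#' @param seed Integer seed.
#' @return Object of class \code{mil_config}.
#' @export
mil_config <- function(aggregation_exponent = 3, threshold = 0.4457,
                       l2_alpha = 0.02, initial_lr = 1e-4,
                       lr_halving_epochs = 10, epochs = 20,
                       bag_batch_size = 1,
                       backbone_variant = c("tiny", "standard"),
                       power_mean = FALSE, log_clip = 1e-7, seed = 1L) {
  check_number(aggregation_exponent, "aggregation_exponent", lower = 1)
  check_number(threshold, "threshold", lower = 0, upper = 1,
               open_lower = TRUE, open_upper = TRUE)
  check_number(l2_alpha, "l2_alpha", lower = 0)
  check_number(initial_lr, "initial_lr", lower = 0, open_lower = TRUE)
  check_number(lr_halving_epochs, "lr_halving_epochs", lower = 1)
  check_number(epochs, "epochs", lower = 0)
  if (bag_batch_size != 1)
    stop_param("only bag_batch_size = 1 is supported")
  structure(list(aggregation_exponent = aggregation_exponent,
                 threshold = threshold, l2_alpha = l2_alpha,
                 initial_lr = initial_lr,
                 lr_halving_epochs = as.integer(lr_halving_epochs),
                 epochs = as.integer(epochs), bag_batch_size = 1L,
                 backbone_variant = match.arg(backbone_variant),
                 power_mean = isTRUE(power_mean), log_clip = log_clip,
                 seed = as.integer(seed)),
            class = "mil_config")
}

#' Stack an RGB tile and a nuclei heatmap into a four-channel tile
#'
#' Channel order (R, G, B, H); RGB is scaled to [0, 1], the heatmap is
#' already a probability map.
#'
#' @param rgb_tile H x W x 3 array (0-255 or [0,1]).
#' @param heatmap H x W probability matrix in [0, 1].
#' @return H x W x 4 array on [0, 1].
#' @export
assemble_four_channel <- function(rgb_tile, heatmap) {
  px <- as_image255(rgb_tile) / 255
  if (!all(dim(px)[1:2] == dim(heatmap)))
    stop_param("heatmap and tile spatial sizes differ")
  if (min(heatmap) < 0 || max(heatmap) > 1)
    stop_param("heatmap values must lie in [0, 1]")
  out <- array(0, c(dim(px)[1:2], 4L))
  out[, , 1:3] <- px
  out[, , 4] <- heatmap
  out
}

#' Split a four-channel tile back into RGB and heatmap
#' @param tile H x W x 4 array as produced by
#'   \code{\link{assemble_four_channel}}.
#' @return List with \code{rgb} (0-255) and \code{heatmap}.
#' @export
split_four_channel <- function(tile) {
  stopifnot(length(dim(tile)) == 3L, dim(tile)[3] == 4L)
  list(rgb = tile[, , 1:3, drop = FALSE] * 255, heatmap = tile[, , 4])
}

#' Aggregate per-tile scores into a bag score (signed generalized mean)
#'
#' \code{S = sign(g) * |g|^(1/p)} with \code{g = sum(sign(s) * |s|^p)}:
#' the signed p-norm, identical to \code{(sum(s^p))^(1/p)} for
#' non-negative scores. It keeps the extremes while taking the average
#' into account: p = 1 gives the plain sum and p -> Inf approaches the
#' maximum. Computed in a max-rescaled form so large exponents do not
#' overflow.
#'
#' @param scores Numeric vector of per-tile scores (length >= 1).
#' @param p Exponent (>= 1; default 3).
#' @param power_mean If TRUE, normalize by the tile count before the root
#'   (the \code{(mean s^p)^(1/p)} variant).
#' @return Scalar aggregate score S.
#' @export
aggregate_scores <- function(scores, p = 3, power_mean = FALSE) {
  if (length(scores) == 0) stop_param("cannot aggregate an empty score list")
  check_number(p, "p", lower = 1)
  m <- max(abs(scores))
  if (m == 0) return(0)
  g <- sum(sign(scores) * (abs(scores) / m)^p)
  if (power_mean) g <- g / length(scores)
  sign(g) * m * abs(g)^(1 / p)
}

#' Activate and threshold a bag score
#'
#' @param S Aggregate bag score.
#' @param t Decision threshold in (0, 1) (default 0.4457).
#' @return List with \code{activated} = sigmoid(S) and
#'   \code{predicted_class} (1 = high-score/high-risk class iff
#'   activated strictly exceeds t; a tie at exactly t goes to the
#'   non-exceeding class).
#' @export
classify_bag <- function(S, t = 0.4457) {
  check_number(t, "t", lower = 0, upper = 1, open_lower = TRUE,
               open_upper = TRUE)
  a <- plogis(S)
  list(activated = a, predicted_class = as.integer(a > t))
}

#' Piecewise probability transform of the activated bag score
#'
#' Maps the activated score s onto a probability of the good-outcome
#' class: \code{((t - s)/t + 1) * 0.5} for s <= t and
#' \code{(1 - (s - t)/(1 - t)) * 0.5} for s > t. Continuous and strictly
#' decreasing with fixed points p(0) = 1, p(t) = 0.5, p(1) = 0.
#'
#' @param s Activated score(s) in [0, 1].
#' @param t Threshold in (0, 1).
#' @return Transformed probabilities in [0, 1].
#' @export
transform_probability <- function(s, t = 0.4457) {
  check_number(t, "t", lower = 0, upper = 1, open_lower = TRUE,
               open_upper = TRUE)
  if (any(s < 0 | s > 1)) stop_param("activated scores must lie in [0, 1]")
  ifelse(s <= t, ((t - s) / t + 1) * 0.5, (1 - (s - t) / (1 - t)) * 0.5)
}

#' Cross-entropy with L2 regularization
#'
#' \code{-(1/N) sum(y log p + (1-y) log(1-p)) + alpha * sum(w^2)};
#' probabilities are clipped to \code{[clip, 1-clip]} before logarithms
#' since the transform can reach exactly 0 and 1.
#'
#' @param probs Transformed probabilities p_i.
#' @param labels Bag labels y_i (1 = good outcome).
#' @param weights Trainable-weight vector entering the L2 term.
#' @param alpha Regularization factor (default 0.02).
#' @param clip Log clipping constant (default 1e-7).
#' @return Scalar loss.
#' @export
mil_loss <- function(probs, labels, weights = numeric(0), alpha = 0.02,
                     clip = 1e-7) {
  if (length(probs) == 0) stop_param("empty batch")
  if (length(probs) != length(labels))
    stop_param("probs and labels must have equal length")
  p <- pmin(pmax(probs, clip), 1 - clip)
  -mean(labels * log(p) + (1 - labels) * log(1 - p)) +
    alpha * sum(weights^2)
}

#' Learning-rate schedule: halving decay
#'
#' \code{initial_lr * 0.5^floor(epoch / halving)} with 0-based epochs
#' (epoch 0 -> 1e-4, epoch 10 -> 5e-5, epoch 25 -> 2.5e-5 at defaults).
#'
#' @param epoch 0-based epoch index (vectorized).
#' @param initial_lr Initial learning rate.
#' @param halving Epoch period.
#' @return Learning rate(s).
#' @export
lr_schedule <- function(epoch, initial_lr = 1e-4, halving = 10) {
  initial_lr * 0.5^(floor(epoch / halving))
}

backbone_spec <- function(variant) {
  switch(variant,
    # desk-scale variant: 3 inverted-residual stages at ~0.25 width
    tiny = list(stem = 8L,
                blocks = matrix(c(4L, 8L, 1L, 2L,
                                  4L, 16L, 1L, 2L,
                                  4L, 24L, 1L, 2L), ncol = 4, byrow = TRUE,
                                dimnames = list(NULL, c("t", "c", "n", "s"))),
                head = 64L),
    # published MobileNetV2 topology at width multiplier 1.0
    standard = list(stem = 32L,
                    blocks = matrix(c(1L, 16L, 1L, 1L,
                                      6L, 24L, 2L, 2L,
                                      6L, 32L, 3L, 2L,
                                      6L, 64L, 4L, 2L,
                                      6L, 96L, 3L, 1L,
                                      6L, 160L, 3L, 2L,
                                      6L, 320L, 1L, 1L), ncol = 4,
                                    byrow = TRUE,
                                    dimnames = list(NULL,
                                                    c("t", "c", "n", "s"))),
                    head = 1280L),
    stop_param("unknown backbone variant '", variant, "'"))
}

#' Build a per-tile scoring backbone
#'
#' An inverted-residual bottleneck network (MobileNetV2 topology for the
#' "standard" variant; a 3-stage quarter-width version for "tiny") whose
#' first convolution accepts 4 channels and whose single-unit linear head
#' emits the raw tile score. Initialization is a pure function of the
#' seed.
#'
#' @param variant "tiny" or "standard".
#' @param in_channels Input channels (default 4: RGB + heatmap).
#' @param seed Integer seed.
#' @return Object of class \code{mil_backbone}.
#' @export
build_backbone <- function(variant = c("tiny", "standard"), in_channels = 4,
                           seed = 1L) {
  variant <- match.arg(variant)
  spec <- backbone_spec(variant)
  ptr <- .bb_create(as.integer(in_channels), spec$stem, spec$blocks,
                    spec$head, derive_seed(seed, "backbone-init"))
  structure(list(variant = variant, in_channels = as.integer(in_channels),
                 spec = spec, weights = .bb_get_weights(ptr)),
            class = "mil_backbone")
}

bb_ptr <- function(backbone) {
  ptr <- .bb_create(backbone$in_channels, backbone$spec$stem,
                    backbone$spec$blocks, backbone$spec$head, 1)
  .bb_set_weights(ptr, backbone$weights)
  ptr
}

#' Number of trainable parameters of a backbone
#' @param backbone A \code{mil_backbone} (or \code{mil_model}).
#' @return Integer parameter count.
#' @export
backbone_nparams <- function(backbone) {
  if (inherits(backbone, "mil_model")) backbone <- backbone$backbone
  length(backbone$weights)
}

#' Score tiles with a backbone
#' @param backbone A \code{mil_backbone} or \code{mil_model}.
#' @param tiles List of H x W x 4 arrays on [0, 1].
#' @return Numeric vector of raw tile scores.
#' @export
score_tiles <- function(backbone, tiles) {
  if (inherits(backbone, "mil_model")) backbone <- backbone$backbone
  stopifnot(inherits(backbone, "mil_backbone"))
  if (length(tiles) == 0) stop_param("no tiles to score")
  as.numeric(.bb_forward(bb_ptr(backbone), tiles))
}

bag_tiles <- function(bag) {
  if (inherits(bag, "mil_bag")) bag$tiles
  else if (is.list(bag)) bag
  else stop_param("expected a mil_bag or a list of 4-channel tiles")
}

# Gradient of the aggregate S with respect to each tile score, in the
# same max-rescaled form as aggregate_scores.
aggregate_grad <- function(scores, p, power_mean = FALSE) {
  m <- max(abs(scores))
  if (m == 0) return(rep(0, length(scores)))
  g <- sum(sign(scores) * (abs(scores) / m)^p)
  if (power_mean) g <- g / length(scores)
  if (g == 0) return(rep(0, length(scores)))
  d <- (abs(scores) / m)^(p - 1) * abs(g)^((1 - p) / p)
  if (power_mean) d <- d / length(scores)
  d
}

#' Train the MIL classifier on slide bags
#'
#' Per optimization step (one bag): score every tile, aggregate with the
#' signed generalized mean, apply the sigmoid, transform to a probability,
#' accumulate the L2-regularized cross-entropy, and backpropagate through
#' every tile. Adam with the halving learning-rate schedule. No per-tile
#' label is ever consumed: a bag carries exactly one label.
#'
#' @param bags List of \code{mil_bag} objects spanning both labels.
#' @param config A \code{\link{mil_config}}.
#' @return Object of class \code{mil_model}: trained backbone, config and
#'   per-epoch history (learning rate, mean loss, training accuracy).
#' @export
train_mil <- function(bags, config = mil_config()) {
  stopifnot(inherits(config, "mil_config"))
  if (length(bags) < 2) stop_param("need at least 2 bags")
  labels <- vapply(bags, function(b) b$label, integer(1))
  if (length(unique(labels)) < 2)
    stop_param("training bags must span both labels")
  backbone <- build_backbone(config$backbone_variant, 4L, config$seed)
  ptr <- bb_ptr(backbone)
  t <- config$threshold; p <- config$aggregation_exponent
  alpha <- config$l2_alpha; clip <- config$log_clip
  hist <- with_seed(derive_seed(config$seed, "mil-train"), {
    rows <- vector("list", config$epochs)
    for (ep in seq_len(config$epochs)) {
      lr <- lr_schedule(ep - 1L, config$initial_lr, config$lr_halving_epochs)
      ord <- sample(seq_along(bags))
      ce <- numeric(length(ord)); correct <- logical(length(ord))
      for (k in seq_along(ord)) {
        bag <- bags[[ord[k]]]
        tiles <- bag$tiles
        y <- bag$label
        s <- as.numeric(.bb_forward(ptr, tiles))
        S <- aggregate_scores(s, p, config$power_mean)
        a <- plogis(S)
        prob <- transform_probability(a, t)
        pc <- min(max(prob, clip), 1 - clip)
        dLdp <- (pc - y) / (pc * (1 - pc))
        dpda <- if (a <= t) -1 / (2 * t) else -1 / (2 * (1 - t))
        dadS <- a * (1 - a)
        ds <- dLdp * dpda * dadS *
          aggregate_grad(s, p, config$power_mean)
        .bb_train_bag(ptr, tiles, ds, lr, alpha)
        ce[k] <- -(y * log(pc) + (1 - y) * log(1 - pc))
        correct[k] <- (a > t) == (y == 0)
      }
      rows[[ep]] <- data.frame(epoch = ep, lr = lr,
                               loss = mean(ce) + alpha * .bb_l2(ptr),
                               accuracy = mean(correct))
    }
    do.call(rbind, rows)
  })
  backbone$weights <- .bb_get_weights(ptr)
  structure(list(backbone = backbone, config = config,
                 history = if (config$epochs > 0) hist else
                   data.frame(epoch = integer(0), lr = numeric(0),
                              loss = numeric(0), accuracy = numeric(0))),
            class = "mil_model")
}

#' Score one slide bag
#'
#' Deterministic inference: per-tile scores, signed generalized-mean
#' aggregate, sigmoid activation, transformed probability, and the
#' thresholded class.
#'
#' @param model A \code{mil_model} (or a \code{mil_backbone} scored at the
#'   default operating point).
#' @param bag A \code{mil_bag} or a list of 4-channel tiles.
#' @return Object of class \code{bag_score}: \code{tile_scores},
#'   \code{aggregate}, \code{activated}, \code{prob},
#'   \code{predicted_class} (1 = high-risk) and \code{slide_id}.
#' @export
predict_slide <- function(model, bag) {
  cfg <- if (inherits(model, "mil_model")) model$config else mil_config()
  tiles <- bag_tiles(bag)
  if (length(tiles) == 0) stop_param("empty bag")
  s <- score_tiles(model, tiles)
  S <- aggregate_scores(s, cfg$aggregation_exponent, cfg$power_mean)
  cls <- classify_bag(S, cfg$threshold)
  structure(list(slide_id = if (inherits(bag, "mil_bag")) bag$slide_id
                            else NA_character_,
                 tile_scores = s, aggregate = S,
                 activated = cls$activated,
                 prob = transform_probability(cls$activated, cfg$threshold),
                 predicted_class = cls$predicted_class),
            class = "bag_score")
}

#' @export
print.bag_score <- function(x, ...) {
  cat(sprintf("<bag_score> %s: S = %.4f, activated = %.4f, p = %.4f, class = %d (%s risk)\n",
              x$slide_id, x$aggregate, x$activated, x$prob,
              x$predicted_class,
              if (x$predicted_class == 1) "high" else "low"))
  invisible(x)
}

#' @export
predict.mil_model <- function(object, newdata, ...) {
  bags <- if (inherits(newdata, "mil_bag")) list(newdata) else newdata
  rows <- lapply(bags, function(b) {
    sc <- predict_slide(object, b)
    data.frame(slide_id = sc$slide_id, S = sc$aggregate,
               activated = sc$activated, prob = sc$prob,
               predicted_class = sc$predicted_class,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Retrieve the most predictive tiles of a cohort
#'
#' Tiles from all bags are sorted by raw tile score; the top
#' \code{k_per_class} (highest scores, the high-recurrence-risk extreme)
#' and bottom \code{k_per_class} are returned with slide ids and
#' coordinates. Ties are broken by (slide_id, tile_index) for
#' determinism.
#'
#' @param model A \code{mil_model}.
#' @param bags List of \code{mil_bag} objects.
#' @param k_per_class Tiles per extreme (the published analysis used 200).
#' @return List with data frames \code{high_risk} and \code{low_risk}.
#' @export
rank_tiles <- function(model, bags, k_per_class = 200) {
  rows <- lapply(bags, function(b) {
    s <- score_tiles(model, b$tiles)
    cbind(b$provenance, score = s)
  })
  all_tiles <- do.call(rbind, rows)
  if (nrow(all_tiles) < 2 * k_per_class)
    stop_param("need at least ", 2 * k_per_class, " tiles, have ",
               nrow(all_tiles))
  ord <- order(-all_tiles$score, all_tiles$slide_id, all_tiles$tile_index)
  all_tiles <- all_tiles[ord, ]
  rownames(all_tiles) <- NULL
  list(high_risk = head(all_tiles, k_per_class),
       low_risk = all_tiles[seq(nrow(all_tiles), by = -1,
                                length.out = k_per_class), ])
}

#' @export
print.mil_model <- function(x, ...) {
  cat(sprintf("<mil_model> %s backbone (%s parameters), p = %g, t = %g, alpha = %g\n",
              x$backbone$variant,
              format(backbone_nparams(x), big.mark = ","),
              x$config$aggregation_exponent, x$config$threshold,
              x$config$l2_alpha))
  if (nrow(x$history)) {
    last <- x$history[nrow(x$history), ]
    cat(sprintf("  trained %d epochs; final loss %.4f, training accuracy %.3f\n",
                nrow(x$history), last$loss, last$accuracy))
  } else cat("  untrained (initialization only)\n")
  invisible(x)
}

#' @export
summary.mil_model <- function(object, ...) {
  print(object)
  if (nrow(object$history)) {
    cat("history (last 5 epochs):\n")
    print(utils::tail(object$history, 5), row.names = FALSE)
  }
  invisible(object)
}

#' @export
plot.mil_model <- function(x, ...) {
  if (!nrow(x$history)) stop_param("no training history to plot")
  graphics::par(mfrow = c(1, 2))
  plot(x$history$epoch, x$history$loss, type = "b", xlab = "epoch",
       ylab = "loss", main = "MIL training loss", ...)
  plot(x$history$epoch, x$history$accuracy, type = "b", xlab = "epoch",
       ylab = "training accuracy", main = "bag accuracy", ...)
  graphics::par(mfrow = c(1, 1))
  invisible(x)
}
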