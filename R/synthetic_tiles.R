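# Synthetic histology-tile and slide-bag simulator.
#
# The generator emulates the four histological axes that drive slide-level
# recurrence risk in H&E liver tissue: stromal bands, cytological atypia
# (enlarged, eccentric nuclei), nuclear hyperchromasia (darker nuclei) in
# "signal" tiles of high-risk slides, and denser immune-cell infiltration
# in low-risk tissue. Nuclei are rotated ellipses over an eosin-like
# textured background; stroma is low-frequency oriented fibrous banding.

#' Configuration for the synthetic slide simulator
#'
#' @param n_tiles Number of tiles per slide (bag size).
#' @param tile_size Tile edge length in pixels (>= 32).
#' @param signal_fraction Fraction of tiles in a high-risk slide that carry
#'   the high-risk morphology. Low-risk slides never contain signal tiles.
#'   The deliberate mixing of signal and background tiles inside one bag is
#'   what exercises the MIL assumption that many tiles conflict with the
#'   slide label.
#' @param stroma_probability Probability that a signal tile receives a
#'   fibrous stroma band.
#' @param immune_density Expected immune-cell count per low-risk/background
#'   tile (signal tiles get a quarter of this density).
#' @param nuclei_per_tile Expected tumor-nucleus count per tile.
#' @param seed Integer seed; identical configurations produce bit-identical
#'   output.
#' @return An object of class \code{slide_sim_config}.
#' @export
slide_sim_config <- function(n_tiles = 16, tile_size = 64,
                             signal_fraction = 0.5,
                             stroma_probability = 0.6,
                             immune_density = 4,
                             nuclei_per_tile = 12,
                             seed = 1L) {
  check_number(n_tiles, "n_tiles", lower = 1)
  check_number(tile_size, "tile_size", lower = 32)
  check_number(signal_fraction, "signal_fraction", lower = 0, upper = 1)
  check_number(stroma_probability, "stroma_probability", lower = 0, upper = 1)
  check_number(immune_density, "immune_density", lower = 0)
  check_number(nuclei_per_tile, "nuclei_per_tile", lower = 0)
  structure(list(n_tiles = as.integer(n_tiles),
                 tile_size = as.integer(tile_size),
                 signal_fraction = signal_fraction,
                 stroma_probability = stroma_probability,
                 immune_density = immune_density,
                 nuclei_per_tile = nuclei_per_tile,
                 seed = as.integer(seed)),
            class = "slide_sim_config")
}

# Paint one filled rotated ellipse; returns updated image and mask.
draw_nucleus <- function(img, mask, cx, cy, ra, rb, angle, col) {
  ts_r <- nrow(mask); ts_c <- ncol(mask)
  r0 <- max(1L, floor(cy - ra)); r1 <- min(ts_r, ceiling(cy + ra))
  c0 <- max(1L, floor(cx - ra)); c1 <- min(ts_c, ceiling(cx + ra))
  rows <- r0:r1; cols <- c0:c1
  dy <- outer(rows - cy, rep(1, length(cols)))
  dx <- outer(rep(1, length(rows)), cols - cx)
  u <- dx * cos(angle) + dy * sin(angle)
  v <- -dx * sin(angle) + dy * cos(angle)
  inside <- (u / ra)^2 + (v / rb)^2 <= 1
  if (!any(inside)) return(list(img = img, mask = mask))
  idx <- which(inside, arr.ind = TRUE)
  ri <- rows[idx[, 1]]; ci <- cols[idx[, 2]]
  for (ch in 1:3) img[cbind(ri, ci, ch)] <- col[ch]
  mask[cbind(ri, ci)] <- 1
  list(img = img, mask = mask)
}

#' Generate one synthetic nuclei tile with its ground-truth mask
#'
#' Signal tiles (the high-risk morphology) contain larger, darker and more
#' eccentric nuclei and may carry an oriented fibrous stroma band;
#' background and low-risk tiles contain smaller, paler, rounder nuclei and
#' more small round immune cells. The binary mask is 1 exactly on nucleus
#' interiors (tumor nuclei and immune cells alike).
#'
#' @param config A \code{\link{slide_sim_config}}.
#' @param risk_class "low" or "high" slide context of the tile.
#' @param is_signal Whether this tile carries the high-risk morphology.
#' @param seed Integer seed (defaults to the config seed).
#' @param n_nuclei Optional forced tumor-nucleus count (e.g. 0 for an empty
#'   scene); by default Poisson with mean \code{nuclei_per_tile}.
#' @return A \code{sim_tile}: list with \code{image} (H x W x 3, 0-255),
#'   \code{mask} (H x W, 0/1) and \code{nuclei}, a data frame of nucleus
#'   specifications (center, radii, angle, intensity, type).
#' @export
generate_nuclei_tile <- function(config, risk_class = c("low", "high"),
                                 is_signal = FALSE, seed = config$seed,
                                 n_nuclei = NULL) {
  stopifnot(inherits(config, "slide_sim_config"))
  risk_class <- match.arg(risk_class)
  ts <- config$tile_size
  with_seed(seed, {
    # eosin-like background: pink base, soft gradient, grain
    base <- c(232, 205, 221)
    gx <- matrix(rep(seq_len(ts), each = ts), ts) / ts
    gy <- matrix(rep(seq_len(ts), times = ts), ts) / ts
    grad <- rnorm(1, 0, 4) * gx + rnorm(1, 0, 4) * gy
    img <- array(0, c(ts, ts, 3))
    for (ch in 1:3)
      img[, , ch] <- base[ch] + grad + matrix(rnorm(ts * ts, 0, 5), ts)
    mask <- matrix(0, ts, ts)

    # stroma: low-frequency oriented fibrous banding on signal tiles
    if (is_signal && runif(1) < config$stroma_probability) {
      theta <- runif(1, 0, pi)
      freq <- runif(1, 0.04, 0.1)
      phase <- runif(1, 0, 2 * pi)
      band <- sin(2 * pi * freq * (gx * ts * cos(theta) +
                                   gy * ts * sin(theta)) + phase)
      w <- pmax(band - 0.2, 0) * 0.7
      fib <- c(246, 228, 238)
      for (ch in 1:3)
        img[, , ch] <- img[, , ch] * (1 - w) + fib[ch] * w
    }

    n_tum <- if (is.null(n_nuclei)) rpois(1, config$nuclei_per_tile)
             else as.integer(n_nuclei)
    lambda_imm <- config$immune_density * if (is_signal) 0.25 else 1
    n_imm <- if (lambda_imm > 0) rpois(1, lambda_imm) else 0L

    specs <- list()
    add_spec <- function(cx, cy, ra, rb, angle, intensity, type)
      data.frame(cx = cx, cy = cy, r_major = ra, r_minor = rb,
                 angle = angle, intensity = intensity, type = type,
                 stringsAsFactors = FALSE)

    margin <- 0.15 * ts
    if (n_tum > 0) for (i in seq_len(n_tum)) {
      cx <- runif(1, margin, ts - margin)
      cy <- runif(1, margin, ts - margin)
      if (is_signal) {
        ra <- runif(1, 0.09, 0.14) * ts
        rb <- ra * runif(1, 0.35, 0.7)    # eccentric (atypia)
        intensity <- runif(1, 50, 105)    # dark (hyperchromasia)
      } else {
        ra <- runif(1, 0.05, 0.085) * ts
        rb <- ra * runif(1, 0.7, 1.0)
        intensity <- runif(1, 115, 165)
      }
      angle <- runif(1, 0, pi)
      col <- intensity * c(0.62, 0.45, 0.92)
      d <- draw_nucleus(img, mask, cx, cy, ra, rb, angle, col)
      img <- d$img; mask <- d$mask
      specs[[length(specs) + 1L]] <-
        add_spec(cx, cy, ra, rb, angle, intensity, "tumor_nucleus")
    }
    if (n_imm > 0) for (i in seq_len(n_imm)) {
      cx <- runif(1, margin, ts - margin)
      cy <- runif(1, margin, ts - margin)
      ra <- runif(1, 0.02, 0.035) * ts
      intensity <- runif(1, 60, 90)
      col <- intensity * c(0.5, 0.42, 0.95)
      d <- draw_nucleus(img, mask, cx, cy, ra, ra, 0, col)
      img <- d$img; mask <- d$mask
      specs[[length(specs) + 1L]] <-
        add_spec(cx, cy, ra, ra, 0, intensity, "immune_cell")
    }

    img[img < 0] <- 0; img[img > 255] <- 255
    nuclei <- if (length(specs)) do.call(rbind, specs) else
      data.frame(cx = numeric(0), cy = numeric(0), r_major = numeric(0),
                 r_minor = numeric(0), angle = numeric(0),
                 intensity = numeric(0), type = character(0),
                 stringsAsFactors = FALSE)
    structure(list(image = img, mask = mask, nuclei = nuclei,
                   risk_class = risk_class, is_signal = is_signal),
              class = "sim_tile")
  })
}

#' Generate one synthetic slide bag
#'
#' Packs \code{n_tiles} four-channel tiles (stain-colored RGB plus a
#' nuclei-probability channel) into one bag carrying a single slide-level
#' label. For a high-risk slide, \code{ceiling(signal_fraction * n_tiles)}
#' tiles are signal tiles; low-risk slides contain none. The label follows
#' the convention \code{label = 1} for a good outcome (low risk), so that
#' high activated bag scores indicate high recurrence risk.
#'
#' @param config A \code{\link{slide_sim_config}}.
#' @param risk_class "low" or "high".
#' @param slide_id Slide identifier (default derived from seed and class).
#' @param seed Integer seed (defaults to the config seed).
#' @param heatmap One of "mask" (use the ground-truth nuclei mask as the
#'   fourth channel, the simulator's oracle heatmap) or a function
#'   \code{f(rgb_image)} returning a probability matrix (e.g. a wrapper
#'   around \code{\link{predict_heatmap}}).
#' @return A \code{mil_bag}: list with \code{slide_id}, \code{tiles}
#'   (list of H x W x 4 arrays on [0,1]), a single \code{label}, and a
#'   \code{provenance} data frame recording \code{is_signal} and tile grid
#'   coordinates.
#' @export
generate_bag <- function(config, risk_class = c("low", "high"),
                         slide_id = NULL, seed = config$seed,
                         heatmap = "mask") {
  stopifnot(inherits(config, "slide_sim_config"))
  risk_class <- match.arg(risk_class)
  n <- config$n_tiles
  n_signal <- if (risk_class == "high")
    as.integer(ceiling(config$signal_fraction * n)) else 0L
  if (is.null(slide_id))
    slide_id <- sprintf("sim_%s_%06d", risk_class, seed %% 1000000L)
  with_seed(seed, {
    tile_seeds <- sample.int(2147483000L, n)
    signal_idx <- if (n_signal > 0) sample.int(n, n_signal) else integer(0)
    tiles <- vector("list", n)
    prov <- data.frame(slide_id = slide_id, tile_index = seq_len(n),
                       x = ((seq_len(n) - 1L) %% 4L) * config$tile_size,
                       y = ((seq_len(n) - 1L) %/% 4L) * config$tile_size,
                       is_signal = seq_len(n) %in% signal_idx,
                       stringsAsFactors = FALSE)
    rgb_tiles <- vector("list", n)
    masks <- vector("list", n)
    for (i in seq_len(n)) {
      st <- generate_nuclei_tile(config, risk_class,
                                 is_signal = prov$is_signal[i],
                                 seed = tile_seeds[i])
      rgb_tiles[[i]] <- st$image
      masks[[i]] <- st$mask
      hm <- if (identical(heatmap, "mask")) st$mask else heatmap(st$image)
      tiles[[i]] <- assemble_four_channel(st$image, hm)
    }
    structure(list(slide_id = slide_id, tiles = tiles,
                   label = as.integer(risk_class == "low"),
                   risk_class = risk_class, provenance = prov,
                   rgb_tiles = rgb_tiles, masks = masks),
              class = "mil_bag")
  })
}

#' Generate a cohort of synthetic slide bags
#'
#' @param config A \code{\link{slide_sim_config}}.
#' @param n_per_class Number of slides per risk class.
#' @param seed Master seed for the cohort.
#' @inheritParams generate_bag
#' @return List of \code{mil_bag} objects, classes interleaved.
#' @export
generate_bags <- function(config, n_per_class, seed = config$seed,
                          heatmap = "mask") {
  bags <- vector("list", 2L * n_per_class)
  for (i in seq_len(n_per_class)) {
    for (k in 1:2) {
      cls <- c("low", "high")[k]
      j <- 2L * (i - 1L) + k
      bags[[j]] <- generate_bag(config, cls,
                                slide_id = sprintf("sim_%s_%04d", cls, i),
                                seed = derive_seed(seed, paste0(cls, i)),
                                heatmap = heatmap)
    }
  }
  bags
}

#' @export
print.mil_bag <- function(x, ...) {
  cat(sprintf("<mil_bag> %s: %d tiles (%d px), label = %d (%s risk), %d signal tiles\n",
              x$slide_id, length(x$tiles), nrow(x$tiles[[1]]), x$label,
              x$risk_class, sum(x$provenance$is_signal)))
  invisible(x)
}
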