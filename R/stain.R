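# Structure-preserving stain separation and color normalization.
#
# RGB is converted to optical density (Beer-Lambert), factored into a
# 2 x 3 non-negative stain basis (hematoxylin-like and eosin-like vectors)
# and per-pixel non-negative concentrations via sparse non-negative matrix
# factorization, and re-composed under a reference basis with per-stain
# concentration rescaling.

#' Convert 8-bit RGB values to optical density
#'
#' \code{OD = -log10((pixel + 1) / 256)}; the +1 keeps pure black finite.
#' @param pixels Numeric array/matrix on the 0-255 scale.
#' @return Array of the same shape.
#' @export
rgb_to_od <- function(pixels) -log10((pixels + 1) / 256)

#' Convert optical density back to 8-bit RGB
#' @param od Numeric array of optical densities.
#' @return Array clipped to [0, 255].
#' @export
od_to_rgb <- function(od) {
  x <- 256 * 10^(-od) - 1
  x[x < 0] <- 0; x[x > 255] <- 255
  x
}

# Pixels (n x 3 OD) of the non-white part of one or more tiles.
pool_od_pixels <- function(x, whiteness_cutoff) {
  tiles <- if (is.list(x) && !inherits(x, c("tile_record", "sim_tile")) &&
               !is.array(x)) x else list(x)
  mats <- lapply(tiles, function(t) {
    px <- if (inherits(t, "tile_record")) t$pixels else
      if (inherits(t, "sim_tile")) t$image else as_image255(t)
    keep <- luminance(px) < whiteness_cutoff
    cbind(px[, , 1][keep], px[, , 2][keep], px[, , 3][keep])
  })
  rgb_to_od(do.call(rbind, mats))
}

# Non-negative concentrations C (n x 2) for OD pixels V given a stain
# basis W (2 x 3): per-pixel lasso-penalized NNLS by cyclic coordinate
# descent (closed form per coordinate for the 2-stain case).
stain_concentrations <- function(V, W, lambda = 0, n_iter = 30) {
  G <- W %*% t(W)                   # 2 x 2 Gram
  R <- V %*% t(W)                   # n x 2
  C <- matrix(0, nrow(V), 2)
  for (it in seq_len(n_iter)) {
    C[, 1] <- pmax(0, (R[, 1] - G[1, 2] * C[, 2] - lambda) / G[1, 1])
    C[, 2] <- pmax(0, (R[, 2] - G[1, 2] * C[, 1] - lambda) / G[2, 2])
  }
  C
}

#' Estimate a stain profile from one or more tiles
#'
#' Factorizes the optical-density matrix of the pooled non-white pixels as
#' \code{OD ~ C \%*\% W} with a non-negative 2 x 3 unit-row-norm stain
#' basis \code{W} and non-negative, L1-sparsity-penalized concentrations
#' \code{C}. The basis is taken at robust angular extremes (0.5 and 99.5
#' percentiles) of the pixel directions inside the 2-dimensional singular
#' subspace of the OD cloud: without near-pure pixels the sparse
#' factorization itself is not identifiable (alternating refinement
#' drifts the basis into the data cone), whereas the angular extremes
#' estimate the cone edges directly. Rows are sorted so the more
#' blue-absorbing vector comes first (the hematoxylin-like convention in
#' this toolkit).
#'
#' @param x A tile (\code{tile_record}, \code{sim_tile} or array) or a
#'   list of tiles.
#' @param sparsity L1 penalty on the concentration solve during
#'   estimation (default 0.1).
#' @param angle_quantile Tail probability defining the angular extremes
#'   (default 0.005).
#' @param whiteness_cutoff Pixels at or above this luminance are excluded.
#' @return Object of class \code{stain_profile}: \code{stain_matrix}
#'   (2 x 3, unit rows) and \code{concentration_scale} (per-stain 99th
#'   percentile concentration).
#' @export
estimate_stain_profile <- function(x, sparsity = 0.1,
                                   angle_quantile = 0.005,
                                   whiteness_cutoff = 235) {
  V <- pool_od_pixels(x, whiteness_cutoff)
  if (nrow(V) < 20)
    stop_param("degenerate input: fewer than 20 non-white pixels; ",
               "cannot estimate a stain profile")
  sv <- svd(V, nu = 0, nv = 2)
  B <- sv$v
  B[, 1] <- B[, 1] * sign(sum(B[, 1]))             # orient positively
  P <- V %*% B                                     # n x 2 projections
  phi <- atan2(P[, 2], P[, 1])
  # type-1 quantiles are invariant under duplicating the pixel set
  qs <- quantile(phi, c(angle_quantile, 1 - angle_quantile), names = FALSE,
                 type = 1)
  W <- rbind(cbind(cos(qs[1]), sin(qs[1])) %*% t(B),
             cbind(cos(qs[2]), sin(qs[2])) %*% t(B))
  W <- pmax(W, 1e-8)
  W <- W / sqrt(rowSums(W^2))
  C <- stain_concentrations(V, W, lambda = sparsity)
  if (any(colSums(C) <= 0))
    stop_param("degenerate input: a stain component has zero concentration")
  # more blue-absorbing vector first
  ord <- order(W[, 3], decreasing = TRUE)
  W <- W[ord, , drop = FALSE]
  C <- stain_concentrations(V, W, lambda = 0)
  scale99 <- apply(C, 2, quantile, probs = 0.99, names = FALSE, type = 1)
  if (any(scale99 <= 0))
    stop_param("degenerate input: a stain component has zero concentration")
  dimnames(W) <- list(c("stain1_hematoxylin_like", "stain2_eosin_like"),
                      c("R", "G", "B"))
  structure(list(stain_matrix = W, concentration_scale = scale99),
            class = "stain_profile")
}

#' @export
print.stain_profile <- function(x, ...) {
  cat("<stain_profile>\n")
  print(round(x$stain_matrix, 4))
  cat("concentration scale (99th pct):",
      paste(fmt_num(x$concentration_scale), collapse = ", "), "\n")
  invisible(x)
}

#' Color-normalize a tile to a reference stain profile
#'
#' Per-pixel stain concentrations under the source basis are rescaled by
#' the ratio of reference to source concentration scales and re-composed
#' with the reference stain basis. White pixels (zero optical density)
#' have zero concentrations and therefore stay white. The concentration
#' solve at transformation time is plain NNLS (no sparsity penalty), so
#' self-normalization reproduces the input up to rank-2 model error.
#'
#' @param tile A \code{tile_record}, \code{sim_tile} or image array.
#' @param source \code{stain_profile} of the tile (estimated from it when
#'   omitted).
#' @param reference Target \code{stain_profile}.
#' @return Same type as the input, with normalized pixels in [0, 255].
#' @export
normalize_color <- function(tile, source = NULL, reference) {
  stopifnot(inherits(reference, "stain_profile"))
  px <- if (inherits(tile, "tile_record")) tile$pixels else
    if (inherits(tile, "sim_tile")) tile$image else as_image255(tile)
  if (is.null(source)) source <- estimate_stain_profile(tile)
  stopifnot(inherits(source, "stain_profile"))
  d <- dim(px)
  V <- rgb_to_od(cbind(as.vector(px[, , 1]), as.vector(px[, , 2]),
                       as.vector(px[, , 3])))
  C <- stain_concentrations(V, source$stain_matrix, lambda = 0)
  C <- sweep(C, 2, reference$concentration_scale / source$concentration_scale,
             `*`)
  OD <- C %*% reference$stain_matrix
  out <- od_to_rgb(OD)
  res <- array(0, d)
  for (ch in 1:3) res[, , ch] <- matrix(out[, ch], d[1], d[2])
  if (inherits(tile, "tile_record")) { tile$pixels <- res; return(tile) }
  if (inherits(tile, "sim_tile")) { tile$image <- res; return(tile) }
  res
}

#' The packaged reference stain profile
#'
#' Estimated (deterministically, at first use) from a packaged synthetic
#' reference tile; memoised for the session.
#' @return A \code{stain_profile}.
#' @export
reference_stain_profile <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- slide_sim_config(tile_size = 96, nuclei_per_tile = 18,
                              immune_density = 3, seed = 20220329L)
      ref <- generate_nuclei_tile(cfg, "low", seed = cfg$seed)
      cache <<- estimate_stain_profile(ref)
    }
    cache
  }
})
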