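# Tile extraction and resizing.

#' Construct a tile record
#'
#' @param pixels Square H x W x 3 numeric array on the 8-bit scale (0-255).
#' @param slide_id Source slide identifier.
#' @param origin Integer (x, y) pixel offset of the tile's top-left corner
#'   in the source image, 0-based.
#' @param mpp Microns per pixel (> 0).
#' @return An object of class \code{tile_record}.
#' @export
tile_record <- function(pixels, slide_id = "slide", origin = c(0L, 0L),
                        mpp = 0.25) {
  pixels <- as_image255(pixels)
  d <- dim(pixels)
  if (d[1] != d[2]) stop_param("tile pixels must be square")
  check_number(mpp, "mpp", lower = 0, open_lower = TRUE)
  if (any(origin < 0)) stop_param("tile origin must be non-negative")
  structure(list(pixels = pixels, slide_id = slide_id,
                 origin = as.integer(origin), mpp = mpp),
            class = "tile_record")
}

#' @export
print.tile_record <- function(x, ...) {
  cat(sprintf("<tile_record> %s @(%d,%d): %d px, %.4g um/px\n", x$slide_id,
              x$origin[1], x$origin[2], nrow(x$pixels), x$mpp))
  invisible(x)
}

#' Extract a grid of tiles from a large image, filtering background
#'
#' The image is tiled on a regular grid; a tile is kept iff the fraction of
#' its non-background pixels is at least \code{tissue_threshold}, where a
#' pixel counts as background when its mean RGB luminance is at or above
#' \code{whiteness_cutoff} (standard whole-slide-image practice; the
#' cutoff is a configuration knob since scanners differ).
#'
#' @param image H x W x 3 numeric array (0-255 or [0,1]).
#' @param tile_size Tile edge in pixels.
#' @param stride Grid stride in pixels; defaults to \code{tile_size}
#'   (non-overlapping tiling).
#' @param tissue_threshold Minimum tissue (non-background) fraction in
#'   [0, 1] for a tile to be kept.
#' @param whiteness_cutoff Luminance at or above which a pixel is
#'   background (default 220 of 255).
#' @param slide_id,mpp Metadata stored on each tile.
#' @return List of \code{\link{tile_record}} objects; empty (with a
#'   warning) when the image is smaller than \code{tile_size}.
#' @export
extract_tiles <- function(image, tile_size = 512, stride = tile_size,
                          tissue_threshold = 0.25, whiteness_cutoff = 220,
                          slide_id = "slide", mpp = 0.25) {
  image <- as_image255(image)
  check_number(tissue_threshold, "tissue_threshold", lower = 0, upper = 1)
  h <- dim(image)[1]; w <- dim(image)[2]
  if (h < tile_size || w < tile_size) {
    warning("image (", h, "x", w, ") smaller than tile_size ", tile_size,
            "; no tiles extracted")
    return(list())
  }
  ys <- seq(0L, h - tile_size, by = stride)
  xs <- seq(0L, w - tile_size, by = stride)
  out <- list()
  for (y0 in ys) for (x0 in xs) {
    px <- image[(y0 + 1):(y0 + tile_size), (x0 + 1):(x0 + tile_size), ,
                drop = FALSE]
    tissue <- mean(luminance(px) < whiteness_cutoff)
    if (tissue >= tissue_threshold)
      out[[length(out) + 1L]] <- tile_record(px, slide_id,
                                             origin = c(x0, y0), mpp = mpp)
  }
  out
}

#' Resize a tile with bilinear resampling
#'
#' The microns-per-pixel metadata is rescaled by the size ratio (e.g. a
#' 512 px tile at 0.25 um/px resized to 224 px becomes ~0.571 um/px).
#'
#' @param tile A \code{\link{tile_record}} or plain image array.
#' @param target Target edge length in pixels (single value >= 8; a
#'   non-square request is a parameter error).
#' @return Same type as the input, resized.
#' @export
resize_tile <- function(tile, target) {
  if (length(target) > 1L) {
    if (length(unique(target)) > 1L)
      stop_param("non-square resize requested; tiles must stay square")
    target <- target[1]
  }
  check_number(target, "target", lower = 8)
  target <- as.integer(target)
  is_rec <- inherits(tile, "tile_record")
  px <- if (is_rec) tile$pixels else as_image255(tile)
  old <- dim(px)[1]
  if (target != old) {
    px <- resize_bilinear(px, target)
  }
  if (!is_rec) return(px)
  tile$pixels <- px
  tile$mpp <- tile$mpp * old / target
  tile
}

# Bilinear resize of an H x W (x C) array via EBImage.
resize_bilinear <- function(px, target) {
  two_d <- length(dim(px)) == 2L
  out <- EBImage::resize(EBImage::Image(px), w = target, h = target,
                         filter = "bilinear")
  out <- EBImage::imageData(out)
  if (two_d && length(dim(out)) == 3L) out <- out[, , 1]
  out
}
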