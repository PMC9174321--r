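# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`; the
# caller's RNG stream is untouched. With seed = NULL the current stream
# is used (and advanced).
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  withr::with_seed(as.integer(seed), code)
}

# Deterministically derive a component seed from a master seed and a
# stage label, kept below 2^31 so it is always a valid R integer seed.
derive_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(seed) * 48271 + h * 8191) %% 2147483587) + 1L
}

stop_param <- function(...) stop(..., call. = FALSE)

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         open_lower = FALSE, open_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_param(sprintf("'%s' must be a single finite number", name))
  ok <- if (open_lower) x > lower else x >= lower
  ok <- ok && (if (open_upper) x < upper else x <= upper)
  if (!ok)
    stop_param(sprintf("'%s' = %g is outside its valid range", name, x))
  invisible(x)
}

# Coerce an image to a numeric 8-bit-scale array (0-255). Accepts arrays
# already on 0-255, arrays on [0,1] (as read by png::readPNG), and
# 2-d matrices (promoted to one channel).
as_image255 <- function(x) {
  if (is.matrix(x)) x <- array(x, c(dim(x), 1L))
  if (!is.array(x) || length(dim(x)) != 3L)
    stop_param("image must be a matrix or H x W x C array")
  if (max(x) <= 1 + 1e-12) x <- x * 255
  x
}

# Luminance (mean over channels) of an 8-bit image array.
luminance <- function(pixels) {
  if (length(dim(pixels)) == 2L) return(pixels)
  apply(pixels, c(1, 2), mean)
}

# Read / write 8-bit images through the png package.
read_image <- function(path) {
  as_image255(png::readPNG(path))
}

write_image <- function(pixels, path) {
  x <- pixels / 255
  x[x < 0] <- 0; x[x > 1] <- 1
  if (length(dim(x)) == 3L && dim(x)[3] == 1L) x <- x[, , 1]
  png::writePNG(x, path)
  invisible(path)
}

fmt_num <- function(x, digits = 4) formatC(x, digits = digits, format = "g")
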