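#' Priority map objects
#'
#' A priority map is a non-negative raster aligned to an image, stored as a
#' numeric matrix (rows = image rows, top row first) with a variant tag and
#' the parameters used to build it. Pixel `(row r, col c)` (0-based) covers
#' `[c, c + 1) x [r, r + 1)` and is evaluated at its centre
#' `(c + 0.5, r + 0.5)`.
#'
#' @param values Numeric matrix of finite, non-negative values.
#' @param variant Tag, e.g. `"UC"`, `"UC_E"`, `"UC_P"`, `"CB"`, `"Target"`,
#'   `"Sal"`, `"FDM"`.
#' @param params List of construction parameters (provenance metadata).
#' @return An object of class `priority_map`.
#' @export
priority_map <- function(values, variant = "UC", params = list()) {
  values <- as.matrix(values)
  if (!all(is.finite(values))) abort("priority map values must be finite")
  if (any(values < 0)) abort("priority map values must be non-negative")
  structure(list(values = values, variant = variant, params = params),
            class = "priority_map")
}

#' @export
as.matrix.priority_map <- function(x, ...) x$values

#' @export
dim.priority_map <- function(x) dim(x$values)

#' @export
print.priority_map <- function(x, ...) {
  cat(sprintf("<priority_map %s %dx%d px, range [%.4g, %.4g]>\n",
              x$variant, nrow(x$values), ncol(x$values),
              min(x$values), max(x$values)))
  invisible(x)
}

map_values <- function(m) if (inherits(m, "priority_map")) m$values else as.matrix(m)

#' @describeIn priority_map Long-format view: one row per pixel with
#'   0-based `x`, `y` and `value`.
#' @param x A `priority_map`.
#' @param ... Unused.
#' @method tidy priority_map
#' @export
tidy.priority_map <- function(x, ...) {
  v <- x$values
  tibble(
    x = rep(seq_len(ncol(v)) - 1L, each = nrow(v)),
    y = rep(seq_len(nrow(v)) - 1L, times = ncol(v)),
    value = as.vector(v)
  )
}

#' Evaluate an unnormalized 2D Gaussian on a pixel grid
#'
#' Separable Gaussian evaluated at pixel centres; peak amplitude
#' `amplitude` is attained at `center` (which need not be a pixel centre).
#' With a finite `window` (pixels), values are zeroed outside the square
#' window of that side length around the centre.
#'
#' @param shape `c(height, width)` in pixels.
#' @param center `c(x, y)` in continuous pixel coordinates.
#' @param sigma Standard deviation in pixels; scalar (isotropic) or
#'   `c(sigma_x, sigma_y)`.
#' @param window Optional truncation window side length, pixels.
#' @param amplitude Peak value (default 1; the centre-bias map uses
#'   `1 / (sigma * sqrt(2 * pi))`).
#' @return A numeric matrix of shape `shape`.
#' @export
gaussian_blob <- function(shape, center, sigma, window = NULL, amplitude = 1) {
  stopifnot(length(shape) == 2, all(shape >= 1), all(sigma > 0))
  if (length(sigma) == 1) sigma <- c(sigma, sigma)
  xc <- seq_len(shape[2]) - 0.5
  yc <- seq_len(shape[1]) - 0.5
  gx <- exp(-(xc - center[1])^2 / (2 * sigma[1]^2))
  gy <- exp(-(yc - center[2])^2 / (2 * sigma[2]^2))
  if (!is.null(window)) {
    stopifnot(window >= 1)
    gx[abs(xc - center[1]) > window / 2] <- 0
    gy[abs(yc - center[2]) > window / 2] <- 0
  }
  amplitude * outer(gy, gx)
}

#' Min-max normalize a map to [0, 1]
#'
#' `(m - min) / (max - min)`; a constant map maps to all zeros with a
#' warning.
#'
#' @param m A `priority_map` or matrix.
#' @return Same type as the input, rescaled.
#' @export
minmax_normalize <- function(m) {
  v <- map_values(m)
  rng <- range(v)
  if (diff(rng) == 0) {
    warn("constant map: min-max normalization returns an all-zero map")
    out <- array(0, dim(v))
  } else {
    out <- (v - rng[1]) / (rng[2] - rng[1])
  }
  if (inherits(m, "priority_map")) {
    priority_map(out, m$variant, c(m$params, list(normalized = "minmax")))
  } else {
    out
  }
}

#' Histogram-match a map to a reference
#'
#' Monotone histogram specification by empirical-quantile mapping: values
#' of `m` are binned (`bins` equal-width bins), each bin's empirical CDF
#' position is mapped through the reference's quantile function. Pixel rank
#' order of `m` is preserved up to ties; the output value distribution
#' matches the reference's within bin resolution.
#'
#' @param m Map to transform (`priority_map` or matrix).
#' @param reference Reference map of the same shape (e.g. a
#'   fixation-density map).
#' @param bins Number of bins (default 256).
#' @return Same type as `m`.
#' @export
histogram_match <- function(m, reference, bins = 256) {
  v <- map_values(m)
  r <- map_values(reference)
  if (!all(dim(v) == dim(r))) abort("histogram_match: shape mismatch")
  rng <- range(v)
  if (diff(rng) == 0) {
    out <- array(stats::median(r), dim(v))
  } else {
    br <- seq(rng[1], rng[2], length.out = bins + 1)
    idx <- findInterval(as.vector(v), br, rightmost.closed = TRUE,
                        all.inside = TRUE)
    cdf <- cumsum(tabulate(idx, nbins = bins)) / length(v)
    qref <- quantile(as.vector(r), probs = cdf, names = FALSE, type = 4)
    out <- array(qref[idx], dim(v))
  }
  if (inherits(m, "priority_map")) {
    priority_map(out, m$variant, c(m$params, list(normalized = "histmatch")))
  } else {
    out
  }
}

# odd truncated-window size from a nominal size in pixels
odd_window <- function(size) {
  k <- max(1L, round(size))
  if (k %% 2L == 0L) k <- k + 1L
  k
}

#' Smooth a raster with a truncated Gaussian kernel
#'
#' Separable convolution with a normalized 1D Gaussian kernel of odd length
#' `window` (nominal sizes are rounded up to odd), zero-padded at the
#' borders.
#'
#' @param mat Numeric matrix.
#' @param window Kernel window size in pixels.
#' @param sigma Kernel SD in pixels (default `window / 4`).
#' @return Smoothed matrix of the same shape.
#' @export
gaussian_smooth <- function(mat, window, sigma = window / 4) {
  mat <- as.matrix(mat)
  k <- odd_window(window)
  half <- (k - 1L) / 2L
  kern <- exp(-((-half:half)^2) / (2 * sigma^2))
  kern <- kern / sum(kern)
  conv_mat <- function(n) {
    cm <- matrix(0, n, n)
    for (i in seq_len(n)) {
      j <- (i - half):(i + half)
      ok <- j >= 1 & j <= n
      cm[i, j[ok]] <- kern[ok]
    }
    cm
  }
  conv_mat(nrow(mat)) %*% mat %*% t(conv_mat(ncol(mat)))
}

#' Bilinear resampling of a raster
#'
#' Standard centre-aligned bilinear interpolation (source coordinate of
#' destination pixel i is `(i + 0.5) * old / new - 0.5`); resampling to the
#' original size is the identity.
#'
#' @param mat Numeric matrix.
#' @param new_h,new_w Target dimensions in pixels.
#' @return Resampled matrix of shape `c(new_h, new_w)`.
#' @export
resize_bilinear <- function(mat, new_h, new_w) {
  mat <- as.matrix(mat)
  oh <- nrow(mat); ow <- ncol(mat)
  stopifnot(new_h >= 1, new_w >= 1)
  src <- function(n_new, n_old) {
    s <- (seq_len(n_new) - 0.5) * n_old / n_new - 0.5
    pmin(pmax(s, 0), n_old - 1)
  }
  sy <- src(new_h, oh); sx <- src(new_w, ow)
  y0 <- pmin(floor(sy), oh - 1); y1 <- pmin(y0 + 1, oh - 1); fy <- sy - y0
  x0 <- pmin(floor(sx), ow - 1); x1 <- pmin(x0 + 1, ow - 1); fx <- sx - x0
  a <- mat[y0 + 1, x0 + 1, drop = FALSE]
  b <- mat[y0 + 1, x1 + 1, drop = FALSE]
  cc <- mat[y1 + 1, x0 + 1, drop = FALSE]
  d <- mat[y1 + 1, x1 + 1, drop = FALSE]
  wy <- matrix(fy, new_h, new_w)
  wx <- matrix(fx, new_h, new_w, byrow = TRUE)
  a * (1 - wy) * (1 - wx) + b * (1 - wy) * wx + cc * wy * (1 - wx) + d * wy * wx
}

#' Serialize and load priority-map rasters
#'
#' Rasters are written as plain-text tab-separated matrices (row-major,
#' origin top-left) with a JSON sidecar recording the variant, the min-max
#' scale applied, and the construction parameters. `load_saliency()` reads
#' any such raster (or a bare text matrix), bilinearly resizes it to
#' `shape`, and tags it as a saliency map -- the adapter for precomputed
#' bottom-up saliency models.
#'
#' @param m A `priority_map`.
#' @param path Output `.tsv` path (sidecar written as `<path>.json`).
#' @return `write_map()` returns `path` invisibly; readers return a
#'   `priority_map`.
#' @export
write_map <- function(m, path) {
  stopifnot(inherits(m, "priority_map"))
  v <- m$values
  rng <- range(v)
  scaled <- if (diff(rng) > 0) (v - rng[1]) / (rng[2] - rng[1]) else v * 0
  utils::write.table(scaled, path, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
  sidecar <- list(variant = m$variant, min = rng[1], max = rng[2],
                  height = nrow(v), width = ncol(v), params = m$params)
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_map
#' @export
read_map <- function(path) {
  v <- as.matrix(utils::read.table(path, sep = "\t", header = FALSE))
  dimnames(v) <- NULL
  sidecar_path <- paste0(path, ".json")
  variant <- "Sal"; params <- list()
  if (file.exists(sidecar_path)) {
    sc <- jsonlite::fromJSON(sidecar_path, simplifyVector = TRUE)
    variant <- sc$variant %||% "Sal"
    if (!is.null(sc$min) && !is.null(sc$max) && sc$max > sc$min) {
      v <- v * (sc$max - sc$min) + sc$min
    }
    params <- as.list(sc$params %||% list())
  }
  priority_map(v, variant, params)
}

#' @rdname write_map
#' @param shape Target `c(height, width)`.
#' @export
load_saliency <- function(path, shape) {
  m <- read_map(path)
  v <- m$values
  if (!all(dim(v) == shape)) v <- resize_bilinear(v, shape[1], shape[2])
  priority_map(pmax(v, 0), "Sal", list(source = path))
}

#' Centre-surround contrast stand-in for a saliency model
#'
#' A deliberately simple multi-scale centre-surround contrast map used as a
#' self-contained stand-in in tests and examples: per channel and scale,
#' the absolute difference between the image and its Gaussian blur, summed
#' and min-max normalized. It is not a substitute for a full bottom-up
#' saliency model; precomputed saliency rasters are loaded with
#' [load_saliency()].
#'
#' @param image Numeric matrix (grayscale) or `h x w x channels` array,
#'   values on any scale.
#' @param scales Blur SDs in pixels.
#' @return A `priority_map` tagged `"Sal"`.
#' @export
standin_saliency <- function(image, scales = c(2, 4, 8)) {
  if (length(dim(image)) == 2) image <- array(image, c(dim(image), 1))
  h <- dim(image)[1]; w <- dim(image)[2]
  acc <- matrix(0, h, w)
  ones <- matrix(1, h, w)
  for (ch in seq_len(dim(image)[3])) {
    band <- image[, , ch]
    for (s in scales) {
      # border-corrected blur so a uniform image has exactly zero contrast
      blur <- gaussian_smooth(band, window = 4 * s + 1, sigma = s) /
        gaussian_smooth(ones, window = 4 * s + 1, sigma = s)
      acc <- acc + abs(band - blur)
    }
  }
  if (diff(range(acc)) > 0) acc <- (acc - min(acc)) / diff(range(acc))
  priority_map(acc, "Sal", list(standin = TRUE, scales = scales))
}
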