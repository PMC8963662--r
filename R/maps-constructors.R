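#' Probability of unique object recognition
#'
#' Given competing-category counts `f` over the proposals of one image, the
#' probability that proposal `b` contains a single uniquely recognized
#' object is `1 - f_b / sum(f)`. Over `B >= 2` proposals the outputs lie in
#' `(0, 1)` and sum to `B - 1`.
#'
#' @param f Integer vector of competing counts, all `>= 1`.
#' @return Numeric vector of probabilities, same length as `f`.
#' @examples
#' unique_object_probability(c(3, 2, 1, 4)) # 0.70 0.80 0.90 0.60
#' @export
unique_object_probability <- function(f) {
  if (length(f) == 0) abort("no competing counts supplied")
  if (any(f < 1)) abort("competing counts must be >= 1")
  1 - f / sum(f)
}

#' Self-information of unique recognition
#'
#' `-log(p)` of the unique-recognition probability, base 10 by default (the
#' base in which a proposal competed for by k equally likely categories
#' carries `log10(k)` entropy).
#'
#' @param p Probability in `(0, 1]`.
#' @param base Logarithm base (default 10).
#' @return Self-information value(s), `>= 0`.
#' @export
self_information <- function(p, base = 10) {
  if (any(p <= 0) || any(p > 1)) abort("p must lie in (0, 1]")
  -log(p, base = base)
}

# per-proposal Gaussian SD in pixels: h_b / 4 by default, or a fixed value
resolve_sigma <- function(sigma, box_h) {
  if (is.null(sigma) || identical(sigma, "box_height")) box_h / 4 else sigma
}

prep_detections <- function(det, th_conf, th_nms, preprocessed) {
  det <- as_detections(det)
  if (!preprocessed) {
    det <- filter_by_confidence(det, th_conf)
    det <- nms(det, th_nms)
  }
  det
}

empty_map_warning <- function(variant, shape, params) {
  warn(sprintf("no proposals survive for %s map: returning an all-zero map",
               variant))
  priority_map(matrix(0, shape[1], shape[2]), variant, params)
}

det_shape <- function(det, shape) {
  if (!is.null(shape)) return(shape)
  if (nrow(det) == 0 || !is.finite(det$image_h[1])) {
    abort("image shape unavailable: supply `shape = c(h, w)`")
  }
  c(det$image_h[1], det$image_w[1])
}

#' Object-recognition-uncertainty priority map
#'
#' The core priority map: after confidence filtering and class-agnostic
#' NMS, each surviving proposal contributes an unnormalized Gaussian
#' (centred at the box centre, SD from `sigma`, peak amplitude 1) scaled by
#' `f_b / max_B f_b`, where `f_b` is its competing-category count.
#' Overlapping contributions sum, so the map value at a pixel is the summed
#' uncertainty of all proposals covering it.
#'
#' @param det A detections tibble for one image.
#' @param th_conf,th_nms Detection thresholds (defaults 0.02 and 0.30).
#' @param sigma `"box_height"` for per-box SD `h_b / 4` (default), or a
#'   fixed SD in pixels.
#' @param shape Image `c(h, w)`; taken from the tibble when present.
#' @param preprocessed Set `TRUE` when `det` has already been filtered and
#'   NMS-reduced.
#' @return A `priority_map` tagged `"UC"`.
#' @export
uncertainty_map <- function(det, th_conf = 0.02, th_nms = 0.30,
                            sigma = "box_height", shape = NULL,
                            preprocessed = FALSE) {
  shape <- det_shape(as_detections(det), shape)
  params <- list(th_conf = th_conf, th_nms = th_nms, sigma = sigma)
  det <- prep_detections(det, th_conf, th_nms, preprocessed)
  if (nrow(det) == 0) return(empty_map_warning("UC", shape, params))
  fb <- competing_counts(det, th_conf)
  weights <- fb$f / max(fb$f)
  acc <- matrix(0, shape[1], shape[2])
  for (i in seq_len(nrow(fb))) {
    acc <- acc + weights[i] * gaussian_blob(
      shape,
      center = c(fb$x[i] + fb$w[i] / 2, fb$y[i] + fb$h[i] / 2),
      sigma = resolve_sigma(sigma, fb$h[i])
    )
  }
  priority_map(acc, "UC", params)
}

#' Label-entropy uncertainty map
#'
#' Alternative uncertainty formulation: each proposal's Gaussian is scaled
#' by the Shannon entropy `-sum(w_p log w_p)` of its above-threshold
#' category confidences. Confidences are renormalized to sum to 1 over the
#' above-threshold categories before the entropy (raw detector scores need
#' not form a distribution; `renormalize = FALSE` uses them as-is), and the
#' logarithm is base 10 by default, so k equally confident categories give
#' weight `log10(k)` and a single-category proposal gives 0.
#'
#' @inheritParams uncertainty_map
#' @param log_base Entropy base (default 10).
#' @param renormalize Renormalize above-threshold confidences (default
#'   `TRUE`).
#' @return A `priority_map` tagged `"UC_E"`.
#' @export
label_entropy_map <- function(det, th_conf = 0.02, th_nms = 0.30,
                              sigma = "box_height", shape = NULL,
                              log_base = 10, renormalize = TRUE,
                              preprocessed = FALSE) {
  shape <- det_shape(as_detections(det), shape)
  params <- list(th_conf = th_conf, th_nms = th_nms, sigma = sigma,
                 log_base = log_base, renormalize = renormalize)
  det <- prep_detections(det, th_conf, th_nms, preprocessed)
  if (nrow(det) == 0) return(empty_map_warning("UC_E", shape, params))
  ent <- det |>
    dplyr::filter(.data$score >= th_conf) |>
    dplyr::group_by(.data$box_id) |>
    dplyr::summarise(
      x = .data$x[1], y = .data$y[1], w = .data$w[1], h = .data$h[1],
      weight = {
        wp <- .data$score
        if (renormalize) wp <- wp / sum(wp)
        -sum(wp * log(wp, base = log_base))
      },
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$box_id)
  acc <- matrix(0, shape[1], shape[2])
  for (i in seq_len(nrow(ent))) {
    acc <- acc + ent$weight[i] * gaussian_blob(
      shape,
      center = c(ent$x[i] + ent$w[i] / 2, ent$y[i] + ent$h[i] / 2),
      sigma = resolve_sigma(sigma, ent$h[i])
    )
  }
  priority_map(acc, "UC_E", params)
}

# 0-based inclusive pixel ranges whose centres fall inside a half-open box
box_pixel_range <- function(lo, len, n) {
  first <- max(0, ceiling(lo - 0.5))
  last <- min(n - 1, floor(lo + len - 0.5 - 1e-12))
  if (first > last) NULL else c(first, last)
}

#' Pixel-wise uncertainty map
#'
#' Second alternative formulation: the per-pixel count of
#' confidence-filtered proposal boxes enclosing the pixel (no NMS --
#' counting overlapping proposals is the point), smoothed with a truncated
#' Gaussian kernel whose window is one quarter of the image height (kernel
#' SD = window / 4).
#'
#' @inheritParams uncertainty_map
#' @param smooth Apply the smoothing kernel (default `TRUE`; `FALSE`
#'   returns the raw count map).
#' @return A `priority_map` tagged `"UC_P"`.
#' @export
pixelwise_uncertainty_map <- function(det, th_conf = 0.02, shape = NULL,
                                      smooth = TRUE, preprocessed = FALSE) {
  det <- as_detections(det)
  shape <- det_shape(det, shape)
  params <- list(th_conf = th_conf, smooth = smooth)
  if (!preprocessed) det <- filter_by_confidence(det, th_conf)
  boxes <- dplyr::distinct(det, .data$box_id, .data$x, .data$y,
                           .data$w, .data$h)
  counts <- matrix(0, shape[1], shape[2])
  for (i in seq_len(nrow(boxes))) {
    rr <- box_pixel_range(boxes$y[i], boxes$h[i], shape[1])
    cr <- box_pixel_range(boxes$x[i], boxes$w[i], shape[2])
    if (is.null(rr) || is.null(cr)) next
    counts[(rr[1] + 1):(rr[2] + 1), (cr[1] + 1):(cr[2] + 1)] <-
      counts[(rr[1] + 1):(rr[2] + 1), (cr[1] + 1):(cr[2] + 1)] + 1
  }
  if (nrow(boxes) == 0) {
    warn("no proposals survive for UC_P map: returning an all-zero map")
  }
  if (smooth) {
    win <- odd_window(shape[1] / 4)
    counts <- gaussian_smooth(counts, window = win, sigma = win / 4)
  }
  priority_map(counts, "UC_P", params)
}

#' Centre-bias priority map
#'
#' Isotropic Gaussian centred on the image, with the one-dimensional
#' normal amplitude `1 / (sigma_c * sqrt(2 * pi))` retained (later min-max
#' normalization cancels it, but the map is built as defined).
#'
#' @param shape Image `c(h, w)` in pixels.
#' @param sigma_c Gaussian SD in pixels; defaults to one third of the
#'   image height.
#' @return A `priority_map` tagged `"CB"`.
#' @export
center_bias_map <- function(shape, sigma_c = shape[1] / 3) {
  stopifnot(sigma_c > 0)
  v <- gaussian_blob(shape, center = c(shape[2] / 2, shape[1] / 2),
                     sigma = sigma_c,
                     amplitude = 1 / (sigma_c * sqrt(2 * pi)))
  priority_map(v, "CB", list(sigma_c = sigma_c))
}

# the shared target-map Gaussian: built at square size h_im with
# SD = h_im / 4, bilinearly resampled to the box extent
target_blob <- function(shape, x, y, w, h) {
  him <- shape[1]
  rr <- box_pixel_range(y, h, shape[1])
  cr <- box_pixel_range(x, w, shape[2])
  if (is.null(rr) || is.null(cr)) return(NULL)
  base <- gaussian_blob(c(him, him), center = c(him / 2, him / 2),
                        sigma = him / 4)
  bh <- rr[2] - rr[1] + 1
  bw <- cr[2] - cr[1] + 1
  patch <- resize_bilinear(base, bh, bw)
  list(rows = (rr[1] + 1):(rr[2] + 1), cols = (cr[1] + 1):(cr[2] + 1),
       patch = patch)
}

target_map_impl <- function(det, target_category, conf, variant, shape) {
  det <- as_detections(det)
  shape <- det_shape(det, shape)
  if (!target_category %in% det$category) {
    abort(sprintf("unknown target category '%s'", target_category))
  }
  hits <- det |>
    dplyr::filter(.data$category == target_category, .data$score > conf) |>
    dplyr::distinct(.data$box_id, .data$x, .data$y, .data$w, .data$h)
  acc <- matrix(0, shape[1], shape[2])
  if (nrow(hits) == 0) {
    warn(sprintf(
      "no proposal has %s confidence > %g: returning an all-zero %s map",
      target_category, conf, variant))
  }
  for (i in seq_len(nrow(hits))) {
    tb <- target_blob(shape, hits$x[i], hits$y[i], hits$w[i], hits$h[i])
    if (is.null(tb)) next
    acc[tb$rows, tb$cols] <- acc[tb$rows, tb$cols] + tb$patch
  }
  priority_map(acc, variant,
               list(target_category = target_category, conf = conf))
}

#' Target-feature priority maps for search
#'
#' Both maps place, at qualifying proposal boxes, a Gaussian built at
#' square size equal to the image height with SD one quarter of the image
#' height, bilinearly resampled to the box extent (so its anisotropy
#' follows the box aspect ratio). `target_map_tp()` uses the
#' target-present rule -- only proposals whose target-category confidence
#' exceeds 0.9 qualify (typically exactly one) -- while `target_map_ta()`
#' lowers the cut-off to 0.02 so that weak target-like evidence at every
#' box contributes; overlapping contributions sum. When no proposal
#' qualifies an all-zero map is returned with a warning.
#'
#' @param det A detections tibble for one image.
#' @param target_category Category label of the search target; must occur
#'   in the detection vocabulary.
#' @param conf Confidence cut-off (strict `>`); defaults 0.9 (TP) and
#'   0.02 (TA).
#' @param shape Image `c(h, w)`; taken from the tibble when present.
#' @return A `priority_map` tagged `"Target"`.
#' @export
target_map_tp <- function(det, target_category, conf = 0.9, shape = NULL) {
  target_map_impl(det, target_category, conf, "Target", shape)
}

#' @rdname target_map_tp
#' @export
target_map_ta <- function(det, target_category, conf = 0.02, shape = NULL) {
  target_map_impl(det, target_category, conf, "Target", shape)
}
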