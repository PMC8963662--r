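# Brute-force oracles: direct per-pixel evaluation of the defining
# formulas, written as explicit loops over boxes/rows, independent of the
# vectorized outer-product implementation path.

# IoU by counting integer pixels covered by each box
oracle_iou_pixels <- function(a, b) {
  cover <- function(bx) {
    if (bx[3] == 0 || bx[4] == 0) return(matrix(numeric(0), ncol = 2))
    as.matrix(expand.grid(x = bx[1]:(bx[1] + bx[3] - 1),
                          y = bx[2]:(bx[2] + bx[4] - 1)))
  }
  pa <- cover(a); pb <- cover(b)
  keys_a <- paste(pa[, 1], pa[, 2])
  keys_b <- paste(pb[, 1], pb[, 2])
  inter <- length(intersect(keys_a, keys_b))
  inter / length(union(keys_a, keys_b))
}

# pointwise Gaussian evaluated row by row from the density formula
oracle_gaussian <- function(shape, cx, cy, sx, sy = sx, amplitude = 1) {
  out <- matrix(0, shape[1], shape[2])
  xs <- seq_len(shape[2]) - 0.5
  for (r in seq_len(shape[1])) {
    yv <- r - 0.5
    out[r, ] <- amplitude *
      exp(-((xs - cx)^2 / (2 * sx^2) + (yv - cy)^2 / (2 * sy^2)))
  }
  out
}

# Gaussian-sum map: per surviving box, weight * Gaussian at the box centre
oracle_gaussian_sum <- function(boxes, weights, shape,
                                sigma = NULL) {
  acc <- matrix(0, shape[1], shape[2])
  for (i in seq_len(nrow(boxes))) {
    s <- if (is.null(sigma)) boxes$h[i] / 4 else sigma
    acc <- acc + oracle_gaussian(
      shape,
      cx = boxes$x[i] + boxes$w[i] / 2,
      cy = boxes$y[i] + boxes$h[i] / 2,
      sx = s, sy = s, amplitude = weights[i]
    )
  }
  acc
}

# per-pixel count of boxes whose half-open extent contains the pixel centre
oracle_count_map <- function(boxes, shape) {
  out <- matrix(0, shape[1], shape[2])
  for (r in seq_len(shape[1])) {
    yv <- r - 0.5
    for (cl in seq_len(shape[2])) {
      xv <- cl - 0.5
      n <- 0
      for (i in seq_len(nrow(boxes))) {
        if (xv >= boxes$x[i] && xv < boxes$x[i] + boxes$w[i] &&
            yv >= boxes$y[i] && yv < boxes$y[i] + boxes$h[i]) {
          n <- n + 1
        }
      }
      out[r, cl] <- n
    }
  }
  out
}

# direct 2D convolution with the normalized truncated Gaussian kernel,
# computed as a sum of shifted copies (zero padding)
oracle_smooth2d <- function(mat, window, sigma = NULL) {
  k <- max(1L, round(window)); if (k %% 2L == 0L) k <- k + 1L
  if (is.null(sigma)) sigma <- k / 4 # SD follows the realized odd window
  half <- (k - 1L) / 2L
  k1 <- exp(-((-half:half)^2) / (2 * sigma^2)); k1 <- k1 / sum(k1)
  k2 <- outer(k1, k1)
  n <- nrow(mat); m <- ncol(mat)
  pad <- matrix(0, n + 2 * half, m + 2 * half)
  pad[half + seq_len(n), half + seq_len(m)] <- mat
  out <- matrix(0, n, m)
  for (dr in seq_len(k)) {
    for (dc in seq_len(k)) {
      out <- out + k2[dr, dc] *
        pad[(dr - 1) + seq_len(n), (dc - 1) + seq_len(m)]
    }
  }
  out
}

# entropy weight of a confidence vector from the definition
oracle_entropy_weight <- function(scores, th, base = 10, renorm = TRUE) {
  wp <- scores[scores >= th]
  if (length(wp) == 0) return(NA_real_)
  if (renorm) wp <- wp / sum(wp)
  -sum(wp * log(wp, base = base))
}

# the target-map construction: base square Gaussian of side h_im
# (SD h_im / 4), bilinearly interpolated per destination pixel with the
# centre-aligned mapping, added over the box's pixel extent
oracle_target_map <- function(boxes, shape) {
  him <- shape[1]
  base <- oracle_gaussian(c(him, him), him / 2, him / 2, him / 4)
  acc <- matrix(0, shape[1], shape[2])
  rng <- function(lo, len, n) {
    first <- max(0, ceiling(lo - 0.5))
    last <- min(n - 1, floor(lo + len - 0.5 - 1e-12))
    if (first > last) NULL else first:last
  }
  for (i in seq_len(nrow(boxes))) {
    rows <- rng(boxes$y[i], boxes$h[i], shape[1])
    cols <- rng(boxes$x[i], boxes$w[i], shape[2])
    if (is.null(rows) || is.null(cols)) next
    bh <- length(rows); bw <- length(cols)
    for (rr in seq_len(bh)) {
      sy <- min(max((rr - 0.5) * him / bh - 0.5, 0), him - 1)
      y0 <- min(floor(sy), him - 1); y1 <- min(y0 + 1, him - 1)
      fy <- sy - y0
      for (cc in seq_len(bw)) {
        sx <- min(max((cc - 0.5) * him / bw - 0.5, 0), him - 1)
        x0 <- min(floor(sx), him - 1); x1 <- min(x0 + 1, him - 1)
        fx <- sx - x0
        val <- base[y0 + 1, x0 + 1] * (1 - fy) * (1 - fx) +
          base[y0 + 1, x1 + 1] * (1 - fy) * fx +
          base[y1 + 1, x0 + 1] * fy * (1 - fx) +
          base[y1 + 1, x1 + 1] * fy * fx
        acc[rows[rr] + 1, cols[cc] + 1] <-
          acc[rows[rr] + 1, cols[cc] + 1] + val
      }
    }
  }
  acc
}

# FDM oracle: per-pixel sum of Gaussian evaluations at fixation pixel
# centres, then normalized to sum 1
oracle_fdm <- function(fix, shape, sigma) {
  acc <- matrix(0, shape[1], shape[2])
  for (i in seq_len(nrow(fix))) {
    acc <- acc + oracle_gaussian(shape, floor(fix$x[i]) + 0.5,
                                 floor(fix$y[i]) + 0.5, sigma)
  }
  acc / sum(acc)
}

# patch means by explicit pixel averaging over the 8 x 6 partition
oracle_patch_means <- function(v, grid = c(8, 6)) {
  nc <- grid[1]; nr <- grid[2]
  bw <- ncol(v) %/% nc; bh <- nrow(v) %/% nr
  out <- numeric(nc * nr)
  for (pr in seq_len(nr)) {
    rows <- ((pr - 1) * bh + 1):(if (pr == nr) nrow(v) else pr * bh)
    for (pc in seq_len(nc)) {
      cols <- ((pc - 1) * bw + 1):(if (pc == nc) ncol(v) else pc * bw)
      tot <- 0
      for (r in rows) for (cl in cols) tot <- tot + v[r, cl]
      out[(pr - 1) * nc + pc] <- tot / (length(rows) * length(cols))
    }
  }
  out
}

rel_err <- function(a, b) {
  denom <- max(abs(b))
  if (denom == 0) max(abs(a - b)) else max(abs(a - b)) / denom
}

# random multi-class detection tibble for one image (direct construction,
# no generator involved)
random_detections <- function(shape = c(64, 64), n_boxes = 5, seed = 1,
                              max_cats = 4) {
  withr::with_seed(seed, {
    cats <- category_pool()
    rows <- lapply(seq_len(n_boxes), function(i) {
      w <- sample(6:20, 1); h <- sample(6:20, 1)
      x <- sample(0:(shape[2] - w), 1); y <- sample(0:(shape[1] - h), 1)
      k <- sample(1:max_cats, 1)
      labs <- sample(cats, k + 2)
      sc <- c(runif(k, 0.05, 0.95), runif(2, 0, 0.015))
      tibble::tibble(image_id = "img", image_h = shape[1],
                     image_w = shape[2], box_id = i, x = x, y = y,
                     w = w, h = h, category = labs, score = sc)
    })
    as_detections(dplyr::bind_rows(rows))
  })
}

expect_no_shared_boxes <- function(det) {
  boxes <- dplyr::distinct(det, box_id, x, y, w, h)
  expect_equal(nrow(boxes), length(unique(boxes$box_id)))
}
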