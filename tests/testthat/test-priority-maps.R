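test_that("gaussian_blob matches the closed-form density pointwise", {
  g <- gaussian_blob(c(7, 7), center = c(3.5, 3.5), sigma = 2)
  expect_equal(which(g == max(g)), 25) # centre pixel of a 7x7 raster
  expect_equal(rel_err(g, oracle_gaussian(c(7, 7), 3.5, 3.5, 2)), 0,
               tolerance = 1e-12)
  # one sigma out horizontally: ratio exp(1/2)
  expect_equal(g[4, 4] / g[4, 6], exp(2^2 / (2 * 2^2)))
  # truncated support is exactly zero outside the window
  gt <- gaussian_blob(c(21, 21), center = c(10.5, 10.5), sigma = 3,
                      window = 7)
  expect_equal(gt[1, 1], 0)
  expect_gt(gt[11, 11], 0)
})

test_that("unique-recognition probabilities follow the competing-count normalization", {
  expect_equal(unique_object_probability(c(3, 2, 1, 4)),
               c(0.70, 0.80, 0.90, 0.60))
  expect_equal(unique_object_probability(c(1, 1)), c(0.5, 0.5))
  expect_equal(unique_object_probability(rep(5, 5)), rep(0.8, 5))
  expect_error(unique_object_probability(numeric(0)))
  expect_error(unique_object_probability(c(1, 0)))
  # outputs sum to B - 1 for any valid count vector
  withr::with_seed(2, {
    for (i in 1:10) {
      f <- sample(1:6, sample(2:8, 1), replace = TRUE)
      expect_equal(sum(unique_object_probability(f)), length(f) - 1)
    }
  })
})

test_that("self-information is -log10(p), decreasing, zero at certainty", {
  expect_equal(self_information(1), 0)
  expect_equal(self_information(0.70), -log10(0.7))
  expect_equal(round(self_information(0.70), 3), 0.155)
  expect_error(self_information(0))
  p <- seq(0.05, 1, by = 0.05)
  expect_true(all(diff(self_information(p)) < 0))
  expect_equal(self_information(0.5, base = 2), 1)
})

test_that("uncertainty map weights proposals by f_b / max f_b", {
  # single proposal whose centre is a pixel centre: peak weight exactly 1
  det <- as_detections(tibble::tibble(
    image_id = "img", image_h = 64, image_w = 64, box_id = 1L,
    x = 10, y = 12, w = 9, h = 9, category = c("cup", "tv"),
    score = c(0.9, 0.1)
  ))
  m <- uncertainty_map(det, shape = c(64, 64))
  expect_equal(max(as.matrix(m)), 1, tolerance = 1e-9)

  # two far-apart proposals with f = 4 and 2: peak ratio approx 2
  mk <- function(i, b, sc) tibble::tibble(
    image_id = "img", image_h = 64, image_w = 64, box_id = i,
    x = b[1], y = b[2], w = b[3], h = b[4],
    category = names(sc), score = unname(sc)
  )
  det <- as_detections(dplyr::bind_rows(
    mk(1L, c(2, 2, 8, 8), c(cup = 0.9, tv = 0.1, car = 0.1, bowl = 0.1)),
    mk(2L, c(52, 52, 8, 8), c(fork = 0.8, knife = 0.1))
  ))
  m <- as.matrix(uncertainty_map(det, shape = c(64, 64)))
  expect_equal(m[7, 7] / m[57, 57], 2, tolerance = 1e-3)
})

test_that("uncertainty and entropy maps equal the per-pixel formula oracle", {
  for (seed in 1:6) {
    det <- random_detections(n_boxes = 4, seed = seed)
    surv <- nms(filter_by_confidence(det, 0.02), 0.30)
    fb <- competing_counts(surv, 0.02)

    m <- uncertainty_map(det, shape = c(64, 64))
    expect_lte(rel_err(as.matrix(m),
                       oracle_gaussian_sum(fb, fb$f / max(fb$f), c(64, 64))),
               1e-9)

    ent <- vapply(fb$box_id, function(b) {
      oracle_entropy_weight(surv$score[surv$box_id == b], 0.02)
    }, numeric(1))
    me <- label_entropy_map(det, shape = c(64, 64))
    expect_lte(rel_err(as.matrix(me),
                       oracle_gaussian_sum(fb, ent, c(64, 64))), 1e-9)
  }
})

test_that("entropy weights hit their closed-form limits", {
  # odd box sides put the Gaussian peak on a pixel centre
  mk <- function(sc) tibble::tibble(
    image_id = "img", image_h = 32, image_w = 32, box_id = 1L,
    x = 10, y = 10, w = 9, h = 9, category = names(sc), score = unname(sc)
  )
  # single above-threshold category: zero entropy, zero map
  m <- expect_silent(label_entropy_map(as_detections(mk(c(cup = 0.9)))))
  expect_equal(max(as.matrix(m)), 0)
  # k equal confidences: log10(k)
  sc <- setNames(rep(0.2, 4), c("cup", "tv", "car", "bowl"))
  m <- label_entropy_map(as_detections(mk(sc)))
  expect_equal(max(as.matrix(m)), log10(4), tolerance = 1e-9)
  # renormalized two-score case
  m <- label_entropy_map(as_detections(mk(c(cup = 0.5, bowl = 0.03))))
  p <- c(0.5, 0.03) / 0.53
  expect_equal(max(as.matrix(m)), -sum(p * log10(p)), tolerance = 1e-9)
})

test_that("pixel-wise uncertainty counts enclosing boxes then smooths", {
  # empty image: zero map with a warning
  det0 <- random_detections(n_boxes = 1, seed = 1)[0, ]
  expect_warning(m0 <- pixelwise_uncertainty_map(det0, shape = c(32, 32)),
                 "all-zero")
  expect_equal(sum(as.matrix(m0)), 0)

  # one box: the unsmoothed map is the box indicator
  det <- as_detections(tibble::tibble(
    image_id = "img", image_h = 32, image_w = 32, box_id = 1L,
    x = 4, y = 6, w = 10, h = 5, category = "cup", score = 0.9
  ))
  m <- as.matrix(pixelwise_uncertainty_map(det, smooth = FALSE))
  expect_equal(sum(m), 50)
  expect_equal(m[7, 5], 1)
  expect_equal(m[6, 5], 0)

  # overlapping boxes: counts match per-pixel enumeration, smoothing
  # matches the direct 2D convolution
  for (seed in c(2, 8)) {
    det <- random_detections(n_boxes = 3, seed = seed)
    boxes <- dplyr::distinct(det, box_id, x, y, w, h)
    counts <- oracle_count_map(boxes, c(64, 64))
    raw <- as.matrix(pixelwise_uncertainty_map(det, smooth = FALSE,
                                               shape = c(64, 64)))
    expect_identical(raw, counts)
    sm <- as.matrix(pixelwise_uncertainty_map(det, shape = c(64, 64)))
    expect_lte(rel_err(sm, oracle_smooth2d(counts, 64 / 4)), 1e-9)
  }
})

test_that("equal competing counts make the Gaussian-sum variants proportional", {
  mk <- function(i, b, sc) tibble::tibble(
    image_id = "img", image_h = 64, image_w = 64, box_id = i,
    x = b[1], y = b[2], w = b[3], h = b[4],
    category = names(sc), score = unname(sc)
  )
  det <- as_detections(dplyr::bind_rows(
    mk(1L, c(2, 2, 10, 12), c(cup = 0.9, tv = 0.2)),
    mk(2L, c(30, 8, 14, 9), c(car = 0.7, bowl = 0.05)),
    mk(3L, c(12, 40, 11, 16), c(fork = 0.6, knife = 0.3))
  )) # every proposal has exactly f = 2
  surv <- nms(det, 0.30)
  fb <- competing_counts(surv, 0.02)
  expect_true(all(fb$f == 2))
  m <- as.matrix(uncertainty_map(surv, preprocessed = TRUE,
                                 shape = c(64, 64)))
  plain <- oracle_gaussian_sum(fb, rep(1, nrow(fb)), c(64, 64))
  expect_lte(rel_err(m, plain), 1e-9) # weights f/max f all equal 1
})

test_that("uncertainty map is order-invariant and additive over distant proposals", {
  det <- random_detections(n_boxes = 4, seed = 17)
  perm <- withr::with_seed(3, sample(nrow(det)))
  m1 <- as.matrix(uncertainty_map(det, shape = c(64, 64)))
  m2 <- as.matrix(uncertainty_map(det[perm, ], shape = c(64, 64)))
  expect_equal(m1, m2, tolerance = 1e-12)

  mk <- function(i, b, sc) tibble::tibble(
    image_id = "img", image_h = 96, image_w = 96, box_id = i,
    x = b[1], y = b[2], w = b[3], h = b[4],
    category = names(sc), score = unname(sc)
  )
  a <- mk(1L, c(4, 4, 8, 8), c(cup = 0.9, tv = 0.05))
  b <- mk(2L, c(80, 80, 8, 8), c(car = 0.8, bowl = 0.05))
  both <- as_detections(dplyr::bind_rows(a, b))
  msum <- as.matrix(uncertainty_map(both, shape = c(96, 96)))
  ma <- as.matrix(uncertainty_map(as_detections(a), shape = c(96, 96)))
  mb <- as.matrix(uncertainty_map(as_detections(b), shape = c(96, 96)))
  expect_equal(msum, ma + mb, tolerance = 1e-12)
})

test_that("centre-bias map matches the amplitude-carrying closed form", {
  m <- as.matrix(center_bias_map(c(11, 11), sigma_c = 3))
  expect_equal(which(m == max(m), arr.ind = TRUE)[1, ],
               c(row = 6, col = 6)) # ((w-1)/2, (h-1)/2) 0-based = pixel 5
  expect_equal(m, m[11:1, ], tolerance = 1e-12)
  expect_equal(m, m[, 11:1], tolerance = 1e-12)
  expect_lte(rel_err(m, oracle_gaussian(c(11, 11), 5.5, 5.5, 3,
                                        amplitude = 1 / (3 * sqrt(2 * pi)))),
             1e-9)
  # even-sized image is symmetric about its centre too
  m2 <- as.matrix(center_bias_map(c(10, 16)))
  expect_equal(m2, m2[10:1, ], tolerance = 1e-12)
})

test_that("target maps place the resampled square Gaussian at qualifying boxes", {
  mk <- function(i, b, sc) tibble::tibble(
    image_id = "img", image_h = 48, image_w = 64, box_id = i,
    x = b[1], y = b[2], w = b[3], h = b[4],
    category = names(sc), score = unname(sc)
  )
  det <- as_detections(dplyr::bind_rows(
    mk(1L, c(10, 8, 12, 16), c(cup = 0.95, bowl = 0.3)),
    mk(2L, c(40, 30, 10, 10), c(cup = 0.2, tv = 0.7))
  ))
  # TP rule: only the >0.9 box; argmax at its centre
  m <- as.matrix(target_map_tp(det, "cup"))
  am <- which(m == max(m), arr.ind = TRUE)[1, ]
  expect_equal(unname(am), c(16, 16), tolerance = 1) # centre (16, 16) px
  expect_equal(sum(m[, 41:64]), 0)

  # no qualifying box: zero map plus a warning
  expect_warning(z <- target_map_ta(det, "tv", conf = 0.95), "all-zero")
  expect_equal(sum(as.matrix(z)), 0)

  # unknown category errors
  expect_error(target_map_tp(det, "zebra"), "unknown target category")

  # TA rule includes every box with target confidence > 0.02, additively
  mta <- as.matrix(target_map_ta(det, "cup"))
  m1 <- as.matrix(target_map_tp(det, "cup", conf = 0.9))
  m2 <- suppressWarnings(as.matrix(
    target_map_ta(dplyr::filter(det, box_id == 2), "cup")))
  expect_equal(mta, m1 + m2, tolerance = 1e-12)

  # oracle equivalence of the full construction
  boxes <- dplyr::distinct(det, box_id, x, y, w, h)
  expect_lte(rel_err(mta, oracle_target_map(boxes, c(48, 64))), 1e-9)
})

test_that("a square box of the image height reduces to the unresampled Gaussian", {
  det <- as_detections(tibble::tibble(
    image_id = "img", image_h = 32, image_w = 48, box_id = 1L,
    x = 8, y = 0, w = 32, h = 32, category = "cup", score = 0.95
  ))
  m <- as.matrix(target_map_tp(det, "cup"))
  direct <- gaussian_blob(c(32, 32), center = c(16, 16), sigma = 8)
  expect_equal(m[, 9:40], direct, tolerance = 1e-12)
})

test_that("min-max normalization rescales to [0, 1] preserving ranks", {
  expect_equal(minmax_normalize(matrix(c(0, 5, 10), 1)),
               matrix(c(0, 0.5, 1), 1))
  v <- withr::with_seed(5, matrix(runif(100), 10))
  n1 <- minmax_normalize(v)
  expect_equal(min(n1), 0)
  expect_equal(max(n1), 1)
  expect_identical(order(n1), order(v))
  expect_equal(minmax_normalize(n1), n1) # idempotent once in [0, 1]
  expect_warning(z <- minmax_normalize(matrix(1, 3, 3)), "constant")
  expect_equal(sum(z), 0)
})

test_that("histogram matching reproduces the reference distribution", {
  withr::with_seed(8, {
    m <- matrix(runif(48 * 64), 48)
    ref <- matrix(rbeta(48 * 64, 0.5, 3), 48)
  })
  out <- histogram_match(m, ref)
  expect_identical(dim(out), dim(m))
  # rank order preserved up to ties
  expect_true(all(diff(out[order(m)]) >= 0))
  # KS distance between matched output and reference below bin resolution
  ks <- suppressWarnings(stats::ks.test(as.vector(out), as.vector(ref)))
  expect_lt(unname(ks$statistic), 0.02)
  # identity and constant-reference cases
  self <- histogram_match(m, m)
  expect_true(all(diff(self[order(m)]) >= 0)) # rank-equivalent up to ties
  expect_lt(unname(suppressWarnings(
    stats::ks.test(as.vector(self), as.vector(m)))$statistic), 0.02)
  flat <- histogram_match(m, matrix(0.3, 48, 64))
  expect_true(all(flat == 0.3))
  expect_error(histogram_match(m, matrix(0, 2, 2)), "shape mismatch")
})

test_that("map rasters round-trip through the text serialization", {
  m <- priority_map(withr::with_seed(2, matrix(runif(30 * 40), 30)),
                    "UC", list(sigma = "box_height"))
  tmp <- withr::local_tempfile(fileext = ".tsv")
  write_map(m, tmp)
  back <- read_map(tmp)
  expect_equal(back$values, m$values, tolerance = 1e-9)
  expect_equal(back$variant, "UC")
  # the saliency adapter resizes to the requested shape
  sal <- load_saliency(tmp, c(60, 80))
  expect_identical(dim(sal), c(60L, 80L))
  expect_equal(sal$variant, "Sal")
})

test_that("the stand-in saliency map highlights contrast", {
  flat <- matrix(0.5, 48, 48)
  expect_equal(sum(as.matrix(standin_saliency(flat))), 0)
  disk <- flat
  for (r in 1:48) for (cl in 1:48) {
    if ((r - 12)^2 + (cl - 12)^2 <= 16) disk[r, cl] <- 1
  }
  m <- as.matrix(standin_saliency(disk))
  am <- which(m == max(m), arr.ind = TRUE)[1, ]
  expect_lte((am[1] - 12)^2 + (am[2] - 12)^2, 36)
})
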