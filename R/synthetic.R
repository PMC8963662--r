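#' Default category pool
#'
#' Eighteen everyday object categories (the size of the target-category
#' vocabulary in the COCO-Search18 benchmark) used as the global label
#' pool by the synthetic generators.
#'
#' @return Character vector of 18 category labels.
#' @export
category_pool <- function() {
  c("bottle", "bowl", "car", "chair", "clock", "cup", "fork", "keyboard",
    "knife", "laptop", "microwave", "mouse", "oven", "potted plant",
    "sink", "stop sign", "toilet", "tv")
}

#' Generate a synthetic scene of ground-truth objects
#'
#' Places `n_objects` integer-coordinate boxes inside the image,
#' deterministically for a given seed. Under the `"disjoint"` overlap
#' policy boxes are rejection-sampled until pairwise disjoint (bounded
#' retries; an infeasible spec raises an error).
#'
#' @param n_objects Number of objects (`>= 0`).
#' @param shape Image `c(h, w)` in pixels.
#' @param size_range Inclusive box side range `c(min, max)` in pixels.
#' @param overlap `"any"` (default) or `"disjoint"`.
#' @param categories Category pool to draw labels from.
#' @param object_categories Optional fixed label per object (length
#'   `n_objects`); overrides random draws.
#' @param image_id Image identifier.
#' @param seed Integer seed; generation is bit-reproducible given it.
#' @return Tibble `image_id`, `image_h`, `image_w`, `box_id`, `x`, `y`,
#'   `w`, `h`, `category`.
#' @export
gen_scene <- function(n_objects, shape = c(60, 80), size_range = c(10, 24),
                      overlap = c("any", "disjoint"),
                      categories = category_pool(),
                      object_categories = NULL,
                      image_id = "img1", seed = 1) {
  overlap <- match.arg(overlap)
  stopifnot(n_objects >= 0, size_range[1] >= 1,
            size_range[2] <= min(shape))
  if (!is.null(object_categories)) {
    stopifnot(length(object_categories) == n_objects)
  }
  withr::with_seed(seed, {
    boxes <- tibble(box_id = integer(), x = numeric(), y = numeric(),
                    w = numeric(), h = numeric())
    tries <- 0
    b <- 0
    while (b < n_objects) {
      if (tries > 200 * max(1, n_objects)) {
        abort("could not place all objects under the overlap policy")
      }
      tries <- tries + 1
      w <- sample(size_range[1]:size_range[2], 1)
      h <- sample(size_range[1]:size_range[2], 1)
      x <- sample(0:(shape[2] - w), 1)
      y <- sample(0:(shape[1] - h), 1)
      if (overlap == "disjoint" && nrow(boxes) > 0) {
        ious <- bbox_iou(x, y, w, h, boxes$x, boxes$y, boxes$w, boxes$h)
        if (any(ious > 0)) next
      }
      b <- b + 1
      boxes <- dplyr::bind_rows(boxes, tibble(box_id = b, x = x, y = y,
                                              w = w, h = h))
    }
    cats <- if (is.null(object_categories)) {
      sample(categories, n_objects, replace = TRUE)
    } else {
      object_categories
    }
    dplyr::bind_cols(
      tibble(image_id = rep(image_id, n_objects),
             image_h = rep(shape[1], n_objects),
             image_w = rep(shape[2], n_objects)),
      boxes,
      tibble(category = cats)
    )
  })
}

#' Generate detector output for a synthetic scene
#'
#' Emulates multi-class detector output: one proposal per ground-truth
#' object (optionally spatially jittered), whose number of categories with
#' confidence at or above `th_conf` equals the requested competition
#' level. The true category receives the top score, `competition - 1`
#' distractor categories receive above-threshold scores, and a few
#' sub-threshold nuisance scores are added to exercise confidence
#' filtering. Deterministic given the seed.
#'
#' @param scene A scene tibble from [gen_scene()].
#' @param competition Number of plausible categories per object (`>= 1`),
#'   recycled over objects.
#' @param score_noise SD of Gaussian noise added to the drawn scores
#'   (clipped back to valid ranges; default 0).
#' @param jitter Maximum absolute box shift in pixels (integer, default 0).
#' @param th_conf Confidence threshold the competition level is defined
#'   against (default 0.02).
#' @param distractor_pool Categories the distractor labels are drawn from
#'   (default: the full pool except each object's true category).
#' @param categories Full category pool.
#' @param n_subthreshold Nuisance categories per proposal (default 2).
#' @param seed Integer seed.
#' @return A detections tibble.
#' @export
gen_detections <- function(scene, competition = 1, score_noise = 0,
                           jitter = 0, th_conf = 0.02,
                           distractor_pool = NULL,
                           categories = category_pool(),
                           n_subthreshold = 2, seed = 1) {
  n <- nrow(scene)
  competition <- rep_len(competition, n)
  if (any(competition < 1)) abort("competition must be >= 1 per object")
  withr::with_seed(seed, {
    rows <- purrr::map(seq_len(n), function(i) {
      true_cat <- scene$category[i]
      pool <- distractor_pool %||% setdiff(categories, true_cat)
      pool <- setdiff(pool, true_cat)
      k <- competition[i] - 1
      if (k > length(pool)) {
        abort("competition exceeds the category pool size")
      }
      distractors <- if (k > 0) sample(pool, k) else character()
      sub_pool <- setdiff(categories, c(true_cat, distractors))
      nsub <- min(n_subthreshold, length(sub_pool))
      subs <- if (nsub > 0) sample(sub_pool, nsub) else character()
      clamp <- function(v, lo, hi) pmin(pmax(v, lo), hi)
      s_true <- clamp(runif(1, 0.55, 0.95) + rnorm(1, 0, score_noise),
                      0.5, 1)
      s_dis <- clamp(runif(k, th_conf + 0.005, 0.45) +
                       rnorm(k, 0, score_noise), th_conf, 0.49)
      s_sub <- runif(nsub, 0, th_conf * 0.9)
      dx <- if (jitter > 0) sample(-jitter:jitter, 1) else 0
      dy <- if (jitter > 0) sample(-jitter:jitter, 1) else 0
      x <- clamp(scene$x[i] + dx, 0, scene$image_w[i] - scene$w[i])
      y <- clamp(scene$y[i] + dy, 0, scene$image_h[i] - scene$h[i])
      tibble(
        image_id = scene$image_id[i],
        image_h = scene$image_h[i], image_w = scene$image_w[i],
        box_id = scene$box_id[i],
        x = x, y = y, w = scene$w[i], h = scene$h[i],
        category = c(true_cat, distractors, subs),
        score = c(s_true, s_dis, s_sub)
      )
    })
    as_detections(dplyr::bind_rows(rows))
  })
}

#' Sample fixation sequences from a mixture of priority maps
#'
#' Gaze is simulated by drawing each fixation i.i.d. from the density
#' `d = (1 - epsilon) * sum(w_i * m_i / sum(m_i)) + epsilon * uniform`;
#' every subject receives `n_fixations` ordered fixations. Fixation
#' coordinates are the sampled pixel centres. No sequential scanpath
#' structure (saccade-length priors, inhibition of return) is modelled:
#' the per-index analyses treat fixation ordinals independently.
#'
#' @param maps List of `priority_map`s (same shape, min-max normalized).
#' @param weights Non-negative mixture weights summing to 1, one per map.
#' @param n_subjects,n_fixations Cohort size and fixations per subject.
#' @param epsilon Uniform floor in `[0, 1]` (default 0.05); keeps the
#'   density strictly positive so downstream logistic fits never see
#'   perfectly separable data.
#' @param image_id Image identifier stamped on the rows.
#' @param seed Integer seed.
#' @return A fixations tibble.
#' @export
gen_fixations <- function(maps, weights, n_subjects, n_fixations,
                          epsilon = 0.05, image_id = "img1", seed = 1) {
  stopifnot(length(maps) == length(weights), all(weights >= 0))
  if (abs(sum(weights) - 1) > 1e-9) abort("mixture weights must sum to 1")
  stopifnot(epsilon >= 0, epsilon <= 1)
  shp <- dim(maps[[1]])
  npix <- prod(shp)
  d <- matrix(0, shp[1], shp[2])
  for (i in seq_along(maps)) {
    v <- map_values(maps[[i]])
    if (!all(dim(v) == shp)) abort("all maps must share one shape")
    tot <- sum(v)
    if (tot > 0) d <- d + weights[i] * v / tot
  }
  d <- (1 - epsilon) * d + epsilon / npix
  if (sum(d) == 0) abort("all-zero mixture density")
  d <- d / sum(d)
  withr::with_seed(seed, {
    idx <- sample.int(npix, n_subjects * n_fixations, replace = TRUE,
                      prob = as.vector(d))
    row <- (idx - 1) %% shp[1]
    col <- (idx - 1) %/% shp[1]
    tibble(
      subject_id = rep(sprintf("s%02d", seq_len(n_subjects)),
                       each = n_fixations),
      image_id = image_id,
      fix_index = rep(seq_len(n_fixations), times = n_subjects),
      x = col + 0.5,
      y = row + 0.5
    )
  })
}

#' End-to-end weight-recovery experiment
#'
#' The synthetic counterpart of the map-weighting study: for each image a
#' scene and detector output are generated, three feature maps are built
#' with the package's own constructors (object-recognition uncertainty,
#' centre bias, and a target-absent-style target map for a per-image
#' target category), multi-subject scanpaths are sampled from the known
#' convex mixture of those maps, and the full evaluation pipeline
#' (fixation-density maps, histogram matching, patch means, per-index
#' logistic mixed models, weight table) is run to recover the mixture
#' weighting.
#'
#' @param weights True mixture weights `c(uc, cb, target)` summing to 1.
#' @param n_images,n_subjects,n_fixations Cohort sizes.
#' @param shape Image `c(h, w)` (default 60 x 80 so the 8 x 6 patch grid
#'   has 10 x 10 px cells).
#' @param n_objects Objects per scene (default 5; one is always the
#'   target category).
#' @param epsilon Uniform sampling floor (default 0.05).
#' @param n_scene_types Number of scene-type labels used as the random
#'   intercept grouping (default 4).
#' @param match_fdm Histogram-match feature maps to per-image FDMs before
#'   patch averaging (default `TRUE`, the study protocol).
#' @param random Random-intercept groupings (default `"scene_type"`).
#' @param nagq Passed to [fit_glmm()].
#' @param seed Integer seed.
#' @return A list of class `recovery_experiment`: `weight_table`,
#'   `results` (per-index `glmm_result`s), `z` (fixation x feature
#'   z-matrix), `instances`, and the generating spec.
#' @export
weight_recovery_experiment <- function(weights = c(uc = 0.6, cb = 0.3,
                                                   target = 0.1),
                                       n_images = 200, n_subjects = 10,
                                       n_fixations = 9, shape = c(60, 80),
                                       n_objects = 5, epsilon = 0.05,
                                       n_scene_types = 4,
                                       match_fdm = TRUE,
                                       random = "scene_type",
                                       nagq = 0, seed = 1) {
  if (length(weights) < 2) abort("at least two mixture features required")
  if (is.null(names(weights))) {
    names(weights) <- c("uc", "cb", "target")[seq_along(weights)]
  }
  pool <- category_pool()
  seeds <- withr::with_seed(seed, {
    matrix(sample.int(.Machine$integer.max, n_images * 3), ncol = 3)
  })
  scene_types <- withr::with_seed(seed, {
    sample(sprintf("scene%02d", seq_len(n_scene_types)), n_images,
           replace = TRUE)
  })
  target_cats <- withr::with_seed(seed + 1L, {
    sample(pool, n_images, replace = TRUE)
  })

  per_image <- purrr::map(seq_len(n_images), function(i) {
    id <- sprintf("im%04d", i)
    tgt <- target_cats[i]
    cats <- c(tgt, sample_from(setdiff(pool, tgt), n_objects - 1,
                               seeds[i, 1]))
    scene <- gen_scene(n_objects, shape, object_categories = cats,
                       image_id = id, seed = seeds[i, 1])
    det <- gen_detections(scene,
                          competition = 1 + (seq_len(n_objects) - 1) %% 4,
                          distractor_pool = setdiff(pool, tgt),
                          seed = seeds[i, 2])
    maps <- list(
      uc = uncertainty_map(det, shape = shape),
      cb = center_bias_map(shape),
      target = suppressWarnings(target_map_ta(det, tgt, shape = shape))
    )[names(weights)]
    maps <- lapply(maps, function(m) suppressWarnings(minmax_normalize(m)))
    fx <- gen_fixations(maps, unname(weights), n_subjects, n_fixations,
                        epsilon = epsilon, image_id = id,
                        seed = seeds[i, 3])
    list(id = id, maps = maps, fix = fx)
  })

  fix <- dplyr::bind_rows(purrr::map(per_image, "fix"))
  maps_tbl <- purrr::map(per_image, function(p) {
    tibble(image_id = p$id, feature = names(p$maps), map = unname(p$maps))
  }) |> dplyr::bind_rows()
  fdms <- if (match_fdm) {
    fd <- purrr::map(per_image, function(p) {
      build_fdm(dplyr::filter(fix, .data$image_id == p$id), shape)
    })
    setNames(fd, purrr::map_chr(per_image, "id"))
  } else {
    NULL
  }
  image_meta <- tibble(
    image_id = purrr::map_chr(per_image, "id"),
    scene_type = scene_types,
    target_category = target_cats
  )

  feat_patches <- patch_feature_table(maps_tbl, fdms = fdms)
  results <- purrr::map(seq_len(n_fixations), function(n) {
    tab <- build_observation_table(maps_tbl, fix, n,
                                   feature_patches = feat_patches,
                                   image_meta = image_meta)
    fit_glmm(tab, features = names(weights), random = random, nagq = nagq)
  })
  inst <- instance_proportions(fix, n_fixations)
  wt <- weight_table(results, inst)
  z <- as.matrix(dplyr::select(
    tidyr::pivot_wider(
      dplyr::select(attr(wt, "statistics"), "fix_index", "term",
                    "statistic"),
      names_from = "term", values_from = "statistic"
    ),
    -"fix_index"
  ))
  structure(list(
    weight_table = wt, results = results, z = z, instances = inst,
    spec = list(weights = weights, n_images = n_images,
                n_subjects = n_subjects, n_fixations = n_fixations,
                shape = shape, n_objects = n_objects, epsilon = epsilon,
                match_fdm = match_fdm, seed = seed)
  ), class = "recovery_experiment")
}

sample_from <- function(pool, k, seed) {
  withr::with_seed(seed, sample(pool, k, replace = TRUE))
}

#' @export
print.recovery_experiment <- function(x, ...) {
  cat(sprintf("<recovery_experiment: %d images x %d subjects, true weights %s>\n",
              x$spec$n_images, x$spec$n_subjects,
              paste(sprintf("%s=%.2f", names(x$spec$weights),
                            x$spec$weights), collapse = ", ")))
  print(x$weight_table)
  invisible(x)
}
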