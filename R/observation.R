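#' Patch means over an 8 x 6 scene grid
#'
#' The image is partitioned into `grid[1]` columns by `grid[2]` rows of
#' patches (default 8 x 6 = 48); when the image dimensions are not
#' divisible, the remainder pixels are assigned to the last column/row.
#' Patches are indexed 0..47 in row-major order.
#'
#' @param m A `priority_map` or matrix.
#' @param grid `c(columns, rows)` (default `c(8, 6)`).
#' @return Tibble `patch_index`, `value` (mean map value in the patch).
#' @export
patch_means <- function(m, grid = c(8, 6)) {
  v <- map_values(m)
  nc <- grid[1]; nr <- grid[2]
  cw <- patch_breaks(ncol(v), nc)
  rh <- patch_breaks(nrow(v), nr)
  vals <- numeric(nc * nr)
  for (r in seq_len(nr)) {
    for (c in seq_len(nc)) {
      vals[(r - 1) * nc + c] <-
        mean(v[(rh[r] + 1):rh[r + 1], (cw[c] + 1):cw[c + 1]])
    }
  }
  tibble(patch_index = seq_len(nc * nr) - 1L, value = vals)
}

# 0-based cumulative boundaries of n cells over len pixels,
# remainder pixels in the last cell
patch_breaks <- function(len, n) {
  base <- len %/% n
  if (base < 1) abort("image too small for the patch grid")
  widths <- rep(base, n)
  widths[n] <- widths[n] + len - base * n
  cumsum(c(0, widths))
}

#' Patch index of an image point
#'
#' @param x,y 0-based pixel coordinates (vectorised).
#' @param shape Image `c(h, w)`.
#' @param grid `c(columns, rows)` (default `c(8, 6)`).
#' @return Integer patch indices, row-major 0-based.
#' @export
patch_of_point <- function(x, y, shape, grid = c(8, 6)) {
  cw <- patch_breaks(shape[2], grid[1])
  rh <- patch_breaks(shape[1], grid[2])
  col <- findInterval(x, cw, rightmost.closed = TRUE, all.inside = TRUE) - 1L
  row <- findInterval(y, rh, rightmost.closed = TRUE, all.inside = TRUE) - 1L
  row * grid[1] + col
}

#' Build the patch-level observation table for the GLMM analysis
#'
#' One row per subject x image x patch at fixation ordinal `n`:
#' `fixated` is 1 iff that subject's `n`-th new fixation on that image
#' falls inside the patch, and each feature column holds the mean priority
#' map value over the patch. The preprocessing order is fixed: maps are
#' histogram-matched to the per-image FDM (when `fdms` is supplied), patch
#' means are taken, and each feature column is then min-max normalized to
#' `[0, 1]` across the whole table. Every subject-image pair in `fix`
#' contributes 48 rows (all-zero `fixated` when the trial has no `n`-th
#' fixation), so the table has exactly
#' `n_images x n_subjects x 48` rows.
#'
#' @param maps Tibble with columns `image_id`, `feature`, `map`
#'   (list-column of `priority_map`s), one row per image-feature pair.
#' @param fix A fixations tibble.
#' @param n Fixation ordinal the table is built at.
#' @param fdms Optional named list (by `image_id`) of reference FDMs for
#'   histogram matching.
#' @param grid Patch grid `c(columns, rows)` (default `c(8, 6)`).
#' @param normalize Min-max normalize feature columns (default `TRUE`).
#' @param image_meta Optional tibble with `image_id` plus grouping labels
#'   (`scene_type`, `target_category`) joined onto the table.
#' @param feature_patches Optional precomputed result of
#'   [patch_feature_table()] (the per-patch feature means do not depend on
#'   the fixation ordinal, so batch analyses compute them once).
#' @return Tibble `subject_id`, `image_id`, `patch_index`, `fixated`,
#'   one column per feature, plus any grouping labels.
#' @export
build_observation_table <- function(maps, fix, n, fdms = NULL,
                                    grid = c(8, 6), normalize = TRUE,
                                    image_meta = NULL,
                                    feature_patches = NULL) {
  stopifnot(all(c("image_id", "feature", "map") %in% names(maps)))
  fix <- as_fixations(fix)
  images <- unique(fix$image_id)
  subjects <- unique(fix$subject_id)
  features <- unique(maps$feature)
  missing <- setdiff(
    paste(rep(images, each = length(features)), features),
    paste(maps$image_id, maps$feature)
  )
  if (length(missing) > 0) {
    abort(paste0("missing map for image/feature: ",
                 paste(head(missing, 5), collapse = "; ")))
  }

  shape <- dim(maps$map[[1]])
  npatch <- prod(grid)

  feat_patches <- feature_patches %||%
    patch_feature_table(maps, fdms = fdms, grid = grid,
                        normalize = normalize, images = images)

  sel <- select_fixation(fix, n) |>
    dplyr::mutate(patch_index = patch_of_point(.data$x, .data$y, shape, grid),
                  fixated = 1L) |>
    dplyr::select("subject_id", "image_id", "patch_index", "fixated")

  tab <- tidyr::expand_grid(
    subject_id = subjects,
    image_id = images,
    patch_index = seq_len(npatch) - 1L
  ) |>
    dplyr::left_join(sel, by = c("subject_id", "image_id", "patch_index")) |>
    dplyr::mutate(fixated = dplyr::coalesce(.data$fixated, 0L)) |>
    dplyr::left_join(feat_patches, by = c("image_id", "patch_index"))

  if (!is.null(image_meta)) {
    tab <- dplyr::left_join(tab, image_meta, by = "image_id")
  }
  attr(tab, "features") <- features
  attr(tab, "fixation_index") <- n
  tab
}

#' Per-patch feature means for every image
#'
#' The fixation-independent half of the observation table: each priority
#' map is (optionally) histogram-matched to its image's FDM, averaged over
#' the patch grid, and each feature column is min-max normalized to
#' `[0, 1]` across all images -- in that fixed order.
#'
#' @inheritParams build_observation_table
#' @param images Optional subset of image ids.
#' @return Tibble `image_id`, `patch_index`, one column per feature.
#' @export
patch_feature_table <- function(maps, fdms = NULL, grid = c(8, 6),
                                normalize = TRUE, images = NULL) {
  stopifnot(all(c("image_id", "feature", "map") %in% names(maps)))
  if (!is.null(images)) {
    maps <- dplyr::filter(maps, .data$image_id %in% images)
  }
  features <- unique(maps$feature)
  out <- maps |>
    dplyr::mutate(pm = purrr::map2(.data$map, .data$image_id, function(m, id) {
      if (!is.null(fdms)) {
        ref <- fdms[[as.character(id)]]
        if (is.null(ref)) abort(sprintf("no FDM supplied for image %s", id))
        m <- histogram_match(m, ref)
      }
      patch_means(m, grid)$value
    })) |>
    dplyr::select("image_id", "feature", "pm") |>
    tidyr::unnest_longer("pm", values_to = "value", indices_to = "pidx") |>
    dplyr::mutate(patch_index = .data$pidx - 1L) |>
    dplyr::select(-"pidx") |>
    tidyr::pivot_wider(names_from = "feature", values_from = "value")
  if (normalize) {
    for (f in features) {
      col <- out[[f]]
      rng <- range(col)
      out[[f]] <- if (diff(rng) > 0) {
        (col - rng[1]) / (rng[2] - rng[1])
      } else {
        col * 0
      }
    }
  }
  out
}
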