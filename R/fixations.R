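#' Read and write fixation tables
#'
#' Fixation sequences are tidy tibbles with one row per fixation:
#' `subject_id`, `image_id`, `fix_index` (1-based ordinal of the new
#' fixation within the trial, strictly increasing), `x`, `y` (0-based
#' pixels, origin top-left). The CSV dialect has exactly that header; an
#' optional `duration_ms` column is carried through but ignored.
#'
#' @param path CSV path.
#' @return A fixations tibble.
#' @export
read_fixations <- function(path) {
  fix <- readr::read_csv(path, show_col_types = FALSE)
  as_fixations(fix)
}

#' @rdname read_fixations
#' @param fix A fixations tibble.
#' @export
write_fixations <- function(fix, path) {
  readr::write_csv(as_fixations(fix), path)
  invisible(path)
}

#' @rdname read_fixations
#' @export
as_fixations <- function(fix) {
  needed <- c("subject_id", "image_id", "fix_index", "x", "y")
  missing <- setdiff(needed, names(fix))
  if (length(missing) > 0) {
    abort(paste0("fixation table is missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  fix <- as_tibble(fix)
  if (nrow(fix) > 0) {
    bad <- fix |>
      dplyr::group_by(.data$subject_id, .data$image_id) |>
      dplyr::summarise(ok = all(diff(c(0, .data$fix_index)) > 0),
                       .groups = "drop")
    if (any(!bad$ok)) {
      abort("fix_index must increase strictly from 1 within each trial")
    }
  }
  fix
}

#' Fixation-density map
#'
#' Ground truth for map evaluation: a unit delta mass at each fixation's
#' pixel centre, convolved with an isotropic Gaussian (full support) and
#' renormalized to sum to 1.
#'
#' @param fix A fixations tibble (any number of subjects).
#' @param shape Image `c(h, w)` in pixels.
#' @param sigma Smoothing SD in pixels; default `shape[1] / 24`
#'   (roughly one degree of visual angle at typical eye-tracking geometry).
#' @param fix_index Optional vector of fixation ordinals to keep.
#' @return A `priority_map` tagged `"FDM"` whose values sum to 1.
#' @export
build_fdm <- function(fix, shape, sigma = shape[1] / 24, fix_index = NULL) {
  fix <- as_fixations(fix)
  if (!is.null(fix_index)) {
    fix <- dplyr::filter(fix, .data$fix_index %in% !!fix_index)
  }
  if (nrow(fix) == 0) abort("no fixations left to build an FDM from")
  acc <- matrix(0, shape[1], shape[2])
  px <- floor(fix$x); py <- floor(fix$y)
  if (any(px < 0 | px >= shape[2] | py < 0 | py >= shape[1])) {
    abort("fixation coordinates fall outside the image")
  }
  for (i in seq_len(nrow(fix))) {
    acc <- acc + gaussian_blob(shape, center = c(px[i] + 0.5, py[i] + 0.5),
                               sigma = sigma)
  }
  priority_map(acc / sum(acc), "FDM", list(sigma = sigma))
}

#' Normalized scanpath saliency
#'
#' The map is standardized to zero mean and unit population SD over its
#' pixels; NSS is the mean standardized value at the fixated pixels. 0 is
#' chance level; 1 means fixations land one SD above the map average. A
#' constant map scores 0 with a warning. Invariant under positive affine
#' transforms of the map.
#'
#' @param m A `priority_map` or matrix.
#' @param fixations Data frame with `x`, `y` columns (0-based pixels) or a
#'   two-column matrix.
#' @return NSS score (numeric scalar).
#' @export
nss <- function(m, fixations) {
  v <- map_values(m)
  if (is.matrix(fixations)) {
    fixations <- tibble(x = fixations[, 1], y = fixations[, 2])
  }
  if (nrow(fixations) == 0) abort("at least one fixation is required")
  px <- floor(fixations$x); py <- floor(fixations$y)
  if (any(px < 0 | px >= ncol(v) | py < 0 | py >= nrow(v))) {
    abort("fixation coordinates fall outside the map")
  }
  s <- sqrt(mean((v - mean(v))^2))
  if (s == 0) {
    warn("constant map: NSS defined as 0")
    return(0)
  }
  z <- (v - mean(v)) / s
  mean(z[cbind(py + 1, px + 1)])
}

#' Select the n-th new fixation per trial
#'
#' Returns, for every subject-image pair whose sequence reaches ordinal
#' `n`, that single fixation. The number of returned rows is the instance
#' count for fixation index `n`.
#'
#' @param fix A fixations tibble.
#' @param n Fixation ordinal (1-9 in the analyses here).
#' @return Tibble of selected fixations (possibly empty).
#' @export
select_fixation <- function(fix, n) {
  fix <- as_fixations(fix)
  stopifnot(n >= 1)
  dplyr::filter(fix, .data$fix_index == n)
}

#' Instance proportions per fixation index
#'
#' The proportion of subject-image trials contributing to each fixation
#' ordinal 1..`max_index`; the proportions sum to 1 over the column.
#'
#' @param fix A fixations tibble.
#' @param max_index Largest ordinal considered (default 9).
#' @return Tibble `fix_index`, `n_instances`, `proportion`.
#' @export
instance_proportions <- function(fix, max_index = 9) {
  fix <- as_fixations(fix)
  counts <- vapply(seq_len(max_index),
                   function(n) nrow(select_fixation(fix, n)), numeric(1))
  total <- sum(counts)
  tibble(
    fix_index = seq_len(max_index),
    n_instances = counts,
    proportion = if (total > 0) counts / total else rep(0, max_index)
  )
}
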