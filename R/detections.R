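#' Multi-class object detections as a tidy tibble
#'
#' Detections are represented as a long tibble with one row per
#' proposal-category score: columns `image_id`, `image_h`, `image_w`,
#' `box_id`, `x`, `y`, `w`, `h`, `category`, `score`. Boxes use 0-based
#' pixel coordinates with origin at the top-left corner and half-open
#' extents `[x, x + w) x [y, y + h)`; `box_id` preserves input order
#' within each image.
#'
#' @param df A data frame with the columns above (extra columns kept).
#' @return A validated detections tibble.
#' @export
as_detections <- function(df) {
  needed <- c("image_id", "image_h", "image_w", "box_id",
              "x", "y", "w", "h", "category", "score")
  missing <- setdiff(needed, names(df))
  if (length(missing) > 0) {
    abort(paste0("detections tibble is missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  df <- as_tibble(df)
  if (nrow(df) > 0) {
    if (any(df$w <= 0) || any(df$h <= 0)) {
      abort("all boxes must have positive width and height")
    }
    if (any(df$score < 0 | df$score > 1)) {
      abort("confidence scores must lie in [0, 1]")
    }
  }
  df
}

#' Intersection-over-union of bounding boxes
#'
#' Area ratio of two axis-aligned boxes under the half-open convention
#' `[x, x + w) x [y, y + h)`; on integer boxes this equals the ratio of
#' overlapping to covered pixel counts. All arguments are vectorised.
#'
#' @param ax,ay,aw,ah First box (left, top, width, height), pixels.
#' @param bx,by,bw,bh Second box.
#' @return IoU value(s) in `[0, 1]`.
#' @examples
#' bbox_iou(0, 0, 10, 10, 5, 0, 10, 10) # 1/3
#' @export
bbox_iou <- function(ax, ay, aw, ah, bx, by, bw, bh) {
  ix <- pmax(0, pmin(ax + aw, bx + bw) - pmax(ax, bx))
  iy <- pmax(0, pmin(ay + ah, by + bh) - pmax(ay, by))
  inter <- ix * iy
  union <- aw * ah + bw * bh - inter
  inter / union
}

#' Clip boxes to image bounds
#'
#' Boxes partially outside the image are clipped to it; proposals that fall
#' fully outside are dropped with a warning.
#'
#' @param det A detections tibble (see [as_detections()]).
#' @return The clipped detections tibble.
#' @export
clip_detections <- function(det) {
  det <- as_detections(det)
  if (nrow(det) == 0) return(det)
  x1 <- pmin(pmax(det$x, 0), det$image_w)
  y1 <- pmin(pmax(det$y, 0), det$image_h)
  x2 <- pmin(pmax(det$x + det$w, 0), det$image_w)
  y2 <- pmin(pmax(det$y + det$h, 0), det$image_h)
  keep <- (x2 - x1) > 0 & (y2 - y1) > 0
  if (any(!keep)) {
    warn(sprintf("dropping %d proposal(s) lying fully outside the image",
                 length(unique(det$box_id[!keep]))))
  }
  det$x <- x1
  det$y <- y1
  det$w <- x2 - x1
  det$h <- y2 - y1
  det[keep, , drop = FALSE]
}

#' Filter proposals and category scores by confidence
#'
#' A proposal is kept iff its maximum category confidence reaches
#' `th_conf`; within kept proposals, category entries with confidence below
#' `th_conf` are dropped. Input order is preserved.
#'
#' @param det A detections tibble.
#' @param th_conf Confidence threshold in `[0, 1]` (default 0.02).
#' @return The filtered detections tibble.
#' @export
filter_by_confidence <- function(det, th_conf = 0.02) {
  det <- as_detections(det)
  stopifnot(th_conf >= 0, th_conf <= 1)
  if (nrow(det) == 0 || th_conf == 0) return(det)
  det |>
    dplyr::group_by(.data$image_id, .data$box_id) |>
    dplyr::filter(max(.data$score) >= th_conf) |>
    dplyr::ungroup() |>
    dplyr::filter(.data$score >= th_conf)
}

#' Non-maximum suppression on object proposals
#'
#' Greedy NMS ranked by each proposal's maximum category score (ties broken
#' by input order): the top box is kept and every remaining box whose IoU
#' with a kept box strictly exceeds `th_nms` is suppressed. By default the
#' suppression is class-agnostic, producing a one-to-one mapping between
#' surviving proposals and distinct physical objects; `per_category = TRUE`
#' restricts suppression to proposals sharing their top-scoring category.
#'
#' @param det A detections tibble.
#' @param th_nms IoU threshold in `[0, 1]` (default 0.30).
#' @param per_category Suppress only within top-category groups.
#' @return Detections tibble containing the surviving proposals.
#' @export
nms <- function(det, th_nms = 0.30, per_category = FALSE) {
  det <- as_detections(det)
  stopifnot(th_nms >= 0, th_nms <= 1)
  if (nrow(det) == 0) return(det)
  kept <- det |>
    dplyr::group_by(.data$image_id) |>
    dplyr::group_map(function(d, key) {
      boxes <- d |>
        dplyr::group_by(.data$box_id) |>
        dplyr::summarise(
          x = .data$x[1], y = .data$y[1], w = .data$w[1], h = .data$h[1],
          top = max(.data$score),
          top_cat = .data$category[which.max(.data$score)],
          .groups = "drop"
        ) |>
        dplyr::arrange(dplyr::desc(.data$top), .data$box_id)
      keep <- logical(nrow(boxes))
      alive <- rep(TRUE, nrow(boxes))
      for (i in seq_len(nrow(boxes))) {
        if (!alive[i]) next
        keep[i] <- TRUE
        if (i == nrow(boxes)) break
        j <- which(alive)
        j <- j[j > i]
        if (per_category) j <- j[boxes$top_cat[j] == boxes$top_cat[i]]
        if (length(j) == 0) next
        ious <- bbox_iou(boxes$x[i], boxes$y[i], boxes$w[i], boxes$h[i],
                         boxes$x[j], boxes$y[j], boxes$w[j], boxes$h[j])
        alive[j[ious > th_nms]] <- FALSE
      }
      tibble(image_id = key$image_id, box_id = boxes$box_id[keep])
    }) |>
    dplyr::bind_rows()
  dplyr::semi_join(det, kept, by = c("image_id", "box_id"))
}

#' Competing-category counts per proposal
#'
#' For each surviving proposal, the number of object categories whose
#' confidence reaches `th_conf` -- the competing-object count f_b that
#' drives the uncertainty map. A proposal with no category at or above the
#' threshold should already have been filtered out and raises an error.
#'
#' @param det A detections tibble (confidence-filtered, NMS-reduced).
#' @param th_conf Confidence threshold (default 0.02).
#' @return Tibble `image_id`, `box_id`, `x`, `y`, `w`, `h`, `f` (one row
#'   per proposal, input order preserved).
#' @export
competing_counts <- function(det, th_conf = 0.02) {
  det <- as_detections(det)
  out <- det |>
    dplyr::group_by(.data$image_id, .data$box_id) |>
    dplyr::summarise(
      x = .data$x[1], y = .data$y[1], w = .data$w[1], h = .data$h[1],
      f = sum(.data$score >= th_conf),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$image_id, .data$box_id)
  if (nrow(out) > 0 && any(out$f == 0)) {
    abort(paste0(
      "proposal(s) with no category confidence >= th_conf encountered ",
      "(box_id ", paste(out$box_id[out$f == 0], collapse = ", "),
      "); run filter_by_confidence() first"
    ))
  }
  out
}

#' Read and write multi-class detection files
#'
#' The native dialect is a JSON array of records
#' `{image_id, image_height, image_width, bbox: [x, y, w, h],
#' scores: {category: confidence, ...}}`. A strict COCO-results file
#' (`image_id`, `category_id`, `bbox`, `score` per record) is also
#' accepted; records sharing an identical bbox within an image are
#' coalesced into one multi-class proposal. Boxes are clipped to the image
#' on read.
#'
#' @param path Path to a JSON detection file.
#' @param clip Clip boxes to image bounds on read (default `TRUE`).
#' @return A detections tibble.
#' @export
read_detections <- function(path, clip = TRUE) {
  recs <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (length(recs) == 0) {
    return(as_detections(tibble(
      image_id = character(), image_h = numeric(), image_w = numeric(),
      box_id = integer(), x = numeric(), y = numeric(), w = numeric(),
      h = numeric(), category = character(), score = numeric()
    )))
  }
  coco <- !is.null(recs[[1]]$category_id) && is.null(recs[[1]]$scores)
  rows <- purrr::imap(recs, function(r, i) {
    bb <- unlist(r$bbox)
    if (length(bb) != 4 || any(!is.finite(bb))) {
      abort(sprintf("malformed bbox in record %d (image_id %s)",
                    i, as.character(r$image_id %||% "<missing>")))
    }
    if (coco) {
      sc <- setNames(as.numeric(r$score), as.character(r$category_id))
    } else {
      sc <- unlist(r$scores)
      if (is.null(sc) || length(sc) == 0 || is.null(names(sc))) {
        abort(sprintf("malformed scores in record %d (image_id %s)",
                      i, as.character(r$image_id %||% "<missing>")))
      }
    }
    tibble(
      image_id = as.character(r$image_id),
      image_h = as.numeric(r$image_height %||% NA_real_),
      image_w = as.numeric(r$image_width %||% NA_real_),
      record = i,
      x = bb[1], y = bb[2], w = bb[3], h = bb[4],
      category = names(sc), score = as.numeric(sc)
    )
  })
  det <- dplyr::bind_rows(rows)
  # coalesce records sharing a bbox (COCO single-category dialect)
  det <- det |>
    dplyr::group_by(.data$image_id, .data$x, .data$y, .data$w, .data$h) |>
    dplyr::mutate(key = min(.data$record)) |>
    dplyr::group_by(.data$image_id) |>
    dplyr::mutate(box_id = match(.data$key, sort(unique(.data$key)))) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$image_id, .data$box_id) |>
    dplyr::select("image_id", "image_h", "image_w", "box_id",
                  "x", "y", "w", "h", "category", "score")
  det <- as_detections(det)
  if (clip && all(is.finite(det$image_h))) det <- clip_detections(det)
  det
}

#' @rdname read_detections
#' @param det A detections tibble to serialize.
#' @export
write_detections <- function(det, path) {
  det <- as_detections(det)
  recs <- det |>
    dplyr::group_by(.data$image_id, .data$box_id) |>
    dplyr::group_map(function(d, key) {
      list(
        image_id = key$image_id,
        image_height = d$image_h[1],
        image_width = d$image_w[1],
        bbox = c(d$x[1], d$y[1], d$w[1], d$h[1]),
        scores = as.list(setNames(d$score, d$category))
      )
    })
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
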