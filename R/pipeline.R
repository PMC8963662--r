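#' Default pipeline configuration
#'
#' Configuration for [run_pipeline()], overridable via a YAML file or a
#' named list. Defaults carry the study parameters: confidence threshold
#' 0.02, NMS IoU threshold 0.30, TP/TA target-confidence cut-offs 0.9 and
#' 0.02, an 8 x 6 patch grid, and a maximum fixation ordinal of 9.
#'
#' @return A named list of defaults.
#' @export
default_config <- function() {
  list(
    detections = NULL,     # path to a detection JSON file
    fixations = NULL,      # path to a fixation CSV file
    maps_dir = NULL,       # directory of precomputed map rasters (.tsv)
    out_dir = "gazepriority-run",
    th_conf = 0.02,
    th_nms = 0.30,
    sigma = "box_height",  # per-box SD h_b / 4, or a fixed number
    sigma_c = NULL,        # centre-bias SD; default h_im / 3
    fdm_sigma = NULL,      # FDM smoothing SD; default h_im / 24
    grid = c(8, 6),
    max_fixation = 9,
    variants = c("uc", "cb"),
    target_category = NULL,
    target_conf = list(tp = 0.9, ta = 0.02),
    glmm_mode = "joint",
    random = "scene_type",
    nagq = 0,
    match_fdm = TRUE,
    simulate = NULL,       # list(weights, n_images, n_subjects, ...)
    seed = 1
  )
}

#' Validate a pipeline configuration
#'
#' Unknown keys raise an error naming the key; thresholds are checked to
#' lie in `[0, 1]` and referenced input paths to exist.
#'
#' @param cfg Named list of overrides (possibly from [yaml::read_yaml()]).
#' @return The merged, validated configuration.
#' @export
validate_config <- function(cfg = list()) {
  defaults <- default_config()
  unknown <- setdiff(names(cfg), names(defaults))
  if (length(unknown) > 0) {
    abort(paste0("unknown config key(s): ", paste(unknown, collapse = ", ")))
  }
  cfg <- modifyList(defaults, cfg, keep.null = TRUE)
  for (k in c("th_conf", "th_nms")) {
    if (cfg[[k]] < 0 || cfg[[k]] > 1) {
      abort(sprintf("config key '%s' must lie in [0, 1]", k))
    }
  }
  for (k in c("detections", "fixations", "maps_dir")) {
    if (!is.null(cfg[[k]]) && !file.exists(cfg[[k]])) {
      abort(sprintf("config key '%s': path '%s' does not exist", k, cfg[[k]]))
    }
  }
  cfg
}

#' Build the configured priority maps for one image
#'
#' @param det Detections tibble for one image (may be empty).
#' @param cfg Validated configuration.
#' @param shape Image `c(h, w)`.
#' @return Named list of `priority_map`s, keyed by variant.
#' @export
build_maps <- function(det, cfg, shape) {
  out <- list()
  for (v in cfg$variants) {
    out[[v]] <- switch(
      v,
      uc = uncertainty_map(det, cfg$th_conf, cfg$th_nms, cfg$sigma,
                           shape = shape),
      uce = label_entropy_map(det, cfg$th_conf, cfg$th_nms, cfg$sigma,
                              shape = shape),
      ucp = pixelwise_uncertainty_map(det, cfg$th_conf, shape = shape),
      cb = center_bias_map(shape, cfg$sigma_c %||% (shape[1] / 3)),
      `target-tp` = target_map_tp(det, cfg$target_category,
                                  cfg$target_conf$tp, shape = shape),
      `target-ta` = target_map_ta(det, cfg$target_category,
                                  cfg$target_conf$ta, shape = shape),
      abort(sprintf("unknown map variant '%s'", v))
    )
  }
  out
}

#' Run the evaluation pipeline
#'
#' Ties the stages together: either simulates a cohort (when
#' `cfg$simulate` is set) or reads detection and fixation files, builds
#' the configured priority maps, and evaluates them by per-fixation-index
#' NSS and the patch-grid GLMM weighting. Results (`nss.csv`,
#' `glmm_results.csv` mirroring the SE/z/p layout, `weight_table.csv`)
#' and a manifest (parameters, per-stage counts, warnings) are written to
#' `cfg$out_dir`. Deterministic given the configuration and seed.
#'
#' @param cfg Configuration list or path to a YAML file.
#' @return Invisibly, the output directory; the manifest is
#'   `<out_dir>/manifest.json`.
#' @export
run_pipeline <- function(cfg = list()) {
  if (is.character(cfg)) cfg <- yaml::read_yaml(cfg)
  cfg <- validate_config(cfg)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  warnings_seen <- character()
  note <- function(...) {
    msg <- sprintf(...)
    message("[gazepriority] ", msg)
  }
  manifest <- list(package_version = as.character(utils::packageVersion("gazepriority")),
                   r_version = R.version.string,
                   config = cfg[!vapply(cfg, is.null, logical(1))],
                   stages = list())

  capture_warnings <- function(expr) {
    withCallingHandlers(expr, warning = function(w) {
      warnings_seen <<- c(warnings_seen, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  }

  if (!is.null(cfg$simulate)) {
    note("stage simulate")
    sim <- cfg$simulate
    exp <- capture_warnings(do.call(weight_recovery_experiment, c(
      sim, list(seed = cfg$seed, nagq = cfg$nagq, random = cfg$random,
                match_fdm = cfg$match_fdm)
    )))
    readr::write_csv(exp$weight_table, file.path(cfg$out_dir, "weight_table.csv"))
    readr::write_csv(attr(exp$weight_table, "statistics"),
                     file.path(cfg$out_dir, "glmm_results.csv"))
    readr::write_csv(exp$instances, file.path(cfg$out_dir, "instances.csv"))
    manifest$stages$simulate <- list(
      n_images = exp$spec$n_images, n_subjects = exp$spec$n_subjects,
      n_fixations = exp$spec$n_fixations,
      true_weights = as.list(exp$spec$weights)
    )
  } else {
    if (is.null(cfg$detections) || is.null(cfg$fixations)) {
      abort("either 'simulate' or both 'detections' and 'fixations' must be set")
    }
    note("stage detections: %s", cfg$detections)
    det <- read_detections(cfg$detections)
    fix <- read_fixations(cfg$fixations)
    images <- unique(fix$image_id)
    manifest$stages$inputs <- list(n_images = length(images),
                                   n_proposals = length(unique(paste(det$image_id, det$box_id))),
                                   n_fixations = nrow(fix))

    note("stage maps: %d image(s), variants %s", length(images),
         paste(cfg$variants, collapse = ","))
    maps_tbl <- dplyr::bind_rows(lapply(images, function(id) {
      d <- dplyr::filter(det, .data$image_id == id)
      shape <- c(d$image_h[1], d$image_w[1])
      m <- capture_warnings(build_maps(d, cfg, shape))
      if (!is.null(cfg$maps_dir)) {
        # precomputed rasters (e.g. external saliency) override/extend
        for (p in list.files(cfg$maps_dir, pattern = paste0("^", id, "_.*\\.tsv$"),
                             full.names = TRUE)) {
          v <- sub("\\.tsv$", "", sub(paste0("^", id, "_"), "", basename(p)))
          m[[v]] <- load_saliency(p, shape)
        }
      }
      tibble(image_id = id, feature = names(m), map = unname(m))
    }))
    map_dir <- file.path(cfg$out_dir, "maps")
    dir.create(map_dir, showWarnings = FALSE)
    for (i in seq_len(nrow(maps_tbl))) {
      write_map(maps_tbl$map[[i]],
                file.path(map_dir, sprintf("%s_%s.tsv", maps_tbl$image_id[i],
                                           maps_tbl$feature[i])))
    }

    note("stage eval: NSS and GLMM over fixations 1..%d", cfg$max_fixation)
    shape <- dim(maps_tbl$map[[1]])
    fdms <- setNames(lapply(images, function(id) {
      capture_warnings(build_fdm(dplyr::filter(fix, .data$image_id == id),
                                 shape,
                                 sigma = cfg$fdm_sigma %||% (shape[1] / 24)))
    }), images)

    nss_tbl <- dplyr::bind_rows(lapply(seq_len(cfg$max_fixation), function(n) {
      sel <- select_fixation(fix, n)
      dplyr::bind_rows(lapply(cfg$variants, function(v) {
        scores <- vapply(images, function(id) {
          s <- dplyr::filter(sel, .data$image_id == id)
          if (nrow(s) == 0) return(NA_real_)
          m <- maps_tbl$map[[which(maps_tbl$image_id == id &
                                     maps_tbl$feature == v)]]
          capture_warnings(nss(m, s))
        }, numeric(1))
        tibble(fix_index = n, feature = v,
               nss = mean(scores, na.rm = TRUE),
               n_images = sum(!is.na(scores)))
      }))
    }))
    readr::write_csv(nss_tbl, file.path(cfg$out_dir, "nss.csv"))

    feat_patches <- capture_warnings(
      patch_feature_table(maps_tbl, fdms = if (cfg$match_fdm) fdms else NULL,
                          grid = cfg$grid)
    )
    results <- lapply(seq_len(cfg$max_fixation), function(n) {
      tab <- build_observation_table(maps_tbl, fix, n, grid = cfg$grid,
                                     feature_patches = feat_patches)
      capture_warnings(fit_glmm(tab, features = cfg$variants,
                                random = intersect(cfg$random, names(tab)),
                                mode = cfg$glmm_mode, nagq = cfg$nagq))
    })
    inst <- instance_proportions(fix, cfg$max_fixation)
    wt <- capture_warnings(weight_table(results, inst))
    readr::write_csv(wt, file.path(cfg$out_dir, "weight_table.csv"))
    readr::write_csv(attr(wt, "statistics"),
                     file.path(cfg$out_dir, "glmm_results.csv"))
    manifest$stages$eval <- list(
      n_models = length(results),
      converged = vapply(results, function(r) r$converged, logical(1))
    )
  }

  manifest$warnings <- unique(warnings_seen)
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(cfg$out_dir)
}
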