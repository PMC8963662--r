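#' Logistic mixed-model weighting of priority-map features
#'
#' Fits the patch-fixated/not responses of an observation table with a
#' logistic (logit-link) model in which all listed features enter jointly
#' as fixed effects -- each z-statistic then measures that map's unique
#' contribution -- and each grouping in `random` contributes a random
#' intercept (fitted with [lme4::glmer()]). With no random grouping an
#' ordinary logistic regression ([stats::glm()]) is used. A
#' `mode = "per_feature"` variant fits one single-feature model per map
#' instead.
#'
#' Identical feature columns are rejected as rank-deficient; complete
#' separation and non-convergence are surfaced as warnings and recorded on
#' the result, never silently ignored.
#'
#' @param table An observation table from [build_observation_table()].
#' @param features Character vector of feature column names; defaults to
#'   the table's recorded features.
#' @param random Character vector of grouping columns for random
#'   intercepts (e.g. `c("scene_type", "target_category")`); `NULL` for a
#'   plain logistic fit.
#' @param mode `"joint"` (default) or `"per_feature"`.
#' @param nagq `nAGQ` passed to [lme4::glmer()]; the default 0 uses the
#'   fast penalized-likelihood approximation, 1 the Laplace approximation.
#' @return A `glmm_result`: per-feature `estimate`, `std.error`,
#'   `statistic` (z), `p.value`, plus random-effect variances and
#'   convergence information. `tidy()` and `glance()` methods apply.
#' @export
fit_glmm <- function(table, features = attr(table, "features"),
                     random = NULL, mode = c("joint", "per_feature"),
                     nagq = 0) {
  mode <- match.arg(mode)
  if (is.null(features) || length(features) == 0) {
    abort("no feature columns given")
  }
  missing <- setdiff(c(features, random), names(table))
  if (length(missing) > 0) {
    abort(paste0("column(s) not in table: ", paste(missing, collapse = ", ")))
  }
  for (f in features) {
    if (diff(range(table[[f]])) == 0) {
      abort(sprintf("feature '%s' is constant", f))
    }
  }
  if (length(features) > 1) {
    for (i in seq_along(features)[-1]) {
      for (j in seq_len(i - 1)) {
        if (isTRUE(all.equal(table[[features[i]]], table[[features[j]]],
                             tolerance = 0))) {
          abort(sprintf("rank-deficient design: features '%s' and '%s' are identical",
                        features[j], features[i]))
        }
      }
    }
  }
  usable <- random[vapply(random, function(g) {
    length(unique(table[[g]])) >= 2
  }, logical(1))]
  if (length(random) > 0 && length(usable) < length(random)) {
    warn(paste0("dropping random grouping(s) with < 2 levels: ",
                paste(setdiff(random, usable), collapse = ", ")))
  }

  if (mode == "per_feature") {
    fits <- lapply(features, function(f) {
      fit_glmm_one(table, f, usable, nagq)
    })
  } else {
    fits <- list(fit_glmm_one(table, features, usable, nagq))
  }

  coefs <- dplyr::bind_rows(lapply(fits, `[[`, "coefs"))
  coefs <- dplyr::filter(coefs, .data$term %in% features)
  structure(list(
    coefficients = coefs,
    ranef_variance = do.call(c, lapply(fits, `[[`, "ranef_variance")),
    converged = all(vapply(fits, `[[`, logical(1), "converged")),
    separation = any(vapply(fits, `[[`, logical(1), "separation")),
    messages = unlist(lapply(fits, `[[`, "messages")),
    mode = mode,
    nobs = nrow(table),
    fixation_index = attr(table, "fixation_index"),
    fits = lapply(fits, `[[`, "fit")
  ), class = "glmm_result")
}

fit_glmm_one <- function(table, features, random, nagq) {
  rhs <- paste(sprintf("`%s`", features), collapse = " + ")
  msgs <- character()
  sep <- FALSE
  conv <- TRUE
  if (length(random) > 0) {
    form <- stats::as.formula(paste(
      "fixated ~", rhs, "+",
      paste(sprintf("(1 | `%s`)", random), collapse = " + ")
    ))
    fit <- withCallingHandlers(
      lme4::glmer(form, data = table, family = stats::binomial(),
                  nAGQ = nagq),
      warning = function(w) {
        msgs <<- c(msgs, conditionMessage(w))
        invokeRestart("muffleWarning")
      },
      message = function(m) {
        msgs <<- c(msgs, conditionMessage(m))
        invokeRestart("muffleMessage")
      }
    )
    conv <- length(fit@optinfo$conv$lme4) == 0
    sm <- summary(fit)$coefficients
    vc <- lme4::VarCorr(fit)
    rv <- vapply(vc, function(v) v[1, 1], numeric(1))
  } else {
    form <- stats::as.formula(paste("fixated ~", rhs))
    fit <- withCallingHandlers(
      stats::glm(form, data = table, family = stats::binomial()),
      warning = function(w) {
        msgs <<- c(msgs, conditionMessage(w))
        if (grepl("fitted probabilities numerically 0 or 1",
                  conditionMessage(w))) sep <<- TRUE
        invokeRestart("muffleWarning")
      }
    )
    conv <- fit$converged
    if (any(is.na(stats::coef(fit)))) {
      abort("rank-deficient design: aliased coefficients in the logistic fit")
    }
    sm <- summary(fit)$coefficients
    rv <- numeric(0)
  }
  if (!conv) warn(paste0("model did not converge: ",
                         paste(msgs, collapse = "; ")))
  if (sep) warn("possible complete separation in the logistic fit")
  coefs <- tibble(
    term = gsub("`", "", rownames(sm)),
    estimate = sm[, "Estimate"],
    std.error = sm[, "Std. Error"],
    statistic = sm[, "Estimate"] / sm[, "Std. Error"],
    p.value = 2 * pnorm(-abs(sm[, "Estimate"] / sm[, "Std. Error"]))
  )
  list(coefs = coefs, ranef_variance = rv, converged = conv,
       separation = sep, messages = msgs, fit = fit)
}

#' @export
print.glmm_result <- function(x, ...) {
  cat(sprintf("<glmm_result fixation %s, %s, n = %d%s>\n",
              x$fixation_index %||% "?", x$mode, x$nobs,
              if (x$converged) "" else ", NOT converged"))
  print(x$coefficients)
  invisible(x)
}

#' @describeIn fit_glmm Per-feature coefficient table
#'   (`term`, `estimate`, `std.error`, `statistic`, `p.value`).
#' @param x A `glmm_result`.
#' @param ... Unused.
#' @method tidy glmm_result
#' @export
tidy.glmm_result <- function(x, ...) x$coefficients

#' @describeIn fit_glmm One-row model summary: observations, convergence,
#'   separation flag, random-effect variances.
#' @method glance glmm_result
#' @export
glance.glmm_result <- function(x, ...) {
  tibble(
    nobs = x$nobs,
    fixation_index = x$fixation_index %||% NA_integer_,
    converged = x$converged,
    separation = x$separation,
    n_random = length(x$ranef_variance),
    max_ranef_variance = if (length(x$ranef_variance) > 0) {
      max(x$ranef_variance)
    } else {
      NA_real_
    }
  )
}

#' Normalized feature-weight table across fixation indices
#'
#' Converts per-fixation-index GLMM results into the weight table used to
#' compare priority maps: for each fixation row, negative z-statistics are
#' clamped to zero and the remainder normalized to sum to 1 (a row with no
#' positive z falls back to uniform weights with a warning); the instance
#' column is the per-index count of contributing trials, normalized to sum
#' to 1 over the column. Raw z-statistics and Bonferroni-adjusted p-values
#' (across features x fixation indices) are kept in the long companion
#' table `attr(, "statistics")`.
#'
#' @param results List of `glmm_result` objects, one per fixation index.
#' @param instances Numeric vector of contributing-trial counts, same
#'   length, or the tibble from [instance_proportions()].
#' @return A `weight_table` tibble: `fix_index`, one weight column per
#'   feature, `instances`.
#' @export
weight_table <- function(results, instances) {
  stopifnot(length(results) > 0)
  if (is.data.frame(instances)) instances <- instances$n_instances
  if (length(instances) != length(results)) {
    abort("one instance count per fixation index is required")
  }
  long <- purrr::imap(results, function(r, i) {
    dplyr::mutate(tidy(r),
                  fix_index = r$fixation_index %||% i)
  }) |> dplyr::bind_rows()
  long$p.bonferroni <- pmin(1, long$p.value * nrow(long))

  wide <- long |>
    dplyr::select("fix_index", "term", "statistic") |>
    tidyr::pivot_wider(names_from = "term", values_from = "statistic")
  feats <- setdiff(names(wide), "fix_index")
  zmat <- as.matrix(wide[feats])
  wmat <- pmax(zmat, 0)
  rs <- rowSums(wmat)
  if (any(rs == 0)) {
    warn("row(s) with no positive z-statistic: falling back to uniform weights")
    wmat[rs == 0, ] <- 1
    rs[rs == 0] <- length(feats)
  }
  wmat <- wmat / rs
  out <- dplyr::bind_cols(
    wide["fix_index"],
    as_tibble(wmat),
    tibble(instances = if (sum(instances) > 0) {
      instances / sum(instances)
    } else {
      rep(0, length(instances))
    })
  )
  attr(out, "statistics") <- long
  attr(out, "features") <- feats
  class(out) <- c("weight_table", class(out))
  out
}

#' @export
print.weight_table <- function(x, ...) {
  NextMethod()
  invisible(x)
}
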