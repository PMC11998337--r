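#' Construct a call set
#'
#' A call set records which plants a screening stage flagged as candidate
#' mutants, at which confidence level, with optional per-panel detail and the
#' parent call sets a combined set was built from.
#'
#' @param method one of `"scatter"`, `"growth"`, `"combined"`, `"manual"`.
#' @param level confidence level used (`NA` for manual calls).
#' @param flagged character vector of flagged plant ids.
#' @param population character vector of all plant ids screened.
#' @param per_panel optional named list mapping panel `"i:j"` to flagged ids.
#' @param parents optional list of parent call sets (for combined calls).
#' @param fit_failures optional ids flagged separately because their model
#'   fit failed (reported, never silently merged into `flagged`).
#' @return object of class `call_set`.
#' @export
call_set <- function(method, level, flagged, population,
                     per_panel = NULL, parents = NULL, fit_failures = NULL) {
  method <- match.arg(method, c("scatter", "growth", "combined", "manual"))
  flagged <- unique(as.character(flagged))
  population <- as.character(population)
  if (!all(flagged %in% population)) {
    stopf("flagged ids outside the population: %s",
          paste(setdiff(flagged, population), collapse = ", "))
  }
  structure(
    list(method = method, level = level, flagged = flagged,
         population = population, per_panel = per_panel,
         parents = parents, fit_failures = fit_failures),
    class = "call_set"
  )
}

#' @export
print.call_set <- function(x, ...) {
  lev <- if (is.na(x$level %||% NA)) "manual" else sprintf("%.4g", x$level)
  cat(sprintf("Call set [%s, level %s]: %d of %d plants flagged\n",
              x$method, lev, length(x$flagged), length(x$population)))
  if (length(x$fit_failures)) {
    cat(sprintf("  + %d fit-failure candidate(s): %s\n",
                length(x$fit_failures), paste(x$fit_failures, collapse = ", ")))
  }
  invisible(x)
}

#' Fit a bivariate confidence ellipse to one scatter panel
#'
#' Classical Mahalanobis ellipse: sample mean and covariance of the two
#' coordinates, with the boundary at the chi-square (2 df) quantile of the
#' requested confidence level.  Under a bivariate normal model the squared
#' Mahalanobis distance is chi-square(2), so a fraction `level` of null points
#' falls inside.
#'
#' @param points n x 2 numeric matrix (n >= 3).
#' @param level confidence level in (0, 1).
#' @param pair optional identifier (e.g. `c("FAC_1","FAC_2")`) used in error
#'   messages and panel labels.
#' @return object of class `ellipse_model`: list with `center`, `covariance`,
#'   `level`, `threshold` (the chi-square quantile) and `pair`.
#' @export
fit_pair_ellipse <- function(points, level = 0.95, pair = NULL) {
  points <- as.matrix(points)
  if (ncol(points) != 2) stopf("ellipse fitting needs an n x 2 matrix")
  if (nrow(points) < 3) stopf("ellipse fitting needs at least 3 points")
  if (level <= 0 || level >= 1) stopf("level must be in (0, 1)")
  ctr <- colMeans(points)
  cov2 <- stats::cov(points)
  ev <- eigen(cov2, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= max(ev) * 1e-12 || min(ev) <= 0) {
    stopf("degenerate geometry in panel %s: singular covariance (collinear or constant points)",
          if (is.null(pair)) "(unnamed)" else paste(pair, collapse = " vs "))
  }
  structure(
    list(center = ctr, covariance = cov2, level = level,
         threshold = stats::qchisq(level, df = 2), pair = pair),
    class = "ellipse_model"
  )
}

#' Squared Mahalanobis distances to an ellipse center
#'
#' @param model an [fit_pair_ellipse()] result.
#' @param points n x 2 matrix.
#' @return numeric vector of squared Mahalanobis distances.
#' @export
ellipse_distance2 <- function(model, points) {
  stopifnot(inherits(model, "ellipse_model"))
  stats::mahalanobis(as.matrix(points), model$center, model$covariance)
}

#' Which points fall outside a confidence ellipse?
#'
#' @inheritParams ellipse_distance2
#' @return logical vector, `TRUE` for points outside the ellipse.
#' @export
ellipse_outside <- function(model, points) {
  ellipse_distance2(model, points) > model$threshold
}

#' Boundary polygon of a confidence ellipse (for plotting)
#'
#' @param model an [fit_pair_ellipse()] result.
#' @param n number of boundary points.
#' @return n x 2 matrix tracing the ellipse boundary.
#' @export
ellipse_boundary <- function(model, n = 181) {
  stopifnot(inherits(model, "ellipse_model"))
  eg <- eigen(model$covariance, symmetric = TRUE)
  theta <- seq(0, 2 * pi, length.out = n)
  circ <- cbind(cos(theta), sin(theta)) %*%
    diag(sqrt(model$threshold * eg$values)) %*% t(eg$vectors)
  sweep(circ, 2, model$center, `+`)
}

#' Scatter-matrix confidence-ellipse screening
#'
#' Screens every unordered pair of factor scores (or any multivariate score
#' matrix): for each pair a confidence ellipse is fitted at the requested
#' level and points outside it are flagged; a plant is called a candidate
#' mutant if it is flagged in at least `min_panels` panels (default 1, i.e.
#' outside any single ellipse).  With a single score column the "panel"
#' degenerates to a two-sided normal-quantile interval at the same level.
#'
#' Because the overall call is a union over k(k-1)/2 panels, the population
#' flag rate at a given level exceeds the single-panel rate `1 - level`; this
#' union inflation is why low confidence levels produce high false positive
#' rates in practice.
#'
#' @param scores a `factor_scores` object or a numeric matrix (plants x
#'   dimensions, rownames = plant ids).
#' @param levels numeric vector of confidence levels.
#' @param min_panels minimum number of panels a plant must be outside to be
#'   flagged overall.
#' @param method label stored in the returned call sets.
#' @return a named list of [call_set()]s, one per level (names are the
#'   levels); each retains the per-panel flag detail.
#' @export
screen_scatter_matrix <- function(scores, levels = default_levels(),
                                  min_panels = 1, method = "scatter") {
  x <- if (inherits(scores, "factor_scores")) scores$scores else as.matrix(scores)
  if (length(levels) == 0) stopf("empty level list")
  ids <- rownames(x) %||% sprintf("P%03d", seq_len(nrow(x)))
  rownames(x) <- ids
  k <- ncol(x)

  out <- lapply(levels, function(level) {
    per_panel <- list()
    hits <- integer(length(ids))
    if (k == 1) {
      zc <- (x[, 1] - mean(x[, 1])) / stats::sd(x[, 1])
      outside <- abs(zc) > stats::qnorm((1 + level) / 2)
      per_panel[["1"]] <- ids[outside]
      hits <- hits + outside
    } else {
      for (i in seq_len(k - 1)) {
        for (j in seq((i + 1), k)) {
          pair <- colnames(x)[c(i, j)] %||% c(i, j)
          mod <- fit_pair_ellipse(x[, c(i, j)], level = level, pair = pair)
          outside <- ellipse_outside(mod, x[, c(i, j)])
          per_panel[[paste(pair, collapse = ":")]] <- ids[outside]
          hits <- hits + outside
        }
      }
    }
    call_set(method = method, level = level,
             flagged = ids[hits >= min_panels], population = ids,
             per_panel = per_panel)
  })
  names(out) <- as.character(levels)
  out
}

#' Default confidence-level sweep
#'
#' The default sweep covers 75, 80, 85, 90, 95, 99 and 99.9 per cent; an
#' alternate, sparser preset (95, 97, 99, 99.5, 99.9) is available via
#' `preset = "strict"`.  The two presets reflect the two level lists in
#' common use for this screen; which one applies is a study choice.
#'
#' @param preset `"sweep"` (default) or `"strict"`.
#' @return numeric vector of confidence levels in (0, 1).
#' @export
default_levels <- function(preset = c("sweep", "strict")) {
  preset <- match.arg(preset)
  switch(preset,
         sweep = c(0.75, 0.80, 0.85, 0.90, 0.95, 0.99, 0.999),
         strict = c(0.95, 0.97, 0.99, 0.995, 0.999))
}
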