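#' Logistic growth curve
#'
#' Evaluates `area(t) = h / (1 + x1 * exp(-x2 * t))`: `h` is the asymptotic
#' (maximum) leaf area in mm^2, `x1` a positive shape/offset parameter
#' (area at t = 0 is `h / (1 + x1)`), `x2` the relative growth rate per day.
#' The curve is monotone increasing with its inflection (area = h/2) at
#' `t = log(x1) / x2`.
#'
#' @param t time in days.
#' @param h,x1,x2 curve parameters.
#' @return leaf area, mm^2.
#' @export
lgc_area <- function(t, h, x1, x2) h / (1 + x1 * exp(-x2 * t))

# optimizer bounds; h bound is relative to the observed maximum
.lgc_bounds <- function(max_area) {
  list(lower = c(h = 1e-8, x1 = 1e-6, x2 = 1e-4),
       upper = c(h = 10 * max_area, x1 = 1e6, x2 = 5))
}

#' Fit the logistic growth curve to one plant's leaf-area series
#'
#' Bounded nonlinear least squares (Levenberg-Marquardt) of
#' `area(t) = h / (1 + x1 * exp(-x2 t))` over the full series, with
#' data-driven initialization (`h` from the maximum area, `x2` and `x1`
#' from a log-linear regression of the logit-transformed areas) and 5
#' jittered multi-starts on a fixed RNG stream.  After the curve fit, the
#' correction offsets `k` and `s` are the model-minus-observed residuals at
#' two anchor times: `p1` (the observed day closest to the median day,
#' by default) and `p2` (the final observed day).  They measure how far the
#' plant's realized growth at mid-series and at the end deviates from its
#' own fitted curve.
#'
#' Ill-conditioned data never raise from the optimizer: a series with no
#' growth signal returns `converged = FALSE` with the `degenerate` flag set.
#'
#' @param series data frame with columns `day` and `leaf_area` for a single
#'   plant (a `plant_id` column, if present, must be constant).
#' @param p1,p2 anchor times (days); defaults are the median and last
#'   observed day.
#' @param n_starts number of multi-start attempts.
#' @return object of class `lgc_fit`: list with `plant_id`, `h`, `x1`, `x2`,
#'   `k`, `s`, `p1`, `p2`, `rss`, `converged`, `degenerate`, `n_points`,
#'   `message`.
#' @export
fit_lgc <- function(series, p1 = NULL, p2 = NULL, n_starts = 5) {
  if (!all(c("day", "leaf_area") %in% names(series))) {
    stopf("series needs columns 'day' and 'leaf_area'")
  }
  pid <- if ("plant_id" %in% names(series)) {
    u <- unique(series$plant_id)
    if (length(u) > 1) stopf("fit_lgc() fits one plant at a time; got %d ids", length(u))
    u
  } else NA_character_
  ord <- order(series$day)
  day <- as.numeric(series$day[ord])
  area <- as.numeric(series$leaf_area[ord])
  if (anyDuplicated(day)) stopf("duplicate days in series for plant %s", pid)
  n <- length(day)
  if (n < 4) stopf("ineligible series (plant %s): %d < 4 time points", pid, n)
  if (all(area == 0)) stopf("ineligible series (plant %s): all areas zero", pid)

  base <- list(plant_id = pid, h = NA_real_, x1 = NA_real_, x2 = NA_real_,
               k = NA_real_, s = NA_real_, p1 = NA_real_, p2 = NA_real_,
               rss = NA_real_, converged = FALSE, degenerate = FALSE,
               n_points = n, message = "")
  if (stats::sd(area) == 0) {
    base$degenerate <- TRUE
    base$message <- "constant series: no growth signal"
    class(base) <- "lgc_fit"
    return(base)
  }

  b <- .lgc_bounds(max(area))
  h0 <- 1.05 * max(area)
  a0 <- max(area[1], 1e-8)
  x10 <- min(max(h0 / a0 - 1, b$lower["x1"] * 2), b$upper["x1"] / 2)
  # log-linear estimate: log(h0/a - 1) = log(x1) - x2 * t
  ok <- area > 0 & area < h0 * 0.999
  x20 <- 0.3
  if (sum(ok) >= 2) {
    y <- log(h0 / area[ok] - 1)
    sl <- stats::coef(stats::lm(y ~ day[ok]))
    if (is.finite(sl[2]) && sl[2] < 0) x20 <- min(max(-sl[2], 0.01), 4)
    if (is.finite(sl[1])) x10 <- min(max(exp(sl[1]), b$lower["x1"] * 2),
                                     b$upper["x1"] / 2)
  }
  start0 <- c(h = h0, x1 = x10, x2 = x20)

  jitters <- with_seed(20201L, {
    cbind(1, matrix(exp(stats::rnorm(3 * max(n_starts - 1, 0), sd = 0.4)),
                    nrow = 3))
  })
  best <- NULL
  msg <- character(0)
  dat <- data.frame(day = day, area = area)
  for (j in seq_len(n_starts)) {
    st <- pmin(pmax(start0 * jitters[, j], b$lower * 1.000001), b$upper * 0.999999)
    fit <- tryCatch(
      minpack.lm::nlsLM(
        area ~ h / (1 + x1 * exp(-x2 * day)),
        data = dat, start = as.list(st),
        lower = b$lower, upper = b$upper,
        control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-15,
                                             ptol = 1e-15)
      ),
      error = function(e) e
    )
    if (inherits(fit, "error")) {
      msg <- c(msg, conditionMessage(fit))
      next
    }
    rss <- sum(stats::resid(fit)^2)
    if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
  }
  if (is.null(best)) {
    base$message <- paste(unique(msg), collapse = "; ")
    class(base) <- "lgc_fit"
    return(base)
  }

  cf <- stats::coef(best$fit)
  p1 <- p1 %||% day[which.min(abs(day - stats::median(day)))]
  p2 <- p2 %||% day[n]
  obs_at <- function(p) {
    i <- which.min(abs(day - p))
    area[i]
  }
  pred <- function(t) lgc_area(t, cf["h"], cf["x1"], cf["x2"])
  out <- base
  out$h <- unname(cf["h"]); out$x1 <- unname(cf["x1"]); out$x2 <- unname(cf["x2"])
  out$p1 <- p1; out$p2 <- p2
  out$k <- unname(pred(p1) - obs_at(p1))
  out$s <- unname(pred(p2) - obs_at(p2))
  out$rss <- best$rss
  out$converged <- TRUE
  class(out) <- "lgc_fit"
  out
}

#' @export
print.lgc_fit <- function(x, ...) {
  if (x$converged) {
    cat(sprintf("LGC fit%s: h = %.4g mm^2, x1 = %.4g, x2 = %.4g /day (RSS %.4g, %d points)\n",
                if (is.na(x$plant_id)) "" else paste0(" [", x$plant_id, "]"),
                x$h, x$x1, x$x2, x$rss, x$n_points))
    cat(sprintf("  anchors: k = %.4g at day %g, s = %.4g at day %g\n",
                x$k, x$p1, x$s, x$p2))
  } else {
    cat(sprintf("LGC fit%s: NOT converged (%s)\n",
                if (is.na(x$plant_id)) "" else paste0(" [", x$plant_id, "]"),
                if (x$degenerate) "degenerate series" else x$message))
  }
  invisible(x)
}

#' Predict leaf area from a fitted logistic growth curve
#'
#' @param fit a converged [fit_lgc()] result.
#' @param t days.
#' @return predicted leaf area, mm^2.
#' @export
lgc_predict <- function(fit, t) {
  stopifnot(inherits(fit, "lgc_fit"))
  if (!fit$converged) stopf("cannot predict from an unconverged fit")
  lgc_area(t, fit$h, fit$x1, fit$x2)
}

#' Fit logistic growth curves for a whole population
#'
#' Splits a long leaf-area table by plant and fits each series with
#' [fit_lgc()].  Plants with fewer than 4 time points or all-zero areas are
#' ineligible and skipped with a warning; fit failures are kept as
#' unconverged rows so downstream screening can report them.
#'
#' @param series long data frame (`plant_id`, `day`, `leaf_area`), e.g. from
#'   [generate_growth_series()].
#' @param ... passed to [fit_lgc()].
#' @return data frame of class `lgc_fits`, one row per fitted plant with
#'   columns `plant_id, h, x1, x2, k, s, p1, p2, rss, converged, degenerate,
#'   n_points`.
#' @export
fit_lgc_population <- function(series, ...) {
  stopifnot(all(c("plant_id", "day", "leaf_area") %in% names(series)))
  rows <- lapply(split(series, series$plant_id), function(d) {
    f <- tryCatch(fit_lgc(d, ...), error = function(e) e)
    if (inherits(f, "error")) {
      warnf("skipping plant %s: %s", d$plant_id[1], conditionMessage(f))
      return(NULL)
    }
    data.frame(plant_id = f$plant_id, h = f$h, x1 = f$x1, x2 = f$x2,
               k = f$k, s = f$s, p1 = f$p1, p2 = f$p2, rss = f$rss,
               converged = f$converged, degenerate = f$degenerate,
               n_points = f$n_points, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  # preserve input plant order (split() sorts by id; ids are zero-padded so
  # this is usually already the input order)
  out <- out[order(match(out$plant_id, unique(series$plant_id))), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("lgc_fits", "data.frame")
  out
}

#' Screen fitted growth parameters for outlier plants
#'
#' Standardizes the fitted `(h, k, s, x1, x2)` columns across converged
#' plants and applies the pairwise confidence-ellipse screen to every
#' parameter pair: a plant outside the ellipse in at least one panel is a
#' candidate mutant by growth dynamics.  Plants whose fits did not converge
#' cannot be placed in parameter space; they are reported separately as
#' fit-failure candidates on the returned call set, never silently merged.
#'
#' @param fits an `lgc_fits` data frame from [fit_lgc_population()].
#' @param level confidence level.
#' @param min_panels minimum number of panels outside to flag overall.
#' @return a [call_set()] with `method = "growth"`.
#' @export
screen_growth_params <- function(fits, level = 0.95, min_panels = 1) {
  stopifnot(is.data.frame(fits))
  conv <- fits[fits$converged, , drop = FALSE]
  if (nrow(conv) < 10) {
    stopf("insufficient data: %d converged fits (need >= 10)", nrow(conv))
  }
  pars <- as.matrix(conv[, c("h", "k", "s", "x1", "x2")])
  rownames(pars) <- conv$plant_id
  # center always; scale only non-constant columns so that a zero-variance
  # parameter surfaces as a degenerate-geometry error in the ellipse stage
  sds <- apply(pars, 2, stats::sd)
  zs <- sweep(pars, 2, colMeans(pars), `-`)
  zs <- sweep(zs, 2, ifelse(sds > 0, sds, 1), `/`)
  cs <- screen_scatter_matrix(zs, levels = level, min_panels = min_panels,
                              method = "growth")[[1]]
  cs$population <- as.character(fits$plant_id)
  cs$fit_failures <- as.character(fits$plant_id[!fits$converged])
  cs
}
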