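#' Standardize a phenotype table to z-scores
#'
#' Centers and scales every numeric trait column to mean 0, SD 1 (sample SD,
#' n - 1 denominator), the prerequisite for correlation-scale principal
#' components when traits mix units (areas in mm^2, lengths in mm, unitless
#' indices).  Zero-variance columns carry no screening information and are
#' dropped with a warning; their names are recorded in attribute
#' `"dropped"`.
#'
#' @param table a phenotype data frame (metadata columns `plant_id`, `plate`,
#'   `well`, `line_id` are ignored if present) or a numeric matrix.
#' @return numeric matrix of z-scores, rows named by `plant_id` when
#'   available; attributes `"center"`, `"scale"`, `"dropped"`.
#' @export
standardize_traits <- function(table) {
  if (is.data.frame(table)) {
    meta <- intersect(c("plant_id", "plate", "well", "line_id"), names(table))
    ids <- if ("plant_id" %in% meta) table$plant_id else rownames(table)
    x <- as.matrix(table[setdiff(names(table), meta)])
    if (!is.numeric(x)) stopf("non-numeric trait columns present")
    rownames(x) <- ids
  } else {
    x <- as.matrix(table)
  }
  if (nrow(x) < 3) stopf("standardization needs at least 3 plants")
  if (ncol(x) < 2) stopf("standardization needs at least 2 traits")
  if (anyNA(x)) stopf("missing trait values; clean the table first")

  sds <- apply(x, 2, stats::sd)
  drop <- names(which(sds == 0))
  if (length(drop)) {
    warnf("dropping %d zero-variance trait column(s): %s",
          length(drop), paste(drop, collapse = ", "))
    x <- x[, sds > 0, drop = FALSE]
    sds <- sds[sds > 0]
  }
  if (ncol(x) < 2) stopf("fewer than 2 non-constant trait columns remain")
  ctr <- colMeans(x)
  z <- scale(x, center = ctr, scale = sds)
  attr(z, "scaled:center") <- NULL
  attr(z, "scaled:scale") <- NULL
  structure(z, center = ctr, scale = sds, dropped = drop)
}

#' Principal-component factor scores of a standardized trait matrix
#'
#' Eigendecomposes the sample correlation matrix of the standardized traits
#' and retains components whose eigenvalue exceeds `retention_threshold`
#' (Kaiser-style rule, default 1).  Scores are the projections rescaled to
#' unit sample variance per component — the "factor scores" used as screening
#' variables downstream.  A deterministic sign convention (the
#' largest-magnitude loading of each component is positive) makes scores
#' reproducible across trait orderings.
#'
#' @param z standardized matrix from [standardize_traits()].
#' @param retention_threshold eigenvalue cutoff for retention; if no
#'   eigenvalue exceeds it the first component is retained with a warning.
#' @param rotate reserved flag for factor rotation; only `"none"` is
#'   implemented (no rotation method is assumed by the screening procedure).
#' @return object of class `factor_scores`: list with `scores` (n x k matrix,
#'   columns `FAC_1..FAC_k`), `eigenvalues` (all, non-increasing),
#'   `loadings` (trait x component correlations, retained components),
#'   `variance_explained` (cumulative proportion over retained components),
#'   `k`, `retention_threshold`.
#' @export
compute_factors <- function(z, retention_threshold = 1.0, rotate = c("none")) {
  rotate <- match.arg(rotate)
  z <- as.matrix(z)
  if (anyNA(z)) stopf("NaN/NA in standardized input")
  n <- nrow(z)
  m <- ncol(z)
  cmat <- stats::cor(z)
  eig <- eigen(cmat, symmetric = TRUE)
  values <- eig$values
  k <- sum(values > retention_threshold)
  if (k < 1) {
    warnf("no eigenvalue exceeds %.3g; retaining the first component",
          retention_threshold)
    k <- 1L
  }
  vec <- eig$vectors[, seq_len(k), drop = FALSE]
  # sign convention: largest-magnitude loading positive
  for (j in seq_len(k)) {
    i <- which.max(abs(vec[, j]))
    if (vec[i, j] < 0) vec[, j] <- -vec[, j]
  }
  scores <- z %*% vec
  # projections have sample variance = eigenvalue; rescale to unit variance
  scores <- sweep(scores, 2, sqrt(values[seq_len(k)]), `/`)
  colnames(scores) <- sprintf("FAC_%d", seq_len(k))
  rownames(scores) <- rownames(z)
  loadings <- sweep(vec, 2, sqrt(values[seq_len(k)]), `*`)
  dimnames(loadings) <- list(colnames(z), colnames(scores))
  structure(
    list(scores = scores,
         eigenvalues = values,
         loadings = loadings,
         variance_explained = cumsum(values[seq_len(k)]) / m,
         k = k,
         retention_threshold = retention_threshold),
    class = "factor_scores"
  )
}

#' @export
print.factor_scores <- function(x, ...) {
  cat(sprintf("Factor scores: %d plants, %d retained components (eigenvalue > %.3g)\n",
              nrow(x$scores), x$k, x$retention_threshold))
  cat(sprintf("  cumulative variance explained: %.1f%%\n",
              100 * x$variance_explained[x$k]))
  invisible(x)
}

#' Ward/Euclidean hierarchical clustering of plants
#'
#' Agglomerative clustering of the standardized phenotype matrix with Ward's
#' minimum-variance criterion on Euclidean distances (the `ward.D2` linkage,
#' which operates on unsquared distances), plus a flat cut at a requested
#' cluster count.  This is the dendrogram-and-heatmap view of the population;
#' outlier calling itself is done in factor-score space.
#'
#' @param z standardized matrix from [standardize_traits()]; rownames are
#'   plant ids and must be unique.
#' @param k_clusters number of flat clusters to cut (default 2).
#' @return object of class `phenotype_clustering`: list with `hclust` (the
#'   [stats::hclust] tree), `labels` (named integer cluster memberships) and
#'   `k_clusters`.
#' @export
cluster_phenotypes <- function(z, k_clusters = 2) {
  z <- as.matrix(z)
  if (nrow(z) < 2) stopf("clustering needs at least 2 plants")
  ids <- rownames(z)
  if (!is.null(ids) && anyDuplicated(ids)) {
    stopf("duplicate plant ids: %s",
          paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  hc <- stats::hclust(stats::dist(z, method = "euclidean"), method = "ward.D2")
  labels <- stats::cutree(hc, k = min(k_clusters, nrow(z)))
  structure(list(hclust = hc, labels = labels, k_clusters = k_clusters),
            class = "phenotype_clustering")
}

#' @export
print.phenotype_clustering <- function(x, ...) {
  cat(sprintf("Ward/Euclidean clustering of %d plants, cut into %d clusters\n",
              length(x$labels), length(unique(x$labels))))
  print(table(cluster = x$labels))
  invisible(x)
}
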