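# Independent small-n oracle for Ward linkage on Euclidean distances:
# Lance-Williams recurrence on squared distances, heights reported on the
# distance scale (the ward.D2 convention).  Deliberately brute force and
# independent of stats::hclust.
lw_ward_heights <- function(points) {
  n <- nrow(points)
  d2 <- as.matrix(stats::dist(points))^2
  size <- rep(1, n)
  active <- seq_len(n)
  heights <- numeric(n - 1)
  for (step in seq_len(n - 1)) {
    best <- c(NA, NA)
    bestv <- Inf
    for (a in seq_along(active)) {
      for (b in seq_along(active)) {
        if (b <= a) next
        v <- d2[active[a], active[b]]
        if (v < bestv) {
          bestv <- v
          best <- c(active[a], active[b])
        }
      }
    }
    i <- best[1]; j <- best[2]
    heights[step] <- sqrt(bestv)
    ni <- size[i]; nj <- size[j]
    for (k in active) {
      if (k == i || k == j) next
      nk <- size[k]
      d2new <- ((ni + nk) * d2[i, k] + (nj + nk) * d2[j, k] - nk * d2[i, j]) /
        (ni + nj + nk)
      d2[i, k] <- d2[k, i] <- d2new
    }
    size[i] <- ni + nj
    active <- setdiff(active, j)
  }
  heights
}

# n x 2 matrix with exact sample mean (0,0) and exact identity sample
# covariance: the unit cross scaled so var = 1 with the n-1 denominator.
exact_identity_points <- function() {
  a <- sqrt(3 / 2)
  rbind(c(a, 0), c(-a, 0), c(0, a), c(0, -a))
}

# Two columns with an exact given sample correlation, built from
# orthonormalized standard-normal draws.
exact_corr_pair <- function(n, r, seed = 1) {
  set.seed(seed)
  z1 <- scale(rnorm(n))[, 1]
  z2 <- rnorm(n)
  z2 <- z2 - mean(z2)
  z2 <- z2 - z1 * sum(z1 * z2) / sum(z1^2)
  z2 <- z2 / stats::sd(z2)
  cbind(t1 = z1, t2 = r * z1 + sqrt(1 - r^2) * z2)
}

# A minimal truth table for hand-built call sets.
toy_truth <- function(n, mutant_ids) {
  ids <- sprintf("P%03d", seq_len(n))
  data.frame(plant_id = ids, is_mutant = ids %in% mutant_ids,
             line_id = ifelse(ids %in% mutant_ids, "M01", "WT"),
             stringsAsFactors = FALSE)
}
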