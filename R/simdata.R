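#' Configuration for a synthetic screening population
#'
#' Bundles every knob of the synthetic-population generator: population and
#' mutant counts, the latent-factor trait model, the size of mutant effects on
#' static traits and on growth dynamics, the measurement-noise level, and the
#' imaging schedule.  Defaults emulate a single screening trial of a mutant
#' population grown in six-well plates: 102 plants of which 8 are mutants
#' drawn from 6 distinct lines (so some lines occupy several positions),
#' 45 morphometric traits generated from 8 latent factors, and rosette-area
#' measurements every other day from transplant to day 28.
#'
#' @param n_plants total number of plants in the population.
#' @param n_mutant_plants number of mutant individuals (a line may be planted
#'   at several positions, so this can exceed `n_mutant_lines`).
#' @param n_mutant_lines number of distinct mutant lines.
#' @param n_traits number of static phenotype traits.
#' @param n_latent_factors number of latent factors generating the trait
#'   correlation structure; with the default block loadings, eigenvalue-above-1
#'   retention on a clean population recovers exactly this many components.
#' @param trait_effect_size per-affected-trait mutant shift, in within-trait
#'   standard-deviation units.
#' @param n_affected_traits number of traits shifted per mutant line.
#' @param growth_effect multiplicative perturbation applied to a mutant
#'   line's growth parameters `h` (asymptotic area) and `x2` (growth rate).
#' @param noise_cv coefficient of variation of the multiplicative area
#'   measurement noise.
#' @param days integer vector of measurement days (strictly increasing).
#' @param plate_layout wells per plate.
#' @param seed integer seed; every random draw in the generators flows from it.
#'
#' @return an object of class `screening_config` (a validated list).
#' @examples
#' cfg <- screening_config(n_plants = 30, n_mutant_plants = 3, n_mutant_lines = 2)
#' pop <- generate_population(cfg)
#' table(pop$truth$is_mutant)
#' @export
screening_config <- function(n_plants = 102,
                             n_mutant_plants = 8,
                             n_mutant_lines = 6,
                             n_traits = 45,
                             n_latent_factors = 8,
                             trait_effect_size = 4,
                             n_affected_traits = 3,
                             growth_effect = 2,
                             noise_cv = 0.02,
                             days = seq(0L, 28L, by = 2L),
                             plate_layout = 6,
                             seed = 1L) {
  cfg <- list(
    n_plants = as.integer(n_plants),
    n_mutant_plants = as.integer(n_mutant_plants),
    n_mutant_lines = as.integer(n_mutant_lines),
    n_traits = as.integer(n_traits),
    n_latent_factors = as.integer(n_latent_factors),
    trait_effect_size = as.numeric(trait_effect_size),
    n_affected_traits = as.integer(n_affected_traits),
    growth_effect = as.numeric(growth_effect),
    noise_cv = as.numeric(noise_cv),
    days = as.numeric(days),
    plate_layout = as.integer(plate_layout),
    seed = as.integer(seed)
  )
  counts <- c("n_plants", "n_mutant_plants", "n_mutant_lines", "n_traits",
              "n_latent_factors", "n_affected_traits", "plate_layout")
  for (f in counts) {
    if (is.na(cfg[[f]]) || cfg[[f]] < 0) {
      stopf("configuration error: '%s' must be a non-negative count", f)
    }
  }
  if (cfg$n_mutant_plants > cfg$n_plants) {
    stopf("configuration error: n_mutant_plants (%d) exceeds n_plants (%d)",
          cfg$n_mutant_plants, cfg$n_plants)
  }
  if (cfg$n_mutant_lines > cfg$n_mutant_plants) {
    stopf("configuration error: n_mutant_lines (%d) exceeds n_mutant_plants (%d)",
          cfg$n_mutant_lines, cfg$n_mutant_plants)
  }
  if (cfg$n_mutant_plants > 0 && cfg$n_mutant_lines == 0) {
    stopf("configuration error: mutant plants require n_mutant_lines >= 1")
  }
  if (length(cfg$days) == 0) {
    stopf("configuration error: 'days' is empty")
  }
  if (any(diff(cfg$days) <= 0)) {
    stopf("configuration error: 'days' must be strictly increasing")
  }
  if (cfg$noise_cv < 0) stopf("configuration error: noise_cv must be >= 0")
  if (cfg$n_affected_traits > cfg$n_traits) {
    stopf("configuration error: n_affected_traits exceeds n_traits")
  }
  class(cfg) <- "screening_config"
  cfg
}

#' @export
print.screening_config <- function(x, ...) {
  cat("Screening population configuration\n")
  cat(sprintf("  plants: %d (%d mutants in %d lines)\n",
              x$n_plants, x$n_mutant_plants, x$n_mutant_lines))
  cat(sprintf("  traits: %d from %d latent factors; effect %.1f SD on %d traits\n",
              x$n_traits, x$n_latent_factors, x$trait_effect_size,
              x$n_affected_traits))
  cat(sprintf("  growth: x%.2f on (h, x2); noise CV %.3f; days %g..%g (%d points)\n",
              x$growth_effect, x$noise_cv, min(x$days), max(x$days),
              length(x$days)))
  cat(sprintf("  seed: %d\n", x$seed))
  invisible(x)
}

# Fixed catalog of synthetic trait scales.  Traits are generic morphometric
# stand-ins (areas in mm^2, lengths in mm, unitless indices); the catalog is
# deterministic so the same config always describes the same measurement
# scales.  Blocks assign each trait to one latent factor, round-robin.
trait_catalog <- function(n_traits, n_latent_factors) {
  idx <- seq_len(n_traits)
  block <- ((idx - 1L) %% n_latent_factors) + 1L
  kind <- rep(c("area", "length", "index"), length.out = n_latent_factors)[block]
  mean <- ifelse(kind == "area", 600 + 35 * idx,
                 ifelse(kind == "length", 18 + 0.8 * idx, 0.55))
  sd <- ifelse(kind == "index", 0.07, 0.12 * mean)
  data.frame(
    trait = sprintf("trait_%02d", idx),
    block = block,
    kind = kind,
    unit = c(area = "mm2", length = "mm", index = "unitless")[kind],
    mean = mean,
    sd = sd,
    stringsAsFactors = FALSE
  )
}

# Loading of each trait on its block factor.  0.97 gives within-block trait
# correlations of ~0.94, so a block of m traits has leading eigenvalue
# 1 + (m - 1) * 0.94 and minor eigenvalues ~0.06: eigenvalue-above-1
# retention recovers exactly one component per latent factor, and the
# retained components carry > 90% of the total variance.
.trait_loading <- 0.97

#' Generate a synthetic screening population
#'
#' Draws a wild-type baseline population from a block-correlated Gaussian
#' trait model (each trait loads on one of `n_latent_factors` latent factors)
#' and superimposes line-specific mutant effects: each mutant line shifts
#' `n_affected_traits` randomly chosen traits by `trait_effect_size` standard
#' deviations (random sign per trait), and every plant of the same line shares
#' the line's shift regardless of its plate position.  The trait-selection
#' draw for each line uses a line-specific sub-seed, so duplicate positions of
#' a line are exchangeable.
#'
#' @param config a [screening_config()].
#' @return a list with elements `phenotypes` (data frame: `plant_id`, `plate`,
#'   `well`, `line_id`, then trait columns) and `truth` (data frame:
#'   `plant_id`, `is_mutant`, `line_id`).  The trait catalog (scales and
#'   units) is attached as attribute `"catalog"`.
#' @seealso [generate_growth_series()] for the matching longitudinal data.
#' @export
generate_population <- function(config) {
  stopifnot(inherits(config, "screening_config"))
  n <- config$n_plants
  m <- config$n_traits
  k <- config$n_latent_factors
  cat_tab <- trait_catalog(m, k)

  with_seed(config$seed, {
    plant_id <- sprintf("P%03d", seq_len(n))
    plate <- sprintf("plate_%02d", ((seq_len(n) - 1L) %/% config$plate_layout) + 1L)
    well <- sprintf("W%d", ((seq_len(n) - 1L) %% config$plate_layout) + 1L)

    # latent factors and unique noise on the standardized trait scale
    fac <- matrix(stats::rnorm(n * k), n, k)
    eps <- matrix(stats::rnorm(n * m), n, m)
    lam <- .trait_loading
    z <- fac[, cat_tab$block, drop = FALSE] * lam + sqrt(1 - lam^2) * eps

    # mutant positions and line assignment (each line used at least once,
    # remaining positions recycle lines -> duplicated plantings)
    is_mutant <- rep(FALSE, n)
    line_id <- rep("WT", n)
    if (config$n_mutant_plants > 0) {
      mut_idx <- sort(sample.int(n, config$n_mutant_plants))
      line_of <- rep(seq_len(config$n_mutant_lines),
                     length.out = config$n_mutant_plants)
      line_of <- sample(line_of)
      is_mutant[mut_idx] <- TRUE
      line_id[mut_idx] <- sprintf("M%02d", line_of)
      for (l in seq_len(config$n_mutant_lines)) {
        members <- mut_idx[line_of == l]
        if (length(members) == 0) next
        shift <- with_seed(sub_seed(config$seed, 1000L + l), {
          traits <- sample.int(m, config$n_affected_traits)
          signs <- sample(c(-1, 1), config$n_affected_traits, replace = TRUE)
          list(traits = traits, delta = signs * config$trait_effect_size)
        })
        z[members, shift$traits] <- z[members, shift$traits] +
          matrix(shift$delta, length(members), config$n_affected_traits,
                 byrow = TRUE)
      }
    }

    x <- sweep(sweep(z, 2, cat_tab$sd, `*`), 2, cat_tab$mean, `+`)
    colnames(x) <- cat_tab$trait
    phenotypes <- data.frame(plant_id = plant_id, plate = plate, well = well,
                             line_id = line_id, stringsAsFactors = FALSE)
    phenotypes <- cbind(phenotypes, as.data.frame(x))
    truth <- data.frame(plant_id = plant_id, is_mutant = is_mutant,
                        line_id = line_id, stringsAsFactors = FALSE)
    attr(phenotypes, "catalog") <- cat_tab
    list(phenotypes = phenotypes, truth = truth)
  })
}

# Wild-type logistic growth baseline for rosette projected area.
# h: asymptotic area (mm^2); x1: shape offset (area at day 0 = h / (1 + x1));
# x2: relative growth rate (1/day).  Values give a ~33 mm^2 seedling growing
# to ~2000 mm^2 with the fast-growth phase around day 12.
.wt_growth <- list(h = 2000, x1 = 60, x2 = 0.35)

#' Generate longitudinal leaf-area series for a population
#'
#' Evaluates the logistic growth curve `area(t) = h / (1 + x1 * exp(-x2 t))`
#' at the configured measurement days for every plant and applies
#' multiplicative Gaussian measurement noise with coefficient of variation
#' `noise_cv` (truncated at zero).  Wild-type plants share the baseline
#' parameters; each mutant line's `h` and `x2` are multiplied by
#' `growth_effect`.  The per-plant generating parameters are attached as
#' attribute `"true_params"` so parameter-recovery tests can compare fitted
#' against generating values.
#'
#' @param config a [screening_config()].
#' @param truth ground-truth data frame from [generate_population()].
#' @return a long data frame (`plant_id`, `day`, `leaf_area`) of class
#'   `growth_series`, with attribute `"true_params"`.
#' @export
generate_growth_series <- function(config, truth) {
  stopifnot(inherits(config, "screening_config"))
  if (length(config$days) == 0) stopf("configuration error: 'days' is empty")
  need <- c("plant_id", "is_mutant", "line_id")
  if (!all(need %in% names(truth))) {
    stopf("truth must contain columns %s", paste(need, collapse = ", "))
  }
  if (nrow(truth) != config$n_plants ||
      sum(truth$is_mutant) != config$n_mutant_plants) {
    stopf("truth is inconsistent with config (%d plants / %d mutants expected)",
          config$n_plants, config$n_mutant_plants)
  }

  ge <- ifelse(truth$is_mutant, config$growth_effect, 1)
  pars <- data.frame(
    plant_id = truth$plant_id,
    h = .wt_growth$h * ge,
    x1 = .wt_growth$x1,
    x2 = .wt_growth$x2 * ge,
    stringsAsFactors = FALSE
  )

  days <- config$days
  out <- with_seed(sub_seed(config$seed, 2L), {
    area <- lapply(seq_len(nrow(pars)), function(i) {
      mu <- lgc_area(days, pars$h[i], pars$x1[i], pars$x2[i])
      if (config$noise_cv > 0) {
        mu <- mu * (1 + stats::rnorm(length(days), sd = config$noise_cv))
      }
      pmax(mu, 0)
    })
    data.frame(
      plant_id = rep(pars$plant_id, each = length(days)),
      day = rep(days, times = nrow(pars)),
      leaf_area = unlist(area),
      stringsAsFactors = FALSE
    )
  })
  attr(out, "true_params") <- pars
  class(out) <- c("growth_series", "data.frame")
  out
}

#' Printed visual-screening counts of the three manual trials
#'
#' Returns the packaged counts of three rounds of naked-eye mutant screening
#' (total plants, actual mutants, predicted mutants, correct predictions,
#' prediction errors, undetected mutants) together with the originally
#' printed accuracy / false-positive-rate / false-negative-rate values.  The
#' printed trial-3 FPR is internally inconsistent with its own counts;
#' [table1_report()] recomputes all ratios and flags that discrepancy.
#'
#' @return a data frame of class `screening_counts`, one row per trial.
#' @export
load_table1_fixture <- function() {
  path <- system.file("extdata", "table1_visual_counts.csv",
                      package = "phenoscreen", mustWork = TRUE)
  counts <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_screening_counts(counts)
  class(counts) <- c("screening_counts", "data.frame")
  counts
}

#' Validate screening-count identities
#'
#' Checks the two structural identities every set of screening counts must
#' satisfy: `correctly_predicted + undetected = actual_mutants` and
#' `correctly_predicted + prediction_errors = predicted_mutants`, plus
#' non-negativity.
#'
#' @param counts data frame with columns `trial`, `total_plants`,
#'   `actual_mutants`, `predicted_mutants`, `correctly_predicted`,
#'   `prediction_errors`, `undetected`.
#' @return `counts`, invisibly; errors with the violated identity otherwise.
#' @export
validate_screening_counts <- function(counts) {
  need <- c("trial", "total_plants", "actual_mutants", "predicted_mutants",
            "correctly_predicted", "prediction_errors", "undetected")
  miss <- setdiff(need, names(counts))
  if (length(miss)) stopf("missing count columns: %s", paste(miss, collapse = ", "))
  num <- counts[setdiff(need, "trial")]
  if (any(unlist(num) < 0)) stopf("validation error: counts must be non-negative")
  bad1 <- counts$correctly_predicted + counts$undetected != counts$actual_mutants
  if (any(bad1)) {
    stopf("validation error in trial %s: correctly_predicted + undetected != actual_mutants",
          paste(counts$trial[bad1], collapse = ", "))
  }
  bad2 <- counts$correctly_predicted + counts$prediction_errors != counts$predicted_mutants
  if (any(bad2)) {
    stopf("validation error in trial %s: correctly_predicted + prediction_errors != predicted_mutants",
          paste(counts$trial[bad2], collapse = ", "))
  }
  invisible(counts)
}
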