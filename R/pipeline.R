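write_manifest <- function(out_dir, seed, config, files, warnings = character(0),
                           timings = NULL) {
  digests <- as.list(tools::md5sum(file.path(out_dir, files)))
  names(digests) <- files
  manifest <- list(
    package = "phenoscreen",
    version = as.character(utils::packageVersion("phenoscreen")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed,
    config = config,
    files = digests,
    warnings = warnings,
    timings_sec = timings
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Simulate a screening population to disk
#'
#' Generates phenotype, growth and ground-truth tables for a configuration
#' and writes them as CSV (`phenotypes.csv`, `growth.csv`, `truth.csv`)
#' plus a JSON run manifest with the seed, the config snapshot and MD5
#' digests of every output file, so reruns are verifiable by digest.
#'
#' @param config a [screening_config()] or a path to a YAML/JSON config file
#'   whose fields are [screening_config()] arguments.
#' @param out_dir output directory (created if missing).
#' @return the manifest, invisibly.
#' @export
run_simulate <- function(config, out_dir) {
  if (is.character(config)) config <- read_config(config)
  stopifnot(inherits(config, "screening_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  t0 <- proc.time()[["elapsed"]]
  pop <- generate_population(config)
  growth <- generate_growth_series(config, pop$truth)
  utils::write.csv(pop$phenotypes, file.path(out_dir, "phenotypes.csv"),
                   row.names = FALSE)
  utils::write.csv(pop$truth, file.path(out_dir, "truth.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(growth), file.path(out_dir, "growth.csv"),
                   row.names = FALSE)
  utils::write.csv(attr(growth, "true_params"),
                   file.path(out_dir, "true_growth_params.csv"),
                   row.names = FALSE)
  write_manifest(out_dir, config$seed, unclass(config),
                 c("phenotypes.csv", "truth.csv", "growth.csv",
                   "true_growth_params.csv"),
                 timings = list(simulate = proc.time()[["elapsed"]] - t0))
}

#' Read a screening config from YAML or JSON
#'
#' @param path file whose top-level fields are [screening_config()] arguments.
#' @return a [screening_config()].
#' @export
read_config <- function(path) {
  fields <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  known <- names(formals(screening_config))
  unknown <- setdiff(names(fields), known)
  if (length(unknown)) {
    stopf("configuration error: unknown field(s) %s",
          paste(unknown, collapse = ", "))
  }
  do.call(screening_config, fields)
}

check_schema <- function(df, need, what) {
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stopf("schema error in %s: missing column(s) %s", what,
          paste(miss, collapse = ", "))
  }
  invisible(df)
}

#' Screen a population from CSV inputs to disk
#'
#' Runs the full machine screen on a phenotype table and a growth table
#' (e.g. written by [run_simulate()] or exported from an imaging system):
#' factor extraction, scatter-matrix ellipse calls, growth-curve fits and
#' parameter-space calls, combined calls and — when ground truth is
#' supplied — metrics per confidence level.  Writes `factor_scores.csv`,
#' `factor_model.json` (eigenvalues + loadings), `lgc_fits.csv`,
#' `calls_<level>.json`, `metrics.csv` and a manifest.
#'
#' @param phenotypes path to the phenotype CSV (plant_id, plate, well,
#'   line_id, trait columns).
#' @param growth path to the growth CSV (plant_id, day, leaf_area).
#' @param out_dir output directory.
#' @param truth optional path to a truth CSV (plant_id, is_mutant, line_id).
#' @param levels confidence levels.
#' @param rule combination rule (`"union"` or `"intersection"`).
#' @param seed seed recorded in the manifest (the screen itself is
#'   deterministic given its inputs).
#' @return list with `scores`, `fits`, `calls`, `metrics` (or `NULL`),
#'   invisibly.
#' @export
run_screen <- function(phenotypes, growth, out_dir, truth = NULL,
                       levels = default_levels(), rule = "union", seed = 1L) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  phe <- check_schema(utils::read.csv(phenotypes, stringsAsFactors = FALSE),
                      c("plant_id", "trait_01"), "phenotypes")
  gro <- check_schema(utils::read.csv(growth, stringsAsFactors = FALSE),
                      c("plant_id", "day", "leaf_area"), "growth")

  warnings <- character(0)
  wh <- withCallingHandlers({
    z <- standardize_traits(phe)
    scores <- compute_factors(z)
    fits <- fit_lgc_population(gro)
    list(z = z, scores = scores, fits = fits)
  }, warning = function(w) {
    warnings <<- c(warnings, conditionMessage(w))
    invokeRestart("muffleWarning")
  })
  scores <- wh$scores
  fits <- wh$fits

  scores_df <- data.frame(plant_id = rownames(scores$scores),
                          as.data.frame(scores$scores))
  utils::write.csv(scores_df, file.path(out_dir, "factor_scores.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(eigenvalues = scores$eigenvalues,
         variance_explained = scores$variance_explained,
         k = scores$k,
         loadings = as.data.frame(scores$loadings)),
    file.path(out_dir, "factor_model.json"), auto_unbox = TRUE, digits = NA)
  utils::write.csv(as.data.frame(fits), file.path(out_dir, "lgc_fits.csv"),
                   row.names = FALSE)

  files <- c("factor_scores.csv", "factor_model.json", "lgc_fits.csv")
  scatter <- screen_scatter_matrix(scores, levels = levels)
  calls <- list()
  for (lv in as.character(levels)) {
    growth_cs <- screen_growth_params(fits, level = as.numeric(lv))
    cs <- combine_calls(scatter[[lv]], growth_cs, rule = rule)
    calls[[lv]] <- cs
    fn <- sprintf("calls_%s.json", lv)
    jsonlite::write_json(
      list(method = cs$method, level = cs$level, rule = cs$rule,
           flagged = cs$flagged, fit_failures = cs$fit_failures,
           scatter_flagged = cs$parents$scatter$flagged,
           growth_flagged = cs$parents$growth$flagged,
           per_panel = cs$parents$scatter$per_panel),
      file.path(out_dir, fn), auto_unbox = FALSE, digits = NA)
    files <- c(files, fn)
  }

  metrics <- NULL
  if (!is.null(truth)) {
    tru <- check_schema(utils::read.csv(truth, stringsAsFactors = FALSE),
                        c("plant_id", "is_mutant"), "truth")
    tru$is_mutant <- as.logical(tru$is_mutant)
    metrics <- do.call(rbind, lapply(calls, evaluate_calls, truth = tru))
    utils::write.csv(as.data.frame(metrics), file.path(out_dir, "metrics.csv"),
                     row.names = FALSE)
    files <- c(files, "metrics.csv")
  }
  write_manifest(out_dir, seed,
                 list(levels = levels, rule = rule,
                      phenotypes = phenotypes, growth = growth),
                 files, warnings = warnings)
  invisible(list(scores = scores, fits = fits, calls = calls,
                 metrics = metrics))
}

#' Emit the manual-screening table report to disk
#'
#' Writes the packaged manual-trial counts, the recomputed metrics (with the
#' mean-of-ratios row) and the printed-vs-recomputed discrepancy report (see
#' [table1_report()]) as CSV/JSON.
#'
#' @param out_dir output directory.
#' @return the [table1_report()], invisibly.
#' @export
run_table1 <- function(out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  rep <- table1_report()
  utils::write.csv(rep$metrics, file.path(out_dir, "table1_metrics.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(consistent = rep$consistent, discrepancies = rep$discrepancies),
    file.path(out_dir, "table1_discrepancies.json"),
    auto_unbox = TRUE, digits = NA)
  write_manifest(out_dir, NA,
                 list(fixture = "table1_visual_counts.csv"),
                 c("table1_metrics.csv", "table1_discrepancies.json"))
  invisible(rep)
}
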