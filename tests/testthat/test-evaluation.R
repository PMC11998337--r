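pop10 <- sprintf("P%03d", 1:10)

cs <- function(flagged, method = "scatter", level = 0.95, population = pop10) {
  call_set(method, level, flagged, population)
}

test_that("call combination follows set union / intersection with provenance", {
  a <- cs(c("P003", "P005"))
  b <- cs(c("P005", "P009"), method = "growth")
  u <- combine_calls(a, b)
  expect_setequal(u$flagged, c("P003", "P005", "P009"))
  expect_equal(u$rule, "union")
  expect_equal(u$provenance[["P005"]], c("scatter", "growth"))
  expect_equal(u$provenance[["P003"]], "scatter")

  i <- combine_calls(a, b, rule = "intersection")
  expect_equal(i$flagged, "P005")

  empty_growth <- cs(character(0), method = "growth")
  expect_setequal(combine_calls(a, empty_growth)$flagged, a$flagged)

  other <- call_set("growth", 0.95, "Q1", population = c("Q1", "Q2", "Q3"))
  expect_error(combine_calls(a, other), "population mismatch")
})

test_that("call sets refuse flags outside their population", {
  expect_error(call_set("scatter", 0.95, "P999", pop10), "outside the population")
})

test_that("evaluation reproduces the first manual trial's ratios from equivalent sets", {
  # trial-1 counts: 102 plants, 8 mutants, 14 predicted of which 7 correct
  ids <- sprintf("P%03d", 1:102)
  mutants <- ids[1:8]
  flagged <- c(ids[1:7], ids[9:15])  # 7 correct + 7 errors
  truth <- data.frame(plant_id = ids, is_mutant = ids %in% mutants)
  m <- evaluate_calls(call_set("manual", NA, flagged, ids), truth)
  expect_equal(m$accuracy, 0.875)
  expect_equal(m$fnr, 0.125)
  expect_equal(round(m$fpr_per_plant, 3), 0.069)
  expect_equal(m$fpr_per_predicted, 0.5)
  expect_equal(m$correctly_predicted, 7)
  expect_equal(m$undetected, 1)
})

test_that("perfect, empty and mutant-free populations hit the documented edges", {
  truth <- toy_truth(10, c("P002", "P007"))
  perfect <- evaluate_calls(cs(c("P002", "P007")), truth)
  expect_equal(perfect$accuracy, 1)
  expect_equal(perfect$fnr, 0)
  expect_equal(perfect$fpr_per_predicted, 0)
  expect_equal(perfect$fpr_per_plant, 0)

  none <- evaluate_calls(cs(character(0)), truth)
  expect_equal(none$accuracy, 0)
  expect_equal(none$fnr, 1)
  expect_equal(none$fpr_per_predicted, 0)
  expect_equal(none$fpr_per_plant, 0)

  no_mut <- evaluate_calls(cs("P003"), toy_truth(10, character(0)))
  expect_true(is.na(no_mut$accuracy))
  expect_true(is.na(no_mut$fnr))
  expect_equal(no_mut$fpr_per_plant, 0.1)
})

test_that("accuracy and FNR always sum to one (shared denominator)", {
  set.seed(31)
  truth <- toy_truth(30, sprintf("P%03d", sample(30, 5)))
  for (i in 1:10) {
    flagged <- sprintf("P%03d", sample(30, sample(0:15, 1)))
    m <- evaluate_calls(cs(flagged, population = truth$plant_id), truth)
    expect_equal(m$accuracy + m$fnr, 1)
  }
})

test_that("the manual-trial table reproduces its printed accuracy and FNR columns", {
  met <- metrics_from_counts(load_table1_fixture())
  expect_equal(round(met$accuracy, 3), c(0.875, 0.429, 0.625))
  expect_equal(round(met$fnr, 3), c(0.125, 0.571, 0.375))
  expect_equal(round(mean(met$accuracy), 3), 0.643)
  expect_equal(round(mean(met$fnr), 3), 0.357)
  # per-plant FPR matches the printed values for trials 1-2 only
  expect_equal(round(met$fpr_per_plant, 3)[1:2], c(0.069, 0.046))
})

test_that("method comparison summarizes manual trials by mean of ratios", {
  machine <- data.frame(method = "combined", level = 0.95, accuracy = 0.9,
                        fnr = 0.1, fpr_per_predicted = 0.5, fpr_per_plant = 0.2)
  cmp <- compare_methods(machine, load_table1_fixture())
  expect_equal(round(cmp$manual_mean[["accuracy"]], 3), 0.643)
  expect_equal(round(cmp$manual_mean[["fnr"]], 3), 0.357)
  expect_equal(cmp$deltas$d_accuracy, 0.9 - cmp$manual_mean[["accuracy"]])
})

test_that("the fixture report flags exactly the irreproducible trial-3 FPR", {
  rep <- table1_report()
  expect_false(rep$consistent)
  expect_equal(nrow(rep$discrepancies), 1)
  expect_equal(rep$discrepancies$trial, 3)
  expect_equal(rep$discrepancies$metric, "fpr")
  expect_equal(rep$discrepancies$printed, 0.058)
  expect_equal(rep$discrepancies$recomputed, 0.078)    # 8 / 102
  expect_equal(rep$discrepancies$recomputed_alt, 0.615)  # 8 / 13
  # and the mean row reproduces the printed means
  mean_row <- rep$metrics[rep$metrics$trial == "mean", ]
  expect_equal(round(mean_row$accuracy, 3), 0.643)
  expect_equal(round(mean_row$fnr, 3), 0.357)
})

test_that("a single-level sweep equals a direct evaluation at that level", {
  cfg <- screening_config(n_plants = 40, n_mutant_plants = 4,
                          n_mutant_lines = 2, seed = 77)
  pop <- generate_population(cfg)
  gr <- generate_growth_series(cfg, pop$truth)
  fs <- compute_factors(standardize_traits(pop$phenotypes))
  fits <- fit_lgc_population(gr)
  sw <- confidence_sweep(fs, fits, pop$truth, levels = 0.95)
  direct <- evaluate_calls(
    combine_calls(screen_scatter_matrix(fs, levels = 0.95)[[1]],
                  screen_growth_params(fits, level = 0.95)),
    pop$truth)
  expect_equal(nrow(sw), 1)
  expect_equal(as.data.frame(sw), as.data.frame(direct), ignore_attr = TRUE)
  expect_error(confidence_sweep(fs, fits, pop$truth, levels = numeric(0)),
               "empty level list")
})
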