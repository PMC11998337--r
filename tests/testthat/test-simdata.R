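test_that("population generation is deterministic and label counts match config", {
  cfg <- screening_config(seed = 7)
  a <- generate_population(cfg)
  b <- generate_population(cfg)
  expect_identical(a, b)

  expect_equal(sum(a$truth$is_mutant), 8)
  expect_equal(sum(!a$truth$is_mutant), 94)
  expect_equal(nrow(a$phenotypes), 102)
  expect_false(anyDuplicated(a$phenotypes$plant_id) > 0)
  expect_identical(a$truth$plant_id, a$phenotypes$plant_id)

  none <- generate_population(screening_config(n_mutant_plants = 0,
                                               n_mutant_lines = 0, seed = 7))
  expect_false(any(none$truth$is_mutant))
  expect_true(all(none$truth$line_id == "WT"))
})

test_that("plants of the same mutant line share the line's trait shift", {
  cfg <- screening_config(n_mutant_plants = 6, n_mutant_lines = 2,
                          noise_cv = 0, seed = 11)
  pop <- generate_population(cfg)
  cat_tab <- attr(pop$phenotypes, "catalog")
  traits <- as.matrix(pop$phenotypes[, cat_tab$trait])
  z <- sweep(sweep(traits, 2, cat_tab$mean, `-`), 2, cat_tab$sd, `/`)
  wt <- z[!pop$truth$is_mutant, , drop = FALSE]
  for (line in setdiff(unique(pop$truth$line_id), "WT")) {
    members <- z[pop$truth$line_id == line, , drop = FALSE]
    # line members deviate from the WT trait means in the same direction by
    # ~ the configured 4 SD on the affected traits
    dev <- sweep(members, 2, colMeans(wt), `-`)
    big <- abs(colMeans(dev)) > 2
    expect_equal(sum(big), cfg$n_affected_traits)
    if (nrow(members) > 1) {
      signs <- sign(dev[, big, drop = FALSE])
      expect_true(all(apply(signs, 2, function(s) length(unique(s)) == 1)))
    }
  }
})

test_that("invalid configurations are rejected with informative errors", {
  expect_error(screening_config(n_mutant_plants = 200), "exceeds n_plants")
  expect_error(screening_config(n_mutant_lines = 10, n_mutant_plants = 8),
               "exceeds n_mutant_plants")
  expect_error(screening_config(days = c(0, 4, 2)), "strictly increasing")
  expect_error(screening_config(days = numeric(0)), "empty")
  expect_error(screening_config(n_traits = -1), "non-negative")
})

test_that("noiseless growth series lie exactly on the generating logistic", {
  cfg <- screening_config(n_plants = 5, n_mutant_plants = 1,
                          n_mutant_lines = 1, noise_cv = 0, seed = 3)
  pop <- generate_population(cfg)
  gr <- generate_growth_series(cfg, pop$truth)
  pars <- attr(gr, "true_params")
  for (i in seq_len(nrow(pars))) {
    obs <- gr$leaf_area[gr$plant_id == pars$plant_id[i]]
    expected <- lgc_area(cfg$days, pars$h[i], pars$x1[i], pars$x2[i])
    expect_equal(max(abs(obs - expected)), 0)
  }
  # mutant line perturbed multiplicatively on (h, x2)
  mut <- pars[pop$truth$is_mutant, ]
  wt <- pars[!pop$truth$is_mutant, ][1, ]
  expect_equal(mut$h / wt$h, rep(cfg$growth_effect, nrow(mut)))
  expect_equal(mut$x2 / wt$x2, rep(cfg$growth_effect, nrow(mut)))
})

test_that("logistic curve passes through its inflection point at h/2", {
  expect_equal(lgc_area(log(50) / 0.4, h = 100, x1 = 50, x2 = 0.4), 50)
})

test_that("measurement noise reproduces the configured coefficient of variation", {
  cfg <- screening_config(n_plants = 50, n_mutant_plants = 0,
                          n_mutant_lines = 0, noise_cv = 0.02, seed = 5)
  pop <- generate_population(cfg)
  gr <- generate_growth_series(cfg, pop$truth)
  final <- gr$leaf_area[gr$day == max(cfg$days)]
  expect_length(final, 50)
  cv <- sd(final) / mean(final)
  expect_gt(cv, 0.01)
  expect_lt(cv, 0.04)
  # determinism of the growth draw too
  gr2 <- generate_growth_series(cfg, pop$truth)
  expect_identical(as.data.frame(gr), as.data.frame(gr2))
})

test_that("growth generation validates its inputs", {
  cfg <- screening_config(n_plants = 10, n_mutant_plants = 2,
                          n_mutant_lines = 1, seed = 2)
  pop <- generate_population(cfg)
  bad <- pop$truth
  bad$is_mutant[1] <- TRUE
  expect_error(generate_growth_series(cfg, bad), "inconsistent")
})

test_that("the packaged manual-screening counts satisfy both count identities", {
  counts <- load_table1_fixture()
  expect_equal(nrow(counts), 3)
  expect_equal(counts$correctly_predicted + counts$undetected,
               counts$actual_mutants)
  expect_equal(counts$correctly_predicted + counts$prediction_errors,
               counts$predicted_mutants)

  t1 <- counts[counts$trial == 1, ]
  expect_equal(t1$total_plants, 102)
  expect_equal(t1$actual_mutants, 8)
  expect_equal(t1$correctly_predicted, 7)
  expect_equal(counts$undetected[counts$trial == 2], 8)

  broken <- counts
  broken$undetected[1] <- 5
  expect_error(validate_screening_counts(broken),
               "undetected != actual_mutants")
})
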