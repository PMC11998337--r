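days <- seq(0, 28, by = 2)

series_from <- function(h, x1, x2, days. = days, noise = 0, seed = 1,
                        plant_id = NULL) {
  mu <- lgc_area(days., h, x1, x2)
  if (noise > 0) {
    set.seed(seed)
    mu <- pmax(mu * (1 + rnorm(length(mu), sd = noise)), 0)
  }
  d <- data.frame(day = days., leaf_area = mu)
  if (!is.null(plant_id)) d$plant_id <- plant_id
  d
}

test_that("noiseless series recover their generating parameters near-exactly", {
  fit <- fit_lgc(series_from(100, 50, 0.4))
  expect_true(fit$converged)
  expect_lt(abs(fit$h - 100) / 100, 1e-6)
  expect_lt(abs(fit$x1 - 50) / 50, 1e-6)
  expect_lt(abs(fit$x2 - 0.4) / 0.4, 1e-6)
  expect_lt(abs(fit$k), 1e-6)
  expect_lt(abs(fit$s), 1e-6)
  expect_equal(fit$p1, 14)  # median observed day
  expect_equal(fit$p2, 28)  # final observed day
})

test_that("prediction satisfies the logistic identities", {
  fit <- fit_lgc(series_from(100, 50, 0.4))
  expect_equal(lgc_predict(fit, log(fit$x1) / fit$x2), fit$h / 2,
               tolerance = 1e-10)
  expect_equal(lgc_predict(fit, 40 / fit$x2), fit$h, tolerance = 1e-12)
  expect_equal(lgc_area(0, 100, 50, 0.4), 100 / 51)
  expect_equal(lgc_predict(fit, 0), 100 / 51, tolerance = 1e-5)
})

test_that("ineligible and degenerate series are handled without optimizer errors", {
  expect_error(fit_lgc(data.frame(day = c(0, 2, 4), leaf_area = c(1, 2, 3))),
               "ineligible.*4 time points")
  expect_error(fit_lgc(data.frame(day = days, leaf_area = rep(0, length(days)))),
               "ineligible.*zero")
  flat <- fit_lgc(data.frame(day = days, leaf_area = rep(5, length(days))))
  expect_false(flat$converged)
  expect_true(flat$degenerate)
  expect_error(lgc_predict(flat, 10), "unconverged")
})

test_that("time-shifting the series maps x1 -> x1 * exp(x2 * shift), h and x2 fixed", {
  delta <- 5
  d0 <- series_from(100, 50, 0.4)
  f0 <- fit_lgc(d0)
  d1 <- transform(d0, day = day + delta)  # same areas, relabelled days
  f1 <- fit_lgc(d1)
  expect_equal(f1$h, f0$h, tolerance = 1e-6)
  expect_equal(f1$x2, f0$x2, tolerance = 1e-6)
  expect_equal(f1$x1, f0$x1 * exp(f0$x2 * delta), tolerance = 1e-5)
})

test_that("median parameter-recovery error stays small at 2% noise and degrades with noise", {
  rel_err <- function(noise, n = 30) {
    errs <- vapply(seq_len(n), function(i) {
      f <- fit_lgc(series_from(100, 50, 0.4, noise = noise, seed = 1000 + i))
      if (!f$converged) return(NA_real_)
      max(abs(f$h - 100) / 100, abs(f$x2 - 0.4) / 0.4)
    }, 0)
    median(errs, na.rm = TRUE)
  }
  grid <- vapply(c(0, 0.02, 0.08), rel_err, 0)
  expect_lt(grid[2], 0.05)
  expect_true(all(diff(grid) >= 0))
})

test_that("population fitting keeps unconverged rows and skips ineligible plants", {
  ok <- series_from(100, 50, 0.4, plant_id = "P001")
  flat <- data.frame(plant_id = "P002", day = days, leaf_area = 5)
  short <- data.frame(plant_id = "P003", day = c(0, 2, 4), leaf_area = c(1, 2, 3))
  expect_warning(fits <- fit_lgc_population(rbind(ok, flat, short)),
                 "skipping plant P003")
  expect_equal(fits$plant_id, c("P001", "P002"))
  expect_equal(fits$converged, c(TRUE, FALSE))
})

test_that("growth-parameter screening flags a planted h-doubled outlier", {
  pop <- lapply(1:20, function(i) {
    h <- if (i == 13) 200 else 100
    series_from(h, 50, 0.4, noise = 0.02, seed = 300 + i,
                plant_id = sprintf("P%03d", i))
  })
  fits <- fit_lgc_population(do.call(rbind, pop))
  cs <- screen_growth_params(fits, level = 0.95)
  expect_true("P013" %in% cs$flagged)
  expect_equal(cs$method, "growth")
  # nesting across levels is inherited from the ellipse stage
  strict <- screen_growth_params(fits, level = 0.999)
  expect_true(all(strict$flagged %in% cs$flagged))
})

test_that("identical noiseless plants give a degenerate-geometry error", {
  pop <- lapply(1:12, function(i) {
    series_from(100, 50, 0.4, plant_id = sprintf("P%03d", i))
  })
  fits <- fit_lgc_population(do.call(rbind, pop))
  expect_error(screen_growth_params(fits, level = 0.95), "degenerate geometry")
})

test_that("too few converged fits is an explicit insufficient-data error", {
  pop <- lapply(1:6, function(i) {
    series_from(100, 50, 0.4, noise = 0.05, seed = i, plant_id = sprintf("P%03d", i))
  })
  fits <- fit_lgc_population(do.call(rbind, pop))
  expect_error(screen_growth_params(fits), "insufficient data")
})

test_that("unconverged plants surface as fit-failure candidates, not merged flags", {
  pop <- lapply(1:14, function(i) {
    series_from(100, 50, 0.4, noise = 0.02, seed = 600 + i,
                plant_id = sprintf("P%03d", i))
  })
  flat <- data.frame(plant_id = "P099", day = days, leaf_area = 7)
  fits <- fit_lgc_population(rbind(do.call(rbind, pop), flat))
  cs <- screen_growth_params(fits, level = 0.9)
  expect_true("P099" %in% cs$fit_failures)
  expect_false("P099" %in% cs$flagged)
  expect_true("P099" %in% cs$population)
})
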