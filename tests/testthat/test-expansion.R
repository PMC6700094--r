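test_that("relative expansion divides means with the density inversion", {
  data <- make_measurements(list(
    list(id = "same", kind = "thickness", uncleared = c(5, 6, 7),
         cleared = c(5, 6, 7)),
    list(id = "dens", kind = "density", uncleared = c(180, 220),
         cleared = c(90, 110)),
    list(id = "vol", kind = "volume", uncleared = c(480, 520),
         cleared = c(800, 880))
  ))
  rel <- relative_expansion(data)
  expect_equal(rel$relative_expansion[rel$measure_id == "same"], 1.0)
  # density inverts: uncleared mean 200 over cleared mean 100
  expect_equal(rel$relative_expansion[rel$measure_id == "dens"], 2.0)
  expect_equal(rel$relative_expansion[rel$measure_id == "vol"], 840 / 500)
})

test_that("degenerate measurement tables are rejected", {
  m <- expansion_measure("d", "density")
  only_cleared <- measurement_set(m, "cleared", c(1, 2))
  expect_error(relative_expansion(only_cleared), "lacks one condition")

  zero_cleared <- dplyr::bind_rows(
    measurement_set(m, "uncleared", c(1, 2)),
    measurement_set(m, "cleared", c(0, 0)))
  expect_error(relative_expansion(zero_cleared), "zero denominator")

  mixed <- dplyr::bind_rows(
    measurement_set(m, "uncleared", c(1, 2)),
    measurement_set(m, "cleared", c(1, 2)))
  mixed$units[1] <- "um^3"
  expect_error(relative_expansion(mixed), "mixes units")

  expect_error(measurement_set(m, "cleared", numeric(0)), "non-empty")
  expect_error(measurement_set(m, "cleared", c(1, -2)), "non-negative")
})

test_that("adjust_ratio reproduces the published adjusted ratios at 2 dp", {
  tab <- published_expansion_table()
  adj <- adjust_ratio(tab)
  expect_equal(round(adj$adjusted_expansion_ratio, 2),
               c(1.35, 1.42, 1.10, 1.41, 1.19, 1.13, 1.12, 1.13, 1.14, 1.08))
  # spot checks in the three kinds
  expect_equal(round(adjust_ratio(tibble::tibble(
    dimensionality = 2, relative_expansion = 1.83))$adjusted_expansion_ratio, 2), 1.35)
  expect_equal(round(adjust_ratio(tibble::tibble(
    dimensionality = 3, relative_expansion = 1.68))$adjusted_expansion_ratio, 2), 1.19)
  expect_equal(adjust_ratio(tibble::tibble(
    dimensionality = 1, relative_expansion = 1.14))$adjusted_expansion_ratio, 1.14)
})

test_that("the d-th root adjustment inverts the d-th power exactly", {
  for (r in c(0.7, 1, 1.08, 1.2, 1.83, 2.5)) {
    for (d in 1:3) {
      adj <- adjust_ratio(tibble::tibble(dimensionality = d,
                                         relative_expansion = r^d))
      expect_equal(adj$adjusted_expansion_ratio, r, tolerance = 1e-12)
    }
  }
  # identity at no expansion, monotone in the relative expansion
  grid <- adjust_ratio(tibble::tibble(dimensionality = 3,
                                      relative_expansion = seq(0.5, 3, 0.1)))
  expect_true(all(diff(grid$adjusted_expansion_ratio) > 0))
  expect_error(adjust_ratio(tibble::tibble(dimensionality = 2,
                                           relative_expansion = -1)),
               "must be > 0")
})

test_that("cv matches the two-pass oracle to 1e-12", {
  cases <- list(c(2, 4, 4, 4, 5, 5, 7, 9), c(1.0, 1.2),
                runif(50, 0.5, 2), rlnorm(20))
  set.seed(1)
  for (x in cases) {
    expect_equal(cv(x), oracle_cv(x), tolerance = 1e-12)
  }
  expect_equal(cv(c(2, 4, 4, 4, 5, 5, 7, 9)), 0.427618, tolerance = 1e-6)
  expect_equal(cv(c(1.0, 1.2)), 0.1285649, tolerance = 1e-6)
  expect_identical(cv(rep(3, 5)), 0)
  expect_error(cv(1), "at least 2")
  expect_error(cv(c(-1, 1)), "zero mean")
})

test_that("the clearing CV of the published adjusted ratios is 0.110", {
  adj <- c(1.35, 1.42, 1.10, 1.41, 1.19, 1.13, 1.12, 1.13, 1.14, 1.08)
  expect_equal(round(clearing_cv(adj), 3), 0.110)
  expect_identical(clearing_cv(rep(1.2, 4)), 0)
  expect_equal(clearing_cv(tibble::tibble(adjusted_expansion_ratio = c(1, 1.2))),
               0.1285649, tolerance = 1e-6)
})

test_that("the acceptability threshold is the mean of uncleared per-measure CVs", {
  # engineer sets with known CVs: constant lists give 0
  const <- make_measurements(list(
    list(id = "a", kind = "density", uncleared = rep(5, 4), cleared = rep(5, 4)),
    list(id = "b", kind = "volume", uncleared = rep(2, 4), cleared = rep(2, 4))
  ))
  expect_identical(acceptability_threshold(const)$threshold, 0)

  # two sets with CVs 0.10 and 0.20 by construction (n = 2: cv = |d|/(m*sqrt(2)))
  mk2 <- function(m, cv_target) c(m * (1 - cv_target / sqrt(2)),
                                  m * (1 + cv_target / sqrt(2)))
  two <- make_measurements(list(
    list(id = "a", kind = "density", uncleared = mk2(10, 0.10), cleared = c(1, 1)),
    list(id = "b", kind = "volume", uncleared = mk2(10, 0.20), cleared = c(1, 1))
  ))
  expect_equal(acceptability_threshold(two)$threshold, 0.15, tolerance = 1e-12)

  # five engineered CVs -> mean 0.1462
  cvs <- c(0.104, 0.027, 0.2, 0.2, 0.2)
  five <- make_measurements(lapply(seq_along(cvs), function(i)
    list(id = paste0("m", i), kind = "volume", uncleared = mk2(10, cvs[i]),
         cleared = c(1, 1))))
  expect_equal(acceptability_threshold(five)$threshold, 0.1462, tolerance = 1e-12)

  single <- make_measurements(list(
    list(id = "a", kind = "density", uncleared = 5, cleared = c(1, 1))))
  expect_error(acceptability_threshold(single), "fewer than 2")
})

test_that("the verdict compares clearing CV to the threshold, boundary uniform", {
  expect_identical(uniformity_verdict(0.110, 0.173)$verdict, "uniform")
  expect_identical(uniformity_verdict(0.2, 0.1)$verdict, "non_uniform")
  expect_identical(uniformity_verdict(0.15, 0.15)$verdict, "uniform")
})

test_that("clearing_report chains the full analysis and serializes", {
  mk2 <- function(m, cv_target) c(m * (1 - cv_target / sqrt(2)),
                                  m * (1 + cv_target / sqrt(2)))
  data <- make_measurements(list(
    list(id = "dens", kind = "density", uncleared = mk2(200, 0.1),
         cleared = mk2(200 / 1.44, 0.1)),
    list(id = "vol", kind = "volume", uncleared = mk2(500, 0.1),
         cleared = mk2(500 * 1.728, 0.1)),
    list(id = "thick", kind = "thickness", uncleared = mk2(1000, 0.1),
         cleared = mk2(1200, 0.1))
  ))
  rep <- clearing_report(data)
  expect_s3_class(rep, "clearing_report")
  expect_equal(tidy(rep)$adjusted_expansion_ratio, rep(1.2, 3), tolerance = 1e-9)
  expect_lt(rep$clearing_cv, 1e-9)
  expect_equal(rep$threshold, 0.1, tolerance = 1e-12)
  expect_identical(rep$verdict, "uniform")
  g <- glance(rep)
  expect_identical(g$n_measures, 3L)

  json <- withr::local_tempfile(fileext = ".json")
  csv <- withr::local_tempfile(fileext = ".csv")
  write_clearing_report(rep, json, csv)
  payload <- jsonlite::read_json(json, simplifyVector = TRUE)
  expect_identical(payload$verdict, "uniform")
  expect_equal(payload$clearing_cv, rep$clearing_cv, tolerance = 1e-5)
  flat <- utils::read.csv(csv)
  expect_identical(names(flat), c("measure_id", "kind", "relative_expansion",
                                  "adjusted_expansion_ratio"))
  expect_identical(nrow(flat), 3L)
})
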