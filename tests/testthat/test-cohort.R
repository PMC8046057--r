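test_that("reference intervals match the closed-form t interval", {
  ri <- reference_interval(c(7, 7, 7, 7))
  expect_equal(ri$ci_low, 7)
  expect_equal(ri$ci_high, 7)

  ri3 <- reference_interval(c(1, 2, 3))
  half <- qt(0.975, 2) * sd(c(1, 2, 3)) / sqrt(3)
  expect_equal(ri3$mean, 2, tolerance = 1e-12)
  expect_equal(ri3$ci_low, 2 - half, tolerance = 1e-10)
  expect_equal(ri3$ci_high, 2 + half, tolerance = 1e-10)

  # widening the SD widens the interval monotonically
  w <- vapply(c(1, 2, 4), function(s) {
    r <- reference_interval(c(10 - s, 10, 10 + s))
    r$ci_high - r$ci_low
  }, numeric(1))
  expect_true(all(diff(w) > 0))

  # population reference band mode
  rr <- reference_interval(c(1, 2, 3), type = "reference")
  expect_equal(rr$ci_high - rr$ci_low, 2 * qnorm(0.975) * 1, tolerance = 1e-10)

  expect_error(reference_interval(5), "at least 2")
})

test_that("classification against the band uses closed bounds", {
  ri <- reference_interval(c(10, 12, 14))
  expect_equal(as.character(classify_within_limits(ri$ci_low, ri)), "within")
  expect_equal(as.character(classify_within_limits(ri$ci_low - 1e-9, ri)), "below")
  expect_equal(as.character(classify_within_limits(ri$ci_high + 1e-9, ri)), "above")

  # simulated cohorts with a -20% shift classify below for that metric
  set.seed(8)
  for (k in 1:20) {
    ctrl <- rnorm(6, 100, 2)
    ri <- reference_interval(ctrl)
    shifted <- rnorm(4, 80, 2)
    expect_true(all(classify_within_limits(shifted, ri) == "below"))
  }
})

test_that("fold and percent change are exact arithmetic", {
  expect_equal(fold_change(5, 5), 1)
  expect_equal(fold_change(58.5, 0.1), 585)
  expect_error(fold_change(1, 0), "fold change")

  expect_equal(percent_change(1080, 1200), -10)
  expect_equal(percent_change(3, 3), 0)
  set.seed(12)
  for (k in 1:10) {
    a <- runif(1, 1, 100); b <- runif(1, 1, 100)
    expect_equal(percent_change(a, b), (a / b - 1) * 100, tolerance = 1e-12)
  }
})

toy_table <- function() {
  data.frame(
    patient = rep(c("C1", "C2", "C3", "P1", "P2"), times = 2),
    tooth = paste0(rep(c("c1", "c2", "c3", "x1", "x2"), times = 2),
                   rep(c("_m1", "_m2"), each = 5)),
    group = rep(c("control", "control", "control", "case", "case"), times = 2),
    metric = rep(c("density", "thickness"), each = 5),
    value = c(1195, 1200, 1205, 1080, 1078, 0.10, 0.11, 0.105, 0.05, 0.055))
}

test_that("cohort reports tabulate, classify and reproduce deterministically", {
  tb <- cohort_table(toy_table())
  rep1 <- cohort_report(tb)
  expect_equal(nrow(rep1$summary), 2)
  expect_equal(nrow(rep1$values), nrow(tb))

  # classifications in the report equal row-wise classify_within_limits
  for (mt in rep1$summary$metric) {
    ri <- rep1$intervals[[mt]]
    v <- rep1$values[rep1$values$metric == mt, ]
    expect_equal(v$classification, classify_within_limits(v$value, ri))
  }

  # -10% density effect is recovered and the cases sit below the band
  dens <- rep1$summary[rep1$summary$metric == "density", ]
  expect_equal(dens$percent_change, 100 * (1079 - 1200) / 1200)
  expect_true(all(rep1$values$classification[
    rep1$values$metric == "density" & rep1$values$group == "case"] == "below"))

  # regeneration from the same table is identical
  rep2 <- cohort_report(tb)
  expect_identical(rep1$summary, rep2$summary)
  expect_identical(rep1$values, rep2$values)

  # a metric missing a group is skipped with a warning
  tb2 <- toy_table()
  tb2 <- tb2[!(tb2$metric == "thickness" & tb2$group == "case"), ]
  expect_warning(r2 <- cohort_report(cohort_table(tb2)), "skipped")
  expect_equal(r2$summary$metric, "density")

  expect_error(cohort_table(data.frame(x = 1)), "columns")
  dup <- toy_table(); dup$tooth[2] <- dup$tooth[1]
  expect_error(cohort_table(dup), "duplicate")
})

test_that("cohort report writes CSVs and plots", {
  out <- file.path(tempdir(), "dm_report_test")
  rep1 <- cohort_report(cohort_table(toy_table()))
  write_cohort_report(rep1, out)
  expect_true(file.exists(file.path(out, "summary.csv")))
  expect_true(file.exists(file.path(out, "values.csv")))
  expect_true(file.exists(file.path(out, "density.png")))
  back <- read.csv(file.path(out, "summary.csv"))
  expect_equal(back$control_mean, rep1$summary$control_mean)
  unlink(out, recursive = TRUE)
})
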