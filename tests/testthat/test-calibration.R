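test_that("fit_calibration recovers affine standard curves", {
  # identity
  c1 <- fit_calibration(c(0, 1), c(0, 1))
  expect_equal(c1$slope, 1)
  expect_equal(c1$intercept, 0)
  expect_equal(c1$r_squared, 1)

  # affine inversion: greys constructed as (d - 10) / 2 -> slope 2, intercept 10
  d <- c(100, 400, 800, 1200, 1600)
  g <- (d - 10) / 2
  c2 <- fit_calibration(g, d)
  expect_equal(c2$slope, 2, tolerance = 1e-12)
  expect_equal(c2$intercept, 10, tolerance = 1e-10)
  expect_equal(c2$r_squared, 1, tolerance = 1e-12)

  # noisy rods vs an independent normal-equations computation
  set.seed(41)
  for (k in 1:5) {
    g <- sort(runif(5, 0, 1000))
    d <- 1.8 * g + 120 + rnorm(5, 0, 25)
    fit <- fit_calibration(g, d)
    sxx <- sum((g - mean(g))^2)
    slope_ref <- sum((g - mean(g)) * (d - mean(d))) / sxx
    int_ref <- mean(d) - slope_ref * mean(g)
    expect_equal(fit$slope, slope_ref, tolerance = 1e-10)
    expect_equal(fit$intercept, int_ref, tolerance = 1e-10)
    expect_true(fit$r_squared >= 0 && fit$r_squared <= 1)
  }

  expect_error(fit_calibration(c(5, 5), c(100, 200)), "degenerate")
  expect_error(fit_calibration(3, 100), "at least 2")
})

test_that("apply_calibration transforms voxelwise and round-trips a phantom", {
  v <- array(runif(4 * 4 * 4, 0, 100), dim = c(4, 4, 4))
  ident <- fit_calibration(c(0, 1), c(0, 1))
  expect_equal(apply_calibration(v, ident, 10)$data, v)

  cur <- fit_calibration(c(0, 1), c(10, 12))  # density = 2 grey + 10
  one <- array(100, dim = c(1, 1, 1))
  expect_equal(as.numeric(apply_calibration(one, cur, 10)$data), 210)

  # round-trip: fit on a noisy generated standard, apply, rod means ~ nominal
  dens <- c(100, 400, 800, 1200, 1600)
  p <- generate_calibration_phantom(dens, grey_slope = 0.5,
                                    grey_intercept = -20, noise_sd = 15,
                                    rod_radius = 10L, rod_length = 30L,
                                    seed = 9L)
  fit <- fit_calibration(rod_mean_greys(p$volume, p$rod_masks), dens)
  cal <- apply_calibration(p$volume, fit, 10)
  got <- vapply(p$rod_masks, function(m) mean(cal$data[m]), numeric(1))
  n <- sum(p$rod_masks[[1]])
  expect_true(all(abs(got - dens) < 4 * 15 / 0.5 / sqrt(n)))

  # monotone: grey ordering preserved under a positive slope
  expect_true(all(diff(fit$slope * sort(runif(50)) + fit$intercept) > 0))
})

test_that("calibration curves serialize to JSON and back", {
  cur <- fit_calibration(c(10, 20, 30), c(100, 210, 290))
  path <- tempfile(fileext = ".json")
  write_calibration(cur, path)
  back <- read_calibration(path)
  expect_equal(back$slope, cur$slope)
  expect_equal(back$intercept, cur$intercept)
  expect_equal(back$rod_densities, cur$rod_densities)
  unlink(path)
})
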