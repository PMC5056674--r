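test_that("trapezoidal AUC handles triangles, constants and additivity", {
  tri <- data.frame(time = 0:2, conc = c(0, 10, 0))
  expect_equal(auc_trapezoid(tri), 10)
  flat <- data.frame(time = c(1, 2.5, 4), conc = c(3, 3, 3))
  expect_equal(auc_trapezoid(flat, 1, 4), 3 * 3)
  # interpolated edges and additivity over a split window
  expect_equal(auc_trapezoid(tri, 0, 1) + auc_trapezoid(tri, 1, 2),
               auc_trapezoid(tri, 0, 2))
  expect_equal(auc_trapezoid(tri, 0.5, 1.5), 7.5)  # 10 minus two 1.25 corners
  expect_error(auc_trapezoid(tri, 1, 5), "window")
  expect_error(auc_trapezoid(tri, 2, 1), "window")
})

test_that("windowed peaks resolve a biphasic profile", {
  t <- seq(0, 24, by = 0.05)
  curve <- data.frame(
    time = t,
    conc = 8 * exp(-(t - 1.5)^2 / 0.8) + 6 * exp(-(t - 6.5)^2 / 3))
  first <- cmax_tmax(curve, window = c(0, 4))
  second <- cmax_tmax(curve, window = c(4, 24))
  expect_equal(first$tmax, 1.5, tolerance = 0.05)
  expect_equal(second$tmax, 6.5, tolerance = 0.05)
  expect_gt(first$cmax, second$cmax)
  # monotone rising curve peaks at the window end
  rising <- data.frame(time = 0:10, conc = (0:10)^1.5)
  expect_equal(cmax_tmax(rising)$tmax, 10)
  # ties resolve to the earliest time
  flat <- data.frame(time = 0:5, conc = rep(2, 6))
  expect_equal(cmax_tmax(flat)$tmax, 0)
  expect_error(cmax_tmax(flat, window = c(7, 9)), "empty window")
  met <- pk_metrics(curve)
  expect_equal(nrow(met), 3)
  expect_equal(met$auc[1], met$auc[2] + met$auc[3], tolerance = 1e-9)
})

test_that("fold error is symmetric with a strict two-fold boundary", {
  expect_equal(fold_error(5, 5), 1)
  expect_equal(fold_error(10, 5), 2)
  expect_equal(fold_error(3, 5), fold_error(5, 3))
  expect_equal(fold_error(0.6 * 7, 7), 1 / 0.6)
  expect_error(fold_error(0, 1), "positive")
  # the conventional adequacy cut is strict: exactly two-fold fails
  expect_false(fold_error(10, 5) < 2)
  expect_true(fold_error(0.6 * 7, 7) < 2)
})

test_that("two-fold overlay scores identical and discordant curves", {
  t <- seq(0, 12, by = 0.25)
  pred <- data.frame(time = t, conc = 10 * exp(-t / 4) * (1 - exp(-2 * t)))
  obs_same <- data.frame(time = c(1, 2, 4, 8), mean = NA)
  obs_same$mean <- stats::approx(pred$time, pred$conc, obs_same$time)$y
  ov <- two_fold_overlay(pred, obs_same)
  expect_equal(attr(ov, "fraction_within"), 1)
  obs_off <- obs_same
  obs_off$mean <- obs_off$mean / 3
  expect_equal(attr(two_fold_overlay(pred, obs_off), "fraction_within"), 0)
  expect_error(two_fold_overlay(pred, data.frame(time = 50, mean = 1)),
               "span")
})

test_that("overlay pass rate under lognormal noise matches the sampling oracle", {
  # with multiplicative lognormal error of CV 30%, the probability that an
  # observation falls within two-fold of truth is 2 * pnorm(log 2 / sdlog) - 1
  set.seed(42)
  sdlog <- sqrt(log(1 + 0.3^2))
  expected <- 2 * stats::pnorm(log(2) / sdlog) - 1
  t <- seq(0.5, 200, by = 0.5)
  pred <- data.frame(time = t, conc = rep(10, length(t)))
  obs <- data.frame(time = t, mean = 10 * exp(stats::rnorm(length(t), 0, sdlog)))
  ov <- two_fold_overlay(pred, obs)
  expect_equal(attr(ov, "fraction_within"), expected, tolerance = 0.03)
})

test_that("observed curves round-trip through CSV", {
  obs <- tibble::tibble(time = c(0.5, 1, 2), mean = c(2.2, 5.1, 4.3),
                        sd = c(0.5, 1.2, 1.0))
  path <- withr::local_tempfile(fileext = ".csv")
  write_observed_curve(obs, path)
  back <- read_observed_curve(path)
  expect_equal(as.data.frame(back), as.data.frame(obs))
})
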