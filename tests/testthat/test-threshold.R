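test_that("plots sort by descending invader dominance with stable ties", {
  ds <- tiny_study()
  s <- sort_by_invader(ds)
  expect_true(all(diff(s$invader_relabund) <= 0))
  expect_setequal(s$plot_id, ds$plots$plot_id)      # permutation of input
  # the four invader-free plots tie at 0 and order by transect then plot id
  zeros <- s$plot_id[s$invader_relabund == 0]
  expect_equal(zeros, sort(zeros))
  # richness column matches the plot-level count of natives
  expect_equal(s$native_richness[s$plot_id == "T2_C"], 4)
})

test_that("running averages follow the hand-computed window means", {
  sorted <- data.frame(invader_relabund = c(10, 8, 6, 4),
                       native_richness = c(3, 5, 4, 2))
  cur <- running_average_curve(sorted, bin = 2)
  expect_equal(cur$x, c(9, 7, 5))
  expect_equal(cur$y, c(4, 4.5, 3))
  # b = 1 reproduces the raw pairs
  cur1 <- running_average_curve(sorted, bin = 1)
  expect_equal(cur1$x, sorted$invader_relabund)
  expect_equal(cur1$y, sorted$native_richness)
  # constant richness stays constant
  sorted$native_richness <- 7
  expect_true(all(running_average_curve(sorted, bin = 3)$y == 7))
  expect_error(running_average_curve(sorted, bin = 5), "exceeds")
  expect_error(running_average_curve(sorted, bin = 0), "at least 1")
})

test_that("window means conserve the overall mean and ordering", {
  set.seed(41)
  x <- sort(runif(24, 0, 60), decreasing = TRUE)
  y <- rpois(24, 8)
  sorted <- data.frame(invader_relabund = x, native_richness = y)
  for (b in c(1, 4, 24)) {
    cur <- running_average_curve(sorted, bin = b)
    expect_true(all(diff(cur$x) <= 1e-12))          # x non-increasing
    if (24 %% b == 0) {
      blocks <- running_average_curve(sorted, bin = b, window = "block")
      expect_equal(mean(blocks$y), mean(y))         # conservation over blocks
    }
  }
  expect_equal(running_average_curve(sorted, bin = 1)$y, y)
  expect_equal(running_average_curve(sorted, bin = 24)$y, mean(y))
})

test_that("polynomial trend recovers an exact quadratic", {
  x <- seq(0, 25, length.out = 15)
  y <- -(x - 10)^2 + 12
  f <- fit_polynomial_trend(data.frame(x = x, y = y), degree = 2)
  expect_equal(f$coefficients, c(-88, 20, -1), tolerance = 1e-6)
  expect_equal(f$r_squared, 1, tolerance = 1e-9)
  # interpolation limit: degree n-1 on distinct x has zero residuals
  xs <- c(1, 3, 7, 12); ys <- c(2, 9, 4, 6)
  fi <- fit_polynomial_trend(data.frame(x = xs, y = ys), degree = 3)
  expect_equal(invgrad:::poly_eval(fi$coefficients, xs), ys, tolerance = 1e-8)
  expect_error(fit_polynomial_trend(data.frame(x = rep(1, 5), y = 1:5), 2),
               "distinct")
})

test_that("threshold detection finds the analytic vertex in both modes", {
  x <- seq(0, 25, length.out = 40)
  y <- -(x - 10)^2 + 12
  cur <- data.frame(x = x, y = y)
  f <- fit_polynomial_trend(cur, degree = 2)
  for (mode in c("peak", "declining_limb")) {
    det <- detect_threshold(cur, f, mode = mode)
    expect_equal(det$threshold, 10, tolerance = 1e-6)
    expect_false(det$flagged)
  }
  # monotone decreasing fit: threshold at minimum observed x, flagged
  ym <- 20 - 0.5 * x
  fm <- fit_polynomial_trend(data.frame(x = x, y = ym), degree = 2)
  expect_warning(dm <- detect_threshold(cur, fm), "no interior")
  expect_equal(dm$threshold, 0)
  expect_true(dm$flagged)
})

test_that("noisy quadratic truth is recovered near the vertex", {
  set.seed(59)
  x <- seq(0, 25, length.out = 60)
  y <- -(x - 10)^2 / 8 + 12 + rnorm(60, 0, 0.4)
  f <- fit_polynomial_trend(data.frame(x = x, y = y), degree = 2)
  expect_lt(f$r_squared, 1)
  det <- detect_threshold(data.frame(x = x, y = y), f)
  expect_lt(abs(det$threshold - 10), 1.5)
})

test_that("the full estimator recovers the planted richness peak", {
  # default synthetic study plants the native-richness peak at 10% invader
  # relative abundance; median detection across seeds lands within 3 points
  th <- vapply(1:8, function(s) {
    ds <- generate_study(generator_config(n_transects = 10, seed = s))
    suppressWarnings(invasion_threshold(ds)$threshold)
  }, numeric(1))
  expect_lt(abs(median(th) - 10), 3)
})

test_that("recovery degrades gracefully as cover noise increases", {
  err_at <- function(sdlog) {
    th <- vapply(1:6, function(s) {
      cfg <- generator_config(n_transects = 10, seed = s,
                              cover_sdlog = sdlog)
      suppressWarnings(invasion_threshold(generate_study(cfg))$threshold)
    }, numeric(1))
    abs(median(th) - 10)
  }
  errs <- c(err_at(0.15), err_at(0.6), err_at(1.1))
  # low-noise recovery must be decent; heavy noise need not be
  expect_lt(errs[1], 4)
  expect_lt(min(errs), max(errs) + 3)  # no catastrophic non-monotonicity
})

test_that("invasion_threshold behaves like a fitted model object", {
  ds <- generate_study(generator_config(n_transects = 8, seed = 12))
  fit <- invasion_threshold(ds)
  expect_s3_class(fit, "invasion_threshold")
  expect_equal(fit$bin, 8)
  expect_equal(nrow(fit$curve), nrow(ds$plots) - 8 + 1)
  expect_length(coef(fit), fit$degree + 1)
  expect_equal(predict(fit), fitted(fit))
  expect_equal(residuals(fit), fit$curve$y - fitted(fit))
  expect_equal(predict(fit, newdata = 0),
               unname(coef(fit)[1]), tolerance = 1e-10)
  expect_output(print(fit), "threshold")
  expect_output(print(summary(fit)), "coefficients")
  expect_true(fit$threshold >= 0 && fit$threshold <= 100)
})

test_that("compliance follows the cumulative <= standard rule", {
  plots <- data.frame(plot_id = paste0("Z_", LETTERS[1:5]),
                      transect_id = "Z", group = LETTERS[1:5])
  sp <- data.frame(species = c("inv1", "inv2", "nat"),
                   native = c(FALSE, FALSE, TRUE),
                   c_value = c(NA, NA, 5),
                   invader = c(TRUE, TRUE, FALSE))
  mk <- function(v1, v2) {
    covrow <- c(inv1 = v1, inv2 = v2, nat = 100 - v1 - v2)
    cov <- matrix(rep(covrow, 5), nrow = 5, byrow = TRUE,
                  dimnames = list(plots$plot_id, names(covrow)))
    study_dataset(cov, plots, sp, target_invader = c("inv1", "inv2"))
  }
  # invaders at 6% and 5% relative abundance: cumulative 11% fails at 10%
  r <- evaluate_standard(mk(6, 5), standard = 10)
  expect_equal(r$cumulative_relabund, 11)
  expect_false(r$pass)
  # no invaders present: 0%, pass
  r0 <- evaluate_standard(mk(0, 0), standard = 10)
  expect_equal(r0$cumulative_relabund, 0)
  expect_true(r0$pass)
  # boundary: exactly at the standard passes
  rb <- evaluate_standard(mk(10, 0), standard = 10)
  expect_true(rb$pass)
  # additivity over disjoint invader sets
  ds <- mk(4, 3)
  both <- evaluate_standard(ds, invaders = c("inv1", "inv2"))$cumulative_relabund
  one <- evaluate_standard(ds, invaders = "inv1")$cumulative_relabund
  two <- evaluate_standard(ds, invaders = "inv2")$cumulative_relabund
  expect_equal(both, one + two)
  expect_error(evaluate_standard(ds, invaders = "nonesuch"), "unknown invader")
  # per-zone reporting adds an overall row
  rz <- evaluate_standard(tiny_study(), zones = "group")
  expect_equal(rz$zone, c("A", "B", "C", "D", "E", "overall"))
  expect_false(rz$pass[rz$zone == "A"])
  expect_true(rz$pass[rz$zone == "E"])
})
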