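test_that("weighted square error matches hand arithmetic", {
  s1 <- ts_summary(1, 10, 1, 3L, cs0 = 30, ce = 0.1)       # weight = 1
  expect_equal(weighted_sse(s1, 10), 0)
  expect_equal(weighted_sse(s1, 8), 4)
  s2 <- ts_summary(c(1, 2), c(10, 5), c(2, 0.5), c(3L, 3L), cs0 = 30, ce = 0.1)
  # weights (0.25, 4); residuals (2, 0.5) -> 0.25*4 + 4*0.25 = 2
  expect_equal(weighted_sse(s2, c(8, 4.5)), 2)
  expect_error(weighted_sse(s2, 1:3), "alignment")
})

test_that("E is zero only at a perfect fit", {
  s <- make_summary(c(1, 3, 7), c(20, 10, 4))
  expect_equal(weighted_sse(s, s$means), 0)
  expect_gt(weighted_sse(s, s$means + 1e-6), 0)
})

test_that("noise-free first-order data are recovered exactly", {
  for (kf in c(0.2, 1.0, 2.2, 15)) {
    for (ce in c(0.01, 0.1, 1)) {
      s <- make_summary(c(1:7, 11, 14, 21, 28),
                        first_order_concentration(c(1:7, 11, 14, 21, 28),
                                                  kf, 30, ce),
                        ce = ce)
      fit <- fit_first_order(s)
      expect_equal(fit$kf_hat, kf, tolerance = 1e-8)
      expect_lt(fit$e_min, 1e-12)
    }
  }
})

test_that("flat data give a zero rate constant", {
  s <- make_summary(c(1, 3, 7, 14), rep(30, 4))
  fit <- fit_first_order(s)
  expect_equal(fit$kf_hat, 0)
  expect_equal(fit$e_min, 0)
})

test_that("pooling conditions with a common kf changes nothing", {
  days <- c(1:7, 11, 14, 21, 28)
  s1 <- make_summary(days, first_order_concentration(days, 15, 30, 0.01), ce = 0.01)
  s2 <- make_summary(days, first_order_concentration(days, 15, 30, 0.1), ce = 0.1)
  pooled <- fit_first_order(list(s1, s2))
  expect_equal(pooled$kf_hat, fit_first_order(s1)$kf_hat, tolerance = 1e-8)
  expect_equal(pooled$kf_hat, fit_first_order(s2)$kf_hat, tolerance = 1e-8)
  expect_equal(pooled$n_points, 22L)
})

test_that("the pooled estimate lies between the per-condition estimates", {
  set.seed(42)
  days <- c(1, 2, 4, 7, 14)
  for (rep in 1:5) {
    m1 <- pmax(0, first_order_concentration(days, 2, 30, 0.1) + rnorm(5, 0, 2))
    m2 <- pmax(0, first_order_concentration(days, 2, 30, 0.5) + rnorm(5, 0, 2))
    s1 <- make_summary(days, m1, ce = 0.1)
    s2 <- make_summary(days, m2, ce = 0.5)
    k1 <- fit_first_order(s1)$kf_hat
    k2 <- fit_first_order(s2)$kf_hat
    kp <- fit_first_order(list(s1, s2))$kf_hat
    expect_gte(kp, min(k1, k2) - 1e-8)
    expect_lte(kp, max(k1, k2) + 1e-8)
  }
})

test_that("fit at fixed km recovers the rate ratio in the first-order limit", {
  ss <- noise_free_summaries(first_order_params(15), ce = 0.01)
  km <- 1e4 * 30
  fit <- fit_kcat_at_km(ss, km)
  expect_equal(fit$kcat_hat / km, 15, tolerance = 1e-3)
})

test_that("fit at fixed km returns zero for undegraded data", {
  s <- make_summary(c(1, 3, 7), rep(30, 3))
  fit <- fit_kcat_at_km(s, km = 10)
  expect_equal(fit$kcat_hat, 0)
  expect_equal(fit$e_min, 0)
})

test_that("fit at fixed km beats a dense brute-force scan", {
  set.seed(7)
  days <- c(1, 3, 7, 14, 28)
  means <- pmax(0, integrate_mm(days, 2, 10, 30, 0.1) + rnorm(5, 0, 1.5))
  s <- make_summary(days, means)
  for (km in c(1, 10, 1000)) {
    fit <- fit_kcat_at_km(s, km)
    grid <- seq(0, 10 * max(fit$kcat_hat, 1), length.out = 1e4)
    brute <- min(vapply(grid, function(k)
      weighted_sse(s, integrate_mm(days, k, km, 30, 0.1)), numeric(1)))
    expect_lte(fit$e_min, brute + 1e-9 * (1 + brute))
  }
})

test_that("a one-point km grid degenerates to a single fixed-km fit", {
  s <- make_summary(c(1, 3, 7), c(20, 10, 4))
  surf <- km_error_surface(s, km_grid = 10)
  single <- fit_kcat_at_km(s, 10)
  expect_equal(surf$best_kcat, single$kcat_hat, tolerance = 1e-8)
  expect_equal(surf$e_values, single$e_min, tolerance = 1e-10)
})

test_that("first-order truth yields a decreasing surface with a ratio plateau", {
  ss <- noise_free_summaries(first_order_params(15))
  surf <- km_error_surface(ss, km_grid_default(n = 40))
  expect_true(all(diff(surf$e_values) <= 1e-9 * max(surf$e_values)))
  top <- surf$km_grid >= max(surf$km_grid) / 10
  plateau <- surf$ratio[top]
  expect_lt((max(plateau) - min(plateau)) / max(plateau), 1e-3)
  expect_equal(mean(plateau), 15, tolerance = 1e-3)
  expect_equal(classify_kinetics(surf), "first_order_limit")
})

test_that("saturable truth yields an interior minimum near the true km", {
  ss <- noise_free_summaries(mm_params(kcat = 2, km = 10))
  grid <- km_grid_default(n = 40)
  surf <- km_error_surface(ss, grid)
  i <- which.min(surf$e_values)
  step <- grid[2] / grid[1]
  expect_lt(abs(log(grid[i] / 10)), log(step) * 1.0001)  # within one grid step
  expect_equal(classify_kinetics(surf), "michaelis_menten")
})

test_that("warm-started and cold-started sweeps agree", {
  set.seed(11)
  days <- c(1, 2, 4, 7, 14, 28)
  means <- pmax(0, first_order_concentration(days, 3, 30, 0.1) + rnorm(6, 0, 2))
  s <- make_summary(days, means)
  grid <- km_grid_default(n = 25)
  warm <- km_error_surface(s, grid, warm_start = TRUE)
  cold <- km_error_surface(s, grid, warm_start = FALSE)
  expect_equal(warm$e_values, cold$e_values, tolerance = 1e-6)
  expect_equal(warm$best_kcat, cold$best_kcat, tolerance = 1e-4)
})

test_that("classification handles degenerate and narrow surfaces", {
  # perfectly fittable single timepoint: flat zero surface -> ambiguous
  s <- make_summary(c(1, 2), c(30, 30))
  surf <- km_error_surface(s, km_grid_default(n = 20))
  expect_equal(classify_kinetics(surf), "ambiguous")
  narrow <- structure(list(km_grid = c(1, 10, 99), best_kcat = 1:3,
                           e_values = c(3, 2, 1), ratio = 1:3 / c(1, 10, 99)),
                      class = "error_surface")
  expect_error(classify_kinetics(narrow), "insufficient grid")
})

test_that("fit_kinetics routes to the supported model class", {
  fo <- fit_kinetics(noise_free_summaries(first_order_params(2.2), ce = 0.1),
                     km_grid_default(n = 30))
  expect_equal(fo$model_class, "first_order_limit")
  expect_equal(fo$kf_hat, 2.2, tolerance = 1e-6)
  mm <- fit_kinetics(noise_free_summaries(mm_params(2, 10)),
                     km_grid_default(n = 30))
  expect_equal(mm$model_class, "michaelis_menten")
  expect_null(mm$kf_hat)
  expect_equal(mm$mm_hat$km, 10, tolerance = 0.7)
})
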