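test_that("simulated tables have the designed shape and determinism", {
  d <- study_design(list(
    condition("c1", "ProteinaseK", 0.1, method = "continuous"),
    condition("c2", "ProteinaseK", 1, method = "continuous")))
  m <- simulate_study(d, first_order_params(2.2), noise_model(scale = 0.05),
                      seed = 3)
  expect_equal(nrow(m), 2 * 11 * 3)  # 2 conditions x 11 days x n=3
  expect_setequal(unique(m$day), c(1:7, 11, 14, 21, 28))
  expect_identical(
    m, simulate_study(d, first_order_params(2.2), noise_model(scale = 0.05),
                      seed = 3))
  d2 <- discrete_design()
  m2 <- simulate_study(d2, first_order_params(15), noise_model(scale = 0.1),
                       seed = 3)
  expect_equal(nrow(m2), 2 * 11 * 5)  # discrete method carries n = 5
  expect_true(all(m2$percent_mass_remaining >= 0))
})

test_that("zero noise puts every replicate exactly on the model curve", {
  d <- discrete_design(ce = 0.1)
  m <- simulate_study(d, first_order_params(15), noise_model(scale = 0), seed = 1)
  day1 <- m$percent_mass_remaining[m$day == 1]
  expect_equal(day1, rep(100 * exp(-1.5), 5), tolerance = 1e-10)
  # mass column consistent with percent via the cylinder volume
  vol <- pi * 1^2 * 2 / 1000
  expect_equal(m$mass_mg, m$percent_mass_remaining / 100 * 30 * vol,
               tolerance = 1e-10)
})

test_that("replicate means track the curve at small noise", {
  d <- discrete_design(ce = 0.1)
  m <- simulate_study(d, first_order_params(15), noise_model(scale = 0.02),
                      seed = 8)
  day1 <- m$percent_mass_remaining[m$day == 1]
  expect_equal(mean(day1), 100 * exp(-1.5), tolerance = 0.15)
})

test_that("per-day noise models are honored", {
  d <- study_design(list(condition("a", "ProteinaseK", 0.1)),
                    sampling_days = c(1, 2, 3))
  sds <- c(5, 1, 0.1)
  m <- simulate_study(d, first_order_params(1),
                      noise_model("per_day_sd", sds), seed = 4)
  expect_equal(nrow(m), 9)
  expect_error(
    simulate_study(d, first_order_params(1), noise_model("per_day_sd", c(1, 2))),
    "sampling days")
})

test_that("missing truth for a condition is a configuration error", {
  d <- discrete_design()
  expect_error(
    simulate_study(d, list(d0.01 = first_order_params(15)), noise_model()),
    "configuration error")
})

test_that("replicate summaries use the n-1 standard deviation and floors", {
  m <- data.frame(condition_id = "x", enzyme = "ProteinaseK",
                  enzyme_conc_U_per_mL = 0.1, wa_hours = 12,
                  method = "discrete", radius_mm = 1, height_mm = 2,
                  day = c(1, 1, 1, 2, 2, 2, 3),
                  replicate = c(1:3, 1:3, 1),
                  percent_mass_remaining = c(100 / 3, 200 / 3, 100,
                                             50, 50, 50, 10))
  s <- summarize_replicates(m, cs0 = 30)
  expect_equal(s$means, c(20, 15, 3))           # percent -> mg/mL at cs0 = 30
  expect_equal(s$sds[1], 10)                    # replicates {10,20,30} mg/mL
  expect_equal(s$sds[2], 0)                     # identical replicates
  expect_true(is.na(s$sds[3]))                  # single replicate
  expect_equal(s$ns, c(3L, 3L, 1L))
  # floored weight = 1/(0.01*30)^2 on degenerate days
  expect_equal(s$weights[2], 1 / 0.3^2)
  expect_equal(s$weights[3], 1 / 0.3^2)
  expect_identical(s$floored, c(FALSE, TRUE, TRUE))
  expect_equal(s$weights[1], 1 / 100)
})

test_that("mass-based tables are converted through the scaffold geometry", {
  vol <- pi * 1^2 * 2 / 1000
  m <- data.frame(condition_id = "x", enzyme = "ProteinaseK",
                  enzyme_conc_U_per_mL = 0.1, wa_hours = 12,
                  method = "discrete", radius_mm = 1, height_mm = 2,
                  day = c(1, 1), replicate = 1:2,
                  percent_mass_remaining = c(50, 60),
                  mass_mg = c(15, 18) * vol)
  s <- summarize_replicates(m, cs0 = 30)
  expect_equal(s$means, 16.5, tolerance = 1e-10)
})

test_that("measurement CSV round-trips and validates", {
  d <- discrete_design()
  m <- simulate_study(d, first_order_params(15), noise_model(scale = 0.1),
                      seed = 5)
  path <- tempfile(fileext = ".csv")
  write_measurements(m, path)
  back <- read_measurements(path)
  expect_equal(back$percent_mass_remaining, m$percent_mass_remaining,
               tolerance = 1e-9)
  s1 <- summarize_replicates(m, "d0.1")
  s2 <- summarize_replicates(back, "d0.1", cs0 = 30)
  expect_equal(s1$means, s2$means, tolerance = 1e-9)
  bad <- tempfile(fileext = ".csv")
  utils::write.csv(data.frame(day = 1), bad, row.names = FALSE)
  expect_error(read_measurements(bad), "lacks columns")
})

test_that("simulate -> summarize -> fit recovers the generating constant", {
  # Round-trip calibration at 10% noise: the 3-SD recovery bound is a
  # statistical statement (the truncated-Gaussian generator biases cells whose
  # curve sits near zero), so it is asserted as aggregate coverage over
  # 3 outer replicate datasets per (kf, ce) cell rather than per single run.
  runs <- 0L; hits <- 0L
  cell <- 0L
  for (kf in c(0.2, 1, 2.2, 15)) {
    for (ce in c(0.01, 0.1, 1)) {
      cell <- cell + 1L
      d <- discrete_design(ce = ce)
      for (rep in 1:3) {
        m <- simulate_study(d, first_order_params(kf),
                            noise_model(scale = 0.1),
                            seed = 100 * cell + rep)
        s <- summarize_replicates(m)
        mc <- mc_first_order_uncertainty(s, n_sets = 200,
                                         seed = 100 * cell + rep + 50)
        runs <- runs + 1L
        hits <- hits + (abs(mc$kf_mean - kf) < 3 * max(mc$kf_sd, 1e-6))
      }
    }
  }
  expect_gte(hits / runs, 0.8)
})

test_that("scenario presets build runnable designs", {
  tab <- scenario_presets()
  expect_gte(nrow(tab), 10)
  sc <- scenario_presets("discrete_pk_12h_pooled")
  expect_s3_class(sc$design, "study_design")
  expect_equal(sc$truth$kf, 15)
  expect_equal(vapply(sc$design$conditions, function(x) x$enzyme_conc,
                      numeric(1)), c(0.01, 0.1))
  expect_error(scenario_presets("nope"), "unknown scenario")
})
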