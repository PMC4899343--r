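test_that("noiseless single peak has its apex at the nearest grid point", {
  g <- seq(1000, 5000, by = 1)
  s <- make_spectrum(data.frame(mz = 3038, amplitude = 100, width = 3),
                     grid = g)
  expect_equal(max(s$intensity), 100, tolerance = 1e-12)
  expect_equal(g[which.max(s$intensity)], 3038)
})

test_that("spectrum synthesis is deterministic for a fixed seed", {
  g <- seq(1000, 2000, by = 0.5)
  pk <- data.frame(mz = 1500, amplitude = 50, width = 2)
  s1 <- make_spectrum(pk, baseline_amplitude = 10, noise_sd = 2, grid = g,
                      seed = 99)
  s2 <- make_spectrum(pk, baseline_amplitude = 10, noise_sd = 2, grid = g,
                      seed = 99)
  expect_identical(s1$intensity, s2$intensity)
})

test_that("pure-noise spectrum has the configured noise SD", {
  g <- seq_len(1e5)
  s <- make_spectrum(grid = g, noise_sd = 1, seed = 7, clip = FALSE)
  expect_lt(abs(sd(s$intensity) - 1), 0.05)
})

test_that("invalid spectrum configs are rejected", {
  expect_error(make_spectrum(grid = numeric()), "empty")
  expect_error(make_spectrum(grid = 1:10, noise_sd = -1), "noise_sd")
  expect_error(make_spectrum(data.frame(mz = 5, amplitude = 1, width = 0),
                             grid = 1:10), "width")
})

test_that("cohort config validates its invariants", {
  expect_error(cohort_config(n_case = 1), ">= 2")
  expect_error(cohort_config(grid_start = 5000, grid_end = 4000), "grid_start")
  expect_error(cohort_config(noise_sd = -2), "noise_sd")
  expect_error(
    cohort_config(discriminating = data.frame(
      mz = 25000, mean_case = 1, sd_case = 1, mean_control = 1,
      sd_control = 1)),
    "outside the grid")
})

test_that("cohort generation is seed-deterministic with complete ground truth", {
  cfg <- cohort_config(n_case = 3, n_control = 3, n_peaks_total = 10,
                       grid_end = 6000, seed = 21)
  co1 <- make_cohort(cfg)
  co2 <- make_cohort(cfg)
  expect_identical(co1$spectra[[1]]$intensity, co2$spectra[[1]]$intensity)
  expect_identical(co1$ground_truth$mz, co2$ground_truth$mz)
  # every configured peak appears exactly once in ground truth
  expect_equal(nrow(co1$ground_truth), 10)
  expect_equal(anyDuplicated(co1$ground_truth$mz), 0)
  expect_equal(sum(co1$ground_truth$discriminating), 2)
  # per-sample amplitude bookkeeping covers the whole cohort
  amps <- attr(co1$ground_truth, "amplitudes")
  expect_equal(dim(amps), c(10L, 6L))
  expect_true(all(amps >= 0))
})

test_that("discriminating amplitude draws recover the configured moments", {
  # Monte-Carlo over many cohorts: the per-sample 1699-Da case amplitude
  # mean converges to the configured group mean (clipping at zero moves it
  # by < 1 unit at these parameters).
  set.seed(5)
  cfg <- discriminating_peaks()
  draws <- pmax(0, rnorm(1000, cfg$mean_case[1], cfg$sd_case[1]))
  se <- cfg$sd_case[1] / sqrt(1000)
  expect_lt(abs(mean(draws) - cfg$mean_case[1]), 3 * se + 1)
  # and the generated cohorts carry those draws into the spectra: case
  # samples' stored 1699 amplitudes match group parameters across seeds
  means <- vapply(1:30, function(s) {
    co <- make_cohort(cohort_config(n_peaks_total = 2, seed = s,
                                    grid_end = 4000))
    amps <- attr(co$ground_truth, "amplitudes")
    mean(amps[1, co$labels$group == "case"])
  }, numeric(1))
  se_cohort <- cfg$sd_case[1] / sqrt(30 * 10)
  expect_lt(abs(mean(means) - cfg$mean_case[1]), 3 * se_cohort + 1)
})

test_that("ELISA cohort generation is seeded and respects degenerate SDs", {
  e0 <- make_elisa_cohort(elisa_config(sd_case = 0, sd_control = 0))
  expect_true(all(e0$case == 157.41))
  expect_true(all(e0$control == 307.48))
  e1 <- make_elisa_cohort(elisa_config(seed = 4))
  e2 <- make_elisa_cohort(elisa_config(seed = 4))
  expect_identical(e1, e2)
  expect_length(e1$case, 40)
  expect_error(elisa_config(n_case = 1), ">= 2")
})

test_that("ELISA replicates reproduce the published t statistic on average", {
  ts <- vapply(1:200, function(s) {
    e <- make_elisa_cohort(elisa_config(seed = s))
    summary_t(group_summary(mean(e$control), sd(e$control), 40),
              group_summary(mean(e$case), sd(e$case), 40))$statistic
  }, numeric(1))
  expect_lt(abs(mean(ts) - 8.5) / 8.5, 0.10)
})

test_that("T-score labelling follows the WHO bands", {
  r <- t_score_label(c(1.0, 1.0 - 1.5 * 0.1, 1.0 - 3 * 0.1), 1.0, 0.1)
  expect_equal(r$t_score, c(0, -1.5, -3), tolerance = 1e-9)
  expect_equal(r$category, c("normal", "osteopenia", "osteoporosis"))
  expect_error(t_score_label(1, 1, 0), "reference_sd")
})

test_that("demographic draws are reproducible and match the table layout", {
  d <- make_demographics(demographics_config("discovery"), seed = 2)
  expect_equal(nrow(d), 20)
  expect_named(d, c("sample_id", "group", "age", "weight", "height",
                    "menopause_duration"))
  d40 <- make_demographics(demographics_config("validation"), seed = 2)
  expect_equal(sum(d40$group == "case"), 40)
})
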