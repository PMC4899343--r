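test_that("noise estimation recovers a known sigma and resists one big peak", {
  set.seed(4)
  g <- seq(1000, 3000, by = 0.5)
  s <- mass_spectrum("a", g, rnorm(length(g), 0, 1))
  est <- estimate_noise(s, window = 250)
  interior <- seq(500, length(g) - 500)
  expect_lt(max(abs(est[interior] - 1)), 0.2)
  # all-zero spectrum -> zero noise
  z <- mass_spectrum("z", g, rep(0, length(g)))
  expect_true(all(estimate_noise(z, window = 250) == 0))
  # robustness: a huge peak inflates the local estimate less than 2x
  sp <- mass_spectrum("p", g, rnorm(length(g), 0, 1) +
                        1000 * exp(-(g - 2000)^2 / (2 * 9)))
  est_p <- estimate_noise(sp, window = 250)
  expect_lt(est_p[which.min(abs(g - 2000))], 2)
  expect_error(estimate_noise(s, window = 5000), "span")
})

test_that("peak detection finds the apex with the constructed SNR", {
  set.seed(9)
  g <- seq(1000, 3000, by = 0.5)
  s <- mass_spectrum("a", g, rnorm(length(g), 0, 1) +
                       100 * exp(-(g - 2000)^2 / (2 * 16)))
  pk <- detect_peaks(s, snr_min = 3, window = 250)
  top <- pk[which.max(pk$intensity), ]
  expect_lt(abs(top$mz - 2000), 1.5)
  expect_gt(top$snr, 50)   # ~100 against unit noise
  expect_lt(top$snr, 200)
})

test_that("sub-threshold peaks are filtered and monotone spectra are empty", {
  # amplitude-2 peak against a unit noise floor: SNR = 2 < 3 -> removed
  g <- seq(1000, 3000, by = 0.5)
  s <- mass_spectrum("a", g, 2 * exp(-(g - 2000)^2 / (2 * 16)))
  unit_noise <- rep(1, length(g))
  kept <- detect_peaks(s, snr_min = 3, noise = unit_noise)
  expect_equal(nrow(kept), 0)
  found <- detect_peaks(s, snr_min = 0, noise = unit_noise)
  expect_equal(found$mz, 2000)
  expect_equal(found$snr, 2, tolerance = 1e-9)
  mono <- mass_spectrum("m", g, seq_along(g) * 0.01)
  expect_equal(nrow(detect_peaks(mono)), 0)
})

test_that("snr filtering is monotone: lower threshold is a superset", {
  set.seed(13)
  g <- seq(1000, 2000, by = 0.5)
  s <- mass_spectrum("a", g, abs(rnorm(length(g), 0, 1)) +
                       30 * exp(-(g - 1500)^2 / (2 * 4)))
  p0 <- detect_peaks(s, snr_min = 0, window = 200)
  p3 <- detect_peaks(s, snr_min = 3, window = 200)
  expect_true(all(p3$mz %in% p0$mz))
  expect_gte(nrow(p0), nrow(p3))
})

test_that("clustering joins peaks inside 0.3% and splits beyond it", {
  mk <- function(mz, id) data.frame(mz = mz, intensity = 10, snr = 5)
  cl <- cluster_peaks(list(A = mk(1000.0), B = mk(1002.0)),
                      tolerance_frac = 0.003)
  expect_length(cl, 1)
  expect_equal(cl[[1]]$prevalence, 1)
  cl2 <- cluster_peaks(list(A = mk(1000.0), B = mk(1005.0)),
                       tolerance_frac = 0.003)
  expect_length(cl2, 2)
})

test_that("clustering matches the component oracle on random instances", {
  skip_if_not_installed("igraph")
  set.seed(17)
  for (i in 1:30) {
    inst <- make_cluster_instance()
    per_sample <- split(inst[c("mz", "intensity")], inst$sample)
    cl <- cluster_peaks(per_sample, tolerance_frac = 0.003)
    oracle <- components_cluster_oracle(sort(inst$mz), 0.003)
    # same number of clusters and same group sizes
    expect_equal(length(cl), max(oracle))
    expect_equal(sort(vapply(cl, function(c) nrow(c$members), integer(1))),
                 sort(as.integer(table(oracle))))
  }
})

test_that("clustering is invariant to sample order and caps one member per sample", {
  set.seed(23)
  inst <- make_cluster_instance()
  per_sample <- split(inst[c("mz", "intensity")], inst$sample)
  cl1 <- cluster_peaks(per_sample)
  cl2 <- cluster_peaks(rev(per_sample))
  expect_equal(vapply(cl1, `[[`, numeric(1), "representative_mz"),
               vapply(cl2, `[[`, numeric(1), "representative_mz"))
  # same-sample conflict: more intense member wins, loser becomes singleton
  conflicted <- list(
    A = data.frame(mz = c(2000.0, 2001.0), intensity = c(5, 50)),
    B = data.frame(mz = 2000.5, intensity = 20))
  cl3 <- cluster_peaks(conflicted)
  for (c in cl3)
    expect_equal(anyDuplicated(c$members$sample_id), 0)
  main <- cl3[[which.max(vapply(cl3, function(c) nrow(c$members), integer(1)))]]
  expect_equal(sort(main$members$intensity), c(20, 50))
})

test_that("prevalence filtering keeps the 10% boundary and drops below it", {
  mk_cluster <- function(n_members, n_samples) {
    peaks <- lapply(seq_len(n_samples), function(i) {
      if (i <= n_members) data.frame(mz = 5000 + 0.01 * i, intensity = 10)
      else data.frame(mz = numeric(), intensity = numeric())
    })
    names(peaks) <- paste0("s", seq_len(n_samples))
    cluster_peaks(peaks)
  }
  cl1 <- mk_cluster(1, 20)   # 5% prevalence
  expect_length(prevalence_filter(cl1, 0.10), 0)
  cl2 <- mk_cluster(2, 20)   # exactly 10%
  expect_length(prevalence_filter(cl2, 0.10), 1)
  cl20 <- mk_cluster(20, 20) # ubiquitous
  expect_length(prevalence_filter(cl20, 0.10), 1)
})

test_that("build_matrix places absences as zero and validates inputs", {
  peaks <- list(
    a = data.frame(mz = c(1500, 2500), intensity = c(10, 20)),
    b = data.frame(mz = 1500.5, intensity = 12),
    c = data.frame(mz = c(1500.2, 2500.9), intensity = c(9, 18)),
    d = data.frame(mz = 2501.1, intensity = 25))
  labels <- data.frame(sample_id = c("a", "b", "c", "d"),
                       group = c("case", "case", "control", "control"))
  pm <- build_matrix(cluster_peaks(peaks), labels)
  expect_equal(dim(pm$intensity), c(2L, 4L))
  expect_equal(sum(pm$intensity == 0), 2)  # b misses 2500, d misses 1500
  expect_true(all(diff(pm$mz) > 0))
  expect_error(build_matrix(cluster_peaks(peaks),
                            labels[1:3, ]), "not in the label table")
  empty <- cluster_peaks(list(a = data.frame(mz = numeric(),
                                             intensity = numeric())))
  expect_error(build_matrix(empty, labels), "no clusters")
})

test_that("the default cohort yields complete truth recovery with bounded excess", {
  co <- make_cohort(cohort_config(seed = 31))
  prep <- preprocess_spectra(co$spectra,
                             preprocess_config(normalization = "none"))
  # reference SNR to raw-signal noise, as the pipeline does
  noise <- lapply(co$spectra, function(s)
    estimate_noise(crop_low_mass(s, 1000), window = 250))
  pks <- lapply(seq_along(prep), function(i)
    detect_peaks(prep[[i]], snr_min = 3, window = 250, noise = noise[[i]]))
  names(pks) <- names(prep)
  clf <- prevalence_filter(cluster_peaks(pks))
  pm <- build_matrix(clf, co$labels)
  truth <- co$ground_truth$mz
  recovered <- vapply(truth, function(m)
    any(abs(pm$mz - m) <= 0.003 * m), logical(1))
  expect_gte(mean(recovered), 0.97)
  expect_lte(nrow(pm$intensity), 1.45 * 133)
  expect_gte(nrow(pm$intensity), 133)
})
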