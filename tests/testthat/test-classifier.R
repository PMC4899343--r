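test_that("LOOCV is perfect in the separable limit with exactly n folds", {
  toy <- toy_separable_matrix(n_per_group = 6)
  rep <- loocv(toy$x, toy$labels)
  expect_equal(rep$sensitivity, 1)
  expect_equal(rep$specificity, 1)
  expect_equal(rep$youden_j, 1)
  expect_equal(nrow(rep$predictions), 12)
  expect_equal(rep$tp + rep$fn + rep$tn + rep$fp, 12)
  # decision values separate the groups with the case-positive convention
  expect_true(all(rep$predictions$decision[toy$labels == "case"] > 0))
  expect_true(all(rep$predictions$decision[toy$labels == "control"] < 0))
})

test_that("LOOCV on label-free data sits at chance level", {
  set.seed(18)
  accs <- replicate(60, {
    x <- matrix(rnorm(20 * 3), 20, 3, dimnames = list(NULL, c("a", "b", "c")))
    loocv(x, sample(rep(c("case", "control"), each = 10)))$accuracy
  })
  expect_lt(abs(mean(accs) - 0.5), 0.15)
})

test_that("held-out samples cannot leak into standardization or training", {
  set.seed(19)
  x <- cbind(sig = c(rnorm(6, 2, 1), rnorm(6, -2, 1)), jnk = rnorm(12))
  labs <- rep(c("case", "control"), each = 6)
  spec <- classifier_spec()
  r1 <- loocv(x, labs, spec)
  # fold isolation oracle: for each i, train on x[-i] (standardized on
  # x[-i] only) and predict x[i]; must reproduce loocv exactly
  for (i in c(1, 5, 12)) {
    xtr <- x[-i, ]
    ctr <- colMeans(xtr); scl <- apply(xtr, 2, sd)
    fit <- e1071::svm(scale(xtr, ctr, scl),
                      factor(labs[-i], levels = c("control", "case")),
                      type = "C-classification", kernel = "radial",
                      gamma = spec$gamma, cost = spec$cost, scale = FALSE)
    p <- predict(fit, scale(x[i, , drop = FALSE], ctr, scl))
    expect_identical(r1$predictions$predicted[i], as.character(p))
  }
  # the held-out sample's own label is irrelevant to its prediction
  labs2 <- labs
  labs2[1] <- "control"
  r2 <- loocv(x, labs2, spec)
  expect_identical(r1$predictions$predicted[1], r2$predictions$predicted[1])
})

test_that("single-class training folds are refused", {
  x <- matrix(rnorm(6), 3, 2, dimnames = list(NULL, c("a", "b")))
  expect_error(loocv(x, c("case", "control", "control")), "single class")
})

test_that("GA with one candidate returns it; the trace never decreases", {
  toy <- toy_separable_matrix()
  one <- ga_svm(toy$x[, 1, drop = FALSE], toy$labels, seed = 1)
  expect_equal(one$subset, 1L)
  full <- ga_svm(toy$x, toy$labels,
                 ga = ga_params(population = 12, generations = 8,
                                subset_min = 1, subset_max = 2, seed = 2))
  expect_true(all(diff(full$trace) >= 0))
})

test_that("GA selection is deterministic for a fixed seed", {
  set.seed(20)
  x <- matrix(rnorm(16 * 6), 16, 6,
              dimnames = list(NULL, sprintf("%d", 1:6)))
  x[, 2] <- x[, 2] + rep(c(2, -2), each = 8)
  labs <- rep(c("case", "control"), each = 8)
  g <- ga_params(population = 10, generations = 6, subset_min = 1,
                 subset_max = 3, seed = 33)
  s1 <- ga_select(x, labs, ga = g)
  s2 <- ga_select(x, labs, ga = g)
  expect_identical(s1$subset, s2$subset)
  expect_identical(s1$trace, s2$trace)
})

test_that("GA finds the exhaustive-optimal pair on a signal-bearing problem", {
  set.seed(27)
  n <- 10
  disc <- discriminating_peaks()
  x <- cbind(
    pmax(0, c(rnorm(n, disc$mean_case[1], disc$sd_case[1]),
              rnorm(n, disc$mean_control[1], disc$sd_control[1]))),
    pmax(0, c(rnorm(n, disc$mean_case[2], disc$sd_case[2]),
              rnorm(n, disc$mean_control[2], disc$sd_control[2]))),
    matrix(rlnorm(2 * n * 8, log(150), 0.4), 2 * n, 8))
  colnames(x) <- sprintf("f%02d", 1:10)
  labs <- rep(c("case", "control"), each = n)
  spec <- classifier_spec()
  sel <- ga_select(x, labs, ga = ga_params(subset_min = 2, subset_max = 2,
                                           seed = 7), spec = spec)
  expect_equal(sel$fitness, exhaustive_best_pair_fitness(x, labs, spec),
               tolerance = 1e-12)
})

test_that("the final model exposes scatter coordinates matching an eigen oracle", {
  toy <- toy_separable_matrix()
  fm <- fit_final_model(toy$x, toy$labels)
  expect_equal(nrow(fm$scatter), 12)
  # decision values separate groups in full-data training too
  expect_true(all(fm$scatter$decision[toy$labels == "case"] > 0))
  expect_true(all(fm$scatter$decision[toy$labels == "control"] < 0))
  # PC1 from an independent eigendecomposition of the covariance
  xs <- scale(toy$x, center = fm$center, scale = fm$scale)
  ev <- eigen(crossprod(xs))$vectors[, 1]
  oracle_pc1 <- as.numeric(xs %*% ev)
  # sign of a principal axis is arbitrary
  err <- min(max(abs(fm$scatter$pc1 - oracle_pc1)),
             max(abs(fm$scatter$pc1 + oracle_pc1)))
  expect_lt(err, 1e-8)
})

test_that("ga_svm methods print, summarize, predict and plot", {
  toy <- toy_separable_matrix()
  m <- ga_svm(toy$x, toy$labels,
              ga = ga_params(population = 8, generations = 4,
                             subset_min = 1, subset_max = 2, seed = 3))
  expect_output(print(m), "GA \\+ SVM")
  expect_output(print(summary(m)), "gamma")
  pr <- predict(m, toy$x)
  expect_equal(pr$predicted, toy$labels)
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(m))
})
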