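test_that("rank-sum test gives the exact enumeration p on textbook input", {
  r <- wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$p_value, 0.1, tolerance = 1e-12)
  expect_true(r$exact)
  expect_equal(r$statistic, 6)  # ranks 1+2+3
})

test_that("identical samples give p = 1 and monotone transforms change nothing", {
  x <- c(3, 1, 4, 1, 5)
  expect_equal(wilcoxon_rank_sum(x, x)$p_value, 1)
  set.seed(6)
  a <- runif(6); b <- runif(7) + 0.3
  p1 <- wilcoxon_rank_sum(a, b)$p_value
  p2 <- wilcoxon_rank_sum(exp(a), exp(b))$p_value  # strictly monotone map
  expect_equal(p1, p2)
  expect_error(wilcoxon_rank_sum(numeric(), 1:3), "non-empty")
})

test_that("exact p equals full permutation enumeration on random instances", {
  set.seed(14)
  for (i in 1:40) {
    n1 <- sample(2:5, 1); n2 <- sample(2:5, 1)
    x <- runif(n1); y <- runif(n2, 0.2, 1.2)
    r <- wilcoxon_rank_sum(x, y)
    expect_true(r$exact)
    expect_equal(r$p_value, enumeration_wilcoxon_p(x, y), tolerance = 1e-12)
  }
})

test_that("screening returns survivors sorted by p with median directions", {
  set.seed(15)
  m <- rbind(c(rnorm(8, 100, 5), rnorm(8, 100, 5)),   # null
             c(rnorm(8, 200, 10), rnorm(8, 100, 10)), # up in cases
             c(rnorm(8, 50, 5), rnorm(8, 120, 5)))    # down in cases
  colnames(m) <- paste0("s", 1:16)
  labels <- data.frame(sample_id = paste0("s", 1:16),
                       group = rep(c("case", "control"), each = 8))
  pm <- peak_matrix(m, c(1500, 1699, 3038), labels)
  sc <- screen_features(pm, alpha = 0.05)
  expect_setequal(sc$mz, c(1699, 3038))
  expect_equal(sc$direction[sc$mz == 1699], "up")
  expect_equal(sc$direction[sc$mz == 3038], "down")
  expect_true(!is.unsorted(sc$p_value))
  # identical rows across groups -> nothing survives
  flat <- peak_matrix(matrix(rep(c(5, 7), 8), nrow = 1,
                             dimnames = list(NULL, paste0("s", 1:16))),
                      1200, labels)
  expect_equal(nrow(screen_features(flat, alpha = 0.05)), 0)
  # alpha 0 boundary -> nothing survives
  expect_equal(nrow(screen_features(pm, alpha = 0)), 0)
})

test_that("summary t reproduces all published table statistics to 0.01", {
  # secretin ELISA validation: printed t = 8.523
  t5 <- summary_t(group_summary(307.48, 74.68, 40),
                  group_summary(157.41, 82.62, 40))
  expect_lt(abs(round(t5$statistic, 2) - 8.52), 0.011)
  # discovery-cohort clinical features: printed 0.83 / 0.44 / 0.20 / 0.52
  t1 <- demographics_config("discovery")
  printed1 <- c(0.83, 0.44, 0.20, 0.52)
  for (i in 1:4) {
    t <- summary_t(group_summary(t1$mean_case[i], t1$sd_case[i], 10),
                   group_summary(t1$mean_control[i], t1$sd_control[i], 10))
    expect_lt(abs(round(abs(t$statistic), 2) - printed1[i]), 0.011)
    expect_gt(t$p_value, 0.05)
  }
  # validation-cohort clinical features: printed 0.56 / 0.80 / 0.47 / 0.81
  t4 <- demographics_config("validation")
  printed4 <- c(0.56, 0.80, 0.47, 0.81)
  for (i in 1:4) {
    t <- summary_t(group_summary(t4$mean_case[i], t4$sd_case[i], 40),
                   group_summary(t4$mean_control[i], t4$sd_control[i], 40))
    expect_lt(abs(round(abs(t$statistic), 2) - printed4[i]), 0.011)
    expect_gt(t$p_value, 0.05)
  }
})

test_that("summary t handles degenerate and invalid summaries", {
  expect_equal(summary_t(group_summary(5, 0, 4),
                         group_summary(5, 0, 4))$statistic, 0)
  expect_error(group_summary(1, -1, 5), "sd")
  expect_error(group_summary(1, 1, 1), "n must be")
})

test_that("Youden index arithmetic and threshold scan match brute force", {
  expect_equal(youden(1, 1), 1)
  expect_equal(youden(0.5, 0.5), 0)
  expect_equal(youden(0.90, 1.00), 0.90)
  set.seed(16)
  for (i in 1:25) {
    v <- c(rnorm(8, 1), rnorm(8, 0))
    labs <- rep(c("case", "control"), each = 8)
    bc <- best_cut(v, labs)
    expect_equal(bc$J, brute_force_best_J(v, labs), tolerance = 1e-12)
    expect_equal(bc$J, bc$sensitivity + bc$specificity - 1)
  }
  # perfectly separated: J = 1
  sep <- best_cut(c(10, 11, 12, 0, 1, 2),
                  c("case", "case", "case", "control", "control", "control"))
  expect_equal(sep$J, 1)
  expect_error(best_cut(1:4, rep("case", 4)), "both")
})
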