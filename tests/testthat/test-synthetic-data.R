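test_that("default design reproduces the 6-group x 3-replicate x 2-sex layout", {
  d <- make_design(sim_config())
  expect_equal(nrow(d), 36)
  expect_equal(as.vector(table(d$sex)), c(18, 18))
  expect_true(all(table(d$group) == 6))
  expect_true(all(table(d$group, d$sex) == 3))
  expect_false(anyDuplicated(d$sample_id) > 0)
  expect_true(all(d$covariate >= 0))
})

test_that("zero covariate noise gives exact group means", {
  cfg <- sim_config(covariate_sd = 0)
  d <- make_design(cfg)
  expect_equal(d$covariate, unname(cfg$covariate_means[d$group]))
})

test_that("generator is deterministic under the config seed", {
  cfg <- sim_config(n_proteins = 80, seed = 11)
  expect_identical(make_design(cfg), make_design(cfg))
  s1 <- simulate_study(cfg)
  s2 <- simulate_study(cfg)
  expect_identical(s1$matrix$values, s2$matrix$values)
  expect_identical(s1$truth, s2$truth)
  s3 <- simulate_study(sim_config(n_proteins = 80, seed = 12))
  expect_false(identical(s1$matrix$values, s3$matrix$values))
})

test_that("invalid configs are rejected with the offending field named", {
  expect_error(sim_config(class_proportions = c(pos_corr = 0.5, neg_corr = 0.5,
                                                sex_diff = 0.5, null = 0)),
               "class_proportions")
  expect_error(sim_config(replicates_per_group = 0), "replicates_per_group")
  expect_error(sim_config(residual_sd_log2 = 0), "residual_sd_log2")
  expect_error(sim_config(covariate_means = c(WT00 = -1, GL00 = 0, GL01 = 5,
                                              GL05 = 15, GL40 = 150,
                                              GLR40 = 150)),
               "covariate_means")
  expect_error(sim_config(decoy_fraction = 1), "decoy_fraction")
})

test_that("class counts follow the proportions exactly (largest remainder)", {
  cfg <- sim_config(n_proteins = 103, decoy_fraction = 0.1,
                    class_proportions = c(pos_corr = 0.21, neg_corr = 0.22,
                                          sex_diff = 0.17, null = 0.40))
  st <- simulate_study(cfg)
  counts <- table(st$truth$class)
  expect_equal(unname(counts[["decoy"]]), round(0.1 * 103))
  n_real <- 103 - round(0.1 * 103)
  # largest-remainder apportionment recomputed independently
  quota <- n_real * c(0.21, 0.22, 0.17, 0.40)
  base <- floor(quota)
  extra <- order(quota - base, decreasing = TRUE)[seq_len(n_real - sum(base))]
  base[extra] <- base[extra] + 1
  expect_equal(as.integer(counts[c("pos_corr", "neg_corr", "sex_diff",
                                   "null")]),
               as.integer(base))
})

test_that("noise-free limit: log2 difference equals slope times covariate difference", {
  cfg <- no_dropout(n_proteins = 40, residual_sd_log2 = 1e-9,
                    covariate_sd = 0, decoy_fraction = 0,
                    class_proportions = c(pos_corr = 1, neg_corr = 0,
                                          sex_diff = 0, null = 0),
                    slope_log2_per_unit = 0.02, seed = 3)
  st <- simulate_study(cfg)
  expect_false(anyNA(st$matrix$values))
  l2 <- log2(st$matrix$values)
  i <- which(st$design$sample_id == "F_GL40_R1")
  j <- which(st$design$sample_id == "F_GL00_R1")
  dcov <- st$design$covariate[i] - st$design$covariate[j]
  expect_equal(unname(l2[, i] - l2[, j]), rep(0.02 * dcov, 40),
               tolerance = 1e-6)
})

test_that("zero dropout steepness yields a constant 0.5 missing rate", {
  cfg <- sim_config(n_proteins = 1000, dropout_steepness = 0, seed = 5)
  st <- simulate_study(cfg)
  n_cells <- prod(dim(st$matrix$values))
  rate <- mean(is.na(st$matrix$values))
  expect_lt(abs(rate - 0.5), 3 * sqrt(0.25 / n_cells))
})

test_that("null proteins have zero expected group difference (Monte Carlo)", {
  cfg <- no_dropout(n_proteins = 250, decoy_fraction = 0,
                    class_proportions = c(pos_corr = 0, neg_corr = 0,
                                          sex_diff = 0, null = 1),
                    residual_sd_log2 = 0.5, seed = 9)
  st <- simulate_study(cfg)
  l2 <- log2(st$matrix$values)
  a <- condition_samples(st$design, "GL40", "F")
  b <- condition_samples(st$design, "GL00", "F")
  diffs <- rowMeans(l2[, a]) - rowMeans(l2[, b])
  # each diff has sd residual_sd * sqrt(2/3); mean over 250 proteins
  expect_lt(abs(mean(diffs)), 3 * 0.5 * sqrt(2 / 3) / sqrt(250))
})

test_that("missingness is monotone non-increasing in true intensity (MNAR)", {
  cfg <- sim_config(n_proteins = 2000, seed = 21)
  st <- simulate_study(cfg)
  bins <- cut(as.vector(st$true_log2),
              stats::quantile(st$true_log2, seq(0, 1, 0.2)),
              include.lowest = TRUE)
  rates <- tapply(as.vector(is.na(st$matrix$values)), bins, mean)
  expect_true(all(diff(rates) <= 0.01))
  expect_gt(rates[1], rates[length(rates)])
})

test_that("regression on observed values recovers the simulated slope", {
  cfg <- no_dropout(n_proteins = 30, residual_sd_log2 = 0.05,
                    decoy_fraction = 0,
                    class_proportions = c(pos_corr = 1, neg_corr = 0,
                                          sex_diff = 0, null = 0),
                    slope_log2_per_unit = 0.02, seed = 13)
  st <- simulate_study(cfg)
  for (i in c(1, 15, 30)) {
    fit <- summary(stats::lm(log2(st$matrix$values[i, ]) ~ st$design$covariate))
    est <- fit$coefficients[2, ]
    expect_lt(abs(est[["Estimate"]] - 0.02), 3 * est[["Std. Error"]])
  }
})
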