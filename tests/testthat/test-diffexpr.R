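test_that("group statistics: means, ratio and log2 fold change", {
  d <- tiny_design(groups = c("A", "B"))
  m1 <- tiny_matrix(matrix(c(8, 8, 8, 2, 2, 2), 1), d)
  spec <- comparison_spec(d, "A", "B", sex = "F")
  gs <- group_stats(m1, spec)
  expect_equal(gs$ratio, 4)
  expect_equal(gs$log2fc, 2)
  expect_equal(gs$s_g_sq, 0)
  expect_equal(attr(gs, "d_g"), 4L)

  same <- tiny_matrix(matrix(c(5, 7, 9, 5, 7, 9), 1), d)
  gs2 <- group_stats(same, spec)
  expect_equal(gs2$ratio, 1)
  expect_equal(gs2$log2fc, 0)

  # ratio is a ratio of arithmetic means, not 2^log2fc
  geo <- tiny_matrix(matrix(c(4, 8, 16, 1, 2, 4), 1), d)
  gs3 <- group_stats(geo, spec)
  expect_equal(gs3$log2fc, 2)
  expect_equal(gs3$ratio, 4)
  expect_equal(gs3$ratio, (4 + 8 + 16) / (1 + 2 + 4))
})

test_that("robust Z-scores use median/MAD scaling and reject degenerate spreads", {
  x <- c(-2, -1, 0, 1, 2, -2, -1, 0, 1, 2)
  z <- log_ratio_zscores(x)
  # brute-force oracle
  expect_equal(z, (x - median(x)) / (median(abs(x - median(x))) * 1.4826))
  expect_equal(z[x == 2][1], 2 / 1.4826, tolerance = 1e-12)
  expect_equal(z[x == 0][1], 0)

  expect_error(log_ratio_zscores(c(rep(0, 10), 4)), "MAD")
  expect_error(log_ratio_zscores(c(0, 0, 4)), ">= 10")
})

test_that("empirical-Bayes fit recovers generative hyperparameters", {
  set.seed(101)
  d0 <- 4; s0 <- 0.04; d_g <- 4; n <- 5000
  s2 <- s0 * (rchisq(n, d_g) / d_g) / (rchisq(n, d0) / d0)
  fit <- fit_ebayes(s2, d_g)
  expect_lt(abs(fit$d0 - d0) / d0, 0.2)
  expect_lt(abs(fit$s0_sq - s0) / s0, 0.1)

  # moderated variance is a convex combination
  s2t <- moderated_variance(s2, fit)
  expect_true(all(s2t >= pmin(fit$s0_sq, s2) - 1e-12))
  expect_true(all(s2t <= pmax(fit$s0_sq, s2) + 1e-12))

  # zero dispersion of log variances: infinite prior df
  flat <- fit_ebayes(rep(0.3, 50), d_g)
  expect_identical(flat$d0, Inf)
  expect_equal(flat$s0_sq, 0.3, tolerance = 1e-12)
  expect_equal(moderated_variance(c(0.1, 9), flat), c(0.3, 0.3))

  expect_error(fit_ebayes(rep(0, 50), 4), ">= 10")
})

test_that("empirical-Bayes fit agrees with limma's squeezeVar", {
  skip_if_not_installed("limma")
  set.seed(55)
  s2 <- 0.1 * (rchisq(2000, 4) / 4) / (rchisq(2000, 6) / 6)
  fit <- fit_ebayes(s2, 4)
  sq <- limma::squeezeVar(s2, df = 4)
  expect_equal(fit$d0, sq$df.prior, tolerance = 1e-6)
  expect_equal(fit$s0_sq, sq$var.prior, tolerance = 1e-6)
  expect_equal(moderated_variance(s2, fit), sq$var.post, tolerance = 1e-8)
})

test_that("moderated t reduces to the ordinary pooled t when d0 = 0", {
  set.seed(77)
  d <- tiny_design(groups = c("A", "B"))
  for (i in 1:25) {
    a <- rnorm(3, 10, 1); b <- rnorm(3, 10, 1)
    l2 <- c(a, b)
    gs <- group_stats(tiny_matrix(matrix(2^l2, 1), d),
                      comparison_spec(d, "A", "B", sex = "F"))
    mt <- moderated_t(gs$log2fc, moderated_variance(gs$s_g_sq,
                                                    list(d0 = 0, s0_sq = 1,
                                                         d_g = 4)),
                      3, 3, d0 = 0, d_g = 4)
    oracle <- stats::t.test(a, b, var.equal = TRUE)
    expect_equal(mt$t_mod, unname(oracle$statistic), tolerance = 1e-10)
    expect_equal(mt$p, oracle$p.value, tolerance = 1e-10)
  }
})

test_that("moderated t follows the closed form and its t reference", {
  expect_equal(moderated_t(0, 0.5, 3, 3, 4, 4),
               data.frame(t_mod = 0, p = 1))
  mt <- moderated_t(1, 0.25, 3, 3, 6, 4)
  expect_equal(mt$t_mod, 1 / sqrt(0.25 * (2 / 3)), tolerance = 1e-12)
  expect_equal(mt$p, 2 * stats::pt(-2.449489742783178, df = 10),
               tolerance = 1e-12)
  # infinite prior df: normal reference
  mtn <- moderated_t(1, 0.25, 3, 3, Inf, 4)
  expect_equal(mtn$p, 2 * stats::pnorm(-mtn$t_mod), tolerance = 1e-12)
})

test_that("BH adjustment matches the brute-force step-up oracle", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.3), 0.3)
  set.seed(19)
  for (i in 1:50) {
    p <- runif(sample(5:80, 1))^sample(1:3, 1)
    q <- bh_adjust(p)
    expect_equal(q, bh_oracle(p), tolerance = 1e-12)
    expect_true(all(q >= p))
    expect_true(all(diff(q[order(p)]) >= -1e-12))
  }
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_error(bh_adjust(c(0.5, NA)), "\\[0, 1\\]")
})

test_that("the dual criterion requires both the q-value and the Z-score", {
  expect_identical(call_proteins(0.04, 2.1), "up")
  expect_identical(call_proteins(0.04, 1.0), "ns")
  expect_identical(call_proteins(0.06, -5), "ns")
  expect_identical(call_proteins(0.04, -2.1), "down")
  expect_identical(call_proteins(NA, NA, quantifiable = FALSE),
                   "not_quantifiable")
})

test_that("swapping comparison conditions negates effect statistics only", {
  st <- simulate_study(sim_config(n_proteins = 200, seed = 23))
  imp <- impute_missing(filter_decoys(st$matrix), st$design)
  ab <- run_comparison(imp$matrix, st$design, "GL40", "GL00", sex = "F")
  ba <- run_comparison(imp$matrix, st$design, "GL00", "GL40", sex = "F")
  qf <- ab$call != "not_quantifiable"
  expect_equal(ba$log2fc[qf], -ab$log2fc[qf], tolerance = 1e-12)
  expect_equal(ba$zscore[qf], -ab$zscore[qf], tolerance = 1e-10)
  expect_equal(ba$t_mod[qf], -ab$t_mod[qf], tolerance = 1e-12)
  expect_equal(ba$p[qf], ab$p[qf], tolerance = 1e-12)
  expect_equal(ba$q[qf], ab$q[qf], tolerance = 1e-12)
  expect_identical(ba$call[!qf], ab$call[!qf])
})

test_that("set algebra across comparisons and sexes", {
  rec <- data.frame(
    protein_id = c("P1", "P2", "P1", "P3", "P2"),
    sex = c("F", "F", "M", "M", "M"),
    call = c("up", "down", "down", "up", "ns"),
    stringsAsFactors = FALSE)
  agg <- aggregate_calls(rec)
  expect_equal(agg$union$F, c("P1", "P2"))
  expect_equal(agg$union$M, c("P1", "P3"))
  expect_equal(agg$intersection, "P1")  # P2 significant in females only
  expect_equal(unname(agg$sizes), c(2L, 2L, 1L))

  none <- aggregate_calls(data.frame(protein_id = "P1", sex = "F",
                                     call = "ns"))
  expect_equal(length(none$union$F), 0)
  expect_equal(length(none$intersection), 0)
})
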