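test_that("cosinor fit is exact on noise-free data", {
  set.seed(101)
  for (i in 1:20) {
    M <- runif(1, 1, 10); A <- runif(1, 0.5, 4); phi <- runif(1, 0, 24)
    period <- sample(c(20, 24, 26), 1)
    t <- rep(c(3, 9, 15, 21), each = 3)
    y <- M + A * cos(2 * pi * (t - phi) / period)
    f <- fit_cosinor(y, t, period = period)
    expect_equal(f$mesor, M, tolerance = 1e-8)
    expect_equal(f$amplitude, A, tolerance = 1e-8)
    expect_equal(f$acrophase, phi %% period, tolerance = 1e-8)
  }
})

test_that("constant response gives the degenerate conventions", {
  t <- rep(c(3, 9, 15, 21), each = 2)
  f <- fit_cosinor(rep(7, 8), t)
  expect_equal(f$mesor, 7)
  expect_equal(f$amplitude, 0)
  expect_equal(f$p_amplitude, 1)
  expect_true(is.infinite(f$phase_se))
})

test_that("degenerate designs are rejected", {
  expect_error(fit_cosinor(1:3, c(3, 9, 15)), ">= 4 observations")
  expect_error(fit_cosinor(1:6, rep(c(3, 15), 3)), "3 distinct")
  expect_error(fit_cosinor(1:4, c(3, 9, 15, 21), period = 0), "period")
})

test_that("amplitude is shift-invariant and phase is time-equivariant", {
  set.seed(33)
  t <- rep(c(3, 9, 15, 21), each = 3)
  y <- 5 + 2 * cos(2 * pi * (t - 8) / 24) + rnorm(12, 0, 0.3)
  f1 <- fit_cosinor(y, t)
  f2 <- fit_cosinor(y + 100, t)
  expect_equal(f2$amplitude, f1$amplitude, tolerance = 1e-10)
  expect_equal(f2$mesor, f1$mesor + 100, tolerance = 1e-10)
  expect_equal(f2$acrophase, f1$acrophase, tolerance = 1e-10)
  # relabelling times as t - c moves the fitted peak label to phi - c
  f3 <- fit_cosinor(y, t - 4)
  expect_equal(f3$acrophase %% 24, (f1$acrophase - 4) %% 24,
               tolerance = 1e-8)
})

test_that("matrix fitter agrees with per-gene lm fits", {
  set.seed(5)
  t <- rep(c(3, 9, 15, 21), each = 3)
  Y <- matrix(rnorm(12 * 25, 5), 25, 12,
              dimnames = list(paste0("g", 1:25), NULL))
  Y[1, ] <- 5 + 2 * cos(2 * pi * (t - 3) / 24) + rnorm(12, 0, 0.2)
  res <- circage:::fit_cosinor_matrix(Y, t)
  for (i in c(1, 7, 25)) {
    f <- fit_cosinor(Y[i, ], t)
    expect_equal(res$mesor[i], f$mesor, tolerance = 1e-10)
    expect_equal(res$amplitude[i], f$amplitude, tolerance = 1e-10)
    expect_equal(res$acrophase[i], f$acrophase, tolerance = 1e-10)
    expect_equal(res$p_sin[i], f$p_sin, tolerance = 1e-10)
    expect_equal(res$p_cos[i], f$p_cos, tolerance = 1e-10)
    expect_equal(res$p_amplitude[i], f$p_amplitude, tolerance = 1e-10)
    expect_equal(res$phase_se[i], f$phase_se, tolerance = 1e-8)
  }
})

test_that("quantile residual check is deterministic and validated", {
  set.seed(17)
  t <- rep(c(3, 9, 15, 21), each = 3)
  y <- 5 + 2 * cos(2 * pi * (t - 3) / 24) + rnorm(12, 0, 0.5)
  f <- fit_cosinor(y, t)
  p1 <- quantile_residual_check(f, seed = 42)$resid_p
  p2 <- quantile_residual_check(f, seed = 42)$resid_p
  expect_identical(p1, p2)
  expect_error(quantile_residual_check(f, n_sim = 10), "n_sim")
})

test_that("residual check is calibrated on well-specified data", {
  t <- rep(c(3, 9, 15, 21), each = 3)
  set.seed(7)
  rej <- mean(replicate(200, {
    y <- 5 + 2 * cos(2 * pi * (t - 3) / 24) + rnorm(12, 0, 0.5)
    f <- quantile_residual_check(fit_cosinor(y, t),
                                 seed = sample.int(1e6, 1))
    f$resid_p < 0.05
  }))
  expect_lte(rej, 0.07)
})

test_that("residual check flags gross heteroscedasticity", {
  t <- rep(c(3, 9, 15, 21), each = 24)
  sdv <- ifelse(t >= 15, 5, 0.5)  # 10x noise SD at two timepoints
  set.seed(99)
  hits <- mean(replicate(100, {
    y <- 5 + 2 * cos(2 * pi * (t - 3) / 24) + rnorm(length(t), 0, sdv)
    f <- quantile_residual_check(fit_cosinor(y, t),
                                 seed = sample.int(1e6, 1))
    f$resid_p < 0.05
  }))
  expect_gte(hits, 0.8)
})

test_that("circadian classification applies all four rules", {
  t <- rep(c(3, 9, 15, 21), each = 3)
  set.seed(2)
  strong <- fit_cosinor(5 + 2 * cos(2 * pi * (t - 3) / 24) +
                          rnorm(12, 0, 0.2), t)
  strong <- quantile_residual_check(strong, seed = 1)
  expect_true(classify_circadian(strong)$is_circadian)
  flat <- fit_cosinor(rep(7, 12), t)
  flat <- quantile_residual_check(flat, seed = 1)
  expect_false(classify_circadian(flat)$is_circadian)
  failed <- strong
  failed$resid_p <- 0.01
  expect_false(classify_circadian(failed)$is_circadian)
})

test_that("Brown-Forsythe statistic matches the hand computation", {
  dv <- differential_variability(c(1, 2, 3), c(0, 4, 8))
  expect_equal(dv$statistic, 72 / 34, tolerance = 1e-12)
  expect_equal(dv$p, pf(72 / 34, 1, 4, lower.tail = FALSE),
               tolerance = 1e-12)
  same <- differential_variability(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$statistic, 0)
  expect_equal(same$p, 1)
  const <- differential_variability(rep(2, 4), rep(5, 3))
  expect_equal(const$statistic, 0)
  expect_equal(const$p, 1)
  expect_error(differential_variability(1:2, 1:5), ">= 3")
})

test_that("Brown-Forsythe agrees with the Levene median-centred oracle", {
  skip_if_not_installed("car")
  set.seed(12)
  for (i in 1:10) {
    a <- rnorm(8); b <- rnorm(11, sd = 2)
    dv <- differential_variability(a, b)
    lv <- car::leveneTest(c(a, b), factor(rep(1:2, c(8, 11))),
                          center = median)
    expect_equal(dv$statistic, lv[1, "F value"], tolerance = 1e-10)
    expect_equal(dv$p, lv[1, "Pr(>F)"], tolerance = 1e-10)
  }
})

test_that("variance inflation is detected above the type-I rate", {
  set.seed(21)
  p_null <- replicate(300, differential_variability(rnorm(12),
                                                    rnorm(12))$p)
  p_infl <- replicate(300, differential_variability(rnorm(12),
                                                    rnorm(12, sd = 3))$p)
  expect_gt(mean(p_infl < 0.05), mean(p_null < 0.05))
  expect_gt(mean(p_infl < 0.05), 0.5)
})

test_that("BH adjustment matches the worked example and the oracle", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.05), 0.05)
  expect_identical(bh_adjust(numeric(0)), numeric(0))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(8)
  for (i in 1:1000) {
    p <- runif(sample(1:20, 1))
    expect_equal(bh_adjust(p), bh_oracle(p), tolerance = 1e-12)
  }
  # permutation invariance mapped back to original order
  p <- runif(15)
  perm <- sample(15)
  expect_equal(bh_adjust(p)[perm], bh_adjust(p[perm]), tolerance = 1e-12)
})

test_that("per-gene grouped fitting returns one row per gene per group", {
  sim <- simulate_bulk_timecourse(bulk_sim_config(n_genes = 12,
                                                  frac_rhythmic = 0.5,
                                                  n_replicates = 4,
                                                  seed = 6))
  res <- cosinor_by_gene(sim$dataset, group_by = "age_group", n_sim = 50)
  expect_equal(nrow(res), 24)
  expect_setequal(unique(res$group), c("young", "old"))
  # strong simulated rhythms in the young group are mostly recovered
  young <- res[res$group == "young", ]
  truth <- sim$truth$is_rhythmic[match(young$gene, sim$truth$gene)]
  expect_gt(mean(young$is_circadian[truth]), 0.5)
  expect_lt(mean(young$is_circadian[!truth]), 0.5)
})

test_that("dv_by_gene flags the variance-inflated gene subset", {
  cfg <- bulk_sim_config(n_genes = 100, frac_rhythmic = 0,
                         n_replicates = 12, noise_sd = 0.5,
                         frac_variance_inflated = 0.2,
                         clock_genes = NULL, seed = 14)
  sim <- simulate_bulk_timecourse(cfg)
  res <- dv_by_gene(sim$dataset)
  infl <- sim$truth$variance_inflated[match(res$gene, sim$truth$gene)]
  expect_gt(mean(res$p[infl] < 0.05), mean(res$p[!infl] < 0.05))
})
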