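test_that("ECHO phase conversion matches the closed form", {
  expect_equal(echo_phase_to_24h(0, 24), 0)
  expect_equal(echo_phase_to_24h(30, 24), 6)
  expect_equal(echo_phase_to_24h(13, 26), 12)
  expect_error(echo_phase_to_24h(1, 0), "period")
  # periodic in hours_shifted with the gene's own period
  hs <- seq(-30, 30, by = 0.7)
  expect_equal(echo_phase_to_24h(hs, 26), echo_phase_to_24h(hs + 26, 26),
               tolerance = 1e-10)
  expect_true(all(echo_phase_to_24h(hs, 26) >= 0 &
                    echo_phase_to_24h(hs, 26) < 24))
})

test_that("phase records carry weights and honor the negate flag", {
  pt <- data.frame(gene = c("a", "b"), hours_shifted = c(6, 30),
                   period = c(24, 24), initial_amplitude = c(1, 2))
  rec <- phase_records(pt)
  expect_equal(rec$phase_h, c(6, 6))
  expect_equal(rec$weight, c(1, 2))
  recn <- phase_records(pt, negate_phase = TRUE)
  expect_equal(recn$phase_h, c(18, 18))
})

test_that("weighted circular mean matches the worked examples", {
  expect_equal(weighted_circular_mean(rep(7, 5), runif(5, 0.1, 2))$mean_h,
               7, tolerance = 1e-10)
  wm <- weighted_circular_mean(c(0, 6), c(3, 1))
  expect_equal(wm$mean_h, 24 * atan2(1, 3) / (2 * pi), tolerance = 1e-10)
  anti <- weighted_circular_mean(c(0, 12), c(1, 1))
  expect_identical(anti$status, "undefined")
  expect_true(is.na(anti$mean_h))
  expect_error(weighted_circular_mean(c(0, 6), c(0, 0)), "positive")
  expect_error(weighted_circular_mean(c(0, 6), c(1, -1)), "nonnegative")
})

test_that("weighted circular mean matches the vector-summation oracle", {
  set.seed(15)
  for (i in 1:200) {
    n <- sample(2:30, 1)
    ph <- runif(n, 0, 24)
    w <- runif(n, 0.01, 5)
    wm <- weighted_circular_mean(ph, w)
    expect_equal(wm$mean_h, circ_mean_oracle(ph, w), tolerance = 1e-10)
    # rotation equivariance and weight-scale invariance
    c_shift <- runif(1, 0, 24)
    expect_equal(weighted_circular_mean((ph + c_shift) %% 24, w)$mean_h,
                 (wm$mean_h + c_shift) %% 24, tolerance = 1e-8)
    expect_equal(weighted_circular_mean(ph, w * 7.5)$mean_h, wm$mean_h,
                 tolerance = 1e-12)
  }
})

test_that("Rayleigh test reproduces the worked statistics", {
  ident <- rayleigh_test(rep(5, 4))
  expect_equal(ident$R_bar, 1, tolerance = 1e-12)
  expect_equal(ident$Z, 4, tolerance = 1e-12)
  quartet <- rayleigh_test(c(0, 6, 12, 18))
  expect_equal(quartet$Z, 0, tolerance = 1e-12)
  expect_equal(quartet$p, 1)
  three <- rayleigh_test(c(0, 2, 4))
  expect_equal(three$Z, 2.488, tolerance = 1e-3)
  expect_error(rayleigh_test(c(0, 2)), "n >= 3")
})

test_that("Rayleigh Z grows with concentration", {
  set.seed(25)
  spread <- function(sd) mean(replicate(50,
    rayleigh_test((12 + rnorm(20, 0, sd)) %% 24)$Z))
  expect_gt(spread(1), spread(4))
  expect_gt(spread(4), spread(12))
})

test_that("enrichment retains only sufficiently overlapping sets", {
  rec <- data.frame(gene = paste0("g", 1:30),
                    phase_h = c(rep(6, 15) + seq(-0.5, 0.5, length.out = 15),
                                runif(15, 0, 24)),
                    weight = rep(1, 30))
  sets <- gene_set_collection(list(big = paste0("g", 1:15),
                                   small = paste0("g", 1:5),
                                   partial = paste0("g", c(1:8, 100:110))))
  res <- pathway_phase_enrichment(rec, sets, min_overlap = 10)
  expect_identical(res$pathway, "big")
  expect_equal(res$n_genes, 15L)
  expect_lt(res$p, 0.01)
  expect_warning(pathway_phase_enrichment(rec, sets, min_overlap = 40),
                 "min_overlap")
})

test_that("planted clustered set is detected among uniform sets", {
  pt <- simulate_phase_table(n_sets = 20, genes_per_set = 25,
                             clustered_sd = 0.5, seed = 12)
  res <- pathway_phase_enrichment(phase_records(pt$phases), pt$sets,
                                  min_overlap = 10)
  clustered <- pt$truth$set[pt$truth$clustered]
  expect_true(all(res$fdr[res$pathway %in% clustered] < 0.05))
})

test_that("signed circular shift matches the printed formula", {
  expect_equal(circular_phase_shift(1, 23), 2)
  expect_equal(circular_phase_shift(5, 5), 0)
  expect_equal(circular_phase_shift(17, 5), -12)
  expect_equal(circular_phase_shift(6, 4), 2)
})

test_that("age-group comparison categorizes and filters pathways", {
  young <- data.frame(pathway = c("A", "B", "C", "D"),
                      mean_phase = c(4, 10, 20, 1),
                      fdr = c(0.01, 0.2, 0.03, 0.5))
  old <- data.frame(pathway = c("A", "B", "C", "E"),
                    mean_phase = c(6, 11, 21, 2),
                    fdr = c(0.02, 0.01, 0.8, 0.01))
  res <- compare_age_groups(young, old)
  expect_setequal(res$pathway, c("A", "B", "C"))  # D/E unpaired or ns
  expect_identical(res$category[res$pathway == "A"], "Both")
  expect_identical(res$category[res$pathway == "B"], "Old only")
  expect_identical(res$category[res$pathway == "C"], "Young only")
  expect_equal(res$delta_h[res$pathway == "A"], 2)
  expect_true(all(diff(res$abs_delta) <= 0))
  none <- data.frame(pathway = "Z", mean_phase = 1, fdr = 0.5)
  expect_warning(out <- compare_age_groups(young, none), "both")
  expect_equal(nrow(out), 0)
})

test_that("circadian-call filter applies the stringent thresholds", {
  calls <- data.frame(gene = paste0("g", 1:6),
                      period = c(24, 19, 24, 24, 24, 29),
                      ac_coef = c(0.3, 0.3, 0.1, -0.3, 0.3, 0.3),
                      pvalue = c(0.01, 0.01, 0.01, 0.01, 0.2, 0.01),
                      bh_p = c(0.005, 0.005, 0.005, 0.005, 0.005, 0.005),
                      by_p = c(0.005, 0.005, 0.005, 0.005, 0.005, 0.02))
  out <- filter_circadian_calls(calls)
  expect_setequal(out$gene, c("g1", "g4"))
  expect_error(filter_circadian_calls(calls[, -2]), "missing column")
})
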