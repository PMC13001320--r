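noise_free_cfg <- function(...) {
  bulk_sim_config(n_genes = 1, frac_rhythmic = 1, mesor_range = c(5, 5),
                  amplitude_range = c(2, 2), acrophase_range = c(3, 3),
                  noise_sd = 0, n_replicates = 1, clock_genes = NULL,
                  seed = 7, ...)
}

test_that("noise-free rhythmic gene hits the cosinor values exactly", {
  sim <- simulate_bulk_timecourse(noise_free_cfg())
  young <- sim$dataset$samples$age_group == "young"
  expect_equal(unname(sim$dataset$matrix[1, young]), c(7, 5, 3, 5),
               tolerance = 1e-12)
})

test_that("bulk simulation is seed-deterministic", {
  s1 <- simulate_bulk_timecourse(bulk_sim_config(n_genes = 40, seed = 3,
                                                 n_replicates = 3))
  s2 <- simulate_bulk_timecourse(bulk_sim_config(n_genes = 40, seed = 3,
                                                 n_replicates = 3))
  expect_identical(s1$dataset$matrix, s2$dataset$matrix)
  expect_identical(s1$truth, s2$truth)
})

test_that("rhythmic fraction is assigned deterministically by count", {
  sim <- simulate_bulk_timecourse(bulk_sim_config(n_genes = 200,
                                                  frac_rhythmic = 0.5,
                                                  n_replicates = 2,
                                                  seed = 2))
  expect_identical(sum(sim$truth$is_rhythmic), 100L)
  expect_true(all(which(sim$truth$is_rhythmic) == 1:100))
})

test_that("fewer than 3 distinct timepoints is rejected", {
  expect_error(bulk_sim_config(timepoints = c(3, 15)), "3 distinct")
})

test_that("generator noise matches the configured SD per timepoint", {
  cfg <- bulk_sim_config(n_genes = 1, frac_rhythmic = 0, n_replicates = 500,
                         mesor_range = c(5, 5), noise_sd = 0.5,
                         frac_variance_inflated = 0, clock_genes = NULL,
                         seed = 11)
  sim <- simulate_bulk_timecourse(cfg)
  young <- sim$dataset$samples$age_group == "young"
  sds <- tapply(sim$dataset$matrix[1, young],
                sim$dataset$samples$zt[young], sd)
  expect_true(all(abs(sds - 0.5) / 0.5 < 0.1))
})

test_that("dataset invariants hold on default simulations", {
  sim <- simulate_bulk_timecourse(bulk_sim_config(n_genes = 30, seed = 9,
                                                  n_replicates = 2))
  expect_true(all(sim$dataset$matrix >= 0))
  expect_true(all(sim$dataset$samples$zt >= 0 &
                    sim$dataset$samples$zt < 24))
  expect_setequal(sim$truth$gene, sim$dataset$gene_ids)
})

test_that("population-1 cells sit on the diagonal in the noise-free limit", {
  cp <- simulate_cell_pairs(cell_sim_config(n_cells = 200,
                                            mixture_weights = c(1, 0, 0),
                                            pop1_correlation = 1,
                                            noise_sd = 0, seed = 1))
  expect_identical(cp$cells$x, cp$cells$y)
  expect_true(all(cp$truth$population == 1))
})

test_that("population-2 cells exceed the band by construction", {
  cp <- simulate_cell_pairs(cell_sim_config(n_cells = 300,
                                            mixture_weights = c(0, 1, 0),
                                            epsilon_truth = 1,
                                            noise_sd = 0, seed = 1))
  expect_true(all(cp$cells$y - cp$cells$x > 1))
})

test_that("mixture proportions follow binomial sampling", {
  w <- c(0.8, 0.1, 0.1)
  cp <- simulate_cell_pairs(cell_sim_config(n_cells = 3000,
                                            mixture_weights = w, seed = 5))
  prop <- tabulate(cp$truth$population, 3) / 3000
  se <- sqrt(w * (1 - w) / 3000)
  expect_true(all(abs(prop - w) <= 3 * se))
})

test_that("cell-pair config rejects invalid mixtures", {
  expect_error(cell_sim_config(mixture_weights = c(1.2, -0.1, -0.1)),
               "nonnegative")
  expect_error(cell_sim_config(mixture_weights = c(0.5, 0.4, 0.2)),
               "sum to 1")
})

test_that("phase-table generator plants exact clusters at sd 0", {
  pt <- simulate_phase_table(n_sets = 6, genes_per_set = 15,
                             clustered_sd = 0, seed = 5)
  spread <- tapply(pt$phases$hours_shifted,
                   sub("_g.*", "", pt$phases$gene),
                   function(v) diff(range(v)))
  clustered_sets <- sprintf("set%02d", which(pt$truth$clustered))
  expect_true(all(spread[clustered_sets] == 0))
  expect_true(all(spread[setdiff(names(spread), clustered_sets)] > 0))
  expect_true(all(pt$phases$initial_amplitude > 0))
  expect_error(simulate_phase_table(clustered_sd = -1), "clustered_sd")
})

test_that("phase-table generator is deterministic and shiftable", {
  a <- simulate_phase_table(n_sets = 8, genes_per_set = 10, seed = 4)
  b <- simulate_phase_table(n_sets = 8, genes_per_set = 10, seed = 4)
  expect_identical(a$phases, b$phases)
  shifted <- simulate_phase_table(n_sets = 8, genes_per_set = 10, seed = 4,
                                  center_shift = 6)
  clustered <- a$truth$clustered
  expect_equal((shifted$truth$center - a$truth$center)[clustered] %% 24,
               rep(6, sum(clustered)), tolerance = 1e-12)
  # uniform sets identical under a center shift
  uniform_genes <- grepl(sprintf("set0[5-8]"), a$phases$gene)
  expect_identical(a$phases$hours_shifted[uniform_genes],
                   shifted$phases$hours_shifted[uniform_genes])
})
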