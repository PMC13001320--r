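# Seeded generators that emulate the study design the analysis assumes:
# a 4-timepoint/24 h bulk time course with replicates in two age groups,
# a fibroblast-style per-gene phase table with gene sets, and a
# three-population two-gene single-cell mixture. Each generator draws all
# randomness from one seed and restores the caller's RNG state.

with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv()))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  expr
}

#' Age-effect parameters for the bulk simulator
#'
#' Encodes the age-related distortions the analysis is designed to detect:
#' phase jitter on negative-arm clock genes (loss of anti-phase), an elevated
#' senescence-gene baseline, noise-variance inflation on a gene subset, and
#' independent decoupling noise injected into the clock-senescence gene pair
#' in old samples.
#'
#' @param phase_jitter_sd SD (hours) of the acrophase perturbation applied to
#'   negative-arm genes in old samples.
#' @param baseline_shift Additive log-unit elevation of the designated
#'   senescence gene in old samples (applied as multiplication of the
#'   deterministic signal by `exp(baseline_shift)`).
#' @param variance_inflation Multiplier (>= 1) on `noise_sd` for the
#'   designated variance-inflated gene subset in old samples.
#' @param decoupling_noise_sd SD of independent expression-scale noise added
#'   to both members of the coupled clock-senescence pair in old samples.
#' @export
age_effects <- function(phase_jitter_sd = 2, baseline_shift = 1,
                        variance_inflation = 3, decoupling_noise_sd = 1.5) {
  stopifnot(phase_jitter_sd >= 0, baseline_shift >= 0,
            variance_inflation >= 1, decoupling_noise_sd >= 0)
  list(phase_jitter_sd = phase_jitter_sd, baseline_shift = baseline_shift,
       variance_inflation = variance_inflation,
       decoupling_noise_sd = decoupling_noise_sd)
}

#' Configuration for the bulk time-course simulator
#'
#' Defaults mirror the emulated study design: four Zeitgeber timepoints over
#' 24 h (ZT3/9/15/21), eight replicates per timepoint per age group, a 24 h
#' period, and Gaussian expression-scale noise.
#'
#' @param n_genes Number of genes.
#' @param frac_rhythmic Fraction of genes that carry a cosinor signal; the
#'   first `ceiling(frac_rhythmic * n_genes)` genes are rhythmic.
#' @param timepoints Sampled ZT hours (>= 3 distinct values).
#' @param n_replicates Replicates per timepoint per age group.
#' @param period Oscillation period in hours.
#' @param mesor_range,amplitude_range Uniform sampling ranges for the
#'   rhythm-adjusted mean and half peak-to-trough amplitude.
#' @param acrophase_range Uniform sampling range (hours) for peak time.
#' @param noise_sd Gaussian noise SD on the expression scale.
#' @param frac_variance_inflated Fraction of genes whose old-sample noise is
#'   inflated by `age_effects$variance_inflation`.
#' @param age_effects See [age_effects()].
#' @param clock_genes Named list with entries `positive`, `negative`,
#'   `senescence` giving gene names for the positive-arm gene, the
#'   negative-arm gene (simulated 12 h anti-phase) and the senescence gene
#'   (shares the positive-arm acrophase); `NULL` disables role genes.
#' @param seed Integer seed; same seed, same output.
#' @export
bulk_sim_config <- function(n_genes = 2000, frac_rhythmic = 0.3,
                            timepoints = c(3, 9, 15, 21), n_replicates = 8,
                            period = 24, mesor_range = c(4, 8),
                            amplitude_range = c(1, 3),
                            acrophase_range = c(0, 24), noise_sd = 0.5,
                            frac_variance_inflated = 0.1,
                            age_effects = circage::age_effects(),
                            clock_genes = list(positive = "Bmal1",
                                               negative = "Per2",
                                               senescence = "Cdkn1a"),
                            seed = 1) {
  stopifnot(n_genes >= 1, frac_rhythmic >= 0, frac_rhythmic <= 1,
            period > 0, noise_sd >= 0,
            mesor_range[1] <= mesor_range[2],
            amplitude_range[1] <= amplitude_range[2],
            frac_variance_inflated >= 0, frac_variance_inflated <= 1)
  if (length(unique(timepoints)) < 3)
    stop("need >= 3 distinct timepoints (cosinor unidentifiable otherwise)")
  list(n_genes = n_genes, frac_rhythmic = frac_rhythmic,
       timepoints = timepoints, n_replicates = n_replicates, period = period,
       mesor_range = mesor_range, amplitude_range = amplitude_range,
       acrophase_range = acrophase_range, noise_sd = noise_sd,
       frac_variance_inflated = frac_variance_inflated,
       age_effects = age_effects, clock_genes = clock_genes, seed = seed)
}

cosinor_signal <- function(t, mesor, amplitude, acrophase, period) {
  mesor + amplitude * cos(2 * pi * (t - acrophase) / period)
}

#' Simulate a bulk circadian time course with age effects
#'
#' Rhythmic genes follow `y = M + A*cos(2*pi*(t - phi)/period) + e`,
#' `e ~ N(0, noise_sd^2)`; non-rhythmic genes are flat plus noise. Old-group
#' samples receive the configured [age_effects()]: negative-arm phase jitter,
#' a senescence-gene baseline elevation, variance inflation on a designated
#' subset, and decoupling noise on the clock-senescence pair. Expression is
#' truncated at zero to keep the nonnegativity invariant.
#'
#' @param config A [bulk_sim_config()].
#' @return List with `dataset` (an [expression_dataset()]) and `truth`
#'   (per-gene data frame: gene, is_rhythmic, mesor, amplitude, acrophase,
#'   role, variance_inflated).
#' @export
simulate_bulk_timecourse <- function(config = bulk_sim_config()) {
  cf <- config
  if (length(unique(cf$timepoints)) < 3)
    stop("need >= 3 distinct timepoints (cosinor unidentifiable otherwise)")
  with_seed(cf$seed, {
    n <- cf$n_genes
    n_rhythmic <- ceiling(cf$frac_rhythmic * n)
    roles <- rep("none", n)
    genes <- sprintf("gene_%04d", seq_len(n))
    if (!is.null(cf$clock_genes)) {
      if (n_rhythmic < 3)
        stop("clock role genes require >= 3 rhythmic genes; ",
             "set clock_genes = NULL or raise frac_rhythmic")
      genes[1:3] <- c(cf$clock_genes$positive, cf$clock_genes$negative,
                      cf$clock_genes$senescence)
      roles[1:3] <- c("positive_arm", "negative_arm", "senescence")
    }
    is_rhythmic <- seq_len(n) <= n_rhythmic

    mesor <- stats::runif(n, cf$mesor_range[1], cf$mesor_range[2])
    amplitude <- ifelse(is_rhythmic,
                        stats::runif(n, cf$amplitude_range[1],
                                     cf$amplitude_range[2]), 0)
    acrophase <- stats::runif(n, cf$acrophase_range[1], cf$acrophase_range[2])
    if (!is.null(cf$clock_genes)) {
      acrophase[2] <- (acrophase[1] + cf$period / 2) %% 24  # anti-phase arm
      acrophase[3] <- acrophase[1]                          # coupled pair
    }
    n_inflated <- round(cf$frac_variance_inflated * n)
    variance_inflated <- seq_len(n) > (n - n_inflated)

    # old-group acrophase: negative-arm genes get jittered peak times
    jitter <- stats::rnorm(n, 0, cf$age_effects$phase_jitter_sd)
    acro_old <- ifelse(roles == "negative_arm",
                       (acrophase + jitter) %% 24, acrophase)

    tp <- rep(cf$timepoints, each = cf$n_replicates)
    reps <- rep(seq_len(cf$n_replicates), times = length(cf$timepoints))
    one_age <- function(age) {
      data.frame(sample_id = sprintf("%s_ZT%02d_r%d", age, tp, reps),
                 zt = tp, age_group = age,
                 sex = ifelse(reps %% 2 == 1, "M", "F"),
                 replicate = paste0("r", reps))
    }
    samples <- rbind(one_age("young"), one_age("old"))
    m <- matrix(0, n, nrow(samples), dimnames = list(genes,
                                                     samples$sample_id))
    old <- samples$age_group == "old"
    for (i in seq_len(n)) {
      mu <- numeric(nrow(samples))
      mu[!old] <- cosinor_signal(samples$zt[!old], mesor[i], amplitude[i],
                                 acrophase[i], cf$period)
      mu[old] <- cosinor_signal(samples$zt[old], mesor[i], amplitude[i],
                                acro_old[i], cf$period)
      if (roles[i] == "senescence")
        mu[old] <- mu[old] * exp(cf$age_effects$baseline_shift)
      sd_vec <- rep(cf$noise_sd, nrow(samples))
      if (variance_inflated[i])
        sd_vec[old] <- cf$noise_sd * cf$age_effects$variance_inflation
      m[i, ] <- mu + stats::rnorm(nrow(samples), 0, sd_vec)
      if (roles[i] %in% c("positive_arm", "senescence") &&
          cf$age_effects$decoupling_noise_sd > 0)
        m[i, old] <- m[i, old] +
          stats::rnorm(sum(old), 0, cf$age_effects$decoupling_noise_sd)
    }
    m <- pmax(m, 0)
    truth <- data.frame(gene = genes, is_rhythmic = is_rhythmic,
                        mesor = mesor, amplitude = amplitude,
                        acrophase = acrophase %% 24,
                        acrophase_old = acro_old %% 24, role = roles,
                        variance_inflated = variance_inflated)
    list(dataset = expression_dataset(m, samples), truth = truth)
  })
}

#' Configuration for the two-gene single-cell mixture simulator
#'
#' Three populations on log-normalized (x, y) coordinates: population 1 lies
#' near the diagonal `y = x` with correlation `pop1_correlation`; population
#' 2 satisfies `y > x + epsilon_truth` (high senescence gene relative to
#' clock gene); population 3 is the mirror. All values are simulated directly
#' on the log scale.
#'
#' @param n_cells Number of cells.
#' @param mixture_weights Length-3 nonnegative weights summing to 1.
#' @param pop1_correlation Target Pearson correlation within population 1.
#' @param epsilon_truth Planted band half-width in log units.
#' @param noise_sd Per-coordinate Gaussian noise SD.
#' @param seed Integer seed.
#' @export
cell_sim_config <- function(n_cells = 5000,
                            mixture_weights = c(0.7, 0.15, 0.15),
                            pop1_correlation = 0.9, epsilon_truth = 0.5,
                            noise_sd = 0.1, seed = 1) {
  if (length(mixture_weights) != 3 || any(mixture_weights < 0))
    stop("mixture_weights must be 3 nonnegative values")
  if (abs(sum(mixture_weights) - 1) > 1e-9)
    stop("mixture_weights must sum to 1")
  stopifnot(n_cells >= 1, pop1_correlation >= 0, pop1_correlation <= 1,
            epsilon_truth > 0, noise_sd >= 0)
  list(n_cells = n_cells, mixture_weights = mixture_weights,
       pop1_correlation = pop1_correlation, epsilon_truth = epsilon_truth,
       noise_sd = noise_sd, seed = seed)
}

#' Simulate a three-population two-gene single-cell mixture
#'
#' Population labels are drawn i.i.d. from `mixture_weights`. Population 1
#' cells sit on the diagonal with per-coordinate noise `noise_sd` (so with
#' `noise_sd = 0` and `pop1_correlation = 1` they fall on `y = x` exactly);
#' populations 2 and 3 are offset beyond the planted band by a strictly
#' positive exponential margin, so at `noise_sd = 0` every population-2 cell
#' has `y - x > epsilon_truth` and mirror-wise for population 3.
#'
#' @param config A [cell_sim_config()].
#' @return List with `cells` (data frame: cell_id, x, y) and `truth`
#'   (data frame: cell_id, population).
#' @export
simulate_cell_pairs <- function(config = cell_sim_config()) {
  cf <- config
  with_seed(cf$seed, {
    n <- cf$n_cells
    pop <- sample.int(3, n, replace = TRUE, prob = cf$mixture_weights)
    # spread along the diagonal; tied to noise_sd so pop-1 correlation is
    # pop1_correlation, except in the noise-free limit (correlation 1)
    sd_b <- if (cf$noise_sd > 0 && cf$pop1_correlation < 1)
      cf$noise_sd * sqrt(cf$pop1_correlation / (1 - cf$pop1_correlation))
    else 0.8
    x <- y <- numeric(n)
    i1 <- pop == 1L
    b <- stats::rnorm(sum(i1), 2, sd_b)
    x[i1] <- b
    y[i1] <- b
    i2 <- pop == 2L
    base2 <- stats::rnorm(sum(i2), 1.5, 0.5)
    x[i2] <- base2
    y[i2] <- base2 + cf$epsilon_truth + stats::rexp(sum(i2), rate = 2)
    i3 <- pop == 3L
    base3 <- stats::rnorm(sum(i3), 1.5, 0.5)
    y[i3] <- base3
    x[i3] <- base3 + cf$epsilon_truth + stats::rexp(sum(i3), rate = 2)
    if (cf$noise_sd > 0) {
      x <- x + stats::rnorm(n, 0, cf$noise_sd)
      y <- y + stats::rnorm(n, 0, cf$noise_sd)
    }
    ids <- sprintf("cell_%05d", seq_len(n))
    list(cells = data.frame(cell_id = ids, x = x, y = y),
         truth = data.frame(cell_id = ids, population = pop))
  })
}

#' Simulate an ECHO-style phase table with planted clustered gene sets
#'
#' Generates `n_sets` disjoint gene sets; the first half have phases tightly
#' clustered (wrapped normal, SD `clustered_sd` hours) around a set-specific
#' center, the rest have phases uniform on the 24 h circle. Amplitude
#' weights are drawn uniformly positive. `center_shift` adds a fixed offset
#' to every clustered-set center, so calling twice with the same seed and
#' different shifts yields paired "young"/"old" tables whose clustered sets
#' differ by a known circular phase shift.
#'
#' @param n_sets Number of gene sets.
#' @param genes_per_set Genes per set (>= 1).
#' @param clustered_sd Wrapped-normal SD in hours for clustered sets (>= 0).
#' @param seed Integer seed.
#' @param center_shift Hours added to each clustered set's center.
#' @param period Period written to the phase table (hours).
#' @return List with `phases` (phase-table data frame), `sets`
#'   (a [gene_set_collection()]) and `truth` (set, clustered, center).
#' @export
simulate_phase_table <- function(n_sets = 60, genes_per_set = 30,
                                 clustered_sd = 1, seed = 1,
                                 center_shift = 0, period = 24) {
  if (clustered_sd < 0) stop("clustered_sd must be >= 0")
  stopifnot(genes_per_set >= 1, n_sets >= 1, period > 0)
  with_seed(seed, {
    n_clustered <- floor(n_sets / 2)
    clustered <- seq_len(n_sets) <= n_clustered
    centers <- stats::runif(n_sets, 0, 24)
    centers[clustered] <- (centers[clustered] + center_shift) %% 24
    rows <- lapply(seq_len(n_sets), function(s) {
      g <- sprintf("set%02d_g%03d", s, seq_len(genes_per_set))
      ph <- if (clustered[s])
        (centers[s] + stats::rnorm(genes_per_set, 0, clustered_sd)) %% 24
      else stats::runif(genes_per_set, 0, 24)
      data.frame(gene = g, hours_shifted = ph * period / 24, period = period,
                 initial_amplitude = stats::runif(genes_per_set, 0.2, 3))
    })
    phases <- do.call(rbind, rows)
    sets <- gene_set_collection(
      setNames(lapply(rows, `[[`, "gene"), sprintf("SET_%02d",
                                                   seq_len(n_sets))),
      setNames(ifelse(clustered, "clustered", "uniform"),
               sprintf("SET_%02d", seq_len(n_sets))))
    truth <- data.frame(set = names(sets$sets), clustered = clustered,
                        center = centers)
    list(phases = phases, sets = sets, truth = truth)
  })
}
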