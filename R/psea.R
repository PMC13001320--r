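# Phase-set enrichment on the 24 h circle: conversion of ECHO-style
# "hours shifted" to a standardized 24 h phase, the (unweighted) Rayleigh
# test of circular nonuniformity per gene set, amplitude-weighted circular
# mean phases, BH FDR across retained sets, and signed circular phase
# shifts between age groups. Amplitude weights enter only the mean phase,
# never the Rayleigh statistic.

#' Standardize an ECHO phase to the 24 h circle
#'
#' `phase_h = ((hours_shifted mod period) * 24 / period)`, in [0, 24).
#' Periodic in `hours_shifted` with period `period`.
#'
#' @param hours_shifted Peak offset(s) in hours.
#' @param period Estimated period(s) in hours (> 0).
#' @return Phase(s) in hours on the 24 h circle.
#' @examples
#' echo_phase_to_24h(30, 24)  # 6
#' echo_phase_to_24h(13, 26)  # 12
#' @export
echo_phase_to_24h <- function(hours_shifted, period) {
  if (any(period <= 0)) stop("period must be > 0")
  ((hours_shifted %% period) * 24 / period) %% 24
}

#' Convert a phase table to phase records
#'
#' Standardizes each gene's phase to 24 h and carries the initial amplitude
#' as a nonnegative weight.
#'
#' @param phase_table Data frame with columns gene, hours_shifted, period,
#'   initial_amplitude (see [read_phase_table()]).
#' @param negate_phase Flip the sign of `hours_shifted` first, for ECHO
#'   builds emitting the negated peak-offset convention.
#' @return Data frame: gene, phase_h, weight.
#' @export
phase_records <- function(phase_table, negate_phase = FALSE) {
  pt <- validate_phase_table(phase_table)
  hs <- if (negate_phase) -pt$hours_shifted else pt$hours_shifted
  data.frame(gene = pt$gene,
             phase_h = echo_phase_to_24h(hs, pt$period),
             weight = pt$initial_amplitude)
}

#' Amplitude-weighted circular mean phase
#'
#' With `theta_i = 2*pi*phase_i/24`, the weighted mean direction is
#' `atan2(sum(w_i sin theta_i), sum(w_i cos theta_i)) mod 2*pi`, converted
#' back to hours. The resultant length is normalized by the total weight.
#' A (numerically) zero resultant means the mean is undefined
#' (`status = "undefined"`, mean NA), e.g. perfect antipodal cancellation.
#'
#' @param phases Numeric phases in hours on the 24 h circle.
#' @param weights Nonnegative weights, at least one positive (default:
#'   equal weights).
#' @return List with `mean_h` (hours in [0, 24)), `resultant` (in [0, 1])
#'   and `status` (`"ok"` or `"undefined"`).
#' @examples
#' weighted_circular_mean(c(0, 6), c(3, 1))  # about 1.229 h
#' @export
weighted_circular_mean <- function(phases, weights = rep(1, length(phases))) {
  if (length(phases) != length(weights))
    stop("phases and weights must have equal length")
  if (any(weights < 0)) stop("weights must be nonnegative")
  if (all(weights == 0)) stop("at least one weight must be positive")
  theta <- 2 * pi * phases / 24
  S <- sum(weights * sin(theta))
  C <- sum(weights * cos(theta))
  len <- sqrt(S^2 + C^2)
  if (len < 1e-12 * sum(weights))
    return(list(mean_h = NA_real_, resultant = 0, status = "undefined"))
  list(mean_h = (24 * atan2(S, C) / (2 * pi)) %% 24,
       resultant = len / sum(weights), status = "ok")
}

#' Rayleigh test of circular nonuniformity
#'
#' Unweighted: `R_bar = |sum(exp(i*theta))| / n`, `Z = n * R_bar^2`, with
#' the classical series approximation for the p-value
#' `p = exp(-Z) * [1 + (2Z - Z^2)/(4n) - (24Z - 132Z^2 + 76Z^3 - 9Z^4)/(288n^2)]`,
#' clamped to [0, 1].
#'
#' @param phases Numeric phases in hours on the 24 h circle (n >= 3).
#' @return List with `Z`, `p`, `R_bar`, `n`.
#' @examples
#' rayleigh_test(c(0, 2, 4))  # Z approximately 2.488
#' @export
rayleigh_test <- function(phases) {
  n <- length(phases)
  if (n < 3) stop("Rayleigh test needs n >= 3 phases")
  theta <- 2 * pi * phases / 24
  C <- sum(cos(theta)); S <- sum(sin(theta))
  R_bar <- sqrt(C^2 + S^2) / n
  Z <- n * R_bar^2
  p <- exp(-Z) * (1 + (2 * Z - Z^2) / (4 * n) -
                    (24 * Z - 132 * Z^2 + 76 * Z^3 - 9 * Z^4) /
                      (288 * n^2))
  list(Z = Z, p = min(max(p, 0), 1), R_bar = R_bar, n = n)
}

#' Pathway phase-set enrichment
#'
#' For each gene set with at least `min_overlap` genes present in the phase
#' records (intersection semantics: set genes absent from the records are
#' dropped), computes the unweighted Rayleigh test of phase clustering and
#' the amplitude-weighted mean phase, then adjusts p-values across retained
#' sets with BH FDR.
#'
#' @param records Data frame with columns gene, phase_h, weight (see
#'   [phase_records()]).
#' @param sets A [gene_set_collection()].
#' @param min_overlap Minimum overlapping genes to retain a set.
#' @param fdr_threshold Threshold for the `significant` flag.
#' @return Data frame: pathway, n_genes, mean_phase, resultant, rayleigh_Z,
#'   p, fdr, significant. Empty (with a warning) if no set passes
#'   `min_overlap`.
#' @export
pathway_phase_enrichment <- function(records, sets, min_overlap = 10,
                                     fdr_threshold = 0.05) {
  if (!nrow(records)) stop("phase records are empty")
  stopifnot(inherits(sets, "gene_set_collection"))
  if (anyDuplicated(records$gene))
    stop("duplicate genes in phase records")
  idx <- lapply(sets$sets, function(g)
    which(records$gene %in% g))
  keep <- lengths(idx) >= min_overlap
  if (!any(keep)) {
    warning("no gene set passes min_overlap = ", min_overlap)
    return(data.frame(pathway = character(0), n_genes = integer(0),
                      mean_phase = numeric(0), resultant = numeric(0),
                      rayleigh_Z = numeric(0), p = numeric(0),
                      fdr = numeric(0), significant = logical(0)))
  }
  idx <- idx[keep]
  rows <- lapply(names(idx), function(nm) {
    i <- idx[[nm]]
    rt <- rayleigh_test(records$phase_h[i])
    wm <- if (all(records$weight[i] == 0))
      list(mean_h = NA_real_, resultant = NA_real_)
    else weighted_circular_mean(records$phase_h[i], records$weight[i])
    data.frame(pathway = nm, n_genes = length(i), mean_phase = wm$mean_h,
               resultant = wm$resultant, rayleigh_Z = rt$Z, p = rt$p)
  })
  out <- do.call(rbind, rows)
  out$fdr <- bh_adjust(out$p)
  out$significant <- out$fdr < fdr_threshold
  rownames(out) <- NULL
  out
}

#' Shortest signed circular phase difference
#'
#' `delta_h = ((h_old - h_young + 12) mod 24) - 12`, in [-12, 12). An exact
#' half-cycle difference maps to -12 (half-open range of the formula).
#' Antisymmetric off that boundary and invariant to a common translation of
#' both phases.
#'
#' @param h_old,h_young Phases in hours on the 24 h circle (vectorized).
#' @return Signed difference(s) in hours.
#' @examples
#' circular_phase_shift(1, 23)  # +2
#' @export
circular_phase_shift <- function(h_old, h_young) {
  ((h_old - h_young + 12) %% 24) - 12
}

#' Compare pathway phase enrichment between age groups
#'
#' Pairs pathways present in both result tables, computes the signed
#' circular phase shift (old minus young) and its magnitude, retains
#' pathways significant (per-group FDR below `fdr_threshold`) in at least
#' one group, and categorizes each as "Both", "Young only" or "Old only".
#' Rows are sorted by decreasing |delta_h|.
#'
#' @param young,old Result tables from [pathway_phase_enrichment()] run on
#'   the same gene-set collection.
#' @param fdr_threshold Per-group FDR significance threshold.
#' @return Data frame: pathway, h_young, h_old, delta_h, abs_delta,
#'   fdr_young, fdr_old, category.
#' @export
compare_age_groups <- function(young, old, fdr_threshold = 0.05) {
  common <- intersect(young$pathway, old$pathway)
  if (!length(common)) {
    warning("no pathway is present in both result tables")
    return(data.frame(pathway = character(0), h_young = numeric(0),
                      h_old = numeric(0), delta_h = numeric(0),
                      abs_delta = numeric(0), fdr_young = numeric(0),
                      fdr_old = numeric(0), category = character(0)))
  }
  yy <- young[match(common, young$pathway), ]
  oo <- old[match(common, old$pathway), ]
  sig_y <- yy$fdr < fdr_threshold
  sig_o <- oo$fdr < fdr_threshold
  keep <- sig_y | sig_o
  delta <- circular_phase_shift(oo$mean_phase, yy$mean_phase)
  out <- data.frame(pathway = common, h_young = yy$mean_phase,
                    h_old = oo$mean_phase, delta_h = delta,
                    abs_delta = abs(delta), fdr_young = yy$fdr,
                    fdr_old = oo$fdr,
                    category = ifelse(sig_y & sig_o, "Both",
                                      ifelse(sig_y, "Young only",
                                             "Old only")))
  out <- out[keep, , drop = FALSE]
  out <- out[order(-out$abs_delta), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Filter ECHO-style circadian calls
#'
#' Row filter implementing the stringent fibroblast circadian-call
#' thresholds consumed upstream of enrichment: period within
#' `period_range`, amplitude-change coefficient beyond `min_ac` in absolute
#' value, raw p-value below `max_p`, and both BH- and BY-adjusted p-values
#' below `max_adj_p`.
#'
#' @param calls Data frame with columns `period`, `ac_coef`, `pvalue`,
#'   `bh_p`, `by_p` (additional columns pass through).
#' @param period_range Length-2 inclusive period window in hours.
#' @param min_ac Minimum |amplitude-change coefficient|.
#' @param max_p Maximum raw p-value.
#' @param max_adj_p Maximum BH and BY adjusted p-value.
#' @return The rows passing all filters.
#' @export
filter_circadian_calls <- function(calls, period_range = c(20, 28),
                                   min_ac = 0.15, max_p = 0.05,
                                   max_adj_p = 0.01) {
  need <- c("period", "ac_coef", "pvalue", "bh_p", "by_p")
  missing <- setdiff(need, names(calls))
  if (length(missing))
    stop("calls table is missing column(s): ",
         paste(missing, collapse = ", "))
  keep <- calls$period >= period_range[1] & calls$period <= period_range[2] &
    abs(calls$ac_coef) > min_ac & calls$pvalue < max_p &
    calls$bh_p < max_adj_p & calls$by_p < max_adj_p
  calls[keep, , drop = FALSE]
}
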