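# Single-cell stages: QC threshold filters, library-size log-normalization,
# epsilon-band three-population stratification on a two-gene
# clock-senescence axis, and per-population rank-sum differential
# expression. All inequalities follow the strict conventions of the QC and
# banding rules (a cell exactly at a threshold is kept / population 1).

#' QC thresholds for single-cell filtering
#'
#' Defaults: remove cells with < 200 detected genes, > 10% mitochondrial
#' reads, > 25% ribosomal reads, < 500 UMIs, > 25,000 UMIs, or > 6,000
#' detected genes.
#' @param min_genes,max_genes,min_umi,max_umi,max_mito_frac,max_ribo_frac
#'   Rule thresholds (strict inequalities fire removal).
#' @export
qc_thresholds <- function(min_genes = 200, max_genes = 6000, min_umi = 500,
                          max_umi = 25000, max_mito_frac = 0.10,
                          max_ribo_frac = 0.25) {
  stopifnot(min_genes < max_genes, min_umi < max_umi)
  list(min_genes = min_genes, max_genes = max_genes, min_umi = min_umi,
       max_umi = max_umi, max_mito_frac = max_mito_frac,
       max_ribo_frac = max_ribo_frac)
}

#' Filter cells on QC statistics
#'
#' A cell is removed if ANY rule fires; per-rule removal counts are
#' reported, and a cell failing several rules counts under each.
#'
#' @param per_cell_stats Data frame with columns `cell_id`,
#'   `detected_genes`, `umi`, `mito_frac`, `ribo_frac`.
#' @param thresholds A [qc_thresholds()] list.
#' @return List with `kept` (cell ids), `removed` (cell ids),
#'   `rule_counts` (named integer vector per rule).
#' @export
qc_filter_cells <- function(per_cell_stats, thresholds = qc_thresholds()) {
  need <- c("cell_id", "detected_genes", "umi", "mito_frac", "ribo_frac")
  missing <- setdiff(need, names(per_cell_stats))
  if (length(missing))
    stop("per_cell_stats is missing column(s): ",
         paste(missing, collapse = ", "))
  s <- per_cell_stats
  th <- thresholds
  rules <- cbind(low_genes  = s$detected_genes < th$min_genes,
                 high_genes = s$detected_genes > th$max_genes,
                 low_umi    = s$umi < th$min_umi,
                 high_umi   = s$umi > th$max_umi,
                 high_mito  = s$mito_frac > th$max_mito_frac,
                 high_ribo  = s$ribo_frac > th$max_ribo_frac)
  drop <- rowSums(rules) > 0
  list(kept = s$cell_id[!drop], removed = s$cell_id[drop],
       rule_counts = colSums(rules))
}

#' Library-size log-normalization
#'
#' `value = ln(1 + count * scale_factor / cell_total)`, the standard
#' single-cell log-normalization. Zero counts map to 0 exactly and the
#' result is invariant to scaling all counts of a cell.
#'
#' @param counts Nonnegative genes x cells count matrix.
#' @param scale_factor Target library size (default 10,000).
#' @return Log-normalized matrix of the same shape.
#' @export
lognormalize <- function(counts, scale_factor = 1e4) {
  if (any(counts < 0)) stop("counts must be nonnegative")
  totals <- colSums(counts)
  if (any(totals == 0)) {
    bad <- colnames(counts)[totals == 0]
    if (is.null(bad)) bad <- which(totals == 0)
    stop("zero-total cell(s): ", paste(bad, collapse = ", "))
  }
  log1p(sweep(counts, 2, totals, "/") * scale_factor)
}

#' Stratify cells into three populations on a two-gene axis
#'
#' On log-normalized coordinates (x = clock gene, y = senescence gene):
#' population 2 if `y > x + epsilon`, population 3 if `y < x - epsilon`,
#' otherwise population 1 (the band around the diagonal). Inequalities are
#' strict, so boundary cells fall in population 1; the partition is
#' exhaustive and exclusive and invariant to adding a common constant to
#' both coordinates.
#'
#' @param x,y Equal-length numeric vectors of log-normalized expression.
#' @param epsilon Band half-width in log units (> 0).
#' @return Integer vector of labels in {1, 2, 3}.
#' @examples
#' stratify_populations(c(1, 1, 2), c(1.2, 2, 1), epsilon = 0.5)
#' @export
stratify_populations <- function(x, y, epsilon = 0.5) {
  if (epsilon <= 0) stop("epsilon must be > 0")
  if (length(x) != length(y)) stop("x and y must have equal length")
  ifelse(y > x + epsilon, 2L, ifelse(y < x - epsilon, 3L, 1L))
}

#' Rank-sum differential expression between two cell populations
#'
#' Per gene: two-sided Wilcoxon rank-sum p-value (normal approximation with
#' average ranks for ties and continuity correction), BH FDR across genes,
#' and `avg_log2FC` computed as the difference of group means on the log2
#' scale (natural-log-normalized values divided by ln 2). Direction is `up`
#' when `fdr < alpha` and `avg_log2FC >= up`, `down` mirror-wise, else `ns`.
#'
#' @param matrix Log-normalized genes x cells matrix (natural log).
#' @param labels Population labels per cell (as from
#'   [stratify_populations()]).
#' @param ref_pop,test_pop Populations to compare (test vs reference).
#' @param alpha FDR significance threshold.
#' @param up,down Log2 fold-change thresholds for calling direction.
#' @return Data frame: gene, avg_log2FC, p, fdr, direction.
#' @export
population_de <- function(matrix, labels, ref_pop = 1, test_pop = 2,
                          alpha = 0.05, up = 0.3, down = -0.3) {
  if (ncol(matrix) != length(labels))
    stop("labels must match matrix columns")
  iref <- labels == ref_pop
  itest <- labels == test_pop
  if (!any(iref) || !any(itest))
    stop("empty population: reference has ", sum(iref), " cells, test has ",
         sum(itest))
  if (sum(iref) < 3 || sum(itest) < 3)
    stop("both populations need >= 3 cells")
  ref <- matrix[, iref, drop = FALSE]
  test <- matrix[, itest, drop = FALSE]
  p <- vapply(seq_len(nrow(matrix)), function(i) {
    a <- test[i, ]; b <- ref[i, ]
    if (max(c(a, b)) == min(c(a, b))) return(1)
    suppressWarnings(
      stats::wilcox.test(a, b, exact = FALSE, correct = TRUE)$p.value)
  }, 0)
  lfc <- (rowMeans(test) - rowMeans(ref)) / log(2)
  fdr <- bh_adjust(p)
  direction <- rep("ns", nrow(matrix))
  direction[fdr < alpha & lfc >= up] <- "up"
  direction[fdr < alpha & lfc <= down] <- "down"
  out <- data.frame(gene = rownames(matrix), avg_log2FC = lfc, p = p,
                    fdr = fdr, direction = direction)
  rownames(out) <- NULL
  out
}
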