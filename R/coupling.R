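# Relational circadian metrics on bulk data: above-mean phase windows and
# pairwise gene coupling (correlation + y-on-x regression) with age
# contrasts. Coupling pools samples across all ZTs within a group; the
# regression is oriented with the senescence gene on y and the clock gene
# on x.

#' Above-mean phase window and normalized profile for one gene
#'
#' Given per-ZT mean expression, returns the set of ZTs at which expression
#' strictly exceeds the cycle mean, together with the min-max normalized
#' (0-1) profile. A constant gene yields an empty window and an all-zero
#' profile.
#'
#' @param zt_means Named numeric vector: names are ZT hours, values are mean
#'   expression across replicates at that ZT. At least 2 distinct ZTs.
#' @return List with `window` (numeric ZT hours above the mean) and
#'   `profile` (named numeric in [0, 1]).
#' @examples
#' above_mean_window(c(`3` = 10, `9` = 8, `15` = 2, `21` = 4))
#' @export
above_mean_window <- function(zt_means) {
  if (length(zt_means) < 2) stop("need >= 2 ZT values")
  if (is.null(names(zt_means))) stop("zt_means must be named by ZT hour")
  v <- as.numeric(zt_means)
  rng <- max(v) - min(v)
  profile <- if (rng == 0) rep(0, length(v)) else (v - min(v)) / rng
  names(profile) <- names(zt_means)
  window <- as.numeric(names(zt_means))[v > mean(v)]
  list(window = window, profile = profile)
}

#' Above-mean phase windows for several genes of a dataset
#'
#' Computes per-ZT means across replicates (within an optional metadata
#' subset) and applies [above_mean_window()] per gene.
#'
#' @param dataset An [expression_dataset()].
#' @param genes Gene identifiers to profile.
#' @param subset Optional logical vector over samples.
#' @return Long data frame: gene, zt, mean_expr, profile, above_mean.
#' @export
phase_windows <- function(dataset, genes, subset = NULL) {
  stopifnot(inherits(dataset, "expression_dataset"))
  missing <- setdiff(genes, dataset$gene_ids)
  if (length(missing))
    stop("gene(s) not in dataset: ", paste(missing, collapse = ", "))
  keep <- if (is.null(subset)) rep(TRUE, ncol(dataset$matrix)) else subset
  zt <- dataset$samples$zt[keep]
  out <- lapply(genes, function(g) {
    v <- dataset$matrix[g, keep]
    zm <- tapply(v, zt, mean)
    w <- above_mean_window(zm)
    data.frame(gene = g, zt = as.numeric(names(zm)), mean_expr = as.numeric(zm),
               profile = as.numeric(w$profile),
               above_mean = as.numeric(names(zm)) %in% w$window)
  })
  do.call(rbind, out)
}

#' Pairwise gene coupling: correlation and y-on-x regression
#'
#' Pearson correlation (with two-sided t-test p-value) and ordinary
#' least-squares slope/intercept of `y` on `x`, after an optional
#' `log(v + 1)` transform of both vectors (the default, matching analyses
#' run on log(TPM + 1)).
#'
#' @param x,y Equal-length numeric expression vectors (n >= 3); `x` is the
#'   clock gene, `y` the downstream/senescence gene.
#' @param transform `"log1p"` or `"none"`.
#' @param gene_x,gene_y Optional labels.
#' @return Object of class `coupling_result`: gene_x, gene_y, n, R, p,
#'   slope, intercept, transform, status (`"ok"` or `"constant_x"`, in which
#'   case R is NaN and slope/intercept are NA).
#' @examples
#' gene_pair_coupling(c(1, 2, 3), c(2, 4, 6), transform = "none")
#' @export
gene_pair_coupling <- function(x, y, transform = c("log1p", "none"),
                               gene_x = "x", gene_y = "y") {
  transform <- match.arg(transform)
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3) stop("need n >= 3 samples")
  if (transform == "log1p") { x <- log1p(x); y <- log1p(y) }
  out <- list(gene_x = gene_x, gene_y = gene_y, n = length(x),
              transform = transform, status = "ok")
  if (stats::sd(x) == 0) {
    out$R <- NaN; out$p <- NA_real_
    out$slope <- NA_real_; out$intercept <- NA_real_
    out$status <- "constant_x"
  } else if (stats::sd(y) == 0) {
    out$R <- NaN; out$p <- NA_real_
    out$slope <- 0; out$intercept <- y[1]
    out$status <- "constant_y"
  } else {
    ct <- stats::cor.test(x, y, method = "pearson")
    out$R <- unname(ct$estimate)
    out$p <- ct$p.value
    out$slope <- stats::cov(x, y) / stats::var(x)
    out$intercept <- mean(y) - out$slope * mean(x)
  }
  class(out) <- "coupling_result"
  out
}

#' @export
print.coupling_result <- function(x, ...) {
  cat(sprintf("coupling %s ~ %s (n=%d, %s): R=%.4g, p=%.3g, y = %.4g + %.4g x\n",
              x$gene_y, x$gene_x, x$n, x$transform, x$R, x$p,
              x$intercept, x$slope))
  if (x$status != "ok") cat("  status:", x$status, "\n")
  invisible(x)
}

#' Per-group coupling of one gene pair across a dataset
#'
#' Pools samples over all ZTs within each group (default age_group x sex)
#' and computes [gene_pair_coupling()] per group.
#'
#' @param dataset An [expression_dataset()].
#' @param gene_x,gene_y Gene identifiers (x = clock gene, y = target).
#' @param transform `"log1p"` (default) or `"none"`.
#' @param group_by Metadata columns defining groups; `NULL` pools all.
#' @param per_zt_means Use per-ZT means instead of per-sample points.
#' @return Data frame with one row per group plus a `fits` attribute holding
#'   the `coupling_result` objects.
#' @export
couple_genes <- function(dataset, gene_x, gene_y,
                         transform = c("log1p", "none"),
                         group_by = c("age_group", "sex"),
                         per_zt_means = FALSE) {
  stopifnot(inherits(dataset, "expression_dataset"))
  transform <- match.arg(transform)
  for (g in c(gene_x, gene_y))
    if (!g %in% dataset$gene_ids) stop("gene not in dataset: ", g)
  meta <- dataset$samples
  groups <- if (is.null(group_by)) rep("all", nrow(meta))
  else interaction(meta[group_by], sep = ".", drop = TRUE)
  fits <- lapply(split(seq_len(nrow(meta)), groups), function(idx) {
    xv <- dataset$matrix[gene_x, idx]
    yv <- dataset$matrix[gene_y, idx]
    if (per_zt_means) {
      zt <- meta$zt[idx]
      xv <- as.numeric(tapply(xv, zt, mean))
      yv <- as.numeric(tapply(yv, zt, mean))
    }
    gene_pair_coupling(xv, yv, transform, gene_x, gene_y)
  })
  out <- data.frame(group = names(fits),
                    gene_x = gene_x, gene_y = gene_y,
                    n = vapply(fits, `[[`, 0, "n"),
                    R = vapply(fits, `[[`, 0, "R"),
                    p = vapply(fits, function(f) f$p %||% NA_real_, 0),
                    slope = vapply(fits, `[[`, 0, "slope"),
                    intercept = vapply(fits, `[[`, 0, "intercept"),
                    status = vapply(fits, `[[`, "", "status"))
  rownames(out) <- NULL
  attr(out, "fits") <- fits
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Age contrast of two coupling results
#'
#' Differences (old minus young) of the correlation and the regression
#' intercept for the same gene pair under the same transform.
#'
#' @param young,old `coupling_result` objects for the same pair/transform.
#' @return List of class `coupling_contrast` with R_young, R_old, delta_R,
#'   intercept_young, intercept_old, delta_intercept.
#' @export
coupling_contrast <- function(young, old) {
  stopifnot(inherits(young, "coupling_result"),
            inherits(old, "coupling_result"))
  if (young$gene_x != old$gene_x || young$gene_y != old$gene_y)
    stop("coupling results are for different gene pairs")
  if (young$transform != old$transform)
    stop("coupling results use different transforms")
  structure(list(gene_x = young$gene_x, gene_y = young$gene_y,
                 R_young = young$R, R_old = old$R,
                 delta_R = old$R - young$R,
                 intercept_young = young$intercept,
                 intercept_old = old$intercept,
                 delta_intercept = old$intercept - young$intercept),
            class = "coupling_contrast")
}

#' @export
print.coupling_contrast <- function(x, ...) {
  cat(sprintf("coupling contrast %s ~ %s (old - young):\n", x$gene_y,
              x$gene_x))
  cat(sprintf("  R: %.4g -> %.4g (delta %+.4g)\n", x$R_young, x$R_old,
              x$delta_R))
  cat(sprintf("  intercept: %.4g -> %.4g (delta %+.4g)\n",
              x$intercept_young, x$intercept_old, x$delta_intercept))
  invisible(x)
}
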