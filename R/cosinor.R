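# Per-gene cosinor regression and circadian classification.
#
# The rhythm model is y = M + A*cos(2*pi*(t - phi)/period), fit linearly via
# y ~ sin(2*pi*t/period) + cos(2*pi*t/period). Amplitude and acrophase are
# derived from the sine/cosine coefficients; the joint amplitude test is the
# 2-df F-test of both harmonic terms; the acrophase standard error comes
# from the delta method. Model adequacy is checked with simulated quantile
# residuals (parametric simulation from the fitted Gaussian model, followed
# by a Kolmogorov-Smirnov uniformity test).

#' Fit a fixed-effects cosinor model to one gene
#'
#' Least-squares fit of
#' `y = M + beta_sin*sin(2*pi*t/period) + beta_cos*cos(2*pi*t/period)`.
#' Replicates are treated as independent observations. The amplitude is
#' `A = sqrt(beta_sin^2 + beta_cos^2)` and the acrophase (peak time) is
#' `phi = (period/(2*pi)) * atan2(beta_sin, beta_cos)` mapped into
#' `[0, period)`.
#'
#' @param y Numeric expression vector.
#' @param t Numeric vector of sampling times in hours (same length as `y`,
#'   at least 4 observations over at least 3 distinct times).
#' @param period Oscillation period in hours (fixed; default 24).
#' @param gene Optional gene label carried through to output.
#' @return An object of class `cosinor_fit` with components `mesor`,
#'   `amplitude`, `acrophase`, `p_sin`, `p_cos`, `p_amplitude`, `phase_se`,
#'   `sigma`, `fitted`, `residuals`, plus the data. `resid_p` and
#'   `is_circadian` are filled in by [quantile_residual_check()] and
#'   [classify_circadian()].
#' @examples
#' t <- rep(c(3, 9, 15, 21), each = 3)
#' y <- 5 + 2 * cos(2 * pi * (t - 3) / 24)
#' fit <- fit_cosinor(y, t)
#' coef(fit)
#' @export
fit_cosinor <- function(y, t, period = 24, gene = NA_character_) {
  if (length(y) != length(t)) stop("y and t must have equal length")
  if (length(y) < 4) stop("need >= 4 observations")
  if (length(unique(t)) < 3)
    stop("need >= 3 distinct timepoints; design is rank-deficient")
  if (anyNA(y) || anyNA(t)) stop("y and t must not contain NA")
  if (period <= 0) stop("period must be > 0")

  s <- sin(2 * pi * t / period)
  co <- cos(2 * pi * t / period)
  n <- length(y)

  if (stats::var(y) == 0) {
    fit <- list(gene = gene, mesor = y[1], amplitude = 0,
                acrophase = NA_real_, beta_sin = 0, beta_cos = 0,
                p_sin = 1, p_cos = 1, p_amplitude = 1, phase_se = Inf,
                sigma = 0, period = period, n = n, y = y, t = t,
                fitted = rep(y[1], n), residuals = rep(0, n),
                df_residual = n - 3, resid_p = NA_real_,
                is_circadian = NA)
    class(fit) <- "cosinor_fit"
    return(fit)
  }

  lmfit <- stats::lm(y ~ s + co)
  sm <- suppressWarnings(summary(lmfit))  # exact fits are legitimate here
  beta <- stats::coef(lmfit)
  bs <- beta[["s"]]; bc <- beta[["co"]]
  A <- sqrt(bs^2 + bc^2)
  phi <- ((period / (2 * pi)) * atan2(bs, bc)) %% period

  p_sin <- sm$coefficients["s", "Pr(>|t|)"]
  p_cos <- sm$coefficients["co", "Pr(>|t|)"]
  # joint 2-df F-test of (beta_sin, beta_cos)
  lm0 <- stats::lm(y ~ 1)
  an <- suppressWarnings(stats::anova(lm0, lmfit))
  p_amp <- an[["Pr(>F)"]][2]
  if (is.na(p_amp)) p_amp <- 1  # saturated/degenerate residuals

  # delta-method SE of the acrophase
  V <- suppressWarnings(stats::vcov(lmfit))[c("s", "co"), c("s", "co")]
  grad <- (period / (2 * pi)) * c(bc, -bs) / A^2
  phase_var <- drop(t(grad) %*% V %*% grad)
  phase_se <- if (A > 0 && is.finite(phase_var) && phase_var >= 0)
    sqrt(phase_var) else Inf

  fit <- list(gene = gene, mesor = beta[["(Intercept)"]], amplitude = A,
              acrophase = phi, beta_sin = bs, beta_cos = bc,
              p_sin = p_sin, p_cos = p_cos, p_amplitude = p_amp,
              phase_se = phase_se, sigma = sm$sigma, period = period,
              n = n, y = y, t = t, fitted = stats::fitted(lmfit),
              residuals = stats::residuals(lmfit),
              df_residual = lmfit$df.residual, resid_p = NA_real_,
              is_circadian = NA)
  class(fit) <- "cosinor_fit"
  fit
}

#' @export
print.cosinor_fit <- function(x, ...) {
  cat("Cosinor fit", if (!is.na(x$gene)) paste0("(", x$gene, ")"),
      "- period", x$period, "h,", x$n, "observations\n")
  cat(sprintf("  mesor %.4g, amplitude %.4g, acrophase %.4g h (SE %.3g h)\n",
              x$mesor, x$amplitude, x$acrophase, x$phase_se))
  cat(sprintf("  p_sin %.3g, p_cos %.3g, p_amplitude %.3g, resid_p %s\n",
              x$p_sin, x$p_cos, x$p_amplitude,
              ifelse(is.na(x$resid_p), "<not run>",
                     sprintf("%.3g", x$resid_p))))
  if (!is.na(x$is_circadian))
    cat("  classified circadian:", x$is_circadian, "\n")
  invisible(x)
}

#' @export
coef.cosinor_fit <- function(object, ...) {
  c(mesor = object$mesor, amplitude = object$amplitude,
    acrophase = object$acrophase)
}

#' @export
fitted.cosinor_fit <- function(object, ...) object$fitted

#' @export
residuals.cosinor_fit <- function(object, ...) object$residuals

#' @export
predict.cosinor_fit <- function(object, newtimes = NULL, ...) {
  if (is.null(newtimes)) return(object$fitted)
  object$mesor +
    object$beta_sin * sin(2 * pi * newtimes / object$period) +
    object$beta_cos * cos(2 * pi * newtimes / object$period)
}

#' @export
summary.cosinor_fit <- function(object, ...) {
  out <- data.frame(gene = object$gene, mesor = object$mesor,
                    amplitude = object$amplitude,
                    acrophase = object$acrophase,
                    phase_se = object$phase_se, p_sin = object$p_sin,
                    p_cos = object$p_cos, p_amplitude = object$p_amplitude,
                    resid_p = object$resid_p, sigma = object$sigma,
                    n = object$n, period = object$period,
                    is_circadian = object$is_circadian)
  rownames(out) <- NULL
  out
}

#' @export
plot.cosinor_fit <- function(x, ...) {
  tt <- seq(0, x$period, length.out = 200)
  plot(x$t, x$y, xlab = "time (h)", ylab = "expression",
       main = if (!is.na(x$gene)) x$gene else "cosinor fit", ...)
  graphics::lines(tt, predict(x, tt), col = "steelblue", lwd = 2)
  graphics::abline(h = x$mesor, lty = 3)
  invisible(x)
}

#' Simulated quantile-residual uniformity check
#'
#' Parametric analogue of simulated quantile residuals for the Gaussian
#' cosinor: `n_sim` response sets are simulated from the fitted model, each
#' observation's quantile among its simulated values is computed, and the
#' quantiles are tested for uniformity against U(0, 1) with a one-sample
#' Kolmogorov-Smirnov test. A small p-value flags model inadequacy (for
#' example timepoint-dependent variance).
#'
#' @param fit A `cosinor_fit`.
#' @param n_sim Number of simulated response sets (>= 20).
#' @param seed Integer seed; identical seed gives an identical p-value.
#' @return The fit with `resid_p` filled in.
#' @export
quantile_residual_check <- function(fit, n_sim = 250, seed = 1) {
  stopifnot(inherits(fit, "cosinor_fit"))
  if (n_sim < 20) stop("n_sim must be >= 20")
  if (fit$sigma == 0) {
    fit$resid_p <- 1  # degenerate: model reproduces data exactly
    return(fit)
  }
  with_seed(seed, {
    n <- fit$n
    sims <- matrix(stats::rnorm(n * n_sim, mean = fit$fitted,
                                sd = fit$sigma), nrow = n)
    u <- (rowSums(sims < fit$y) + 0.5) / (n_sim + 1)
    fit$resid_p <- suppressWarnings(
      stats::ks.test(u, "punif")$p.value)
  })
  fit
}

#' Classify a fitted gene as circadian
#'
#' A gene is flagged circadian when it has a significant sine or cosine
#' coefficient, a significant joint amplitude test, an acrophase estimate
#' whose 95% CI is narrower than half the cycle (`1.96 * phase_se < 12`),
#' and an adequate model fit (`resid_p > resid_threshold`).
#'
#' @param fit A `cosinor_fit` with `resid_p` set (see
#'   [quantile_residual_check()]); a missing `resid_p` fails the check.
#' @param alpha Significance level for the coefficient and amplitude tests.
#' @param resid_threshold Lower bound the residual uniformity p-value must
#'   exceed.
#' @return The fit with `is_circadian` set.
#' @export
classify_circadian <- function(fit, alpha = 0.05, resid_threshold = 0.05) {
  stopifnot(inherits(fit, "cosinor_fit"))
  flag <- isTRUE(min(fit$p_sin, fit$p_cos) < alpha) &&
    isTRUE(fit$p_amplitude < alpha) &&
    isTRUE(1.96 * fit$phase_se < 12) &&
    isTRUE(fit$resid_p > resid_threshold)
  fit$is_circadian <- flag
  fit
}

#' Cosinor-fit every gene of a dataset, optionally within groups
#'
#' Vectorised per-group fitting: within each group the harmonic design
#' matrix is shared by all genes, so coefficients, standard errors and the
#' joint amplitude F-test are computed with one linear-algebra pass. Results
#' match per-gene [fit_cosinor()] calls exactly.
#'
#' @param dataset An [expression_dataset()].
#' @param group_by Metadata columns to stratify by (default age_group and
#'   sex); `NULL` fits one pooled model per gene.
#' @param period Period in hours.
#' @param alpha,resid_threshold Classification thresholds, see
#'   [classify_circadian()].
#' @param n_sim Simulations for the residual check; 0 skips it (resid_p NA,
#'   classification then fails the residual criterion).
#' @param seed Seed for the residual-check simulations.
#' @param adjust Apply BH adjustment to `p_amplitude` across genes within
#'   each group and classify on the adjusted value (default FALSE: raw
#'   alpha).
#' @return Data frame with one row per gene per group.
#' @export
cosinor_by_gene <- function(dataset, group_by = c("age_group", "sex"),
                            period = 24, alpha = 0.05,
                            resid_threshold = 0.05, n_sim = 250, seed = 1,
                            adjust = FALSE) {
  stopifnot(inherits(dataset, "expression_dataset"))
  meta <- dataset$samples
  groups <- if (is.null(group_by)) rep("all", nrow(meta))
  else interaction(meta[group_by], sep = ".", drop = TRUE)
  out <- lapply(split(seq_len(nrow(meta)), groups), function(idx) {
    Y <- dataset$matrix[, idx, drop = FALSE]
    tt <- meta$zt[idx]
    res <- fit_cosinor_matrix(Y, tt, period = period)
    if (n_sim > 0) {
      res$resid_p <- resid_check_matrix(Y, tt, res, period, n_sim, seed)
    }
    p_cls <- if (adjust) bh_adjust(res$p_amplitude) else res$p_amplitude
    res$fdr_amplitude <- bh_adjust(res$p_amplitude)
    res$is_circadian <- pmin(res$p_sin, res$p_cos) < alpha &
      p_cls < alpha & 1.96 * res$phase_se < 12 &
      !is.na(res$resid_p) & res$resid_p > resid_threshold
    res
  })
  grp_names <- rep(names(out), vapply(out, nrow, 0L))
  out <- do.call(rbind, out)
  out <- cbind(group = grp_names, out)
  rownames(out) <- NULL
  out
}

# One-pass least squares for all genes sharing a time vector.
fit_cosinor_matrix <- function(Y, t, period = 24) {
  if (length(unique(t)) < 3)
    stop("need >= 3 distinct timepoints; design is rank-deficient")
  n <- length(t)
  X <- cbind(1, sin(2 * pi * t / period), cos(2 * pi * t / period))
  XtXi <- solve(crossprod(X))
  B <- Y %*% X %*% XtXi            # genes x 3 coefficients
  fittedM <- B %*% t(X)
  R <- Y - fittedM
  rss <- rowSums(R^2)
  dfres <- n - 3
  sigma2 <- rss / dfres
  se <- sqrt(outer(sigma2, diag(XtXi)))
  tstat <- B / se
  p_sin <- 2 * stats::pt(abs(tstat[, 2]), dfres, lower.tail = FALSE)
  p_cos <- 2 * stats::pt(abs(tstat[, 3]), dfres, lower.tail = FALSE)
  rss0 <- rowSums((Y - rowMeans(Y))^2)
  Fstat <- ((rss0 - rss) / 2) / sigma2
  p_amp <- stats::pf(Fstat, 2, dfres, lower.tail = FALSE)
  bs <- B[, 2]; bc <- B[, 3]
  A <- sqrt(bs^2 + bc^2)
  phi <- ((period / (2 * pi)) * atan2(bs, bc)) %% period
  Vsub <- XtXi[2:3, 2:3]
  k <- period / (2 * pi)
  phase_var <- sigma2 * k^2 *
    (bc^2 * Vsub[1, 1] - 2 * bs * bc * Vsub[1, 2] + bs^2 * Vsub[2, 2]) / A^4
  phase_se <- ifelse(A > 0, sqrt(phase_var), Inf)
  # flat genes: zero-variance response gets the degenerate convention
  flat <- rss0 == 0
  if (any(flat)) {
    A[flat] <- 0
    phi[flat] <- NA_real_
    p_sin[flat] <- 1; p_cos[flat] <- 1; p_amp[flat] <- 1
    phase_se[flat] <- Inf
  }
  p_amp[is.na(p_amp)] <- 1
  data.frame(gene = rownames(Y), mesor = B[, 1], amplitude = A,
             acrophase = phi, phase_se = phase_se, p_sin = p_sin,
             p_cos = p_cos, p_amplitude = p_amp,
             sigma = sqrt(sigma2), n = n, period = period,
             resid_p = NA_real_)
}

resid_check_matrix <- function(Y, t, res, period, n_sim, seed) {
  X <- cbind(1, sin(2 * pi * t / period), cos(2 * pi * t / period))
  with_seed(seed, {
    vapply(seq_len(nrow(Y)), function(i) {
      if (res$sigma[i] == 0) return(1)
      # fitted values reconstructed from the harmonic coefficients
      bs <- res$amplitude[i] * sin(2 * pi * res$acrophase[i] / period)
      bc <- res$amplitude[i] * cos(2 * pi * res$acrophase[i] / period)
      if (is.na(res$acrophase[i])) { bs <- 0; bc <- 0 }
      mu <- res$mesor[i] + bs * X[, 2] + bc * X[, 3]
      sims <- matrix(stats::rnorm(length(mu) * n_sim, mean = mu,
                                  sd = res$sigma[i]), nrow = length(mu))
      u <- (rowSums(sims < Y[i, ]) + 0.5) / (n_sim + 1)
      suppressWarnings(stats::ks.test(u, "punif")$p.value)
    }, 0)
  })
}

#' Brown-Forsythe differential variability between two groups
#'
#' Levene-type test of equal variance using absolute deviations from group
#' medians: a one-way F on the deviations with 1 and `n_a + n_b - 2` degrees
#' of freedom. Robust to non-normality; used to detect age-related variance
#' inflation.
#'
#' @param values_a,values_b Numeric vectors, each of length >= 3.
#' @return List with `statistic` (F-ratio), `p`, `df`.
#' @examples
#' differential_variability(c(1, 2, 3), c(0, 4, 8))  # F = 72/34
#' @export
differential_variability <- function(values_a, values_b) {
  if (length(values_a) < 3 || length(values_b) < 3)
    stop("each group needs >= 3 values")
  da <- abs(values_a - stats::median(values_a))
  db <- abs(values_b - stats::median(values_b))
  na <- length(da); nb <- length(db)
  gm <- mean(c(da, db))
  ssb <- na * (mean(da) - gm)^2 + nb * (mean(db) - gm)^2
  ssw <- sum((da - mean(da))^2) + sum((db - mean(db))^2)
  df2 <- na + nb - 2
  if (ssw == 0) {
    # both groups' deviations constant: no evidence either way
    stat <- 0
    p <- 1
  } else {
    stat <- ssb / (ssw / df2)
    p <- stats::pf(stat, 1, df2, lower.tail = FALSE)
  }
  list(statistic = stat, p = p, df = c(1, df2))
}

#' Per-gene differential variability across an age contrast
#'
#' Applies [differential_variability()] to every gene, contrasting the two
#' levels of a metadata column (default `age_group`), with BH FDR across
#' genes.
#'
#' @param dataset An [expression_dataset()].
#' @param contrast Metadata column with exactly two levels.
#' @return Data frame: gene, bf_statistic, p, fdr.
#' @export
dv_by_gene <- function(dataset, contrast = "age_group") {
  stopifnot(inherits(dataset, "expression_dataset"))
  g <- dataset$samples[[contrast]]
  lv <- unique(g)
  if (length(lv) != 2) stop("contrast column must have exactly two levels")
  ia <- g == lv[1]; ib <- g == lv[2]
  res <- apply(dataset$matrix, 1, function(v)
    differential_variability(v[ia], v[ib]))
  out <- data.frame(gene = dataset$gene_ids,
                    bf_statistic = vapply(res, `[[`, 0, "statistic"),
                    p = vapply(res, `[[`, 0, "p"))
  out$fdr <- bh_adjust(out$p)
  rownames(out) <- NULL
  out
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Standard step-up false-discovery-rate adjustment, monotone in rank and
#' clipped to 1. Empty input returns an empty vector.
#'
#' @param pvals Numeric vector of p-values in [0, 1].
#' @return Adjusted values in the input order.
#' @export
bh_adjust <- function(pvals) {
  if (!length(pvals)) return(numeric(0))
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvals, method = "BH")
}
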