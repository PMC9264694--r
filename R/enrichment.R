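#' Storey's pi1 replication estimate
#'
#' Estimates the fraction of non-null associations `pi1 = 1 - pi0` in a set
#' of replication p-values. `pi0` is estimated by the Storey smoother: the
#' tail proportions `pi0(lambda) = mean(p > lambda) / (1 - lambda)` are
#' computed over `lambda = 0.05, 0.10, ..., 0.95` and a cubic smoothing
#' spline (3 df) is evaluated at the largest lambda. With fewer than 100
#' p-values the smoother is unstable, so a single conservative evaluation
#' at `lambda = 0.5` is used instead, with a warning.
#'
#' @param p_values Numeric vector of p-values in `(0, 1]`.
#' @return An object of class `decaf_enrichment` with `method = "pi1"`,
#'   `estimate` (pi1, clamped to `[0, 1]`), `pi0` and `n_foreground`.
#' @export
pi1 <- function(p_values) {
  p <- p_values[!is.na(p_values)]
  if (length(p) == 0) stop("no p-values supplied")
  if (any(p <= 0 | p > 1)) stop("p-values must lie in (0, 1]")
  if (length(p) < 100) {
    warning("fewer than 100 p-values; using single-lambda (0.5) estimate")
    pi0 <- min(1, mean(p > 0.5) / 0.5)
  } else {
    lambda <- seq(0.05, 0.95, by = 0.05)
    pi0_l <- vapply(lambda, function(l) mean(p > l) / (1 - l), numeric(1))
    fit <- stats::smooth.spline(lambda, pi0_l, df = 3)
    pi0 <- stats::predict(fit, x = max(lambda))$y
    pi0 <- min(max(pi0, 0), 1)
  }
  structure(list(method = "pi1", estimate = 1 - pi0, pi0 = pi0,
                 p = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                 n_foreground = length(p), n_background = NA_integer_,
                 n_resamples = NA_integer_),
            class = "decaf_enrichment")
}

#' Fisher's exact enrichment of QTLs in GWAS hits
#'
#' Builds the 2x2 contingency table of QTL significance (e.g. FDR < 20%)
#' against GWAS significance (e.g. p < 0.001) over a shared SNP universe and
#' runs Fisher's exact test (conditional-ML odds ratio, exact two-sided p,
#' 95% CI). The p-value can be Bonferroni-adjusted for the number of cell
#' types tested.
#'
#' @param qtl_significant,gwas_significant Aligned logical vectors over the
#'   tested SNPs.
#' @param n_tests Bonferroni divisor applied to the reported adjusted
#'   p-value (default 1).
#' @return A `decaf_enrichment` with `method = "fisher"`, `estimate`
#'   (odds ratio; `NA` with a `structural_zero` flag when a table margin is
#'   zero), `p`, `p_adjusted`, `ci_low`, `ci_high` and the table.
#' @export
fisher_enrichment <- function(qtl_significant, gwas_significant,
                              n_tests = 1) {
  stopifnot(length(qtl_significant) == length(gwas_significant),
            is.logical(qtl_significant), is.logical(gwas_significant))
  tab <- table(factor(qtl_significant, levels = c(TRUE, FALSE)),
               factor(gwas_significant, levels = c(TRUE, FALSE)),
               dnn = c("qtl", "gwas"))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    return(structure(list(method = "fisher", estimate = NA_real_,
                          p = NA_real_, p_adjusted = NA_real_,
                          ci_low = NA_real_, ci_high = NA_real_,
                          table = tab, structural_zero = TRUE,
                          n_foreground = sum(qtl_significant),
                          n_background = sum(!qtl_significant),
                          n_resamples = NA_integer_),
                     class = "decaf_enrichment"))
  }
  ft <- stats::fisher.test(tab)
  structure(list(method = "fisher", estimate = unname(ft$estimate),
                 p = ft$p.value, p_adjusted = min(1, ft$p.value * n_tests),
                 ci_low = ft$conf.int[1], ci_high = ft$conf.int[2],
                 table = tab, structural_zero = FALSE,
                 n_foreground = sum(qtl_significant),
                 n_background = sum(!qtl_significant),
                 n_resamples = NA_integer_),
            class = "decaf_enrichment")
}

#' Mean-Z-squared enrichment against a resampled background
#'
#' Ratio of the mean squared Z score of a foreground SNP set (e.g.
#' significant cfQTLs overlapping a GWAS category) over the mean of
#' `n_resamples` size-matched background resamples (without replacement),
#' with an empirical p-value: the fraction of resample means at least as
#' large as the foreground mean.
#'
#' @param foreground_z Z scores of the foreground SNPs.
#' @param background_z Z scores of the background pool (at least as many as
#'   the foreground).
#' @param n_resamples Number of background resamples (default 100).
#' @param seed Optional seed for reproducible resampling.
#' @return A `decaf_enrichment` with `method = "z2"`, `estimate` (the
#'   ratio), `p` (empirical), and bookkeeping counts.
#' @export
z2_enrichment <- function(foreground_z, background_z, n_resamples = 100,
                          seed = NULL) {
  foreground_z <- foreground_z[is.finite(foreground_z)]
  background_z <- background_z[is.finite(background_z)]
  if (length(foreground_z) == 0) stop("empty foreground")
  if (length(background_z) < length(foreground_z))
    stop("background must be at least as large as foreground")
  if (!is.null(seed)) set.seed(seed)
  fg_mean <- mean(foreground_z^2)
  k <- length(foreground_z)
  null_means <- vapply(seq_len(n_resamples), function(i) {
    mean(sample(background_z, k, replace = FALSE)^2)
  }, numeric(1))
  structure(list(method = "z2", estimate = fg_mean / mean(null_means),
                 p = mean(null_means >= fg_mean),
                 ci_low = NA_real_, ci_high = NA_real_,
                 n_foreground = k, n_background = length(background_z),
                 n_resamples = n_resamples),
            class = "decaf_enrichment")
}

#' @export
print.decaf_enrichment <- function(x, ...) {
  lab <- switch(x$method, pi1 = "pi1", fisher = "odds ratio",
                z2 = "mean Z^2 ratio")
  cat(sprintf("Enrichment (%s): %s = %.4f", x$method, lab, x$estimate))
  if (is.finite(x$p)) cat(sprintf(", p = %.4g", x$p))
  cat("\n")
  invisible(x)
}
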