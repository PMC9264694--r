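# Fast OLS with t-derived signed z per coefficient. The signed z is the
# standard-normal quantile of the two-sided t p-value, keeping the sign of t,
# so eQTL statistics are commensurate with the Wald z of the allelic model.
.ols_zfit <- function(X, y) {
  qrx <- qr(X)
  if (qrx$rank < ncol(X)) return(NULL)
  coef <- qr.coef(qrx, y)
  res <- y - drop(X %*% coef)
  df <- length(y) - ncol(X)
  if (df < 1) return(NULL)
  rss <- sum(res^2)
  sigma2 <- rss / df
  cov <- chol2inv(qr.R(qrx)) * sigma2
  se <- sqrt(diag(cov))
  tval <- coef / se
  logp <- stats::pt(-abs(tval), df, log.p = TRUE)        # log of one tail
  z <- sign(tval) * stats::qnorm(logp, lower.tail = FALSE, log.p = TRUE)
  p <- 2 * exp(logp)
  tss <- sum((y - mean(y))^2)
  list(coefficients = coef, se = se, t = tval, z = z, p = p,
       df = df, r2 = if (tss > 0) 1 - rss / tss else NA_real_)
}

# Rank-based inverse-normal transform (Blom-type offset 0.5).
.inverse_normal <- function(y) {
  stats::qnorm((rank(y, ties.method = "average") - 0.5) / length(y))
}

#' Fit the interaction eQTL (ieQTL) linear model
#'
#' Ordinary least squares on total expression with genotype x cell-fraction
#' (and optionally genotype x purity) interaction terms plus a local CNV
#' covariate. The coefficient tested depends on `mode`:
#' \describe{
#'   \item{cf}{the genotype x fraction interaction (`x:f`) — cell-fraction
#'     QTL. Design: intercept, `x`, `f`, `x:f`, plus `purity`, `x:purity`
#'     and `cnv` when supplied.}
#'   \item{ts}{the genotype x purity interaction (`x:purity`) —
#'     tumor-specific QTL.}
#'   \item{marginal}{the genotype main effect `x`, with no interaction
#'     terms (main-effect covariates are retained).}
#' }
#'
#' @param y Numeric expression vector (normalized upstream; see
#'   `inverse_normal`).
#' @param x Genotype dosage vector (0/1/2 alternative-allele count).
#' @param f Optional cell-fraction vector.
#' @param purity Optional tumor-purity vector in `[0, 1]`.
#' @param cnv Optional per-individual local CNV value (segment mean).
#' @param covariates Optional numeric matrix of additional covariates
#'   (main effects only).
#' @param mode One of `"cf"`, `"ts"`, `"marginal"`.
#' @param inverse_normal Apply a rank-based inverse-normal transform to `y`
#'   before fitting (default `FALSE`).
#' @return An object of class `decaf_eqtlfit`: list with `coefficients`,
#'   `se`, `z`, `p` (named vectors), `test` (name of the tested
#'   coefficient), `z_test`, `p_test`, `n`, `df`, `r2`, `identifiable`.
#' @examples
#' n <- 200; x <- rbinom(n, 2, 0.3); f <- runif(n)
#' y <- 1 + 2 * x + 0.5 * f + 3 * x * f + rnorm(n)
#' fit_ieqtl(y, x, f, mode = "cf")$z_test
#' @export
fit_ieqtl <- function(y, x, f = NULL, purity = NULL, cnv = NULL,
                      covariates = NULL, mode = c("cf", "ts", "marginal"),
                      inverse_normal = FALSE) {
  mode <- match.arg(mode)
  stopifnot(length(x) == length(y))
  if (stats::sd(y) == 0) stop("expression has zero variance")
  if (inverse_normal) y <- .inverse_normal(y)
  n <- length(y)
  X <- cbind(mu = rep(1, n), x = x)
  if (mode == "cf" && is.null(f)) stop("mode 'cf' requires f")
  if (mode == "ts" && is.null(purity)) stop("mode 'ts' requires purity")
  if (!is.null(f)) {
    X <- cbind(X, f = f)
    if (mode != "marginal") X <- cbind(X, `x:f` = x * f)
  }
  if (!is.null(purity)) {
    X <- cbind(X, purity = purity)
    if (mode != "marginal") X <- cbind(X, `x:purity` = x * purity)
  }
  if (!is.null(cnv) && stats::sd(cnv) > 0) X <- cbind(X, cnv = cnv)
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    colnames(covariates) <- colnames(covariates) %||%
      paste0("cov", seq_len(ncol(covariates)))
    X <- cbind(X, covariates)
  }
  test <- switch(mode, cf = "x:f", ts = "x:purity", marginal = "x")
  notid <- function() {
    structure(list(coefficients = NULL, se = NULL, z = NULL, p = NULL,
                   test = test, z_test = NA_real_, p_test = NA_real_,
                   n = n, df = NA_integer_, r2 = NA_real_,
                   identifiable = FALSE),
              class = "decaf_eqtlfit")
  }
  if (n < ncol(X) + 2) return(notid())
  fit <- .ols_zfit(X, y)
  if (is.null(fit)) return(notid())
  structure(list(coefficients = fit$coefficients, se = fit$se, z = fit$z,
                 p = fit$p, test = test,
                 z_test = unname(fit$z[test]), p_test = unname(fit$p[test]),
                 n = n, df = fit$df, r2 = fit$r2, identifiable = TRUE),
            class = "decaf_eqtlfit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.decaf_eqtlfit <- function(x, ...) {
  cat("Interaction eQTL (OLS) fit\n")
  if (!x$identifiable) {
    cat("  not identifiable\n")
    return(invisible(x))
  }
  tab <- cbind(estimate = x$coefficients, se = x$se, z = x$z, p = x$p)
  print(round(tab, 4))
  cat(sprintf("  n = %d, r2 = %.3f, tested: %s (z = %.3f)\n",
              x$n, x$r2, x$test, x$z_test))
  invisible(x)
}
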