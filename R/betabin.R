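#' Beta-binomial log-density (intraclass-correlation parameterization)
#'
#' Density of `k` successes in `n` trials where the success probability is
#' Beta-distributed with mean `p` and intraclass correlation (overdispersion)
#' `rho`, i.e. shape parameters `a = p(1-rho)/rho`, `b = (1-p)(1-rho)/rho`.
#' At `rho = 0` the density reduces to the binomial.
#'
#' @param k Number of successes (alternative-allele reads).
#' @param n Number of trials (total read depth).
#' @param p Mean success probability in (0, 1).
#' @param rho Overdispersion in `[0, 1)`.
#' @param log If `TRUE` (default `FALSE`), return log-density.
#' @return Numeric vector of (log-)densities, recycled to common length.
#' @examples
#' dbetabinom(5, 10, 0.5, 0)      # == dbinom(5, 10, 0.5)
#' dbetabinom(6, 10, 0.5, 0.0263)
#' @export
dbetabinom <- function(k, n, p, rho, log = FALSE) {
  m <- max(length(k), length(n), length(p), length(rho))
  k <- rep_len(k, m); n <- rep_len(n, m)
  p <- rep_len(p, m); rho <- rep_len(rho, m)
  stopifnot(all(rho >= 0), all(rho < 1), all(p > 0), all(p < 1))
  out <- numeric(m)
  bb <- rho > 0
  if (any(bb)) {
    s <- (1 - rho[bb]) / rho[bb]
    a <- p[bb] * s
    b <- (1 - p[bb]) * s
    out[bb] <- lchoose(n[bb], k[bb]) +
      lgamma(k[bb] + a) + lgamma(n[bb] - k[bb] + b) - lgamma(n[bb] + s) -
      lgamma(a) - lgamma(b) + lgamma(s)
  }
  if (any(!bb)) {
    out[!bb] <- stats::dbinom(k[!bb], n[!bb], p[!bb], log = TRUE)
  }
  if (log) out else exp(out)
}

#' Beta-binomial regression log-likelihood for allelic counts
#'
#' Log-likelihood of alternative-allele read counts under a beta-binomial
#' regression with logit link. For observation i with design row `d_i`,
#' the mean allelic fraction is `p_i = plogis(d_i %*% coefficients)` and the
#' count follows `BetaBin(depth_i, p_i, rho_i)` with the per-individual
#' overdispersion `rho_i` held fixed. `rho_i = 0` gives the binomial term.
#'
#' @param counts Data frame of allelic observations with columns `alt_reads`,
#'   `depth` and `overdispersion` (see [simulate_allelic()] or
#'   [build_test_unit()]).
#' @param coefficients Numeric coefficient vector, length `ncol(design)`.
#' @param design Numeric design matrix, one row per observation.
#' @return The scalar log-likelihood.
#' @export
betabin_loglik <- function(counts, coefficients, design) {
  design <- as.matrix(design)
  stopifnot(nrow(design) == nrow(counts), ncol(design) == length(coefficients))
  if (any(counts$depth < 1)) stop("observations with depth 0 are not allowed")
  eta <- drop(design %*% coefficients)
  if (any(!is.finite(eta))) stop("non-finite linear predictor")
  p <- stats::plogis(eta)
  # guard against exact 0/1 fractions from extreme eta
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  sum(dbetabinom(counts$alt_reads, counts$depth, p, counts$overdispersion,
                 log = TRUE))
}

# Gradient of betabin_loglik w.r.t. coefficients. Uses the fact that
# a + b = (1-rho)/rho does not depend on p, so only four digamma terms enter.
.betabin_grad <- function(counts, coefficients, design) {
  eta <- drop(design %*% coefficients)
  p <- pmin(pmax(stats::plogis(eta), 1e-12), 1 - 1e-12)
  k <- counts$alt_reads
  n <- counts$depth
  rho <- counts$overdispersion
  dldp <- numeric(length(k))
  bb <- rho > 0
  if (any(bb)) {
    s <- (1 - rho[bb]) / rho[bb]
    a <- p[bb] * s
    b <- (1 - p[bb]) * s
    dldp[bb] <- s * (digamma(k[bb] + a) - digamma(n[bb] - k[bb] + b) -
                       digamma(a) + digamma(b))
  }
  if (any(!bb)) dldp[!bb] <- (k[!bb] - n[!bb] * p[!bb]) / (p[!bb] * (1 - p[!bb]))
  w <- dldp * p * (1 - p)   # chain rule through the logit link
  drop(crossprod(design, w))
}

#' Estimate per-individual beta-binomial overdispersion
#'
#' Maximum-likelihood estimate of the overdispersion `rho` of a beta-binomial
#' with mean fixed at 0.5, pooled over an individual's heterozygous sites.
#' This is the plug-in overdispersion used by the allelic-imbalance
#' regression; in tumors it can be estimated per CNV region by calling this
#' once per region.
#'
#' @param ref_counts,alt_counts Integer vectors of reference / alternative
#'   read counts, one entry per heterozygous site.
#' @param rho_max Upper clamp for the estimate (default 0.999).
#' @return A list of class `decaf_overdispersion` with elements `rho`, `se`
#'   (from the observed information; `NA` on the boundary), `n_sites`,
#'   `n_reads` and `loglik`.
#' @examples
#' estimate_overdispersion(rep(50, 20), rep(50, 20))$rho  # ~ 0
#' @export
estimate_overdispersion <- function(ref_counts, alt_counts, rho_max = 0.999) {
  keep <- (ref_counts + alt_counts) >= 1
  ref_counts <- ref_counts[keep]; alt_counts <- alt_counts[keep]
  if (length(ref_counts) < 1) stop("no heterozygous sites with depth >= 1")
  n <- ref_counts + alt_counts
  k <- alt_counts
  nll <- function(rho) -sum(dbetabinom(k, n, 0.5, rho, log = TRUE))
  opt <- stats::optimize(nll, interval = c(1e-8, rho_max), tol = 1e-9)
  rho_hat <- opt$minimum
  ll_hat <- -opt$objective
  # compare against the binomial boundary rho = 0
  ll0 <- sum(stats::dbinom(k, n, 0.5, log = TRUE))
  if (ll0 >= ll_hat) {
    rho_hat <- 0
    ll_hat <- ll0
  }
  se <- NA_real_
  if (rho_hat > 1e-6 && rho_hat < rho_max - 1e-6) {
    h <- max(1e-5, rho_hat * 1e-3)
    d2 <- (nll(rho_hat + h) - 2 * nll(rho_hat) + nll(rho_hat - h)) / h^2
    if (is.finite(d2) && d2 > 0) se <- sqrt(1 / d2)
  }
  structure(list(rho = rho_hat, se = se, n_sites = length(k),
                 n_reads = sum(n), loglik = ll_hat),
            class = "decaf_overdispersion")
}

#' Overdispersion estimates for a cohort of individuals
#'
#' Convenience wrapper applying [estimate_overdispersion()] per individual
#' (and optionally per CNV region) across a table of heterozygous-site
#' counts. Individuals with fewer than `min_sites` usable sites receive the
#' cohort fallback value.
#'
#' @param counts Data frame with columns `individual`, `refCount`,
#'   `altCount` and optionally `region` (CNV region id).
#' @param by_region Estimate separately per `region` within individual.
#' @param min_sites Minimum usable sites for an individual-specific estimate
#'   (default 3).
#' @param fallback_rho Cohort default used below `min_sites` (default 0.0263,
#'   a typical tumor RNA-seq value).
#' @return Data frame with columns `individual`, `region`, `rho`, `n_sites`,
#'   `n_reads`.
#' @export
estimate_overdispersion_table <- function(counts, by_region = FALSE,
                                          min_sites = 3,
                                          fallback_rho = 0.0263) {
  stopifnot(all(c("individual", "refCount", "altCount") %in% names(counts)))
  if (by_region && !"region" %in% names(counts))
    stop("by_region = TRUE requires a 'region' column")
  key <- if (by_region) {
    interaction(counts$individual, counts$region, drop = TRUE, sep = "\r")
  } else {
    factor(counts$individual)
  }
  out <- lapply(levels(key), function(lv) {
    rows <- counts[key == lv, , drop = FALSE]
    rows <- rows[rows$refCount + rows$altCount >= 1, , drop = FALSE]
    ind <- rows$individual[1]
    reg <- if (by_region) as.character(rows$region[1]) else "global"
    if (nrow(rows) < min_sites) {
      data.frame(individual = ind, region = reg, rho = fallback_rho,
                 n_sites = nrow(rows),
                 n_reads = sum(rows$refCount + rows$altCount))
    } else {
      est <- estimate_overdispersion(rows$refCount, rows$altCount)
      data.frame(individual = ind, region = reg, rho = est$rho,
                 n_sites = est$n_sites, n_reads = est$n_reads)
    }
  })
  do.call(rbind, out)
}

#' Fit the interaction allelic-imbalance (iAI) regression
#'
#' Beta-binomial regression of haplotype-oriented REF/ALT read counts in
#' heterozygous individuals on cell fraction (and optionally tumor purity and
#' a local CNV covariate), with the per-individual overdispersion fixed
#' during coefficient optimization. The intercept `mu_a` is the logit-scale
#' mean allelic fraction (0 under the null of balance), `alpha_f` measures
#' how the allelic fraction shifts with cell fraction, and the purity
#' coefficient captures tumor-specific imbalance.
#'
#' @param observations Data frame of allelic observations with columns
#'   `alt_reads`, `ref_reads`, `depth`, `overdispersion`, and, as needed,
#'   `f` (cell fraction), `purity`, `cnv_value`.
#' @param include_fraction,include_purity,include_cnv Which covariates enter
#'   the design (intercept always present).
#' @param min_het Minimum number of observations required (default 5); below
#'   this the fit is not attempted.
#' @param max_iter,grad_tol Optimizer limits: BFGS iterations (default 200)
#'   and gradient-norm convergence tolerance (default 1e-8).
#' @return An object of class `decaf_aifit`: list with `coefficients`, `se`,
#'   `vcov`, `z`, `p` (named over `mu_a`, `alpha_f`, `alpha_purity`,
#'   `gamma_cnv` as present), `loglik`, `converged`, `identifiable`,
#'   `n_individuals`.
#' @export
fit_iai <- function(observations, include_fraction = TRUE,
                    include_purity = FALSE, include_cnv = FALSE,
                    min_het = 5, max_iter = 200, grad_tol = 1e-8) {
  obs <- observations[observations$depth >= 1, , drop = FALSE]
  empty <- function(reason) {
    structure(list(coefficients = NULL, se = NULL, z = NULL, p = NULL,
                   loglik = NA_real_, converged = FALSE,
                   identifiable = FALSE, n_individuals = nrow(obs),
                   reason = reason),
              class = "decaf_aifit")
  }
  if (nrow(obs) < min_het) return(empty("fewer observations than min_het"))
  X <- cbind(mu_a = rep(1, nrow(obs)))
  if (include_fraction) {
    if (is.null(obs$f)) stop("include_fraction = TRUE but no 'f' column")
    X <- cbind(X, alpha_f = obs$f)
  }
  if (include_purity) {
    if (is.null(obs$purity)) stop("include_purity = TRUE but no 'purity' column")
    X <- cbind(X, alpha_purity = obs$purity)
  }
  if (include_cnv) {
    cnv <- if (is.null(obs$cnv_value)) rep(0, nrow(obs)) else obs$cnv_value
    # an all-zero CNV column is dropped rather than breaking the fit
    if (stats::sd(cnv) > 0) X <- cbind(X, gamma_cnv = cnv)
  }
  if (qr(X)$rank < ncol(X)) return(empty("design not of full rank"))
  if (nrow(obs) < ncol(X) + 1) return(empty("too few observations for design"))

  # initialize at the binomial-GLM solution (exact MLE when all rho = 0)
  init <- tryCatch(
    suppressWarnings(stats::glm.fit(X, cbind(obs$alt_reads, obs$ref_reads),
                                    family = stats::binomial())$coefficients),
    error = function(e) rep(0, ncol(X)))
  if (any(!is.finite(init))) init <- rep(0, ncol(X))

  nll <- function(b) -betabin_loglik(obs, b, X)
  ngr <- function(b) -.betabin_grad(obs, b, X)
  opt <- stats::optim(init, nll, ngr, method = "BFGS",
                      control = list(maxit = max_iter, reltol = 1e-12))
  gnorm <- sqrt(sum(ngr(opt$par)^2))
  converged <- opt$convergence == 0 || gnorm < grad_tol
  H <- stats::optimHess(opt$par, nll, ngr)
  cov <- tryCatch(solve(H), error = function(e) NULL)
  if (is.null(cov) || any(diag(cov) <= 0)) return(empty("singular information"))
  est <- opt$par
  se <- sqrt(diag(cov))
  names(est) <- names(se) <- colnames(X)
  dimnames(cov) <- list(colnames(X), colnames(X))
  z <- est / se
  p <- 2 * stats::pnorm(-abs(z))
  structure(list(coefficients = est, se = se, vcov = cov, z = z, p = p,
                 loglik = -opt$value, converged = converged,
                 identifiable = TRUE, n_individuals = nrow(obs),
                 reason = NULL),
            class = "decaf_aifit")
}

#' @export
print.decaf_aifit <- function(x, ...) {
  cat("Interaction allelic-imbalance (beta-binomial) fit\n")
  if (!x$identifiable) {
    cat("  not fitted:", x$reason, "\n")
    return(invisible(x))
  }
  tab <- cbind(estimate = x$coefficients, se = x$se, z = x$z, p = x$p)
  print(round(tab, 4))
  cat(sprintf("  n = %d, loglik = %.3f, converged = %s\n",
              x$n_individuals, x$loglik, x$converged))
  invisible(x)
}
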