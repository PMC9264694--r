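#' Simulation configuration
#'
#' Collects every generative parameter of the simulation framework used for
#' power and calibration studies. Defaults are anchored in estimates from
#' tumor RNA-seq data: overdispersion 0.0263, QTL variance explained 0.04,
#' normal-fraction variance 0.0269, CNV variance 0.012, 500 replicates, and
#' genome-wide significance at `0.05 / 20000` (about one test per gene).
#'
#' @param maf Minor allele frequency in `(0, 0.5]` (default 0.25).
#' @param pi_f Allelic fraction of the alternative allele in the focal cell
#'   type (0.5 = null; default 0.5).
#' @param mean_depth Poisson mean of per-individual allelic read depth
#'   (default 100).
#' @param n_individuals Cohort size N (default 400).
#' @param rho Beta-binomial overdispersion of read counts (default 0.0263).
#' @param fraction_source `"uniform"` or a numeric vector of real
#'   deconvolution scores to bootstrap from.
#' @param cnv_fraction Fraction of individuals carrying a CNV at the locus
#'   (default 0.5, reflecting the dense CNV landscape of tumor genomes;
#'   used when `cnv_model != "none"`).
#' @param cnv_model `"none"`, `"fixed"` (a constant shift of the allelic
#'   fraction — the alternative allele consistently amplified) or
#'   `"random"` (the CNV hits a random haplotype per carrier, so the
#'   allelic shift direction is unpredictable from the DNA-derived segment
#'   mean; carriers receive analytically inflated overdispersion in the
#'   analysis columns, mirroring per-CNV-region overdispersion
#'   estimation).
#' @param cnv_pi_shift Magnitude of the CNV-induced allelic-fraction shift
#'   for carriers (default 0.1).
#' @param sigma_effect Variance share of expression explained by the
#'   genotype x fraction term (default 0.04).
#' @param sigma_nf Variance share explained by normal fraction
#'   (default 0.0269).
#' @param sigma_cnv Variance share explained by CNV (default 0.012).
#' @param n_reps Replicates per condition (default 500).
#' @param alpha Significance level for power (default `0.05 / 20000`).
#' @param seed Base random seed.
#' @return A validated list of class `decaf_simconfig`.
#' @export
sim_config <- function(maf = 0.25, pi_f = 0.5, mean_depth = 100,
                       n_individuals = 400, rho = 0.0263,
                       fraction_source = "uniform", cnv_fraction = 0.5,
                       cnv_model = c("none", "fixed", "random"),
                       cnv_pi_shift = 0.1, sigma_effect = 0.04,
                       sigma_nf = 0.0269, sigma_cnv = 0.012, n_reps = 500,
                       alpha = 0.05 / 20000, seed = 1) {
  cnv_model <- match.arg(cnv_model)
  stopifnot(maf > 0, maf <= 0.5, pi_f >= 0, pi_f <= 1, mean_depth > 0,
            n_individuals >= 10, rho >= 0, rho < 1,
            cnv_fraction >= 0, cnv_fraction <= 1,
            sigma_effect >= 0, sigma_nf >= 0, sigma_cnv >= 0,
            n_reps >= 1, alpha > 0, alpha < 1)
  used_cnv <- if (cnv_model == "none") 0 else sigma_cnv
  if (sigma_effect + sigma_nf + used_cnv >= 1)
    stop("variance shares must sum to < 1")
  structure(list(maf = maf, pi_f = pi_f, mean_depth = mean_depth,
                 n_individuals = n_individuals, rho = rho,
                 fraction_source = fraction_source,
                 cnv_fraction = cnv_fraction, cnv_model = cnv_model,
                 cnv_pi_shift = cnv_pi_shift, sigma_effect = sigma_effect,
                 sigma_nf = sigma_nf, sigma_cnv = sigma_cnv,
                 n_reps = n_reps, alpha = alpha, seed = seed),
            class = "decaf_simconfig")
}

#' Draw per-individual cell fractions
#'
#' Either uniform(0, 1) scores or a bootstrap (sampling with replacement)
#' from a supplied vector of real deconvolution scores, so simulations can
#' mirror the skewed fraction distributions seen in real cohorts.
#'
#' @param source `"uniform"`, a numeric vector of scores (length >= 10), or
#'   a path to a TSV whose column `fraction` (or single numeric column)
#'   holds the scores.
#' @param n Number of draws.
#' @param seed Optional seed set before drawing.
#' @return Numeric vector of length `n`. Constant sources are allowed but
#'   flagged with a warning because the interaction becomes unidentifiable.
#' @export
sample_cell_fractions <- function(source = "uniform", n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.character(source) && length(source) == 1 && source == "uniform")
    return(stats::runif(n))
  if (is.character(source)) {
    tab <- utils::read.delim(source, stringsAsFactors = FALSE)
    col <- if ("fraction" %in% names(tab)) "fraction" else {
      num <- names(tab)[vapply(tab, is.numeric, logical(1))]
      if (length(num) == 0) stop("no numeric fraction column in ", source)
      num[1]
    }
    source <- tab[[col]]
  }
  source <- as.numeric(source[!is.na(source)])
  if (length(source) < 10)
    stop("need at least 10 real fraction values to resample from")
  out <- sample(source, n, replace = TRUE)
  if (stats::sd(out) == 0)
    warning("constant cell fractions: interaction effects unidentifiable")
  out
}

# beta-binomial deviates in the intraclass-correlation parameterization
.rbetabinom <- function(n_draws, size, p, rho) {
  if (rho <= 0) return(stats::rbinom(n_draws, size, p))
  s <- (1 - rho) / rho
  pp <- stats::rbeta(n_draws, p * s, (1 - p) * s)
  stats::rbinom(n_draws, size, pp)
}

#' Simulate allelic observations for heterozygous carriers
#'
#' Generates one cohort of heterozygous individuals under the allelic
#' model: the number of heterozygotes is the Hardy-Weinberg expectation
#' `round(2 * maf * (1 - maf) * N)`; each draws a cell fraction `f`, a read
#' depth `D ~ Poisson(mean_depth)`, an allelic fraction
#' `pi = 0.5 (1 - f) + pi_f f` (shifted for CNV carriers — a constant shift
#' under the fixed model, a random-signed shift under the random model),
#' and `ALT ~ BetaBin(D, pi, rho)` with `REF = D - ALT`.
#'
#' @param config A `decaf_simconfig`.
#' @param seed Optional seed (defaults to `config$seed`).
#' @return List with `observations` (data frame `individual_id`,
#'   `ref_reads`, `alt_reads`, `depth`, `overdispersion`, `f`, `cnv_value`,
#'   `cnv_carrier`) and `truth` (`pi_f`, `pi` vector, `n_het`, `n_clipped`).
#' @export
simulate_allelic <- function(config, seed = config$seed) {
  if (!is.null(seed)) set.seed(seed)
  n_het <- round(2 * config$maf * (1 - config$maf) * config$n_individuals)
  if (n_het < 1) stop("no heterozygotes at this MAF and N")
  f <- sample_cell_fractions(config$fraction_source, n_het)
  depth <- stats::rpois(n_het, config$mean_depth)
  pi <- 0.5 * (1 - f) + config$pi_f * f
  carrier <- rep(FALSE, n_het)
  cnv_value <- rep(0, n_het)
  rho_obs <- rep(config$rho, n_het)
  if (config$cnv_model != "none") {
    carrier <- stats::runif(n_het) < config$cnv_fraction
    # the DNA-derived segment value is signed by amplification vs deletion;
    # under the random model the haplotype the CNV sits on — and hence the
    # direction of the allelic shift — is independent of that sign
    sign_ad <- sample(c(-1, 1), n_het, replace = TRUE)
    shift <- switch(config$cnv_model,
                    fixed = rep(config$cnv_pi_shift, n_het),
                    random = sample(c(-1, 1), n_het, replace = TRUE) *
                      config$cnv_pi_shift)
    pi <- pi + ifelse(carrier, shift, 0)
    cnv_value <- ifelse(carrier,
                        if (config$cnv_model == "fixed") config$cnv_pi_shift
                        else sign_ad * config$cnv_pi_shift, 0)
    if (config$cnv_model == "random") {
      # per-CNV-region overdispersion: carriers absorb the unexplained
      # +/- shift variance (shift^2 / (pi0 (1 - pi0)) at pi0 = 0.5)
      rho_obs[carrier] <- min(0.99, config$rho + 4 * config$cnv_pi_shift^2)
    }
  }
  clipped <- pi <= 0.001 | pi >= 0.999
  if (any(clipped))
    warning(sum(clipped), " allelic fraction(s) clipped to (0.001, 0.999)")
  pi <- pmin(pmax(pi, 0.001), 0.999)
  alt <- .rbetabinom(n_het, depth, pi, config$rho)
  obs <- data.frame(individual_id = paste0("het", seq_len(n_het)),
                    ref_reads = depth - alt, alt_reads = alt, depth = depth,
                    overdispersion = rho_obs, f = f,
                    cnv_value = cnv_value, cnv_carrier = carrier,
                    stringsAsFactors = FALSE)
  list(observations = obs,
       truth = list(pi_f = config$pi_f, pi = pi, n_het = n_het,
                    n_clipped = sum(clipped)))
}

#' Simulate total expression under the additive linear model
#'
#' Draws `y = b_nf * NF + b_xf * x * f + b_cnv * CNV + e` with standard
#' normal noise, where each coefficient is scaled so its term explains the
#' configured share of the total variance (`sigma_nf`, `sigma_effect`,
#' `sigma_cnv`). Terms that are constant in the input (e.g. no CNV
#' carriers) are dropped.
#'
#' @param config A `decaf_simconfig`.
#' @param x Genotype dosage vector.
#' @param f Cell-fraction vector.
#' @param nf Normal-fraction vector (1 - purity).
#' @param cnv Per-individual CNV value vector.
#' @param seed Optional seed.
#' @return List with `y` (expression vector) and `truth` (the realized
#'   coefficients).
#' @export
simulate_expression <- function(config, x, f, nf = NULL, cnv = NULL,
                                seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- length(x)
  shares <- c(nf = config$sigma_nf, xf = config$sigma_effect,
              cnv = if (config$cnv_model == "none") 0 else config$sigma_cnv)
  terms <- list(nf = nf, xf = x * f, cnv = cnv)
  active <- names(shares)[shares > 0 &
                            !vapply(terms, is.null, logical(1))]
  active <- active[vapply(terms[active],
                          function(t) stats::sd(t) > 0, logical(1))]
  total_share <- sum(shares[active])
  if (total_share >= 1) stop("variance shares must sum to < 1")
  coefs <- stats::setNames(rep(0, 3), names(shares))
  y <- stats::rnorm(n)
  for (nm in active) {
    b <- sqrt(shares[[nm]] / (1 - total_share))
    z <- (terms[[nm]] - mean(terms[[nm]])) / stats::sd(terms[[nm]])
    y <- y + b * z
    coefs[nm] <- b / stats::sd(terms[[nm]])   # on the raw-term scale
  }
  list(y = y, truth = list(coefficients = coefs, shares = shares[active]))
}

#' Simulate one full cohort for all three tests
#'
#' Generates a cohort in which the interaction eQTL, interaction AI, and
#' combined tests can all be run on the same individuals: genotypes with
#' Hardy-Weinberg expected class counts, cell fractions, tumor purity
#' (uniform on 0.3-0.9), CNV carriers, total expression, and allelic
#' observations for the heterozygotes (the same `f` and CNV status feed
#' both models).
#'
#' @param config A `decaf_simconfig`.
#' @param seed Optional seed (defaults to `config$seed`).
#' @return List with `expression` (`y`, `x`, `f`, `purity`, `cnv_value`),
#'   `allelic` (observation data frame for heterozygotes) and `truth`.
#' @export
simulate_cohort <- function(config, seed = config$seed) {
  if (!is.null(seed)) set.seed(seed)
  N <- config$n_individuals
  n_het <- round(2 * config$maf * (1 - config$maf) * N)
  n_alt <- round(config$maf^2 * N)
  n_ref <- N - n_het - n_alt
  x <- c(rep(0, n_ref), rep(1, n_het), rep(2, n_alt))
  f <- sample_cell_fractions(config$fraction_source, N)
  purity <- stats::runif(N, 0.3, 0.9)
  nf <- 1 - purity
  carrier <- rep(FALSE, N)
  cnv_value <- rep(0, N)
  allelic_sign <- rep(1, N)
  rho_obs <- rep(config$rho, N)
  if (config$cnv_model != "none") {
    carrier <- stats::runif(N) < config$cnv_fraction
    sign_ad <- sample(c(-1, 1), N, replace = TRUE)
    if (config$cnv_model == "random") {
      allelic_sign <- sample(c(-1, 1), N, replace = TRUE)
      cnv_value <- ifelse(carrier, sign_ad * config$cnv_pi_shift, 0)
      rho_obs[carrier] <- min(0.99, config$rho + 4 * config$cnv_pi_shift^2)
    } else {
      cnv_value <- ifelse(carrier, config$cnv_pi_shift, 0)
    }
  }
  expr <- simulate_expression(config, x, f, nf = nf, cnv = cnv_value)
  het_idx <- which(x == 1)
  depth <- stats::rpois(length(het_idx), config$mean_depth)
  pi <- 0.5 * (1 - f[het_idx]) + config$pi_f * f[het_idx]
  if (config$cnv_model != "none") {
    pi <- pi + ifelse(carrier[het_idx],
                      allelic_sign[het_idx] * config$cnv_pi_shift, 0)
  }
  n_clipped <- sum(pi <= 0.001 | pi >= 0.999)
  pi <- pmin(pmax(pi, 0.001), 0.999)
  alt <- .rbetabinom(length(het_idx), depth, pi, config$rho)
  allelic <- data.frame(
    individual_id = paste0("ind", het_idx),
    ref_reads = depth - alt, alt_reads = alt, depth = depth,
    overdispersion = rho_obs[het_idx], f = f[het_idx],
    purity = purity[het_idx], cnv_value = cnv_value[het_idx],
    stringsAsFactors = FALSE)
  list(expression = list(y = expr$y, x = x, f = f, purity = purity,
                         cnv_value = cnv_value),
       allelic = allelic,
       truth = list(pi_f = config$pi_f, n_het = length(het_idx),
                    n_clipped = n_clipped,
                    expr_coefficients = expr$truth$coefficients))
}

# One simulation replicate: p-values of the three tests on a shared cohort.
.decaf_rep <- function(config, seed) {
  cohort <- simulate_cohort(config, seed)
  e <- cohort$expression
  with_cnv <- config$cnv_model != "none"
  efit <- fit_ieqtl(e$y, e$x, f = e$f, purity = e$purity,
                    cnv = if (with_cnv) e$cnv_value else NULL, mode = "cf")
  afit <- fit_iai(cohort$allelic, include_fraction = TRUE,
                  include_purity = FALSE, include_cnv = with_cnv)
  z_e <- if (efit$identifiable) efit$z_test else NA_real_
  z_a <- if (afit$identifiable && afit$converged)
    unname(afit$z["alpha_f"]) else NA_real_
  z_d <- if (any(is.finite(c(z_e, z_a))))
    stouffer_combine(c(z_e, z_a)) else NA_real_
  c(p_ieqtl = 2 * stats::pnorm(-abs(z_e)),
    p_iai = 2 * stats::pnorm(-abs(z_a)),
    p_decaf = 2 * stats::pnorm(-abs(z_d)))
}

#' Power / calibration experiment over a condition grid
#'
#' For each grid cell, runs `n_reps` independent cohort simulations, fits
#' the interaction eQTL, interaction AI and combined tests on each cohort,
#' and reports the fraction of replicates reaching `p < alpha` per test,
#' with its Monte-Carlo standard error. Per-cell and per-replicate seeds
#' are derived deterministically from `seed`, so any cell can be
#' regenerated on its own.
#'
#' @param grid Data frame whose columns override fields of `base_config`
#'   (e.g. `pi_f`, `n_individuals`, `rho`, `cnv_model`); one row per cell.
#'   `NULL` runs the single `base_config` condition.
#' @param base_config A `decaf_simconfig` supplying all other parameters.
#' @param n_reps Replicates per cell (default `base_config$n_reps`).
#' @param alpha Significance level (default `base_config$alpha`).
#' @param seed Master seed (default `base_config$seed`).
#' @return Tidy data frame: one row per cell x test with columns from the
#'   grid plus `test`, `power`, `mc_se`, `n_reps`, `alpha`.
#' @export
power_experiment <- function(grid = NULL, base_config = sim_config(),
                             n_reps = base_config$n_reps,
                             alpha = base_config$alpha,
                             seed = base_config$seed) {
  if (is.null(grid)) grid <- data.frame(row.names = 1)
  n_cells <- max(1, nrow(grid))
  set.seed(seed)
  cell_seeds <- sample.int(.Machine$integer.max - 1, n_cells)
  out <- vector("list", n_cells)
  for (ci in seq_len(n_cells)) {
    cfg <- base_config
    for (nm in names(grid)) cfg[[nm]] <- grid[[nm]][ci]
    set.seed(cell_seeds[ci])
    rep_seeds <- sample.int(.Machine$integer.max - 1, n_reps)
    pmat <- vapply(rep_seeds, function(s) .decaf_rep(cfg, s), numeric(3))
    hits <- rowSums(pmat < alpha, na.rm = TRUE)
    power <- hits / n_reps
    cell <- if (ncol(grid) > 0) grid[ci, , drop = FALSE] else
      data.frame(row.names = 1)
    res <- data.frame(test = c("ieQTL", "iAI", "DeCAF"),
                      power = unname(power),
                      mc_se = sqrt(power * (1 - power) / n_reps),
                      n_reps = n_reps, alpha = alpha,
                      stringsAsFactors = FALSE)
    out[[ci]] <- cbind(cell[rep(1, 3), , drop = FALSE], res)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Power cost of modeling CNVs as a fixed-effect covariate
#'
#' Runs the power study twice over a condition grid — once without CNVs and
#' once with simulated CNV carriers whose DNA-derived CNV value enters both
#' models as a fixed-effect covariate — and summarizes the average fold
#' reduction in combined-test power as the ratio of grid-mean powers.
#' Per-cell ratios are also returned, but the aggregate uses the ratio of
#' means because cell-wise ratios are numerically unstable wherever power
#' approaches zero.
#'
#' @param grid Condition grid (default [default_power_grid()]).
#' @param base_config Base `decaf_simconfig`; its `cnv_model` is overridden.
#' @param cnv_model CNV architecture for the CNV arm (default `"random"`:
#'   the CNV hits a random haplotype, so the covariate absorbs the
#'   expression offset but not the allelic direction).
#' @param n_reps,seed Passed to [power_experiment()]; both arms share the
#'   seed so cells are matched.
#' @return List with `fold` (mean power without CNVs / mean power with
#'   CNVs), `per_cell` (cell-wise powers and ratios), `n_reps`.
#' @export
cnv_power_cost <- function(grid = default_power_grid(),
                           base_config = sim_config(),
                           cnv_model = "random",
                           n_reps = base_config$n_reps,
                           seed = base_config$seed) {
  cfg_no <- base_config
  cfg_no$cnv_model <- "none"
  pw_no <- power_experiment(grid, cfg_no, n_reps = n_reps, seed = seed)
  cfg_cnv <- base_config
  cfg_cnv$cnv_model <- cnv_model
  pw_cnv <- power_experiment(grid, cfg_cnv, n_reps = n_reps, seed = seed)
  d_no <- pw_no$power[pw_no$test == "DeCAF"]
  d_cnv <- pw_cnv$power[pw_cnv$test == "DeCAF"]
  per_cell <- cbind(grid, power_no_cnv = d_no, power_cnv = d_cnv,
                    ratio = d_no / d_cnv)
  list(fold = mean(d_no) / mean(d_cnv), per_cell = per_cell,
       n_reps = n_reps)
}

#' Default power-study grid
#'
#' The grid used for the package's standard power study: focal-cell allelic
#' fractions 0.6, 0.7 and 0.9 crossed with cohort sizes from 100 to 1000,
#' uniform cell fractions.
#'
#' @return Data frame with columns `pi_f` and `n_individuals`.
#' @export
default_power_grid <- function() {
  expand.grid(pi_f = c(0.6, 0.7, 0.9),
              n_individuals = c(100, 200, 400, 600, 800, 1000))
}
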