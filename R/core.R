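#' Combine component Z scores by Stouffer's method
#'
#' Equal-weight Stouffer combination `sum(z) / sqrt(k)` of signed component
#' Z scores, all oriented towards the alternative allele. With one component
#' this is the identity; with equal weights it coincides with
#' inverse-variance meta-analysis, so opposite-signed effects cancel.
#' Non-finite components are dropped before combining.
#'
#' @param z Numeric vector of signed Z scores.
#' @return The combined Z score.
#' @examples
#' stouffer_combine(c(1, 1))        # sqrt(2)
#' stouffer_combine(c(2, -2))       # 0
#' @export
stouffer_combine <- function(z) {
  z <- z[is.finite(z)]
  if (length(z) == 0) stop("no finite Z scores to combine")
  sum(z) / sqrt(length(z))
}

#' Assemble the testing context for one gene
#'
#' Gathers everything [scan_gene()] needs for one (gene, cell type) pair:
#' cis-window SNPs, per-test CNV mask and covariate, the gene's functional
#' (read-carrying) SNPs with the carrier's phased alleles attached,
#' per-individual overdispersion, and aligned expression / fraction / purity
#' vectors.
#'
#' @param gene One-row data frame or list with `gene_id`, `chrom`, `tss`,
#'   optionally `start`, `end` (gene body; defaults to the cis window when
#'   absent).
#' @param genotypes A `decaf_genotypes` panel.
#' @param expression Numeric vector of normalized expression named by
#'   individual (or a gene x individual matrix; the gene's row is taken).
#' @param fractions Data frame from [read_cell_fractions()].
#' @param cell_type Name of the fraction column to test.
#' @param ase Optional allelic count table from [read_ase_counts()].
#' @param cnv Optional CNV segments from [read_cnv_segments()].
#' @param purity_col Name of the purity column in `fractions` (default
#'   `"purity"`; ignored when absent).
#' @param overdispersion Optional data frame `individual`, `rho`; estimated
#'   from `ase` via [estimate_overdispersion_table()] when `NULL`.
#' @param fallback_rho Overdispersion assigned to individuals without an
#'   estimate (default 0.0263).
#' @param window_bp,maf_min Cis-window parameters (see [cis_window_snps()]).
#' @param cnv_threshold,cnv_signed Deep-CNV masking parameters (see
#'   [apply_cnv_mask()]).
#' @return A list of class `decaf_unit`.
#' @export
build_test_unit <- function(gene, genotypes, expression, fractions, cell_type,
                            ase = NULL, cnv = NULL, purity_col = "purity",
                            overdispersion = NULL, fallback_rho = 0.0263,
                            window_bp = 100000, maf_min = 0.01,
                            cnv_threshold = 0.1, cnv_signed = FALSE) {
  if (is.matrix(expression)) {
    if (!gene$gene_id %in% rownames(expression))
      stop("gene ", gene$gene_id, " absent from expression matrix")
    expression <- expression[gene$gene_id, ]
  }
  if (!cell_type %in% names(fractions))
    stop("cell type '", cell_type, "' not found in fractions table")
  samples <- Reduce(intersect, list(genotypes$samples, names(expression),
                                    fractions$individual))
  n_dropped <- length(genotypes$samples) - length(samples)
  if (n_dropped > 0)
    message(n_dropped, " individual(s) dropped: incomplete covariates")
  if (length(samples) == 0) stop("no individuals shared across inputs")
  snps <- cis_window_snps(gene, genotypes, window_bp, maf_min)
  win_start <- max(1, gene$tss - window_bp)
  win_end <- gene$tss + window_bp
  mask <- apply_cnv_mask(samples, cnv, gene$chrom, win_start, win_end,
                         threshold = cnv_threshold, signed = cnv_signed)
  frac <- fractions[match(samples, fractions$individual), ]
  f <- stats::setNames(frac[[cell_type]], samples)
  purity <- if (purity_col %in% names(frac)) {
    stats::setNames(frac[[purity_col]], samples)
  } else NULL

  # functional sites: read-carrying SNPs inside the gene body (or the cis
  # window when the gene extent is unknown), joined to the phased panel so
  # each row carries the individual's haplotype alleles at that site
  functional <- NULL
  rho <- NULL
  if (!is.null(ase) && nrow(ase) > 0) {
    g_start <- if (!is.null(gene$start) && !is.na(gene$start)) gene$start else win_start
    g_end <- if (!is.null(gene$end) && !is.na(gene$end)) gene$end else win_end
    in_gene <- ase$contig == gene$chrom &
      ase$position >= g_start & ase$position <= g_end &
      ase$individual %in% samples
    functional <- ase[in_gene, , drop = FALSE]
    vidx <- match(functional$variant_id, genotypes$variants$variant_id)
    functional <- functional[!is.na(vidx), , drop = FALSE]
    vidx <- vidx[!is.na(vidx)]
    if (nrow(functional) > 0) {
      ij <- cbind(vidx, match(functional$individual, genotypes$samples))
      functional$hap1 <- genotypes$hap1[ij]
      functional$hap2 <- genotypes$hap2[ij]
    }
    if (is.null(overdispersion)) {
      od_in <- data.frame(individual = ase$individual,
                          refCount = ase$refCount, altCount = ase$altCount)
      overdispersion <- estimate_overdispersion_table(
        od_in, fallback_rho = fallback_rho)
    }
    rho <- stats::setNames(
      overdispersion$rho[match(samples, overdispersion$individual)], samples)
    rho[is.na(rho)] <- fallback_rho
  }
  structure(list(gene = gene, snps = snps, samples = samples,
                 expression = expression[samples], f = f, purity = purity,
                 cnv_value = stats::setNames(mask$cnv_value, samples),
                 cnv_masked = stats::setNames(mask$masked, samples),
                 has_cnv = !is.null(cnv), functional = functional,
                 rho = rho, cell_type = cell_type),
            class = "decaf_unit")
}

# Allelic observations for the unit's i-th cis SNP: direct counts when the
# test SNP itself carries reads for that individual, otherwise haplotype-
# aggregated sums over the gene's heterozygous phased functional sites.
.snp_allelic_obs <- function(unit, i, min_reads = 1) {
  fun <- unit$functional
  if (is.null(fun) || nrow(fun) == 0) return(NULL)
  vid <- unit$snps$variants$variant_id[i]
  keep <- unit$samples[!unit$cnv_masked[unit$samples]]
  h1 <- unit$snps$hap1[i, ]
  h2 <- unit$snps$hap2[i, ]
  het <- keep[!is.na(h1[keep]) & !is.na(h2[keep]) &
                (h1[keep] + h2[keep]) == 1]
  if (length(het) == 0) return(NULL)
  rows <- lapply(het, function(ind) {
    mine <- fun[fun$individual == ind, , drop = FALSE]
    if (nrow(mine) == 0) return(NULL)
    if (vid %in% mine$variant_id) {
      r <- mine[mine$variant_id == vid, , drop = FALSE][1, ]
      ref_reads <- r$refCount
      alt_reads <- r$altCount
      n_sites <- 1L
    } else {
      agg <- suppressWarnings(aggregate_haplotype_counts(
        c(h1[[ind]], h2[[ind]]), mine$hap1, mine$hap2,
        mine$refCount, mine$altCount))
      if (agg$n_sites == 0) return(NULL)
      ref_reads <- agg$ref_reads
      alt_reads <- agg$alt_reads
      n_sites <- agg$n_sites
    }
    depth <- ref_reads + alt_reads
    if (depth < min_reads || depth < 1) return(NULL)
    data.frame(individual_id = ind, ref_reads = ref_reads,
               alt_reads = alt_reads, depth = depth,
               overdispersion = unname(unit$rho[ind]),
               f = unname(unit$f[ind]),
               purity = if (is.null(unit$purity)) NA_real_ else unname(unit$purity[ind]),
               cnv_value = unname(unit$cnv_value[ind]),
               n_sites = n_sites, stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0) return(NULL)
  obs <- do.call(rbind, rows)
  if (is.null(unit$purity)) obs$purity <- NULL
  obs
}

#' Scan all cis SNPs of a gene
#'
#' For each SNP in the unit's cis window, fits the interaction eQTL model on
#' all unmasked individuals and the allelic-imbalance model on heterozygous
#' phased carriers (functional SNPs tested with their own reads; distal SNPs
#' with haplotype-aggregated sums of the gene's functional-SNP reads), then
#' combines the two signed Z scores by Stouffer's method. When a component
#' is unavailable for a SNP (e.g. too few heterozygotes for the allelic
#' test) the other component alone is the DeCAF statistic, recorded in
#' `components`.
#'
#' @param unit A `decaf_unit` from [build_test_unit()].
#' @param mode `"cf"` (cell-fraction interaction), `"ts"` (purity
#'   interaction) or `"marginal"` (genotype main effect / population AI).
#' @param min_het Minimum heterozygous observations for the allelic
#'   component (default 5).
#' @param min_reads Minimum read depth per allelic observation (default 1).
#' @param inverse_normal Passed to [fit_ieqtl()].
#' @return Data frame with one row per tested SNP: `gene_id`, `snp_id`,
#'   `cell_type`, `pos`, `mode`, `z_eqtl`, `z_ai`, `z_decaf`, `p`,
#'   `n_total`, `n_het`, `components`, plus component effect estimates
#'   (`beta`, `beta_f`, `mu_a`, `alpha_f`).
#' @export
scan_gene <- function(unit, mode = c("cf", "ts", "marginal"), min_het = 5,
                      min_reads = 1, inverse_normal = FALSE) {
  mode <- match.arg(mode)
  nsnp <- nrow(unit$snps$variants)
  if (nsnp == 0) {
    message("gene ", unit$gene$gene_id, ": no testable cis SNPs")
    return(.empty_scan())
  }
  keep <- unit$samples[!unit$cnv_masked[unit$samples]]
  rows <- vector("list", nsnp)
  for (i in seq_len(nsnp)) {
    vid <- unit$snps$variants$variant_id[i]
    x <- unit$snps$dosage[i, keep]
    ok <- !is.na(x) & is.finite(unit$expression[keep]) & !is.na(unit$f[keep])
    if (!is.null(unit$purity)) ok <- ok & !is.na(unit$purity[keep])
    ids <- keep[ok]
    z_eqtl <- NA_real_
    beta <- beta_f <- NA_real_
    if (length(ids) > 4 && stats::sd(x[ids]) > 0 &&
        stats::sd(unit$expression[ids]) > 0) {
      efit <- fit_ieqtl(
        unit$expression[ids], x[ids], f = unit$f[ids],
        purity = if (is.null(unit$purity)) NULL else unit$purity[ids],
        cnv = if (unit$has_cnv) unit$cnv_value[ids] else NULL,
        mode = mode, inverse_normal = inverse_normal)
      if (efit$identifiable) {
        z_eqtl <- efit$z_test
        beta <- unname(efit$coefficients["x"])
        beta_f <- if ("x:f" %in% names(efit$coefficients))
          unname(efit$coefficients["x:f"]) else NA_real_
      }
    }
    obs <- .snp_allelic_obs(unit, i, min_reads)
    z_ai <- NA_real_
    mu_a <- alpha_f <- NA_real_
    n_het <- if (is.null(obs)) 0L else nrow(obs)
    if (!is.null(obs) && nrow(obs) >= min_het) {
      afit <- fit_iai(obs,
                      include_fraction = (mode != "marginal"),
                      include_purity = (mode == "ts") && !is.null(obs$purity),
                      include_cnv = unit$has_cnv,
                      min_het = min_het)
      if (afit$identifiable && afit$converged) {
        z_ai <- switch(mode,
                       cf = unname(afit$z["alpha_f"]),
                       ts = unname(afit$z["alpha_purity"]),
                       marginal = unname(afit$z["mu_a"]))
        mu_a <- unname(afit$coefficients["mu_a"])
        alpha_f <- if ("alpha_f" %in% names(afit$coefficients))
          unname(afit$coefficients["alpha_f"]) else NA_real_
      }
    }
    comp <- c(if (is.finite(z_eqtl)) "eqtl", if (is.finite(z_ai)) "ai")
    if (length(comp) == 0) next
    z <- stouffer_combine(c(z_eqtl, z_ai))
    rows[[i]] <- data.frame(
      gene_id = unit$gene$gene_id, snp_id = vid,
      cell_type = unit$cell_type, pos = unit$snps$variants$pos[i],
      mode = mode, z_eqtl = z_eqtl, z_ai = z_ai, z_decaf = z,
      p = 2 * stats::pnorm(-abs(z)), n_total = length(ids), n_het = n_het,
      components = paste(comp, collapse = "+"),
      beta = beta, beta_f = beta_f, mu_a = mu_a, alpha_f = alpha_f,
      stringsAsFactors = FALSE)
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0) {
    message("gene ", unit$gene$gene_id, ": no testable cis SNPs")
    return(.empty_scan())
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$pos, out$snp_id, method = "radix"), , drop = FALSE]
}

.empty_scan <- function() {
  data.frame(gene_id = character(0), snp_id = character(0),
             cell_type = character(0), pos = integer(0), mode = character(0),
             z_eqtl = numeric(0), z_ai = numeric(0), z_decaf = numeric(0),
             p = numeric(0), n_total = integer(0), n_het = integer(0),
             components = character(0), beta = numeric(0),
             beta_f = numeric(0), mu_a = numeric(0), alpha_f = numeric(0),
             stringsAsFactors = FALSE)
}

#' Gene-level Bonferroni and per-cell-type BH correction
#'
#' Applies the two-stage multiple-testing procedure to a full scan: within
#' each (gene, cell type) the most significant SNP is selected (ties broken
#' by smaller genomic position, then lexicographic SNP id) and its p-value
#' Bonferroni-corrected for the number of SNPs tested in that gene; the
#' resulting per-gene p-values are then Benjamini-Hochberg corrected across
#' genes within each cell type.
#'
#' @param results Scan results data frame (rows from [scan_gene()], possibly
#'   over many genes and cell types).
#' @return Data frame with one row per (gene, cell type): the top SNP's row
#'   plus `n_snps_tested`, `gene_p_bonferroni` and `fdr` columns, ordered by
#'   cell type then gene.
#' @examples
#' # gene with 10 SNPs and min p = 0.001 has gene_p_bonferroni = 0.01
#' @export
correct_multiple_tests <- function(results) {
  if (nrow(results) == 0) {
    out <- .empty_scan()
    out$n_snps_tested <- integer(0)
    out$gene_p_bonferroni <- numeric(0)
    out$fdr <- numeric(0)
    return(out)
  }
  grp <- interaction(results$cell_type, results$gene_id, drop = TRUE,
                     sep = "\r")
  tops <- lapply(split(seq_len(nrow(results)), grp), function(idx) {
    sub <- results[idx, , drop = FALSE]
    ord <- order(sub$p, sub$pos, sub$snp_id, method = "radix")
    top <- sub[ord[1], , drop = FALSE]
    top$n_snps_tested <- nrow(sub)
    top$gene_p_bonferroni <- min(1, top$p * nrow(sub))
    top
  })
  out <- do.call(rbind, tops)
  rownames(out) <- NULL
  out$fdr <- NA_real_
  for (ct in unique(out$cell_type)) {
    sel <- out$cell_type == ct
    out$fdr[sel] <- stats::p.adjust(out$gene_p_bonferroni[sel],
                                    method = "BH")
  }
  out[order(out$cell_type, out$gene_id, method = "radix"), , drop = FALSE]
}

#' Scan many genes and apply multiple-testing correction
#'
#' Convenience driver over [build_test_unit()], [scan_gene()] and
#' [correct_multiple_tests()] for a set of genes and one cell type.
#'
#' @param genes Gene model data frame (see [read_gene_models()]).
#' @param genotypes A `decaf_genotypes` panel.
#' @param expression Gene x individual expression matrix.
#' @param fractions Cell-fraction / purity covariate table.
#' @param cell_type Fraction column to test.
#' @param mode Test mode, see [scan_gene()].
#' @param ase,cnv Optional allelic counts and CNV segments.
#' @param fdr Significance threshold applied to the `significant` flag
#'   (default 0.10).
#' @param ... Further arguments passed to [build_test_unit()] and
#'   [scan_gene()] (`window_bp`, `maf_min`, `min_het`, ...).
#' @return List with `all` (per-SNP scan rows) and `genes` (top SNP per
#'   gene with `gene_p_bonferroni`, `fdr` and logical `significant`).
#' @export
decaf_scan <- function(genes, genotypes, expression, fractions, cell_type,
                       mode = c("cf", "ts", "marginal"), ase = NULL,
                       cnv = NULL, fdr = 0.10, ...) {
  mode <- match.arg(mode)
  dots <- list(...)
  unit_args <- dots[intersect(names(dots),
                              names(formals(build_test_unit)))]
  scan_args <- dots[intersect(names(dots), names(formals(scan_gene)))]
  all_rows <- lapply(seq_len(nrow(genes)), function(i) {
    unit <- do.call(build_test_unit,
                    c(list(gene = genes[i, , drop = FALSE],
                           genotypes = genotypes, expression = expression,
                           fractions = fractions, cell_type = cell_type,
                           ase = ase, cnv = cnv), unit_args))
    do.call(scan_gene, c(list(unit = unit, mode = mode), scan_args))
  })
  all_rows <- do.call(rbind, all_rows)
  tops <- correct_multiple_tests(all_rows)
  if (nrow(tops) > 0) tops$significant <- tops$fdr <= fdr
  list(all = all_rows, genes = tops)
}
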