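# Fixture builders used across the suite. Everything is generated in code
# at test time; files are written to tempdir().

# Write a small phased VCF. `gt` is a variants x individuals character
# matrix of GT strings ("0|1", "1|1", "./.", "0/1", ...).
write_test_vcf <- function(gt, chrom = "chr1", pos = NULL, ids = NULL,
                           ref = NULL, alt = NULL,
                           path = tempfile(fileext = ".vcf")) {
  nv <- nrow(gt)
  if (is.null(pos)) pos <- seq(1000, by = 1000, length.out = nv)
  if (is.null(ids)) ids <- paste0("rs", seq_len(nv))
  if (is.null(ref)) ref <- rep("A", nv)
  if (is.null(alt)) alt <- rep("G", nv)
  samples <- colnames(gt)
  if (is.null(samples)) samples <- paste0("s", seq_len(ncol(gt)))
  hdr <- c("##fileformat=VCFv4.2",
           paste0("##contig=<ID=", chrom, ">"),
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", samples), collapse = "\t"))
  body <- vapply(seq_len(nv), function(i) {
    paste(c(chrom, pos[i], ids[i], ref[i], alt[i], ".", "PASS", ".", "GT",
            gt[i, ]), collapse = "\t")
  }, character(1))
  writeLines(c(hdr, body), path)
  path
}

# ASEReadCounter-style TSV for given rows.
write_test_ase <- function(df, path = tempfile(fileext = ".tsv")) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# A small complete scan dataset with a known cfQTL architecture:
# one gene, `n` individuals, a causal common SNP at the TSS whose alt
# allele sits on hap1 for every het, and a read-carrying functional SNP in
# the gene body phased with it. Returns the pieces decaf_scan() needs.
make_scan_fixture <- function(n = 120, pi_f = 0.9, sigma_effect = 0.15,
                              depth = 80, seed = 42) {
  set.seed(seed)
  samples <- sprintf("s%03d", seq_len(n))
  # causal SNP genotypes, HWE at maf 0.4
  maf <- 0.4
  x <- rbinom(n, 2, maf)
  het <- x == 1
  # phase: for hets alt on hap1
  gt_causal <- ifelse(x == 0, "0|0", ifelse(x == 2, "1|1", "1|0"))
  # functional SNP: perfectly phased with causal (same haplotypes)
  gt_func <- gt_causal
  # two null SNPs
  gt_null1 <- replicate(n, paste(rbinom(1, 1, 0.3), rbinom(1, 1, 0.3),
                                 sep = "|"))
  gt_null2 <- replicate(n, paste(rbinom(1, 1, 0.2), rbinom(1, 1, 0.2),
                                 sep = "|"))
  gt <- rbind(causal = gt_causal, func = gt_func,
              null1 = gt_null1, null2 = gt_null2)
  colnames(gt) <- samples
  pos <- c(500000, 500800, 520000, 480000)
  vcf <- write_test_vcf(gt, pos = pos,
                        ids = c("rs_causal", "rs_func", "rs_null1",
                                "rs_null2"))
  f <- runif(n)
  # expression: genotype x fraction effect
  y <- sqrt(sigma_effect) * scale(x * f)[, 1] + rnorm(n, sd = 1)
  names(y) <- samples
  expr <- matrix(y, nrow = 1, dimnames = list("GENE1", samples))
  # allelic counts at the functional SNP for hets: alt allele on hap1
  pi_i <- 0.5 * (1 - f[het]) + pi_f * f[het]
  d <- rpois(sum(het), depth) + 1
  alt_counts <- rbinom(sum(het), d, pi_i)
  ase <- read_ase_counts(write_test_ase(
    data.frame(individual = samples[het], contig = "chr1",
               position = 500800, variantID = "rs_func",
               refAllele = "A", altAllele = "G",
               refCount = d - alt_counts, altCount = alt_counts)))
  fractions <- data.frame(individual = samples, myeloid = f,
                          purity = runif(n, 0.3, 0.9))
  genes <- data.frame(gene_id = "GENE1", chrom = "chr1", tss = 500000L,
                      strand = "+", start = 500100L, end = 501500L)
  list(vcf = vcf, genotypes = read_phased_vcf(vcf), expr = expr,
       ase = ase, fractions = fractions, genes = genes, x = x, f = f,
       samples = samples)
}

# Independent beta-binomial log-pmf via numerical integration of the
# binomial pmf against the Beta mixing density (oracle for dbetabinom).
bb_log_pmf_integrate <- function(k, n, p, rho) {
  s <- (1 - rho) / rho
  a <- p * s
  b <- (1 - p) * s
  val <- integrate(function(q) dbinom(k, n, q) * dbeta(q, a, b),
                   lower = 0, upper = 1, rel.tol = 1e-10)$value
  log(val)
}
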