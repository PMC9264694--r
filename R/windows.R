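#' Select cis-window SNPs for a gene
#'
#' Restricts a genotype panel to common SNPs in the cis locus of a gene:
#' positions within `window_bp` of the TSS (closed interval, strand-ignored)
#' with sample minor allele frequency strictly above `maf_min`.
#'
#' @param gene One-row data frame or list with `gene_id`, `chrom`, `tss`.
#' @param genotypes A `decaf_genotypes` panel.
#' @param window_bp Half-window around the TSS in bp (default 100000).
#' @param maf_min MAF threshold, exclusive (default 0.01).
#' @return A `decaf_genotypes` panel containing the selected SNPs (possibly
#'   empty).
#' @export
cis_window_snps <- function(gene, genotypes, window_bp = 100000,
                            maf_min = 0.01) {
  v <- genotypes$variants
  inwin <- v$chrom == gene$chrom &
    v$pos >= gene$tss - window_bp & v$pos <= gene$tss + window_bp
  af <- rowMeans(genotypes$dosage, na.rm = TRUE) / 2
  maf <- pmin(af, 1 - af)
  keep <- inwin & !is.na(maf) & maf > maf_min
  .subset_genotypes(genotypes, which(keep))
}

#' Per-test CNV masking and covariate extraction
#'
#' For a locus, looks up each individual's overlapping CNV segment and (i)
#' masks individuals whose segment mean exceeds the deep-CNV threshold
#' (strict inequality), (ii) returns the segment mean as a covariate for the
#' rest (0 when no segment overlaps). When several segments overlap the
#' locus for one individual, the one with the largest absolute segment mean
#' governs both masking and the covariate.
#'
#' @param individuals Character vector of individual ids in the test.
#' @param segments CNV segment data frame (see [read_cnv_segments()]); may
#'   be `NULL` for no CNV data.
#' @param chrom,start,end Locus (1-based, closed).
#' @param threshold Deep-CNV segment-mean threshold (default 0.1).
#' @param signed If `FALSE` (default) mask on `|segment_mean| > threshold`
#'   (amplifications and deletions alike); if `TRUE`, mask only
#'   `segment_mean > threshold`.
#' @return Data frame with columns `individual`, `cnv_value`, `masked`.
#' @export
apply_cnv_mask <- function(individuals, segments, chrom, start, end,
                           threshold = 0.1, signed = FALSE) {
  cnv_value <- stats::setNames(rep(0, length(individuals)), individuals)
  if (!is.null(segments) && nrow(segments) > 0) {
    hit <- segments$chrom == chrom & segments$start <= end &
      segments$end >= start & segments$individual %in% individuals
    seg <- segments[hit, , drop = FALSE]
    if (nrow(seg) > 0) {
      seg <- seg[order(abs(seg$segment_mean), decreasing = TRUE), ]
      seg <- seg[!duplicated(seg$individual), ]
      cnv_value[seg$individual] <- seg$segment_mean
    }
  }
  masked <- if (signed) cnv_value > threshold else abs(cnv_value) > threshold
  data.frame(individual = individuals, cnv_value = unname(cnv_value),
             masked = unname(masked), stringsAsFactors = FALSE)
}

#' Aggregate allelic reads across a haplotype
#'
#' Sums the reads of an individual's heterozygous, phased functional SNPs
#' onto the two haplotypes of a (distal) test SNP: `alt_reads` collects
#' every read whose allele lies on the haplotype carrying the test SNP's
#' alternative allele, `ref_reads` the complement. Homozygous or unphased
#' functional sites contribute nothing (unphased sites are skipped with a
#' warning).
#'
#' @param test_hap Length-2 integer vector: the individual's phased alleles
#'   (0/1) at the test SNP. Must be heterozygous.
#' @param site_hap1,site_hap2 Integer vectors of the functional sites'
#'   phased alleles on haplotype 1 and 2 (`NA` = unphased).
#' @param ref_counts,alt_counts Read counts at the functional sites.
#' @return List with `ref_reads`, `alt_reads`, `depth`, `n_sites` (number of
#'   heterozygous sites used).
#' @export
aggregate_haplotype_counts <- function(test_hap, site_hap1, site_hap2,
                                       ref_counts, alt_counts) {
  if (length(test_hap) != 2 || anyNA(test_hap) || sum(test_hap) != 1)
    stop("individual must be heterozygous and phased at the test SNP")
  unphased <- is.na(site_hap1) | is.na(site_hap2)
  if (any(unphased))
    warning(sum(unphased), " unphased functional site(s) skipped")
  het <- !unphased & (site_hap1 + site_hap2 == 1)
  h1 <- site_hap1[het]
  rc <- ref_counts[het]
  ac <- alt_counts[het]
  # allele of each functional site on the haplotype carrying the test ALT
  on_alt <- if (test_hap[1] == 1) h1 else 1L - h1
  alt_reads <- sum(ifelse(on_alt == 1L, ac, rc))
  ref_reads <- sum(ifelse(on_alt == 1L, rc, ac))
  list(ref_reads = ref_reads, alt_reads = alt_reads,
       depth = ref_reads + alt_reads, n_sites = sum(het))
}
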