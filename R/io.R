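#' Read phased genotypes from a VCF
#'
#' Loads biallelic SNPs from a VCF into a genotype panel: a variant table
#' plus per-individual dosage and phased haplotype matrices. Multiallelic
#' sites and non-SNP variants are skipped with a warning. Unphased genotypes
#' are kept (dosage is still defined) but flagged, so they are excluded from
#' haplotype-based allelic aggregation.
#'
#' @param path Path to a VCF file (plain or bgzipped).
#' @param region Optional region filter `"chrom:start-end"` (1-based,
#'   closed).
#' @return An object of class `decaf_genotypes`: list with
#'   \describe{
#'     \item{variants}{data frame `variant_id`, `chrom`, `pos`, `ref`,
#'       `alt`.}
#'     \item{dosage}{integer matrix, variants x individuals (NA = missing).}
#'     \item{hap1,hap2}{0/1 matrices of haplotype alleles (NA when
#'       unphased/missing).}
#'     \item{phased}{logical matrix.}
#'     \item{samples}{character vector of individual ids.}
#'   }
#' @export
read_phased_vcf <- function(path, region = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0) stop("VCF contains no variant records: ", path)
  pos <- as.integer(fix$POS)
  snp <- !is.na(fix$REF) & !is.na(fix$ALT) &
    nchar(fix$REF) == 1 & nchar(fix$ALT) == 1 &
    !grepl(",", fix$ALT, fixed = TRUE) & fix$REF != fix$ALT
  if (any(!snp)) {
    warning(sum(!snp), " multiallelic or non-SNP record(s) skipped")
  }
  keep <- snp
  if (!is.null(region)) {
    m <- regmatches(region, regexec("^([^:]+):([0-9]+)-([0-9]+)$", region))[[1]]
    if (length(m) != 4) stop("region must be 'chrom:start-end'")
    keep <- keep & fix$CHROM == m[2] &
      pos >= as.integer(m[3]) & pos <= as.integer(m[4])
  }
  if (!any(keep)) stop("no biallelic SNPs after filtering")
  gt <- vcfR::extract.gt(v, element = "GT")[keep, , drop = FALSE]
  fix <- fix[keep, , drop = FALSE]
  pos <- pos[keep]
  id <- ifelse(is.na(fix$ID) | fix$ID == ".",
               paste0(fix$CHROM, ":", pos, "_", fix$REF, "_", fix$ALT),
               fix$ID)
  parse_allele <- function(g, which) {
    a <- sub(if (which == 1) "^([0-9.]+)[|/].*$" else "^.*[|/]([0-9.]+)$",
             "\\1", g)
    suppressWarnings(as.integer(a))
  }
  a1 <- matrix(parse_allele(gt, 1), nrow = nrow(gt), dimnames = dimnames(gt))
  a2 <- matrix(parse_allele(gt, 2), nrow = nrow(gt), dimnames = dimnames(gt))
  phased <- matrix(grepl("|", gt, fixed = TRUE) & !is.na(a1) & !is.na(a2),
                   nrow = nrow(gt), dimnames = dimnames(gt))
  dosage <- a1 + a2
  hap1 <- a1; hap1[!phased] <- NA_integer_
  hap2 <- a2; hap2[!phased] <- NA_integer_
  rn <- id
  rownames(dosage) <- rownames(hap1) <- rownames(hap2) <- rownames(phased) <- rn
  structure(list(
    variants = data.frame(variant_id = id, chrom = fix$CHROM, pos = pos,
                          ref = fix$REF, alt = fix$ALT,
                          stringsAsFactors = FALSE),
    dosage = dosage, hap1 = hap1, hap2 = hap2, phased = phased,
    samples = colnames(gt)),
    class = "decaf_genotypes")
}

#' @export
print.decaf_genotypes <- function(x, ...) {
  cat(sprintf("Genotype panel: %d SNPs x %d individuals\n",
              nrow(x$variants), length(x$samples)))
  invisible(x)
}

# subset a genotype panel by variant index
.subset_genotypes <- function(g, i) {
  structure(list(variants = g$variants[i, , drop = FALSE],
                 dosage = g$dosage[i, , drop = FALSE],
                 hap1 = g$hap1[i, , drop = FALSE],
                 hap2 = g$hap2[i, , drop = FALSE],
                 phased = g$phased[i, , drop = FALSE],
                 samples = g$samples),
            class = "decaf_genotypes")
}

#' Read per-site allelic read counts (ASEReadCounter dialect)
#'
#' Parses the tab-separated output of GATK ASEReadCounter-style allelic
#' quantification: one row per (individual, site) with reference and
#' alternative read counts. A per-individual column is required (named
#' `individual` or `sample`) unless a single `individual` id is supplied for
#' a one-sample file.
#'
#' @param path Path to a TSV with header columns `contig`, `position`,
#'   `refAllele`, `altAllele`, `refCount`, `altCount` (a `variantID` column
#'   is used when present).
#' @param individual Optional id assigned to every row of a single-sample
#'   file.
#' @return Data frame with columns `individual`, `variant_id`, `contig`,
#'   `position`, `refAllele`, `altAllele`, `refCount`, `altCount`.
#' @export
read_ase_counts <- function(path, individual = NULL) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  req <- c("contig", "position", "refAllele", "altAllele",
           "refCount", "altCount")
  missing_cols <- setdiff(req, names(tab))
  if (length(missing_cols) > 0) {
    stop("allelic count file lacks required column(s): ",
         paste(missing_cols, collapse = ", "),
         " (expected ASEReadCounter header: ", paste(req, collapse = ", "), ")")
  }
  if (is.null(individual)) {
    ind_col <- intersect(c("individual", "sample"), names(tab))
    if (length(ind_col) == 0)
      stop("no 'individual'/'sample' column; supply individual= for ",
           "single-sample files")
    ind <- tab[[ind_col[1]]]
  } else {
    ind <- rep(individual, nrow(tab))
  }
  if (nrow(tab) > 0 && (any(tab$refCount < 0) || any(tab$altCount < 0)))
    stop("negative read counts are invalid")
  vid <- if ("variantID" %in% names(tab) && nrow(tab) > 0) {
    ifelse(is.na(tab$variantID) | tab$variantID == ".",
           paste0(tab$contig, ":", tab$position, "_",
                  tab$refAllele, "_", tab$altAllele),
           tab$variantID)
  } else {
    if (nrow(tab) == 0) character(0)
    else paste0(tab$contig, ":", tab$position, "_",
                tab$refAllele, "_", tab$altAllele)
  }
  data.frame(individual = as.character(ind), variant_id = vid,
             contig = as.character(tab$contig),
             position = as.integer(tab$position),
             refAllele = as.character(tab$refAllele),
             altAllele = as.character(tab$altAllele),
             refCount = as.integer(tab$refCount),
             altCount = as.integer(tab$altCount),
             stringsAsFactors = FALSE)
}

#' Read per-individual cell-fraction / purity covariates
#'
#' @param path TSV with an `individual` column and one numeric column per
#'   deconvolution score (and optionally `purity`).
#' @return Data frame; negative fractions or purity outside `[0, 1]` raise
#'   an error.
#' @export
read_cell_fractions <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!"individual" %in% names(tab)) stop("missing 'individual' column")
  num <- setdiff(names(tab), "individual")
  for (cn in num) {
    v <- tab[[cn]]
    if (!is.numeric(v)) stop("column '", cn, "' is not numeric")
    if (cn == "purity") {
      if (any(v < 0 | v > 1, na.rm = TRUE))
        stop("purity must lie in [0, 1]")
    } else if (any(v < 0, na.rm = TRUE)) {
      stop("negative cell-fraction score in column '", cn, "'")
    }
  }
  tab
}

#' Read per-individual CNV segments
#'
#' @param path TSV with columns `individual`, `chrom`, `start`, `end`
#'   (1-based, closed) and `segment_mean` (log2 tumor/normal ratio).
#' @return Data frame of segments.
#' @export
read_cnv_segments <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  req <- c("individual", "chrom", "start", "end", "segment_mean")
  if (!all(req %in% names(tab)))
    stop("CNV file must have columns: ", paste(req, collapse = ", "))
  if (any(tab$start > tab$end)) stop("segment with start > end")
  tab$start <- as.integer(tab$start)
  tab$end <- as.integer(tab$end)
  tab
}

#' Read gene models (TSS table)
#'
#' @param path TSV with columns `gene_id`, `chrom`, `tss`, `strand` and
#'   optionally `start`, `end` (gene body, used to locate functional SNPs).
#' @return Data frame of gene models.
#' @export
read_gene_models <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  req <- c("gene_id", "chrom", "tss", "strand")
  if (!all(req %in% names(tab)))
    stop("gene model file must have columns: ", paste(req, collapse = ", "))
  if (any(tab$tss < 1)) stop("tss must be >= 1")
  tab$tss <- as.integer(tab$tss)
  tab
}

#' Read per-individual total expression
#'
#' @param path TSV matrix with genes in rows (first column `gene_id`) and
#'   individuals in columns.
#' @return Numeric matrix, genes x individuals.
#' @export
read_expression <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!"gene_id" %in% names(tab)) stop("missing 'gene_id' column")
  m <- as.matrix(tab[setdiff(names(tab), "gene_id")])
  rownames(m) <- tab$gene_id
  storage.mode(m) <- "double"
  if (any(!is.finite(m))) stop("non-finite expression values")
  m
}

#' Write scan results to a TSV
#'
#' Writes a deterministic tab-separated table of association results with
#' core columns `snp`, `gene`, `cell_type`, `z`, `p`, `fdr` first, followed
#' by component effect columns. Rows are ordered by gene, then snp, then
#' cell type, so re-writing identical results is byte-identical.
#'
#' @param results Data frame as produced by [decaf_scan()] /
#'   [correct_multiple_tests()] (columns `snp_id`, `gene_id`, `cell_type`,
#'   `z_decaf`, `p`; `fdr` may be absent for unpruned scans).
#' @param path Output file path.
#' @return Invisibly, the written data frame.
#' @export
write_results <- function(results, path) {
  core <- data.frame(
    snp = results$snp_id %||% character(0),
    gene = results$gene_id %||% character(0),
    cell_type = results$cell_type %||% character(0),
    z = results$z_decaf %||% numeric(0),
    p = results$p %||% numeric(0),
    fdr = if (!is.null(results$fdr)) results$fdr else rep(NA_real_, nrow(results)),
    stringsAsFactors = FALSE)
  extra <- setdiff(names(results),
                   c("snp_id", "gene_id", "cell_type", "z_decaf", "p", "fdr"))
  out <- cbind(core, results[extra])
  ord <- order(out$gene, out$snp, out$cell_type, method = "radix")
  out <- out[ord, , drop = FALSE]
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out)
}
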