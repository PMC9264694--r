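test_that("Stouffer combination has its closed forms and properties", {
  expect_equal(stouffer_combine(c(1, 1)), sqrt(2), tolerance = 1e-5)
  expect_equal(stouffer_combine(c(2, -2)), 0)
  expect_equal(stouffer_combine(c(1.96, 0)), (1.96 + 0) / sqrt(2),
               tolerance = 1e-5)
  expect_equal(stouffer_combine(1.7), 1.7)            # single component
  expect_error(stouffer_combine(numeric(0)), "no finite")
  expect_error(stouffer_combine(NA_real_), "no finite")
  # k identical z combine to z * sqrt(k); permutation-invariant
  z <- c(0.4, -1.1, 2.2)
  expect_equal(stouffer_combine(rep(1.3, 4)), 1.3 * 2)
  expect_equal(stouffer_combine(z), stouffer_combine(rev(z)))
  # combining with a zero component scales the z by 1/sqrt(2)
  expect_equal(2 * pnorm(-abs(stouffer_combine(c(2.5, 0)))),
               2 * pnorm(-abs(2.5 / sqrt(2))))
})

test_that("gene-level Bonferroni and per-cell-type BH match hand computation", {
  mk <- function(gene, p, pos) {
    data.frame(gene_id = gene, snp_id = paste0("rs", seq_along(p)),
               cell_type = "tcell", pos = pos, mode = "cf",
               z_eqtl = NA, z_ai = NA, z_decaf = qnorm(p / 2),
               p = p, n_total = 100L, n_het = 10L, components = "eqtl",
               beta = NA, beta_f = NA, mu_a = NA, alpha_f = NA)
  }
  # gene with 10 SNPs, min p 0.001 -> gene_p 0.01
  g1 <- mk("G1", c(0.001, seq(0.2, 0.9, length.out = 9)), 1:10)
  out1 <- correct_multiple_tests(g1)
  expect_equal(out1$gene_p_bonferroni, 0.01)
  expect_equal(out1$n_snps_tested, 10L)
  # four genes with gene_p .01 .02 .03 .04 -> BH all 0.04
  res <- rbind(mk("G1", 0.01, 1), mk("G2", 0.02, 1),
               mk("G3", 0.03, 1), mk("G4", 0.04, 1))
  out <- correct_multiple_tests(res)
  expect_equal(out$fdr, rep(0.04, 4))
  # single gene keeps its own p as fdr
  out2 <- correct_multiple_tests(mk("G9", 0.2, 1))
  expect_equal(out2$fdr, 0.2)
  # BH q-values are monotone in sorted gene_p order
  set.seed(30)
  many <- do.call(rbind, lapply(1:25, function(i)
    mk(sprintf("G%02d", i), runif(1), 1)))
  outm <- correct_multiple_tests(many)
  ord <- order(outm$gene_p_bonferroni)
  expect_true(all(diff(outm$fdr[ord]) >= -1e-12))
})

test_that("top-SNP selection breaks ties by position then id", {
  tie <- data.frame(gene_id = "G1", snp_id = c("rsB", "rsA", "rsC"),
                    cell_type = "tcell", pos = c(500L, 300L, 300L),
                    mode = "cf", z_eqtl = NA, z_ai = NA, z_decaf = 2,
                    p = 0.02, n_total = 50L, n_het = 8L,
                    components = "eqtl", beta = NA, beta_f = NA,
                    mu_a = NA, alpha_f = NA)
  out <- correct_multiple_tests(tie)
  expect_equal(out$snp_id, "rsA")   # smaller pos wins, then lexicographic
})

test_that("a full scan finds the simulated causal cfQTL and ranks it first", {
  fx <- make_scan_fixture(n = 150, pi_f = 0.9, sigma_effect = 0.15,
                          seed = 31)
  unit <- build_test_unit(fx$genes[1, ], fx$genotypes, fx$expr,
                          fx$fractions, cell_type = "myeloid", ase = fx$ase)
  res <- scan_gene(unit, mode = "cf")
  expect_true(all(c("rs_causal", "rs_func") %in% res$snp_id))
  expect_true(all(diff(res$pos) >= 0))            # deterministic order
  top <- res$snp_id[which.max(abs(res$z_decaf))]
  expect_true(top %in% c("rs_causal", "rs_func"))
  # causal SNP carries both components; its AI stat used aggregated hets
  causal <- res[res$snp_id == "rs_causal", ]
  expect_equal(causal$components, "eqtl+ai")
  expect_gt(causal$n_het, 10)
  expect_lt(causal$p, 0.01)
})

test_that("the AI component degrades gracefully below min_het", {
  fx <- make_scan_fixture(n = 150, seed = 32)
  unit <- build_test_unit(fx$genes[1, ], fx$genotypes, fx$expr,
                          fx$fractions, cell_type = "myeloid", ase = fx$ase)
  res <- scan_gene(unit, mode = "cf", min_het = 10000)
  expect_true(all(res$components == "eqtl"))
  expect_equal(res$z_decaf, res$z_eqtl)   # single-component Stouffer
})

test_that("scan without allelic data reduces to the interaction eQTL", {
  fx <- make_scan_fixture(n = 120, seed = 33)
  unit <- build_test_unit(fx$genes[1, ], fx$genotypes, fx$expr,
                          fx$fractions, cell_type = "myeloid", ase = NULL)
  res <- scan_gene(unit, mode = "cf")
  expect_true(nrow(res) > 0)
  expect_true(all(is.na(res$z_ai)))
  expect_equal(res$z_decaf, res$z_eqtl)
})

test_that("deep-CNV carriers are excluded from a test", {
  fx <- make_scan_fixture(n = 150, seed = 34)
  cnv <- data.frame(individual = fx$samples[1:30], chrom = "chr1",
                    start = 1L, end = 1000000L, segment_mean = 0.5)
  unit <- build_test_unit(fx$genes[1, ], fx$genotypes, fx$expr,
                          fx$fractions, cell_type = "myeloid", ase = fx$ase,
                          cnv = cnv)
  res <- scan_gene(unit, mode = "cf")
  expect_true(all(res$n_total <= 120))
  # shallow CNVs stay in and feed the covariate instead
  cnv$segment_mean <- 0.05
  unit2 <- build_test_unit(fx$genes[1, ], fx$genotypes, fx$expr,
                           fx$fractions, cell_type = "myeloid",
                           ase = fx$ase, cnv = cnv)
  res2 <- scan_gene(unit2, mode = "cf")
  expect_true(all(res2$n_total == 150))
})

test_that("decaf_scan drives multiple genes and flags significance", {
  fx <- make_scan_fixture(n = 150, pi_f = 0.9, sigma_effect = 0.2,
                          seed = 35)
  out <- decaf_scan(fx$genes, fx$genotypes, fx$expr, fx$fractions,
                    cell_type = "myeloid", mode = "cf", ase = fx$ase,
                    fdr = 0.10)
  expect_named(out, c("all", "genes"))
  expect_equal(nrow(out$genes), 1L)
  expect_true(out$genes$significant)
  # marginal and ts modes run on the same inputs
  out_m <- decaf_scan(fx$genes, fx$genotypes, fx$expr, fx$fractions,
                      cell_type = "myeloid", mode = "marginal",
                      ase = fx$ase)
  expect_equal(out_m$all$mode[1], "marginal")
  out_t <- decaf_scan(fx$genes, fx$genotypes, fx$expr, fx$fractions,
                      cell_type = "myeloid", mode = "ts", ase = fx$ase)
  expect_equal(out_t$all$mode[1], "ts")
})
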