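---
title: "Methods: combined total and allelic cfQTL mapping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: combined total and allelic cfQTL mapping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(decafr)
```

# The model

`decafr` tests, for every common SNP in the cis window of a gene (TSS
± 100 kb, closed interval, strand ignored; sample MAF strictly above 1%),
whether the variant's regulatory effect scales with the abundance of a
cell type in bulk tissue. Two components are fitted on the same cohort
and combined.

**Interaction eQTL (total expression).** Ordinary least squares on
`y ~ mu + x + f + x:f`, optionally extended with `purity`, `x:purity` and
a local CNV covariate. `x` is the alternative-allele dosage (0/1/2), `f`
the per-individual deconvolution score for the tested cell type. The
cell-fraction mode tests `x:f`, the tumor-specific mode tests `x:purity`,
the marginal mode tests `x` with no interaction terms. The t statistic of
the tested coefficient is converted to a signed standard-normal `z`
through its two-sided p-value (computed on the log scale so extreme
statistics do not underflow), making it commensurate with the Wald z of
the allelic component.

**Interaction allelic imbalance (read counts).** Individuals heterozygous
and phased at the test SNP contribute one observation: reference- and
alternative-haplotype read counts over the gene's read-carrying
("functional") SNPs. A functional SNP is tested with its own counts;
a distal SNP receives the haplotype-oriented sums of all heterozygous
phased functional sites (homozygous or unphased sites contribute
nothing — read totals are conserved, and flipping every site's phase
swaps the two counts exactly). The counts follow a beta-binomial
regression with logit link: the mean allelic fraction is
`p_i = logistic(mu_a + alpha_f f_i [+ alpha_p purity_i + gamma c_i])` and
the count variance uses the intraclass-correlation parameterization
`a = p(1-rho)/rho`, `b = (1-p)(1-rho)/rho`, which reduces to the binomial
at `rho = 0`. `mu_a = 0` corresponds to a balanced allelic fraction of
0.5; `alpha_f != 0` means the imbalance tracks the cell fraction.

The per-individual overdispersion `rho_i` is estimated once per
individual (optionally per CNV region) by maximum likelihood over all of
that individual's heterozygous sites with the mean fixed at 0.5, clamped
to [0, 0.999], and then held fixed while the regression coefficients are
optimized (two-stage fit). Coefficients are maximized by BFGS with an
analytic gradient, initialized at the binomial-GLM solution; standard
errors come from the observed information (numeric Hessian at the
optimum). Convergence requires the optimizer's own criterion or a
gradient norm below 1e-8, within 200 iterations.

**Combination.** The two signed Z scores, both oriented to the
alternative allele, combine as `z = sum(z_k) / sqrt(k)` (Stouffer, equal
weights — equivalent to an equal-weight inverse-variance meta-analysis,
so opposite-signed effects cancel). When only one component is available
(for example fewer than `min_het` heterozygotes for the allelic test) the
combined statistic is that component alone, and the `components` column
records the provenance. The components are independent because the eQTL
test uses variance between genotype classes while the AI test uses
variance between alleles within heterozygotes; the joint-null calibration
test in the suite exercises exactly this assumption with both components
computed on the same simulated individuals.

A note on the denominator: the combination divides by the square *root*
of the number of components. Only that normalization yields a
standard-normal combined statistic and the meta-analysis equivalence; the
suite asserts both numerically.

**Multiple testing.** Per gene and cell type, the most significant SNP is
selected (ties broken by smaller genomic position, then lexicographic SNP
id — a deterministic artifact rule) and its p-value Bonferroni-corrected
by the number of SNPs tested in that gene; gene-level p-values are then
BH-corrected across genes within each cell type, with 10% FDR as the
default reporting threshold.

# Tumor-specific handling

* **Purity.** Tumor purity enters the eQTL model as `purity` and
  `x:purity` (the `ts` mode tests the interaction), and the AI model as
  an additive logit-scale term — the only meaningful analogue, since the
  AI model conditions on heterozygotes and has no dosage term to
  interact with. With purity defined as `1 - NF`, the ts z flips sign
  exactly under the NF parameterization (asserted in the suite).
* **CNVs.** The per-individual local segment mean (log2 tumor/normal
  ratio) is a fixed-effect covariate in both models. Individuals whose
  overlapping segment exceeds the deep-CNV threshold (strictly,
  `|segment_mean| > 0.1`) are masked from that test. Masking uses the
  absolute value by default because deletions distort expression and
  imbalance as much as amplifications; a `signed` flag restores the
  one-sided reading. When several segments overlap a locus, the one with
  the largest absolute mean governs both the mask and the covariate.
  A per-CNV-region overdispersion partition is available in
  `estimate_overdispersion_table(by_region = TRUE)`.

# Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `window_bp` | 100000 | cis half-window around the TSS (bp) |
| `maf_min` | 0.01 | sample MAF, strict lower bound |
| `cnv_threshold` | 0.1 | deep-CNV segment-mean mask, strict |
| `min_het` | 5 | minimum heterozygous observations for the AI component |
| `min_reads` | 1 | minimum read depth per allelic observation |
| `fallback_rho` | 0.0263 | overdispersion for individuals with too few sites |
| `fdr` | 0.10 | reporting threshold after BH |

`min_het` and `min_reads` are engineering defaults: no principled minima
exist for the AI component, and below `min_het` the statistic degrades
gracefully to the eQTL component. Expression is used as provided (the
intended input is upper-quartile-normalized counts); a rank-based
inverse-normal transform is available behind `inverse_normal = TRUE` but
off by default, since the interaction term's interpretation is cleanest
on the supplied scale. Individuals missing any required covariate are
dropped from the affected model with a logged count.

# The simulation framework

`sim_config()` fixes the generative conditions; defaults are anchored in
tumor RNA-seq estimates: overdispersion `rho = 0.0263`, QTL variance
share `sigma_effect = 0.04`, normal-fraction share `sigma_nf = 0.0269`,
CNV share `sigma_cnv = 0.012`, 500 replicates per condition, and
genome-wide significance at `0.05/20000`. Where no value is stated
anywhere, the package fixes one realistic choice and keeps it: MAF 0.25
(a typical common variant), mean read depth 100, purity uniform on
[0.3, 0.9] (a TCGA-like range), CNV carrier fraction 0.5 (tumor genomes
are CNV-dense; in clear-cell kidney cancer most samples carry large
arm-level events), allelic CNV shift 0.1 on the fraction scale.

Each replicate generates one cohort shared by all three tests:

* genotype classes at their rounded Hardy-Weinberg expectations
  (`round(2 maf (1-maf) N)` heterozygotes, matching the expected-count
  construction rather than binomial sampling);
* cell fractions uniform on [0, 1] or bootstrapped from a supplied
  vector of real deconvolution scores (the uniform case is optimistic —
  real immune-fraction scores are skewed low, which is why the power
  study supports both sources);
* allelic counts for heterozygotes: depth `D ~ Poisson(mean_depth)`,
  allelic fraction `pi = 0.5(1-f) + pi_f f` (clipped to
  (0.001, 0.999) with a counter in the truth record),
  `ALT ~ BetaBin(D, pi, rho)`, `REF = D - ALT`;
* expression `y = b_nf NF + b_xf (x f) + b_cnv CNV + e`, `e` standard
  normal, each coefficient scaled so its standardized term explains
  exactly its configured variance share (the shares must sum below 1);
* power = fraction of replicates with `p < alpha`, with exact
  Monte-Carlo standard errors; per-cell and per-replicate seeds derive
  hierarchically from the master seed, so any grid cell can be
  regenerated alone.

**CNV architectures.** Two generative models are provided. Under the
`fixed` model a carrier's alternative allele is consistently amplified:
the allelic shift is a constant the signed covariate absorbs, so it
costs essentially no power and serves as the benign case. Under the
`random` model the CNV hits a random haplotype: the DNA-derived segment
value (signed by amplification versus deletion) still absorbs the
expression offset, but the allelic shift direction is independent of it
and cannot be regressed out. This is precisely the situation that
motivates estimating overdispersion per CNV region in real data; with
one observation per simulated individual that estimation step is
represented analytically, by inflating carriers' analysis
overdispersion by `shift^2 / 0.25` (the variance of a +/-`shift`
coin-flip at a balanced fraction). The calibration suite verifies that
all three tests keep nominal type-I error under CNV-containing nulls
with this treatment.

**CNV power cost.** `cnv_power_cost()` runs the default grid
(`pi_f` in {0.6, 0.7, 0.9} crossed with N in {100, ..., 1000}) twice —
no CNVs versus random-architecture CNVs with the covariate in both
models — and reports the average fold change in combined-test power as
the ratio of grid-mean powers. The aggregate deliberately avoids
averaging per-cell ratios: wherever power approaches zero a cell-wise
ratio is unbounded Monte-Carlo noise (a 0.03/0.005 cell would contribute
"6x" on its own), while the ratio of means is stable at the study's
replicate counts.

# Problem sizes

The shipped statistical suite runs the calibration study at 2000
replicates per null condition (four conditions: CNV presence crossed
with overdispersion 0 / 0.0263), the power-dominance study at 500
replicates per cell over the 18-cell default grid, the CNV power-cost
experiment at 500 replicates per condition arm, and parameter-recovery
studies at 200 replicates (cohorts of 500 heterozygotes at depth 100).
These sizes give Monte-Carlo standard errors near 0.005-0.022 on a
power scale, small against the effects under test.

# What the simulations do and do not show

The generator reproduces the statistical skeleton of the design —
mixture allelic fractions, read-level noise with overdispersion,
variance-calibrated expression effects, CNV disruption — but not
everything real data brings: no LD between test and functional SNPs
(the scan handles it; the power study tests one causal SNP), no
deconvolution error in `f` beyond what a supplied real-score bootstrap
carries, no mapping bias (inputs are assumed WASP-filtered upstream),
no somatic point mutations, and the purity term is independent of `f`
in simulation while real fractions correlate with purity. Passing the
suite therefore certifies calibration and relative power under the
modeled mechanisms, not discovery rates on any particular real cohort.

# Known limitations

* Power is low for rare cell types (low fraction mean or variance) — an
  intrinsic limit, since `alpha_f` and `beta_f` are scaled by the
  fraction's spread.
* Effect sizes are on the scale of the supplied deconvolution score, not
  of a true cell percentage.
* The AI component requires phase; trans effects are out of reach by
  construction.
* The random-effect CNV regression variant is implemented only as a
  generative architecture in the simulator; the analysis side ships the
  selected fixed-effect-covariate plus masking combination.
* Wald inference is mildly optimistic at very small heterozygote counts;
  `min_het` exists to keep the AI component out of that regime.
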