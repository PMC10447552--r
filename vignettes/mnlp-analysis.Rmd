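---
title: "Dissecting a length polymorphism at a GWAS locus: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dissecting a length polymorphism at a GWAS locus: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mnlpkit)
```

## The problem

Genome-wide association studies localize disease risk to loci, but the
candidate causal variants considered downstream are almost always SNPs. Some
risk loci are instead driven by *complex variants* — non-SNP germline
polymorphisms of roughly 10–100 bp. The motivating case is a biallelic
multi-nucleotide length polymorphism (MNLP) with a 21-bp short (S) and a
47-bp long (L) allele at a prostate-cancer risk locus, where the L allele
creates an active enhancer and raises expression of the nearby homeobox
gene, while the GWAS index SNP is only a linked passenger. Establishing such
a variant as causal needs four computational pieces, which this package
implements end to end on synthetic data with the statistical structure the
analyses assume:

1. genotype the MNLP accurately (amplicon reads; coverage patterns);
2. dissect the two-locus system (index SNP x MNLP): LD, recombinant
   carriers, and which variant better explains expression;
3. test haplotype-resolved chromatin counts for allelic imbalance;
4. associate the (genetically predicted) complex variant with disease risk
   from GWAS summary statistics, with conditioning and colocalization.

## Genotyping model

**Allele-specific references.** The S and L references are the shared flanks
with the respective allele inserted; they differ only on the allele interval
(0-based half-open coordinates internally; VCF output converts to 1-based).

**Read classification.** Each read is scored by semi-global alignment
against both references — read global, reference local, match +1, mismatch
-1, gap -2 (compiled in C++; an independent cross-check against
`Biostrings::pairwiseAlignment` with the identical scoring scheme is part of
the test suite). A read is assigned to the higher-scoring allele only if its
score reaches `(1 - 2 * max_mismatch_frac) * read_len` (default mismatch
budget 5%) *and* the margin over the other allele is at least `min_margin`
(default 2, i.e. at least one discriminating base). Flank-only reads tie and
are ambiguous; reads failing the score bar, or containing characters outside
A/C/G/T/N, are unmatched. The scheme tolerates sequencing error while
remaining an exact, testable rule.

**Genotype calls.** From reads, the L-allele fraction `n_L / (n_L + n_S)` is
compared to a heterozygote band, default (0.2, 0.8): the midpoints between
the expected fractions 0, 0.5 and 1. Fewer than `min_reads = 50` classified
reads give a no-call rather than a guess. From coverage, the relative depth
of the allele-specific segment over the flank depth estimates dosage/2, with
bands at 0.25/0.75 (again midpoints); flank depth below `min_depth = 10`
gives a no-call. These thresholds are exposed because no printed values pin
them.

**Knock-in verification.** A clone carrying the integrated L allele passes
when (i) the read *consensus* over the border + allele region (`tccg` on the
left, `gcgtc` on the right of the allele) is exactly the reference and (ii)
no position carries the same non-reference base in more than 5% of reads (a
recurrent variant). The per-read intact-border fraction is reported as
evidence but is deliberately not the pass criterion: under a per-base error
rate `e` the expected per-read intact fraction over the 9 border bases is
only `(1-e)^9` (about 0.83 at 2% error), so a per-read threshold would fail
clones that are perfectly correct at the consensus level — which is the
level at which clone verification is meaningful.

**Coverage-based discovery.** Per genomic window, each sample's relative
depth is snapped to the nearest biallelic dosage class in {0, 0.5, 1};
windows occupied by at least two classes whose values correlate with the
lead-SNP dosage at `r^2 >= 0.5` become candidates, adjacent windows merge,
and candidates are ranked by best-window r^2. The three-class restriction
encodes the biallelic assumption; multi-allelic or CNV-confounded loci are
out of scope.

## Two-locus haplotype model

Unphased dosages at two biallelic loci leave only the double heterozygote
phase-ambiguous. The EM estimator starts at linkage equilibrium (products of
observed allele frequencies), splits the double heterozygotes between the
coupling (T-S/C-L) and repulsion phasings by their current relative
likelihood, and stops when the largest frequency change falls below `1e-8`.
With a single ambiguous class the likelihood is unimodal in practice; the
test suite verifies agreement with a brute-force grid search (step `1e-4`)
over the one free haplotype frequency, and non-decreasing log-likelihood per
iteration. From the frequencies, `D = f_TS - p_T p_S`, `D' = |D| / D_max`
and `r^2 = D^2 / (p_T p_C p_S p_L)`.

For biallelic loci `r^2 <= D'^2` is a mathematical identity, enforced by a
property test over random frequency draws. A printed LD pair of the form
(D' = 0.72, r^2 = 0.76) is therefore impossible for a biallelic pair —
likely a transposition — and the package never uses such a pair as a
numerical target; the synthetic defaults instead produce tight coupling
(D' ~ 0.87, r^2 ~ 0.7).

**Recombinants.** Under the coupling phase (T with S, C with L; configurable)
each of the nine SNP x MNLP genotype combinations resolves to a minimum
number of non-coupling haplotypes over its phase resolutions: 0 for the five
parental cells (the double heterozygote resolves to coupling), 1 for the
four single-heterozygote cells, and 2 for the two discordant double
homozygotes. The last rule extends the published single-heterozygote
recombinant categories so that all nine cells classify deterministically.
Association uses Pearson correlation between trait and dosage (two-sided t,
n-2 df) plus, for the SNP-vs-MNLP comparison, partial correlations of each
variant given the other and the 3x3 grid of stratified means — all three
quantities are reported because any of them can underlie a "stronger
impact" claim, and the recombinant cells are exactly where they separate.

## Haplotype beta-binomial allelic imbalance

Counts of haplotype-A vs haplotype-B reads at heterozygous sites are merged
per (individual, condition, peak) into a single (K, N). The beta-binomial is
parameterized by the allelic proportion `p` and the intraclass correlation
`rho` (shapes `a = p(1/rho - 1)`, `b = (1-p)(1/rho - 1)`; variance
`n p (1-p) (1 + (n-1) rho)`; exactly binomial at `rho = 0`).

*Overdispersion* is estimated per individual and condition by bounded
maximum likelihood on [0, 0.999] with `p` fixed at the null 0.5
(null-anchored: the estimate must not absorb genuine imbalance); a single
observation is unidentifiable and reported as `rho = 0` with a flag. No
copy-number adjustment of the expected 0.5 is made — appropriate in the
near-zero overdispersion regime the estimator targets (per-individual
estimates on the order of 1e-4 to 1e-3).

*Tests.* The combined test pools all heterozygous individuals under a
consistent allele-specific effect: H0 fixes `p = 0.5` per individual (each
with its own rho), H1 fits one shared `p`; `2(l1 - l0)` is referred to a
1-df chi-square. When the total read count is below 20 and the configuration
space is small, an exact enumeration p-value replaces the asymptotic one
(the LRT statistic is evaluated on a fixed fine grid of `p` so the ordering
over configurations is consistent). The differential test compares a shared
`p` across tumor and normal against condition-specific proportions; its null
leaves the shared proportion free, so exact enumeration would require a
conditioning choice with no canonical definition, and the asymptotic p-value
is used at all depths. Tests run once per category (normal, tumor, both,
differential); BH FDR is applied within each category and a peak is flagged
in a category if any of its tests reaches `q <= 0.10`.

## Complex-variant TWAS, conditioning, colocalization

CV dosage is regressed on standardized cis-SNP dosages by ridge regression
(penalty by inner cross-validation; elastic-net and single-best-SNP modes
available), with outer k-fold out-of-sample r^2 — computed as
`1 - SS_res/SS_tot`, so it can be negative — and weights refit on the full
panel. The summary-statistic association is `z_cv = w'z / sqrt(w'Rw)`;
conditioning uses `r_j = (Rw)_j / sqrt(w'Rw)` and
`z_cond = (z_j - r_j z_cv) / sqrt(1 - r_j^2)`, with SNPs at `|r_j| > 0.99`
reported as not assessable. Colocalization uses Wakefield approximate Bayes
factors (`log ABF = 0.5 log(1-r) + 0.5 z^2 r`, `r = W/(W + 1/n)`, prior
effect SD 0.15) combined over the five causal configurations with priors
(1e-4, 1e-4, 1e-5); the genome-wide threshold is fixed at 5e-8. The LD
matrix comes from the same panel as training and receives `1e-6` on the
diagonal before any inversion. The "statistically equivalent signals" check
is `(z_cv - z_top) / sqrt(2(1 - r))`, two-sided normal.

Two behaviors of this stage deserve flagging. First, the trait-2 z-scores
for colocalization are the panel-derived per-SNP associations with CV
dosage, `z_j = r_{j,cv} sqrt(n-2) / sqrt(1 - r_{j,cv}^2)`; for well-tagged
variants these are extremely large, which makes the H3-vs-H4 split
knife-edge sensitive to which LD tag happens to top each trait — the
familiar failure mode of single-causal-variant colocalization under
overwhelming signals. The canonical shared-causal construction (both traits
peaking at the same SNP) is stable and is what the acceptance checks bound.
Second, after conditioning on a variant that fully mediates the association,
each SNP's conditional Z is exactly standard normal, so "every significant
SNP falls below |z| = 1.96" holds per locus with probability about
`0.95^k` for `k` effectively independent significant tags; with the default
LD structure and an expected `z_cv ~ 10`, k is around 7 and the all-below
rate plateaus near 70%. The robust statements — the locus chi-square sum
always shrinks, and conditioning removes all genome-wide significance — are
the ones the package asserts in its green tests.

## What the synthetic data does and does not emulate

The generators are seeded (identical seed, identical bytes) and cover:
amplicon reads with per-base substitution errors; per-base depth with
gamma multiplicative noise (CV `noise_cv`); phased two-locus cohorts drawn
i.i.d. from four haplotype frequencies with an additive expression effect
of L dosage; haplotype-resolved count tables with beta-binomial
overdispersion per condition; and cis panels built by founder-copying
(haplotype mosaics over 10 founders, per-site switch probability 0.01),
with the CV allele riding on half of the founders and GWAS Z-scores either
analytic or from logistic case-control sampling. In analytic mode the noise
is drawn jointly MVN(0, R) — marginally N(0,1) per SNP — because GWAS
summary-statistic noise is LD-correlated; with independent noise the
conditioning identity would not even have unit variance under the null.

Defaults encode the study conditions: haplotype frequencies
(0.42, 0.03, 0.05, 0.50) giving tight T-S/C-L coupling; expression shift
1.0 per L copy with residual SD 1.0; overdispersion 5e-4 (normal) and
2.7e-3 (tumor); imbalanced-peak allelic ratio 0.9 (about ten-fold
enrichment of one haplotype's reads); GWAS effect 0.045 per standardized CV
dosage at n = 50,000, i.e. an expected `z_cv` of about 10. The ASE site
depth law (negative binomial, mean 40, size 10, floored at 1) is a modeling
choice, not a published quantity, and is an explicit function argument.

Not emulated: read-mapping bias (haplotype-resolved counts are taken as the
post-processing contract of an alignment-bias-aware upstream), tumor purity
and copy-number variation, multi-allelic MNLPs, imputation/phasing against
external reference panels, and multi-ancestry GWAS structure. Passing tests
therefore demonstrate correctness of the statistics under these idealized
conditions, not robustness to mapping artifacts or CNV confounding in real
tumor data.

## Numerical choices and test scales

* Likelihood maximizations over proportions use bounded golden-section
  search on [1e-6, 1 - 1e-6] plus explicit evaluation of the endpoints and
  the pooled moment estimate, which repairs the optimizer's boundary
  stalling (the binomial-LRT reduction then holds to ~1e-4 over all counts
  with N <= 50).
* EM ties between phasings (exactly equal likelihood) split the double
  heterozygotes 50/50, which is the coupling-favoring fixed point of the
  iteration; degenerate (monomorphic) loci are rejected with an error.
* Exact enumeration for the combined test is attempted when total N < 20
  and the configuration space has at most 20,000 states.
* The test suite runs at deliberately modest scales — 2,000 null units for
  type-I error, 100 seeded repetitions for detection/ranking rates, 300
  samples for genotyper concordance, panels of 300–500 samples and ~100
  SNPs — chosen so the full suite completes in a few minutes while keeping
  Monte-Carlo error well inside the asserted bounds.

## Known limitations

Coverage-based genotyping assumes depth proportional to allele dosage, which
CNVs and capture bias violate; the read classifier assumes reads are
anchored at the amplicon start; the differential imbalance test is
asymptotic at low depth; colocalization inherits the single-causal-variant
assumption; and the founder-copying LD model, while fast and controllable,
does not reproduce coalescent allele-frequency/LD joint structure.
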