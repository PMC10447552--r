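# mnlpkit

Establishing a **multi-nucleotide length polymorphism (MNLP)** as a candidate
causal GWAS variant. GWAS loci are usually fine-mapped down to SNPs, but some
risk loci are driven by longer "complex variants" — biallelic polymorphisms
whose alleles differ in length (here a 21-bp short "S" and a 47-bp long "L"
allele embedded between shared flanks) and that standard SNP pipelines
mis-genotype or miss entirely. `mnlpkit` implements the computational arm of
such a dissection, for statistical geneticists and regulatory genomicists
working on prostate-cancer-style eQTL loci:

* **Genotyping** — classify deep-amplicon reads against S/L allele-specific
  references by semi-global alignment (match +1, mismatch −1, gap −2) and
  call genotypes from the L-read fraction; or call genotypes from sequencing
  coverage patterns, where the relative depth `d` of the allele-specific
  segment estimates allele dosage/2 (`d ≤ 0.25` → S/S, `0.25 < d < 0.75` →
  S/L, `d ≥ 0.75` → L/L). Knock-in clones are verified from the `tccg` /
  `gcgtc` border sequences flanking the integrated allele.
* **Two-locus dissection** — EM haplotype-frequency estimation for the index
  SNP × MNLP pair, LD statistics `D`, `D′ = |D|/D_max`,
  `r² = D²/(p_T p_C p_S p_L)`, the 3×3 genotype grid, classification of
  recombinant individuals (genotypes not composable from coupling
  haplotypes T–S / C–L), and Pearson genotype–expression association with
  partial correlations separating the two linked variants.
* **Allelic imbalance (chromQTL)** — a haplotype beta-binomial test with
  per-individual overdispersion ρ (variance `n p (1−p) (1 + (n−1) ρ)`),
  peak-level count merging, 100-kb variant-to-peak assignment, combined
  (normal / tumor / both) and differential likelihood-ratio tests, and
  Benjamini–Hochberg peak flagging at 10% FDR.
* **Complex-variant discovery and TWAS-style association** — coverage-dip
  screening of cohort depth matrices against lead-SNP dosage; ridge
  prediction of CV dosage from cis SNPs with cross-validation;
  summary-statistic association `z_cv = wᵀz / √(wᵀRw)`; LD-based
  conditioning `z_cond = (z − r z_cv)/√(1−r²)`; and approximate-Bayes-factor
  colocalization (PP0–PP4).
* **Synthetic data** — seeded generators for every input (amplicon FASTQ,
  depth profiles, phased two-locus cohorts, haplotype-resolved count tables,
  cis SNP panels with GWAS Z-scores), so the full pipeline runs and is
  tested without any external data.

## Worked example

```r
library(mnlpkit)
model  <- population_model()                       # study-like defaults
cohort <- gen_two_locus_cohort(model, n = 121, seed = 42)
em     <- em_haplotype_freqs(cohort)
ld_stats(em)
#> LD: D = 0.2052, D' = 0.8858, r2 = 0.6760 (p_T = 0.471, p_S = 0.508)

classify_recombinant("T/T", "S/L")$min_recombinant_haplotypes
#> [1] 1        # a T/T carrier of one L allele needs one recombinant haplotype

tab <- gen_ase_counts(model, n_individuals = 10, peaks = synth_peaks(5, 1), seed = 42)
run_ase_analysis(tab)
#> Allelic-imbalance analysis: 20 tests across 5 peaks (FDR 0.10)
#>   imbalanced peaks:
#>     peak_01 [both]
#>     peak_01 [normal]
#>     peak_01 [tumor]

panel <- gen_cv_panel(model, 500, seed = 42)
cv_twas(panel, seed = 42)
#> CV genetic predictor (ridge): training r2 = 0.950, CV r2 = 0.929 (p = 9.95e-289)
#> TWAS-style CV association: z = 9.281 (p = 1.68e-20)
#>   top GWAS SNP snp_050: z = 6.923; equivalence p = 0.00803
#>   PP4 (shared causal variant) = 1.000
```

Reading the numbers: the EM recovers tight coupling of the T risk allele
with the short allele (D′ ≈ 0.89, r² ≈ 0.68 at n = 121); the single planted
imbalanced peak — whose long-allele haplotype carries ~90% of the chromatin
reads — is the only peak flagged at 10% FDR; and the genetically predicted
complex-variant dosage associates with the simulated disease at genome-wide
significance (p < 5 × 10⁻⁸) with full colocalization support.

A complete simulate → genotype → LD → imbalance → TWAS run with per-file
checksums is one call:

```r
run_pipeline(list(seed = 5), out_dir = "out")
```

or, from a shell, `Rscript inst/scripts/mnlp-pipeline.R --out out --seed 5`.

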