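# Top-level orchestration: simulate -> genotype -> LD/recombinants -> ASE ->
# CV-TWAS, with a reproducibility manifest.

default_run_config <- function() {
  list(
    seed = 1L,
    out_dir = NULL,
    stages = c("simulate", "genotype", "ld", "ase", "cvtwas"),
    model = list(),                # population_model() overrides
    n_cohort = 121L,
    n_ase_individuals = 20L,
    ase_peaks = 5L,
    ase_imbalanced = 1L,
    sites_per_peak = 3L,
    n_panel = 500L,
    amplicon = list(n_reads = 2000L, error_rate = 0.001),
    depth = list(mean_depth = 60, noise_cv = 0.1),
    genotyping = list(min_reads = 50, het_band = c(0.2, 0.8),
                      hom_absent_max = 0.25, hom_present_min = 0.75),
    fdr = 0.10,
    folds = 5L
  )
}

#' Validate and complete a pipeline run configuration
#'
#' Unknown keys are rejected; missing keys take their documented defaults.
#' A configuration can also be loaded from a JSON file.
#'
#' @param config named list of overrides, or a path to a JSON file.
#' @return A complete configuration list of class `run_config`.
#' @export
run_config <- function(config = list()) {
  if (is.character(config) && length(config) == 1L)
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  def <- default_run_config()
  unknown <- setdiff(names(config), names(def))
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  for (k in names(config)) {
    def[[k]] <- if (is.list(def[[k]]) && is.list(config[[k]]))
      utils::modifyList(def[[k]], config[[k]]) else config[[k]]
  }
  structure(def, class = "run_config")
}

#' Run the synthetic-data analysis pipeline end to end
#'
#' Generates a seeded synthetic data set (two-locus cohort, amplicon reads,
#' depth profiles, allele-specific counts, complex-variant panel), genotypes
#' the MNLP by reads and by coverage, estimates haplotype frequencies and LD,
#' classifies recombinants and compares eQTL strength, runs the four-category
#' allelic-imbalance analysis, and performs the CV-TWAS association with
#' conditioning and colocalization. Every stage output is written under
#' `out_dir` and checksummed into a manifest.
#'
#' @param config a [run_config()] (or list/JSON path accepted by it).
#' @param out_dir output directory (created if needed); overrides
#'   `config$out_dir`.
#' @return List of class `run_manifest`: `version`, `config_hash`, `files`
#'   (named md5 checksums), `stages` run and a `summary` list of headline
#'   numbers.
#' @export
run_pipeline <- function(config = list(), out_dir = NULL) {
  cfg <- if (inherits(config, "run_config")) config else run_config(config)
  out_dir <- out_dir %||% cfg$out_dir
  if (is.null(out_dir)) stop("no output directory given (config$out_dir or out_dir)")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  model <- do.call(population_model, cfg$model)
  spec <- mnlp_allele_spec()
  refs <- build_allele_references(spec)
  seed <- as.integer(cfg$seed)
  summary <- list()
  files <- character()
  keep <- function(name) files <<- c(files, file.path(out_dir, name))

  if ("simulate" %in% cfg$stages) {
    cohort <- gen_two_locus_cohort(model, cfg$n_cohort, seed)
    write_tsv(cohort, file.path(out_dir, "cohort.tsv")); keep("cohort.tsv")
    peaks <- synth_peaks(cfg$ase_peaks, cfg$ase_imbalanced)
    write_bed(peaks, file.path(out_dir, "peaks.bed")); keep("peaks.bed")
    ase <- gen_ase_counts(model, cfg$n_ase_individuals, peaks,
                          cfg$sites_per_peak, seed = seed + 1L)
    write_tsv(ase, file.path(out_dir, "ase_counts.tsv")); keep("ase_counts.tsv")
    panel <- gen_cv_panel(model, cfg$n_panel, seed = seed + 2L)
    write_tsv(data.frame(snp = panel$snp_id, pos = panel$pos,
                         z = panel$gwas_z, n = panel$gwas_n),
              file.path(out_dir, "gwas_z.tsv")); keep("gwas_z.tsv")
    reads <- gen_amplicon_reads(spec, "S/L", cfg$amplicon$n_reads,
                                cfg$amplicon$error_rate, seed = seed + 3L)
    write_fastq(reads, file.path(out_dir, "amplicon.fastq")); keep("amplicon.fastq")
    truth_gt <- c("S/S", "S/L", "L/L")[
      pmin(3L, cohort$mnlp_dosage[seq_len(min(12L, nrow(cohort)))] + 1L)]
    depths <- gen_depth_profiles(spec, truth_gt, cfg$depth$mean_depth,
                                 cfg$depth$noise_cv, seed = seed + 4L)
    write_tsv(as.data.frame(depths$l_depth),
              file.path(out_dir, "l_depth.tsv")); keep("l_depth.tsv")
  } else stop("the 'simulate' stage is required: it feeds every other stage")

  if ("genotype" %in% cfg$stages) {
    cls <- classify_amplicon_reads(reads, refs)
    call_reads <- call_genotype_from_reads(cls, cfg$genotyping$min_reads,
                                           cfg$genotyping$het_band)
    calls_cov <- call_genotypes_from_coverage(
      depths, refs, hom_absent_max = cfg$genotyping$hom_absent_max,
      hom_present_min = cfg$genotyping$hom_present_min)
    write_tsv(calls_cov, file.path(out_dir, "coverage_calls.tsv"))
    keep("coverage_calls.tsv")
    write_vcf(rbind(data.frame(sample_id = "amplicon_sample",
                               genotype = call_reads$genotype),
                    data.frame(sample_id = calls_cov$sample_id,
                               genotype = calls_cov$genotype)),
              spec, file.path(out_dir, "genotypes.vcf"))
    keep("genotypes.vcf")
    summary$amplicon_genotype <- call_reads$genotype
    summary$coverage_concordance <- mean(calls_cov$genotype == truth_gt)
  }

  if ("ld" %in% cfg$stages) {
    em <- em_haplotype_freqs(cohort)
    ld <- ld_stats(em)
    rec <- vapply(seq_len(nrow(cohort)), function(i) {
      snp_gt <- c("C/C", "T/C", "T/T")[cohort$snp_dosage[i] + 1L]
      mnlp_gt <- c("S/S", "S/L", "L/L")[cohort$mnlp_dosage[i] + 1L]
      classify_recombinant(snp_gt, mnlp_gt)$is_recombinant
    }, logical(1))
    assoc <- genotype_trait_association(cohort$trait, cohort$mnlp_dosage)
    cmp <- compare_eqtl_variants(cohort$trait, cohort$snp_dosage,
                                 cohort$mnlp_dosage)
    jsonlite::write_json(
      list(hap_freqs = as.list(round(em$freqs, 6)),
           D = ld$D, D_prime = ld$D_prime, r2 = ld$r2,
           n_recombinant = sum(rec),
           mnlp_trait_r = assoc$r, mnlp_trait_p = assoc$p_value,
           partial_r_mnlp = cmp$partial_r_mnlp,
           partial_r_snp = cmp$partial_r_snp),
      file.path(out_dir, "ld_eqtl.json"), auto_unbox = TRUE, digits = NA)
    keep("ld_eqtl.json")
    summary$D_prime <- ld$D_prime
    summary$r2 <- ld$r2
    summary$n_recombinant <- sum(rec)
  }

  if ("ase" %in% cfg$stages) {
    ana <- run_ase_analysis(ase, q = cfg$fdr)
    write_tsv(ana$results, file.path(out_dir, "ase_results.tsv"))
    keep("ase_results.tsv")
    write_tsv(ana$peak_flags, file.path(out_dir, "ase_flags.tsv"))
    keep("ase_flags.tsv")
    summary$imbalanced_peaks <- unique(
      ana$peak_flags$peak_id[ana$peak_flags$flagged])
  }

  if ("cvtwas" %in% cfg$stages) {
    tw <- cv_twas(panel, folds = cfg$folds, seed = seed + 5L)
    jsonlite::write_json(
      list(cv_r2 = tw$weights$cv_r2, z_cv = tw$twas$z_cv,
           p = tw$twas$p_value, equiv_p = tw$twas$equiv_p,
           pp = as.list(tw$coloc$pp),
           n_neutralized = sum(abs(tw$conditional$z) > 5.45 &
                               abs(tw$conditional$z_cond) < 1.96,
                               na.rm = TRUE)),
      file.path(out_dir, "cvtwas.json"), auto_unbox = TRUE, digits = NA)
    keep("cvtwas.json")
    write_tsv(tw$conditional, file.path(out_dir, "conditional_z.tsv"))
    keep("conditional_z.tsv")
    summary$z_cv <- tw$twas$z_cv
    summary$pp4 <- unname(tw$coloc$pp["PP4"])
  }

  cfg_file <- tempfile(fileext = ".json")
  on.exit(unlink(cfg_file), add = TRUE)
  jsonlite::write_json(unclass(cfg), cfg_file, auto_unbox = TRUE, digits = NA)
  manifest <- structure(list(
    tool = "mnlpkit",
    version = as.character(utils::packageVersion("mnlpkit")),
    config_hash = unname(tools::md5sum(cfg_file)),
    files = tools::md5sum(sort(files)),
    stages = cfg$stages,
    summary = summary), class = "run_manifest")
  jsonlite::write_json(
    list(tool = manifest$tool, version = manifest$version,
         config_hash = manifest$config_hash,
         files = as.list(manifest$files)),
    file.path(out_dir, "manifest.json"), auto_unbox = TRUE)
  manifest
}

#' @export
print.run_manifest <- function(x, ...) {
  cat(sprintf("mnlpkit %s pipeline run (%d outputs, config %s)\n",
              x$version, length(x$files), substr(x$config_hash, 1, 8)))
  for (k in names(x$summary)) {
    v <- x$summary[[k]]
    cat(sprintf("  %s: %s\n", k, paste(format(v, digits = 4), collapse = ", ")))
  }
  invisible(x)
}
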