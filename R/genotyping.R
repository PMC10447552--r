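# MNLP genotyping: read classification against allele-specific references,
# coverage-ratio calls, knock-in verification, coverage-based discovery of
# candidate complex variants.

#' Build S and L allele-specific reference sequences
#'
#' @param spec an [mnlp_allele_spec()].
#' @param min_flank minimum flank length required for read anchoring.
#' @return List of class `allele_references`: `s_ref`, `l_ref` (full flanked
#'   contexts) and 0-based half-open allele intervals `s_interval`,
#'   `l_interval`.
#' @examples
#' refs <- build_allele_references(mnlp_allele_spec())
#' nchar(refs$l_ref) - nchar(refs$s_ref)  # 26 for the default 21/47 alleles
#' @export
build_allele_references <- function(spec, min_flank = 20L) {
  stopifnot(inherits(spec, "mnlp_allele_spec"))
  if (nchar(spec$flank_left) < min_flank || nchar(spec$flank_right) < min_flank)
    stop(sprintf("flanks shorter than the classifier's %d-nt anchor", min_flank))
  fl <- nchar(spec$flank_left)
  structure(list(
    s_ref = paste0(spec$flank_left, spec$seq_s, spec$flank_right),
    l_ref = paste0(spec$flank_left, spec$seq_l, spec$flank_right),
    s_interval = c(fl, fl + nchar(spec$seq_s)),
    l_interval = c(fl, fl + nchar(spec$seq_l)),
    name_s = spec$name_s, name_l = spec$name_l),
    class = "allele_references")
}

# semi-global alignment scores of reads against a reference (match +1,
# mismatch -1, gap -2; read global, reference local; N mismatches
# everything); compiled scorer in src/semiglobal.cpp
semiglobal_scores <- function(seqs, ref) {
  .semiglobal_scores(seqs, ref, 1, -1, -2)
}

#' Classify amplicon reads to the S or L allele
#'
#' Each read is aligned semi-globally (read global, reference local; match
#' +1, mismatch -1, gap -2) against both allele-specific references. A read
#' is assigned to the higher-scoring allele when its score reaches
#' `(1 - 2 * max_mismatch_frac) * read_len` and the score margin over the
#' other allele is at least `min_margin`; reads passing the score bar with a
#' smaller margin are ambiguous (e.g. flank-only reads) and reads failing it
#' (or containing non-ACGTN characters) are unmatched.
#'
#' @param reads a `fastq_reads` data.frame (or any data.frame with a `seq`
#'   column), e.g. from [gen_amplicon_reads()] or [read_fastq()].
#' @param refs an [build_allele_references()] result.
#' @param max_mismatch_frac maximum tolerated mismatch fraction.
#' @param min_margin minimum score margin between the two alleles.
#' @return List of class `read_classification`: counts `n_s`, `n_l`,
#'   `n_ambiguous`, `n_unmatched`, `n_total`, the per-read `assignment`, and
#'   `read_types` (classified-read sequence frequency table, most frequent
#'   first).
#' @export
classify_amplicon_reads <- function(reads, refs, max_mismatch_frac = 0.05,
                                    min_margin = 2) {
  stopifnot(inherits(refs, "allele_references"))
  seqs <- toupper(if (is.data.frame(reads)) reads$seq else as.character(reads))
  n <- length(seqs)
  assignment <- rep(NA_character_, n)
  if (n > 0L) {
    bad <- grepl("[^ACGTN]", seqs)
    if (any(bad))
      warning(sprintf("%d reads contain non-ACGTN characters; counted unmatched", sum(bad)))
    ok <- which(!bad)
    assignment[bad] <- "unmatched"
    if (length(ok) > 0L) {
      sc_s <- semiglobal_scores(seqs[ok], refs$s_ref)
      sc_l <- semiglobal_scores(seqs[ok], refs$l_ref)
      rl <- nchar(seqs[ok])
      thr <- (1 - 2 * max_mismatch_frac) * rl
      best <- pmax(sc_s, sc_l)
      margin <- abs(sc_s - sc_l)
      cls <- ifelse(best < thr, "unmatched",
             ifelse(margin < min_margin, "ambiguous",
             ifelse(sc_s > sc_l, "S", "L")))
      assignment[ok] <- cls
    }
  }
  classified <- assignment %in% c("S", "L")
  rt <- if (any(classified)) sort(table(seqs[classified]), decreasing = TRUE)
        else table(character())
  structure(list(n_s = sum(assignment == "S"),
                 n_l = sum(assignment == "L"),
                 n_ambiguous = sum(assignment == "ambiguous"),
                 n_unmatched = sum(assignment == "unmatched"),
                 n_total = n,
                 assignment = assignment,
                 read_types = rt),
            class = "read_classification")
}

#' @export
print.read_classification <- function(x, ...) {
  cat(sprintf("Read classification: %d reads (S %d, L %d, ambiguous %d, unmatched %d)\n",
              x$n_total, x$n_s, x$n_l, x$n_ambiguous, x$n_unmatched))
  invisible(x)
}

new_genotype_call <- function(genotype, l_fraction, evidence, qc_status,
                              qc_reason = NA_character_) {
  structure(list(genotype = genotype, l_fraction = l_fraction,
                 evidence = evidence, qc_status = qc_status,
                 qc_reason = qc_reason),
            class = "genotype_call")
}

#' @export
print.genotype_call <- function(x, ...) {
  cat(sprintf("MNLP genotype: %s (L fraction %s, qc %s%s)\n", x$genotype,
              if (is.na(x$l_fraction)) "NA" else sprintf("%.3f", x$l_fraction),
              x$qc_status,
              if (is.na(x$qc_reason)) "" else paste0(": ", x$qc_reason)))
  invisible(x)
}

#' Call an MNLP genotype from classified amplicon reads
#'
#' The L-allele read fraction `n_l / (n_l + n_s)` is compared against a
#' heterozygote band: above its upper edge the call is L/L, below the lower
#' edge S/S, inside the band S/L. Fewer than `min_reads` classified reads
#' yield a no-call rather than a guess.
#'
#' @param cls a [classify_amplicon_reads()] result.
#' @param min_reads minimum classified reads for a call.
#' @param het_band lower/upper L-fraction bounds of the heterozygote band.
#' @return A `genotype_call`.
#' @export
call_genotype_from_reads <- function(cls, min_reads = 50, het_band = c(0.2, 0.8)) {
  stopifnot(inherits(cls, "read_classification"))
  nc <- cls$n_s + cls$n_l
  ev <- list(n_s = cls$n_s, n_l = cls$n_l, n_classified = nc)
  if (nc == 0L)
    return(new_genotype_call("no-call", NA_real_, ev, "fail", "insufficient reads"))
  lf <- cls$n_l / nc
  if (nc < min_reads)
    return(new_genotype_call("no-call", lf, ev, "fail", "insufficient reads"))
  gt <- if (lf > het_band[2]) "L/L" else if (lf < het_band[1]) "S/S" else "S/L"
  new_genotype_call(gt, lf, ev, "pass")
}

#' Estimate the population L-allele frequency from pooled amplicon reads
#'
#' @param cls a [classify_amplicon_reads()] result from a pooled-DNA run.
#' @param conf confidence level of the Wilson score interval.
#' @return List with `freq_l`, `ci` (Wilson interval), `n_classified`.
#' @export
estimate_pool_allele_freq <- function(cls, conf = 0.95) {
  stopifnot(inherits(cls, "read_classification"))
  nc <- cls$n_s + cls$n_l
  if (nc < 1L) stop("no classified reads; cannot estimate allele frequency")
  ci <- as.numeric(stats::prop.test(cls$n_l, nc, conf.level = conf,
                                    correct = FALSE)$conf.int)
  list(freq_l = cls$n_l / nc, ci = ci, n_classified = nc)
}

#' Call an MNLP genotype from a coverage profile
#'
#' The relative depth `d` of the allele-specific segment (mean depth over the
#' L-specific interval of the L reference divided by mean flank depth)
#' estimates L dosage / 2: `d >= hom_present_min` calls L/L,
#' `d <= hom_absent_max` calls S/S, in between S/L. The symmetric S-side
#' ratio is reported as supporting evidence when an S-reference profile is
#' supplied. Flank depth below `min_depth` yields a no-call.
#'
#' @param profile either a numeric per-base depth vector over the L
#'   reference, or a list with `l_depth` (and optionally `s_depth`).
#' @param refs an [build_allele_references()] result.
#' @param hom_absent_max,hom_present_min relative-depth thresholds.
#' @param min_depth minimum mean flank depth for a call.
#' @return A `genotype_call` with depth-ratio evidence.
#' @export
call_genotype_from_coverage <- function(profile, refs, hom_absent_max = 0.25,
                                        hom_present_min = 0.75, min_depth = 10) {
  stopifnot(inherits(refs, "allele_references"))
  l_depth <- if (is.list(profile)) profile$l_depth else profile
  iv <- refs$l_interval
  if (iv[2] <= iv[1]) stop("empty allele interval")
  if (length(l_depth) < iv[2]) stop("depth profile shorter than the L reference")
  allele_idx <- (iv[1] + 1L):iv[2]
  flank_idx <- setdiff(seq_along(l_depth), allele_idx)
  flank_depth <- mean(l_depth[flank_idx])
  ev <- list(flank_depth = flank_depth)
  if (!is.finite(flank_depth) || flank_depth <= 0)
    stop("flank depth must be positive")
  d <- mean(l_depth[allele_idx]) / flank_depth
  ev$rel_depth_l <- d
  if (is.list(profile) && !is.null(profile$s_depth)) {
    sv <- refs$s_interval
    s_allele <- (sv[1] + 1L):sv[2]
    s_flank <- setdiff(seq_along(profile$s_depth), s_allele)
    ev$rel_depth_s <- mean(profile$s_depth[s_allele]) / mean(profile$s_depth[s_flank])
  }
  if (flank_depth < min_depth)
    return(new_genotype_call("no-call", NA_real_, ev, "fail", "flank depth below minimum"))
  gt <- if (d >= hom_present_min) "L/L" else if (d <= hom_absent_max) "S/S" else "S/L"
  new_genotype_call(gt, d, ev, "pass")
}

#' Call MNLP genotypes for every sample of a depth-profile set
#'
#' @param profiles a `depth_profiles` object from [gen_depth_profiles()] or
#'   assembled from TSV depth matrices.
#' @param refs an [build_allele_references()] result.
#' @param ... passed to [call_genotype_from_coverage()].
#' @return data.frame with `sample_id`, `genotype`, `rel_depth_l`,
#'   `qc_status`.
#' @export
call_genotypes_from_coverage <- function(profiles, refs, ...) {
  stopifnot(inherits(profiles, "depth_profiles"))
  calls <- lapply(seq_len(nrow(profiles$l_depth)), function(i) {
    call_genotype_from_coverage(
      list(l_depth = profiles$l_depth[i, ], s_depth = profiles$s_depth[i, ]),
      refs, ...)
  })
  data.frame(sample_id = rownames(profiles$l_depth),
             genotype = vapply(calls, `[[`, "", "genotype"),
             rel_depth_l = vapply(calls, function(x)
               x$evidence$rel_depth_l %||% NA_real_, numeric(1)),
             qc_status = vapply(calls, `[[`, "", "qc_status"),
             stringsAsFactors = FALSE)
}

#' Verify a long-allele knock-in clone from amplicon reads
#'
#' Checks that the short border sequences flanking the integrated L allele
#' are intact and that no recurrent non-reference base segregates in the
#' clone's reads. Reads are first classified; L-assigned reads anchored at
#' the amplicon start are compared position-by-position to the L reference.
#' The clone passes when the read consensus over the border + allele region
#' is exactly the reference and no position carries a non-reference base in
#' more than `recurrent_frac` of reads (sporadic sequencing errors are
#' tolerated); the per-read intact-border fraction is reported as evidence.
#'
#' @param reads amplicon reads (data.frame with `seq`).
#' @param refs an [build_allele_references()] result.
#' @param border_left,border_right border sequences immediately flanking the
#'   allele (must match the reference at those positions).
#' @param recurrent_frac recurrence threshold for a non-reference base.
#' @return List of class `knockin_report`: `pass`, `border_fraction`,
#'   `n_l_reads`, `recurrent_variants` (data.frame), `reason`.
#' @export
verify_knockin <- function(reads, refs, border_left = "tccg",
                           border_right = "gcgtc", recurrent_frac = 0.05) {
  stopifnot(inherits(refs, "allele_references"))
  bl <- toupper(border_left); br <- toupper(border_right)
  iv <- refs$l_interval
  ref_bl <- substr(refs$l_ref, iv[1] - nchar(bl) + 1L, iv[1])
  ref_br <- substr(refs$l_ref, iv[2] + 1L, iv[2] + nchar(br))
  if (!identical(ref_bl, bl) || !identical(ref_br, br))
    stop("border sequences are not adjacent to the allele interval in the L reference")
  cls <- classify_amplicon_reads(reads, refs)
  seqs <- toupper(if (is.data.frame(reads)) reads$seq else as.character(reads))
  lseqs <- seqs[!is.na(cls$assignment) & cls$assignment == "L"]
  fail <- function(reason) structure(
    list(pass = FALSE, border_fraction = NA_real_, n_l_reads = length(lseqs),
         recurrent_variants = data.frame(), reason = reason),
    class = "knockin_report")
  if (length(lseqs) == 0L) return(fail("no L-classified reads"))
  span <- iv[2] + nchar(br)
  covered <- lseqs[nchar(lseqs) >= span]
  if (length(covered) == 0L) return(fail("no reads span the allele and borders"))
  # per-read intact borders (evidence; sensitive to sequencing error)
  bl_obs <- substr(covered, iv[1] - nchar(bl) + 1L, iv[1])
  br_obs <- substr(covered, iv[2] + 1L, iv[2] + nchar(br))
  border_fraction <- mean(bl_obs == bl & br_obs == br)
  # positionwise consensus and recurrent non-reference bases over the
  # border + allele region
  region <- (iv[1] - nchar(bl) + 1L):(iv[2] + nchar(br))
  ref_ch <- strsplit(refs$l_ref, "")[[1]]
  chmat <- do.call(rbind, strsplit(substr(covered, 1L, span), ""))
  consensus_ok <- TRUE
  rec <- list()
  for (j in region) {
    tab <- table(chmat[, j])
    cons <- names(tab)[which.max(tab)]
    if (cons != ref_ch[j]) consensus_ok <- FALSE
    nonref <- tab[names(tab) != ref_ch[j]]
    hit <- nonref[nonref / nrow(chmat) > recurrent_frac]
    if (length(hit) > 0L)
      rec[[length(rec) + 1L]] <- data.frame(
        position = j, base = names(hit),
        fraction = as.numeric(hit) / nrow(chmat))
  }
  rec_df <- if (length(rec)) do.call(rbind, rec) else data.frame()
  pass <- consensus_ok && nrow(rec_df) == 0L
  structure(list(pass = pass, border_fraction = border_fraction,
                 n_l_reads = length(covered), recurrent_variants = rec_df,
                 reason = if (pass) NA_character_
                          else if (!consensus_ok) "consensus deviates from reference in border/allele region"
                          else "recurrent non-reference base detected"),
            class = "knockin_report")
}

#' @export
print.knockin_report <- function(x, ...) {
  cat(sprintf("Knock-in verification: %s (border fraction %s over %d L reads)\n",
              if (isTRUE(x$pass)) "PASS" else paste0("FAIL - ", x$reason),
              if (is.na(x$border_fraction)) "NA" else sprintf("%.3f", x$border_fraction),
              x$n_l_reads))
  invisible(x)
}

#' Discover candidate complex variants from a cohort depth matrix
#'
#' Emulates the coverage-based screen of tumor-cohort alignments: per locus
#' window, each sample's relative depth is snapped to the nearest biallelic
#' dosage class in {0, 0.5, 1}; windows occupied by at least two classes
#' whose class values correlate with the lead GWAS SNP dosage at
#' `r^2 >= min_r2` become candidates, adjacent candidate windows are merged,
#' and merged candidates are ranked by their best window r^2.
#'
#' @param depth_matrix samples x windows matrix of relative depth
#'   (copy-number scale: ~1 means both alleles present).
#' @param lead_snp_dosage per-sample dosage of the lead GWAS SNP (0/1/2).
#' @param window_bp window width used to lay out candidate coordinates when
#'   `windows` is not given.
#' @param min_r2 minimum squared Pearson correlation with the lead SNP.
#' @param windows optional data.frame (`contig`, `start`, `end`), one row per
#'   depth-matrix column, 0-based half-open.
#' @return data.frame of merged candidates (`contig`, `start`, `end`,
#'   `n_windows`, `r2`, `rank`), best first; attribute `classes` holds the
#'   samples x windows class matrix.
#' @export
discover_complex_variants <- function(depth_matrix, lead_snp_dosage,
                                      window_bp = 500, min_r2 = 0.5,
                                      windows = NULL) {
  depth_matrix <- as.matrix(depth_matrix)
  if (nrow(depth_matrix) < 10L) stop("need >= 10 samples for coverage-based discovery")
  if (length(lead_snp_dosage) != nrow(depth_matrix))
    stop("'lead_snp_dosage' length must equal the sample count")
  if (stats::var(lead_snp_dosage) == 0) stop("monomorphic lead SNP")
  if (is.null(windows)) {
    windows <- data.frame(contig = "locus",
                          start = (seq_len(ncol(depth_matrix)) - 1L) * window_bp,
                          end = seq_len(ncol(depth_matrix)) * window_bp)
  }
  if (nrow(windows) != ncol(depth_matrix))
    stop("'windows' must have one row per depth-matrix column")
  cls_levels <- c(0, 0.5, 1)
  classes <- apply(depth_matrix, c(1, 2), function(d)
    cls_levels[which.min(abs(cls_levels - d))])
  r2 <- vapply(seq_len(ncol(classes)), function(j) {
    cl <- classes[, j]
    if (length(unique(cl)) < 2L) return(NA_real_)
    stats::cor(cl, lead_snp_dosage)^2
  }, numeric(1))
  cand <- which(!is.na(r2) & r2 >= min_r2)
  if (length(cand) == 0L) {
    out <- data.frame(contig = character(), start = integer(), end = integer(),
                      n_windows = integer(), r2 = numeric(), rank = integer())
    attr(out, "classes") <- classes
    return(out)
  }
  grp <- cumsum(c(1L, diff(cand) > 1L))
  merged <- do.call(rbind, lapply(split(cand, grp), function(idx) {
    data.frame(contig = windows$contig[idx[1]],
               start = windows$start[idx[1]],
               end = windows$end[idx[length(idx)]],
               n_windows = length(idx),
               r2 = max(r2[idx]))
  }))
  merged <- merged[order(-merged$r2), , drop = FALSE]
  merged$rank <- seq_len(nrow(merged))
  rownames(merged) <- NULL
  attr(merged, "classes") <- classes
  merged
}
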