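#' Describe the two alleles of a multi-nucleotide length polymorphism
#'
#' An MNLP is a biallelic polymorphism whose alleles differ in length (here a
#' short "S" allele and a long "L" allele) embedded between shared flanking
#' sequences. The spec object is the single source from which allele-specific
#' reference sequences, simulated amplicons and coverage profiles are built.
#'
#' The default sequences are synthetic placeholders with the canonical
#' lengths (21 bp short, 47 bp long); only the lengths, flanks and the border
#' bases adjacent to the allele drive downstream computation, so any real
#' locus can be substituted via the arguments or [read_allele_spec_fasta()].
#'
#' @param seq_s,seq_l DNA strings for the short and long allele. Must differ
#'   in length.
#' @param flank_left,flank_right shared flanking DNA (>= 30 nt each),
#'   identical across the two alleles.
#' @param name_s,name_l allele labels.
#' @return An object of class `mnlp_allele_spec`.
#' @examples
#' spec <- mnlp_allele_spec()
#' nchar(spec$seq_l) - nchar(spec$seq_s)  # 26
#' @export
mnlp_allele_spec <- function(seq_s = default_mnlp_sequences()$seq_s,
                             seq_l = default_mnlp_sequences()$seq_l,
                             flank_left = default_mnlp_sequences()$flank_left,
                             flank_right = default_mnlp_sequences()$flank_right,
                             name_s = "S", name_l = "L") {
  for (nm in c("seq_s", "seq_l", "flank_left", "flank_right")) {
    v <- get(nm)
    if (!is_dna(v)) stop(sprintf("'%s' must be a non-empty A/C/G/T string", nm))
  }
  seq_s <- toupper(seq_s); seq_l <- toupper(seq_l)
  flank_left <- toupper(flank_left); flank_right <- toupper(flank_right)
  if (nchar(seq_s) == nchar(seq_l))
    stop("alleles must differ in length (length polymorphism)")
  if (nchar(flank_left) < 30L || nchar(flank_right) < 30L)
    stop("flanks must be at least 30 nt")
  s_ctx <- paste0(flank_left, seq_s, flank_right)
  l_ctx <- paste0(flank_left, seq_l, flank_right)
  if (grepl(s_ctx, l_ctx, fixed = TRUE) || grepl(l_ctx, s_ctx, fixed = TRUE))
    stop("alleles are not distinguishable: one flanked context contains the other")
  structure(list(name_s = name_s, seq_s = seq_s,
                 name_l = name_l, seq_l = seq_l,
                 flank_left = flank_left, flank_right = flank_right),
            class = "mnlp_allele_spec")
}

#' Default placeholder sequences for the MNLP alleles
#'
#' 21-bp short and 47-bp long allele plus 39-nt shared flanks. The left flank
#' ends in `tccg` and the right flank starts with `gcgtc`, the border bases
#' checked by [verify_knockin()].
#' @return Named list with `seq_s`, `seq_l`, `flank_left`, `flank_right`.
#' @export
default_mnlp_sequences <- function() {
  list(
    seq_s       = "TGACCCTGAAGTTCATCTGCA",
    seq_l       = "CATGGTCCTGCTGGAGTTCGTGACCGCCGCCGGGATCACTCTCGGCA",
    flank_left  = "AGCTGACCTGAAGTTCATCTGCACCACCGGCAAGTTCCG",
    flank_right = "GCGTCAGGAGCGCACCATCTTCTTCAAGGACGACGGCAA"
  )
}

#' @export
print.mnlp_allele_spec <- function(x, ...) {
  cat("MNLP allele spec\n")
  cat(sprintf("  %s allele: %d bp   %s allele: %d bp\n",
              x$name_s, nchar(x$seq_s), x$name_l, nchar(x$seq_l)))
  cat(sprintf("  flanks: %d / %d nt\n", nchar(x$flank_left), nchar(x$flank_right)))
  invisible(x)
}

#' Load an allele spec from a two-record FASTA file
#'
#' The FASTA must hold exactly two records, the full S and L amplicon
#' contexts sharing identical flanks; the shared prefix/suffix are taken as
#' flanks and the differing middle as the alleles.
#'
#' @param path FASTA file with two records named for the alleles (first =
#'   short context, second = long context, by sequence length).
#' @return An `mnlp_allele_spec`.
#' @export
read_allele_spec_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  if (length(seqs) != 2L) stop("expected exactly two FASTA records (S and L contexts)")
  s <- as.character(seqs[[which.min(lengths(seqs))]])
  l <- as.character(seqs[[which.max(lengths(seqs))]])
  nms <- names(seqs)[order(lengths(seqs))]
  # longest common prefix / suffix define the flanks
  pre <- 0L
  while (pre < nchar(s) && substr(s, pre + 1L, pre + 1L) == substr(l, pre + 1L, pre + 1L))
    pre <- pre + 1L
  suf <- 0L
  while (suf < nchar(s) - pre &&
         substr(s, nchar(s) - suf, nchar(s) - suf) == substr(l, nchar(l) - suf, nchar(l) - suf))
    suf <- suf + 1L
  mnlp_allele_spec(
    seq_s = substr(s, pre + 1L, nchar(s) - suf),
    seq_l = substr(l, pre + 1L, nchar(l) - suf),
    flank_left = substr(s, 1L, pre),
    flank_right = substr(s, nchar(s) - suf + 1L, nchar(s)),
    name_s = nms[1L], name_l = nms[2L]
  )
}
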