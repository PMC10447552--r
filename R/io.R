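# Standard-format readers and writers. Internal coordinates are 0-based
# half-open; conversion to 1-based happens only in the VCF writer and the
# BED reader.

#' Read a FASTQ file
#'
#' @param path FASTQ file (4-line records, uncompressed).
#' @return data.frame of class `fastq_reads` with `id`, `seq`, `qual`.
#' @export
read_fastq <- function(path) {
  lines <- readLines(path)
  n <- length(lines)
  if (n %% 4L != 0L)
    stop(sprintf("malformed FASTQ: truncated record starting at line %d",
                 (n %/% 4L) * 4L + 1L))
  if (n == 0L)
    return(structure(data.frame(id = character(), seq = character(),
                                qual = character(), stringsAsFactors = FALSE),
                     class = c("fastq_reads", "data.frame")))
  idx <- seq(1L, n, by = 4L)
  hdr <- lines[idx]
  plus <- lines[idx + 2L]
  bad <- which(!startsWith(hdr, "@"))
  if (length(bad))
    stop(sprintf("malformed FASTQ: header does not start with '@' at line %d",
                 idx[bad[1]]))
  bad <- which(!startsWith(plus, "+"))
  if (length(bad))
    stop(sprintf("malformed FASTQ: separator does not start with '+' at line %d",
                 idx[bad[1]] + 2L))
  seqs <- lines[idx + 1L]
  quals <- lines[idx + 3L]
  bad <- which(nchar(seqs) != nchar(quals))
  if (length(bad))
    stop(sprintf("malformed FASTQ: sequence/quality length mismatch at line %d",
                 idx[bad[1]] + 3L))
  structure(data.frame(id = sub("^@", "", hdr), seq = seqs, qual = quals,
                       stringsAsFactors = FALSE),
            class = c("fastq_reads", "data.frame"))
}

#' Write reads to a FASTQ file
#'
#' @param reads data.frame with `id`, `seq`, `qual`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  if (nrow(reads) == 0L) { writeLines(character(), path); return(invisible(path)) }
  out <- as.vector(rbind(paste0("@", reads$id), reads$seq, "+", reads$qual))
  writeLines(out, path)
  invisible(path)
}

#' Write the allele-specific references to FASTA
#'
#' @param refs an [build_allele_references()] result.
#' @param path output FASTA path.
#' @return `path`, invisibly.
#' @export
write_allele_references_fasta <- function(refs, path) {
  stopifnot(inherits(refs, "allele_references"))
  set <- Biostrings::DNAStringSet(c(refs$s_ref, refs$l_ref))
  names(set) <- c(refs$name_s, refs$name_l)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Write MNLP genotype calls as a VCF
#'
#' One VCF 4.2 record with the S allele sequence as REF and the symbolic
#' allele `<L>` as ALT; allele lengths are carried in INFO (`SLEN`, `LLEN`,
#' `SVLEN` = length difference). Genotypes are 0/0 (S/S), 0/1 (S/L), 1/1
#' (L/L) or ./. (no-call).
#'
#' @param calls data.frame with `sample_id` and `genotype` (values `"S/S"`,
#'   `"S/L"`, `"L/L"` or `"no-call"`).
#' @param spec an [mnlp_allele_spec()].
#' @param path output path.
#' @param contig,pos VCF CHROM and 1-based POS of the MNLP.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(calls, spec, path, contig = "chr5", pos = 1887000L) {
  stopifnot(inherits(spec, "mnlp_allele_spec"))
  gt_map <- c("S/S" = "0/0", "S/L" = "0/1", "L/S" = "0/1", "L/L" = "1/1",
              "no-call" = "./.")
  gt <- gt_map[calls$genotype]
  if (anyNA(gt)) stop("unrecognized genotype value in calls")
  svlen <- nchar(spec$seq_l) - nchar(spec$seq_s)
  hdr <- c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s>", contig),
    "##ALT=<ID=L,Description=\"Long MNLP allele (symbolic)\">",
    "##INFO=<ID=SLEN,Number=1,Type=Integer,Description=\"Short allele length\">",
    "##INFO=<ID=LLEN,Number=1,Type=Integer,Description=\"Long allele length\">",
    "##INFO=<ID=SVLEN,Number=1,Type=Integer,Description=\"Length difference L - S\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", calls$sample_id), collapse = "\t"))
  rec <- paste(c(contig, pos, "MNLP", spec$seq_s, "<L>", ".", "PASS",
                 sprintf("SLEN=%d;LLEN=%d;SVLEN=%d", nchar(spec$seq_s),
                         nchar(spec$seq_l), svlen),
                 "GT", unname(gt)), collapse = "\t")
  writeLines(c(hdr, rec), path)
  invisible(path)
}

#' Read a BED peak file
#'
#' @param path BED file (0-based half-open).
#' @return data.frame with `peak_id`, `contig`, `start`, `end` (0-based
#'   half-open) and `center` (floor midpoint).
#' @export
read_bed <- function(path) {
  gr <- as.data.frame(rtracklayer::import(path, format = "BED"))
  start0 <- gr$start - 1L
  end0 <- gr$end
  if (any(end0 <= start0)) stop("BED interval with end <= start")
  nm <- if (!is.null(gr$name) && !all(is.na(gr$name))) gr$name
        else sprintf("peak_%03d", seq_len(nrow(gr)))
  data.frame(peak_id = nm,
             contig = as.character(gr$seqnames),
             start = start0, end = end0,
             center = (start0 + end0) %/% 2L,
             stringsAsFactors = FALSE)
}

#' Write peaks to BED
#'
#' @param peaks data.frame with `contig`, `start`, `end` (0-based
#'   half-open) and optionally `peak_id`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(peaks, path) {
  nm <- peaks$peak_id %||% sprintf("peak_%03d", seq_len(nrow(peaks)))
  writeLines(sprintf("%s\t%d\t%d\t%s", peaks$contig, peaks$start, peaks$end, nm),
             path)
  invisible(path)
}

#' Read a schema-validated TSV table
#'
#' @param path TSV file with a header row.
#' @param schema named character vector mapping required column names to
#'   types (`"character"`, `"integer"`, `"numeric"`, `"logical"`).
#' @return data.frame with the validated columns coerced to their types.
#' @export
read_tsv_table <- function(path, schema = NULL) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (is.null(schema)) return(df)
  miss <- setdiff(names(schema), names(df))
  if (length(miss))
    stop("missing required columns: ", paste(miss, collapse = ", "))
  for (col in names(schema)) {
    v <- df[[col]]
    cast <- switch(schema[[col]],
                   character = as.character,
                   integer = as.integer,
                   numeric = as.numeric,
                   logical = as.logical,
                   stop("unknown schema type: ", schema[[col]]))
    suppressWarnings(cv <- cast(v))
    if (nrow(df) > 0L && anyNA(cv) && !anyNA(v))
      stop(sprintf("column '%s' cannot be read as %s", col, schema[[col]]))
    df[[col]] <- cv
  }
  df
}

#' Write a TSV table
#'
#' @param df data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
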