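#' Read sequences from FASTA
#'
#' @param path FASTA file (multi-record, wrapped lines, case-insensitive).
#' @return named character vector of upper-case sequences; names are the
#'   first whitespace-delimited token of each header.
#' @export
read_fasta <- function(path) {
  as_ref_set(Biostrings::readDNAStringSet(path, format = "fasta"))
}

#' Read sequences (and qualities) from FASTQ
#'
#' @param path FASTQ file.
#' @return list with `seq` (named character vector) and `qual` (named
#'   character vector of Phred strings).
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE)
  qual <- as.character(S4Vectors::mcols(x)$qualities)
  seqs <- as_ref_set(x)
  names(qual) <- names(seqs)
  list(seq = seqs, qual = qual)
}

#' Write alignments as SAM
#'
#' Emits a headered, unsorted SAM file: `@HD`, one `@SQ` per reference, and
#' `@PG`; one line per alignment record, unmapped reads with flag 4.  Every
#' mapped record carries `NM:i` (edit distance), `AS:i` (rescored alignment
#' score) and `ZE:f` (E-value) tags.  By default `=`/`X` CIGAR ops are
#' collapsed to `M`.
#'
#' @param alignments `nm_alignments` from [map_reads()].
#' @param path output file.
#' @param extended_cigar keep `=`/`X` ops (default `FALSE`).
#' @param program command-line string recorded in `@PG`.
#' @return `path`, invisibly.
#' @export
write_sam <- function(alignments, path, extended_cigar = FALSE,
                      program = "nanomapr") {
  stopifnot(inherits(alignments, "nm_alignments"))
  refs <- attr(alignments, "ref_names")
  lens <- attr(alignments, "ref_lens")
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", refs, lens),
           sprintf("@PG\tID:nanomapr\tPN:nanomapr\tCL:%s", program))
  body <- vapply(alignments, function(a) {
    cig <- a$cigar
    if (!identical(cig, "*") && !extended_cigar)
      cig <- collapse_cigar(cig)
    paste(a$qname, a$flag,
          if (is.na(a$ref)) "*" else a$ref,
          a$pos + 1L,  # SAM is 1-based
          a$mapq, cig, "*", 0L, 0L, a$seq, a$qual,
          sep = "\t") |>
      (\(line) if (bitwAnd(a$flag, 4L)) line
               else paste(line,
                          sprintf("NM:i:%d", a$edit),
                          sprintf("AS:i:%d", a$score),
                          sprintf("ZE:f:%.3g", a$evalue),
                          sep = "\t"))()
  }, "")
  writeLines(c(hdr, body), path)
  invisible(path)
}

# collapse =/X runs into M for default SAM output
collapse_cigar <- function(cigar) {
  merge_cigar(gsub("=|X", "M", cigar))
}
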