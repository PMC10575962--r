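#' Read paired FASTQ files into a read-pair tibble
#'
#' Mates are matched by position; the two files must have equal length.
#' Gzipped input is supported.
#'
#' @param r1,r2 Paths to the R1 and R2 FASTQ files.
#' @return Tibble with columns `read_id`, `r1_seq`, `r1_qual`, `r2_seq`,
#'   `r2_qual` (qualities as Phred+33 strings).
#' @export
read_fastq_pairs <- function(r1, r2) {
  f1 <- Biostrings::readDNAStringSet(r1, format = "fastq", with.qualities = TRUE)
  f2 <- Biostrings::readDNAStringSet(r2, format = "fastq", with.qualities = TRUE)
  if (length(f1) != length(f2))
    abort("truncated input: R1 and R2 have different read counts")
  tibble(
    read_id = sub(" .*", "", names(f1)),
    r1_seq = unname(as.character(f1)),
    r1_qual = unname(as.character(S4Vectors::mcols(f1)$qualities)),
    r2_seq = unname(as.character(f2)),
    r2_qual = unname(as.character(S4Vectors::mcols(f2)$qualities))
  )
}

#' Write a read-pair tibble as paired FASTQ
#'
#' @param pairs Read-pair tibble (see [read_fastq_pairs()]).
#' @param r1,r2 Output paths; a `.gz` suffix triggers gzip compression.
#' @return Invisibly, the two paths.
#' @export
write_fastq_pairs <- function(pairs, r1, r2) {
  wr <- function(seqs, quals, ids, path) {
    x <- Biostrings::DNAStringSet(seqs)
    names(x) <- ids
    Biostrings::writeXStringSet(
      x, path, format = "fastq",
      qualities = Biostrings::BStringSet(quals),
      compress = grepl("\\.gz$", path))
  }
  wr(pairs$r1_seq, pairs$r1_qual, pairs$read_id, r1)
  wr(pairs$r2_seq, pairs$r2_qual, pairs$read_id, r2)
  invisible(c(r1, r2))
}
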