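#' Build a base-quality-filtered pileup for one amplicon
#'
#' Aggregates aligned mates into per-position evidence. A base contributes
#' to the counts only when its Phred score is strictly greater than
#' `min_base_phred` (default 30, so Phred >= 31 counts). Deleted positions
#' increment the deletion count (deletions carry no base quality and
#' always count); insertions are recorded between columns, keyed by the
#' inserted sequence, and count when every inserted base passes. Soft
#' clips are ignored.
#'
#' @param alignments Tibble from [align_reads()], all rows on one
#'   amplicon: `start`, `cigar`, `seq`, `qual`.
#' @param amplicon One-row amplicon tibble.
#' @param min_base_phred Strict lower bound on contributing base quality.
#' @return An `amp_pileup`: list with `amplicon_id`, `ref`, `tbl` (tibble
#'   `pos` 0-based, `ref_base`, `A`, `C`, `G`, `T`, `del`, `depth`),
#'   `insertions` and `deletions` event tibbles (0-based `pos`; insertions
#'   sit immediately before `pos`), and `n_reads`.
#' @export
build_pileup <- function(alignments, amplicon, min_base_phred = 30L) {
  ref <- amplicon$reference_seq
  L <- nchar(ref)
  if (nrow(alignments) > 0 &&
      "amplicon_id" %in% names(alignments) &&
      !all(alignments$amplicon_id == amplicon$amplicon_id))
    abort("alignments must all reference the pileup's amplicon")
  if (nrow(alignments) == 0) {
    p <- list(counts = matrix(0L, 5, L),
              insertions = data.frame(pos = integer(0), seq = character(0),
                                      count = integer(0)),
              deletions = data.frame(pos = integer(0), len = integer(0),
                                     count = integer(0)))
  } else {
    p <- cpp_pileup(as.integer(alignments$start), alignments$cigar,
                    alignments$seq, alignments$qual, L,
                    as.integer(min_base_phred), 33L)
  }
  counts <- p$counts
  tbl <- tibble(
    pos = 0:(L - 1L),
    ref_base = strsplit(ref, "")[[1]],
    A = counts[1, ], C = counts[2, ], G = counts[3, ], T = counts[4, ],
    del = counts[5, ])
  tbl$depth <- tbl$A + tbl$C + tbl$G + tbl$T + tbl$del
  structure(list(amplicon_id = amplicon$amplicon_id, ref = ref, tbl = tbl,
                 insertions = as_tibble(p$insertions),
                 deletions = as_tibble(p$deletions),
                 n_reads = nrow(alignments)),
            class = "amp_pileup")
}

#' @export
print.amp_pileup <- function(x, ...) {
  cat("<amp_pileup> ", x$amplicon_id, ": ", nchar(x$ref), " positions, ",
      x$n_reads, " reads, median depth ",
      stats::median(x$tbl$depth), "\n", sep = "")
  invisible(x)
}

# left-normalise a deletion of `len` reference bases starting at 0-based
# `pos`: shift left while the base entering the gap equals the base leaving
normalise_deletion <- function(ref, pos, len) {
  while (pos > 0 &&
         substr(ref, pos, pos) == substr(ref, pos + len, pos + len))
    pos <- pos - 1L
  pos
}

# left-normalise an insertion of `seq` before 0-based `pos` (rotate while
# the preceding reference base equals the last inserted base)
normalise_insertion <- function(ref, pos, seq) {
  len <- nchar(seq)
  while (pos > 0 && substr(ref, pos, pos) == substr(seq, len, len)) {
    seq <- paste0(substr(seq, len, len), substr(seq, 1, len - 1))
    pos <- pos - 1L
  }
  list(pos = pos, seq = seq)
}
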