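#' Trim barcode, primer and low-quality tail from assigned read pairs
#'
#' For each mate, the 8-base inline barcode plus the matched primer are
#' stripped from the 5' end; the 3' end is then truncated by a
#' Trimmomatic-style sliding-window rule (default window 4, mean Phred >=
#' 20): the mate is cut at the first window whose mean falls below the
#' threshold, keeping any immediately following bases that individually
#' pass. Pairs with either mate shorter than `min_length` after trimming
#' are discarded (`kept = FALSE`), not errored.
#'
#' @param pairs Read-pair tibble carrying an `amplicon_id` column (see
#'   [assign_amplicons()]).
#' @param panel A `panel_manifest` (primer lengths per amplicon).
#' @param window,min_mean_q,min_length Sliding-window size, mean-quality
#'   threshold and minimum retained mate length; default to the panel
#'   thresholds (4, 20, 50).
#' @param barcode_len Inline barcode length (8).
#' @return `pairs` with `r1_seq`/`r1_qual`/`r2_seq`/`r2_qual` replaced by
#'   their trimmed versions and a logical `kept` column.
#' @export
trim_pairs <- function(pairs, panel,
                       window = panel$thresholds$trim_window,
                       min_mean_q = panel$thresholds$trim_min_mean_q,
                       min_length = panel$thresholds$trim_min_length,
                       barcode_len = 8L) {
  pairs <- as_tibble(pairs)
  if (!"amplicon_id" %in% names(pairs))
    abort("pairs must carry amplicon_id (run assign_amplicons() first)")
  a <- panel$amplicons
  idx <- match(pairs$amplicon_id, a$amplicon_id)
  fp_len <- nchar(a$fwd_primer)[idx]
  rp_len <- nchar(a$rev_primer)[idx]

  trim_mate <- function(seqs, quals, strip) {
    keep_head <- nchar(seqs) - strip
    short <- is.na(strip) | keep_head < 0
    strip[short] <- 0L
    s <- substr(seqs, strip + 1L, nchar(seqs))
    q <- substr(quals, strip + 1L, nchar(quals))
    keep <- cpp_window_trim(q, as.integer(window), min_mean_q, 33L)
    list(seq = substr(s, 1L, keep), qual = substr(q, 1L, keep),
         short = short)
  }
  m1 <- trim_mate(pairs$r1_seq, pairs$r1_qual, barcode_len + fp_len)
  m2 <- trim_mate(pairs$r2_seq, pairs$r2_qual, barcode_len + rp_len)
  kept <- !m1$short & !m2$short &
    nchar(m1$seq) >= min_length & nchar(m2$seq) >= min_length &
    !is.na(pairs$amplicon_id)
  dplyr::mutate(pairs,
                r1_seq = m1$seq, r1_qual = m1$qual,
                r2_seq = m2$seq, r2_qual = m2$qual,
                kept = kept)
}

#' Trim a single read pair
#'
#' Scalar convenience wrapper around [trim_pairs()]; returns `NULL` when
#' the pair is discarded.
#'
#' @param pair One-row read-pair tibble (or list with `r1_seq`, `r1_qual`,
#'   `r2_seq`, `r2_qual`).
#' @param amplicon One-row amplicon tibble the pair belongs to.
#' @param panel A `panel_manifest`.
#' @inheritParams trim_pairs
#' @return One-row trimmed tibble, or `NULL` if discarded.
#' @export
trim_pair <- function(pair, amplicon, panel,
                      window = panel$thresholds$trim_window,
                      min_mean_q = panel$thresholds$trim_min_mean_q,
                      min_length = panel$thresholds$trim_min_length,
                      barcode_len = 8L) {
  p <- as_tibble(as.list(pair)[c("r1_seq", "r1_qual", "r2_seq", "r2_qual")])
  p$amplicon_id <- amplicon$amplicon_id
  out <- trim_pairs(p, panel, window, min_mean_q, min_length, barcode_len)
  if (!out$kept) NULL else out
}
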