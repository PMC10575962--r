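#' Build a depth-masked consensus sequence from a sample pileup
#'
#' Each position is called as the majority base among quality-passing
#' observations when total passing depth reaches `min_depth` (default
#' 20-fold); ties and under-covered positions are masked `N`. Samples
#' whose uncalled fraction exceeds `max_uncalled` (default 90%) are
#' flagged excluded. Indels are not represented: the consensus stays in
#' reference coordinates (one character per reference position), which is
#' what the downstream Hamming-distance machinery expects.
#'
#' @param pileup An `amp_pileup` for one sample and amplicon.
#' @param min_depth Minimum depth to call a position.
#' @param max_uncalled Maximum tolerated `N` fraction before exclusion.
#' @return Tibble row: `amplicon_id`, `sequence`, `called_fraction`,
#'   `excluded`.
#' @export
build_consensus <- function(pileup, min_depth = 20L, max_uncalled = 0.90) {
  tbl <- pileup$tbl
  counts <- rbind(tbl$A, tbl$C, tbl$G, tbl$T)
  top <- apply(counts, 2, max)
  n_top <- colSums(counts == rep(top, each = 4) & counts > 0)
  base <- BASES[max.col(t(counts), ties.method = "first")]
  called <- tbl$depth >= min_depth & n_top == 1 & top > 0
  seq <- ifelse(called, base, "N")
  frac <- mean(seq != "N")
  tibble(amplicon_id = pileup$amplicon_id,
         sequence = paste(seq, collapse = ""),
         called_fraction = frac,
         excluded = (1 - frac) > max_uncalled)
}
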