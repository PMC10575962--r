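#' Assign read pairs to panel amplicons by primer match
#'
#' The forward primer is sought at the start of R1 (after the 8-base
#' barcode) and the reverse primer at the start of R2. A mate matches an
#' amplicon when the Hamming distance to its primer is at most
#' `primer_max_mismatch` and the minimum over amplicons is unique. Both
#' mates must identify the same amplicon; disagreement is flagged
#' `chimera`, no in-tolerance primer on either mate `unassigned`.
#'
#' @param pairs Read-pair tibble (typically demultiplexed).
#' @param panel A `panel_manifest`.
#' @param primer_max_mismatch Per-primer mismatch tolerance; defaults to
#'   the panel threshold (2).
#' @param barcode_len Length of the inline barcode preceding the primer
#'   (8; use 0 for reads already barcode-stripped).
#' @return `pairs` plus `amplicon_id` (`NA` unless assigned) and
#'   `assign_status` in `assigned`/`unassigned`/`chimera`.
#' @export
assign_amplicons <- function(pairs, panel,
                             primer_max_mismatch = panel$thresholds$primer_max_mismatch,
                             barcode_len = 8L) {
  pairs <- as_tibble(pairs)
  a <- panel$amplicons
  if (nrow(pairs) == 0)
    return(dplyr::mutate(pairs, amplicon_id = character(0),
                         assign_status = character(0)))
  h1 <- cpp_best_hamming(pairs$r1_seq, a$fwd_primer, as.integer(barcode_len))
  h2 <- cpp_best_hamming(pairs$r2_seq, a$rev_primer, as.integer(barcode_len))
  ok1 <- h1$best_dist <= primer_max_mismatch & h1$best_dist < h1$second_dist
  ok2 <- h2$best_dist <= primer_max_mismatch & h2$best_dist < h2$second_dist
  id1 <- ifelse(ok1, a$amplicon_id[h1$best], NA_character_)
  id2 <- ifelse(ok2, a$amplicon_id[h2$best], NA_character_)
  status <- dplyr::case_when(
    !is.na(id1) & !is.na(id2) & id1 == id2 ~ "assigned",
    !is.na(id1) & !is.na(id2) ~ "chimera",
    TRUE ~ "unassigned")
  dplyr::mutate(pairs,
                amplicon_id = ifelse(status == "assigned", id1, NA_character_),
                assign_status = status)
}

#' @rdname assign_amplicons
#' @param pair One-row read pair.
#' @return For `assign_amplicon()`: the amplicon id, `"chimera"` or
#'   `"unassigned"`.
#' @export
assign_amplicon <- function(pair, panel,
                            primer_max_mismatch = panel$thresholds$primer_max_mismatch,
                            barcode_len = 8L) {
  out <- assign_amplicons(as_tibble(as.list(pair)[c("r1_seq", "r2_seq")]),
                          panel, primer_max_mismatch, barcode_len)
  if (out$assign_status == "assigned") out$amplicon_id else out$assign_status
}

# Exact / mismatch-only fast path: when the read differs from the expected
# reference window by a handful of substitutions, the optimal affine-gap
# alignment is that gapless overlay (one substitution costs 5 here, the
# cheapest gap pairing 7+), so the DP can be skipped.
fast_path_align <- function(seq, ref, d0, max_mm = 3L,
                            match = 2L, mismatch = -3L) {
  n <- nchar(seq)
  if (d0 < 0 || d0 + n > nchar(ref)) return(NULL)
  win <- substr(ref, d0 + 1L, d0 + n)
  mm <- which(charToRaw(win) != charToRaw(seq))
  if (length(mm) > max_mm) return(NULL)
  if (length(mm) == 0) {
    cigar <- paste0(n, "=")
  } else {
    ops <- rep("=", n)
    ops[mm] <- "X"
    r <- rle(ops)
    cigar <- paste0(r$lengths, r$values, collapse = "")
  }
  list(score = (n - length(mm)) * match + length(mm) * mismatch,
       start = d0, cigar = cigar, aligned = TRUE)
}

#' Align a trimmed mate to its amplicon reference
#'
#' Banded glocal alignment: global in the read, local in the reference,
#' affine gap scoring (defaults match +2, mismatch -3, gap open -5, gap
#' extend -2; a length-k gap costs open + k*extend). R2 mates are
#' reverse-complemented before alignment. Indels are left-aligned. Reads
#' whose optimal alignment would run past a reference end have the
#' overhang soft-clipped (`S` in the cigar) and those bases are ignored
#' downstream. The band (half-width `band` around the expected diagonal)
#' is widened adaptively whenever the optimal path touches its edge.
#'
#' @param seq,qual Trimmed mate sequence and Phred+33 quality string.
#' @param amplicon One-row amplicon tibble.
#' @param mate `"R1"` or `"R2"`.
#' @param band Band half-width (panel default 16); `Inf` disables banding.
#' @param d0 Expected 0-based start offset on the reference; by default
#'   derived from the primer layout (R1 starts after the forward primer,
#'   R2 ends before the reverse primer), falling back to a 12-mer seed.
#' @param match,mismatch,gap_open,gap_extend Scoring parameters.
#' @return One-row tibble: `start` (0-based), `cigar` (`=XIDS` ops),
#'   `score`, and the aligned-orientation `seq`/`qual`.
#' @export
align_read <- function(seq, qual, amplicon, mate = "R1", band = 16L,
                       d0 = NULL, match = 2L, mismatch = -3L,
                       gap_open = -5L, gap_extend = -2L) {
  ref <- amplicon$reference_seq
  if (identical(mate, "R2")) {
    seq <- revcomp(seq)
    qual <- rev_qual(qual)
  }
  n_ref <- nchar(ref)
  if (is.null(d0)) {
    d0 <- if (identical(mate, "R1")) nchar(amplicon$fwd_primer)
          else n_ref - nchar(amplicon$rev_primer) - nchar(seq)
    if (d0 < 0 || d0 + nchar(seq) > n_ref) {
      seed <- regexpr(substr(seq, 1, 12), ref, fixed = TRUE)
      d0 <- if (seed > 0) seed - 1L else 0L
    }
  }
  fp <- fast_path_align(seq, ref, d0, match = match, mismatch = mismatch)
  if (!is.null(fp)) {
    res <- fp
  } else {
    b <- if (is.finite(band)) as.integer(band) else n_ref
    repeat {
      res <- cpp_align(seq, ref, as.integer(d0), b,
                       as.integer(match), as.integer(mismatch),
                       as.integer(gap_open), as.integer(gap_extend))
      if (!isTRUE(res$hit_edge) || b >= n_ref) break
      b <- min(b * 2L, n_ref)
    }
  }
  tibble(start = res$start, cigar = res$cigar, score = res$score,
         seq = seq, qual = qual)
}

#' Align all kept mates of a trimmed, assigned read-pair set
#'
#' @param pairs Output of [trim_pairs()] (rows with `kept == FALSE` or no
#'   amplicon are skipped).
#' @param panel A `panel_manifest`.
#' @inheritParams align_read
#' @return Tibble with one row per aligned mate: identifying columns plus
#'   `mate`, `start`, `cigar`, `score`, oriented `seq`/`qual`.
#' @export
align_reads <- function(pairs, panel, band = panel$thresholds$band) {
  pairs <- dplyr::filter(as_tibble(pairs), .data$kept, !is.na(.data$amplicon_id))
  if (nrow(pairs) == 0)
    return(tibble(read_id = character(0), amplicon_id = character(0),
                  mate = character(0), start = integer(0),
                  cigar = character(0), score = integer(0),
                  seq = character(0), qual = character(0)))
  amap <- split(seq_len(nrow(pairs)), pairs$amplicon_id)
  out <- vector("list", 2L * length(amap))
  k <- 0L
  keep_cols <- intersect(c("read_id", "sample_id", "amplicon_id"),
                         names(pairs))
  for (aid in names(amap)) {
    amp <- panel$amplicons[panel$amplicons$amplicon_id == aid, ]
    ref <- amp$reference_seq
    n_ref <- nchar(ref)
    rows <- amap[[aid]]
    for (mate in c("R1", "R2")) {
      if (mate == "R1") {
        sq <- pairs$r1_seq[rows]
        ql <- pairs$r1_qual[rows]
        d0 <- rep(nchar(amp$fwd_primer), length(rows))
      } else {
        sq <- revcomp(pairs$r2_seq[rows])
        ql <- rev_qual(pairs$r2_qual[rows])
        d0 <- n_ref - nchar(amp$rev_primer) - nchar(sq)
      }
      bad <- d0 < 0 | d0 + nchar(sq) > n_ref
      d0[bad] <- 0L
      al <- cpp_align_batch(sq, ref, as.integer(d0),
                            as.integer(min(band, n_ref)), 2L, -3L, -5L, -2L,
                            3L)
      k <- k + 1L
      out[[k]] <- dplyr::bind_cols(
        pairs[rows, keep_cols, drop = FALSE],
        tibble(mate = mate, start = al$start, cigar = al$cigar,
               score = al$score, seq = sq, qual = ql))
    }
  }
  dplyr::bind_rows(out[seq_len(k)])
}
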