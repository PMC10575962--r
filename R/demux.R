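#' Match an observed 8-bp barcode against a registry
#'
#' Returns the unique barcode at minimal Hamming distance when that
#' distance is at most `max_mismatch` and the minimum is unique; ties and
#' out-of-tolerance observations are unassigned (`NA`).
#'
#' @param observed Observed 8-base sequence(s).
#' @param barcodes Barcode registry: tibble with `barcode_id` and
#'   `sequence`, or a named character vector.
#' @param max_mismatch Maximum Hamming distance accepted (default 1).
#' @return Character vector of barcode ids, `NA` where unassigned.
#' @export
match_barcode <- function(observed, barcodes, max_mismatch = 1) {
  if (is.data.frame(barcodes)) {
    ids <- barcodes$barcode_id
    seqs <- barcodes$sequence
  } else {
    ids <- names(barcodes)
    seqs <- unname(barcodes)
  }
  if (any(nchar(observed) != 8)) abort("observed barcode must be 8 bases")
  h <- cpp_best_hamming(observed, seqs, 0L)
  ok <- h$best_dist <= max_mismatch & h$best_dist < h$second_dist
  ifelse(ok, ids[h$best], NA_character_)
}

#' Demultiplex pooled read pairs by inline barcode combination
#'
#' The forward barcode is read from the first 8 bases of R1 and the
#' reverse barcode from the first 8 bases of R2 (both sit 5' of the
#' primer). Each barcode is matched independently under
#' [match_barcode()] rules; the (forward, reverse) id pair is then looked
#' up in the sample sheet. Pairs whose combination is not registered go to
#' the unassigned bin, so assigned + unassigned always equals the input
#' count and no pair lands in two bins.
#'
#' @param pairs Read-pair tibble ([read_fastq_pairs()] or
#'   [simulate_cohort()] output).
#' @param sheet Validated sample sheet.
#' @param panel A `panel_manifest`.
#' @param max_mismatch Per-barcode mismatch tolerance; defaults to the
#'   panel threshold (1).
#' @return A `demux_result`: list with `pairs` (input plus `sample_id`,
#'   `NA` = unassigned) and `summary` (per-sample counts plus an
#'   `<unassigned>` row).
#' @export
demultiplex <- function(pairs, sheet, panel,
                        max_mismatch = panel$thresholds$barcode_max_mismatch) {
  pairs <- as_tibble(pairs)
  if (nrow(pairs) == 0) {
    res <- list(pairs = dplyr::mutate(pairs, sample_id = character(0)),
                summary = tibble(sample_id = character(0), n_pairs = integer(0)))
    return(structure(res, class = "demux_result"))
  }
  if (any(nchar(pairs$r1_seq) < 8 | nchar(pairs$r2_seq) < 8))
    abort("read shorter than the 8-base barcode")
  fwd <- match_barcode(substr(pairs$r1_seq, 1, 8), panel$barcodes, max_mismatch)
  rev_ <- match_barcode(substr(pairs$r2_seq, 1, 8), panel$barcodes, max_mismatch)
  key <- paste(fwd, rev_, sep = "\r")
  sheet_key <- paste(sheet$fwd_barcode, sheet$rev_barcode, sep = "\r")
  sample_id <- sheet$sample_id[match(key, sheet_key)]
  out <- dplyr::mutate(pairs, sample_id = sample_id)
  summary <- out %>%
    dplyr::count(.data$sample_id, name = "n_pairs") %>%
    dplyr::mutate(sample_id = ifelse(is.na(.data$sample_id), "<unassigned>",
                                     .data$sample_id)) %>%
    arrange(.data$sample_id)
  structure(list(pairs = out, summary = summary), class = "demux_result")
}

#' @export
print.demux_result <- function(x, ...) {
  n <- nrow(x$pairs)
  un <- sum(is.na(x$pairs$sample_id))
  cat("<demux_result> ", n, " pairs: ", n - un, " assigned, ", un,
      " unassigned\n", sep = "")
  invisible(x)
}
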