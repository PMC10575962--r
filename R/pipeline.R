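#' Run the full assay pipeline on pooled read pairs
#'
#' Demultiplex by barcode combination, assign amplicons by primer, trim,
#' align, build per-sample quality-filtered pileups, call and filter
#' variants, take the cohort union, genotype every sample at every union
#' variant, annotate consequences, match known resistance markers and
#' build depth-masked consensus sequences.
#'
#' @param pairs Pooled read-pair tibble ([read_fastq_pairs()] or
#'   [simulate_cohort()]`$pairs`).
#' @param sheet Validated sample sheet.
#' @param panel A `panel_manifest`; its thresholds drive every stage.
#' @param amplicons Optional subset of amplicon ids to process.
#' @return An `amp_run` list: `demux` (summary), `assign` (status
#'   counts), `pileups` (nested `[[sample]][[amplicon]]`), `variants`
#'   (cohort-union PASS calls), `genotypes`, `consequences`,
#'   `marker_hits`, `consensus`.
#' @export
run_pipeline <- function(pairs, sheet, panel, amplicons = NULL) {
  thr <- panel$thresholds
  dm <- demultiplex(pairs, sheet, panel)
  asn <- assign_amplicons(dm$pairs, panel)
  if (!is.null(amplicons))
    asn <- dplyr::filter(asn, is.na(.data$amplicon_id) |
                           .data$amplicon_id %in% amplicons)
  tr <- trim_pairs(asn, panel)
  tr <- dplyr::filter(tr, !is.na(.data$sample_id))
  al <- align_reads(tr, panel)

  pileups <- list()
  calls <- list()
  for (s in unique(al$sample_id)) {
    als <- al[al$sample_id == s, ]
    for (aid in unique(als$amplicon_id)) {
      amp <- panel$amplicons[panel$amplicons$amplicon_id == aid, ]
      pl <- build_pileup(als[als$amplicon_id == aid, ], amp,
                         min_base_phred = thr$min_base_phred)
      pileups[[s]][[aid]] <- pl
      calls[[paste(s, aid)]] <-
        call_variants(pl, amp, min_allele_depth = thr$min_allele_depth)
    }
  }
  all_calls <- dplyr::bind_rows(calls)
  union_calls <- if (nrow(all_calls))
    all_calls %>%
      group_by(.data$amplicon_id, .data$contig, .data$pos, .data$ref,
               .data$alt, .data$type) %>%
      summarise(depth = max(.data$depth), alt_depth = max(.data$alt_depth),
                alt_fraction = max(.data$alt_fraction), .groups = "drop") %>%
      mutate(filter = "PASS") %>%
      arrange(.data$contig, .data$pos, .data$ref, .data$alt)
  else all_calls

  genotypes <- if (nrow(union_calls) && length(pileups))
    genotype_cohort(pileups, union_calls, panel) %>%
      left_join(sheet[, c("sample_id", "population")], by = "sample_id")
  else tibble()

  consequences <- if (nrow(union_calls))
    annotate_variants(union_calls, panel) else tibble()
  marker_hits <- if (nrow(consequences))
    match_known_markers(consequences, panel$markers) else tibble()

  consensus <- dplyr::bind_rows(lapply(names(pileups), function(s) {
    dplyr::bind_rows(lapply(pileups[[s]], build_consensus,
                            min_depth = thr$consensus_min_depth,
                            max_uncalled = thr$max_uncalled_fraction)) %>%
      mutate(sample_id = s, .before = 1)
  }))

  structure(list(demux = dm$summary,
                 assign = dplyr::count(asn, .data$assign_status),
                 pileups = pileups, variants = union_calls,
                 genotypes = genotypes, consequences = consequences,
                 marker_hits = marker_hits, consensus = consensus),
            class = "amp_run")
}

#' @export
print.amp_run <- function(x, ...) {
  cat("<amp_run>\n")
  cat("  samples:", length(x$pileups), " variants:",
      nrow(x$variants), " marker hits:", nrow(x$marker_hits), "\n")
  invisible(x)
}

#' Dosage matrix from a genotype table
#'
#' @param genotypes Output of [genotype_cohort()].
#' @return Numeric samples x variants matrix of alternate-allele dosages
#'   (`NA` = no-call), ready for [ld_r2()].
#' @export
dosage_matrix <- function(genotypes) {
  w <- tidyr::pivot_wider(as_tibble(genotypes)[, c("sample_id", "variant_id",
                                                   "dosage")],
                          names_from = "variant_id",
                          values_from = "dosage")
  m <- as.matrix(w[, -1, drop = FALSE])
  rownames(m) <- w$sample_id
  storage.mode(m) <- "double"
  m
}
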