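#' Annotate a variant's codon-level consequence
#'
#' Panel-aware consequence calling. Substitutions inside a coding
#' amplicon's complete-codon span are translated through the amplicon's
#' CDS map (honouring strand and frame): the reference and alternate
#' codons are compared and the change classed `synonymous` or `missense`
#' (amino-acid changes to or from a stop are reported as missense with
#' `Ter`). Indels in coding regions are classed by length modulo 3
#' (`frameshift_indel` / `inframe_indel`); variants outside a CDS are
#' `noncoding` (`noncoding_indel` for indels) with the amplicon's region
#' label (`promoter` for promoter amplicons). Codon numbering is native;
#' when the amplicon carries a non-zero `aa_alias_offset` the
#' cross-species alias label (e.g. ace-1 643 -> N485I) is attached.
#'
#' @param variant One-row `amp_calls` tibble.
#' @param amplicon One-row amplicon tibble containing the variant.
#' @return One-row consequence tibble.
#' @export
annotate_variant <- function(variant, amplicon) {
  L <- nchar(amplicon$reference_seq)
  offset <- as.integer(variant$pos - amplicon$genomic_start)
  if (is.na(offset) || offset < 0 || offset >= L)
    abort("variant outside amplicon bounds")
  base <- tibble(
    variant_id = variant_key(variant),
    amplicon_id = amplicon$amplicon_id, gene = amplicon$gene,
    contig = variant$contig, pos = variant$pos,
    ref = variant$ref, alt = variant$alt, type = variant$type,
    region = NA_character_, class = NA_character_,
    ref_codon = NA_character_, alt_codon = NA_character_,
    ref_aa = NA_character_, alt_aa = NA_character_,
    codon_number = NA_integer_, aa_change = NA_character_,
    alias = NA_character_)

  in_cds <- FALSE
  if (isTRUE(amplicon$coding)) {
    off_s <- if (identical(amplicon$strand, "-")) L - 1L - offset else offset
    cds_pos <- off_s - amplicon$cds_offset
    n_codons <- (L - amplicon$cds_offset) %/% 3L
    in_cds <- cds_pos >= 0 && cds_pos < 3L * n_codons
  }

  if (variant$type != "snp") {
    indel_len <- abs(nchar(variant$ref) - nchar(variant$alt))
    base$region <- if (isTRUE(amplicon$coding)) "coding"
                   else amplicon$region_type
    base$class <- if (!isTRUE(amplicon$coding) || !in_cds) "noncoding_indel"
                  else if (indel_len %% 3L == 0L) "inframe_indel"
                  else "frameshift_indel"
    return(base)
  }

  if (!isTRUE(amplicon$coding) || !in_cds) {
    base$region <- if (isTRUE(amplicon$coding)) "noncoding"
                   else amplicon$region_type
    base$class <- "noncoding"
    return(base)
  }

  s <- sense_seq(amplicon)
  off_s <- if (identical(amplicon$strand, "-")) L - 1L - offset else offset
  allele_ref <- variant$ref
  allele_alt <- variant$alt
  if (identical(amplicon$strand, "-")) {
    allele_ref <- chartr("ACGT", "TGCA", allele_ref)
    allele_alt <- chartr("ACGT", "TGCA", allele_alt)
  }
  cds_pos <- off_s - amplicon$cds_offset
  codon_idx <- cds_pos %/% 3L
  within <- cds_pos %% 3L
  cstart <- amplicon$cds_offset + 3L * codon_idx
  ref_codon <- substr(s, cstart + 1L, cstart + 3L)
  if (substr(ref_codon, within + 1L, within + 1L) != allele_ref)
    warn(paste0("reference allele does not match amplicon reference at ",
                base$variant_id))
  alt_codon <- ref_codon
  substr(alt_codon, within + 1L, within + 1L) <- allele_alt
  ref_aa1 <- translate_codon(ref_codon)
  alt_aa1 <- translate_codon(alt_codon)
  codon_number <- amplicon$codon_number_start + codon_idx

  base$region <- "coding"
  base$class <- if (ref_aa1 == alt_aa1) "synonymous" else "missense"
  base$ref_codon <- ref_codon
  base$alt_codon <- alt_codon
  base$ref_aa <- aa_three(ref_aa1)
  base$alt_aa <- aa_three(alt_aa1)
  base$codon_number <- as.integer(codon_number)
  base$aa_change <- paste0(base$ref_aa, codon_number, base$alt_aa)
  if (!is.na(amplicon$aa_alias_offset) && amplicon$aa_alias_offset != 0L &&
      base$class == "missense")
    base$alias <- paste0(ref_aa1, codon_number + amplicon$aa_alias_offset,
                         alt_aa1)
  base
}

#' Annotate a table of calls against the panel
#'
#' @param calls An `amp_calls` tibble.
#' @param panel A `panel_manifest`.
#' @return Consequence tibble, one row per call.
#' @export
annotate_variants <- function(calls, panel) {
  calls <- as_tibble(calls)
  purrr::map_dfr(seq_len(nrow(calls)), function(i) {
    amp <- panel$amplicons[
      panel$amplicons$amplicon_id == calls$amplicon_id[i], ]
    annotate_variant(calls[i, ], amp)
  })
}

#' Match consequences against the known resistance-marker table
#'
#' A missense marker hits when gene, native codon number and mutant amino
#' acid all agree; a promoter-indel marker hits when the anchored genomic
#' position and inserted sequence match. Hits carry the marker's
#' insecticide-association note.
#'
#' @param consequences Output of [annotate_variants()].
#' @param markers Marker table (`panel$markers`).
#' @return Tibble of hits: `marker_id`, `variant_id`, `gene`, `alias`,
#'   `association`.
#' @export
match_known_markers <- function(consequences, markers) {
  cq <- as_tibble(consequences)
  hits <- list()
  mm <- markers[markers$variant_class == "missense", , drop = FALSE]
  if (nrow(mm) && nrow(cq)) {
    j <- dplyr::inner_join(
      dplyr::filter(cq, .data$class == "missense"),
      mm, by = c(gene = "gene", codon_number = "codon",
                 alt_aa = "mut_aa"))
    if (nrow(j))
      hits$missense <- tibble(marker_id = j$marker_id,
                              variant_id = j$variant_id, gene = j$gene,
                              alias = j$alias.y, association = j$association)
  }
  mp <- markers[markers$variant_class == "promoter_indel", , drop = FALSE]
  if (nrow(mp) && nrow(cq)) {
    ins <- dplyr::filter(cq, .data$type == "ins")
    if (nrow(ins)) {
      j <- dplyr::inner_join(
        dplyr::mutate(ins, inserted_seq = substring(.data$alt, 2)),
        mp, by = c(contig = "genomic_contig", pos = "genomic_pos",
                   "inserted_seq"))
      if (nrow(j))
        hits$promoter <- tibble(marker_id = j$marker_id,
                                variant_id = j$variant_id, gene = j$gene.x,
                                alias = j$alias.y, association = j$association)
    }
  }
  out <- dplyr::bind_rows(hits)
  if (nrow(out) == 0)
    out <- tibble(marker_id = character(0), variant_id = character(0),
                  gene = character(0), alias = character(0),
                  association = character(0))
  dplyr::distinct(out)
}

#' Summarise marker prevalence across genotyped samples
#'
#' Per marker (overall and per population when a `population` column is
#' present): genotype-class counts and percentages among genotyped
#' samples (no-calls excluded), carriage (R/R plus R/S, the fraction of
#' samples carrying at least one resistant allele) and the
#' resistant-allele frequency `(2*nRR + nRS) / (2*n)`. Percentages are
#' rounded to one decimal, half up; raw counts are retained so either
#' reading can be checked.
#'
#' @param genotypes Genotype tibble ([genotype_cohort()]), optionally with
#'   a `population` column.
#' @param hits Marker hits ([match_known_markers()]).
#' @return Tibble with one row per marker (x population, plus an `All`
#'   row when populations are present).
#' @export
marker_summary <- function(genotypes, hits) {
  g <- dplyr::inner_join(as_tibble(genotypes), as_tibble(hits),
                         by = "variant_id")
  summarise_block <- function(d, pop) {
    d <- dplyr::filter(d, .data$genotype != "no_call")
    if (nrow(d) == 0) return(NULL)
    d %>%
      group_by(.data$marker_id, .data$association) %>%
      summarise(
        n_genotyped = dplyr::n(),
        n_RR = sum(.data$genotype == "hom_alt"),
        n_RS = sum(.data$genotype == "het"),
        n_SS = sum(.data$genotype == "hom_ref"),
        .groups = "drop") %>%
      mutate(
        population = pop,
        pct_RR = round_half_up(100 * .data$n_RR / .data$n_genotyped),
        pct_RS = round_half_up(100 * .data$n_RS / .data$n_genotyped),
        pct_SS = round_half_up(100 * .data$n_SS / .data$n_genotyped),
        carriage_pct = round_half_up(
          100 * (.data$n_RR + .data$n_RS) / .data$n_genotyped),
        allele_freq_pct = round_half_up(
          100 * (2 * .data$n_RR + .data$n_RS) / (2 * .data$n_genotyped)))
  }
  if (nrow(g) == 0) abort("no genotyped samples for any marker")
  out <- list(summarise_block(g, "All"))
  if ("population" %in% names(g))
    out <- c(out, lapply(split(g, g$population), function(d)
      summarise_block(d, d$population[1])))
  res <- dplyr::bind_rows(out)
  select(res, "marker_id", "population", "association", "n_genotyped",
         "n_RR", "n_RS", "n_SS", "pct_RR", "pct_RS", "pct_SS",
         "carriage_pct", "allele_freq_pct")
}
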