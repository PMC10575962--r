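#' Call variants from a quality-filtered pileup
#'
#' Every non-reference allele (substitution base, insertion or deletion
#' event) whose allele depth reaches `min_allele_depth` (default 20 reads)
#' yields a PASS call; with `include_filtered = TRUE` sub-threshold
#' alleles are emitted with filter status `low_allele_depth` instead of
#' being omitted. The alternate fraction is allele depth over total
#' passing depth at the column (the anchor column for indels). Indels are
#' left-normalised and reported VCF-style with a one-base anchor;
#' multi-allelic columns yield one record per qualifying allele.
#' Zero-depth columns are skipped.
#'
#' @param pileup An `amp_pileup`.
#' @param amplicon One-row amplicon tibble (genomic coordinates).
#' @param min_allele_depth Minimum allele depth for PASS (20).
#' @param include_filtered Emit sub-threshold alleles as filtered records.
#' @return An `amp_calls` tibble: `amplicon_id`, `contig`, `pos` (1-based
#'   genomic), `ref`, `alt`, `type`, `depth`, `alt_depth`, `alt_fraction`,
#'   `filter`.
#' @export
call_variants <- function(pileup, amplicon, min_allele_depth = 20L,
                          include_filtered = FALSE) {
  ref <- pileup$ref
  g0 <- amplicon$genomic_start          # genomic coord of 0-based offset 0
  tbl <- pileup$tbl
  recs <- list()

  # substitutions
  long <- tidyr::pivot_longer(tbl, cols = c("A", "C", "G", "T"),
                              names_to = "alt", values_to = "alt_depth")
  long <- dplyr::filter(long, .data$alt != .data$ref_base,
                        .data$alt_depth > 0, .data$depth > 0)
  if (!include_filtered)
    long <- dplyr::filter(long, .data$alt_depth >= min_allele_depth)
  if (nrow(long))
    recs$snp <- tibble(
      pos0 = long$pos, ref = long$ref_base, alt = long$alt, type = "snp",
      depth = long$depth, alt_depth = long$alt_depth)

  base_at <- function(p0) substring(ref, p0 + 1L, p0 + 1L)  # vectorised
  col_depth <- function(p0) {
    d <- tbl$depth[match(p0, tbl$pos)]
    ifelse(is.na(d), 0L, d)
  }

  ins <- pileup$insertions
  if (nrow(ins)) {
    norm <- purrr::map2(ins$pos, ins$seq, ~normalise_insertion(ref, .x, .y))
    ins$pos <- purrr::map_int(norm, "pos")
    ins$seq <- purrr::map_chr(norm, "seq")
    ins <- ins %>%
      group_by(.data$pos, .data$seq) %>%
      summarise(count = sum(.data$count), .groups = "drop") %>%
      dplyr::filter(.data$pos > 0)      # unanchorable at reference start
    if (nrow(ins))
      recs$ins <- tibble(
        pos0 = as.integer(ins$pos - 1L),
        ref = base_at(ins$pos - 1L),
        alt = paste0(base_at(ins$pos - 1L), ins$seq), type = "ins",
        depth = col_depth(ins$pos - 1L), alt_depth = ins$count)
  }

  del <- pileup$deletions
  if (nrow(del)) {
    del$pos <- purrr::map2_int(del$pos, del$len,
                               ~normalise_deletion(ref, .x, .y))
    del <- del %>%
      group_by(.data$pos, .data$len) %>%
      summarise(count = sum(.data$count), .groups = "drop") %>%
      dplyr::filter(.data$pos > 0)
    if (nrow(del))
      recs$del <- tibble(
        pos0 = as.integer(del$pos - 1L),
        ref = substring(ref, del$pos, del$pos + del$len),
        alt = base_at(del$pos - 1L), type = "del",
        depth = col_depth(del$pos - 1L), alt_depth = del$count)
  }

  out <- dplyr::bind_rows(recs)
  if (nrow(out) == 0)
    return(structure(tibble(amplicon_id = character(0), contig = character(0),
                            pos = double(0), ref = character(0),
                            alt = character(0), type = character(0),
                            depth = integer(0), alt_depth = integer(0),
                            alt_fraction = double(0), filter = character(0)),
                     class = c("amp_calls", "tbl_df", "tbl", "data.frame")))
  out <- out %>%
    dplyr::filter(.data$type == "snp" | .data$alt_depth > 0) %>%
    mutate(
      amplicon_id = amplicon$amplicon_id,
      contig = amplicon$genomic_contig,
      pos = g0 + .data$pos0,
      alt_fraction = pmin(1, .data$alt_depth / pmax(.data$depth, 1L)),
      filter = ifelse(.data$alt_depth >= min_allele_depth, "PASS",
                      "low_allele_depth")) %>%
    dplyr::filter(include_filtered | .data$filter == "PASS") %>%
    select("amplicon_id", "contig", "pos", "ref", "alt", "type", "depth",
           "alt_depth", "alt_fraction", "filter") %>%
    arrange(.data$contig, .data$pos, .data$ref, .data$alt)
  structure(out, class = c("amp_calls", class(tibble())))
}

variant_key <- function(calls) {
  paste(calls$contig, calls$pos, calls$ref, calls$alt, sep = ":")
}
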