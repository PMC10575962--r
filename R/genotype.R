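#' Classify genotypes from alternate-allele fractions
#'
#' Allele-fraction genotyping for deep amplicon data: fractions below
#' `het_low` are homozygous reference (S/S), fractions in the closed band
#' `[het_low, het_high]` heterozygous (R/S), and fractions above
#' `het_high` homozygous alternate (R/R). Defaults follow the < 20% /
#' 20--80% / > 80% convention; both band edges are heterozygous. The
#' three classes partition `[0, 1]` for any `0 < het_low < het_high < 1`.
#'
#' @param alt_fraction Numeric vector of alternate-allele fractions.
#' @param het_low,het_high Heterozygote band edges.
#' @return Character vector in `hom_ref` / `het` / `hom_alt`.
#' @export
classify_genotype <- function(alt_fraction, het_low = 0.20, het_high = 0.80) {
  if (any(alt_fraction < 0 | alt_fraction > 1, na.rm = TRUE))
    abort("alt_fraction must lie in [0, 1]")
  if (!(het_low > 0 && het_low < het_high && het_high < 1))
    abort("need 0 < het_low < het_high < 1")
  dplyr::case_when(
    is.na(alt_fraction) ~ NA_character_,
    alt_fraction < het_low ~ "hom_ref",
    alt_fraction <= het_high ~ "het",
    TRUE ~ "hom_alt")
}

# depth and alt-depth for one variant in one sample pileup
extract_allele_depths <- function(pileup, variant, amplicon) {
  offset <- as.integer(variant$pos - amplicon$genomic_start)
  tbl <- pileup$tbl
  row <- match(offset, tbl$pos)
  if (is.na(row)) return(list(depth = 0L, alt_depth = 0L))
  if (variant$type == "snp") {
    list(depth = tbl$depth[row], alt_depth = tbl[[variant$alt]][row])
  } else if (variant$type == "ins") {
    seq <- substring(variant$alt, 2)
    ev <- pileup$insertions
    cnt <- 0L
    if (nrow(ev)) {
      norm <- purrr::map2(ev$pos, ev$seq,
                          ~normalise_insertion(pileup$ref, .x, .y))
      hit <- purrr::map_int(norm, "pos") == offset + 1L &
        purrr::map_chr(norm, "seq") == seq
      cnt <- sum(ev$count[hit])
    }
    list(depth = tbl$depth[row], alt_depth = as.integer(cnt))
  } else {
    len <- nchar(variant$ref) - 1L
    ev <- pileup$deletions
    cnt <- 0L
    if (nrow(ev)) {
      pos_n <- purrr::map2_int(ev$pos, ev$len,
                               ~normalise_deletion(pileup$ref, .x, .y))
      hit <- pos_n == offset + 1L & ev$len == len
      cnt <- sum(ev$count[hit])
    }
    list(depth = tbl$depth[row], alt_depth = as.integer(cnt))
  }
}

#' Genotype every sample at a set of variants
#'
#' For each sample and each (cohort-union) variant, the alternate-allele
#' fraction is read from the sample's pileup and classified with
#' [classify_genotype()]. Sites whose total passing depth falls below the
#' caller minimum (`min_allele_depth`) are `no_call`. The dosage column
#' (0/1/2 alternate alleles, `NA` for no-calls) feeds the LD machinery.
#'
#' @param pileups Nested named list: `pileups[[sample_id]][[amplicon_id]]`
#'   is an `amp_pileup` (see [run_pipeline()]).
#' @param variants An `amp_calls` tibble of variants to genotype (one row
#'   per unique variant).
#' @param panel A `panel_manifest`.
#' @param het_low,het_high,min_depth Genotyping thresholds; default from
#'   the panel.
#' @return Tibble: `sample_id`, `variant_id`, `amplicon_id`, `type`,
#'   `depth`, `alt_depth`, `alt_fraction`, `genotype`, `dosage`.
#' @export
genotype_cohort <- function(pileups, variants, panel,
                            het_low = panel$thresholds$het_low,
                            het_high = panel$thresholds$het_high,
                            min_depth = panel$thresholds$min_allele_depth) {
  variants <- dplyr::distinct(as_tibble(variants), .data$contig, .data$pos,
                              .data$ref, .data$alt, .keep_all = TRUE)
  vid <- variant_key(variants)
  rows <- list()
  for (s in names(pileups)) {
    for (i in seq_len(nrow(variants))) {
      v <- variants[i, ]
      pl <- pileups[[s]][[v$amplicon_id]]
      amp <- panel$amplicons[panel$amplicons$amplicon_id == v$amplicon_id, ]
      d <- if (is.null(pl)) list(depth = 0L, alt_depth = 0L)
           else extract_allele_depths(pl, v, amp)
      frac <- if (d$depth > 0) d$alt_depth / d$depth else NA_real_
      cls <- if (d$depth < min_depth) "no_call"
             else classify_genotype(frac, het_low, het_high)
      rows[[length(rows) + 1L]] <- tibble(
        sample_id = s, variant_id = vid[i], amplicon_id = v$amplicon_id,
        type = v$type, depth = d$depth, alt_depth = d$alt_depth,
        alt_fraction = frac, genotype = cls,
        dosage = c(hom_ref = 0L, het = 1L, hom_alt = 2L,
                   no_call = NA_integer_)[cls])
    }
  }
  dplyr::bind_rows(rows)
}
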