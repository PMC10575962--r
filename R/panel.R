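#' Default analysis thresholds
#'
#' The filtering and genotyping defaults used throughout the toolkit:
#' minimum allele depth of 20 reads, base Phred strictly greater than 30,
#' heterozygote band of 20--80% alternate-allele fraction, consensus depth
#' of at least 20-fold with samples dropped above 90% uncalled bases, one
#' barcode mismatch, two primer mismatches, and a 97% species-identity
#' threshold. All are overridable through the panel's `thresholds.json`
#' sidecar or by editing the returned list.
#'
#' @return Named list of threshold values.
#' @export
default_thresholds <- function() {
  list(
    min_allele_depth = 20L,
    min_base_phred = 30L,
    het_low = 0.20,
    het_high = 0.80,
    consensus_min_depth = 20L,
    max_uncalled_fraction = 0.90,
    barcode_max_mismatch = 1L,
    primer_max_mismatch = 2L,
    species_identity_threshold = 0.97,
    trim_window = 4L,
    trim_min_mean_q = 20L,
    trim_min_length = 50L,
    band = 16L
  )
}

#' Path to the packaged DRC panel definition
#'
#' The packaged panel mirrors the structure of the published An. funestus
#' assay: 17 amplicons over nine genes (vgsc 6, rdl 2, ace-1 3, GSTe2 1,
#' CYP6P4 1, CYP6P9a 1, cox-1 1, mt-ND5 1, ITS2 1), ~500 bp references,
#' 20-bp terminal primers, ten shared 8-bp barcodes and the known
#' resistance-marker table. Reference and primer sequences are synthetic
#' placeholders (with wild-type codons planted at every marker position);
#' substitute the real assay manifest for production use.
#'
#' @return Directory path containing `amplicons.tsv`, `barcodes.tsv`,
#'   `markers.tsv`, `samples.tsv` and `thresholds.json`.
#' @export
drc_panel_path <- function() {
  system.file("extdata", "drc_panel", package = "resistamp", mustWork = TRUE)
}

amp_cols <- c("amplicon_id", "gene", "genomic_contig", "genomic_start",
              "strand", "coding", "region_type", "cds_offset",
              "codon_number_start", "aa_alias_offset", "fwd_primer",
              "rev_primer", "reference_seq")

#' Load and validate a panel manifest
#'
#' Reads the assay definition from a directory holding `amplicons.tsv`,
#' `barcodes.tsv`, `markers.tsv` and an optional `thresholds.json`
#' (missing threshold entries fall back to [default_thresholds()]).
#' Validation enforces: unique amplicon ids; reference and primers over
#' A/C/G/T; the forward primer a prefix of the reference and the
#' reverse-complemented reverse primer its suffix; CDS fields present on
#' coding amplicons; barcodes of length 8 and pairwise distinct; and every
#' missense marker codon inside some coding amplicon's codon range (with
#' the reference codon translating to the marker's reference amino acid).
#'
#' @param dir Directory containing the manifest files.
#' @return A `panel_manifest` object: list with tibbles `amplicons`,
#'   `barcodes`, `markers` and the `thresholds` list.
#' @export
load_panel <- function(dir) {
  if (!dir.exists(dir)) abort(paste0("panel directory not found: ", dir))
  amp_path <- file.path(dir, "amplicons.tsv")
  if (!file.exists(amp_path)) abort("amplicons.tsv not found")
  amplicons <- readr::read_tsv(amp_path, show_col_types = FALSE,
                               col_types = readr::cols(
                                 genomic_start = readr::col_double(),
                                 coding = readr::col_logical(),
                                 .default = readr::col_character()))
  for (col in c("cds_offset", "codon_number_start", "aa_alias_offset"))
    if (col %in% names(amplicons))
      amplicons[[col]] <- as.integer(amplicons[[col]])
  if (nrow(amplicons) == 0) abort("no amplicons in manifest")
  missing <- setdiff(amp_cols, names(amplicons))
  if (length(missing))
    abort(paste0("amplicons.tsv missing columns: ",
                 paste(missing, collapse = ", ")))

  barcodes <- readr::read_tsv(file.path(dir, "barcodes.tsv"),
                              show_col_types = FALSE,
                              col_types = readr::cols(.default = "c"))
  markers <- readr::read_tsv(file.path(dir, "markers.tsv"),
                             show_col_types = FALSE,
                             col_types = readr::cols(
                               codon = readr::col_integer(),
                               genomic_pos = readr::col_double(),
                               .default = readr::col_character()))

  thr <- default_thresholds()
  thr_path <- file.path(dir, "thresholds.json")
  if (file.exists(thr_path)) {
    user <- jsonlite::read_json(thr_path, simplifyVector = TRUE)
    thr[names(user)] <- user
  }

  panel <- structure(list(amplicons = as_tibble(amplicons),
                          barcodes = as_tibble(barcodes),
                          markers = as_tibble(markers),
                          thresholds = thr),
                     class = "panel_manifest")
  validate_panel(panel)
  panel
}

#' Validate a panel manifest
#'
#' @param panel A `panel_manifest`.
#' @return The panel, invisibly; aborts with a descriptive error on the
#'   first violated invariant.
#' @export
validate_panel <- function(panel) {
  a <- panel$amplicons
  if (nrow(a) == 0) abort("no amplicons")
  if (anyDuplicated(a$amplicon_id))
    abort("duplicate amplicon_id in manifest")
  bad <- !is_dna(a$reference_seq) | !is_dna(a$fwd_primer) | !is_dna(a$rev_primer)
  if (any(bad))
    abort(paste0("non-DNA characters in amplicon(s): ",
                 paste(a$amplicon_id[bad], collapse = ", ")))
  pref_ok <- startsWith(a$reference_seq, a$fwd_primer)
  suf_ok <- endsWith(a$reference_seq, revcomp(a$rev_primer))
  if (any(!pref_ok | !suf_ok))
    abort(paste0("primer not consistent with reference ends: ",
                 paste(a$amplicon_id[!pref_ok | !suf_ok], collapse = ", ")))
  cod <- a$coding
  if (any(cod & (is.na(a$cds_offset) | is.na(a$codon_number_start))))
    abort("coding amplicon missing CDS fields")
  if (any(cod & !(a$cds_offset %in% 0:2)))
    abort("cds_offset must be 0, 1 or 2")
  if (any(cod & a$codon_number_start < 1))
    abort("codon_number_start must be >= 1")
  if (any(cod & !(a$strand %in% c("+", "-"))))
    abort("strand must be + or -")

  b <- panel$barcodes
  if (any(nchar(b$sequence) != 8)) abort("barcodes must be 8 bp")
  if (anyDuplicated(b$sequence)) abort("barcode sequences must be distinct")
  if (anyDuplicated(b$barcode_id)) abort("barcode ids must be distinct")

  m <- panel$markers
  mm <- m[m$variant_class == "missense", , drop = FALSE]
  if (nrow(mm)) {
    rng <- codon_ranges(panel)
    for (i in seq_len(nrow(mm))) {
      r <- rng[rng$gene == mm$gene[i] &
                 rng$codon_start <= mm$codon[i] &
                 rng$codon_end >= mm$codon[i], , drop = FALSE]
      if (nrow(r) == 0)
        abort(paste0("marker ", mm$marker_id[i],
                     " codon outside all coding amplicons"))
      ref_aa <- aa_three(translate_codon(
        ref_codon_seq(panel, r$amplicon_id[1], mm$codon[i])))
      if (!is.na(mm$ref_aa[i]) && !identical(ref_aa, mm$ref_aa[i]))
        abort(paste0("marker ", mm$marker_id[i],
                     ": reference codon translates to ", ref_aa,
                     ", expected ", mm$ref_aa[i]))
    }
  }
  invisible(panel)
}

# codon span covered (complete codons only) per coding amplicon
codon_ranges <- function(panel) {
  a <- panel$amplicons[panel$amplicons$coding, , drop = FALSE]
  n_codons <- (nchar(a$reference_seq) - a$cds_offset) %/% 3L
  tibble(amplicon_id = a$amplicon_id, gene = a$gene,
         codon_start = a$codon_number_start,
         codon_end = a$codon_number_start + n_codons - 1L)
}

# sense-strand sequence of an amplicon (CDS-forward orientation)
sense_seq <- function(amp_row) {
  if (identical(amp_row$strand, "-")) revcomp(amp_row$reference_seq)
  else amp_row$reference_seq
}

# reference codon (sense orientation) for a native codon number
ref_codon_seq <- function(panel, amplicon_id, codon) {
  a <- panel$amplicons[panel$amplicons$amplicon_id == amplicon_id, ]
  off <- a$cds_offset + 3L * (codon - a$codon_number_start)
  substr(sense_seq(a), off + 1L, off + 3L)
}

#' Write a panel manifest back to disk
#'
#' Inverse of [load_panel()]: `load_panel(save_panel(panel, dir))` restores
#' identical contents.
#'
#' @param panel A `panel_manifest`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
save_panel <- function(panel, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_tsv(panel$amplicons, file.path(dir, "amplicons.tsv"))
  readr::write_tsv(panel$barcodes, file.path(dir, "barcodes.tsv"))
  readr::write_tsv(panel$markers, file.path(dir, "markers.tsv"))
  writeLines(jsonlite::toJSON(panel$thresholds, auto_unbox = TRUE,
                              pretty = TRUE, digits = NA),
             file.path(dir, "thresholds.json"))
  invisible(dir)
}

#' @export
print.panel_manifest <- function(x, ...) {
  cat("<panel_manifest>\n")
  cat(" ", nrow(x$amplicons), "amplicons over",
      length(unique(x$amplicons$gene)), "genes;",
      nrow(x$barcodes), "barcodes;", nrow(x$markers), "known markers\n")
  g <- table(x$amplicons$gene)
  cat("  genes:", paste0(names(g), " (", g, ")", collapse = ", "), "\n")
  invisible(x)
}

#' Load and validate a sample sheet
#'
#' A sample sheet maps each sample to its forward/reverse inline-barcode
#' combination and collection-site population label. Barcode combinations
#' must be unique within a pool and every barcode id must exist in the
#' panel registry.
#'
#' @param path TSV with columns `sample_id`, `fwd_barcode`, `rev_barcode`,
#'   `population`.
#' @param panel A `panel_manifest` supplying the barcode registry.
#' @return Tibble with one row per sample.
#' @export
load_sample_sheet <- function(path, panel) {
  sheet <- readr::read_tsv(path, show_col_types = FALSE,
                           col_types = readr::cols(.default = "c"))
  validate_sample_sheet(sheet, panel)
}

#' @rdname load_sample_sheet
#' @param sheet An in-memory sample-sheet data frame to validate.
#' @export
validate_sample_sheet <- function(sheet, panel) {
  sheet <- as_tibble(sheet)
  need <- c("sample_id", "fwd_barcode", "rev_barcode", "population")
  missing <- setdiff(need, names(sheet))
  if (length(missing))
    abort(paste0("sample sheet missing columns: ",
                 paste(missing, collapse = ", ")))
  if (anyDuplicated(sheet$sample_id)) abort("duplicate sample_id")
  combo <- paste(sheet$fwd_barcode, sheet$rev_barcode)
  if (anyDuplicated(combo))
    abort("duplicate forward/reverse barcode combination")
  known <- panel$barcodes$barcode_id
  bad <- !(sheet$fwd_barcode %in% known) | !(sheet$rev_barcode %in% known)
  if (any(bad))
    abort(paste0("unknown barcode id for sample(s): ",
                 paste(sheet$sample_id[bad], collapse = ", ")))
  sheet
}

#' Minimum reads per amplicon in a pool
#'
#' Pool-coverage arithmetic: with `total_reads` sequenced over a pool of
#' `n_amplicons` sample-amplicon products, each amplicon receives at least
#' `floor(total_reads / n_amplicons)` reads under an even split. A MiSeq
#' pool of 50,000 reads over 170 amplicons guarantees 294 reads per
#' amplicon.
#'
#' @param total_reads Total read count for the pool.
#' @param n_amplicons Number of amplicon products in the pool.
#' @return Integer floor quotient.
#' @export
min_reads_per_amplicon <- function(total_reads, n_amplicons) {
  if (n_amplicons < 1) abort("n_amplicons must be >= 1")
  if (total_reads < 0) abort("total_reads must be >= 0")
  as.integer(total_reads %/% n_amplicons)
}
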