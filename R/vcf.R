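#' Write calls (and per-sample genotypes) as VCF 4.2
#'
#' Sites carry `DP` (total passing depth), `AD` (alternate allele depth)
#' and `AMP`/`GENE`/`TYPE` in INFO; FILTER reflects the call status. When
#' a genotype table is supplied, per-sample columns carry
#' `GT:DP:AD`, with `AD` as `ref,alt` depths and `./.` for no-calls.
#' Multi-allelic columns are written as one biallelic record per allele.
#'
#' @param calls An `amp_calls` tibble, sorted by contig and position
#'   (unsorted input errors).
#' @param path Output path.
#' @param genotypes Optional genotype tibble from [genotype_cohort()]
#'   (columns `sample_id`, `variant_id`, `genotype`, `depth`,
#'   `alt_depth`).
#' @param gene Optional named vector mapping amplicon id to gene for the
#'   INFO field; taken from `panel` if given.
#' @param panel Optional `panel_manifest` used to annotate GENE.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(calls, path, genotypes = NULL, panel = NULL,
                      gene = NULL) {
  calls <- as_tibble(calls)
  if (nrow(calls) > 1) {
    o <- order(calls$contig, calls$pos)
    if (!identical(o, seq_len(nrow(calls))))
      abort("calls must be sorted by contig and position")
  }
  if (is.null(gene) && !is.null(panel))
    gene <- setNames(panel$amplicons$gene, panel$amplicons$amplicon_id)

  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=resistamp",
    "##FILTER=<ID=low_allele_depth,Description=\"Allele depth below minimum\">",
    "##INFO=<ID=AMP,Number=1,Type=String,Description=\"Amplicon id\">",
    "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene\">",
    "##INFO=<ID=TYPE,Number=1,Type=String,Description=\"snp, ins or del\">",
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Total passing depth\">",
    "##INFO=<ID=AD,Number=1,Type=Integer,Description=\"Alternate allele depth\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Sample depth\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Ref,alt allele depths\">",
    paste0("##contig=<ID=", unique(calls$contig), ">"))

  cols <- c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO")
  samples <- character(0)
  gt_wide <- NULL
  if (!is.null(genotypes) && nrow(calls) > 0) {
    samples <- sort(unique(genotypes$sample_id))
    cols <- c(cols, "FORMAT", samples)
    gt_map <- c(hom_ref = "0/0", het = "0/1", hom_alt = "1/1",
                no_call = "./.")
    g <- genotypes %>%
      mutate(field = ifelse(
        .data$genotype == "no_call", "./.",
        paste0(gt_map[.data$genotype], ":", .data$depth, ":",
               .data$depth - .data$alt_depth, ",", .data$alt_depth)))
    gt_wide <- tidyr::pivot_wider(
      g[, c("sample_id", "variant_id", "field")],
      names_from = "sample_id", values_from = "field")
  }

  lines <- c(hdr, paste(cols, collapse = "\t"))
  if (nrow(calls) > 0) {
    info <- paste0(
      "AMP=", calls$amplicon_id,
      ifelse(is.null(gene) | is.na(gene[calls$amplicon_id]), "",
             paste0(";GENE=", gene[calls$amplicon_id])),
      ";TYPE=", calls$type, ";DP=", calls$depth, ";AD=", calls$alt_depth)
    pos_chr <- format(calls$pos, scientific = FALSE, trim = TRUE)
    body <- paste(calls$contig, pos_chr, ".", calls$ref, calls$alt, ".",
                  calls$filter, info, sep = "\t")
    if (length(samples)) {
      body <- paste(body, "GT:DP:AD", sep = "\t")
      idx <- match(variant_key(calls), gt_wide$variant_id)
      for (s in samples) {
        f <- gt_wide[[s]][idx]
        f[is.na(f)] <- "./."
        body <- paste(body, f, sep = "\t")
      }
    }
    lines <- c(lines, body)
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a VCF produced by [write_vcf()]
#'
#' Parses through `VariantAnnotation::readVcf()` (the independent VCF
#' machinery, not this package's writer) and maps records back to the
#' `amp_calls` layout plus a long genotype tibble.
#'
#' @param path VCF path.
#' @return List with `calls` and (when sample columns are present)
#'   `genotypes`.
#' @export
read_vcf <- function(path) {
  if (!requireNamespace("VariantAnnotation", quietly = TRUE))
    abort("read_vcf() needs the VariantAnnotation package")
  v <- VariantAnnotation::readVcf(path, genome = "amplicon")
  rr <- SummarizedExperiment::rowRanges(v)
  info <- VariantAnnotation::info(v)
  calls <- tibble(
    amplicon_id = as.character(info$AMP),
    contig = as.character(GenomicRanges::seqnames(rr)),
    pos = as.numeric(GenomicRanges::start(rr)),
    ref = as.character(rr$REF),
    alt = vapply(rr$ALT, function(a) as.character(a)[1], ""),
    type = as.character(info$TYPE),
    depth = as.integer(info$DP),
    alt_depth = as.integer(info$AD),
    filter = as.character(rr$FILTER))
  calls$alt_fraction <- calls$alt_depth / pmax(calls$depth, 1L)
  out <- list(calls = calls)
  gt <- VariantAnnotation::geno(v)
  if ("GT" %in% names(gt) && ncol(gt$GT) > 0) {
    gmat <- gt$GT
    dp <- gt$DP
    ad <- gt$AD
    class_map <- c("0/0" = "hom_ref", "0/1" = "het", "1/1" = "hom_alt",
                   "./." = "no_call")
    long <- expand.grid(i = seq_len(nrow(gmat)), s = colnames(gmat),
                        stringsAsFactors = FALSE)
    js <- match(long$s, colnames(gmat))
    idx <- cbind(long$i, js)
    ad2 <- vapply(seq_len(nrow(long)), function(k) {
      x <- if (is.array(ad) && length(dim(ad)) == 3)
        ad[long$i[k], js[k], ] else ad[[long$i[k], js[k]]]
      if (length(x) >= 2 && !is.na(x[2])) as.integer(x[2]) else NA_integer_
    }, integer(1))
    out$genotypes <- tibble(
      sample_id = long$s,
      variant_id = variant_key(calls)[long$i],
      genotype = unname(class_map[gmat[idx]]),
      depth = as.integer(dp[idx]),
      alt_depth = ad2)
  }
  out
}
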