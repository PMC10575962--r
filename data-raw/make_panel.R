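# Generates the packaged DRC assay definition under inst/extdata/drc_panel/.
# References and primers are SYNTHETIC placeholders with the real panel's
# structure (17 amplicons over 9 genes, ~500 bp, planted wild-type codons at
# every known marker position); users substitute the real assay manifest.
# Run once from the repository root: Rscript data-raw/make_panel.R

set.seed(20231013L)

BASES <- c("A", "C", "G", "T")

rand_dna <- function(n) paste(sample(BASES, n, replace = TRUE), collapse = "")

revcomp <- function(x) {
  chartr("ACGT", "TGCA", vapply(strsplit(x, "")[[1]], identity, ""),
  )
}
revcomp <- function(x) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", x), "")[[1]]), collapse = "")
}

plant <- function(seq, offset0, codon) {  # offset0 is 0-based
  substr(seq, offset0 + 1, offset0 + nchar(codon)) <- codon
  seq
}

codon_offset <- function(cds_offset, codon_start, codon) {
  cds_offset + 3L * (codon - codon_start)
}

amp <- list()
add_amp <- function(id, gene, len, coding, strand, cds_offset, codon_start,
                    alias_offset, contig, gstart, planted = list(),
                    fix = list(), region = if (coding) "coding" else "noncoding") {
  s <- rand_dna(len)   # sense orientation (CDS-forward for coding amplicons)
  for (p in planted) s <- plant(s, codon_offset(cds_offset, codon_start, p$codon), p$seq)
  for (f in fix) s <- plant(s, f$offset, f$seq)
  ref <- if (identical(strand, "-")) revcomp(s) else s
  amp[[id]] <<- data.frame(
    amplicon_id = id, gene = gene, genomic_contig = contig,
    genomic_start = gstart, strand = ifelse(coding, strand, "+"),
    coding = coding, region_type = region,
    cds_offset = ifelse(coding, cds_offset, NA_integer_),
    codon_number_start = ifelse(coding, codon_start, NA_integer_),
    aa_alias_offset = ifelse(coding, alias_offset, NA_integer_),
    fwd_primer = substr(ref, 1, 20),
    rev_primer = revcomp(substr(ref, nchar(ref) - 19, nchar(ref))),
    reference_seq = ref, stringsAsFactors = FALSE)
}

cd <- function(codon, seq) list(codon = codon, seq = seq)

add_amp("VGSCI",   "vgsc", 452, TRUE, "+", 1, 380, 0, "2RL", 42338400,
        planted = list(cd(410, "GTA")))                      # Val410
add_amp("VGSCIIa", "vgsc", 470, TRUE, "+", 2, 740, 0, "2RL", 42339500,
        planted = list(cd(763, "TTC"), cd(768, "ATC"),       # Phe763 Ile768
                       cd(788, "CTG"), cd(793, "GGT")))      # Leu788 Gly793
add_amp("VGSCIIb", "vgsc", 455, TRUE, "+", 0, 860, 0, "2RL", 42340400)
add_amp("VGSCIII", "vgsc", 460, TRUE, "+", 0, 990, 0, "2RL", 42341000,
        planted = list(cd(1014, "TTA")))                     # Leu1014 (kdr)
add_amp("VGSCIV",  "vgsc", 464, TRUE, "+", 1, 1480, 0, "2RL", 42343200,
        planted = list(cd(1508, "TTC"), cd(1549, "AAC")))    # Phe1508 Asn1549
add_amp("VGSCV",   "vgsc", 458, TRUE, "+", 0, 1720, 0, "2RL", 42345000,
        planted = list(cd(1763, "GAT")))                     # Asp1763
add_amp("RDL1",    "rdl",  450, TRUE, "+", 0, 250, 0, "2RL", 25420000,
        planted = list(cd(296, "GCT")))                      # Ala296
add_amp("RDL2",    "rdl",  445, TRUE, "+", 2, 430, 0, "2RL", 25421000)
add_amp("ACE1I",   "ace-1", 450, TRUE, "+", 0, 80, 0, "2RL", 19553000,
        planted = list(cd(119, "GGC")))                      # Gly119
add_amp("ACE1II",  "ace-1", 455, TRUE, "+", 1, 340, 0, "2RL", 19554000)
add_amp("ACE1III", "ace-1", 460, TRUE, "+", 1, 600, -158, "2RL", 19555000,
        planted = list(cd(643, "AAC")))                      # Asn643 (-> N485)
add_amp("GSTE2",   "GSTe2", 460, TRUE, "+", 0, 60, 0, "2RL", 75252400,
        planted = list(cd(80, "GGA"), cd(119, "CTT"),        # Gly80 Leu119
                       cd(134, "GTC"), cd(146, "AAA")))      # Val134 Lys146
add_amp("CYP6P4",  "CYP6P4", 460, TRUE, "-", 1, 270, 0, "2RL", 8560700,
        planted = list(cd(288, "ATT"), cd(289, "GGA"), cd(291, "AAT"),
                       cd(294, "CTT"), cd(295, "AAG"), cd(297, "GAA"),
                       cd(404, "GAT"), cd(414, "ATA")))
# CYP6P9a promoter amplicon: non-coding; 2-bp insertion site anchored after
# offset 149 (0-based); ref[149] = G so an "AT" insertion cannot left-shift.
add_amp("CYP6P9A", "CYP6P9a", 460, FALSE, "+", NA, NA, NA, "2RL", 8570000,
        fix = list(list(offset = 148, seq = "AGCA")), region = "promoter")
add_amp("COX1",    "cox-1",  465, TRUE, "+", 0, 50, 0, "Mt", 1400)
add_amp("ND5",     "mt-ND5", 462, TRUE, "+", 0, 30, 0, "Mt", 6800)
add_amp("ITS2",    "ITS2",   440, FALSE, "+", NA, NA, NA, "rDNA", 1200)

amps <- do.call(rbind, amp)
stopifnot(nrow(amps) == 17, length(unique(amps$gene)) == 9)

# primer starts must be separable at the primer-mismatch tolerance
ham <- function(a, b) sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
prs <- c(amps$fwd_primer, amps$rev_primer)
d <- outer(seq_along(prs), seq_along(prs),
           Vectorize(function(i, j) if (i == j) 99L else ham(prs[i], prs[j])))
stopifnot(min(d) >= 6)

# ten shared 8-bp barcodes, pairwise Hamming distance >= 4
repeat {
  bc <- replicate(10, rand_dna(8))
  dd <- outer(1:10, 1:10, Vectorize(function(i, j)
    if (i == j) 99L else ham(bc[i], bc[j])))
  if (min(dd) >= 4 && !anyDuplicated(bc)) break
}
barcodes <- data.frame(barcode_id = sprintf("BC%02d", 1:10), sequence = bc,
                       stringsAsFactors = FALSE)

markers <- data.frame(
  marker_id = c("vgsc_L1014F", "vgsc_L1014S", "vgsc_V410L", "vgsc_F1508C",
                "vgsc_N1549Y", "vgsc_D1763Y", "ace1_G119S", "ace1_N643I",
                "rdl_A296S", "gste2_L119F", "cyp6p9a_ins"),
  gene = c(rep("vgsc", 6), "ace-1", "ace-1", "rdl", "GSTe2", "CYP6P9a"),
  codon = c(1014, 1014, 410, 1508, 1549, 1763, 119, 643, 296, 119, NA),
  ref_aa = c("Leu", "Leu", "Val", "Phe", "Asn", "Asp", "Gly", "Asn", "Ala",
             "Leu", NA),
  mut_aa = c("Phe", "Ser", "Leu", "Cys", "Tyr", "Tyr", "Ser", "Ile", "Ser",
             "Phe", NA),
  alias = c("L1014F (kdr)", "L1014S (kdr)", "V410L", "F1508C", "N1549Y",
            "D1763Y", "G119S", "N485I (Torpedo californica)", "A296S (rdl)",
            "L119F", "CYP6P9a promoter 2-bp insertion"),
  variant_class = c(rep("missense", 10), "promoter_indel"),
  association = c(rep("pyrethroid/DDT (kdr)", 2), "pyrethroid", "pyrethroid",
                  "pyrethroid", "pyrethroid", "organophosphate/carbamate",
                  "carbamate (bendiocarb)", "cyclodiene (dieldrin)", "DDT",
                  "pyrethroid"),
  genomic_contig = c(rep(NA, 10), "2RL"),
  genomic_pos = c(rep(NA, 10), 8570000 + 149),
  inserted_seq = c(rep(NA, 10), "AT"),
  stringsAsFactors = FALSE)

samples <- data.frame(
  sample_id = c(sprintf("Tch%03d", 1:70), sprintf("Tsh%03d", 1:10)),
  fwd_barcode = sprintf("BC%02d", rep(1:10, 8)),
  rev_barcode = sprintf("BC%02d", rep(1:8, each = 10)),
  population = c(rep("Tchonka", 70), rep("Tushunguti", 10)),
  stringsAsFactors = FALSE)

thr <- list(min_allele_depth = 20L, min_base_phred = 30L, het_low = 0.20,
            het_high = 0.80, consensus_min_depth = 20L,
            max_uncalled_fraction = 0.90, barcode_max_mismatch = 1L,
            primer_max_mismatch = 2L, species_identity_threshold = 0.97,
            trim_window = 4L, trim_min_mean_q = 20L, trim_min_length = 50L,
            band = 16L)

dir.create("inst/extdata/drc_panel", recursive = TRUE, showWarnings = FALSE)
wt <- function(x, f) write.table(x, file.path("inst/extdata/drc_panel", f),
                                 sep = "\t", quote = FALSE, row.names = FALSE)
wt(amps, "amplicons.tsv")
wt(barcodes, "barcodes.tsv")
wt(markers, "markers.tsv")
wt(samples, "samples.tsv")
writeLines(jsonlite::toJSON(thr, auto_unbox = TRUE, pretty = TRUE, digits = NA),
           "inst/extdata/drc_panel/thresholds.json")
cat("wrote inst/extdata/drc_panel\n")
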