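test_that("allele-fraction bands classify genotypes with closed het edges", {
  expect_equal(classify_genotype(0.15), "hom_ref")
  expect_equal(classify_genotype(0.199999), "hom_ref")
  expect_equal(classify_genotype(0.20), "het")     # 20% is heterozygous
  expect_equal(classify_genotype(0.50), "het")
  expect_equal(classify_genotype(0.80), "het")     # 80% is heterozygous
  expect_equal(classify_genotype(0.81), "hom_alt")
  expect_equal(classify_genotype(1.0), "hom_alt")
  expect_error(classify_genotype(1.2), "0, 1")
})

test_that("the three classes partition [0,1] for any valid thresholds", {
  set.seed(14)
  for (k in 1:25) {
    lo <- runif(1, 0.01, 0.5)
    hi <- runif(1, lo + 0.01, 0.99)
    fr <- c(0, lo - 1e-9, lo, runif(30), hi, hi + 1e-9, 1)
    cls <- classify_genotype(fr, lo, hi)
    expect_true(all(cls %in% c("hom_ref", "het", "hom_alt")))
    expect_false(any(is.na(cls)))
    # monotone in the fraction
    expect_true(all(diff(match(cls[order(fr)],
                               c("hom_ref", "het", "hom_alt"))) >= 0))
  }
})

test_that("ace-1 codon 643 Asn>Ile is annotated with its N485I alias", {
  panel <- load_test_panel()
  amp <- panel$amplicons[panel$amplicons$amplicon_id == "ACE1III", ]
  # codon 643 occupies offsets 130..132 (cds_offset 1, start codon 600)
  off <- amp$cds_offset + 3 * (643 - amp$codon_number_start)
  expect_equal(substr(amp$reference_seq, off + 1, off + 3), "AAC")
  v <- tibble::tibble(amplicon_id = "ACE1III", contig = amp$genomic_contig,
                      pos = amp$genomic_start + off + 1, ref = "A",
                      alt = "T", type = "snp", depth = 100L, alt_depth = 50L,
                      alt_fraction = 0.5, filter = "PASS")
  cq <- annotate_variant(v, amp)
  expect_equal(cq$class, "missense")
  expect_equal(cq$aa_change, "Asn643Ile")
  expect_equal(cq$alias, "N485I")
  expect_equal(cq$ref_codon, "AAC")
  expect_equal(cq$alt_codon, "ATC")

  # a marker-table lookup identifies the bendiocarb-resistance marker
  hits <- match_known_markers(cq, panel$markers)
  expect_equal(hits$marker_id, "ace1_N643I")
  expect_match(hits$association, "bendiocarb")
})

test_that("third-position silent changes are synonymous and never hits", {
  panel <- load_test_panel()
  amp <- panel$amplicons[panel$amplicons$amplicon_id == "ACE1III", ]
  off <- amp$cds_offset + 3 * (643 - amp$codon_number_start)
  # AAC -> AAT both encode Asn
  v <- tibble::tibble(amplicon_id = "ACE1III", contig = amp$genomic_contig,
                      pos = amp$genomic_start + off + 2, ref = "C",
                      alt = "T", type = "snp", depth = 100L, alt_depth = 50L,
                      alt_fraction = 0.5, filter = "PASS")
  cq <- annotate_variant(v, amp)
  expect_equal(cq$class, "synonymous")
  expect_equal(nrow(match_known_markers(cq, panel$markers)), 0L)
})

test_that("the CYP6P9a promoter insertion is a non-coding marker hit", {
  panel <- load_test_panel()
  amp <- panel$amplicons[panel$amplicons$amplicon_id == "CYP6P9A", ]
  mk <- panel$markers[panel$markers$marker_id == "cyp6p9a_ins", ]
  anchor0 <- mk$genomic_pos - amp$genomic_start
  v <- tibble::tibble(
    amplicon_id = "CYP6P9A", contig = amp$genomic_contig,
    pos = mk$genomic_pos,
    ref = substr(amp$reference_seq, anchor0 + 1, anchor0 + 1),
    alt = paste0(substr(amp$reference_seq, anchor0 + 1, anchor0 + 1),
                 mk$inserted_seq),
    type = "ins", depth = 100L, alt_depth = 60L, alt_fraction = 0.6,
    filter = "PASS")
  cq <- annotate_variant(v, amp)
  expect_equal(cq$class, "noncoding_indel")
  expect_equal(cq$region, "promoter")
  expect_true(is.na(cq$aa_change))           # no amino-acid change
  hits <- match_known_markers(cq, panel$markers)
  expect_equal(hits$marker_id, "cyp6p9a_ins")
  expect_match(hits$association, "pyrethroid")
})

test_that("annotation agrees with brute-force translation on both strands", {
  skip_if_not_installed("Biostrings")
  set.seed(61)
  for (strand in c("+", "-")) {
    L <- 60L
    cds_offset <- 1L
    sense <- rand_dna(L)
    ref <- if (strand == "-") revcomp_chr(sense) else sense
    amp <- make_amplicon(ref, coding = TRUE, strand = strand,
                         cds_offset = cds_offset, codon_number_start = 10L,
                         gstart = 2000)
    n_codons <- (L - cds_offset) %/% 3L
    ref_prot <- as.character(Biostrings::translate(Biostrings::DNAString(
      substr(sense, cds_offset + 1, cds_offset + 3 * n_codons)),
      no.init.codon = TRUE))
    for (offset in 0:(L - 1)) {
      ref_b <- substr(ref, offset + 1, offset + 1)
      for (alt_b in setdiff(c("A", "C", "G", "T"), ref_b)) {
        v <- tibble::tibble(amplicon_id = amp$amplicon_id, contig = "chrT",
                            pos = 2000 + offset, ref = ref_b, alt = alt_b,
                            type = "snp", depth = 10L, alt_depth = 5L,
                            alt_fraction = 0.5, filter = "PASS")
        cq <- annotate_variant(v, amp)
        # oracle: mutate the full sequence, re-extract and translate the CDS
        mut_ref <- ref
        substr(mut_ref, offset + 1, offset + 1) <- alt_b
        mut_sense <- if (strand == "-") revcomp_chr(mut_ref) else mut_ref
        mut_prot <- as.character(Biostrings::translate(Biostrings::DNAString(
          substr(mut_sense, cds_offset + 1, cds_offset + 3 * n_codons)),
          no.init.codon = TRUE))
        diff_at <- which(strsplit(ref_prot, "")[[1]] !=
                           strsplit(mut_prot, "")[[1]])
        off_s <- if (strand == "-") L - 1 - offset else offset
        in_cds <- off_s >= cds_offset && off_s < cds_offset + 3 * n_codons
        if (!in_cds) {
          expect_equal(cq$class, "noncoding")
        } else if (length(diff_at) == 0) {
          expect_equal(cq$class, "synonymous")
        } else {
          expect_equal(cq$class, "missense")
          expect_equal(cq$codon_number, 10L + diff_at - 1L)
          expect_equal(aa_one(cq$alt_aa),
                       substr(mut_prot, diff_at, diff_at))
        }
      }
    }
  }
})

test_that("marker prevalence arithmetic matches the printed percentages", {
  hit <- tibble::tibble(marker_id = "cyp6p9a_ins", variant_id = "v1",
                        gene = "CYP6P9a", alias = "ins",
                        association = "pyrethroid")
  gt <- function(n_rr, n_rs, n_ss, vid = "v1") {
    tibble::tibble(
      sample_id = sprintf("S%03d", seq_len(n_rr + n_rs + n_ss)),
      variant_id = vid,
      genotype = c(rep("hom_alt", n_rr), rep("het", n_rs),
                   rep("hom_ref", n_ss)),
      depth = 100L, alt_depth = 50L, alt_fraction = 0.5,
      dosage = c(rep(2L, n_rr), rep(1L, n_rs), rep(0L, n_ss)))
  }
  # 34/8/4 of 46 genotyped: the printed 73.9 / 17.4 / 8.7 split
  s1 <- marker_summary(gt(34, 8, 4), hit)
  expect_equal(s1$pct_RR, 73.9)
  expect_equal(s1$pct_RS, 17.4)
  expect_equal(s1$pct_SS, 8.7)
  expect_equal(s1$carriage_pct, 91.3)

  # 1 hom-alt + 9 het of 68: carriage 14.7%, allele frequency 8.1%
  s2 <- marker_summary(gt(1, 9, 58), hit)
  expect_equal(s2$carriage_pct, 14.7)
  expect_equal(s2$allele_freq_pct, 8.1)

  # all hom-ref
  s3 <- marker_summary(gt(0, 0, 30), hit)
  expect_equal(s3$carriage_pct, 0)
  expect_equal(s3$allele_freq_pct, 0)

  # properties: carriage + %SS ~ 100 and the exact allele-count identity
  set.seed(4)
  for (k in 1:20) {
    n <- sample(3:120, 1)
    parts <- as.vector(stats::rmultinom(1, n, runif(3)))
    s <- marker_summary(gt(parts[1], parts[2], parts[3]), hit)
    expect_lt(abs(s$carriage_pct + s$pct_SS - 100), 0.15)
    expect_equal(s$allele_freq_pct,
                 round(100 * (2 * parts[1] + parts[2]) / (2 * n) + 1e-9, 1))
    expect_equal(s$n_RR + s$n_RS + s$n_SS, n)
  }
  expect_error(marker_summary(gt(0, 0, 0), hit), "no genotyped")
})
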