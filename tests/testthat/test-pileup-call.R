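set.seed(99)
REF60 <- rand_dna(60)
AMP60 <- make_amplicon(REF60, coding = FALSE, gstart = 100)

test_that("base quality filter is strict: Phred 30 out, Phred 31 in", {
  n <- 30
  als <- make_alignments(rep(0L, n), rep("60=", n), rep(REF60, n),
                         replicate(n, rep(31L, 60), simplify = FALSE))
  pl <- build_pileup(als, AMP60, min_base_phred = 30)
  expect_true(all(pl$tbl$depth == n))          # Phred 31 counts everywhere

  als30 <- make_alignments(0L, "60=", REF60, list(rep(30L, 60)))
  pl30 <- build_pileup(als30, AMP60, min_base_phred = 30)
  expect_true(all(pl30$tbl$depth == 0))        # Phred exactly 30 excluded

  # mixed qualities: only the passing bases count
  quals <- rep(35L, 60); quals[10:19] <- 30L
  plmix <- build_pileup(make_alignments(0L, "60=", REF60, list(quals)),
                        AMP60, min_base_phred = 30)
  expect_equal(plmix$tbl$depth, c(rep(1L, 9), rep(0L, 10), rep(1L, 41)))
})

test_that("deletions span columns without contributing bases", {
  als <- make_alignments(0L, "20=2D38=",
                         paste0(substr(REF60, 1, 20), substr(REF60, 23, 60)),
                         list(rep(35L, 58)))
  pl <- build_pileup(als, AMP60, min_base_phred = 30)
  expect_equal(pl$tbl$del[21:22], c(1L, 1L))
  expect_equal(pl$tbl$A[21] + pl$tbl$C[21] + pl$tbl$G[21] + pl$tbl$T[21], 0L)
  expect_equal(pl$tbl$depth[21], 1L)           # deletion counts toward depth
  expect_equal(nrow(pl$deletions), 1L)
  expect_equal(pl$deletions$len, 2L)
})

test_that("pileup depth never exceeds covering reads", {
  panel <- load_test_panel()
  sheet <- load_test_sheet(panel)
  spec <- random_cohort_spec(panel, sheet, n_samples = 2, depth = 15,
                             error_rate = 0.01, seed = 5,
                             low_phred = 10L, low_tail = 40L)
  sim <- simulate_cohort(spec)
  run <- run_pipeline(sim$pairs, sheet, panel,
                      amplicons = c("COX1", "GSTE2"))
  for (s in names(run$pileups)) for (pl in run$pileups[[s]]) {
    expect_true(all(pl$tbl$depth <= 2 * 15))
  }
})

mutated_pileup <- function(alt_n, ref_n = 100L - alt_n, pos0 = 25L) {
  alt_base <- setdiff(c("A", "C", "G", "T"),
                      substr(REF60, pos0 + 1, pos0 + 1))[1]
  mut <- REF60
  substr(mut, pos0 + 1, pos0 + 1) <- alt_base
  seqs <- c(rep(REF60, ref_n), rep(mut, alt_n))
  n <- length(seqs)
  als <- make_alignments(rep(0L, n), rep("60=", n), seqs,
                         replicate(n, rep(35L, 60), simplify = FALSE))
  list(pl = build_pileup(als, AMP60, 30), alt = alt_base)
}

test_that("allele-depth filter: 19 never called, 20 always called", {
  low <- mutated_pileup(19L)
  calls19 <- call_variants(low$pl, AMP60, min_allele_depth = 20)
  expect_equal(nrow(calls19), 0L)
  # but visible when filtered records are requested
  all19 <- call_variants(low$pl, AMP60, min_allele_depth = 20,
                         include_filtered = TRUE)
  expect_equal(all19$filter, "low_allele_depth")

  hi <- mutated_pileup(20L)
  calls20 <- call_variants(hi$pl, AMP60, min_allele_depth = 20)
  expect_equal(nrow(calls20), 1L)
  expect_equal(calls20$filter, "PASS")
  expect_equal(calls20$alt_fraction, 0.20)
  expect_equal(calls20$pos, 100 + 25)
  expect_equal(calls20$alt, hi$alt)
})

test_that("multi-allelic columns yield one record per allele", {
  pos0 <- 30L
  ref_b <- substr(REF60, pos0 + 1, pos0 + 1)
  alts <- setdiff(c("A", "C", "G", "T"), ref_b)[1:2]
  muts <- vapply(alts, function(b) {
    m <- REF60; substr(m, pos0 + 1, pos0 + 1) <- b; m
  }, "")
  seqs <- c(rep(REF60, 50), rep(muts[1], 25), rep(muts[2], 25))
  als <- make_alignments(rep(0L, 100), rep("60=", 100), seqs,
                         replicate(100, rep(35L, 60), simplify = FALSE))
  calls <- call_variants(build_pileup(als, AMP60, 30), AMP60,
                         min_allele_depth = 20)
  at <- calls[calls$pos == 100 + pos0, ]
  expect_equal(nrow(at), 2L)
  expect_setequal(at$alt, alts)
  expect_equal(at$alt_depth, c(25L, 25L))
  expect_equal(at$depth, c(100L, 100L))
})

test_that("multiple indel events keep their own anchor bases", {
  # two insertion events at different positions in one pileup: each call
  # must carry the anchor base at its own position (vectorisation guard)
  mk <- function(cigar, seq_fn, n) {
    s <- seq_fn(REF60)
    make_alignments(rep(0L, n), rep(cigar, n), rep(s, n),
                    replicate(n, rep(35L, nchar(s)), simplify = FALSE))
  }
  ins1 <- function(r) paste0(substr(r, 1, 10), "TT", substr(r, 11, 60))
  ins2 <- function(r) paste0(substr(r, 1, 40), "GG", substr(r, 41, 60))
  stopifnot(substr(REF60, 10, 10) != "T", substr(REF60, 40, 40) != "G")
  als <- dplyr::bind_rows(mk("10=2I50=", ins1, 25), mk("40=2I20=", ins2, 30))
  calls <- call_variants(build_pileup(als, AMP60, 30), AMP60,
                         min_allele_depth = 20)
  calls <- calls[order(calls$pos), ]
  expect_equal(nrow(calls), 2L)
  expect_equal(calls$ref, c(substr(REF60, 10, 10), substr(REF60, 40, 40)))
  expect_equal(calls$alt, c(paste0(substr(REF60, 10, 10), "TT"),
                            paste0(substr(REF60, 40, 40), "GG")))
  expect_equal(calls$alt_depth, c(25L, 30L))

  # likewise two deletion events
  del1 <- function(r) paste0(substr(r, 1, 15), substr(r, 18, 60))
  del2 <- function(r) paste0(substr(r, 1, 45), substr(r, 47, 60))
  # contexts where left-normalisation cannot shift the events
  stopifnot(substr(REF60, 15, 15) != substr(REF60, 17, 17),
            substr(REF60, 45, 45) != substr(REF60, 46, 46))
  alsd <- dplyr::bind_rows(mk("15=2D43=", del1, 25), mk("45=1D14=", del2, 30))
  cd <- call_variants(build_pileup(alsd, AMP60, 30), AMP60,
                      min_allele_depth = 20)
  cd <- cd[order(cd$pos), ]
  expect_equal(nrow(cd), 2L)
  expect_equal(cd$ref, c(substr(REF60, 15, 17), substr(REF60, 45, 46)))
  expect_equal(cd$alt, c(substr(REF60, 15, 15), substr(REF60, 45, 45)))
})

test_that("insertion evidence is keyed by position and sequence", {
  ins_read <- paste0(substr(REF60, 1, 40), "TT", substr(REF60, 41, 60))
  # guard: context chosen so the insertion cannot left-shift
  stopifnot(substr(REF60, 40, 40) != "T")
  als <- make_alignments(rep(0L, 25), rep("40=2I20=", 25),
                         rep(ins_read, 25),
                         replicate(25, rep(35L, 62), simplify = FALSE))
  pl <- build_pileup(als, AMP60, 30)
  expect_equal(nrow(pl$insertions), 1L)
  expect_equal(pl$insertions$count, 25L)
  calls <- call_variants(pl, AMP60, min_allele_depth = 20)
  expect_equal(calls$type, "ins")
  expect_equal(calls$pos, 100 + 39)
  expect_equal(calls$alt, paste0(substr(REF60, 40, 40), "TT"))
})
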