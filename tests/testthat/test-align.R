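toy_amp <- function(ref) make_amplicon(ref, coding = FALSE)

test_that("amplicon assignment requires concordant primers", {
  panel <- load_test_panel()
  a <- panel$amplicons
  ace <- a[a$amplicon_id == "ACE1III", ]
  other <- a[a$amplicon_id == "GSTE2", ]
  pad <- function(p) paste0(strrep("A", 8), p, strrep("G", 100))
  pair <- tibble::tibble(r1_seq = pad(ace$fwd_primer),
                         r2_seq = pad(ace$rev_primer))
  expect_equal(assign_amplicon(pair, panel), "ACE1III")

  none <- tibble::tibble(r1_seq = pad(strrep("A", 20)),
                         r2_seq = pad(strrep("A", 20)))
  expect_equal(assign_amplicon(none, panel), "unassigned")

  chim <- tibble::tibble(r1_seq = pad(ace$fwd_primer),
                         r2_seq = pad(other$rev_primer))
  expect_equal(assign_amplicon(chim, panel), "chimera")
})

test_that("glocal alignment matches the worked scoring examples", {
  set.seed(42)
  ref <- rand_dna(400)
  amp <- toy_amp(ref)
  q35 <- function(n) strrep(rawToChar(as.raw(35 + 33)), n)

  read <- substr(ref, 1, 200)
  al <- align_read(read, q35(200), amp, mate = "R1", d0 = 0)
  expect_equal(al$start, 0L)
  expect_equal(al$cigar, "200=")
  expect_equal(al$score, 400L)

  mut <- read
  substr(mut, 51, 51) <- setdiff(c("A", "C", "G", "T"), substr(mut, 51, 51))[1]
  al2 <- align_read(mut, q35(200), amp, mate = "R1", d0 = 0)
  expect_equal(al2$score, 199L * 2L - 3L)
  expect_equal(al2$cigar, "50=1X149=")
})

test_that("insertions are placed at the leftmost equivalent position", {
  ref <- "ACGTAAAAACGTACG"           # A-homopolymer at offsets 4..8
  q <- "ACGTAAAAAAACGTACG"           # two extra As inside the run
  amp <- toy_amp(ref)
  al <- align_read(q, strrep("I", nchar(q)), amp, d0 = 0, band = 100)
  expect_equal(al$cigar, "4=2I11=")  # insertion anchored at run start
  expect_equal(al$start, 0L)
})

test_that("banded alignment equals full dynamic programming (oracle)", {
  set.seed(202)
  n_cases <- 200
  for (k in seq_len(n_cases)) {
    n_ref <- sample(30:60, 1)
    ref <- rand_dna(n_ref)
    m <- sample(10:min(30, n_ref), 1)
    start <- sample(0:(n_ref - m), 1)
    q <- substr(ref, start + 1, start + m)
    # corrupt with up to 2 substitutions and possibly a small indel
    nmut <- sample(0:2, 1)
    for (t in seq_len(nmut)) {
      p <- sample(m, 1)
      substr(q, p, p) <- sample(c("A", "C", "G", "T"), 1)
    }
    if (runif(1) < 0.3 && nchar(q) > 6) {
      p <- sample(nchar(q) - 2, 1)
      if (runif(1) < 0.5) q <- paste0(substr(q, 1, p), substr(q, p + 2, nchar(q)))
      else q <- paste0(substr(q, 1, p), sample(c("A", "C", "G", "T"), 1),
                       substr(q, p + 1, nchar(q)))
    }
    full <- cpp_align(q, ref, 0L, nchar(ref) + 1L, 2L, -3L, -5L, -2L)
    expect_equal(full$score, oracle_align_score(q, ref))
    banded <- cpp_align(q, ref, start, 16L, 2L, -3L, -5L, -2L)
    if (!isTRUE(banded$hit_edge))
      expect_equal(banded$score, full$score)
  }
})

test_that("reads overhanging the reference are soft-clipped and ignored", {
  ref <- rand_dna(60)
  amp <- toy_amp(ref)
  q <- paste0(substr(ref, 41, 60), "ACGTT")   # 5-base overhang past the end
  al <- align_read(q, strrep("I", nchar(q)), amp, d0 = 40, band = 100)
  expect_equal(al$start, 40L)
  expect_match(al$cigar, "S$")
  pl <- build_pileup(
    make_alignments(al$start, al$cigar, al$seq, list(rep(35L, nchar(q)))),
    make_amplicon(ref, coding = FALSE), min_base_phred = 30)
  expect_equal(sum(pl$tbl$depth), 20L)        # clipped bases contribute nothing
})

test_that("indel representations converge to one left-normalised call", {
  set.seed(7)
  left <- rand_dna(80)
  substr(left, 80, 80) <- "A"      # stop the run shifting past the anchor
  right <- rand_dna(80)
  substr(right, 1, 1) <- "C"       # keep the homopolymer exactly 5 long
  ref <- paste0(left, "GGGGG", right)         # homopolymer 81..85
  amp <- make_amplicon(ref, coding = FALSE, gstart = 500)
  # reads carrying a 2-base deletion drawn from either end of the run
  hap <- paste0(left, "GGG", right)
  reads <- substring(hap, c(1, 20, 40), c(120, 140, 160))
  als <- lapply(seq_along(reads), function(i)
    align_read(reads[i], strrep("I", nchar(reads[i])), amp,
               d0 = c(0, 19, 39)[i], band = 30))
  al <- dplyr::bind_rows(als)
  pl <- build_pileup(
    make_alignments(al$start, al$cigar, al$seq,
                    lapply(nchar(reads), function(n) rep(35L, n))),
    amp, min_base_phred = 30)
  calls <- call_variants(pl, amp, min_allele_depth = 3)
  delc <- calls[calls$type == "del", ]
  expect_equal(nrow(delc), 1L)                # one normalised event
  expect_equal(delc$pos, 500 + 80 - 1)        # anchored before the run
  expect_equal(delc$alt_depth, 3L)
})
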