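# Independent oracles and fixture builders used across the suite.

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                              collapse = "")

revcomp_chr <- function(x) {
  vapply(x, function(s)
    paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = ""),
    "", USE.NAMES = FALSE)
}

# Full (unbanded) semi-global affine-gap DP, plain R. Global in the query
# with free leading/trailing reference and terminal query clips at
# reference ends; gap of length k costs open + k*extend. Returns the
# optimal score only -- the oracle against the banded C++ aligner.
oracle_align_score <- function(q, ref, match = 2, mismatch = -3,
                               gap_open = -5, gap_extend = -2) {
  qc <- strsplit(q, "")[[1]]
  rc <- strsplit(ref, "")[[1]]
  m <- length(qc); n <- length(rc)
  NEG <- -1e9
  M <- matrix(NEG, m + 1, n + 1)
  X <- matrix(NEG, m + 1, n + 1)
  Y <- matrix(NEG, m + 1, n + 1)
  M[1, ] <- 0
  M[, 1] <- 0
  for (i in 2:(m + 1)) {
    for (j in 2:(n + 1)) {
      s <- if (qc[i - 1] == rc[j - 1]) match else mismatch
      M[i, j] <- max(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1]) + s
      X[i, j] <- max(M[i, j - 1] + gap_open + gap_extend,
                     X[i, j - 1] + gap_extend)
      Y[i, j] <- max(M[i - 1, j] + gap_open + gap_extend,
                     Y[i - 1, j] + gap_extend)
    }
  }
  max(M[m + 1, ], M[, n + 1])
}

# brute-force nucleotide diversity: explicit double loop, pairwise deletion
oracle_pi <- function(seqs) {
  m <- do.call(rbind, strsplit(seqs, ""))
  n <- nrow(m)
  vals <- c()
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    comp <- m[i, ] != "N" & m[j, ] != "N"
    if (sum(comp) == 0) next
    vals <- c(vals, sum(m[i, comp] != m[j, comp]) / sum(comp))
  }
  mean(vals)
}

oracle_hap_div <- function(seqs) {
  n <- length(seqs)
  p <- as.numeric(table(seqs)) / n
  n / (n - 1) * (1 - sum(p^2))
}

# enumerate all spanning trees of a complete graph on n <= 6 labelled
# nodes (via edge subsets of size n-1) and return the minimum total weight
oracle_min_spanning_weight <- function(d) {
  n <- nrow(d)
  edges <- which(upper.tri(d), arr.ind = TRUE)
  combs <- utils::combn(nrow(edges), n - 1)
  best <- Inf
  for (k in seq_len(ncol(combs))) {
    sel <- edges[combs[, k], , drop = FALSE]
    # connectivity check via union-find
    parent <- seq_len(n)
    find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
    acyclic <- TRUE
    for (e in seq_len(nrow(sel))) {
      a <- find(sel[e, 1]); b <- find(sel[e, 2])
      if (a == b) { acyclic <- FALSE; break }
      parent[a] <- b
    }
    if (!acyclic) next
    w <- sum(d[sel])
    if (w < best) best <- w
  }
  best
}

# one-row amplicon constructor for unit fixtures
make_amplicon <- function(seq, id = "AMP1", gene = "toy", contig = "chrT",
                          gstart = 1000, strand = "+", coding = TRUE,
                          region_type = if (coding) "coding" else "noncoding",
                          cds_offset = 0L, codon_number_start = 1L,
                          aa_alias_offset = 0L, primer_len = 10L) {
  tibble::tibble(
    amplicon_id = id, gene = gene, genomic_contig = contig,
    genomic_start = gstart, strand = strand, coding = coding,
    region_type = region_type,
    cds_offset = if (coding) as.integer(cds_offset) else NA_integer_,
    codon_number_start = if (coding) as.integer(codon_number_start)
                         else NA_integer_,
    aa_alias_offset = if (coding) as.integer(aa_alias_offset)
                      else NA_integer_,
    fwd_primer = substr(seq, 1, primer_len),
    rev_primer = revcomp_chr(substr(seq, nchar(seq) - primer_len + 1,
                                    nchar(seq))),
    reference_seq = seq)
}

# synthetic alignments (pre-set cigars) for pileup fixtures
make_alignments <- function(starts, cigars, seqs, phreds) {
  tibble::tibble(start = starts, cigar = cigars, seq = seqs,
                 qual = vapply(phreds, function(p) intToUtf8(p + 33L), ""))
}

load_test_panel <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- load_panel(drc_panel_path())
    cache
  }
})

load_test_sheet <- function(panel = load_test_panel()) {
  load_sample_sheet(file.path(drc_panel_path(), "samples.tsv"), panel)
}
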