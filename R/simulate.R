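#' Truth variants for every known marker in a panel
#'
#' Builds the simulator's variant definitions from the marker table: for
#' each missense marker, the first single-base change of the planted
#' reference codon that encodes the mutant amino acid (honouring amplicon
#' strand); for promoter-indel markers, the anchored insertion. Each
#' definition carries its VCF-style key (`contig:pos:ref:alt`,
#' left-normalised) so pipeline output can be compared back to truth.
#'
#' @param panel A `panel_manifest`.
#' @return Tibble of variant definitions: `variant_id`, `amplicon_id`,
#'   `type`, `pos` (0-based reference offset; insertion point for `ins`),
#'   `ref`, `alt`, `len`, `vcf_key`, `haploid`.
#' @export
marker_truth_variants <- function(panel) {
  rng <- codon_ranges(panel)
  rows <- list()
  for (i in seq_len(nrow(panel$markers))) {
    mk <- panel$markers[i, ]
    if (mk$variant_class == "missense") {
      r <- rng[rng$gene == mk$gene & rng$codon_start <= mk$codon &
                 rng$codon_end >= mk$codon, ][1, ]
      amp <- panel$amplicons[panel$amplicons$amplicon_id == r$amplicon_id, ]
      s <- sense_seq(amp)
      L <- nchar(s)
      cidx <- mk$codon - amp$codon_number_start
      cstart <- amp$cds_offset + 3L * cidx
      ref_codon <- substr(s, cstart + 1L, cstart + 3L)
      target <- aa_one(mk$mut_aa)
      found <- NULL
      for (within in 0:2) {
        for (b in setdiff(BASES, substr(ref_codon, within + 1, within + 1))) {
          alt_codon <- ref_codon
          substr(alt_codon, within + 1, within + 1) <- b
          if (translate_codon(alt_codon) == target) {
            found <- list(within = within, alt = b); break
          }
        }
        if (!is.null(found)) break
      }
      if (is.null(found))
        abort(paste0("no single-base change reaches ", mk$mut_aa,
                     " for marker ", mk$marker_id))
      off_s <- cstart + found$within
      minus <- identical(amp$strand, "-")
      pos0 <- if (minus) L - 1L - off_s else off_s
      ref_b <- substr(s, off_s + 1L, off_s + 1L)
      alt_b <- found$alt
      if (minus) {
        ref_b <- chartr("ACGT", "TGCA", ref_b)
        alt_b <- chartr("ACGT", "TGCA", alt_b)
      }
      rows[[length(rows) + 1L]] <- tibble(
        variant_id = mk$marker_id, amplicon_id = amp$amplicon_id,
        type = "snp", pos = pos0, ref = ref_b, alt = alt_b, len = 1L,
        vcf_key = paste(amp$genomic_contig, amp$genomic_start + pos0,
                        ref_b, alt_b, sep = ":"),
        haploid = FALSE)
    } else if (mk$variant_class == "promoter_indel") {
      amp <- panel$amplicons[
        panel$amplicons$genomic_contig == mk$genomic_contig &
          panel$amplicons$genomic_start <= mk$genomic_pos &
          panel$amplicons$genomic_start + nchar(panel$amplicons$reference_seq) >
            mk$genomic_pos, ][1, ]
      anchor0 <- as.integer(mk$genomic_pos - amp$genomic_start)
      ins_point <- anchor0 + 1L
      nrm <- normalise_insertion(amp$reference_seq, ins_point, mk$inserted_seq)
      anchor_b <- substr(amp$reference_seq, nrm$pos, nrm$pos)
      rows[[length(rows) + 1L]] <- tibble(
        variant_id = mk$marker_id, amplicon_id = amp$amplicon_id,
        type = "ins", pos = nrm$pos, ref = anchor_b,
        alt = nrm$seq, len = nchar(nrm$seq),
        vcf_key = paste(amp$genomic_contig,
                        amp$genomic_start + nrm$pos - 1L, anchor_b,
                        paste0(anchor_b, nrm$seq), sep = ":"),
        haploid = FALSE)
    }
  }
  dplyr::bind_rows(rows)
}

#' Add neutral truth SNPs on the phylogenetic amplicons
#'
#' Sprinkles haploid substitution variants over the mitochondrial and
#' ribosomal amplicons so simulated cohorts show haplotype structure.
#'
#' @param panel A `panel_manifest`.
#' @param per_amplicon SNPs per phylogenetic amplicon.
#' @return Truth-variant tibble (see [marker_truth_variants()]).
#' @export
phylo_truth_variants <- function(panel, per_amplicon = 3L) {
  phylo <- panel$amplicons[panel$amplicons$gene %in%
                             c("cox-1", "mt-ND5", "ITS2"), ]
  rows <- list()
  for (i in seq_len(nrow(phylo))) {
    amp <- phylo[i, ]
    L <- nchar(amp$reference_seq)
    pos <- as.integer(round(seq(60, min(220, L - 40),
                                length.out = per_amplicon)))
    for (p in pos) {
      ref_b <- substr(amp$reference_seq, p + 1, p + 1)
      alt_b <- setdiff(BASES, ref_b)[1]
      rows[[length(rows) + 1L]] <- tibble(
        variant_id = paste0(amp$amplicon_id, "_s", p),
        amplicon_id = amp$amplicon_id, type = "snp", pos = p,
        ref = ref_b, alt = alt_b, len = 1L,
        vcf_key = paste(amp$genomic_contig, amp$genomic_start + p,
                        ref_b, alt_b, sep = ":"),
        haploid = TRUE)
    }
  }
  dplyr::bind_rows(rows)
}

#' Specify a synthetic sequencing cohort
#'
#' Bundles everything [simulate_cohort()] needs: the panel, the samples
#' with their barcode combinations, the truth variants, per-sample truth
#' genotypes, per-amplicon read depth, substitution error rate, quality
#' profile and seed. Defaults state the emulated world: 100 read pairs
#' per sample-amplicon, 2 x 250 bp mates, constant Phred 35, substitution
#' error 1e-3.
#'
#' @param panel A `panel_manifest`.
#' @param samples Sample sheet rows to simulate.
#' @param variants Truth-variant tibble.
#' @param genotypes Tibble `sample_id`, `variant_id`, `genotype`
#'   (`hom_ref`/`het`/`hom_alt`).
#' @param depth Read pairs per sample-amplicon: scalar or named by
#'   amplicon id.
#' @param error_rate Per-base substitution error probability.
#' @param phred Constant base quality; `low_phred`/`low_tail` optionally
#'   set the last `low_tail` bases of each mate to a second level.
#' @param read_len Mate length (250).
#' @param seed Integer seed; the whole simulation is reproducible from it.
#' @param low_phred,low_tail Optional two-level quality profile.
#' @return A `sim_spec` object.
#' @export
sim_spec <- function(panel, samples, variants, genotypes, depth = 100L,
                     error_rate = 0.001, phred = 35L, read_len = 250L,
                     seed = 1L, low_phred = NULL, low_tail = 0L) {
  if (error_rate < 0 || error_rate > 1) abort("error_rate must be in [0,1]")
  if (any(depth < 0)) abort("depths must be >= 0")
  amp <- panel$amplicons
  v <- as_tibble(variants)
  bad <- !(v$amplicon_id %in% amp$amplicon_id)
  if (any(bad)) abort("truth variant outside panel amplicons")
  for (i in seq_len(nrow(v))) {
    a <- amp[amp$amplicon_id == v$amplicon_id[i], ]
    if (v$pos[i] < 0 || v$pos[i] >= nchar(a$reference_seq))
      abort("truth variant position outside its amplicon")
    if (v$type[i] == "snp" &&
        substr(a$reference_seq, v$pos[i] + 1, v$pos[i] + 1) != v$ref[i])
      abort("truth SNP reference allele mismatch")
    if (nchar(a$fwd_primer) + nchar(a$rev_primer) >= nchar(a$reference_seq))
      abort("amplicon shorter than its primer span")
  }
  g <- as_tibble(genotypes)
  if (!all(g$genotype %in% c("hom_ref", "het", "hom_alt")))
    abort("genotype must be hom_ref, het or hom_alt")
  hap <- v$haploid[match(g$variant_id, v$variant_id)]
  if (any(hap & g$genotype == "het", na.rm = TRUE))
    abort("haploid loci cannot be heterozygous")
  structure(list(panel = panel, samples = as_tibble(samples), variants = v,
                 genotypes = g, depth = depth, error_rate = error_rate,
                 phred = phred, read_len = read_len, seed = seed,
                 low_phred = low_phred, low_tail = low_tail),
            class = "sim_spec")
}

# apply truth variants (rows of the variant tibble) to a reference string
apply_variants <- function(ref, vars) {
  if (nrow(vars) == 0) return(ref)
  vars <- vars[order(-vars$pos), ]
  for (i in seq_len(nrow(vars))) {
    v <- vars[i, ]
    if (v$type == "snp") {
      substr(ref, v$pos + 1, v$pos + 1) <- v$alt
    } else if (v$type == "ins") {
      ref <- paste0(substr(ref, 1, v$pos), v$alt,
                    substr(ref, v$pos + 1, nchar(ref)))
    } else {
      ref <- paste0(substr(ref, 1, v$pos),
                    substr(ref, v$pos + v$len + 1, nchar(ref)))
    }
  }
  ref
}

#' Spike substitution errors into sequences
#'
#' Each base is independently substituted with probability `rate`, to a
#' uniformly random different base. Deterministic under `seed`; with
#' `seed = NULL` the current RNG stream is used.
#'
#' @param seqs Character vector of DNA sequences.
#' @param rate Per-base substitution probability in `[0, 1]`.
#' @param seed Optional integer seed.
#' @return Mutated sequences.
#' @export
spike_errors <- function(seqs, rate, seed = NULL) {
  if (rate < 0 || rate > 1) abort("rate must be in [0,1]")
  if (!is.null(seed)) set.seed(seed)
  if (rate == 0 || length(seqs) == 0) return(seqs)
  vapply(seqs, function(s) {
    n <- nchar(s)
    k <- rbinom(1, n, rate)
    if (k == 0) return(s)
    pos <- sample.int(n, k)
    ch <- strsplit(s, "")[[1]]
    ch[pos] <- vapply(ch[pos], function(b) sample(setdiff(BASES, b), 1), "")
    paste(ch, collapse = "")
  }, "", USE.NAMES = FALSE)
}

#' Simulate a pooled amplicon-sequencing cohort
#'
#' Emits pooled paired reads with the assay's structure: each mate is the
#' 8-base inline barcode followed by primer plus insert; R1 covers the
#' amplicon 5' end, R2 the reverse-complemented 3' end, at fixed
#' `read_len`. For heterozygous samples every read pair draws its
#' haplotype from Bernoulli(0.5), so alleles co-occurring on one
#' haplotype stay linked within reads; homozygous classes use the fixed
#' allele. Substitution errors are applied i.i.d. at `error_rate`. The
#' returned truth tables make every downstream stage checkable: the
#' read-to-(sample, amplicon) map, the genotype matrix with VCF-style
#' keys, and expected depth-masked consensus sequences for
#' (sample, amplicon) combinations where the outcome is deterministic
#' (no het or indel variant; primer shadows masked `N`) under error-free
#' deep sequencing.
#'
#' @param spec A `sim_spec`.
#' @return A list with `pairs` (read-pair tibble, pool-shuffled),
#'   `truth` (list: `reads`, `genotypes`, `variants`,
#'   `expected_consensus`) and `spec`.
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"))
  set.seed(spec$seed)
  panel <- spec$panel
  amp <- panel$amplicons
  bc <- setNames(panel$barcodes$sequence, panel$barcodes$barcode_id)
  depth_of <- function(aid) {
    if (is.null(names(spec$depth))) return(as.integer(spec$depth[1]))
    d <- spec$depth[aid]
    if (is.na(d)) 0L else as.integer(d)
  }
  out_r1 <- list(); out_r2 <- list(); out_truth <- list()
  cons_rows <- list()
  g <- spec$genotypes
  for (si in seq_len(nrow(spec$samples))) {
    srow <- spec$samples[si, ]
    bcf <- bc[[srow$fwd_barcode]]; bcr <- bc[[srow$rev_barcode]]
    gs <- g[g$sample_id == srow$sample_id, ]
    for (ai in seq_len(nrow(amp))) {
      a <- amp[ai, ]
      D <- depth_of(a$amplicon_id)
      if (D == 0) next
      va <- spec$variants[spec$variants$amplicon_id == a$amplicon_id, ]
      va <- dplyr::inner_join(va, gs, by = "variant_id")
      hap1 <- apply_variants(a$reference_seq,
                             va[va$genotype == "hom_alt", ])
      hap2 <- apply_variants(a$reference_seq,
                             va[va$genotype %in% c("hom_alt", "het"), ])
      ins_len <- spec$read_len - 8L
      draw <- if (identical(hap1, hap2)) rep(0L, D)
              else rbinom(D, 1L, 0.5)
      haps <- ifelse(draw == 1L, hap2, hap1)
      r1 <- paste0(bcf, substr(haps, 1, ins_len))
      r2 <- paste0(bcr, substr(revcomp(haps), 1, ins_len))
      key <- paste(srow$sample_id, a$amplicon_id, sep = "\r")
      out_r1[[key]] <- r1
      out_r2[[key]] <- r2
      out_truth[[key]] <- tibble(sample_id = srow$sample_id,
                                 amplicon_id = a$amplicon_id, n = D)

      # expected consensus where deterministic
      het_or_indel <- any(va$genotype == "het") ||
        any(va$type != "snp" & va$genotype != "hom_ref")
      if (!het_or_indel) {
        L <- nchar(a$reference_seq)
        covered <- rep(FALSE, L)
        covered[(nchar(a$fwd_primer) + 1):min(ins_len, L)] <- TRUE
        lo <- max(1L, L - ins_len + 1L)
        hi <- L - nchar(a$rev_primer)
        if (lo <= hi) covered[lo:hi] <- TRUE
        ch <- strsplit(hap1, "")[[1]]
        ch[!covered] <- "N"
        cons_rows[[key]] <- tibble(sample_id = srow$sample_id,
                                   amplicon_id = a$amplicon_id,
                                   sequence = paste(ch, collapse = ""))
      }
    }
  }
  r1 <- unlist(out_r1, use.names = FALSE)
  r2 <- unlist(out_r2, use.names = FALSE)
  tr <- dplyr::bind_rows(out_truth)
  reads_map <- tibble(sample_id = rep(tr$sample_id, tr$n),
                      amplicon_id = rep(tr$amplicon_id, tr$n))
  n <- length(r1)
  reads_map$read_id <- sprintf("read%07d", seq_len(n))
  if (spec$error_rate > 0) {
    r1 <- spike_errors(r1, spec$error_rate)
    r2 <- spike_errors(r2, spec$error_rate)
  }
  qual_for <- function(s) {
    q <- strrep(intToUtf8(spec$phred + 33L), nchar(s))
    if (!is.null(spec$low_phred) && spec$low_tail > 0) {
      tail_len <- pmin(spec$low_tail, nchar(s))
      q <- paste0(substr(q, 1, nchar(s) - tail_len),
                  strrep(intToUtf8(spec$low_phred + 33L), tail_len))
    }
    q
  }
  ord <- sample.int(n)            # pool shuffle
  pairs <- tibble(read_id = reads_map$read_id,
                  r1_seq = r1, r1_qual = qual_for(r1),
                  r2_seq = r2, r2_qual = qual_for(r2))[ord, ]
  genotypes <- dplyr::left_join(
    spec$genotypes,
    spec$variants[, c("variant_id", "amplicon_id", "vcf_key", "type")],
    by = "variant_id")
  genotypes$dosage <- c(hom_ref = 0L, het = 1L,
                        hom_alt = 2L)[genotypes$genotype]
  list(pairs = pairs,
       truth = list(reads = reads_map[, c("read_id", "sample_id",
                                          "amplicon_id")],
                    genotypes = genotypes,
                    variants = spec$variants,
                    expected_consensus = dplyr::bind_rows(cons_rows)),
       spec = spec)
}

#' Random cohort specification over the packaged marker set
#'
#' Draws per-sample truth genotypes at every marker variant (plus neutral
#' phylogenetic SNPs) under Hardy-Weinberg proportions at alternate
#' allele frequency `alt_freq` (haploid loci draw hom_ref/hom_alt), and
#' wires them to the first `n_samples` rows of the sample sheet.
#'
#' @param panel A `panel_manifest`.
#' @param sheet Sample sheet (defaults to the packaged 80-sample sheet).
#' @param n_samples Cohort size.
#' @param alt_freq Alternate-allele frequency used for the draws.
#' @param seed Seed for the genotype draws (also passed to the spec).
#' @inheritParams sim_spec
#' @return A `sim_spec`.
#' @export
random_cohort_spec <- function(panel, sheet = NULL, n_samples = 20L,
                               alt_freq = 0.3, depth = 100L,
                               error_rate = 0.001, seed = 1L, ...) {
  if (is.null(sheet))
    sheet <- load_sample_sheet(file.path(drc_panel_path(), "samples.tsv"),
                               panel)
  samples <- head(sheet, n_samples)
  variants <- dplyr::bind_rows(marker_truth_variants(panel),
                               phylo_truth_variants(panel))
  set.seed(seed)
  draws <- list()
  for (i in seq_len(nrow(variants))) {
    v <- variants[i, ]
    cls <- if (v$haploid) {
      sample(c("hom_ref", "hom_alt"), nrow(samples), TRUE,
             prob = c(1 - alt_freq, alt_freq))
    } else {
      sample(c("hom_ref", "het", "hom_alt"), nrow(samples), TRUE,
             prob = c((1 - alt_freq)^2, 2 * alt_freq * (1 - alt_freq),
                      alt_freq^2))
    }
    draws[[i]] <- tibble(sample_id = samples$sample_id,
                         variant_id = v$variant_id, genotype = cls)
  }
  sim_spec(panel, samples, variants, dplyr::bind_rows(draws),
           depth = depth, error_rate = error_rate, seed = seed, ...)
}
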