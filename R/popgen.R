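seq_matrix <- function(seqs) {
  if (length(unique(nchar(seqs))) != 1)
    abort("sequences must be aligned to equal length")
  do.call(rbind, strsplit(seqs, ""))
}

#' Nucleotide diversity (pi) of an aligned sequence set
#'
#' Mean over all unordered sequence pairs of the proportion of differing
#' sites, comparing only positions where both sequences are non-N
#' (pairwise deletion). Pairs with zero comparable sites are skipped with
#' a warning.
#'
#' @param seqs Character vector of equal-length aligned sequences over
#'   `A`/`C`/`G`/`T`/`N`.
#' @return Nucleotide diversity in `[0, 1]`.
#' @export
nucleotide_diversity <- function(seqs) {
  if (length(seqs) < 2) abort("need at least 2 sequences")
  m <- seq_matrix(seqs)
  n <- nrow(m)
  ok <- m != "N"
  vals <- numeric(0)
  skipped <- 0L
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      comp <- ok[i, ] & ok[j, ]
      nc <- sum(comp)
      if (nc == 0) { skipped <- skipped + 1L; next }
      vals <- c(vals, sum(m[i, comp] != m[j, comp]) / nc)
    }
  }
  if (skipped > 0)
    warn(paste0(skipped, " pair(s) with no comparable sites skipped"))
  if (length(vals) == 0) abort("no comparable pairs")
  mean(vals)
}

#' Per-site nucleotide diversity
#'
#' Unbiased per-site heterozygosity for a biallelic site:
#' `2*j*(n-j) / (n*(n-1))` with `j` alternate alleles among `n` sampled.
#'
#' @param n_alleles Total alleles sampled at the site (>= 2).
#' @param alt_count Alternate-allele count, `0 <= j <= n`.
#' @return Per-site diversity (vectorised).
#' @export
site_pi <- function(n_alleles, alt_count) {
  if (any(n_alleles < 2)) abort("n_alleles must be >= 2")
  if (any(alt_count < 0 | alt_count > n_alleles))
    abort("alt_count must lie in [0, n_alleles]")
  2 * alt_count * (n_alleles - alt_count) / (n_alleles * (n_alleles - 1))
}

#' Haplotype count and diversity
#'
#' Haplotypes are equivalence classes of identical sequences; diversity is
#' `H = n/(n-1) * (1 - sum(p_i^2))` over haplotype frequencies.
#' Sequences containing `N` are excluded from haplotype counting by
#' default (`na_action = "exclude"`); `na_action = "drop_sites"` instead
#' removes every column containing an `N` in any sequence before
#' collapsing.
#'
#' @param seqs Aligned equal-length sequences.
#' @param na_action How to handle sequences with uncalled bases.
#' @return List with `n_seq` (used), `n_hap`, `H`, and the haplotype
#'   table (`haplotypes`: sequence + count, most frequent first).
#' @export
haplotype_stats <- function(seqs, na_action = c("exclude", "drop_sites")) {
  na_action <- match.arg(na_action)
  if (length(seqs) < 2) abort("need at least 2 sequences")
  if (na_action == "drop_sites" && any(grepl("N", seqs, fixed = TRUE))) {
    m <- seq_matrix(seqs)
    keep <- colSums(m == "N") == 0
    seqs <- apply(m[, keep, drop = FALSE], 1, paste, collapse = "")
  } else {
    seqs <- seqs[!grepl("N", seqs, fixed = TRUE)]
  }
  n <- length(seqs)
  if (n < 2) abort("fewer than 2 usable sequences after N handling")
  tab <- sort(table(seqs), decreasing = TRUE)
  p <- as.numeric(tab) / n
  list(n_seq = n, n_hap = length(tab),
       H = n / (n - 1) * (1 - sum(p^2)),
       haplotypes = tibble(sequence = names(tab), count = as.integer(tab)))
}

#' Amplicon diversity summary
#'
#' Convenience wrapper producing the per-amplicon diversity table:
#' number of sequences, haplotype count and diversity, and nucleotide
#' diversity. Columns that are `N` in every sequence (e.g. primer
#' shadows never covered after trimming) carry no pairwise information
#' and are removed before haplotype collapsing; sequences with residual
#' `N`s follow `na_action`.
#'
#' @inheritParams haplotype_stats
#' @return One-row tibble: `n_seq`, `n_hap`, `hap_diversity`,
#'   `nuc_diversity`.
#' @export
diversity_stats <- function(seqs, na_action = c("exclude", "drop_sites")) {
  na_action <- match.arg(na_action)
  pi <- nucleotide_diversity(seqs)
  m <- seq_matrix(seqs)
  informative <- colSums(m != "N") > 0
  seqs2 <- apply(m[, informative, drop = FALSE], 1, paste, collapse = "")
  h <- haplotype_stats(seqs2, na_action)
  tibble(n_seq = length(seqs), n_hap = h$n_hap, hap_diversity = h$H,
         nuc_diversity = pi)
}

#' Pairwise linkage disequilibrium (r-squared) of genotype dosages
#'
#' Squared Pearson correlation of dosage vectors (0/1/2 alternate
#' alleles), computed per pair over complete cases. Monomorphic vectors
#' have no defined correlation and yield `NA`. The statistic is symmetric
#' and invariant to swapping allele labels (dosage `d -> 2 - d`).
#'
#' @param dosages Numeric matrix, samples x variants (dimnames kept), with
#'   `NA` for missing genotypes.
#' @return Symmetric matrix of r-squared values with unit diagonal (where
#'   defined).
#' @export
ld_r2 <- function(dosages) {
  dosages <- as.matrix(dosages)
  if (ncol(dosages) < 2) abort("need at least 2 variants")
  ok <- colSums(!is.na(dosages)) >= 2
  r <- suppressWarnings(cor(dosages, use = "pairwise.complete.obs"))
  r[!ok, ] <- NA
  r[, !ok] <- NA
  r^2
}

#' Weir & Cockerham fixation index between two populations
#'
#' Per-site two-population Fst from allele counts, using the Weir &
#' Cockerham (1984) variance-component estimator in its allele-count
#' (haploid) form: `theta = a / (a + b)` with `a` the between-population
#' and `b` the within-population component. Sites where `a + b = 0`
#' (e.g. both populations monomorphic for the same allele) are undefined
#' and skipped from the mean, which is the ratio of summed components.
#' The estimator reaches exactly 1 when the populations are fixed for
#' different alleles and is unbiased around 0 (slightly negative values,
#' bounded by `-1/(n_bar - 1)`, occur when frequencies coincide).
#'
#' @param pop_a,pop_b Per-site allele counts: data frames (or lists) with
#'   vectors `n` (total alleles sampled) and `alt` (alternate-allele
#'   count), one entry per site.
#' @return An `fst_result`: tibble with per-site `a`, `b` and `fst`, with
#'   the ratio-of-sums mean in `attr(, "mean_fst")`.
#' @export
fst_wc <- function(pop_a, pop_b) {
  n1 <- pop_a$n; j1 <- pop_a$alt
  n2 <- pop_b$n; j2 <- pop_b$alt
  if (length(n1) != length(n2)) abort("populations must cover the same sites")
  if (any(n1 < 1) || any(n2 < 1)) abort("each population needs >= 1 allele per site")
  p1 <- j1 / n1; p2 <- j2 / n2
  nbar <- (n1 + n2) / 2
  nc <- (n1 + n2) - (n1^2 + n2^2) / (n1 + n2)
  pbar <- (n1 * p1 + n2 * p2) / (n1 + n2)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / nbar
  a <- (nbar / nc) * (s2 - (pbar * (1 - pbar) - s2 / 2) / (nbar - 1))
  b <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) - s2 / 2)
  fst <- ifelse(a + b == 0, NA_real_, a / (a + b))
  out <- tibble(site = seq_along(n1), a = a, b = b, fst = fst)
  usable <- !is.na(fst)
  attr(out, "mean_fst") <-
    if (any(usable)) sum(a[usable]) / sum(a[usable] + b[usable]) else NA_real_
  class(out) <- c("fst_result", class(out))
  out
}

#' @export
print.fst_result <- function(x, ...) {
  cat("<fst_result> ", sum(!is.na(x$fst)), " of ", nrow(x),
      " sites defined; mean Fst = ",
      format(attr(x, "mean_fst"), digits = 4), "\n", sep = "")
  NextMethod()
}

#' Minimum-spanning haplotype network
#'
#' Builds the pairwise Hamming-distance graph over haplotypes, extracts a
#' minimum spanning tree (Kruskal; ties broken by lexicographic node
#' order) and then adds every non-tree edge whose distance equals the
#' maximum edge weight on the tree path between its endpoints as a tie
#' ("alternative") edge -- the usual minimum-spanning-network
#' construction. Distances ignore indels: sequences must be pre-aligned
#' and of equal length.
#'
#' @param haplotypes Tibble with `sequence` and `count` (plus optional
#'   per-population count columns, carried through), or a bare character
#'   vector of sequences (counted as given).
#' @return A `hap_network`: list with `nodes` (id, sequence, count, ...)
#'   and `edges` (`from`, `to`, `dist`, `in_mst`, `tie_edge`).
#' @export
min_spanning_network <- function(haplotypes) {
  if (is.character(haplotypes)) {
    tab <- table(haplotypes)
    haplotypes <- tibble(sequence = names(tab), count = as.integer(tab))
  }
  h <- as_tibble(haplotypes)
  if (nrow(h) < 1) abort("need at least one haplotype")
  if (anyDuplicated(h$sequence)) abort("haplotype sequences must be unique")
  n <- nrow(h)
  nodes <- dplyr::mutate(h, id = paste0("H", seq_len(n)), .before = 1)
  if (n == 1) {
    return(structure(list(
      nodes = nodes,
      edges = tibble(from = character(0), to = character(0),
                     dist = integer(0), in_mst = logical(0),
                     tie_edge = logical(0))), class = "hap_network"))
  }
  m <- seq_matrix(h$sequence)
  d <- matrix(0L, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    d[i, j] <- d[j, i] <- sum(m[i, ] != m[j, ])
  edges <- tibble(i = rep(seq_len(n - 1), times = (n - 1):1),
                  j = unlist(lapply(seq_len(n - 1), function(i) (i + 1):n)))
  edges$dist <- d[cbind(edges$i, edges$j)]
  edges <- edges[order(edges$dist, edges$i, edges$j), ]

  # Kruskal with union-find
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  in_mst <- logical(nrow(edges))
  for (k in seq_len(nrow(edges))) {
    ri <- find(edges$i[k]); rj <- find(edges$j[k])
    if (ri != rj) { parent[ri] <- rj; in_mst[k] <- TRUE }
  }
  edges$in_mst <- in_mst

  # path-max over the tree for the tie rule
  adj <- lapply(seq_len(n), function(i) list())
  for (k in which(in_mst)) {
    i <- edges$i[k]; j <- edges$j[k]; w <- edges$dist[k]
    adj[[i]] <- c(adj[[i]], list(c(j, w)))
    adj[[j]] <- c(adj[[j]], list(c(i, w)))
  }
  # running maximum edge weight along the unique tree path
  path_max <- function(from, to) {
    best <- rep(NA_integer_, n)
    best[from] <- 0L
    queue <- from
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      for (e in adj[[v]]) {
        if (is.na(best[e[1]])) {
          best[e[1]] <- max(best[v], e[2])
          queue <- c(queue, e[1])
        }
      }
    }
    best[to]
  }
  tie <- logical(nrow(edges))
  for (k in which(!in_mst)) {
    tie[k] <- edges$dist[k] == path_max(edges$i[k], edges$j[k])
  }
  keep <- in_mst | tie
  out_edges <- tibble(from = nodes$id[edges$i[keep]],
                      to = nodes$id[edges$j[keep]],
                      dist = edges$dist[keep],
                      in_mst = edges$in_mst[keep],
                      tie_edge = !edges$in_mst[keep])
  structure(list(nodes = nodes, edges = out_edges), class = "hap_network")
}

#' @export
print.hap_network <- function(x, ...) {
  cat("<hap_network> ", nrow(x$nodes), " haplotypes, ",
      sum(x$edges$in_mst), " tree edges, ", sum(x$edges$tie_edge),
      " tie edges\n", sep = "")
  invisible(x)
}

#' Identity-based species assignment
#'
#' Aligns a consensus sequence against each labelled reference with the
#' glocal aligner and scores percent identity over aligned non-N columns
#' (gap columns excluded). The best label is returned when its identity
#' reaches `threshold` (default 97%); otherwise the call is unresolved.
#' The runner-up margin supports reporting borderline assignments.
#'
#' @param consensus A consensus sequence (may contain `N`).
#' @param refs Named character vector of reference sequences (names =
#'   species labels).
#' @param threshold Minimum identity for a resolved call.
#' @return One-row tibble: `species`, `identity`, `margin`, `resolved`,
#'   plus the full per-reference identity table in `attr(, "identities")`.
#' @export
identify_species <- function(consensus, refs, threshold = 0.97) {
  if (length(refs) == 0) abort("empty reference set")
  if (is.null(names(refs)) || any(!nzchar(names(refs))))
    abort("references must be named by species")
  ident <- vapply(refs, function(r) {
    a <- cpp_align(consensus, r, 0L, nchar(r), 2L, -3L, -5L, -2L)
    qpos <- 0L; rpos <- a$start
    matches <- 0L; compared <- 0L
    for (piece in regmatches(a$cigar, gregexpr("[0-9]+[=XIDS]", a$cigar))[[1]]) {
      len <- as.integer(sub("[=XIDS]", "", piece))
      op <- sub("[0-9]+", "", piece)
      if (op %in% c("=", "X")) {
        qb <- substr(consensus, qpos + 1L, qpos + len)
        rb <- substr(r, rpos + 1L, rpos + len)
        qc <- charToRaw(qb); rc <- charToRaw(rb)
        nonN <- qc != charToRaw("N")[1]
        compared <- compared + sum(nonN)
        matches <- matches + sum(nonN & qc == rc)
        qpos <- qpos + len; rpos <- rpos + len
      } else if (op == "I" || op == "S") qpos <- qpos + len
      else rpos <- rpos + len
    }
    if (compared == 0) return(NA_real_)
    matches / compared
  }, numeric(1))
  ord <- order(ident, decreasing = TRUE)
  best <- ord[1]
  margin <- if (length(ident) > 1) ident[best] - ident[ord[2]] else NA_real_
  resolved <- !is.na(ident[best]) && ident[best] >= threshold
  out <- tibble(
    species = if (resolved) names(refs)[best] else NA_character_,
    identity = unname(ident[best]), margin = unname(margin),
    resolved = resolved)
  attr(out, "identities") <- tibble(species = names(refs),
                                    identity = unname(ident))
  out
}
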