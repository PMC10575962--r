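test_that("nucleotide diversity matches direct counts and the brute force", {
  expect_equal(nucleotide_diversity(rep("ACGTACGT", 3)), 0)

  s1 <- paste(rep("A", 100), collapse = "")
  s2 <- paste(c(rep("A", 99), "C"), collapse = "")
  expect_equal(nucleotide_diversity(c(s1, s2)), 0.01)

  set.seed(91)
  for (k in 1:20) {
    n <- sample(3:8, 1)
    L <- sample(20:60, 1)
    base <- rand_dna(L)
    seqs <- vapply(seq_len(n), function(i) {
      s <- base
      for (t in seq_len(sample(0:4, 1))) {
        p <- sample(L, 1)
        substr(s, p, p) <- sample(c("A", "C", "G", "T", "N"), 1)
      }
      s
    }, "")
    expect_equal(nucleotide_diversity(seqs), oracle_pi(seqs),
                 tolerance = 1e-12)
  }
})

test_that("per-site pi matches its closed form and the sequence version", {
  expect_equal(site_pi(10, 0), 0)
  expect_equal(site_pi(4, 1), 0.5)
  expect_equal(site_pi(4, 2), 2 / 3)
  expect_error(site_pi(1, 0), ">= 2")
  expect_error(site_pi(4, 5), "alt_count")

  # consistency: one segregating site on haploid sequences
  set.seed(5)
  for (k in 1:10) {
    n <- sample(3:12, 1)
    j <- sample(0:n, 1)
    seqs <- paste0("AC", c(rep("G", n - j), rep("T", j)), "CA")
    expect_equal(nucleotide_diversity(seqs) * 5, site_pi(n, j),
                 tolerance = 1e-12)
  }
})

test_that("haplotype statistics match their closed forms", {
  all_same <- haplotype_stats(rep("AAAA", 4))
  expect_equal(all_same$n_hap, 1L)
  expect_equal(all_same$H, 0)

  two_by_two <- haplotype_stats(c("AAAA", "AAAA", "CCCC", "CCCC"))
  expect_equal(two_by_two$n_hap, 2L)
  expect_equal(two_by_two$H, 2 / 3)

  distinct <- haplotype_stats(c("AAAA", "CCCC", "GGGG", "TTTT", "ACGT"))
  expect_equal(distinct$H, 1)

  set.seed(8)
  for (k in 1:10) {
    seqs <- sample(c("AAA", "AAC", "ACC", "CCC"), sample(4:20, 1), TRUE)
    h <- haplotype_stats(seqs)
    expect_equal(h$H, oracle_hap_div(seqs), tolerance = 1e-12)
    expect_lte(h$n_hap, length(seqs))
  }

  # N-containing sequences are excluded by default, not collapsed
  h <- haplotype_stats(c("AAAA", "AAAA", "AANA"))
  expect_equal(h$n_seq, 2L)
  expect_equal(h$n_hap, 1L)
})

test_that("LD r-squared behaves as squared Pearson correlation", {
  # identical dosage vectors across 71 samples -> exactly 1
  d <- rep(0, 71); d[c(10, 42)] <- 1
  m <- cbind(v1 = d, v2 = d)
  r2 <- ld_r2(m)
  expect_identical(r2[1, 2], 1)

  # perfect anti-correlation is also r^2 = 1
  m2 <- cbind(a = c(0, 1, 2, 1, 0), b = c(2, 1, 0, 1, 2))
  expect_equal(ld_r2(m2)[1, 2], 1)

  # monomorphic -> undefined
  m3 <- cbind(a = c(1, 1, 1, 1), b = c(0, 1, 2, 1))
  expect_true(is.na(ld_r2(m3)[1, 2]))

  # symmetry, range, allele-label swap invariance
  set.seed(12)
  m4 <- matrix(sample(c(0, 1, 2, NA), 60, TRUE, c(.4, .3, .2, .1)), 20, 3)
  colnames(m4) <- paste0("v", 1:3)
  r <- ld_r2(m4)
  expect_equal(r, t(r))
  expect_true(all(r >= -1e-12 & r <= 1 + 1e-12, na.rm = TRUE))
  m5 <- m4; m5[, 2] <- 2 - m5[, 2]
  expect_equal(ld_r2(m5), r)
})

test_that("Weir-Cockerham Fst hits its limits and the formula oracle", {
  # fixed difference -> exactly 1
  fixed <- fst_wc(list(n = 40, alt = 40), list(n = 40, alt = 0))
  expect_identical(fixed$fst, 1)

  # identical frequencies, equal sizes: the unbiased estimator sits at
  # -1/(n_bar - 1), within [-eps, 1]
  same <- fst_wc(list(n = 40, alt = 10), list(n = 40, alt = 10))
  expect_equal(same$fst, -1 / 39, tolerance = 1e-12)
  expect_gte(same$fst, -1 / 39 - 1e-12)
  expect_lte(same$fst, 1)

  # hand-evaluated estimator: A 10/40, B 30/40
  n1 <- 40; j1 <- 10; n2 <- 40; j2 <- 30
  p1 <- j1 / n1; p2 <- j2 / n2
  nbar <- (n1 + n2) / 2
  nc <- (n1 + n2) - (n1^2 + n2^2) / (n1 + n2)
  pbar <- (n1 * p1 + n2 * p2) / (n1 + n2)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / nbar
  a <- (nbar / nc) * (s2 - (pbar * (1 - pbar) - s2 / 2) / (nbar - 1))
  b <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) - s2 / 2)
  res <- fst_wc(list(n = 40, alt = 10), list(n = 40, alt = 30))
  expect_equal(res$fst, a / (a + b), tolerance = 1e-12)
  expect_gt(res$fst, 0)

  # mean is the ratio of summed components; undefined sites skipped
  multi <- fst_wc(list(n = c(40, 40, 40), alt = c(40, 10, 0)),
                  list(n = c(40, 40, 40), alt = c(0, 30, 0)))
  expect_true(is.na(multi$fst[3]))
  expect_equal(attr(multi, "mean_fst"),
               sum(multi$a[1:2]) / sum(multi$a[1:2] + multi$b[1:2]))
  expect_true(all(multi$fst >= -0.05 & multi$fst <= 1, na.rm = TRUE))
})

test_that("the minimum-spanning network contains an MST plus tie edges", {
  one <- min_spanning_network("ACGT")
  expect_equal(nrow(one$nodes), 1L)
  expect_equal(nrow(one$edges), 0L)

  # chain: A-B 1, B-C 1, A-C 2 -> two tree edges, the long edge excluded
  chain <- min_spanning_network(c("AAAA", "AAAC", "AACC"))
  expect_equal(sum(chain$edges$in_mst), 2L)
  expect_equal(nrow(chain$edges), 2L)
  expect_true(all(chain$edges$dist == 1))

  # square: four haplotypes, adjacent distances 1 -> 3 tree + 1 tie edge
  sq <- min_spanning_network(c("AA", "AC", "CC", "CA"))
  expect_equal(sum(sq$edges$in_mst), 3L)
  expect_equal(sum(sq$edges$tie_edge), 1L)
  expect_true(all(sq$edges$dist == 1))

  # property: tree edges form a spanning tree of minimum total weight
  set.seed(33)
  for (k in 1:12) {
    n <- sample(3:6, 1)
    seqs <- unique(vapply(seq_len(n), function(i) rand_dna(6), ""))
    net <- min_spanning_network(seqs)
    tree <- net$edges[net$edges$in_mst, ]
    expect_equal(nrow(tree), length(seqs) - 1L)
    g <- igraph::graph_from_data_frame(tree[, c("from", "to")],
                                       directed = FALSE,
                                       vertices = net$nodes$id)
    expect_true(igraph::is_connected(g))
    # exhaustive spanning-tree enumeration gives the same minimum weight
    m <- do.call(rbind, strsplit(seqs, ""))
    d2 <- matrix(0L, length(seqs), length(seqs))
    for (i in seq_along(seqs)) for (j in seq_along(seqs))
      d2[i, j] <- sum(m[i, ] != m[j, ])
    expect_equal(sum(tree$dist), oracle_min_spanning_weight(d2))
    # every tie edge closes a cycle whose tree path has equal maximum
    expect_true(all(net$edges$dist[net$edges$tie_edge] >= 1))
  }
})

test_that("species are assigned by percent identity with a threshold", {
  set.seed(55)
  fun_ref <- rand_dna(300)
  gam_ref <- fun_ref
  for (p in c(30, 90, 150, 210, 270)) {
    substr(gam_ref, p, p) <-
      setdiff(c("A", "C", "G", "T"), substr(gam_ref, p, p))[1]
  }
  refs <- c(`An. funestus` = fun_ref, `An. gambiae` = gam_ref)

  exact <- identify_species(fun_ref, refs)
  expect_equal(exact$species, "An. funestus")
  expect_equal(exact$identity, 1)

  # consensus 3 mismatches from funestus, 0 from gambiae
  q <- gam_ref
  res <- identify_species(q, refs)
  expect_equal(res$species, "An. gambiae")
  expect_equal(res$identity, 1)
  ids <- attr(res, "identities")
  expect_equal(ids$identity[ids$species == "An. funestus"], 295 / 300)

  # below the threshold the call is unresolved
  noisy <- rand_dna(300)
  un <- identify_species(noisy, refs, threshold = 0.97)
  expect_false(un$resolved)
  expect_true(is.na(un$species))

  # N positions are excluded from the comparison
  masked <- paste0(strrep("N", 50), substr(fun_ref, 51, 300))
  resN <- identify_species(masked, refs)
  expect_equal(resN$species, "An. funestus")
  expect_equal(resN$identity, 1)
})
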