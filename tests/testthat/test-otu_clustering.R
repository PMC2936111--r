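test_that("dereplication conserves counts and groups exact duplicates", {
  seqs <- c(rep("AAAACCCC", 5), rep("GGGGTTTT", 3), "ACACACAC")
  tags <- mk_tags(seqs, samples = rep(c("S1", "S2", "S1"), c(4, 4, 1)))
  u <- dereplicate(tags)
  expect_equal(nrow(u$useqs), 3L)
  expect_equal(sort(u$useqs$weight, decreasing = TRUE), c(5L, 3L, 1L))
  expect_equal(sum(u$useqs$weight), nrow(tags))
  expect_equal(sum(u$counts), nrow(tags))
  expect_equal(colnames(u$counts), c("S1", "S2"))

  distinct <- mk_tags(c("AAAA", "CCCC", "GGGG"))
  expect_equal(dereplicate(distinct)$useqs$weight, rep(1L, 3))
  expect_equal(nrow(dereplicate(mk_tags(character(0)))$useqs), 0L)
})

test_that("gap-aware p follows the single-event gap rule", {
  expect_equal(gap_aware_p("ACGT--ACGT", "ACGTTTACGT"), 1 / 9)
  expect_equal(gap_aware_p("ACGTACGT--", "ACGTACGTTT"), 0)
  expect_equal(gap_aware_p("ACGTACGT", "ACGTACGT"), 0)
  # symmetry and range on random gapped rows, against the R oracle
  set.seed(8)
  alpha <- c("A", "C", "G", "T", "-")
  for (k in 1:50) {
    L <- sample(10:40, 1)
    a <- paste(sample(alpha, L, replace = TRUE, prob = c(2, 2, 2, 2, 1)),
               collapse = "")
    b <- paste(sample(alpha, L, replace = TRUE, prob = c(2, 2, 2, 2, 1)),
               collapse = "")
    want <- oracle_gap_p(a, b)
    if (is.na(want)) {
      expect_error(gap_aware_p(a, b), "incomparable")
    } else {
      p <- gap_aware_p(a, b)
      expect_equal(p, want)
      expect_equal(gap_aware_p(b, a), p)
      expect_gte(p, 0); expect_lte(p, 1)
    }
  }
})

test_that("Jukes-Cantor correction matches the closed form and saturates", {
  expect_equal(jukes_cantor(0), 0)
  expect_equal(jukes_cantor(0.1), -0.75 * log(1 - 0.4 / 3))
  expect_equal(jukes_cantor(0.1), 0.107326, tolerance = 1e-5)
  expect_lt(jukes_cantor(0.74), 5)
  expect_warning(d <- jukes_cantor(0.75), "saturation")
  expect_equal(d, 5)
})

test_that("distance matrix is symmetric and matches per-pair closed form", {
  u <- c(A = "ACGTACGTACGTACGTACGT", B = "ACGTACGTACGTACGTACGA",
         C = "ACGTACGAACGTACGAACGT")
  m <- distance_matrix(u)
  expect_equal(m, t(m))
  expect_equal(diag(m), c(A = 0, B = 0, C = 0))
  aln <- star_align(u)
  for (i in names(u)) for (j in names(u)) {
    if (i == j) next
    expect_equal(m[i, j], jukes_cantor(gap_aware_p(aln[[i]], aln[[j]])))
  }
  ident <- distance_matrix(c(x = "ACGT", y = "ACGT"))
  expect_equal(unname(ident), matrix(0, 2, 2))
})

test_that("star alignment preserves sequences and aligns relatives", {
  set.seed(14)
  center <- rnd_dna(60)
  seqs <- c(u1 = center,
            u2 = mut_n(center, 2),
            u3 = paste0(substr(center, 1, 30), "ACGT", substr(center, 31, 60)),
            u4 = substr(center, 5, 55))
  aln <- star_align(seqs)
  expect_length(unique(nchar(aln)), 1L)
  expect_equal(unname(gsub("-", "", aln)), unname(seqs))
  expect_equal(gap_aware_p(aln[["u1"]], aln[["u4"]]), 0)  # nested fragment
})

test_that("furthest-neighbour clustering satisfies the complete-linkage rule", {
  m <- matrix(c(0, .02, .06, .02, 0, .08, .06, .08, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  parts <- cluster_furthest_neighbor(m, c(0.05, 0.10))
  expect_equal(unname(lapply(parts[[1]]$clusters, sort)),
               list(c("A", "B"), "C"))
  expect_length(parts[[2]]$clusters, 1L)  # C joins once max(.06,.08) <= .10

  zero <- cluster_furthest_neighbor(m, 0)[[1]]
  expect_length(zero$clusters, 3L)
})

test_that("clustering matches independent oracles on random matrices", {
  set.seed(77)
  for (rep in 1:15) {
    n <- sample(4:25, 1)
    d <- matrix(0, n, n)
    d[upper.tri(d)] <- runif(n * (n - 1) / 2, 0, 0.3)
    d <- d + t(d)
    labels <- sprintf("u%02d", 1:n)
    dimnames(d) <- list(labels, labels)
    cut <- runif(1, 0.02, 0.25)
    mine <- partition_from_otu(
      cluster_furthest_neighbor(d, cut)[[1]], labels)
    brute <- canon_partition(oracle_complete_linkage(d, cut))
    expect_equal(mine, brute)
    hc <- stats::cutree(stats::hclust(stats::as.dist(d), "complete"), h = cut)
    expect_equal(mine, canon_partition(unname(split(seq_len(n), hc))))
  }
})

test_that("OTU counts are non-increasing in the distance cutoff", {
  set.seed(99)
  n <- 30
  d <- matrix(0, n, n)
  d[upper.tri(d)] <- runif(n * (n - 1) / 2, 0, 0.4)
  d <- d + t(d)
  dimnames(d) <- list(sprintf("u%02d", 1:n), sprintf("u%02d", 1:n))
  cuts <- c(0, 0.05, 0.1, 0.2, 0.3, 0.5)
  sizes <- vapply(cluster_furthest_neighbor(d, cuts),
                  function(p) length(p$clusters), 0L)
  expect_true(all(diff(sizes) <= 0))
})

test_that("expand_to_table conserves abundances and picks representatives", {
  tags <- mk_tags(c(rep("AAAACCCCGGGG", 5), rep("AAAACCCCGGGA", 3),
                    rep("TTTTTTTTGGGG", 2)),
                  samples = c(rep("S1", 5), rep("S2", 3), rep("S1", 2)))
  u <- dereplicate(tags)
  # the far-out TTTT... sequence saturates the JC correction (documented cap)
  m <- suppressWarnings(distance_matrix(u))
  part <- cluster_furthest_neighbor(
    m, 0.15, weights = setNames(u$useqs$weight, u$useqs$useq_id))[[1]]
  tab <- expand_to_table(part, u)
  expect_equal(sum(tab), nrow(tags))
  expect_equal(colSums(tab), c(S1 = 7, S2 = 3))
  # the first OTU merges the two near-identical sequences; its
  # representative is the highest-weight member
  expect_equal(unname(attr(tab, "representatives")[1]), "AAAACCCCGGGG")

  single <- cluster_furthest_neighbor(m, 0)[[1]]
  tab0 <- expand_to_table(single, u)
  expect_equal(sort(rowSums(tab0), decreasing = TRUE),
               sort(u$useqs$weight, decreasing = TRUE),
               ignore_attr = "names")
})
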