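test_that("pairwise similarity matches its definition on forced cases", {
  s <- rnd_dna(60)
  expect_equal(pairwise_similarity(s, s), 1.0)

  set.seed(4)
  b <- mut_n(s, 6)  # 6 substitutions among 60 aligned positions
  expect_equal(pairwise_similarity(s, b), 0.9)

  ref <- rnd_dna(1000)
  tag <- substr(ref, 401, 460)  # internal window; terminal gaps free
  expect_equal(pairwise_similarity(tag, ref), 1.0)
})

test_that("aligner agrees with Biostrings on both gap conventions", {
  skip_if_not_installed("Biostrings")
  set.seed(11)
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                  baseOnly = TRUE)
  for (k in 1:40) {
    ref <- rnd_dna(sample(100:200, 1))
    st <- sample(1:100, 1)
    w <- strsplit(substr(ref, st, min(nchar(ref), st + sample(39:59, 1))),
                  "", fixed = TRUE)[[1]]
    for (i in which(runif(length(w)) < 0.08))
      w[i] <- sample(setdiff(c("A", "C", "G", "T"), w[i]), 1)
    if (runif(1) < 0.3) w <- w[-sample(length(w), 1)]  # indel
    tag <- paste(w, collapse = "")
    for (mode in c(TRUE, FALSE)) {
      type <- if (mode) "global-local" else "overlap"
      expect_equal(
        align_free_end(tag, ref, a_global = mode)$score,
        Biostrings::score(Biostrings::pairwiseAlignment(
          Biostrings::DNAString(tag), Biostrings::DNAString(ref),
          type = type, substitutionMatrix = mat,
          gapOpening = 2, gapExtension = 1)),
        info = paste("mode", type))
    }
  }
})

test_that("candidate search is exhaustive, sorted, and deterministic on ties", {
  db <- mk_refdb(paste0("R", 1:5),
                 c("ACGTACGTACGTACGTACGT", "ACGTACGTACGTACGTACGA",
                   "TTTTTTTTTTGGGGGGGGGG", "ACGTACGTACGTACGTACGT",
                   "CCCCACGTACGTACGTCCCC"),
                 phylum = paste0("P", 1:5))
  tag <- "ACGTACGTACGTACGTACGT"
  hits <- find_candidates(tag, db, n_hits = 100)
  expect_equal(nrow(hits), 5L)  # fewer refs than n_hits
  expect_equal(hits$similarity, sort(hits$similarity, decreasing = TRUE))
  # R1 and R4 are identical references: tie broken by ref_id
  expect_equal(hits$ref_id[1:2], c("R1", "R4"))
  expect_equal(hits$similarity[1:2], c(1, 1))
  expect_equal(find_candidates(tag, db, n_hits = 2)$ref_id, c("R1", "R4"))
  expect_error(find_candidates(tag, db[0, ]), "empty")
})

test_that("k-mer prefiltered search equals the exhaustive scan", {
  set.seed(21)
  base <- rnd_dna(80)
  db <- mk_refdb(sprintf("R%03d", 1:60),
                 vapply(1:60, function(i) mut_n(base, sample(0:25, 1)), ""),
                 phylum = rep(paste0("P", 1:6), each = 10))
  tag <- mut_n(substr(base, 11, 70), 2)
  a <- find_candidates(tag, db, prefilter = TRUE, prefilter_keep = 20L)
  b <- find_candidates(tag, db, prefilter = FALSE)
  # prefilter keeps fewer refs; the returned top hits must coincide
  expect_equal(a$ref_id[1:10], b$ref_id[1:10])
  expect_equal(a$similarity[1:10], b$similarity[1:10])
})

test_that("nearest-set selection implements the 0.1% divergence window", {
  hits <- data.frame(ref_id = c("a", "b", "c"),
                     similarity = c(0.970, 0.9695, 0.950))
  expect_equal(select_nearest_set(hits)$ref_id, c("a", "b"))
  expect_equal(nrow(select_nearest_set(hits[1, ])), 1L)
  same <- data.frame(ref_id = letters[1:4], similarity = rep(0.9, 4))
  expect_equal(nrow(select_nearest_set(same)), 4L)
})

test_that("majority-rule taxonomy follows the rank thresholds and 60% rule", {
  db <- mk_refdb(c("r1", "r2", "r3"), rep("ACGT", 3),
                 phylum = rep("Chloroflexi", 3),
                 class = c("Anaerolineae", "Anaerolineae", "SAR202"),
                 order = c("O1", "O2", "O3"))
  nearest <- data.frame(ref_id = c("r1", "r2", "r3"),
                        similarity = c(0.86, 0.86, 0.86))
  res <- assign_taxonomy(nearest, db)
  expect_equal(unname(res$labels[c("phylum", "class", "order")]),
               c("Chloroflexi", "Anaerolineae", ""))
  expect_equal(res$status, "assigned")

  low <- data.frame(ref_id = "r1", similarity = 0.74)
  res <- assign_taxonomy(low, db)
  expect_true(all(res$labels == ""))
  expect_equal(res$status, "unassigned_low_similarity")

  full_db <- mk_refdb("q1", "ACGT", "P", "C", "O", "F", "G")
  res <- assign_taxonomy(data.frame(ref_id = "q1", similarity = 1.0), full_db)
  expect_equal(unname(res$labels), c("P", "C", "O", "F", "G"))
})

test_that("cluster assignment needs 75% similarity and a 60% majority", {
  db <- mk_refdb(c("r1", "r2", "r3"), rep("ACGT", 3), phylum = rep("P", 3),
                 cluster = c("SC70", "SC70", "SC72"))
  two <- data.frame(ref_id = c("r1", "r2"), similarity = c(0.96, 0.96))
  expect_equal(assign_cluster(two, db), "SC70")

  db2 <- mk_refdb(c("r1", "r2", "r3"), rep("ACGT", 3), phylum = rep("P", 3),
                  cluster = c("SC70", "SC72", NA))
  three <- data.frame(ref_id = c("r1", "r2", "r3"), similarity = rep(0.9, 3))
  expect_true(is.na(assign_cluster(three, db2)))  # 1/3 < 60%

  low <- data.frame(ref_id = c("r1", "r2"), similarity = c(0.70, 0.70))
  expect_true(is.na(assign_cluster(low, db)))
})

test_that("assignments are prefix-complete and monotone in thresholds", {
  set.seed(31)
  ranks <- c("phylum", "class", "order", "family", "genus")
  for (rep in 1:30) {
    n <- sample(1:6, 1)
    db <- mk_refdb(sprintf("x%d", 1:n), replicate(n, rnd_dna(8)),
                   phylum = sample(c("P1", "P2"), n, replace = TRUE),
                   class = sample(c("C1", "C2", ""), n, replace = TRUE),
                   order = sample(c("O1", ""), n, replace = TRUE))
    db$tax_class[db$tax_order != "" & db$tax_class == ""] <- "C1"
    db <- validate_reference_db(db)
    nearest <- data.frame(ref_id = db$ref_id,
                          similarity = rep(runif(1, 0.7, 1), n))
    res <- assign_taxonomy(nearest, db)
    lab <- res$labels
    filled <- lab != ""
    expect_false(any(diff(as.integer(filled)) > 0))  # prefix-complete
    # raising a rank threshold never gains an assignment at that rank
    for (r in ranks) {
      args <- setNames(list(min(1, unclass(assignment_thresholds())[[r]] + 0.03)), r)
      th2 <- tryCatch(do.call(assignment_thresholds, args),
                      error = function(e) NULL)
      if (is.null(th2)) next
      res2 <- assign_taxonomy(nearest, db, th2)
      expect_false(res2$labels[[r]] != "" && lab[[r]] == "")
    }
  }
})

test_that("assign_tags equals the per-tag procedure and propagates duplicates", {
  set.seed(5)
  base <- rnd_dna(70)
  db <- mk_refdb(c("R1", "R2"), c(base, mut_n(base, 20)),
                 phylum = c("P1", "P2"), class = c("C1", "C2"),
                 order = c("O1", "O2"), family = c("F1", "F2"),
                 genus = c("G1", "G2"), cluster = c("SC01", NA))
  tagseq <- substr(base, 6, 62)
  tags <- mk_tags(c(tagseq, tagseq, mut_n(tagseq, 1)),
                  samples = c("S1", "S2", "S1"))
  res <- assign_tags(tags, db)
  expect_equal(nrow(res), 3L)
  expect_equal(res$genus, rep("G1", 3))
  expect_equal(res$cluster, rep("SC01", 3))
  expect_equal(res$best_similarity[1], res$best_similarity[2])
  one <- assign_taxonomy(select_nearest_set(find_candidates(tagseq, db)), db)
  expect_equal(res$best_similarity[1], one$best_similarity)
  expect_equal(res$status[1], one$status)
})
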