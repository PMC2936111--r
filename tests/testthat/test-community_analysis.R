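mk_manifest <- function() {
  validate_manifest(data.frame(
    sample_id = c("a1", "a2", "l1", "w1", "w2"),
    group = c("adult", "adult", "larvae", "seawater", "seawater"),
    species = c("sp1", "sp1", "sp1", "", ""),
    replicate = c(1L, 2L, 1L, 1L, 2L), stringsAsFactors = FALSE))
}

mk_assignments <- function(sample_id, genus = "", cluster = NA_character_,
                           n = 1L) {
  do.call(rbind, lapply(seq_len(n), function(i) data.frame(
    tag_id = paste0(sample_id, "_", genus, "_", cluster, "_", i,
                    "_", sample(1e6, 1)),
    sample_id = sample_id, best_similarity = 0.96, nearest_set_size = 1L,
    phylum = ifelse(genus == "", "", "P"), class = ifelse(genus == "", "", "C"),
    order = ifelse(genus == "", "", "O"), family = ifelse(genus == "", "", "F"),
    genus = genus, cluster = cluster, status = ifelse(genus == "",
      "unassigned_low_similarity", "assigned"), stringsAsFactors = FALSE)))
}

test_that("taxon profiles express tag proportions in percent", {
  asn <- rbind(mk_assignments("a1", "G", n = 49),
               mk_assignments("a1", "H", n = 41),
               mk_assignments("a1", "", n = 10))
  prof <- taxon_profiles(asn, mk_manifest(), rank = "genus")
  expect_equal(prof$profiles["a1", "G"], 49)  # 49 of 100 tags
  expect_equal(prof$profiles["a1", "H"], 41)
  expect_equal(unname(prof$unassigned["a1"]), 10)
  expect_equal(sum(prof$profiles["a1", ]) + prof$unassigned[["a1"]], 100)

  none <- mk_assignments("a1", "", n = 5)
  p0 <- taxon_profiles(none, mk_manifest(), rank = "genus")
  expect_equal(ncol(p0$profiles), 0L)
  expect_equal(unname(p0$unassigned["a1"]), 100)

  basis <- taxon_profiles(asn, mk_manifest(), rank = "genus",
                          basis = "assigned_tags")
  expect_equal(basis$profiles["a1", "G"], 100 * 49 / 90)
})

test_that("Bray-Curtis similarity follows its closed form", {
  m <- rbind(x = c(60, 40), y = c(40, 60))
  colnames(m) <- c("t1", "t2")
  bc <- bray_curtis_matrix(m)
  expect_equal(bc["x", "y"], 80)
  expect_equal(diag(bc), c(x = 100, y = 100))
  expect_equal(bc, t(bc))

  ident <- rbind(a = c(50, 50), b = c(50, 50))
  expect_equal(bray_curtis_matrix(ident)["a", "b"], 100)
  disjoint <- rbind(a = c(100, 0), b = c(0, 100))
  expect_equal(bray_curtis_matrix(disjoint)["a", "b"], 0)
  zero <- rbind(a = c(0, 0), b = c(0, 0))
  expect_error(bray_curtis_matrix(zero), "all-zero")
})

test_that("Bray-Curtis agrees with vegan on random profiles", {
  skip_if_not_installed("vegan")
  set.seed(23)
  m <- matrix(runif(5 * 8, 0, 20), 5, 8,
              dimnames = list(paste0("s", 1:5), paste0("t", 1:8)))
  bc <- bray_curtis_matrix(m)
  vd <- as.matrix(vegan::vegdist(m, method = "bray"))
  expect_equal(bc / 100, 1 - vd, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("cluster occurrence counts tags and group fractions", {
  asn <- rbind(mk_assignments("a1", "G", cluster = "SC1", n = 5),
               mk_assignments("a2", "G", cluster = "SC1", n = 3),
               mk_assignments("a2", "G", n = 2),
               mk_assignments("w1", "G", n = 4))
  occ <- cluster_occurrence(asn, mk_manifest())
  expect_equal(unname(occ$counts["SC1", c("a1", "a2", "w1")]), c(5L, 3L, 0L))
  expect_equal(unname(occ$group_fraction["adult"]), 8 / 10)
  expect_equal(unname(occ$group_fraction["seawater"]), 0)

  empty <- cluster_occurrence(mk_assignments("a1", "G", n = 3), mk_manifest())
  expect_equal(nrow(empty$counts), 0L)
})

test_that("transmission calls implement the detection rule", {
  asn <- rbind(mk_assignments("a1", "G", cluster = "SC1", n = 5),
               mk_assignments("a2", "G", cluster = "SC1", n = 3),
               mk_assignments("l1", "G", cluster = "SC1", n = 2),
               mk_assignments("a1", "G", cluster = "SC2", n = 4),
               mk_assignments("w1", "G", cluster = "SC2", n = 1))
  occ <- cluster_occurrence(asn, mk_manifest())
  calls <- classify_transmission(occ)
  expect_equal(calls$call[calls$cluster == "SC1"], "sponge_exclusive")
  # a single tag in a single seawater replicate counts as detection
  expect_equal(calls$call[calls$cluster == "SC2"], "also_in_seawater")
  s <- attr(calls, "summary")
  expect_equal(s$n_detected, 2L)
  expect_equal(s$n_also_in_seawater, 1L)
  expect_equal(s$pct_exclusive, 50)

  strict <- classify_transmission(occ, min_count = 2L)
  expect_equal(strict$call[strict$cluster == "SC2"], "sponge_exclusive")
})

test_that("a designed 16-of-33 exclusive matrix reports 48.48%", {
  n_cl <- 33L
  rows <- list()
  for (i in seq_len(n_cl)) {
    rows[[length(rows) + 1L]] <-
      mk_assignments("a1", "G", cluster = sprintf("SC%02d", i), n = 2)
    if (i > 16L)  # 17 clusters also appear in seawater
      rows[[length(rows) + 1L]] <-
        mk_assignments("w2", "G", cluster = sprintf("SC%02d", i), n = 1)
  }
  occ <- cluster_occurrence(do.call(rbind, rows), mk_manifest())
  s <- attr(classify_transmission(occ), "summary")
  expect_equal(s$n_detected, 33L)
  expect_equal(s$n_also_in_seawater, 17L)
  expect_equal(s$pct_exclusive, 100 * 16 / 33)
  expect_equal(s$pct_exclusive, 48.48, tolerance = 1e-3)
})

test_that("transmission summary counts are always consistent", {
  set.seed(41)
  for (rep in 1:10) {
    rows <- list()
    for (i in 1:8) {
      for (s in sample(c("a1", "a2", "l1", "w1", "w2"), sample(1:4, 1))) {
        rows[[length(rows) + 1L]] <-
          mk_assignments(s, "G", cluster = paste0("SC", i),
                         n = sample(1:3, 1))
      }
    }
    occ <- cluster_occurrence(do.call(rbind, rows), mk_manifest())
    calls <- classify_transmission(occ)
    s <- attr(calls, "summary")
    expect_equal(s$n_detected, nrow(calls))
    expect_equal(sum(calls$call == "sponge_exclusive") +
                   s$n_also_in_seawater, s$n_detected)
    expect_equal(calls$call == "sponge_exclusive", !calls$in_seawater)
  }
})
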