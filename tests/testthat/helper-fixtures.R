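# Shared fixtures and independent oracle implementations.

rnd_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

mk_tags <- function(seqs, samples = "S1", ids = NULL) {
  samples <- rep_len(samples, length(seqs))
  ids <- ids %||% sprintf("t%03d", seq_along(seqs))
  spongetag:::new_tag_set(data.frame(
    tag_id = ids, sample_id = samples, sequence = seqs,
    length = nchar(seqs), stringsAsFactors = FALSE))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Hand-buildable reference db rows (taxonomy as plain columns).
mk_refdb <- function(ref_id, sequence, phylum, class = "", order = "",
                     family = "", genus = "", cluster = NA_character_) {
  validate_reference_db(data.frame(
    ref_id = ref_id, sequence = sequence, cluster_label = cluster,
    tax_phylum = phylum, tax_class = class, tax_order = order,
    tax_family = family, tax_genus = genus, stringsAsFactors = FALSE))
}

# Mutate a sequence with exactly n substitutions.
mut_n <- function(s, n) {
  ch <- strsplit(s, "", fixed = TRUE)[[1L]]
  for (i in sample(length(ch), n)) {
    ch[i] <- sample(setdiff(c("A", "C", "G", "T"), ch[i]), 1L)
  }
  paste(ch, collapse = "")
}

# Independent pure-R implementation of the gap-aware mismatch fraction
# (used as the oracle for the C++ kernel).
oracle_gap_p <- function(a, b) {
  A <- strsplit(a, "", fixed = TRUE)[[1L]]
  B <- strsplit(b, "", fixed = TRUE)[[1L]]
  nzA <- which(A != "-"); nzB <- which(B != "-")
  if (!length(nzA) || !length(nzB)) return(NA_real_)
  lo <- max(min(nzA), min(nzB)); hi <- min(max(nzA), max(nzB))
  if (lo > hi) return(NA_real_)
  ev <- 0L; df <- 0L; run_a <- FALSE; run_b <- FALSE
  for (t in lo:hi) {
    x <- A[t]; y <- B[t]
    if (x == "-" && y == "-") next
    if (x == "-") {
      if (!run_a) { ev <- ev + 1L; df <- df + 1L; run_a <- TRUE }
      run_b <- FALSE
    } else if (y == "-") {
      if (!run_b) { ev <- ev + 1L; df <- df + 1L; run_b <- TRUE }
      run_a <- FALSE
    } else {
      run_a <- FALSE; run_b <- FALSE
      if (x %in% c("A", "C", "G", "T") && y %in% c("A", "C", "G", "T")) {
        ev <- ev + 1L
        if (x != y) df <- df + 1L
      }
    }
  }
  if (ev == 0L) return(NA_real_)
  df / ev
}

# Brute-force furthest-neighbour partition at one cutoff: repeatedly merge
# the pair of clusters with the smallest complete-linkage distance while it
# does not exceed the cutoff. Independent of the package's implementation.
oracle_complete_linkage <- function(D, cutoff) {
  clusters <- as.list(seq_len(nrow(D)))
  repeat {
    if (length(clusters) == 1L) break
    best <- Inf; bi <- 0L; bj <- 0L
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)[-seq_len(i)]) {
        d <- max(D[clusters[[i]], clusters[[j]]])
        if (d < best) { best <- d; bi <- i; bj <- j }
      }
    }
    if (best > cutoff) break
    clusters[[bi]] <- c(clusters[[bi]], clusters[[bj]])
    clusters[[bj]] <- NULL
  }
  clusters
}

# canonical form of a partition for comparison
canon_partition <- function(clusters) {
  cl <- unname(lapply(clusters, function(x) sort(x)))
  cl[order(vapply(cl, `[`, cl[[1]][1], 1L))]
}

partition_from_otu <- function(part, labels) {
  canon_partition(lapply(part$clusters, function(mem) match(mem, labels)))
}

# Default synthetic scenario + full pipeline run, computed once and shared
# between the acceptance tests (it is the expensive fixture).
.scn_cache <- new.env(parent = emptyenv())
default_scenario_run <- function() {
  if (!is.null(.scn_cache$run)) return(.scn_cache$run)
  scn <- build_scenario(scenario_spec(seed = 1L))
  dir <- file.path(tempdir(), "spongetag-default-scn")
  write_scenario(scn, dir)
  cfg <- run_config(manifest = file.path(dir, "manifest.tsv"),
                    refdb = file.path(dir, "refdb.tsv"),
                    out_dir = file.path(tempdir(), "spongetag-default-run"))
  res <- suppressMessages(run_pipeline(cfg))
  .scn_cache$run <- list(scn = scn, res = res)
  .scn_cache$run
}
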