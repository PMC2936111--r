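#' Rank-specific similarity thresholds for taxonomic assignment
#'
#' A tag is only assigned at a rank if the similarity to its most similar
#' reference(s) reaches that rank's threshold: 95% for genus, 90% family,
#' 85% order, 80% class, 75% phylum, and 75% for sponge-specific (or
#' sponge-coral-specific) sequence clusters. Comparisons are inclusive
#' (>=). References within `nearest_window` (0.1% sequence divergence) of
#' the best hit form the nearest set; a label is adopted only when at least
#' `majority` (60%) of all nearest-set members share it.
#'
#' @param genus,family,order,class,phylum per-rank similarity thresholds.
#' @param cluster similarity threshold for cluster assignment.
#' @param majority fraction of the nearest set that must share a label.
#' @param nearest_window divergence window (on 1 - similarity) defining the
#'   nearest set relative to the best hit.
#' @return a list of class `assignment_thresholds`.
#' @export
assignment_thresholds <- function(genus = 0.95, family = 0.90, order = 0.85,
                                  class = 0.80, phylum = 0.75,
                                  cluster = 0.75, majority = 0.60,
                                  nearest_window = 0.001) {
  th <- list(genus = genus, family = family, order = order, class = class,
             phylum = phylum, cluster = cluster, majority = majority,
             nearest_window = nearest_window)
  ranks <- unlist(th[TAX_RANKS])  # phylum..genus must be non-decreasing
  if (any(diff(ranks) < 0))
    stop("rank thresholds must satisfy genus >= family >= order >= class >= phylum")
  if (majority <= 0 || majority > 1) stop("majority must be in (0, 1]")
  class(th) <- "assignment_thresholds"
  th
}

#' Similarity between two sequences (free-end-gap alignment)
#'
#' Globally aligns two sequences with terminal gaps free (a short tag is a
#' fragment of a longer reference), then returns `1 - p` where `p` is the
#' gap-aware mismatch fraction of [gap_aware_p()]: terminal gaps ignored,
#' each internal gap run one difference. Alignment scoring: match +1,
#' mismatch -1, gap open -2, gap extend -1.
#'
#' @param a,b DNA sequences (character scalars).
#' @return similarity in `[0, 1]`.
#' @export
pairwise_similarity <- function(a, b) {
  stopifnot(nzchar(a), nzchar(b))
  al <- .cpp_align_free_end(a, b, TRUE)
  if (is.na(al$p)) return(0)
  1 - al$p
}

#' Align two sequences with free end gaps
#'
#' @inheritParams pairwise_similarity
#' @param a_global require all of `a` to be aligned (semi-global, the
#'   default: `a` is a fragment of `b`); with `FALSE` both sequences'
#'   terminal overhangs are free (ends-free overlap alignment).
#' @return list with aligned strings `a` and `b` (equal length, terminal
#'   overhangs as gaps), the alignment `score`, and the gap-aware `p`.
#' @export
align_free_end <- function(a, b, a_global = TRUE) {
  stopifnot(nzchar(a), nzchar(b))
  .cpp_align_free_end(a, b, a_global)
}

# Shared-k-mer counts of `tag` against each reference sequence.
kmer_counts <- function(tag, ref_seqs, k = 8L) {
  n <- nchar(tag)
  if (n < k) return(rep(0L, length(ref_seqs)))
  kmers <- unique(substring(tag, 1:(n - k + 1L), k:n))
  counts <- integer(length(ref_seqs))
  for (km in kmers) counts <- counts + grepl(km, ref_seqs, fixed = TRUE)
  counts
}

#' Find the most similar references for a tag
#'
#' Exhaustive semi-global comparison of the tag against every reference (an
#' in-process replacement for a blast search), optionally preceded by a
#' shared-k-mer prefilter that keeps the `prefilter_keep` references with
#' the most shared 8-mers before exact scoring. Hits are sorted by
#' similarity (descending), ties broken by `ref_id`.
#'
#' @param tag_seq tag sequence (character scalar).
#' @param db a `reference_db` data.frame.
#' @param n_hits number of hits returned (default 100; fewer if the
#'   database is smaller).
#' @param prefilter use the k-mer prefilter (identical results whenever the
#'   database has at most `prefilter_keep` sequences).
#' @param prefilter_k,prefilter_keep k-mer size and number kept.
#' @return data.frame `ref_id`, `similarity`, `rank_order`.
#' @export
find_candidates <- function(tag_seq, db, n_hits = 100L, prefilter = TRUE,
                            prefilter_k = 8L, prefilter_keep = 500L) {
  if (is.null(db) || nrow(db) == 0L) stop("reference database is empty")
  idx <- seq_len(nrow(db))
  if (prefilter && nrow(db) > prefilter_keep) {
    cnt <- kmer_counts(tag_seq, db$sequence, k = prefilter_k)
    ord <- order(-cnt, db$ref_id)
    idx <- sort(ord[seq_len(prefilter_keep)])
  }
  sim <- .cpp_similarity_batch(tag_seq, db$sequence[idx])
  sim[is.na(sim)] <- 0
  ord <- order(-sim, db$ref_id[idx])
  take <- ord[seq_len(min(n_hits, length(ord)))]
  data.frame(ref_id = db$ref_id[idx][take], similarity = sim[take],
             rank_order = seq_along(take), stringsAsFactors = FALSE)
}

#' Select the nearest set of hits
#'
#' Keeps every hit within `window` sequence divergence (default 0.1%) of
#' the most similar hit.
#'
#' @param hits data.frame from [find_candidates()] (sorted by similarity).
#' @param window divergence window.
#' @export
select_nearest_set <- function(hits, window = 0.001) {
  if (nrow(hits) == 0L) stop("empty hit list")
  best <- hits$similarity[1L]
  hits[best - hits$similarity <= window, , drop = FALSE]
}

#' Majority-rule taxonomic assignment from a nearest set
#'
#' Proceeds from phylum to genus. At each rank the tag is assigned label L
#' only if (i) the best similarity reaches the rank threshold, (ii) at
#' least the `majority` fraction of all nearest-set members carry L at that
#' rank (members unannotated at the rank count against the majority), and
#' (iii) those members' coarser ranks match the labels already assigned.
#' Assignment stops at the first failing rank, so results are always
#' prefix-complete.
#'
#' @param nearest data.frame from [select_nearest_set()].
#' @param db a `reference_db` data.frame.
#' @param th thresholds from [assignment_thresholds()].
#' @return list with `labels` (named character, phylum..genus, "" when not
#'   assigned), `best_similarity`, `nearest_set_size`, `status` (one of
#'   `assigned`, `unassigned_low_similarity`, `unassigned_no_majority`,
#'   `no_candidates`).
#' @export
assign_taxonomy <- function(nearest, db, th = assignment_thresholds()) {
  labels <- setNames(character(5), TAX_RANKS)
  if (is.null(nearest) || nrow(nearest) == 0L)
    return(list(labels = labels, best_similarity = NA_real_,
                nearest_set_size = 0L, status = "no_candidates"))
  best <- nearest$similarity[1L]
  n <- nrow(nearest)
  if (best < th$phylum)
    return(list(labels = labels, best_similarity = best,
                nearest_set_size = n, status = "unassigned_low_similarity"))
  ref <- db[match(nearest$ref_id, db$ref_id), , drop = FALSE]
  path_ok <- rep(TRUE, n)  # members consistent with the assigned prefix
  for (r in seq_along(TAX_RANKS)) {
    rank <- TAX_RANKS[r]
    if (best < th[[rank]]) break
    lab <- ref[[paste0("tax_", rank)]]
    cand <- lab[path_ok & lab != ""]
    if (length(cand) == 0L) break
    tab <- sort(table(cand), decreasing = TRUE)
    if (tab[1L] / n < th$majority) break
    win <- names(tab)[1L]
    labels[rank] <- win
    path_ok <- path_ok & lab == win
  }
  status <- if (any(labels != "")) "assigned" else "unassigned_no_majority"
  list(labels = labels, best_similarity = best, nearest_set_size = n,
       status = status)
}

#' Majority-rule assignment to an annotated sequence cluster
#'
#' Returns cluster label C when the best similarity reaches the cluster
#' threshold (75%) and at least the majority fraction of all nearest-set
#' members carry C; members without a cluster label count against the
#' majority.
#'
#' @inheritParams assign_taxonomy
#' @return cluster label, or `NA_character_`.
#' @export
assign_cluster <- function(nearest, db, th = assignment_thresholds()) {
  if (is.null(nearest) || nrow(nearest) == 0L) return(NA_character_)
  if (nearest$similarity[1L] < th$cluster) return(NA_character_)
  lab <- db$cluster_label[match(nearest$ref_id, db$ref_id)]
  lab <- lab[!is.na(lab)]
  if (length(lab) == 0L) return(NA_character_)
  tab <- sort(table(lab), decreasing = TRUE)
  if (tab[1L] / nrow(nearest) < th$majority) return(NA_character_)
  names(tab)[1L]
}

#' Assign taxonomy and cluster labels to a set of tags
#'
#' Runs the full per-tag procedure (candidate search, nearest-set
#' selection, majority-rule taxonomy and cluster assignment) for every tag.
#' Identical sequences are assigned once and the result propagated, which
#' changes nothing in the output but makes deep tag sets tractable.
#'
#' @param tags a `tag_set` data.frame (QC-filtered).
#' @param db a `reference_db` data.frame.
#' @param th thresholds from [assignment_thresholds()].
#' @param n_hits,prefilter,prefilter_keep passed to [find_candidates()].
#' @return data.frame with one row per tag: `tag_id`, `sample_id`,
#'   `best_similarity`, `nearest_set_size`, one column per rank
#'   (`phylum` .. `genus`), `cluster`, `status`.
#' @export
assign_tags <- function(tags, db, th = assignment_thresholds(),
                        n_hits = 100L, prefilter = TRUE,
                        prefilter_keep = 500L) {
  uniq <- unique(tags$sequence)
  res <- vector("list", length(uniq))
  for (k in seq_along(uniq)) {
    hits <- find_candidates(uniq[k], db, n_hits = n_hits,
                            prefilter = prefilter,
                            prefilter_keep = prefilter_keep)
    nearest <- select_nearest_set(hits, window = th$nearest_window)
    tx <- assign_taxonomy(nearest, db, th)
    cl <- assign_cluster(nearest, db, th)
    res[[k]] <- c(list(best_similarity = tx$best_similarity,
                       nearest_set_size = tx$nearest_set_size),
                  as.list(tx$labels),
                  list(cluster = cl, status = tx$status))
  }
  m <- match(tags$sequence, uniq)
  out <- data.frame(tag_id = tags$tag_id, sample_id = tags$sample_id,
                    best_similarity = vapply(res, `[[`, 0, "best_similarity")[m],
                    nearest_set_size = vapply(res, `[[`, 0L, "nearest_set_size")[m],
                    stringsAsFactors = FALSE)
  for (rank in TAX_RANKS)
    out[[rank]] <- vapply(res, `[[`, "", rank)[m]
  out$cluster <- vapply(res, `[[`, "", "cluster")[m]
  out$status <- vapply(res, `[[`, "", "status")[m]
  out
}

#' Write per-tag assignments as TSV
#' @param assignments data.frame from [assign_tags()].
#' @param path output path.
#' @export
write_assignments <- function(assignments, path) {
  x <- assignments
  x$cluster[is.na(x$cluster)] <- ""
  write_table(x, path)
}
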