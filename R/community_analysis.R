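#' Per-sample taxon profiles at a rank
#'
#' Counts assigned tags per taxon label at the requested rank for each
#' sample and converts to percentages. The normalisation basis is either
#' all QC-kept tags of the sample (`all_tags`) or only those assigned at
#' the rank (`assigned_tags`); tags without a label at the rank are
#' reported separately in the `unassigned` component so that, on the
#' `all_tags` basis, labels plus unassigned sum to 100%.
#'
#' @param assignments data.frame from [assign_tags()].
#' @param manifest a `sample_manifest`; every assignment's sample must
#'   resolve.
#' @param rank one of `phylum`, `class`, `order`, `family`, `genus`.
#' @param basis normalisation basis.
#' @return object of class `taxon_profiles`: list with `profiles` (matrix
#'   sample x label, percent), `unassigned` (percent per sample on the
#'   `all_tags` basis), `rank`, `basis`.
#' @export
taxon_profiles <- function(assignments, manifest,
                           rank = c("phylum", "class", "order", "family",
                                    "genus"),
                           basis = c("all_tags", "assigned_tags")) {
  rank <- match.arg(rank)
  basis <- match.arg(basis)
  resolve_samples(assignments, manifest)
  samples <- manifest$sample_id[manifest$sample_id %in% assignments$sample_id]
  lab <- assignments[[rank]]
  assigned <- !is.na(lab) & lab != ""
  labels <- sort(unique(lab[assigned]))
  prof <- matrix(0, length(samples), length(labels),
                 dimnames = list(samples, labels))
  unas <- setNames(numeric(length(samples)), samples)
  for (s in samples) {
    in_s <- assignments$sample_id == s
    n_all <- sum(in_s)
    n_assigned <- sum(in_s & assigned)
    if (length(labels)) {
      t <- table(factor(lab[in_s & assigned], levels = labels))
      denom <- if (basis == "all_tags") n_all else n_assigned
      if (denom > 0) prof[s, ] <- 100 * as.numeric(t) / denom
    }
    unas[s] <- if (n_all > 0) 100 * (n_all - n_assigned) / n_all else 0
  }
  structure(list(profiles = prof, unassigned = unas, rank = rank,
                 basis = basis),
            class = "taxon_profiles")
}

#' Bray-Curtis similarity matrix between sample profiles
#'
#' `S(x, y) = 100 (1 - sum|x_i - y_i| / sum(x_i + y_i))` on relative
#' abundances, the percent similarity commonly drawn as a community
#' heatmap. Labels are unioned across samples with missing values treated
#' as zero. An optional square-root transform of the profiles is available.
#'
#' @param profiles a `taxon_profiles` object or a numeric matrix (samples
#'   in rows).
#' @param sqrt_transform apply `sqrt()` to profiles first.
#' @return symmetric matrix of similarities in `[0, 100]`, diagonal 100.
#' @export
bray_curtis_matrix <- function(profiles, sqrt_transform = FALSE) {
  m <- if (inherits(profiles, "taxon_profiles")) profiles$profiles else profiles
  if (sqrt_transform) m <- sqrt(m)
  n <- nrow(m)
  samples <- rownames(m)
  out <- matrix(100, n, n, dimnames = list(samples, samples))
  for (i in seq_len(n)) {
    for (j in seq_len(n)[-seq_len(i)]) {
      tot <- sum(m[i, ] + m[j, ])
      if (tot == 0)
        stop("Bray-Curtis undefined for all-zero profiles: ",
             samples[i], ", ", samples[j])
      s <- 100 * (1 - sum(abs(m[i, ] - m[j, ])) / tot)
      out[i, j] <- out[j, i] <- s
    }
  }
  out
}

#' Cluster occurrence matrix across samples
#'
#' Tag counts per annotated sequence cluster (e.g. sponge-specific `SC`
#' clusters) and sample, dropping clusters never observed, plus the
#' fraction of tags carrying any cluster label per sample group.
#'
#' @param assignments data.frame from [assign_tags()].
#' @param manifest a `sample_manifest`.
#' @return object of class `cluster_occurrence`: list with `counts`
#'   (matrix cluster x sample), `rel_abundance` (same shape, fraction of
#'   the sample's tags), `group_fraction` (named vector: fraction of tags
#'   with any cluster label per group) and `manifest`.
#' @export
cluster_occurrence <- function(assignments, manifest) {
  resolve_samples(assignments, manifest)
  samples <- manifest$sample_id[manifest$sample_id %in% assignments$sample_id]
  has <- !is.na(assignments$cluster) & assignments$cluster != ""
  clusters <- sort(unique(assignments$cluster[has]))
  counts <- matrix(0L, length(clusters), length(samples),
                   dimnames = list(clusters, samples))
  if (length(clusters)) {
    t <- table(factor(assignments$cluster[has], levels = clusters),
               factor(assignments$sample_id[has], levels = samples))
    counts[] <- as.integer(t)
  }
  n_per_sample <- vapply(samples, function(s)
    sum(assignments$sample_id == s), 0L)
  rel <- sweep(counts, 2L, pmax(n_per_sample, 1L), "/")
  grp <- manifest$group[match(assignments$sample_id, manifest$sample_id)]
  group_fraction <- vapply(sort(unique(grp)), function(g)
    sum(has[grp == g]) / sum(grp == g), 0)
  structure(list(counts = counts, rel_abundance = rel,
                 group_fraction = group_fraction, manifest = manifest),
            class = "cluster_occurrence")
}

#' Classify symbiont transmission mode per cluster
#'
#' A cluster is detected in a sample group when at least `min_count` of
#' its tags occur in at least one sample of that group. Clusters detected
#' in sponges (adults and/or larvae) but never in seawater are called
#' `sponge_exclusive`, implying maintenance by vertical transmission;
#' clusters also detected in seawater (even a single tag in a single
#' replicate) are called `also_in_seawater`, compatible with environmental
#' acquisition from the rare seawater biosphere.
#'
#' @param occ a `cluster_occurrence` object.
#' @param min_count minimum tag count for detection in a sample.
#' @return data.frame of class `transmission_calls` with columns `cluster`,
#'   `in_adult`, `in_larvae`, `in_seawater`, `call`; a `summary` attribute
#'   holds `n_detected`, `n_also_in_seawater`, `pct_exclusive`.
#' @export
classify_transmission <- function(occ, min_count = 1L) {
  m <- occ$manifest
  grp_of <- setNames(m$group, m$sample_id)[colnames(occ$counts)]
  det <- function(g) {
    cols <- which(grp_of == g)
    if (!length(cols)) return(rep(FALSE, nrow(occ$counts)))
    apply(occ$counts[, cols, drop = FALSE] >= min_count, 1L, any)
  }
  in_adult <- det("adult"); in_larvae <- det("larvae"); in_sw <- det("seawater")
  detected <- in_adult | in_larvae | in_sw
  calls <- data.frame(cluster = rownames(occ$counts),
                      in_adult = in_adult, in_larvae = in_larvae,
                      in_seawater = in_sw,
                      call = ifelse(in_sw, "also_in_seawater",
                                    "sponge_exclusive"),
                      stringsAsFactors = FALSE)[detected, , drop = FALSE]
  rownames(calls) <- NULL
  n_det <- nrow(calls)
  n_sw <- sum(calls$in_seawater)
  summary <- list(n_detected = n_det, n_also_in_seawater = n_sw,
                  pct_exclusive = if (n_det > 0) 100 * (n_det - n_sw) / n_det
                                  else NA_real_)
  structure(calls, summary = summary, class = c("transmission_calls",
                                                "data.frame"))
}
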