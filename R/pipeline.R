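#' Configuration for a full pipeline run
#'
#' All module parameters default to the values the assignment and
#' clustering procedures are defined with (QC length 50 nt, thresholds
#' 95/90/85/80/75%, 60% majority, 0.1% nearest window, 95% OTU level,
#' ACE cutoff 10, detection threshold one tag).
#'
#' @param manifest path to the sample manifest TSV; its `fasta` column
#'   locates one tag FASTA per sample, relative to the manifest.
#' @param refdb path to the reference database TSV.
#' @param out_dir output directory, created by [run_pipeline()].
#' @param min_len,max_n QC parameters ([qc_filter_tags()]).
#' @param thresholds an [assignment_thresholds()] object.
#' @param n_hits candidate list size ([find_candidates()]).
#' @param otu_levels similarity levels for OTU clustering (cutoff is
#'   `1 - level` on the corrected distance scale).
#' @param otu_pool pool samples for OTU analysis by `"species"` (group x
#'   species, the study design) or per `"sample"`.
#' @param rare_cutoff ACE rare/abundant cutoff.
#' @param bray_ranks ranks at which Bray-Curtis matrices are computed.
#' @param profile_basis normalisation basis for taxon profiles.
#' @param min_count detection threshold for transmission classification.
#' @param rarefaction_points number of depths per rarefaction curve.
#' @param write_distance_matrices also write PHYLIP distance matrices
#'   (large; off by default).
#' @param seed recorded in the effective config (the pipeline itself is
#'   deterministic).
#' @export
run_config <- function(manifest, refdb, out_dir,
                       min_len = 50L, max_n = 0L,
                       thresholds = assignment_thresholds(),
                       n_hits = 100L,
                       otu_levels = 0.95,
                       otu_pool = c("species", "sample"),
                       rare_cutoff = 10L,
                       bray_ranks = TAX_RANKS,
                       profile_basis = "all_tags",
                       min_count = 1L,
                       rarefaction_points = 10L,
                       write_distance_matrices = FALSE,
                       seed = 1L) {
  cfg <- as.list(environment())
  cfg$otu_pool <- match.arg(otu_pool)
  class(cfg) <- "run_config"
  cfg
}

log_msg <- function(...) {
  message(format(Sys.time(), "[%Y-%m-%d %H:%M:%S] "), ...)
}

#' Run the full tag-analysis pipeline
#'
#' Orchestrates QC, taxonomic/cluster assignment, OTU clustering with
#' abundance mapping, richness and rarefaction estimation, Bray-Curtis
#' comparison and transmission classification, writing every result as a
#' TSV into the output directory together with the effective configuration
#' and a per-stage tag-count table. Deterministic given the configuration.
#'
#' @param cfg a [run_config()].
#' @return (invisibly) a list with the in-memory results and `out_dir`.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  # fail before producing any output
  if (!file.exists(cfg$manifest)) stop("manifest not found: ", cfg$manifest)
  if (!file.exists(cfg$refdb)) stop("reference db not found: ", cfg$refdb)
  manifest <- read_manifest(cfg$manifest)
  if (is.null(manifest$fasta)) stop("manifest lacks a 'fasta' column")
  db <- read_reference_db(cfg$refdb)
  fasta_paths <- file.path(dirname(cfg$manifest), manifest$fasta)
  missing <- fasta_paths[!file.exists(fasta_paths)]
  if (length(missing)) stop("tag FASTA not found: ",
                            paste(missing, collapse = ", "))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)

  # effective config
  eff <- cfg
  eff$thresholds <- paste(names(unclass(cfg$thresholds)),
                          unlist(cfg$thresholds), sep = "=", collapse = ",")
  writeLines(paste(names(unclass(eff)), vapply(unclass(eff), function(v)
    paste(format(v), collapse = ","), ""), sep = "="),
    file.path(cfg$out_dir, "config.txt"))

  log_msg("reading tags for ", nrow(manifest), " samples")
  tags <- do.call(rbind, lapply(seq_len(nrow(manifest)), function(k)
    read_tag_fasta(fasta_paths[k], sample_id = manifest$sample_id[k])))
  tags <- new_tag_set(tags)
  resolve_samples(tags, manifest)

  log_msg("QC filtering ", nrow(tags), " tags")
  qc <- qc_filter_tags(tags, min_len = cfg$min_len, max_n = cfg$max_n)
  kept <- qc$kept
  qc_report <- do.call(rbind, lapply(manifest$sample_id, function(s)
    data.frame(sample_id = s,
               input = sum(tags$sample_id == s),
               kept = sum(kept$sample_id == s),
               removed_short = sum(qc$removed$sample_id == s &
                                     qc$removed$reason == "short"),
               removed_ambiguous = sum(qc$removed$sample_id == s &
                                         qc$removed$reason == "ambiguous"),
               stringsAsFactors = FALSE)))
  write_table(qc_report, file.path(cfg$out_dir, "qc_report.tsv"))
  stopifnot(nrow(qc$kept) + nrow(qc$removed) == nrow(tags))

  log_msg("assigning ", nrow(kept), " tags (",
          length(unique(kept$sequence)), " unique)")
  assignments <- assign_tags(kept, db, th = cfg$thresholds,
                             n_hits = cfg$n_hits)
  write_assignments(assignments, file.path(cfg$out_dir, "assignments.tsv"))

  # ---- OTU clustering and diversity per pool -----------------------------
  pool_of <- if (cfg$otu_pool == "species") {
    ifelse(manifest$group == "seawater", "seawater",
           paste(manifest$group, manifest$species, sep = "_"))
  } else manifest$sample_id
  names(pool_of) <- manifest$sample_id
  otu_tables <- list(); richness <- list(); raref <- list(); ranks_ab <- list()
  for (pool in unique(pool_of)) {
    in_pool <- kept$sample_id %in% manifest$sample_id[pool_of == pool]
    ptags <- kept[in_pool, , drop = FALSE]
    if (nrow(ptags) == 0L) next
    log_msg("OTU clustering pool '", pool, "': ", nrow(ptags), " tags")
    usq <- dereplicate(ptags)
    dm <- suppressWarnings(distance_matrix(usq))
    parts <- cluster_furthest_neighbor(
      dm, cutoffs = 1 - cfg$otu_levels,
      weights = setNames(usq$useqs$weight, usq$useqs$useq_id))
    if (cfg$write_distance_matrices)
      write_distance_matrix(dm, file.path(cfg$out_dir,
                                          paste0("dist_", pool, ".phylip")),
                            dialect = "phylip-lower")
    for (part in parts) {
      tab <- expand_to_table(part, usq)
      lv <- round(100 * part$similarity_level)
      otu_tables[[paste0(pool, "_L", lv)]] <- tab
      write_table(tab, file.path(cfg$out_dir,
                                 sprintf("otu_table_%s_L%d.tsv", pool, lv)),
                  id_col = "otu_id")
      pooled <- rowSums(tab)
      pooled <- pooled[pooled > 0]
      richness[[paste0(pool, "_L", lv)]] <-
        data.frame(pool = pool, level = lv, n_reads = sum(pooled),
                   s_obs = length(pooled), chao1 = chao1(pooled),
                   ace = ace(pooled, cfg$rare_cutoff),
                   stringsAsFactors = FALSE)
      depths <- unique(round(seq(1, sum(pooled),
                                 length.out = cfg$rarefaction_points)))
      rc <- rarefaction_curve(pooled, depths)
      raref[[paste0(pool, "_L", lv)]] <-
        data.frame(pool = pool, level = lv, rc, stringsAsFactors = FALSE)
      ra <- rank_abundance(pooled)
      ranks_ab[[paste0(pool, "_L", lv)]] <-
        data.frame(pool = pool, level = lv, ra, stringsAsFactors = FALSE)
    }
  }
  write_table(do.call(rbind, richness), file.path(cfg$out_dir, "richness.tsv"),
              digits = 2L)
  write_table(do.call(rbind, raref), file.path(cfg$out_dir, "rarefaction.tsv"),
              digits = 4L)
  write_table(do.call(rbind, ranks_ab),
              file.path(cfg$out_dir, "rank_abundance.tsv"))

  # ---- community comparison ---------------------------------------------
  profiles <- list(); bray <- list()
  for (rank in cfg$bray_ranks) {
    prof <- taxon_profiles(assignments, manifest, rank = rank,
                           basis = cfg$profile_basis)
    profiles[[rank]] <- prof
    write_table(prof$profiles,
                file.path(cfg$out_dir, paste0("profiles_", rank, ".tsv")),
                digits = 4L, id_col = "sample_id")
    bc <- bray_curtis_matrix(prof)
    bray[[rank]] <- bc
    write_table(bc, file.path(cfg$out_dir, paste0("braycurtis_", rank, ".tsv")),
                digits = 2L, id_col = "sample_id")
  }

  log_msg("cluster occurrence and transmission classification")
  occ <- cluster_occurrence(assignments, manifest)
  write_table(occ$counts, file.path(cfg$out_dir, "cluster_occurrence.tsv"),
              id_col = "cluster")
  write_table(occ$rel_abundance,
              file.path(cfg$out_dir, "cluster_rel_abundance.tsv"),
              digits = 6L, id_col = "cluster")
  calls <- classify_transmission(occ, min_count = cfg$min_count)
  write_table(as.data.frame(calls), file.path(cfg$out_dir, "transmission.tsv"))
  ts <- attr(calls, "summary")
  write_table(data.frame(n_detected = ts$n_detected,
                         n_also_in_seawater = ts$n_also_in_seawater,
                         pct_exclusive = ts$pct_exclusive),
              file.path(cfg$out_dir, "transmission_summary.tsv"), digits = 2L)

  counts <- data.frame(
    stage = c("input", "qc_kept", "qc_removed", "assigned", "unassigned"),
    n = c(nrow(tags), nrow(qc$kept), nrow(qc$removed),
          sum(assignments$status == "assigned"),
          sum(assignments$status != "assigned")))
  write_table(counts, file.path(cfg$out_dir, "stage_counts.tsv"))
  log_msg("pipeline complete: ", cfg$out_dir)

  invisible(list(out_dir = cfg$out_dir, manifest = manifest,
                 qc_report = qc_report, assignments = assignments,
                 otu_tables = otu_tables,
                 richness = do.call(rbind, richness),
                 rarefaction = do.call(rbind, raref),
                 profiles = profiles, bray_curtis = bray,
                 occurrence = occ, transmission = calls,
                 stage_counts = counts))
}
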