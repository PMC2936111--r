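random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Substitute each position independently with probability `rate` (to one of
# the three other bases). `rate` may be a per-position vector.
mutate_seq <- function(seq, rate) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  hit <- which(runif(length(chars)) < rate)
  for (i in hit) {
    chars[i] <- sample(setdiff(c("A", "C", "G", "T"), chars[i]), 1L)
  }
  paste(chars, collapse = "")
}

#' Simulate a taxonomically structured 16S reference database
#'
#' Evolves a root sequence down a balanced rank tree
#' (phylum > class > order > family > genus > reference) by per-branch
#' substitution, producing references with full five-rank taxonomy paths.
#' Hypervariable-region (V6) positions evolve faster than the backbone, so
#' short tags drawn from the V6 window are informative at fine ranks. A
#' subset of genera receives sponge-specific (`SC`) or
#' sponge-coral-specific (`SCC`) cluster labels shared by all their
#' references.
#'
#' @param n_phyla number of phyla.
#' @param branching named integer vector: children per node at `class`,
#'   `order`, `family`, `genus`, and references per genus (`refs`).
#' @param seq_length reference sequence length (nt).
#' @param v6_start 1-based start of the hypervariable window.
#' @param v6_length length range (min, max) of the per-reference V6 window.
#' @param rates per-branch substitution probability per V6 site at each
#'   level, decreasing from phylum to reference (coarse ranks more
#'   divergent).
#' @param backbone_scale multiplier applied to `rates` outside the V6
#'   window (the backbone is more conserved).
#' @param n_clusters number of genera receiving cluster labels (ignored
#'   when `cluster_genera` is given).
#' @param cluster_genera optional explicit genus labels to annotate.
#' @param seed RNG seed.
#' @return a `reference_db` data.frame; attribute `v6` is a data.frame
#'   (`ref_id`, `start`, `length`) locating each reference's V6 window.
#' @export
simulate_reference_db <- function(n_phyla = 8L,
                                  branching = c(class = 2L, order = 2L,
                                                family = 2L, genus = 2L,
                                                refs = 2L),
                                  seq_length = 150L, v6_start = 46L,
                                  v6_length = c(50L, 60L),
                                  rates = c(phylum = 0.16, class = 0.13,
                                            order = 0.10, family = 0.085,
                                            genus = 0.075, ref = 0.03),
                                  backbone_scale = 0.3,
                                  n_clusters = 24L, cluster_genera = NULL,
                                  seed = NULL) {
  stopifnot(all(diff(rates) <= 0))
  t_path <- 2 * sum(rates)
  if (0.75 * (1 - exp(-4 / 3 * t_path)) > 0.70)
    warning("between-phylum divergence near Jukes-Cantor saturation")
  with_seed(seed, {
    v6_max <- v6_start + max(v6_length) - 1L
    if (v6_max > seq_length) stop("V6 window exceeds sequence length")
    site_rate <- function(level) {
      r <- rep(rates[[level]] * backbone_scale, seq_length)
      r[v6_start:v6_max] <- rates[[level]]
      r
    }
    root <- random_dna(seq_length)
    out <- list(); k <- 0L
    for (p in seq_len(n_phyla)) {
      ps <- mutate_seq(root, site_rate("phylum"))
      p_lab <- sprintf("p%02d", p)
      for (cl in seq_len(branching[["class"]])) {
        cls <- mutate_seq(ps, site_rate("class"))
        c_lab <- paste0(p_lab, "c", cl)
        for (o in seq_len(branching[["order"]])) {
          os <- mutate_seq(cls, site_rate("order"))
          o_lab <- paste0(c_lab, "o", o)
          for (f in seq_len(branching[["family"]])) {
            fs <- mutate_seq(os, site_rate("family"))
            f_lab <- paste0(o_lab, "f", f)
            for (g in seq_len(branching[["genus"]])) {
              gs <- mutate_seq(fs, site_rate("genus"))
              g_lab <- paste0(f_lab, "g", g)
              for (r in seq_len(branching[["refs"]])) {
                rs <- mutate_seq(gs, site_rate("ref"))
                k <- k + 1L
                out[[k]] <- data.frame(
                  ref_id = paste0(g_lab, "r", r), sequence = rs,
                  cluster_label = NA_character_,
                  tax_phylum = p_lab, tax_class = c_lab, tax_order = o_lab,
                  tax_family = f_lab, tax_genus = g_lab,
                  stringsAsFactors = FALSE)
              }
            }
          }
        }
      }
    }
    db <- do.call(rbind, out)
    genera <- unique(db$tax_genus)
    if (is.null(cluster_genera)) {
      n_clusters <- min(n_clusters, length(genera))
      cluster_genera <- sort(sample(genera, n_clusters))
    }
    n_sc <- ceiling(0.8 * length(cluster_genera))
    labels <- paste0(ifelse(seq_along(cluster_genera) <= n_sc, "SC", "SCC"),
                     sprintf("%02d", seq_along(cluster_genera)))
    m <- match(db$tax_genus, cluster_genera)
    db$cluster_label <- ifelse(is.na(m), NA_character_, labels[m])
    v6 <- data.frame(ref_id = db$ref_id, start = v6_start,
                     length = sample(seq(v6_length[1L], v6_length[2L]),
                                     nrow(db), replace = TRUE),
                     stringsAsFactors = FALSE)
    db <- validate_reference_db(db)
    attr(db, "v6") <- v6
    db
  })
}

v6_window <- function(db, ref_id) {
  v6 <- attr(db, "v6")
  if (is.null(v6)) stop("reference db lacks V6 window annotation")
  i <- match(ref_id, v6$ref_id)
  substring(db$sequence[match(ref_id, db$ref_id)], v6$start[i],
            v6$start[i] + v6$length[i] - 1L)
}

# Apply exactly n_sub substitutions and n_ind indels (each indel a deletion
# or a single-base insertion with equal probability) at uniform positions.
apply_read_errors <- function(seq, n_sub, n_ind) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  if (n_sub > 0L) {
    for (i in sample(length(chars), n_sub)) {
      chars[i] <- sample(setdiff(c("A", "C", "G", "T"), chars[i]), 1L)
    }
  }
  if (n_ind > 0L) {
    for (i in sort(sample(length(chars), n_ind), decreasing = TRUE)) {
      if (runif(1) < 0.5) {
        chars <- chars[-i]                       # deletion
      } else {
        chars <- append(chars, sample(c("A", "C", "G", "T"), 1L), after = i - 1L)
      }
    }
  }
  paste(chars, collapse = "")
}

#' Simulate tag reads from a community
#'
#' Draws `n_tags` source references from the community by multinomial
#' sampling; each tag is the reference's V6 window with per-base
#' substitution and indel errors at the stated rates (a flat 454-style
#' error model).
#'
#' @param community named numeric vector of relative abundances over
#'   `ref_id`s (sums to 1).
#' @param db a `reference_db` from [simulate_reference_db()] (carries the
#'   V6 windows).
#' @param n_tags number of tags to draw.
#' @param error_model list with `sub_rate` and `indel_rate`.
#' @param sample_id sample id recorded on every tag.
#' @param seed RNG seed.
#' @return list with `tags` (a `tag_set`) and `sources` (data.frame
#'   `tag_id`, `sample_id`, `ref_id`).
#' @export
simulate_sample <- function(community, db, n_tags,
                            error_model = list(sub_rate = 0.002,
                                               indel_rate = 0.001),
                            sample_id = "S1", seed = NULL) {
  stopifnot(abs(sum(community) - 1) < 1e-8)
  with_seed(seed, {
    refs <- names(community)
    draw <- as.vector(rmultinom(1L, n_tags, community))
    src <- rep(refs, draw)
    if (length(src)) src <- sample(src)  # shuffle read order
    v6 <- setNames(v6_window(db, refs), refs)
    seqs <- unname(v6[src])
    lens <- nchar(seqs)
    n_sub <- rbinom(length(seqs), lens, error_model$sub_rate)
    n_ind <- rbinom(length(seqs), lens, error_model$indel_rate)
    for (i in which(n_sub + n_ind > 0L))
      seqs[i] <- apply_read_errors(seqs[i], n_sub[i], n_ind[i])
    tag_id <- sprintf("%s_t%06d", sample_id, seq_len(n_tags))
    tags <- new_tag_set(data.frame(tag_id = tag_id, sample_id = sample_id,
                                   sequence = seqs, length = nchar(seqs),
                                   stringsAsFactors = FALSE))
    list(tags = tags,
         sources = data.frame(tag_id = tag_id, sample_id = sample_id,
                              ref_id = src, stringsAsFactors = FALSE))
  })
}

#' Scenario specification for the synthetic study design
#'
#' Defaults emulate the study design the package targets: three sponge
#' species with three adult replicates each, three larval samples (species
#' 1), four seawater replicates; lognormal rank abundance with a few
#' dominant taxa and a long rare tail; cluster-labelled (sponge-specific)
#' taxa enriched in their host but seeded into seawater at very low
#' abundance for a configurable fraction of clusters; larvae as an
#' adult community plus a seawater contamination fraction; flat per-base
#' sequencing error.
#'
#' @param n_sponge_species,n_adult_replicates,n_larvae,n_seawater design
#'   sizes.
#' @param tags_per_sample sequencing depth per sample.
#' @param genera_per_species genera in each sponge community.
#' @param clusters_per_species cluster-labelled genera per sponge species.
#' @param seawater_genera genera private to the seawater community.
#' @param rank_abundance lognormal `meanlog`/`sdlog` on the abundance
#'   scale.
#' @param contamination_fraction seawater fraction mixed into each larval
#'   community.
#' @param rare_shared_fraction fraction of each sponge's cluster-labelled
#'   genera seeded into seawater.
#' @param rare_abundance per-reference relative abundance of seeded taxa
#'   in seawater (default 1e-4: detection is stochastic across
#'   replicates).
#' @param cluster_floor minimum relative abundance of each cluster-labelled
#'   genus within its host community (symbionts are enriched in hosts).
#' @param error_model list with `sub_rate`, `indel_rate`.
#' @param refdb arguments forwarded to [simulate_reference_db()].
#' @param seed master RNG seed.
#' @export
scenario_spec <- function(n_sponge_species = 3L, n_adult_replicates = 3L,
                          n_larvae = 3L, n_seawater = 4L,
                          tags_per_sample = 5000L,
                          genera_per_species = 30L,
                          clusters_per_species = 8L,
                          seawater_genera = 38L,
                          rank_abundance = c(meanlog = 0, sdlog = 1.5),
                          contamination_fraction = 0.2,
                          rare_shared_fraction = 0.5,
                          rare_abundance = 1e-4,
                          cluster_floor = 0.002,
                          error_model = list(sub_rate = 0.002,
                                             indel_rate = 0.001),
                          refdb = list(), seed = 1L) {
  spec <- as.list(environment())
  stopifnot(tags_per_sample >= 1L,
            contamination_fraction >= 0, contamination_fraction <= 1,
            rare_shared_fraction >= 0, rare_shared_fraction <= 1,
            rare_abundance >= 0, rare_abundance <= 1)
  class(spec) <- "scenario_spec"
  spec
}

lognormal_community <- function(ref_ids, meanlog, sdlog) {
  w <- rlnorm(length(ref_ids), meanlog, sdlog)
  setNames(w / sum(w), ref_ids)
}

#' Build a full synthetic scenario with ground truth
#'
#' Generates the reference database, the true per-sample communities, the
#' manifest, and all tag reads. Adult communities are drawn per species
#' from lognormal rank abundances with cluster-labelled genera enforced to
#' at least `cluster_floor` relative abundance; each larval community is
#' `(1 - f) * adult + f * seawater`; the seawater community holds its own
#' genera plus `rare_shared_fraction` of each sponge's cluster-labelled
#' genera at `rare_abundance` per reference. A cluster's true transmission
#' status is `sponge_exclusive` exactly when none of its references were
#' seeded into seawater.
#'
#' @param spec a [scenario_spec()].
#' @return object of class `tag_scenario`: list with `tags` (all samples),
#'   `manifest`, `refdb`, `truth` (list: `communities`, `tag_sources`,
#'   `cluster_status`, `designed_pct_exclusive`) and `spec`.
#' @export
build_scenario <- function(spec = scenario_spec()) {
  refdb_args <- spec$refdb
  refdb_args$seed <- refdb_args$seed %||% derive_seed(spec$seed, 1L)
  db <- do.call(simulate_reference_db, refdb_args)

  with_seed(derive_seed(spec$seed, 2L), {
    labeled <- unique(db$tax_genus[!is.na(db$cluster_label)])
    unlabeled <- setdiff(unique(db$tax_genus), labeled)
    need_lab <- spec$n_sponge_species * spec$clusters_per_species
    need_unl <- spec$n_sponge_species *
      (spec$genera_per_species - spec$clusters_per_species) +
      spec$seawater_genera
    if (length(labeled) < need_lab || length(unlabeled) < need_unl)
      stop("reference database too small for the requested scenario")
    lab_pool <- sample(labeled)
    unl_pool <- sample(unlabeled)
    genus_refs <- split(db$ref_id, db$tax_genus)

    meanlog <- spec$rank_abundance[["meanlog"]]
    sdlog <- spec$rank_abundance[["sdlog"]]
    communities <- list()
    sponge_clusters <- list()
    for (i in seq_len(spec$n_sponge_species)) {
      gl <- lab_pool[seq_len(spec$clusters_per_species) +
                       (i - 1L) * spec$clusters_per_species]
      gu <- unl_pool[seq_len(spec$genera_per_species -
                               spec$clusters_per_species) +
                       (i - 1L) * (spec$genera_per_species -
                                     spec$clusters_per_species)]
      refs <- unlist(genus_refs[c(gl, gu)], use.names = FALSE)
      com <- lognormal_community(refs, meanlog, sdlog)
      # host enrichment floor for cluster-labelled genera
      for (g in gl) {
        gr <- genus_refs[[g]]
        tot <- sum(com[gr])
        if (tot < spec$cluster_floor)
          com[gr] <- com[gr] * spec$cluster_floor / tot
      }
      com <- com / sum(com)
      communities[[paste0("sponge", i)]] <- com
      sponge_clusters[[i]] <- gl
    }
    sw_own_genera <- unl_pool[need_unl - spec$seawater_genera +
                                seq_len(spec$seawater_genera)]
    sw_refs <- unlist(genus_refs[sw_own_genera], use.names = FALSE)
    sw_own <- lognormal_community(sw_refs, meanlog, sdlog)
    # seed a fraction of each sponge's cluster genera into seawater
    seeded_genera <- unlist(lapply(sponge_clusters, function(gl) {
      k <- round(spec$rare_shared_fraction * length(gl))
      if (k > 0L) sample(gl, k) else character(0)
    }))
    seeded_refs <- unlist(genus_refs[seeded_genera], use.names = FALSE)
    seed_mass <- spec$rare_abundance * length(seeded_refs)
    seawater <- c(sw_own * (1 - seed_mass),
                  setNames(rep(spec$rare_abundance, length(seeded_refs)),
                           seeded_refs))
    communities[["seawater"]] <- seawater

    f <- spec$contamination_fraction
    adult1 <- communities[["sponge1"]]
    all_refs <- union(names(adult1), names(seawater))
    lar <- setNames(numeric(length(all_refs)), all_refs)
    lar[names(adult1)] <- (1 - f) * adult1
    lar[names(seawater)] <- lar[names(seawater)] + f * seawater
    lar <- lar[lar > 0]
    communities[["larvae"]] <- lar / sum(lar)

    # manifest
    rows <- list()
    for (i in seq_len(spec$n_sponge_species))
      for (r in seq_len(spec$n_adult_replicates))
        rows[[length(rows) + 1L]] <-
          data.frame(sample_id = sprintf("sp%d_ad%d", i, r), group = "adult",
                     species = paste0("sponge", i), replicate = r,
                     stringsAsFactors = FALSE)
    for (r in seq_len(spec$n_larvae))
      rows[[length(rows) + 1L]] <-
        data.frame(sample_id = sprintf("sp1_lv%d", r), group = "larvae",
                   species = "sponge1", replicate = r,
                   stringsAsFactors = FALSE)
    for (r in seq_len(spec$n_seawater))
      rows[[length(rows) + 1L]] <-
        data.frame(sample_id = sprintf("sw%d", r), group = "seawater",
                   species = "", replicate = r, stringsAsFactors = FALSE)
    manifest <- validate_manifest(do.call(rbind, rows))

    community_of <- function(s) {
      if (s$group == "adult") communities[[s$species]]
      else if (s$group == "larvae") communities[["larvae"]]
      else communities[["seawater"]]
    }
    tag_list <- list(); src_list <- list()
    for (k in seq_len(nrow(manifest))) {
      s <- manifest[k, ]
      sim <- simulate_sample(community_of(s), db, spec$tags_per_sample,
                             error_model = spec$error_model,
                             sample_id = s$sample_id,
                             seed = derive_seed(spec$seed, 10L + k))
      tag_list[[k]] <- sim$tags
      src_list[[k]] <- sim$sources
    }
    tags <- new_tag_set(do.call(rbind, tag_list))
    sources <- do.call(rbind, src_list)

    cluster_of <- setNames(db$cluster_label, db$tax_genus)
    all_cluster_genera <- unlist(sponge_clusters)
    cluster_status <- data.frame(
      cluster = unname(cluster_of[all_cluster_genera]),
      genus = all_cluster_genera,
      seeded = all_cluster_genera %in% seeded_genera,
      status = ifelse(all_cluster_genera %in% seeded_genera,
                      "also_in_seawater", "sponge_exclusive"),
      stringsAsFactors = FALSE)
    cluster_status <- cluster_status[order(cluster_status$cluster), ]
    rownames(cluster_status) <- NULL

    per_sample_comm <- lapply(seq_len(nrow(manifest)), function(k)
      community_of(manifest[k, ]))
    names(per_sample_comm) <- manifest$sample_id

    structure(list(tags = tags, manifest = manifest, refdb = db,
                   truth = list(communities = per_sample_comm,
                                tag_sources = sources,
                                cluster_status = cluster_status,
                                designed_pct_exclusive =
                                  100 * mean(!cluster_status$seeded)),
                   spec = spec),
              class = "tag_scenario")
  })
}

#' Write a scenario to disk as plain-text files
#'
#' One FASTA per sample (referenced from the manifest's `fasta` column),
#' the manifest, the reference database, and the ground-truth tables.
#'
#' @param scn a `tag_scenario`.
#' @param dir output directory (created if needed).
#' @export
write_scenario <- function(scn, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  m <- scn$manifest
  m$fasta <- paste0(m$sample_id, ".fasta")
  for (k in seq_len(nrow(m))) {
    write_tag_fasta(scn$tags[scn$tags$sample_id == m$sample_id[k], ],
                    file.path(dir, m$fasta[k]))
  }
  write_manifest(m, file.path(dir, "manifest.tsv"))
  write_reference_db(scn$refdb, file.path(dir, "refdb.tsv"))
  write_table(scn$truth$tag_sources, file.path(dir, "truth_tag_sources.tsv"))
  write_table(scn$truth$cluster_status,
              file.path(dir, "truth_cluster_status.tsv"))
  comm <- do.call(rbind, lapply(names(scn$truth$communities), function(s) {
    v <- scn$truth$communities[[s]]
    data.frame(sample_id = s, ref_id = names(v), abundance = unname(v),
               stringsAsFactors = FALSE)
  }))
  write_table(comm, file.path(dir, "truth_communities.tsv"), digits = 8L)
  invisible(dir)
}
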