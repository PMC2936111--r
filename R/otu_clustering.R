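#' Dereplicate tags into unique sequences
#'
#' Collapses identical sequences (exact string match) into unique
#' representatives carrying their total abundance and per-sample counts, so
#' that distance computation and clustering run on the non-redundant set
#' and abundances can be mapped back afterwards.
#'
#' @param tags a `tag_set` data.frame (QC-filtered).
#' @return an object of class `unique_seqs`: list with `useqs` (data.frame
#'   `useq_id`, `sequence`, `weight`), `counts` (matrix unique sequence x
#'   sample) and `members` (list of tag-id vectors).
#' @export
dereplicate <- function(tags) {
  if (nrow(tags) == 0L) {
    return(structure(list(useqs = data.frame(useq_id = character(),
                                             sequence = character(),
                                             weight = integer(),
                                             stringsAsFactors = FALSE),
                          counts = matrix(0L, 0L, 0L),
                          members = list()),
                     class = "unique_seqs"))
  }
  grp <- split(seq_len(nrow(tags)), tags$sequence)
  seqs <- names(grp)
  weight <- lengths(grp)
  ord <- order(-weight, seqs)
  grp <- grp[ord]; seqs <- seqs[ord]; weight <- weight[ord]
  useq_id <- sprintf("U%06d", seq_along(seqs))
  samples <- sort(unique(tags$sample_id))
  counts <- matrix(0L, length(seqs), length(samples),
                   dimnames = list(useq_id, samples))
  for (k in seq_along(grp)) {
    t <- table(tags$sample_id[grp[[k]]])
    counts[k, names(t)] <- as.integer(t)
  }
  members <- lapply(grp, function(i) tags$tag_id[i])
  names(members) <- useq_id
  structure(list(useqs = data.frame(useq_id = useq_id, sequence = seqs,
                                    weight = as.integer(weight),
                                    stringsAsFactors = FALSE),
                 counts = counts, members = members),
            class = "unique_seqs")
}

encode_alignment <- function(rows) {
  lens <- nchar(rows)
  if (length(unique(lens)) > 1L) stop("aligned rows must have equal length")
  chars <- strsplit(rows, "", fixed = TRUE)
  code <- c("-" = 0L, "A" = 1L, "C" = 2L, "G" = 3L, "T" = 4L)
  enc <- function(v) { x <- code[v]; x[is.na(x)] <- 5L; as.integer(x) }
  do.call(rbind, lapply(chars, enc))
}

#' Gap-aware mismatch fraction between two aligned rows
#'
#' Comparison is restricted to the column span where both rows are inside
#' their non-terminal region (terminal gaps are ignored). Each maximal
#' internal gap run in one row counts as a single evolutionary event (one
#' difference, one compared position); base-base columns each count one
#' compared position, mismatches one difference. Columns where both rows
#' have a gap are skipped without interrupting gap runs; columns with an
#' ambiguous base are not compared.
#'
#' @param a,b aligned rows (equal-length strings over `ACGTN-`).
#' @return mismatch fraction `p` in `[0, 1]`.
#' @export
gap_aware_p <- function(a, b) {
  enc <- encode_alignment(c(a, b))
  p <- .cpp_p_pair(enc[1L, ], enc[2L, ])
  if (is.na(p)) stop("incomparable pair: no shared comparable columns")
  p
}

#' Jukes-Cantor distance from a mismatch fraction
#'
#' `d = -(3/4) log(1 - (4/3) p)`. At or beyond the model's saturation point
#' (`p >= 0.75`) the distance is capped at `d_max` with a warning, keeping
#' downstream clustering total.
#'
#' @param p mismatch fraction(s) in `[0, 1]`.
#' @param d_max cap applied at saturation (default 5).
#' @export
jukes_cantor <- function(p, d_max = 5) {
  if (any(p < 0 | p > 1)) stop("p must be in [0, 1]")
  sat <- p >= 0.75
  if (any(sat)) warning(sum(sat), " pair(s) at Jukes-Cantor saturation; capped at ",
                        d_max)
  d <- ifelse(sat, d_max, -0.75 * log1p(-(4 / 3) * p))
  pmin(d, d_max)
}

#' Star alignment of unique sequences
#'
#' Aligns every sequence to a centre sequence (by default the
#' highest-abundance one) with free end gaps and merges the pairwise
#' alignments into a single multiple alignment by projecting insertions
#' onto centre coordinates. A built-in stand-in for an external MSA tool;
#' an externally produced aligned FASTA can be supplied to
#' [distance_matrix()] instead.
#'
#' @param seqs named character vector of sequences.
#' @param center name of the centre sequence (default: first element).
#' @return named character vector of equal-length aligned rows.
#' @export
star_align <- function(seqs, center = NULL) {
  stopifnot(!is.null(names(seqs)))
  if (length(seqs) == 1L) return(seqs)
  center <- center %||% names(seqs)[1L]
  cs <- seqs[[center]]
  lc <- nchar(cs)
  others <- setdiff(names(seqs), center)
  n_ins <- integer(lc + 1L)            # max insertion length per slot
  ins_list <- vector("list", length(others))
  core_list <- vector("list", length(others))
  names(ins_list) <- names(core_list) <- others
  for (nm in others) {
    # member aligned end-to-end (semi-global); centre overhangs free
    al <- .cpp_align_free_end(seqs[[nm]], cs, TRUE)
    ac <- strsplit(al$b, "", fixed = TRUE)[[1L]]
    bc <- strsplit(al$a, "", fixed = TRUE)[[1L]]
    ins <- vector("list", lc + 1L)
    core <- rep("-", lc)
    cpos <- 0L
    for (t in seq_along(ac)) {
      if (ac[t] != "-") {
        cpos <- cpos + 1L
        core[cpos] <- bc[t]
      } else {
        ins[[cpos + 1L]] <- c(ins[[cpos + 1L]], bc[t])
      }
    }
    il <- lengths(ins)
    n_ins <- pmax(n_ins, il)
    ins_list[[nm]] <- ins
    core_list[[nm]] <- core
  }
  pad <- function(chars, width) {
    c(chars, rep("-", width - length(chars)))
  }
  build <- function(core, ins) {
    out <- character(0)
    for (s in seq_len(lc + 1L)) {
      if (n_ins[s] > 0L)
        out <- c(out, pad(if (is.null(ins[[s]])) character(0) else ins[[s]],
                          n_ins[s]))
      if (s <= lc) out <- c(out, core[s])
    }
    paste(out, collapse = "")
  }
  rows <- c(setNames(build(strsplit(cs, "", fixed = TRUE)[[1L]],
                           vector("list", lc + 1L)), center),
            vapply(others, function(nm) build(core_list[[nm]], ins_list[[nm]]),
                   ""))
  rows[names(seqs)]
}

#' Gap-aware Jukes-Cantor distance matrix
#'
#' Builds the pairwise distance matrix used for OTU clustering:
#' `jukes_cantor(gap_aware_p(i, j))` for every pair of aligned rows. The
#' alignment is either supplied (e.g. read from an aligned FASTA produced
#' by an external MSA tool) or built with [star_align()] using the
#' highest-abundance sequence as centre.
#'
#' @param useqs a `unique_seqs` object, or a named character vector of
#'   (unaligned) sequences.
#' @param alignment optional named character vector of aligned rows
#'   covering all sequences.
#' @param d_max saturation cap passed to [jukes_cantor()].
#' @return symmetric distance matrix with zero diagonal.
#' @export
distance_matrix <- function(useqs, alignment = NULL, d_max = 5) {
  if (inherits(useqs, "unique_seqs")) {
    seqs <- setNames(useqs$useqs$sequence, useqs$useqs$useq_id)
  } else seqs <- useqs
  if (length(seqs) == 0L) stop("no sequences")
  if (is.null(alignment)) {
    alignment <- star_align(seqs)  # first element has highest weight
  } else {
    miss <- setdiff(names(seqs), names(alignment))
    if (length(miss)) stop("alignment missing sequences: ",
                           paste(head(miss, 5L), collapse = ", "))
    alignment <- alignment[names(seqs)]
  }
  enc <- encode_alignment(alignment)
  p <- .cpp_p_matrix(enc, names(alignment))
  d <- matrix(jukes_cantor(as.vector(p), d_max = d_max), nrow(p), ncol(p))
  diag(d) <- 0
  dimnames(d) <- list(names(alignment), names(alignment))
  d
}

#' Furthest-neighbour (complete-linkage) OTU clustering
#'
#' Agglomerative clustering in which two clusters may merge at height h
#' only if every cross-pair distance is at most h. The partition at a
#' distance cutoff c is the state after all merges with height <= c; a
#' similarity level s corresponds to cutoff `1 - s` on the corrected
#' distance scale. Tied merge heights are processed in lexicographic order
#' of cluster labels, making results platform-independent.
#'
#' @param m symmetric distance matrix with dimnames.
#' @param cutoffs numeric vector of distance cutoffs in `[0, 1)`.
#' @param weights optional named abundances used to pick each cluster's
#'   representative (highest weight, ties by lexicographic id).
#' @return list of `otu_partition` objects (one per cutoff): each has
#'   `cutoff`, `similarity_level`, `clusters` (named list of member ids)
#'   and `representatives`.
#' @export
cluster_furthest_neighbor <- function(m, cutoffs, weights = NULL) {
  labels <- rownames(m)
  if (is.null(labels)) stop("distance matrix must have labels")
  if (any(cutoffs < 0 | cutoffs >= 1)) stop("cutoffs must be in [0, 1)")
  n <- length(labels)
  rk <- match(labels, sort(labels))
  cl <- .cpp_complete_linkage(m, rk)
  if (is.null(weights)) weights <- setNames(rep(1, n), labels)
  lapply(sort(cutoffs), function(cut) {
    parent <- seq_len(n)
    find <- function(x) {
      while (parent[x] != x) {
        parent[x] <<- parent[parent[x]]  # path halving
        x <- parent[x]
      }
      x
    }
    h <- cl$heights
    for (k in seq_along(h)) {
      if (h[k] > cut) break
      a <- find(cl$merges[k, 1L])
      b <- find(cl$merges[k, 2L])
      # union under the lexicographically smaller representative
      if (rk[a] <= rk[b]) parent[b] <- a else parent[a] <- b
    }
    roots <- labels[vapply(seq_len(n), find, 0L)]
    clusters <- split(labels, roots)
    reps <- vapply(clusters, function(mem) {
      w <- weights[mem]
      mem[order(-w, mem)][1L]
    }, "")
    structure(list(cutoff = cut, similarity_level = 1 - cut,
                   clusters = clusters, representatives = reps),
              class = "otu_partition")
  })
}

#' Map an OTU partition back to per-sample abundances
#'
#' Sums the per-sample counts of a cluster's member unique sequences,
#' recovering the abundance of every OTU in the original (redundant) tag
#' set. Column sums equal per-sample kept-tag counts; the grand total
#' equals the number of dereplicated tags.
#'
#' @param part an `otu_partition`.
#' @param useqs the `unique_seqs` object the partition was computed from.
#' @return an `otu_table`: integer matrix OTU x sample, ordered by
#'   decreasing total abundance, with attributes `similarity_level` and
#'   `representatives` (named vector of representative sequences).
#' @export
expand_to_table <- function(part, useqs) {
  counts <- useqs$counts
  rows <- lapply(part$clusters, function(mem) {
    colSums(counts[mem, , drop = FALSE])
  })
  tab <- do.call(rbind, rows)
  total <- rowSums(tab)
  reps <- part$representatives
  ord <- order(-total, reps)
  tab <- tab[ord, , drop = FALSE]
  reps <- reps[ord]
  otu_ids <- sprintf("OTU%05d", seq_len(nrow(tab)))
  rownames(tab) <- otu_ids
  rep_seq <- setNames(useqs$useqs$sequence[match(reps, useqs$useqs$useq_id)],
                      otu_ids)
  structure(tab, similarity_level = part$similarity_level,
            representatives = rep_seq, class = c("otu_table", class(tab)))
}
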