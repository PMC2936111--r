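#' Read sequence tags from a FASTA file
#'
#' Reads quality-unfiltered V6 tag sequences. The first whitespace-delimited
#' token of each header is the tag id; sequences are uppercased and RNA `U`
#' is normalised to `T`. File order is preserved. Sample attribution comes
#' either from `sample_id` (one FASTA per sample, the recommended layout) or
#' from a `sample=` key in the FASTA header.
#'
#' @param path path to a FASTA file.
#' @param sample_id sample id applied to every record, or `NULL` to take it
#'   from a `sample=<id>` field in each header.
#' @return a data.frame of class `tag_set` with columns `tag_id`,
#'   `sample_id`, `sequence`, `length`.
#' @export
read_tag_fasta <- function(path, sample_id = NULL) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  seqs <- parse_fasta(path)
  if (length(seqs) == 0L) {
    return(new_tag_set(data.frame(tag_id = character(), sample_id = character(),
                                  sequence = character(), length = integer(),
                                  stringsAsFactors = FALSE)))
  }
  headers <- names(seqs)
  tag_id <- vapply(strsplit(headers, "[ \t]+"), `[`, "", 1L)
  if (anyDuplicated(tag_id))
    stop("duplicate tag_id in ", path, ": ",
         paste(unique(tag_id[duplicated(tag_id)]), collapse = ", "))
  if (is.null(sample_id)) {
    m <- regmatches(headers, regexpr("sample=[^ \t]+", headers))
    sid <- rep(NA_character_, length(headers))
    has <- grepl("sample=", headers, fixed = TRUE)
    sid[has] <- sub("^sample=", "", m)
    if (anyNA(sid))
      stop("no sample_id given and no 'sample=' field in header of tag ",
           tag_id[which(is.na(sid))[1L]])
    sample_id <- sid
  }
  sequence <- chartr("u", "t", tolower(unname(seqs)))
  sequence <- toupper(sequence)
  if (any(!grepl("^[ACGTN]*$", sequence)))
    stop("non-DNA characters in sequence of tag ",
         tag_id[which(!grepl("^[ACGTN]*$", sequence))[1L]])
  if (any(nchar(sequence) == 0L))
    stop("empty sequence for tag ", tag_id[which(nchar(sequence) == 0L)[1L]])
  new_tag_set(data.frame(tag_id = tag_id, sample_id = sample_id,
                         sequence = sequence, length = nchar(sequence),
                         stringsAsFactors = FALSE))
}

# Minimal strict FASTA parser reporting the offending line on error.
# (Biostrings::readDNAStringSet is used for well-formed writing/reading
# elsewhere; here parse errors must name the line.)
parse_fasta <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0L) return(setNames(character(), character()))
  is_hdr <- startsWith(lines, ">")
  if (!is_hdr[1L] && any(nzchar(trimws(lines))))
    stop("malformed FASTA at line 1 of ", path, ": expected '>' header")
  idx <- cumsum(is_hdr)
  bad <- which(!is_hdr & nzchar(lines) & idx == 0L)
  if (length(bad)) stop("malformed FASTA at line ", bad[1L], " of ", path)
  headers <- sub("^>", "", lines[is_hdr])
  body <- split(lines[!is_hdr], idx[!is_hdr])
  seqs <- vapply(seq_along(headers), function(i) {
    b <- body[[as.character(i)]]
    if (is.null(b)) "" else paste(gsub("[ \t]", "", b), collapse = "")
  }, "")
  setNames(seqs, headers)
}

new_tag_set <- function(df) {
  stopifnot(identical(names(df),
                      c("tag_id", "sample_id", "sequence", "length")))
  class(df) <- c("tag_set", "data.frame")
  df
}

#' Write tags to FASTA
#'
#' Headers are `tag_id sample=<sample_id>`, so files round-trip through
#' [read_tag_fasta()] without a manifest.
#'
#' @param tags a `tag_set` data.frame.
#' @param path output path.
#' @export
write_tag_fasta <- function(tags, path) {
  x <- Biostrings::DNAStringSet(tags$sequence)
  names(x) <- paste0(tags$tag_id, " sample=", tags$sample_id)
  Biostrings::writeXStringSet(x, path, width = 80L)
  invisible(path)
}

#' Length and ambiguity quality control for tags
#'
#' Tags shorter than `min_len` nucleotides (after upstream primer removal)
#' are flagged low quality and removed, as are tags with more than `max_n`
#' ambiguous bases. The two returned sets partition the input.
#'
#' @param tags a `tag_set` data.frame.
#' @param min_len minimum tag length in nt retained (default 50).
#' @param max_n maximum number of `N` bases allowed (default 0).
#' @return `list(kept = , removed = )`, both `tag_set` data.frames; `removed`
#'   carries a `reason` column.
#' @export
qc_filter_tags <- function(tags, min_len = 50L, max_n = 0L) {
  n_amb <- nchar(tags$sequence) - nchar(gsub("N", "", tags$sequence, fixed = TRUE))
  short <- tags$length < min_len
  ambig <- n_amb > max_n
  keep <- !short & !ambig
  removed <- tags[!keep, , drop = FALSE]
  removed$reason <- ifelse(short[!keep], "short", "ambiguous")
  list(kept = tags[keep, , drop = FALSE], removed = removed)
}

#' Read a sample manifest
#'
#' Tab-separated columns: `sample_id`, `group` (one of `adult`, `larvae`,
#' `seawater`), `species` (empty for seawater), `replicate` (positive
#' integer), and optionally `fasta` (path of the sample's FASTA file,
#' relative to the manifest).
#'
#' @param path path to the manifest TSV.
#' @return a data.frame of class `sample_manifest`.
#' @export
read_manifest <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", quote = "",
                   colClasses = "character", check.names = FALSE)
  need <- c("sample_id", "group", "species", "replicate")
  if (!all(need %in% names(df)))
    stop("manifest must have columns: ", paste(need, collapse = ", "))
  df$replicate <- as.integer(df$replicate)
  validate_manifest(df)
}

#' @export
validate_manifest <- function(m) {
  if (anyDuplicated(m$sample_id))
    stop("duplicate sample_id in manifest: ",
         paste(unique(m$sample_id[duplicated(m$sample_id)]), collapse = ", "))
  bad <- setdiff(unique(m$group), c("adult", "larvae", "seawater"))
  if (length(bad)) stop("unknown sample group(s): ", paste(bad, collapse = ", "))
  if (any(is.na(m$replicate) | m$replicate < 1L))
    stop("replicate must be a positive integer")
  class(m) <- unique(c("sample_manifest", class(m)))
  m
}

#' Write a sample manifest
#' @param m a `sample_manifest` data.frame.
#' @param path output path.
#' @export
write_manifest <- function(m, path) {
  write_table(as.data.frame(m), path)
}

# Every tag must resolve to exactly one manifest entry; fails loudly.
resolve_samples <- function(tags, manifest) {
  miss <- setdiff(unique(tags$sample_id), manifest$sample_id)
  if (length(miss))
    stop("tags reference sample_id(s) absent from manifest: ",
         paste(miss, collapse = ", "))
  invisible(TRUE)
}

#' Read a reference 16S database
#'
#' Four tab-separated columns: `ref_id`, `taxonomy` (semicolon-delimited,
#' phylum to genus, trailing ranks may be empty), `cluster_label` (empty for
#' none; `SC`/`SCC` prefixes mark sponge-specific and sponge-coral-specific
#' sequence clusters), `sequence`. Taxonomy paths must be prefix-complete:
#' an empty rank may not be followed by a named one.
#'
#' @param path path to the TSV.
#' @return a data.frame of class `reference_db` with columns `ref_id`,
#'   `sequence`, `cluster_label` (`NA` for none) and `tax_phylum` ..
#'   `tax_genus`.
#' @export
read_reference_db <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", quote = "",
                   colClasses = "character", check.names = FALSE)
  need <- c("ref_id", "taxonomy", "cluster_label", "sequence")
  if (!all(need %in% names(df)))
    stop("reference db must have columns: ", paste(need, collapse = ", "))
  tax <- parse_taxonomy(df$taxonomy, df$ref_id)
  out <- data.frame(ref_id = df$ref_id,
                    sequence = toupper(chartr("Uu", "Tt", df$sequence)),
                    cluster_label = ifelse(df$cluster_label == "",
                                           NA_character_, df$cluster_label),
                    tax, stringsAsFactors = FALSE)
  validate_reference_db(out)
}

parse_taxonomy <- function(strings, ids) {
  parts <- strsplit(strings, ";", fixed = TRUE)
  tax <- t(vapply(parts, function(p) {
    p <- trimws(p)
    length(p) <- 5L
    p[is.na(p)] <- ""
    p
  }, character(5)))
  colnames(tax) <- paste0("tax_", TAX_RANKS)
  # prefix-completeness: no empty rank followed by a named one
  filled <- tax != ""
  bad <- apply(filled, 1L, function(f) any(diff(as.integer(f)) > 0L))
  if (any(bad))
    stop("taxonomy with internal gap (not prefix-complete) for: ",
         paste(ids[bad], collapse = ", "))
  as.data.frame(tax, stringsAsFactors = FALSE)
}

#' @export
validate_reference_db <- function(db) {
  if (anyDuplicated(db$ref_id))
    stop("duplicate ref_id: ",
         paste(unique(db$ref_id[duplicated(db$ref_id)]), collapse = ", "))
  if (any(db$tax_phylum == ""))
    stop("reference(s) lacking phylum-level annotation: ",
         paste(db$ref_id[db$tax_phylum == ""], collapse = ", "))
  class(db) <- unique(c("reference_db", class(db)))
  db
}

#' Write a reference database TSV
#' @param db a `reference_db` data.frame.
#' @param path output path.
#' @export
write_reference_db <- function(db, path) {
  tax <- apply(as.matrix(db[paste0("tax_", TAX_RANKS)]), 1L, paste,
               collapse = ";")
  out <- data.frame(ref_id = db$ref_id, taxonomy = tax,
                    cluster_label = ifelse(is.na(db$cluster_label), "",
                                           db$cluster_label),
                    sequence = db$sequence, stringsAsFactors = FALSE)
  write_table(out, path)
}

#' Write a distance matrix in PHYLIP format
#'
#' @param m symmetric numeric matrix with dimnames (zero diagonal).
#' @param path output path.
#' @param dialect `"phylip-square"` or `"phylip-lower"`.
#' @details Values are written with 6 decimals, which makes
#'   write-then-read round-trips exact at that precision.
#' @export
write_distance_matrix <- function(m, path,
                                  dialect = c("phylip-square", "phylip-lower")) {
  dialect <- match.arg(dialect)
  n <- nrow(m)
  if (is.null(n) || n == 0L) stop("cannot write an empty distance matrix")
  labels <- rownames(m)
  if (is.null(labels)) stop("distance matrix must have row labels")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(format(n), con)
  for (i in seq_len(n)) {
    vals <- if (dialect == "phylip-square") m[i, ] else m[i, seq_len(i - 1L)]
    writeLines(paste(c(labels[i], sprintf("%.6f", vals)), collapse = "\t"), con)
  }
  invisible(path)
}

#' Read a PHYLIP distance matrix
#' @param path input path.
#' @param dialect `"phylip-square"` or `"phylip-lower"`.
#' @return symmetric numeric matrix with dimnames.
#' @export
read_distance_matrix <- function(path,
                                 dialect = c("phylip-square", "phylip-lower")) {
  dialect <- match.arg(dialect)
  lines <- readLines(path)
  n <- as.integer(trimws(lines[1L]))
  if (is.na(n) || length(lines) < n + 1L) stop("malformed PHYLIP matrix: ", path)
  labels <- character(n)
  m <- matrix(0, n, n)
  for (i in seq_len(n)) {
    f <- strsplit(trimws(lines[i + 1L]), "[ \t]+")[[1L]]
    labels[i] <- f[1L]
    vals <- as.numeric(f[-1L])
    if (dialect == "phylip-square") {
      if (length(vals) != n) stop("row ", i, " has ", length(vals), " values")
      m[i, ] <- vals
    } else {
      if (length(vals) != i - 1L) stop("row ", i, " has ", length(vals), " values")
      if (i > 1L) { m[i, seq_len(i - 1L)] <- vals; m[seq_len(i - 1L), i] <- vals }
    }
  }
  dimnames(m) <- list(labels, labels)
  m
}

#' Write a data frame or matrix as a deterministic TSV
#'
#' Column order is preserved, a header row is always present, and floating
#' point columns are written at fixed precision so identical inputs produce
#' byte-identical files.
#'
#' @param x data.frame or matrix (matrices are written with a leading id
#'   column named by `id_col`).
#' @param path output path.
#' @param digits decimals for numeric (non-integer) columns.
#' @param id_col name for the row-label column when `x` is a matrix.
#' @export
write_table <- function(x, path, digits = 6L, id_col = "id") {
  if (is.matrix(x)) {
    df <- data.frame(rownames(x) %||% as.character(seq_len(nrow(x))),
                     as.data.frame(x), check.names = FALSE,
                     stringsAsFactors = FALSE)
    names(df)[1L] <- id_col
    x <- df
  }
  for (j in seq_along(x)) {
    if (is.double(x[[j]])) x[[j]] <- sprintf(paste0("%.", digits, "f"), x[[j]])
  }
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE)
  invisible(path)
}

#' Read a TSV written by [write_table()]
#' @param path input path.
#' @export
read_table_tsv <- function(path) {
  read.table(path, header = TRUE, sep = "\t", quote = "", check.names = FALSE,
             stringsAsFactors = FALSE)
}
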