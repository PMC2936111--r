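validate_abundance <- function(counts) {
  counts <- counts[counts > 0]
  if (length(counts) == 0L) stop("abundance vector has no positive counts")
  if (any(counts != round(counts))) stop("counts must be integers")
  as.integer(counts)
}

#' Exact rarefaction curve
#'
#' Expected number of OTUs observed in a random subsample of n reads,
#' computed from the hypergeometric closed form
#' `E[S_n] = sum_i (1 - choose(N - N_i, n) / choose(N, n))` using log-gamma
#' arithmetic so deep samples (N ~ 1e5) do not overflow.
#'
#' @param counts vector of positive OTU abundances.
#' @param depths subsample sizes, each between 1 and `sum(counts)`.
#' @return data.frame `depth`, `expected_otus`.
#' @export
rarefaction_curve <- function(counts, depths) {
  counts <- validate_abundance(counts)
  N <- sum(counts)
  if (any(depths < 1 | depths > N)) stop("depths must be in [1, ", N, "]")
  if (any(depths != round(depths))) stop("depths must be integers")
  es <- vapply(depths, function(n) {
    # log C(N - Ni, n) - log C(N, n); term is 0 when N - Ni < n
    ok <- (N - counts) >= n
    lr <- lchoose(N - counts[ok], n) - lchoose(N, n)
    sum(1 - exp(lr)) + sum(!ok)
  }, 0)
  data.frame(depth = as.integer(depths), expected_otus = es)
}

#' Chao1 richness estimator
#'
#' Classic form `S_obs + F1^2 / (2 F2)`; the bias-corrected form
#' `S_obs + F1 (F1 - 1) / (2 (F2 + 1))` is used when requested and as the
#' automatic fallback when no doubletons are present.
#'
#' @param counts vector of positive OTU abundances.
#' @param bias_corrected use the bias-corrected form unconditionally.
#' @export
chao1 <- function(counts, bias_corrected = FALSE) {
  counts <- validate_abundance(counts)
  s_obs <- length(counts)
  f1 <- sum(counts == 1L)
  f2 <- sum(counts == 2L)
  if (bias_corrected || f2 == 0L)
    s_obs + f1 * (f1 - 1) / (2 * (f2 + 1))
  else
    s_obs + f1^2 / (2 * f2)
}

#' ACE richness estimator
#'
#' Abundance-based coverage estimator with the conventional rare/abundant
#' split at `rare_cutoff` reads (default 10). When every rare OTU is a
#' singleton the sample coverage estimate is zero and the function falls
#' back to bias-corrected Chao1 with a warning.
#'
#' @param counts vector of positive OTU abundances.
#' @param rare_cutoff maximum count for an OTU to be treated as rare.
#' @export
ace <- function(counts, rare_cutoff = 10L) {
  counts <- validate_abundance(counts)
  rare <- counts[counts <= rare_cutoff]
  s_abund <- sum(counts > rare_cutoff)
  s_rare <- length(rare)
  if (s_rare == 0L) return(length(counts))
  n_rare <- sum(rare)
  f1 <- sum(rare == 1L)
  c_ace <- 1 - f1 / n_rare
  if (c_ace == 0) {
    warning("all rare OTUs are singletons; falling back to bias-corrected Chao1")
    return(chao1(counts, bias_corrected = TRUE))
  }
  ks <- seq_len(rare_cutoff)
  fk <- vapply(ks, function(k) sum(rare == k), 0L)
  gamma2 <- max((s_rare / c_ace) * sum(ks * (ks - 1) * fk) /
                  (n_rare * (n_rare - 1)) - 1, 0)
  s_abund + s_rare / c_ace + (f1 / c_ace) * gamma2
}

#' Rank-abundance curve
#'
#' @param counts vector of positive OTU abundances.
#' @param max_ranks optional truncation (e.g. first 1400 ranks for display).
#' @return data.frame `rank`, `count` with counts sorted decreasing
#'   (stable, so ties keep their input order).
#' @export
rank_abundance <- function(counts, max_ranks = NULL) {
  counts <- validate_abundance(counts)
  s <- sort(counts, decreasing = TRUE, method = "radix")  # stable
  out <- data.frame(rank = seq_along(s), count = s)
  if (!is.null(max_ranks)) out <- out[seq_len(min(max_ranks, nrow(out))), ]
  out
}

#' Richness summary for an OTU table
#'
#' @param otu_table integer matrix OTU x sample (an [expand_to_table()]
#'   result); columns may also be pooled beforehand.
#' @param rare_cutoff passed to [ace()].
#' @return data.frame with one row per column: `sample`, `n_reads`,
#'   `s_obs`, `chao1`, `ace`.
#' @export
richness_summary <- function(otu_table, rare_cutoff = 10L) {
  do.call(rbind, lapply(colnames(otu_table), function(s) {
    v <- otu_table[, s]
    v <- v[v > 0]
    data.frame(sample = s, n_reads = sum(v), s_obs = length(v),
               chao1 = chao1(v), ace = ace(v, rare_cutoff),
               stringsAsFactors = FALSE)
  }))
}
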