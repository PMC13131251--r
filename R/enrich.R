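#' Read a GMT gene-set file
#'
#' One set per line: name, description, then tab-separated member symbols.
#' Members are deduplicated; sets outside the size bounds (after
#' deduplication) are dropped.
#'
#' @param path GMT file path.
#' @param min_size,max_size inclusive set-size bounds (defaults 10/500).
#' @return list with `sets` (named list of character vectors) and
#'   `descriptions` (named character vector).
#' @export
read_gmt <- function(path, min_size = 10, max_size = 500) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3)
  if (length(bad))
    stop("malformed GMT line ", bad[1], ": fewer than 3 tab-separated fields")
  nms <- vapply(fields, `[`, character(1), 1)
  if (anyDuplicated(nms))
    stop("duplicate set names: ",
         paste(unique(nms[duplicated(nms)]), collapse = ", "))
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- nms
  descriptions <- vapply(fields, `[`, character(1), 2)
  names(descriptions) <- nms
  keep <- lengths(sets) >= min_size & lengths(sets) <= max_size
  list(sets = sets[keep], descriptions = descriptions[keep])
}

#' Build a ranked gene list from meta-analysis results
#'
#' Ranks genes by pooled log2FC (directional mode) or its absolute value
#' (non-directional mode), restricted to converged fits. Ties in the
#' statistic are broken by descending absolute statistic, then lexicographic
#' gene symbol, so the order is total and deterministic.
#'
#' @param meta a `meta_results` data.frame (see [run_meta()]).
#' @param mode `"directional"` or `"absolute"`.
#' @return named numeric vector, sorted in decreasing rank order.
#' @export
rank_genes <- function(meta, mode = c("directional", "absolute")) {
  mode <- match.arg(mode)
  ok <- meta$converged & is.finite(meta$log2fc)
  stat <- meta$log2fc[ok]
  genes <- meta$gene[ok]
  if (mode == "absolute") stat <- abs(stat)
  o <- order(-stat, -abs(stat), genes)
  out <- stat[o]
  names(out) <- genes[o]
  if (anyDuplicated(names(out))) stop("duplicate genes in ranking")
  out
}

#' Weighted Kolmogorov-Smirnov enrichment score
#'
#' Walks the ranked list accumulating `|r|^p / sum_{g in S} |r|^p` at set
#' members and `-1/(N - |S|)` elsewhere; the enrichment score is the running
#' sum's maximal absolute deviation from zero (sign retained; a magnitude tie
#' between the positive and negative extremum resolves positive). The leading
#' edge contains the set members at or before the extremum (at or after it,
#' for negative scores).
#'
#' @param ranked named statistic vector in decreasing rank order (see
#'   [rank_genes()]).
#' @param set character vector of member symbols.
#' @param p_exp weight exponent on the statistic (default 1).
#' @return list with `es`, `leading_edge`, and `size` (members in universe).
#' @export
enrichment_score <- function(ranked, set, p_exp = 1) {
  N <- length(ranked)
  hit <- names(ranked) %in% set
  s <- sum(hit)
  if (s == 0) stop("set has no members in the ranked universe")
  if (s == N) stop("set equals the ranked universe")
  r <- abs(ranked)^p_exp
  denom <- sum(r[hit])
  if (denom == 0) stop("degenerate ranking: zero total weight over members")
  inc <- ifelse(hit, r / denom, -1 / (N - s))
  running <- cumsum(inc)
  i_pos <- which.max(running)
  i_neg <- which.min(running)
  # magnitude ties between the positive and negative extremum go positive
  if (running[[i_pos]] >= -running[[i_neg]]) {
    i_max <- i_pos
  } else {
    i_max <- i_neg
  }
  es <- running[[i_max]]
  le <- if (es >= 0) {
    names(ranked)[seq_len(i_max)][hit[seq_len(i_max)]]
  } else {
    names(ranked)[i_max:N][hit[i_max:N]]
  }
  list(es = unname(es), leading_edge = le, size = s)
}

# Enrichment score from sorted hit positions only (same walk as
# enrichment_score, O(s)); used for permutations.
es_from_positions <- function(pos, r, N, denom = NULL) {
  s <- length(pos)
  if (is.null(denom)) denom <- sum(r[pos])
  cum_hit <- cumsum(r[pos]) / denom
  miss_before <- (pos - seq_len(s)) / (N - s)
  at_hit <- cum_hit - miss_before
  before_hit <- c(0, cum_hit[-s]) - miss_before
  hi <- max(at_hit)
  lo <- min(before_hit)
  if (hi >= -lo) hi else lo
}

#' Preranked gene-set enrichment with gene-permutation p-values
#'
#' For each set of in-universe size s, compares its enrichment score against
#' scores of `nperm` random size-s gene samples from the universe. The
#' p-value is one-sided on the sign of the observed score,
#' `(1 + #{same-sign permuted ES at least as extreme}) / (n_same_sign + 1)`
#' (the preranked-GSEA convention), so the minimum attainable p is bounded
#' by the permutation count and null p-values are uniform. A normalized
#' score (ES over the mean same-sign permuted |ES|) is reported alongside.
#' FDR is Benjamini-Hochberg across the collection.
#'
#' @param ranked named statistic vector from [rank_genes()].
#' @param collection list as returned by [read_gmt()], or a bare named list
#'   of sets.
#' @param nperm permutations per set size (>= 100).
#' @param seed integer seed.
#' @param p_exp weight exponent.
#' @return data.frame: set, size, es, nes, pval, fdr, leading_edge
#'   (comma-joined).
#' @export
gsea_pvalues <- function(ranked, collection, nperm = 1000, seed = 1L,
                         p_exp = 1) {
  if (nperm < 100) stop("nperm must be >= 100")
  sets <- if (!is.null(collection$sets)) collection$sets else collection
  N <- length(ranked)
  r <- abs(ranked)^p_exp
  obs <- lapply(sets, function(s) {
    members <- intersect(s, names(ranked))
    if (!length(members)) return(NULL)
    enrichment_score(ranked, members, p_exp = p_exp)
  })
  keep <- !vapply(obs, is.null, logical(1))
  sets <- sets[keep]
  obs <- obs[keep]
  sizes <- vapply(obs, `[[`, integer(1) + 0, "size")

  set.seed(seed)
  perm_by_size <- list()
  for (s in sort(unique(sizes))) {
    perm_by_size[[as.character(s)]] <- vapply(seq_len(nperm), function(i) {
      es_from_positions(sort.int(sample.int(N, s)), r, N)
    }, numeric(1))
  }

  res <- data.frame(set = names(sets), size = sizes,
                    es = vapply(obs, `[[`, numeric(1), "es"),
                    nes = NA_real_, pval = NA_real_,
                    leading_edge = vapply(obs, function(o)
                      paste(o$leading_edge, collapse = ","), character(1)),
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(res))) {
    perms <- perm_by_size[[as.character(res$size[i])]]
    es <- res$es[i]
    if (es >= 0) {
      side <- perms[perms >= 0]
      count <- sum(side >= es)
    } else {
      side <- perms[perms < 0]
      count <- sum(side <= es)
    }
    res$pval[i] <- (1 + count) / (length(side) + 1)
    res$nes[i] <- if (length(side)) es / mean(abs(side)) else NA_real_
  }
  res$fdr <- bh_adjust(res$pval)
  rownames(res) <- NULL
  res[, c("set", "size", "es", "nes", "pval", "fdr", "leading_edge")]
}
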