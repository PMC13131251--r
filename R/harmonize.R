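#' Read a per-contrast differential-expression result table
#'
#' Reads a tab-separated export with columns `element_id`, `gene_symbol`,
#' `log2fc`, `tstat`, `pvalue` and applies the annotation exclusion rule:
#' rows with empty, missing, or ambiguous (multi-symbol, pipe- or
#' comma-delimited) gene annotations are dropped. Rows with non-numeric
#' effect estimates are dropped with a warning reporting their count.
#'
#' @param path TSV path.
#' @return data.frame of probe-level rows with clean annotations.
#' @export
read_contrast_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  required <- c("element_id", "gene_symbol", "log2fc", "tstat", "pvalue")
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols))
    stop("format error: missing column(s): ",
         paste(missing_cols, collapse = ", "))
  for (col in c("log2fc", "tstat", "pvalue")) {
    suppressWarnings(tab[[col]] <- as.numeric(tab[[col]]))
  }
  bad_num <- !is.finite(tab$log2fc) | !is.finite(tab$tstat)
  if (any(bad_num))
    warning(sum(bad_num), " row(s) with non-numeric or non-finite log2fc/tstat dropped")
  sym <- tab$gene_symbol
  ambiguous <- is.na(sym) | !nzchar(trimws(sym)) | grepl("[|,]", sym)
  tab[!bad_num & !ambiguous, required]
}

#' Collapse probe-level rows to gene-level effect sizes
#'
#' Gene-level log2FC is the arithmetic mean of probe log2FCs. Probe standard
#' errors are recovered from the Wald identity `se_p = |log2fc_p / tstat_p|`;
#' the variance of the gene-level mean is pooled either assuming independent
#' probe errors, `sv = sum(se_p^2) / P^2`, or perfectly correlated ones,
#' `sv = mean(se_p^2)`. Probes with `|tstat|` below `t_tol` carry no usable
#' standard error and are excluded from the variance pooling (but still
#' contribute to the mean); genes with no usable probe are dropped with a
#' warning.
#'
#' @param probe_rows data.frame as returned by [read_contrast_table()].
#' @param probe_corr `"independent"` (default) or `"perfect"` probe-error
#'   correlation assumption for pooling.
#' @param t_tol tolerance below which a t-statistic is treated as degenerate.
#' @return data.frame with columns gene, log2fc, se, sv, n_probes.
#' @export
collapse_to_gene <- function(probe_rows, probe_corr = c("independent", "perfect"),
                             t_tol = 1e-8) {
  probe_corr <- match.arg(probe_corr)
  stopifnot(all(is.finite(probe_rows$log2fc)), all(is.finite(probe_rows$tstat)))
  usable <- abs(probe_rows$tstat) >= t_tol
  se_p <- ifelse(usable, abs(probe_rows$log2fc / probe_rows$tstat), NA_real_)
  split_idx <- split(seq_len(nrow(probe_rows)), probe_rows$gene_symbol)
  out <- lapply(names(split_idx), function(g) {
    i <- split_idx[[g]]
    lfc <- mean(probe_rows$log2fc[i])
    iu <- i[usable[i]]
    if (!length(iu)) return(NULL)
    sv <- if (probe_corr == "independent") {
      sum(se_p[iu]^2) / length(iu)^2
    } else {
      mean(se_p[iu]^2)
    }
    data.frame(gene = g, log2fc = lfc, se = sqrt(sv), sv = sv,
               n_probes = length(i), stringsAsFactors = FALSE)
  })
  dropped <- vapply(out, is.null, logical(1))
  if (any(dropped))
    warning(sum(dropped), " gene(s) dropped: no probe with usable t-statistic")
  res <- do.call(rbind, out[!dropped])
  rownames(res) <- NULL
  res
}

#' Align gene-level effects across contrasts and apply the coverage filter
#'
#' Builds the gene x contrast matrices of log2 fold changes and sampling
#' variances over the union of (case-sensitively matched) gene symbols,
#' preserving the contrast order of the metadata table, and removes genes
#' represented in fewer than `min_contrasts` contrasts. The default threshold
#' is `ceiling(0.722 * C)` — 13 when C = 18 contrasts.
#'
#' @param gene_effect_lists named list (one element per contrast, names =
#'   contrast ids) of [collapse_to_gene()] outputs.
#' @param metadata contrast-metadata data.frame (`dataset_id`, `contrast_id`,
#'   `sd_hours`, `rs_hours`, `n`).
#' @param min_contrasts minimum per-gene coverage; `NULL` for the default.
#' @return object of class `gene_effect_matrix`: list with `genes`,
#'   `contrasts` (metadata), `effects`, `variances` (matrices with NA for
#'   absent cells) and `coverage`.
#' @export
align_and_filter <- function(gene_effect_lists, metadata, min_contrasts = NULL) {
  stopifnot(nrow(metadata) >= 1)
  cids <- metadata$contrast_id
  missing_tables <- setdiff(cids, names(gene_effect_lists))
  if (length(missing_tables))
    stop("no gene-effect table for contrast(s): ",
         paste(missing_tables, collapse = ", "))
  C <- length(cids)
  if (is.null(min_contrasts)) min_contrasts <- ceiling(0.722 * C)
  if (min_contrasts < 2) stop("min_contrasts must be >= 2")
  genes <- sort(unique(unlist(lapply(gene_effect_lists[cids],
                                     function(x) x$gene))))
  eff <- matrix(NA_real_, length(genes), C, dimnames = list(genes, cids))
  var_ <- eff
  for (cid in cids) {
    tab <- gene_effect_lists[[cid]]
    if (is.null(tab) || !nrow(tab)) next
    if (anyDuplicated(tab$gene))
      stop("duplicate (gene, contrast) pair in contrast ", cid,
           ": collapse failed upstream")
    eff[tab$gene, cid] <- tab$log2fc
    var_[tab$gene, cid] <- tab$sv
  }
  coverage <- rowSums(!is.na(eff))
  keep <- coverage >= min_contrasts
  structure(list(genes = genes[keep], contrasts = metadata,
                 effects = eff[keep, , drop = FALSE],
                 variances = var_[keep, , drop = FALSE],
                 coverage = coverage[keep],
                 min_contrasts = min_contrasts),
            class = "gene_effect_matrix")
}

#' Harmonize a set of contrast tables from disk
#'
#' Convenience wrapper: read each per-contrast TSV, collapse to gene level,
#' align and coverage-filter.
#'
#' @param paths named character vector of contrast TSV paths (names =
#'   contrast ids).
#' @param metadata contrast-metadata data.frame.
#' @inheritParams align_and_filter
#' @inheritParams collapse_to_gene
#' @return a `gene_effect_matrix`.
#' @export
harmonize_contrasts <- function(paths, metadata, min_contrasts = NULL,
                                probe_corr = "independent") {
  effects <- lapply(paths, function(p)
    collapse_to_gene(read_contrast_table(p), probe_corr = probe_corr))
  align_and_filter(effects, metadata, min_contrasts = min_contrasts)
}

#' Display label for a contrast
#'
#' "DATASET SDh" with "+ RSh RS" appended when recovery sleep is present,
#' mirroring forest-plot row labels.
#'
#' @param metadata contrast-metadata data.frame (or one row thereof).
#' @return character vector of labels.
#' @export
contrast_label <- function(metadata) {
  lab <- sprintf("%s %gh SD", metadata$dataset_id, metadata$sd_hours)
  has_rs <- metadata$rs_hours > 0
  lab[has_rs] <- sprintf("%s + %gh RS", lab[has_rs], metadata$rs_hours[has_rs])
  lab
}

#' Write a gene-effect matrix as a wide TSV pair
#'
#' @param mat a `gene_effect_matrix`.
#' @param effects_path,variances_path output TSV paths.
#' @return invisibly, the two paths.
#' @export
write_effect_matrix <- function(mat, effects_path, variances_path) {
  for (field in c("effects", "variances")) {
    path <- if (field == "effects") effects_path else variances_path
    df <- data.frame(gene = mat$genes, mat[[field]], coverage = mat$coverage,
                     check.names = FALSE, stringsAsFactors = FALSE)
    write_tsv_num(df, path)
  }
  invisible(c(effects_path, variances_path))
}
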