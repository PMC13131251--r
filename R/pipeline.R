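#' Two-sample t-test power via the noncentral t distribution
#'
#' Power of a two-sided two-sample t-test for a standardized effect size d,
#' splitting `n_total` into groups of floor and ceiling of n/2.
#'
#' @param n_total total animals across both groups (>= 4).
#' @param d standardized mean difference (Cohen's d, > 0).
#' @param alpha two-sided significance level.
#' @return power in (0, 1).
#' @export
power_check <- function(n_total, d, alpha = 0.05) {
  if (n_total < 4) stop("n_total must be >= 4")
  if (d <= 0) stop("effect size d must be positive")
  n1 <- floor(n_total / 2)
  n2 <- ceiling(n_total / 2)
  df <- n1 + n2 - 2
  ncp <- d * sqrt(n1 * n2 / (n1 + n2))
  crit <- stats::qt(1 - alpha / 2, df)
  stats::pt(-crit, df, ncp) + 1 - stats::pt(crit, df, ncp)
}

#' Forest-plot data for one gene
#'
#' One row per contributing contrast (label, observed log2FC, 95% Wald CI)
#' plus a pooled "RE Model" row taken from the meta-analysis fit.
#'
#' @param gene gene symbol.
#' @param meta `meta_results` table.
#' @param mat the `gene_effect_matrix` the results were fitted from.
#' @return data.frame: label, log2fc, ci_lb, ci_ub, pooled (logical).
#' @export
export_forest <- function(gene, meta, mat) {
  i <- match(gene, mat$genes)
  if (is.na(i)) {
    near <- utils::head(agrep(gene, mat$genes, value = TRUE, max.distance = 0.2), 5)
    stop("gene '", gene, "' not in the effect matrix",
         if (length(near)) paste0("; nearest symbols: ",
                                  paste(near, collapse = ", ")) else "")
  }
  present <- !is.na(mat$effects[i, ])
  y <- mat$effects[i, present]
  se <- sqrt(mat$variances[i, present])
  crit <- stats::qnorm(0.975)
  rows <- data.frame(label = contrast_label(mat$contrasts[present, ]),
                     log2fc = unname(y), ci_lb = unname(y - crit * se),
                     ci_ub = unname(y + crit * se), pooled = FALSE,
                     stringsAsFactors = FALSE)
  m <- meta[meta$gene == gene, ]
  if (nrow(m) == 1 && isTRUE(m$converged)) {
    rows <- rbind(rows, data.frame(label = "RE Model", log2fc = m$log2fc,
                                   ci_lb = m$ci_lb, ci_ub = m$ci_ub,
                                   pooled = TRUE, stringsAsFactors = FALSE))
  }
  rows
}

#' Compare moderated and intercept-only pooled effects
#'
#' Regresses the moderated-model SD effect on the intercept-only pooled
#' effect over the intercept-only DEGs. A slope above 1 indicates that
#' contrasts with recovery sleep diluted the plain pooled effects.
#'
#' @param meta_plain intercept-only `meta_results`.
#' @param meta_mod moderated `meta_results`.
#' @param q FDR threshold selecting the DEGs compared.
#' @return list: slope, slope_se, n_genes, n_opposite_rs (DEGs whose RS
#'   coefficient opposes their SD effect).
#' @export
dilution_report <- function(meta_plain, meta_mod, q = 0.05) {
  degs <- meta_plain$gene[!is.na(meta_plain$fdr) & meta_plain$fdr < q]
  merged <- merge(meta_plain[meta_plain$gene %in% degs, c("gene", "log2fc")],
                  meta_mod[, c("gene", "log2fc", "beta_rs", "converged")],
                  by = "gene", suffixes = c("_plain", "_moderated"))
  merged <- merged[merged$converged, ]
  if (nrow(merged) < 3) stop("too few DEGs for the dilution comparison")
  fit <- stats::lm(log2fc_moderated ~ log2fc_plain, data = merged)
  sl <- summary(fit)$coefficients[2, 1:2]
  list(slope = unname(sl[1]), slope_se = unname(sl[2]),
       n_genes = nrow(merged),
       n_opposite_rs = sum(sign(merged$beta_rs) !=
                             sign(merged$log2fc_plain), na.rm = TRUE))
}

#' Run the full pipeline over a configuration
#'
#' Executes harmonize -> meta-analysis (intercept-only and moderated) ->
#' preranked enrichment (directional and absolute rankings) -> validation
#' re-analysis -> congruence, writing all result tables under `out_dir` and
#' returning (and writing) a manifest with input checksums, seeds, package
#' version and summary counts. Any stage error aborts with the stage name;
#' tables written before the failure are left in place.
#'
#' @param config list with elements `contrast_paths` (named character
#'   vector), `metadata_path`, `gmt_path`, `counts_path`, `samples_path`,
#'   and optionally `out_dir` (default `tempfile()`), `min_contrasts`,
#'   `q` (default 0.05), `nperm` (default 1000), `seed` (default 1),
#'   `probe_corr`.
#' @return manifest list, invisibly; also written as `manifest.json`.
#' @export
run_pipeline <- function(config) {
  q <- config$q %||% 0.05
  if (q <= 0 || q >= 1) stop("q must lie in (0, 1)")
  seed <- as.integer(config$seed %||% 1L)
  nperm <- config$nperm %||% 1000
  out_dir <- config$out_dir %||% tempfile("sleepmeta_run_")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  inputs <- c(config$contrast_paths, config$metadata_path, config$gmt_path,
              config$counts_path, config$samples_path)
  if (!all(file.exists(inputs)))
    stop("missing input file(s): ",
         paste(inputs[!file.exists(inputs)], collapse = ", "))

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  metadata <- stage("harmonize", utils::read.delim(config$metadata_path,
                                                   stringsAsFactors = FALSE))
  mat <- stage("harmonize",
               harmonize_contrasts(config$contrast_paths, metadata,
                                   min_contrasts = config$min_contrasts,
                                   probe_corr = config$probe_corr %||%
                                     "independent"))
  write_effect_matrix(mat, file.path(out_dir, "effects.tsv"),
                      file.path(out_dir, "variances.tsv"))

  meta_plain <- stage("metacore", run_meta(mat, "intercept", q = q))
  meta_mod <- stage("metacore", run_meta(mat, "moderated", q = q))
  write_tsv_num(meta_plain, file.path(out_dir, "meta_intercept.tsv"))
  write_tsv_num(meta_mod, file.path(out_dir, "meta_moderated.tsv"))

  gmt <- stage("enrich", read_gmt(config$gmt_path))
  gsea <- list()
  for (mode in c("directional", "absolute")) {
    ranked <- stage("enrich", rank_genes(meta_plain, mode))
    gsea[[mode]] <- stage("enrich",
                          gsea_pvalues(ranked, gmt, nperm = nperm, seed = seed))
    write_tsv_num(gsea[[mode]],
                  file.path(out_dir, sprintf("gsea_%s.tsv", mode)))
  }

  counts_df <- stage("rnaseq_validate",
                     utils::read.delim(config$counts_path, check.names = FALSE,
                                       stringsAsFactors = FALSE))
  counts <- as.matrix(counts_df[, -1, drop = FALSE])
  rownames(counts) <- counts_df[[1]]
  samples <- stage("rnaseq_validate",
                   utils::read.delim(config$samples_path,
                                     stringsAsFactors = FALSE))
  de <- stage("rnaseq_validate", run_de_analysis(counts, samples))
  write_tsv_num(de, file.path(out_dir, "validation_de.tsv"))
  cong <- stage("rnaseq_validate", congruence(meta_plain, de, q = q))
  write_tsv_num(cong$pairs, file.path(out_dir, "congruence_pairs.tsv"))

  dil <- stage("report", tryCatch(dilution_report(meta_plain, meta_mod, q = q),
                                  error = function(e) NULL))

  s_plain <- attr(meta_plain, "summary")
  manifest <- list(
    package_version = as.character(utils::packageVersion("sleepmeta")),
    seed = seed, q = q, nperm = nperm,
    input_md5 = as.list(tools::md5sum(inputs)),
    genes_analysed = unname(s_plain["total"]),
    genes_stable = unname(s_plain["stable"]),
    n_degs = unname(s_plain["significant"]),
    n_degs_moderated = unname(attr(meta_mod, "summary")["significant"]),
    gsea_significant = vapply(gsea, function(g) sum(g$fdr < q), numeric(1)),
    congruence = cong[c("n_degs", "n_represented", "n_same_direction",
                        "n_fully_validated", "ols_slope", "spearman_rho")],
    dilution = if (is.null(dil)) NULL else dil
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
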