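#' Default multi-study contrast design
#'
#' Returns the contrast-metadata table that the synthetic generator emulates:
#' 18 sleep-deprivation (SD) vs. control contrasts drawn from 8 studies, with
#' SD durations between 3 and 12 h and recovery sleep (RS, 0--18 h) present in
#' 6 contrasts from 3 of the studies. Per-contrast sample sizes are plausible
#' animal counts on the scale of the public studies being emulated.
#'
#' @return A data.frame with columns `dataset_id`, `contrast_id`, `sd_hours`,
#'   `rs_hours` (0 = no recovery sleep) and `n` (animals contributing to the
#'   contrast).
#' @export
default_contrast_design <- function() {
  design <- data.frame(
    dataset_id = c(rep("SYN001", 3), rep("SYN002", 2), rep("SYN003", 4),
                   "SYN004", "SYN005", rep("SYN006", 4), "SYN007",
                   rep("SYN008", 2)),
    sd_hours = c(6, 9, 12,  6, 6,  6, 6, 5, 5,  12,  5,  3, 6, 9, 12,  4,  6, 4),
    rs_hours = c(0, 0, 0,   0, 18, 1, 2, 3, 6,  0,   0,  0, 0, 0, 0,   0,  0, 2),
    n        = c(22, 22, 22, 6, 6, 26, 26, 26, 26, 9, 20, 27, 27, 27, 27, 4, 22, 22),
    stringsAsFactors = FALSE
  )
  design$contrast_id <- sprintf("%s_c%d", design$dataset_id,
                                stats::ave(seq_len(nrow(design)),
                                           design$dataset_id, FUN = seq_along))
  design[, c("dataset_id", "contrast_id", "sd_hours", "rs_hours", "n")]
}

#' Simulation configuration
#'
#' Bundles and validates all parameters of the synthetic multi-study
#' generator. Defaults emulate the statistical structure of the emulated
#' meta-analysis design: 18 contrasts from 8 studies
#' ([default_contrast_design()]), a mostly-null transcriptome with a 10%
#' differentially expressed (DE) fraction, small true effects (SD 0.1 log2FC),
#' per-gene between-contrast heterogeneity tau^2 in [0, 0.005], sampling
#' variance 0.005 at a reference group size of 10 animals scaling as 1/n, and
#' full reversal of SD effects by recovery sleep.
#'
#' @param n_genes number of simulated genes.
#' @param design contrast-metadata data.frame (see [default_contrast_design()]).
#' @param prop_de fraction of genes with non-null true SD effects.
#' @param effect_sd standard deviation (log2FC units) of non-null true effects.
#' @param tau2_range length-2 interval from which per-gene heterogeneity
#'   variances are drawn uniformly.
#' @param base_sv sampling variance of a contrast-level log2FC at `n_ref`
#'   animals; contrast `c` gets `base_sv * n_ref / n_c`.
#' @param n_ref reference animal count for `base_sv`.
#' @param rs_reversal fraction of the SD effect undone by recovery sleep: the
#'   generative RS coefficient is `-rs_reversal * mu_true`.
#' @param missing_rate probability that a gene is absent from a given contrast.
#' @param probes_per_gene named numeric vector of probabilities over probe
#'   counts, e.g. `c("1" = .85, "2" = .10, "3" = .05)`.
#' @param seed integer seed; fixed seed implies byte-identical outputs.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 2000,
                       design = default_contrast_design(),
                       prop_de = 0.1,
                       effect_sd = 0.1,
                       tau2_range = c(0, 0.005),
                       base_sv = 0.005,
                       n_ref = 10,
                       rs_reversal = 1,
                       missing_rate = 0.1,
                       probes_per_gene = c("1" = 0.85, "2" = 0.10, "3" = 0.05),
                       seed = 1L) {
  if (n_genes < 1) stop("configuration error: need at least one gene")
  if (nrow(design) < 1) stop("configuration error: need at least one contrast")
  for (nm in c("prop_de", "missing_rate", "rs_reversal")) {
    val <- get(nm)
    if (!is.numeric(val) || val < 0 || val > 1)
      stop("configuration error: ", nm, " must lie in [0, 1]")
  }
  if (base_sv <= 0) stop("configuration error: base_sv must be positive")
  if (length(tau2_range) != 2 || any(tau2_range < 0) ||
      tau2_range[1] > tau2_range[2])
    stop("configuration error: tau2_range must be a nonnegative interval")
  if (any(design$n < 2)) stop("configuration error: contrasts need n >= 2")
  if (abs(sum(probes_per_gene) - 1) > 1e-8 || any(probes_per_gene < 0))
    stop("configuration error: probes_per_gene must be a probability vector")
  structure(list(n_genes = n_genes, design = design, prop_de = prop_de,
                 effect_sd = effect_sd, tau2_range = tau2_range,
                 base_sv = base_sv, n_ref = n_ref, rs_reversal = rs_reversal,
                 missing_rate = missing_rate, probes_per_gene = probes_per_gene,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate per-contrast differential-expression tables with known truth
#'
#' Draws per-gene true SD effects and heterogeneity, then for every contrast
#' generates probe-level result rows mimicking a curated re-analysis export
#' (`element_id`, `gene_symbol`, `log2fc`, `tstat`, `pvalue`).
#'
#' Generative model, per gene g and contrast c (sampling variance
#' `v_gc = base_sv * n_ref / n_c`):
#' \deqn{theta_gc = mu_g + rsEffect_g * 1[RS_c > 0] + u_gc,\quad
#'       u_gc ~ N(0, tau2_g)}
#' Each of the P probes observes `theta_gc + eta_p` with
#' `eta_p ~ N(0, P * v_gc)`, and reports variance `P * v_gc`
#' (`tstat = log2fc / sqrt(P * v_gc)`); the probe-average is therefore
#' exactly `N(theta_gc, v_gc)`, so gene-level collapse recovers a correctly
#' calibrated effect/variance pair for any probe count.
#'
#' @param config a [sim_config()] object.
#' @return A list with `truth` (gene, mu_true, tau2_true, rs_effect_true,
#'   is_de), `tables` (named list of per-contrast probe-level data.frames) and
#'   `metadata` (the contrast design).
#' @export
simulate_contrast_tables <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  ng <- config$n_genes
  design <- config$design
  genes <- sprintf("G%05d", seq_len(ng))

  n_de <- round(config$prop_de * ng)
  is_de <- c(rep(TRUE, n_de), rep(FALSE, ng - n_de))
  mu_true <- ifelse(is_de, stats::rnorm(ng, 0, config$effect_sd), 0)
  tau2_true <- stats::runif(ng, config$tau2_range[1], config$tau2_range[2])
  rs_effect_true <- -config$rs_reversal * mu_true
  truth <- data.frame(gene = genes, mu_true = mu_true, tau2_true = tau2_true,
                      rs_effect_true = rs_effect_true, is_de = is_de,
                      stringsAsFactors = FALSE)

  probe_counts <- as.integer(names(config$probes_per_gene))
  tables <- vector("list", nrow(design))
  names(tables) <- design$contrast_id
  for (ci in seq_len(nrow(design))) {
    v_c <- config$base_sv * config$n_ref / design$n[ci]
    rs_ind <- as.numeric(design$rs_hours[ci] > 0)
    present <- stats::runif(ng) >= config$missing_rate
    idx <- which(present)
    if (!length(idx)) next
    theta <- mu_true[idx] + rs_effect_true[idx] * rs_ind +
      stats::rnorm(length(idx), 0, sqrt(tau2_true[idx]))
    P <- sample(probe_counts, length(idx), replace = TRUE,
                prob = config$probes_per_gene)
    rows_gene <- rep.int(seq_along(idx), P)
    probe_no <- sequence(P)
    pv <- P[rows_gene] * v_c                       # per-probe variance
    lfc <- theta[rows_gene] + stats::rnorm(length(rows_gene), 0, sqrt(pv))
    tstat <- lfc / sqrt(pv)
    tables[[ci]] <- data.frame(
      element_id = sprintf("%s_p%d", genes[idx][rows_gene], probe_no),
      gene_symbol = genes[idx][rows_gene],
      log2fc = lfc,
      tstat = tstat,
      pvalue = 2 * stats::pnorm(-abs(tstat)),
      stringsAsFactors = FALSE
    )
  }
  list(truth = truth, tables = tables, metadata = design)
}

#' Simulate a two-group RNA-Seq validation count matrix
#'
#' Negative-binomial counts for a control vs. sleep-deprivation design in
#' which the SD group's log2 mean is shifted by each gene's true effect.
#' Library sizes are drawn log-uniformly so TMM normalization is exercised.
#'
#' @param truth truth table from [simulate_contrast_tables()].
#' @param n_samples_per_group samples per condition (default 43, the size of
#'   the emulated validation dataset).
#' @param seed integer seed.
#' @param dispersion negative-binomial dispersion (must be > 0).
#' @param lib_range length-2 range of library sizes (log-uniform draw).
#' @param base_log2cpm_range range of baseline log2-CPM abundances.
#' @return list with `counts` (genes x samples integer matrix) and `samples`
#'   (data.frame: sample_id, condition in {CTRL, SD}).
#' @export
simulate_validation_counts <- function(truth, n_samples_per_group = 43,
                                       seed = 1L, dispersion = 0.05,
                                       lib_range = c(8e6, 4e7),
                                       base_log2cpm_range = c(0, 9)) {
  if (n_samples_per_group < 2)
    stop("configuration error: need at least 2 samples per group")
  if (dispersion <= 0)
    stop("configuration error: dispersion must be positive")
  set.seed(seed)
  ng <- nrow(truth)
  ns <- 2L * n_samples_per_group
  condition <- rep(c("CTRL", "SD"), each = n_samples_per_group)
  lib <- exp(stats::runif(ns, log(lib_range[1]), log(lib_range[2])))
  base_cpm <- 2^stats::runif(ng, base_log2cpm_range[1], base_log2cpm_range[2])
  shift <- 2^truth$mu_true
  mu <- outer(base_cpm, lib / 1e6)
  mu[, condition == "SD"] <- mu[, condition == "SD"] * shift
  counts <- matrix(stats::rnbinom(ng * ns, mu = mu, size = 1 / dispersion),
                   nrow = ng,
                   dimnames = list(truth$gene,
                                   sprintf("S%03d_%s", seq_len(ns), condition)))
  samples <- data.frame(sample_id = colnames(counts), condition = condition,
                        stringsAsFactors = FALSE)
  list(counts = counts, samples = samples)
}

#' Write a gene-set collection to a GMT file
#'
#' Standard GMT: one set per line, tab-separated `name`, `description`,
#' then member symbols.
#'
#' @param sets named list of character vectors (set members).
#' @param path output file path.
#' @param descriptions optional character vector of per-set descriptions
#'   (defaults to "na").
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(names(sets)) || any(!nzchar(names(sets))))
    stop("all gene sets must be named")
  if (anyDuplicated(names(sets)))
    stop("duplicate set names: ",
         paste(unique(names(sets)[duplicated(names(sets))]), collapse = ", "))
  if (any(lengths(sets) == 0)) stop("empty gene set not allowed")
  if (is.null(descriptions)) descriptions <- rep("na", length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Draw random gene sets from a gene universe
#'
#' Convenience generator for enrichment fixtures: uniformly sized random
#' subsets of the supplied symbols, plus (optionally) sets loaded onto the
#' truly differentially expressed genes so enrichment is detectable.
#'
#' @param genes gene universe.
#' @param n_sets number of sets.
#' @param size_range inclusive range of set sizes.
#' @param seed integer seed.
#' @return named list of character vectors.
#' @export
random_gene_sets <- function(genes, n_sets = 50, size_range = c(10, 50),
                             seed = 1L) {
  set.seed(seed)
  sets <- lapply(seq_len(n_sets), function(i) {
    s <- sample(seq(size_range[1], size_range[2]), 1)
    sample(genes, s)
  })
  names(sets) <- sprintf("SET_%03d", seq_len(n_sets))
  sets
}

#' Write simulated study files to a directory
#'
#' Materializes a [simulate_contrast_tables()] result as the on-disk layout
#' consumed by the pipeline: one TSV per contrast, a contrast-metadata TSV,
#' a truth TSV, a GMT file of random gene sets, and a validation count matrix
#' with its sample table.
#'
#' @param sim result of [simulate_contrast_tables()].
#' @param dir output directory (created if needed).
#' @param gmt_sets optional named list of gene sets; defaults to random sets
#'   over the simulated symbols.
#' @param validation optional result of [simulate_validation_counts()].
#' @return named list of file paths.
#' @export
write_study_files <- function(sim, dir, gmt_sets = NULL, validation = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()
  paths$contrasts <- character(0)
  for (cid in names(sim$tables)) {
    if (is.null(sim$tables[[cid]])) next
    p <- file.path(dir, paste0(cid, ".tsv"))
    write_tsv_num(sim$tables[[cid]], p)
    paths$contrasts[cid] <- p
  }
  paths$metadata <- file.path(dir, "contrast_metadata.tsv")
  write_tsv_num(sim$metadata, paths$metadata)
  paths$truth <- file.path(dir, "truth.tsv")
  write_tsv_num(sim$truth, paths$truth)
  if (is.null(gmt_sets))
    gmt_sets <- random_gene_sets(sim$truth$gene, seed = 1L)
  paths$gmt <- file.path(dir, "gene_sets.gmt")
  write_gmt(gmt_sets, paths$gmt)
  if (!is.null(validation)) {
    paths$counts <- file.path(dir, "validation_counts.tsv")
    cdf <- data.frame(gene = rownames(validation$counts), validation$counts,
                      check.names = FALSE, stringsAsFactors = FALSE)
    write_tsv_num(cdf, paths$counts, signif_digits = NA)
    paths$samples <- file.path(dir, "validation_samples.tsv")
    write_tsv_num(validation$samples, paths$samples)
  }
  paths
}

# TSV writer used across modules: tab-separated, no quoting, floats at
# 6 significant digits unless signif_digits is NA.
write_tsv_num <- function(df, path, signif_digits = 6) {
  if (!is.na(signif_digits)) {
    num <- vapply(df, is.double, logical(1))
    df[num] <- lapply(df[num], signif, digits = signif_digits)
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
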