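#!/usr/bin/env Rscript
# Stage 1: generate the synthetic multi-study inputs.
#
# Emulates the harmonized design under study: 18 SD-vs-control contrasts
# from 8 studies (SD 3-12 h; recovery sleep 0-18 h in 6 contrasts from 3
# studies), a mostly-null transcriptome with 10% DE genes, per-gene
# heterogeneity, 1/n sampling variance, multi-probe platforms and gene
# missingness, plus a two-group negative-binomial count matrix for the
# validation stage. All downstream stages read from results/data/.

suppressMessages(library(sleepmeta))

seed <- 1L
out <- "results/data"

cfg <- sim_config(n_genes = 2000, effect_sd = 0.2, seed = seed)
sim <- simulate_contrast_tables(cfg)
val <- simulate_validation_counts(sim$truth, n_samples_per_group = 43,
                                  seed = seed)

# gene sets: random background plus two sets loaded on true DE genes, so
# the enrichment stage has known signal to find
de_up <- sim$truth$gene[sim$truth$is_de & sim$truth$mu_true > 0.1]
de_dn <- sim$truth$gene[sim$truth$is_de & sim$truth$mu_true < -0.1]
sets <- c(list(TRUE_SD_UP = head(de_up, 40), TRUE_SD_DOWN = head(de_dn, 40)),
          random_gene_sets(sim$truth$gene, n_sets = 150,
                           size_range = c(10, 40), seed = seed))

paths <- write_study_files(sim, out, gmt_sets = sets, validation = val)

cat(sprintf("wrote %d contrast tables, metadata, truth, %d gene sets and a %d x %d count matrix under %s\n",
            length(paths$contrasts), length(sets),
            nrow(val$counts), ncol(val$counts), out))
cat(sprintf("true DE genes: %d of %d (effect SD %.2f log2FC)\n",
            sum(sim$truth$is_de), cfg$n_genes, cfg$effect_sd))
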