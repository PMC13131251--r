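nb_counts <- function(n_genes, n_samples, mean_range = c(20, 2000),
                      dispersion = 0.05, seed = 1) {
  set.seed(seed)
  mu <- exp(runif(n_genes, log(mean_range[1]), log(mean_range[2])))
  matrix(rnbinom(n_genes * n_samples, mu = mu, size = 1 / dispersion),
         nrow = n_genes,
         dimnames = list(sprintf("G%04d", 1:n_genes),
                         sprintf("S%02d", 1:n_samples)))
}

test_that("the mean-count filter is strict below the threshold", {
  m <- rbind(all9 = rep(9, 4), exactly10 = rep(10, 4), high = rep(100, 4))
  out <- suppressMessages(filter_low_counts(m))
  expect_equal(rownames(out), c("exactly10", "high"))
  # engineered low rows are removed exactly
  big <- nb_counts(300, 6, mean_range = c(50, 500), seed = 2)
  big[1:100, ] <- 3
  out2 <- suppressMessages(filter_low_counts(big))
  expect_equal(nrow(out2), 200)
  expect_error(suppressMessages(filter_low_counts(big * 0)), "no genes")
})

test_that("TMM factors: symmetry, pure depth differences, geometric mean 1", {
  m <- nb_counts(400, 2, seed = 3)
  m <- cbind(m, m[, 1])                          # two identical columns
  f <- tmm_factors(m[, c(1, 3)])
  expect_equal(unname(f), c(1, 1), tolerance = 1e-12)
  doubled <- cbind(m[, 1], 2 * m[, 1])
  f2 <- tmm_factors(doubled)
  expect_equal(unname(f2), c(1, 1), tolerance = 1e-12)
  f3 <- tmm_factors(nb_counts(500, 5, seed = 4))
  expect_equal(exp(mean(log(f3))), 1, tolerance = 1e-12)
})

test_that("TMM matches a naive direct-formula oracle on random matrices", {
  for (seed in 1:5) {
    m <- nb_counts(200, 4, seed = seed)
    m <- m + 1                                  # keep all genes expressed
    expect_equal(unname(tmm_factors(m)), naive_tmm(m), tolerance = 1e-10)
  }
})

test_that("log-CPM follows the prior-adjusted formula and scale invariance", {
  counts <- matrix(c(100, 900), nrow = 2,
                   dimnames = list(c("g1", "g2"), "s1"))
  # single sample, library forced to 1e6 via a second balancing gene
  counts <- rbind(counts, filler = 1e6 - 1000)
  lc <- log_cpm(counts, factors = 1)
  expect_equal(lc["g1", 1], log2(100.5 / (1e6 + 1) * 1e6), tolerance = 1e-9)
  expect_lt(abs(lc["g1", 1] - 6.651), 0.01)

  # all-zero gene is constant across equal-library samples
  m <- nb_counts(50, 4, seed = 5)
  m[1, ] <- 0
  eq <- matrix(rep(round(rowMeans(m)), 4), ncol = 4,
               dimnames = dimnames(m))          # identical columns
  lceq <- log_cpm(eq)
  expect_equal(sd(lceq[1, ]), 0, tolerance = 1e-12)

  # doubling counts and libraries changes high-count log-CPM by < 0.01
  lc1 <- log_cpm(m)
  lc2 <- log_cpm(2 * m)
  hi <- rowMeans(m) >= 100
  expect_lt(max(abs(lc1[hi, ] - lc2[hi, ])), 0.01)
})

test_that("voom weights are flat for homoskedastic data, depth-driven for NB", {
  design <- cbind(1, rep(0:1, each = 4))
  # all genes at the same abundance: a single point on the trend
  set.seed(6)
  flat <- matrix(rpois(200 * 8, 1000), nrow = 200)
  wf <- voom_weights(flat, design = design)
  expect_lt(sd(wf) / mean(wf), 0.10)

  # NB counts across abundances: low-count genes get lower precision weights
  nb <- nb_counts(400, 8, mean_range = c(5, 5000), seed = 7)
  wn <- voom_weights(nb, design = design)
  gene_mean <- rowMeans(nb)
  low <- gene_mean < 50
  expect_gt(sum(low), 20)
  expect_gt(cor(gene_mean[low], rowMeans(wn)[low], method = "spearman"), 0)

  # determinism
  expect_identical(voom_weights(nb, design = design),
                   voom_weights(nb, design = design))
  expect_error(voom_weights(nb[, 1:2], design = design[1:2, ]), "degrees")
})

test_that("moderated t reduces to the classical t when variances are equal", {
  # large residual df so per-gene variances converge to the common value
  set.seed(8)
  n <- 50
  condition <- rep(c("CTRL", "SD"), each = n)
  y <- matrix(rnorm(400 * 2 * n, sd = 0.5), nrow = 400)
  rownames(y) <- sprintf("G%04d", 1:400)
  de <- fit_de(y, NULL, condition)
  tt <- apply(y, 1, function(row)
    stats::t.test(row[condition == "SD"], row[condition == "CTRL"],
                  var.equal = TRUE)$statistic)
  expect_equal(sign(de$t_mod), sign(de$log2fc))
  expect_lt(median(abs(de$t_mod - tt) / abs(tt)), 0.05)
  expect_gt(cor(de$t_mod, tt), 0.99)
})

test_that("the DE pipeline recovers a generated two-fold shift", {
  # direction-balanced truth: TMM's majority-null assumption holds
  truth <- data.frame(gene = sprintf("G%04d", 1:400),
                      mu_true = rep(c(0, 1, -1), c(300, 50, 50)),
                      stringsAsFactors = FALSE)
  val <- simulate_validation_counts(truth, n_samples_per_group = 20,
                                    seed = 13L)
  de <- suppressMessages(run_de_analysis(val$counts, val$samples))
  shifted <- de$gene %in% truth$gene[truth$mu_true == 1]
  down <- de$gene %in% truth$gene[truth$mu_true == -1]
  expect_gt(mean(de$log2fc[shifted]), 0.9)
  expect_lt(mean(de$log2fc[shifted]), 1.1)
  expect_gt(mean(de$log2fc[down]), -1.1)
  expect_lt(mean(de$log2fc[down]), -0.9)
  # CPM group-ratio oracle agrees with the model estimate
  cpm <- t(t(val$counts) / colSums(val$counts)) * 1e6
  grp <- val$samples$condition
  oracle <- log2(rowMeans(cpm[, grp == "SD"]) / rowMeans(cpm[, grp == "CTRL"]))
  keep <- match(de$gene, rownames(val$counts))
  expect_gt(cor(de$log2fc, oracle[keep]), 0.95)
  expect_lt(mean(de$fdr[shifted] >= 0.05), 0.05)
})

test_that("congruence classification and statistics follow the definitions", {
  meta <- data.frame(gene = sprintf("G%02d", 1:10),
                     log2fc = c(rep(0.5, 5), rep(-0.5, 5)),
                     fdr = rep(0.01, 10), stringsAsFactors = FALSE)
  de <- data.frame(gene = meta$gene, log2fc = meta$log2fc,
                   fdr = rep(0.01, 10), stringsAsFactors = FALSE)
  self <- suppressWarnings(congruence(meta, de))
  expect_equal(self$n_same_direction, 10)
  expect_equal(self$n_fully_validated, 10)
  expect_equal(self$ols_slope, 1, tolerance = 1e-12)
  expect_equal(self$spearman_rho, 1)

  # exactly 3 sign flips -> 7 same-direction
  de3 <- de
  de3$log2fc[c(2, 4, 9)] <- -de3$log2fc[c(2, 4, 9)]
  flip <- congruence(meta, de3)
  expect_equal(flip$n_same_direction, 7)
  # flipped genes can never be fully validated
  expect_lte(flip$n_fully_validated, 7)

  # validation FDR gate
  de4 <- de
  de4$fdr[1:4] <- 0.2
  gated <- suppressWarnings(congruence(meta, de4))
  expect_equal(gated$n_fully_validated, 6)
  expect_equal(gated$n_same_direction, 10)
  expect_error(congruence(meta, de[0, ]), "no gene symbols|share")
})

test_that("congruence counts obey the chain inequality on random inputs", {
  set.seed(14)
  for (rep in 1:10) {
    n <- 50
    meta <- data.frame(gene = sprintf("G%02d", 1:n), log2fc = rnorm(n),
                       fdr = runif(n, 0, 0.2), stringsAsFactors = FALSE)
    de <- data.frame(gene = sample(meta$gene, 40), log2fc = rnorm(40),
                     fdr = runif(40, 0, 0.2), stringsAsFactors = FALSE)
    cs <- tryCatch(congruence(meta, de), error = function(e) NULL)
    if (is.null(cs)) next
    expect_lte(cs$n_fully_validated, cs$n_same_direction)
    expect_lte(cs$n_same_direction, cs$n_represented)
    expect_lte(cs$n_represented, cs$n_degs)
  }
})

test_that("orientation of the validation regression is configurable", {
  set.seed(15)
  meta <- data.frame(gene = sprintf("G%02d", 1:30), log2fc = rnorm(30),
                     fdr = 0.01, stringsAsFactors = FALSE)
  de <- data.frame(gene = meta$gene, log2fc = 2 * meta$log2fc + rnorm(30, 0, .1),
                   fdr = 0.01, stringsAsFactors = FALSE)
  a <- congruence(meta, de, orientation = "de_on_meta")
  b <- congruence(meta, de, orientation = "meta_on_de")
  expect_gt(a$ols_slope, 1.5)
  expect_lt(b$ols_slope, 0.7)
})
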