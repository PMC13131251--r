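test_that("REML heterogeneity is zero for perfectly homogeneous effects", {
  fit <- reml_tau2(c(0.5, 0.5, 0.5), c(0.1, 0.1, 0.1))
  expect_equal(fit$tau2, 0)
  expect_true(fit$converged)
})

test_that("REML matches the brute-force grid oracle on the frozen example", {
  y <- c(0.2, -0.1, 0.4, 0.0)
  v <- c(0.01, 0.02, 0.01, 0.03)
  fit <- reml_tau2(y, v)
  oracle <- grid_reml_tau2(y, v)
  expect_lt(abs(fit$tau2 - oracle), 1e-4)
})

test_that("REML and GLS match independent oracles on random instances", {
  set.seed(101)
  for (rep in 1:40) {
    k <- sample(3:18, 1)
    v <- runif(k, 0.002, 0.05)
    tau2 <- runif(1, 0, 0.05)
    y <- rnorm(k, 0.1, sqrt(v + tau2))
    fit <- reml_tau2(y, v)
    expect_lt(abs(fit$tau2 - grid_reml_tau2(y, v)), 1e-4)
    f <- fit_random_effects(y, v)
    expect_equal(f$mu_hat,
                 drop(gls_oracle(y, v, matrix(1, k, 1), f$tau2_hat)),
                 tolerance = 1e-8)
  }
})

test_that("tau2 = 0 reduces to fixed-effect inverse-variance pooling", {
  y <- c(0.5, 0.5, 0.5)
  v <- c(0.1, 0.1, 0.1)
  f <- fit_random_effects(y, v)
  expect_equal(f$mu_hat, 0.5)
  expect_equal(f$se_mu, sqrt(0.1 / 3), tolerance = 1e-10)
  # heterogeneous v, still homogeneous y: fixed-effect weighted mean
  v2 <- c(0.01, 0.05, 0.2, 0.1)
  y2 <- rep(0.3, 4)
  f2 <- fit_random_effects(y2, v2)
  expect_equal(f2$tau2_hat, 0)
  expect_equal(f2$mu_hat, sum(y2 / v2) / sum(1 / v2))
  expect_equal(f2$se_mu, 1 / sqrt(sum(1 / v2)))
})

test_that("random-effects fits agree with metafor (independent implementation)", {
  skip_if_not_installed("metafor")
  set.seed(55)
  for (rep in 1:10) {
    k <- sample(5:18, 1)
    v <- runif(k, 0.002, 0.03)
    y <- rnorm(k, 0.05, sqrt(v + 0.01))
    f <- fit_random_effects(y, v)
    m <- tryCatch(metafor::rma(yi = y, vi = v, method = "REML",
                               control = list(threshold = 1e-10,
                                              maxiter = 500)),
                  error = function(e) NULL)
    if (is.null(m)) next
    expect_equal(f$tau2_hat, m$tau2, tolerance = 1e-4)
    expect_equal(f$mu_hat, as.numeric(m$beta), tolerance = 1e-5)
    expect_equal(f$se_mu, m$se, tolerance = 1e-5)
    expect_equal(f$p, m$pval, tolerance = 1e-5)
  }
})

test_that("moderated fits match GLS linear algebra and metafor", {
  set.seed(77)
  dur <- c(3, 6, 9, 12, 6, 6, 5, 5, 4, 6, 9, 12, 6, 5, 3, 8, 6, 4)
  rs <- c(0, 0, 0, 0, 1, 1, 0, 1, 0, 0, 1, 0, 1, 1, 0, 0, 0, 0)
  v <- runif(18, 0.002, 0.02)
  y <- 0.2 - 0.005 * (dur - mean(dur)) - 0.15 * rs + rnorm(18, 0, sqrt(v))
  fit <- fit_moderated(y, v, dur, rs)
  X <- cbind(1, dur - mean(dur), rs)
  expect_equal(fit$coefficients$beta,
               drop(gls_oracle(y, v, X, fit$tau2_hat)), tolerance = 1e-8)
  skip_if_not_installed("metafor")
  m <- metafor::rma(yi = y, vi = v, mods = ~I(dur - mean(dur)) + rs,
                    method = "REML",
                    control = list(threshold = 1e-10, maxiter = 500))
  expect_equal(fit$coefficients$beta, as.numeric(m$beta), tolerance = 1e-5)
  expect_equal(fit$coefficients$se, as.numeric(m$se), tolerance = 1e-4)
})

test_that("the noise-free moderated fit inverts the generative RS reversal", {
  dur <- default_contrast_design()$sd_hours
  rs <- as.numeric(default_contrast_design()$rs_hours > 0)
  mu <- 0.2
  y <- mu - mu * rs                      # full reversal, no noise
  v <- rep(1e-6, 18)
  fit <- fit_moderated(y, v, dur, rs)
  cf <- fit$coefficients
  expect_equal(cf$beta[cf$term == "intercept"], 0.2, tolerance = 1e-6)
  expect_equal(cf$beta[cf$term == "rs"], -0.2, tolerance = 1e-6)
  expect_equal(abs(cf$beta[cf$term == "duration"]) < 1e-8, TRUE)
})

test_that("rank-deficient moderator designs fail naming the collinear column", {
  y <- rnorm(6)
  v <- rep(0.01, 6)
  expect_error(fit_moderated(y, v, duration = rep(6, 6), rs = c(0, 1, 0, 1, 0, 1)),
               "duration")
  expect_error(fit_moderated(y, v, duration = 1:6, rs = rep(0, 6)), "rs")
  expect_error(fit_moderated(y[1:3], v[1:3], duration = 1:3, rs = c(0, 1, 0)),
               "insufficient|>= 4")
})

test_that("BH step-up adjustment matches direct arithmetic and p.adjust", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(c(1, 1)), c(1, 1))
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
  set.seed(12)
  for (rep in 1:5) {
    p <- runif(200)^2
    p[sample(200, 10)] <- NA
    q <- bh_adjust(p)
    expect_equal(q, stats::p.adjust(p, method = "BH"))
    expect_true(all(q >= p, na.rm = TRUE))
  }
})

test_that("run_meta fits each gene on its present contrasts with correct FDR basis", {
  sim <- quick_sim(n_genes = 250, seed = 21L)
  mat <- sim_matrix(sim)
  res <- suppressMessages(run_meta(mat))
  expect_equal(nrow(res), length(mat$genes))
  expect_true(all(res$k == mat$coverage))
  expect_true(all(res$fdr >= res$pval, na.rm = TRUE))
  expect_true(all(is.na(res$fdr[!res$converged])))
  # spot-check one gene against a direct fit on its own contrasts
  g <- res$gene[10]
  present <- !is.na(mat$effects[g, ])
  f <- fit_random_effects(mat$effects[g, present], mat$variances[g, present])
  expect_equal(res$log2fc[10], f$mu_hat)
  expect_equal(res$se[10], f$se_mu)
  expect_equal(res$pval[10], f$p)
  # CI is the Wald interval
  crit <- qnorm(0.975)
  expect_equal(res$ci_lb, res$log2fc - crit * res$se, tolerance = 1e-12)
  expect_true(all(res$ci_lb < res$ci_ub))
})

test_that("moderated run reports per-coefficient inference and FDR", {
  sim <- quick_sim(n_genes = 200, seed = 22L)
  mat <- sim_matrix(sim)
  res <- suppressMessages(run_meta(mat, "moderated"))
  expect_true(all(c("beta_duration", "beta_rs", "fdr_rs", "fdr_duration")
                  %in% names(res)))
  ok <- res$converged
  expect_true(all(res$fdr_rs[ok] >= res$pval_rs[ok]))
  # truly reversed genes: RS coefficient opposes the SD intercept
  truth <- sim$truth[match(res$gene, sim$truth$gene), ]
  de <- ok & truth$is_de & abs(truth$mu_true) > 0.15
  if (sum(de) >= 5)
    expect_gt(mean(sign(res$beta_rs[de]) != sign(res$log2fc[de])), 0.8)
})

test_that("type-I error of the Wald z test is near nominal on simulated nulls", {
  sim <- simulate_contrast_tables(sim_config(n_genes = 1200, prop_de = 0,
                                             seed = 31L))
  res <- suppressMessages(run_meta(sim_matrix(sim)))
  rate <- mean(res$pval < 0.05, na.rm = TRUE)
  expect_gt(rate, 0.03)
  expect_lt(rate, 0.08)
})
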