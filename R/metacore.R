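#' Restricted log-likelihood of the random-effects model
#'
#' For effects `y` with sampling variances `v` and fixed-effect design `X`,
#' the restricted log-likelihood at between-study variance `tau2` is
#' \deqn{-\frac12\left[\sum_i \log(v_i+\tau^2) + \log|X^T W X| + r^T W r\right]}
#' with `W = diag(1/(v_i + tau2))` and `r` the weighted-least-squares
#' residuals (additive constants dropped).
#'
#' @param tau2 candidate between-study variance (>= 0).
#' @param y effect vector.
#' @param v sampling-variance vector.
#' @param X design matrix.
#' @return scalar restricted log-likelihood.
#' @export
reml_loglik <- function(tau2, y, v, X) {
  w <- 1 / (v + tau2)
  XtWX <- crossprod(X, X * w)
  beta <- solve(XtWX, crossprod(X, y * w))
  r <- y - X %*% beta
  -0.5 * (sum(log(v + tau2)) + determinant(XtWX, logarithm = TRUE)$modulus[1] +
            sum(w * r^2))
}

# Projection matrix P = W - WX (X'WX)^-1 X'W evaluated at tau2.
reml_projection <- function(tau2, y, v, X) {
  w <- 1 / (v + tau2)
  WX <- X * w
  W <- diag(w, length(v))
  W - WX %*% solve(crossprod(X, WX), t(WX))
}

#' REML estimate of between-contrast heterogeneity
#'
#' Maximizes the restricted log-likelihood over `tau2 >= 0` by Fisher
#' scoring (score `0.5 (y'PPy - tr(P))`, expected information
#' `0.5 tr(P^2)`), projecting negative updates to zero, with a bounded
#' golden-section fallback on `[0, 100 * max(v)]` if scoring fails to
#' converge.
#'
#' @inheritParams reml_loglik
#' @param tol convergence tolerance on tau2.
#' @param maxit maximum scoring iterations.
#' @return list with `tau2` and `converged`.
#' @export
reml_tau2 <- function(y, v, X = matrix(1, length(y), 1),
                      tol = 1e-8, maxit = 100) {
  k <- length(y)
  if (!is.matrix(X)) X <- as.matrix(X)
  if (length(v) != k || nrow(X) != k)
    stop("y, v and X must have matching lengths")
  if (!all(is.finite(y)) || !all(is.finite(v)) || !all(is.finite(X)))
    stop("non-finite inputs")
  if (any(v <= 0)) stop("sampling variances must be positive")
  p <- qr(X)$rank
  if (k <= p) stop("insufficient contrasts: k must exceed rank(X)")

  # DerSimonian-Laird start value (truncated at 0)
  w0 <- 1 / v
  P0 <- reml_projection(0, y, v, X)
  Q <- drop(t(y) %*% P0 %*% y)
  tr_term <- sum(w0) - sum(diag(
    solve(crossprod(X, X * w0), crossprod(X * w0, X * w0))))
  tau2 <- max(0, (Q - (k - p)) / tr_term)

  converged <- FALSE
  for (it in seq_len(maxit)) {
    P <- reml_projection(tau2, y, v, X)
    Py <- P %*% y
    score <- 0.5 * (sum(Py^2) - sum(diag(P)))
    info <- 0.5 * sum(P * P)
    if (!is.finite(score) || !is.finite(info) || info <= 0) break
    step <- score / info
    tau2_new <- tau2 + step
    if (tau2_new < 0) tau2_new <- 0
    if (abs(tau2_new - tau2) < tol ||
        (tau2_new == 0 && tau2 == 0 && score < 0)) {
      tau2 <- tau2_new
      converged <- TRUE
      break
    }
    tau2 <- tau2_new
  }
  if (!converged) {
    upper <- 100 * max(v)
    opt <- tryCatch(
      stats::optimize(reml_loglik, c(0, upper), y = y, v = v, X = X,
                      maximum = TRUE, tol = 1e-10),
      error = function(e) NULL)
    if (!is.null(opt) && is.finite(opt$maximum)) {
      tau2 <- opt$maximum
      # optimize never returns the exact boundary; snap if the boundary wins
      if (reml_loglik(0, y, v, X) >= opt$objective) tau2 <- 0
      converged <- TRUE
    }
  }
  list(tau2 = tau2, converged = converged)
}

# Generalized least squares at fixed tau2: coefficients and covariance.
gls_fit <- function(y, v, X, tau2) {
  w <- 1 / (v + tau2)
  XtWX <- crossprod(X, X * w)
  cov_beta <- solve(XtWX)
  beta <- drop(cov_beta %*% crossprod(X, y * w))
  list(beta = beta, cov = cov_beta)
}

#' Fit an intercept-only random-effects meta-analysis model
#'
#' Inverse-variance pooling with REML heterogeneity: weights
#' `w_i = 1/(v_i + tau2_hat)`, pooled effect `mu_hat = sum(w y)/sum(w)`,
#' `se_mu = sum(w)^(-1/2)`. Inference is a Wald z test by default
#' (`p = 2 Phi(-|z|)`, CI `mu_hat +/- z_{0.975} se_mu`); `test = "t"`
#' substitutes a t reference with k-1 degrees of freedom.
#'
#' @param y contrast-level log2 fold changes.
#' @param v their sampling variances.
#' @param test `"z"` (default) or `"t"`.
#' @return list (class `meta_fit`): k, mu_hat, se_mu, tau2_hat, z, p,
#'   ci_lb, ci_ub, converged.
#' @export
fit_random_effects <- function(y, v, test = c("z", "t")) {
  test <- match.arg(test)
  k <- length(y)
  if (k < 2) stop("insufficient contrasts: k must be >= 2")
  re <- reml_tau2(y, v)
  w <- 1 / (v + re$tau2)
  mu <- sum(w * y) / sum(w)
  se <- sqrt(1 / sum(w))
  z <- mu / se
  if (test == "z") {
    p <- 2 * stats::pnorm(-abs(z))
    crit <- stats::qnorm(0.975)
  } else {
    p <- 2 * stats::pt(-abs(z), df = k - 1)
    crit <- stats::qt(0.975, df = k - 1)
  }
  structure(list(k = k, mu_hat = mu, se_mu = se, tau2_hat = re$tau2,
                 z = z, p = max(p, .Machine$double.xmin),
                 ci_lb = mu - crit * se, ci_ub = mu + crit * se,
                 converged = re$converged && is.finite(se)),
            class = "meta_fit")
}

#' Fit a moderated random-effects meta-regression
#'
#' Design: intercept, SD duration centered on the mean duration across all
#' contrasts of the full design (so the intercept is the SD effect at the
#' average duration with no recovery sleep), and a recovery-sleep (RS)
#' indicator coded as a factor (0 = no RS). Coefficients are GLS at the REML
#' heterogeneity estimate; per-coefficient Wald z inference.
#'
#' @param y,v contrast-level effects and sampling variances.
#' @param duration SD duration (hours) per contrast.
#' @param rs RS indicator (0/1 or logical) per contrast.
#' @param duration_center value to center duration on; defaults to
#'   `mean(duration)` of the supplied contrasts. Pass the design-wide mean
#'   when fitting genes with missing contrasts.
#' @return list (class `meta_reg_fit`): coefficient table (beta, se, z, p per
#'   term), tau2_hat, k, converged.
#' @export
fit_moderated <- function(y, v, duration, rs, duration_center = NULL) {
  k <- length(y)
  if (k < 4) stop("insufficient contrasts: k must be >= 4 for the moderated model")
  if (is.null(duration_center)) duration_center <- mean(duration)
  rs <- as.numeric(rs != 0)
  X <- cbind(intercept = 1, duration = duration - duration_center, rs = rs)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[setdiff(seq_len(ncol(X)), qrX$pivot[seq_len(qrX$rank)])]
    stop("rank-deficient design; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  re <- reml_tau2(y, v, X)
  fit <- gls_fit(y, v, X, re$tau2)
  se <- sqrt(diag(fit$cov))
  z <- fit$beta / se
  p <- 2 * stats::pnorm(-abs(z))
  coefs <- data.frame(term = colnames(X), beta = fit$beta, se = se, z = z,
                      p = pmax(p, .Machine$double.xmin),
                      stringsAsFactors = FALSE)
  rownames(coefs) <- NULL
  structure(list(coefficients = coefs, tau2_hat = re$tau2, k = k,
                 converged = re$converged && all(is.finite(se))),
            class = "meta_reg_fit")
}

#' Benjamini-Hochberg step-up FDR adjustment
#'
#' `q_(i) = min_(j >= i) p_(j) * m / j` capped at 1, mapped back to the
#' input order; `m` counts the non-missing p-values.
#'
#' @param p vector of p-values (NAs allowed; returned as NA).
#' @return adjusted p-values in input order.
#' @export
bh_adjust <- function(p) {
  out <- rep(NA_real_, length(p))
  ok <- which(!is.na(p))
  if (!length(ok)) return(out)
  pv <- p[ok]
  if (any(pv < 0 | pv > 1)) stop("p-values must lie in [0, 1]")
  m <- length(pv)
  o <- order(pv, decreasing = TRUE)          # largest first; stable for ties
  q <- pmin(1, cummin(pv[o] * m / seq(m, 1)))
  out[ok[o]] <- pmax(q, pv[o])               # guard 1-ulp rounding: fdr >= p
  out
}

#' Run the per-gene meta-analysis across a gene-effect matrix
#'
#' Fits the chosen model to every gene on its present contrasts only.
#' Genes whose fit does not converge (or that violate the model's
#' preconditions) are reported with `converged = FALSE` and excluded from
#' the FDR computation, which is applied per model run (per coefficient in
#' the moderated model) over the converged genes.
#'
#' @param mat a `gene_effect_matrix` from [align_and_filter()].
#' @param model `"intercept"` (default) or `"moderated"`.
#' @param q FDR threshold used only for the summary counts.
#' @param test passed to [fit_random_effects()].
#' @return data.frame (class `meta_results`). Intercept model columns:
#'   gene, k, log2fc, ci_lb, ci_ub, se, tstat, pval, tau2, converged, fdr.
#'   Moderated model adds beta_duration/rs columns with their se/p/fdr.
#'   Attribute `summary` holds the counts (total, stable, significant).
#' @export
run_meta <- function(mat, model = c("intercept", "moderated"), q = 0.05,
                     test = "z") {
  model <- match.arg(model)
  stopifnot(inherits(mat, "gene_effect_matrix"))
  md <- mat$contrasts
  dur_center <- mean(md$sd_hours)
  genes <- mat$genes
  rows <- vector("list", length(genes))
  for (i in seq_along(genes)) {
    present <- !is.na(mat$effects[i, ])
    y <- mat$effects[i, present]
    v <- mat$variances[i, present]
    row <- tryCatch({
      if (model == "intercept") {
        f <- fit_random_effects(y, v, test = test)
        data.frame(gene = genes[i], k = f$k, log2fc = f$mu_hat,
                   ci_lb = f$ci_lb, ci_ub = f$ci_ub, se = f$se_mu,
                   tstat = f$z, pval = f$p, tau2 = f$tau2_hat,
                   converged = f$converged, stringsAsFactors = FALSE)
      } else {
        f <- fit_moderated(y, v, duration = md$sd_hours[present],
                           rs = md$rs_hours[present] > 0,
                           duration_center = dur_center)
        cf <- f$coefficients
        ic <- cf[cf$term == "intercept", ]
        du <- cf[cf$term == "duration", ]
        rs <- cf[cf$term == "rs", ]
        crit <- stats::qnorm(0.975)
        data.frame(gene = genes[i], k = f$k, log2fc = ic$beta,
                   ci_lb = ic$beta - crit * ic$se,
                   ci_ub = ic$beta + crit * ic$se,
                   se = ic$se, tstat = ic$z, pval = ic$p,
                   beta_duration = du$beta, se_duration = du$se,
                   pval_duration = du$p,
                   beta_rs = rs$beta, se_rs = rs$se, pval_rs = rs$p,
                   tau2 = f$tau2_hat, converged = f$converged,
                   stringsAsFactors = FALSE)
      }
    }, error = function(e) NULL)
    if (is.null(row)) {
      row <- data.frame(gene = genes[i], k = sum(present), log2fc = NA_real_,
                        ci_lb = NA_real_, ci_ub = NA_real_, se = NA_real_,
                        tstat = NA_real_, pval = NA_real_, tau2 = NA_real_,
                        converged = FALSE, stringsAsFactors = FALSE)
      if (model == "moderated") {
        row$beta_duration <- row$se_duration <- row$pval_duration <- NA_real_
        row$beta_rs <- row$se_rs <- row$pval_rs <- NA_real_
        row <- row[, c("gene", "k", "log2fc", "ci_lb", "ci_ub", "se", "tstat",
                       "pval", "beta_duration", "se_duration", "pval_duration",
                       "beta_rs", "se_rs", "pval_rs", "tau2", "converged")]
      }
    }
    rows[[i]] <- row
  }
  res <- do.call(rbind, rows)
  usable <- res$converged
  res$fdr <- NA_real_
  res$fdr[usable] <- bh_adjust(res$pval[usable])
  if (model == "moderated") {
    res$fdr_duration <- NA_real_
    res$fdr_duration[usable] <- bh_adjust(res$pval_duration[usable])
    res$fdr_rs <- NA_real_
    res$fdr_rs[usable] <- bh_adjust(res$pval_rs[usable])
  }
  n_sig <- sum(res$fdr < q, na.rm = TRUE)
  summary_counts <- c(total = nrow(res), stable = sum(usable),
                      significant = n_sig)
  message(sprintf("meta-analysis (%s model): %d genes, %d stable, %d at FDR < %g",
                  model, nrow(res), sum(usable), n_sig, q))
  structure(res, summary = summary_counts, model = model,
            class = c("meta_results", "data.frame"))
}
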