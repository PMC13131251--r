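# Independent oracles used across the suite. These deliberately use direct,
# unoptimized formulas so they share no code with the implementation.

# Grid-search REML oracle: restricted log-likelihood evaluated from first
# principles on a two-stage grid over [0, upper].
grid_reml_tau2 <- function(y, v, X = matrix(1, length(y), 1),
                           upper = 1, coarse = 1e-3, fine = 1e-5) {
  ll <- function(tau2) {
    w <- 1 / (v + tau2)
    XtWX <- t(X) %*% (X * w)
    beta <- solve(XtWX, t(X) %*% (w * y))
    r <- y - X %*% beta
    -0.5 * (sum(log(v + tau2)) + log(det(XtWX)) + sum(w * r^2))
  }
  g1 <- seq(0, upper, by = coarse)
  t1 <- g1[which.max(vapply(g1, ll, numeric(1)))]
  g2 <- seq(max(0, t1 - 2 * coarse), min(upper, t1 + 2 * coarse), by = fine)
  g2[which.max(vapply(g2, ll, numeric(1)))]
}

# Direct GLS coefficients at a fixed tau2.
gls_oracle <- function(y, v, X, tau2) {
  W <- diag(1 / (v + tau2))
  unname(drop(solve(t(X) %*% W %*% X) %*% t(X) %*% W %*% y))
}

# Naive TMM oracle: direct transcription of the trimmed-mean-of-M-values
# recipe (75th-percentile reference, 30%/5% trims, binomial-variance
# weighting, geometric-mean-1 rescaling).
naive_tmm <- function(counts, logratioTrim = 0.3, sumTrim = 0.05) {
  lib <- colSums(counts)
  f75 <- apply(counts, 2, stats::quantile, probs = 0.75) / lib
  ref <- which.min(abs(f75 - mean(f75)))
  f <- vapply(seq_len(ncol(counts)), function(i) {
    obs <- counts[, i]; rfc <- counts[, ref]
    nO <- lib[i]; nR <- lib[ref]
    logR <- log2((obs / nO) / (rfc / nR))
    absE <- (log2(obs / nO) + log2(rfc / nR)) / 2
    v <- (nO - obs) / nO / obs + (nR - rfc) / nR / rfc
    fin <- is.finite(logR) & is.finite(absE)
    logR <- logR[fin]; absE <- absE[fin]; v <- v[fin]
    if (max(abs(logR)) < 1e-6) return(1)
    n <- length(logR)
    loL <- floor(n * logratioTrim) + 1; hiL <- n + 1 - loL
    loS <- floor(n * sumTrim) + 1; hiS <- n + 1 - loS
    keep <- rank(logR) >= loL & rank(logR) <= hiL &
      rank(absE) >= loS & rank(absE) <= hiS
    2^(sum(logR[keep] / v[keep]) / sum(1 / v[keep]))
  }, numeric(1))
  f / exp(mean(log(f)))
}

# Full running-sum walk used to cross-check the fast positional ES and for
# exhaustive enumeration on tiny universes.
walk_es <- function(stat_sorted, members) {
  N <- length(stat_sorted)
  hit <- names(stat_sorted) %in% members
  s <- sum(hit)
  inc <- ifelse(hit, abs(stat_sorted) / sum(abs(stat_sorted)[hit]),
                -1 / (N - s))
  running <- cumsum(inc)
  hi <- max(running)
  lo <- min(running)
  if (hi >= -lo) hi else lo     # magnitude ties resolve positive

}

# Exhaustive null ES distribution over all size-s subsets of the universe.
exhaustive_es <- function(stat_sorted, s) {
  idx <- utils::combn(length(stat_sorted), s)
  apply(idx, 2, function(i) walk_es(stat_sorted, names(stat_sorted)[i]))
}

# Exact sign-conditional tail probability from a fully enumerated null ES
# distribution: P(same-sign ES at least as extreme | same sign). The
# Monte-Carlo estimate (1 + count)/(n_side + 1) converges to this.
perm_pvalue <- function(es, null_es) {
  if (es >= 0) {
    side <- null_es[null_es >= 0]
    sum(side >= es) / length(side)
  } else {
    side <- null_es[null_es < 0]
    sum(side <= es) / length(side)
  }
}

# Small, fast simulation shared by several tests.
quick_sim <- function(n_genes = 400, seed = 1L, ...) {
  simulate_contrast_tables(sim_config(n_genes = n_genes, seed = seed, ...))
}

# Harmonized matrix straight from a simulation (no disk round-trip).
sim_matrix <- function(sim, ...) {
  align_and_filter(lapply(sim$tables, collapse_to_gene), sim$metadata, ...)
}
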