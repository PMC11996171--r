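# Independent oracle implementations used to cross-check the pipeline.
# They re-derive each quantity step by step from its published definition
# and never call the package functions they validate.

# Trimmed-mean-of-M-values factors, spelled out: reference sample by the
# 75th-percentile rule; per sample, precision-weighted mean of gene-wise
# log2 ratios (M) after trimming 30% of each M tail and 5% of each A
# tail over doubly positive genes; factors renormalized to geometric
# mean 1.
oracle_tmm <- function(counts, lib = colSums(counts),
                       trim_m = 0.3, trim_a = 0.05) {
  q75 <- apply(counts, 2, function(y) quantile(y / sum(y), 0.75))
  ref <- which.min(abs(q75 - mean(q75)))
  fac <- vapply(seq_len(ncol(counts)), function(s) {
    if (s == ref) return(1)
    ys <- counts[, s]; yr <- counts[, ref]
    Ns <- lib[s]; Nr <- lib[ref]
    pos <- ys > 0 & yr > 0
    ys <- ys[pos]; yr <- yr[pos]
    M <- log2((ys / Ns) / (yr / Nr))
    A <- 0.5 * log2((ys / Ns) * (yr / Nr))
    w <- (Ns - ys) / (Ns * ys) + (Nr - yr) / (Nr * yr)
    n <- length(M)
    loM <- floor(n * trim_m) + 1; hiM <- n + 1 - loM
    loA <- floor(n * trim_a) + 1; hiA <- n + 1 - loA
    keep <- rank(M) >= loM & rank(M) <= hiM & rank(A) >= loA & rank(A) <= hiA
    2^(sum(M[keep] / w[keep]) / sum(1 / w[keep]))
  }, 0)
  fac / exp(mean(log(fac)))
}

# One-way fixed-effects ANOVA via stats::aov; in the balanced design the
# textbook between-group mean square is R times the variance of the
# population means, so the package F equals F_aov / R.
oracle_f_aov <- function(X) {
  d <- data.frame(y = as.vector(t(X)),
                  g = factor(rep(seq_len(nrow(X)), each = ncol(X))))
  s <- summary(stats::aov(y ~ g, data = d))[[1]]
  s[["F value"]][1] / ncol(X)
}

# Exact moments of the linear Gaussian causal system (path-rule oracle):
# given slopes and child noise SD, return the implied cor(Pl, Pa).
oracle_cor_pl_pa <- function(model, a, b, cc, noise_sd = 1) {
  v_pl <- 1
  if (model %in% c("I", "II", "III")) {
    cov_pl_a <- a; v_a <- a^2 + noise_sd^2
  } else {
    cov_pl_a <- 0; v_a <- 1
  }
  switch(model,
    I   = (b * cov_pl_a) / sqrt(v_pl * (b^2 * v_a + noise_sd^2)),
    II  = cc / sqrt(v_pl * (cc^2 + noise_sd^2)),
    III = (b * cov_pl_a + cc) /
      sqrt(v_pl * (b^2 * v_a + cc^2 + 2 * b * cc * cov_pl_a + noise_sd^2)),
    IV  = cc / sqrt(v_pl * (b^2 * v_a + cc^2 + noise_sd^2)),
    V   = 0)
}

# partial correlation of x and y given z, from the residuals of the
# marginal regressions (brute-force d-separation check)
oracle_partial_cor <- function(x, y, z) {
  cor(resid(lm(x ~ z)), resid(lm(y ~ z)))
}

# deterministic one-locus viability-selection recursion under Gaussian
# stabilizing selection on the diploid trait value z in {0, a, 2a}
oracle_one_locus_recursion <- function(p0, a, opt, omega, generations) {
  w <- function(z) exp(-(z - opt)^2 / (2 * omega^2))
  p <- p0
  for (g in seq_len(generations)) {
    p2 <- p^2 * w(2 * a); pq <- p * (1 - p) * w(a); q2 <- (1 - p)^2 * w(0)
    p <- (p2 + pq) / (p2 + 2 * pq + q2)
  }
  p
}
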