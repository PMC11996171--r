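# The parallelism statistic. Per putatively adaptive gene, the evolutionary
# response of every evolved sample is its log2 fold change relative to the
# mean ancestral CPM; the heterogeneity of that response across the
# replicate populations, relative to the within-population residual, is
#
#   F = MS_pop / MS_e,
#   MS_pop = sum_i (Xbar_i - Xbar)^2 / (P - 1),
#   MS_e   = sum_ij (X_ij - Xbar_i)^2 / (N - P),
#
# and parallelism is its reciprocal 1/F (log scale: ln(1/F) = -ln F).
# Note MS_pop is the variance of the population means themselves, without
# the replicate-count multiplier of the textbook between-group mean
# square; in the balanced design R * F follows F(P-1, P(R-1)) under the
# null, and all rank-based downstream analyses are unaffected by the
# constant factor.

#' Per-sample evolutionary log2 fold changes
#'
#' `X_ij = log2(CPM of evolved sample j of population i / mean ancestral
#' CPM)`. Compute the CPM with a positive prior count so that a zero
#' ancestral mean cannot produce infinities; with a prior of 0, genes with
#' a zero ancestral mean are returned as `NA` and flagged.
#'
#' @param cpm_table gene x sample CPM matrix (see [cpm_matrix()]).
#' @param design a [sample_design()] covering the samples.
#' @return Gene x evolved-sample matrix of log2 fold changes, with
#'   attributes `population_id` and `replicate_id` (per column) and
#'   `flagged_zero_ancestral` (per gene).
#' @export
log2fc_per_sample <- function(cpm_table, design) {
  miss <- setdiff(design$sample_id, colnames(cpm_table))
  if (length(miss)) pv_stop(sprintf("sample '%s' missing from the CPM table", miss[1L]))
  anc <- design$sample_id[design$role == "ancestral"]
  if (length(anc) < 1L) pv_stop("no ancestral samples in the design")
  evo <- design[design$role == "evolved", , drop = FALSE]
  evo <- evo[order(evo$population_id, evo$replicate_id), , drop = FALSE]
  anc_mean <- rowMeans(cpm_table[, anc, drop = FALSE])
  zero <- anc_mean == 0
  X <- log2(cpm_table[, evo$sample_id, drop = FALSE] / anc_mean)
  X[zero, ] <- NA_real_
  attr(X, "population_id") <- evo$population_id
  attr(X, "replicate_id") <- evo$replicate_id
  attr(X, "flagged_zero_ancestral") <- rownames(cpm_table)[zero]
  X
}

#' F statistic and parallelism for one gene
#'
#' One-way decomposition of a population x replicate matrix of log2 fold
#' changes into between-population (`MS_pop`) and residual (`MS_e`) mean
#' squares, with `F = MS_pop / MS_e` and parallelism `1/F`.
#'
#' @param X numeric matrix, rows = populations (>= 2), columns =
#'   replicates (>= 2), finite entries.
#' @return List with `ms_pop`, `ms_e`, `f`, `parallelism`,
#'   `ln_parallelism`. `MS_e = 0` leaves `f` undefined (`NA`, flagged);
#'   `MS_pop = 0` gives parallelism `Inf`, excluded from log-scale use.
#' @examples
#' f_statistic(matrix(c(1, 3, 5, 7), 2, 2, byrow = TRUE))  # F = 4
#' @export
f_statistic <- function(X) {
  if (!is.matrix(X) || nrow(X) < 2L || ncol(X) < 2L) {
    pv_stop("'X' must be a matrix with >= 2 populations and >= 2 replicates")
  }
  if (anyNA(X) || any(!is.finite(X))) pv_stop("'X' must be finite")
  P <- nrow(X); N <- length(X)
  pop_means <- rowMeans(X)
  grand <- mean(X)
  ms_pop <- sum((pop_means - grand)^2) / (P - 1L)
  ms_e <- sum((X - pop_means)^2) / (N - P)
  if (ms_e == 0) {
    return(list(ms_pop = ms_pop, ms_e = 0, f = NA_real_,
                parallelism = NA_real_, ln_parallelism = NA_real_))
  }
  f <- ms_pop / ms_e
  list(ms_pop = ms_pop, ms_e = ms_e, f = f,
       parallelism = 1 / f,
       ln_parallelism = if (f > 0) -log(f) else Inf)
}

#' Gene-wise parallelism statistics
#'
#' Vectorized [f_statistic()] over the genes of a log2 fold-change matrix
#' as produced by [log2fc_per_sample()]. Populations may have unequal
#' replicate numbers; the residual denominator is then `N - P`.
#'
#' @param fc gene x evolved-sample matrix of log2 fold changes.
#' @param population_id integer vector assigning each column to an evolved
#'   population (defaults to the matrix attribute).
#' @return A `gene_evo_stats` data frame: `gene_id`, `ms_pop`, `ms_e`,
#'   `f`, `parallelism`, `ln_parallelism`, `flagged` (degenerate or
#'   non-finite input).
#' @export
evo_stats <- function(fc, population_id = attr(fc, "population_id")) {
  if (is.null(population_id)) pv_stop("'population_id' required")
  if (length(population_id) != ncol(fc)) {
    pv_stop("'population_id' must have one entry per column of 'fc'")
  }
  pops <- sort(unique(population_id))
  P <- length(pops)
  if (P < 2L) pv_stop("need >= 2 populations")
  n_i <- as.numeric(table(factor(population_id, levels = pops)))
  if (any(n_i < 2L)) pv_stop("every population needs >= 2 replicates")
  N <- ncol(fc)
  # membership matrix: columns -> populations
  Z <- outer(population_id, pops, `==`) * 1
  ok <- rowSums(!is.finite(fc)) == 0
  M <- (fc %*% Z) %*% diag(1 / n_i, P)           # per-population means
  grand <- rowMeans(fc)
  ms_pop <- rowSums((M - grand)^2) / (P - 1L)
  resid <- fc - M %*% t(Z)
  ms_e <- rowSums(resid^2) / (N - P)
  f <- ifelse(ms_e > 0, ms_pop / ms_e, NA_real_)
  parallelism <- ifelse(is.na(f), NA_real_, ifelse(f > 0, 1 / f, Inf))
  lnp <- ifelse(is.na(f) | f <= 0, NA_real_, -log(f))
  out <- data.frame(gene_id = rownames(fc), ms_pop = ms_pop, ms_e = ms_e,
                    f = ifelse(ok, f, NA_real_),
                    parallelism = ifelse(ok, parallelism, NA_real_),
                    ln_parallelism = ifelse(ok, lnp, NA_real_),
                    flagged = !ok | is.na(f) | !is.finite(parallelism),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("gene_evo_stats", "data.frame")
  out
}

#' Replicate frequency spectrum
#'
#' For each gene, `k` is the largest number of populations in which it is
#' called significant in the same direction; the RFS is the histogram of
#' `k` over genes with `k >= 1`.
#'
#' @param calls a `de_calls` table covering all populations
#'   (see [de_test_all()]).
#' @return Data frame `n_populations` (1..P), `n_genes`.
#' @export
build_rfs <- function(calls) {
  P <- length(unique(calls$population_id))
  tab <- direction_counts(calls)
  k <- pmax(tab$n_up, tab$n_down)
  k <- k[k >= 1L]
  data.frame(n_populations = seq_len(P),
             n_genes = as.integer(table(factor(k, levels = seq_len(P)))))
}

# per-gene counts of significant up/down calls across populations
direction_counts <- function(calls) {
  genes <- unique(calls$gene_id)
  up <- tapply(calls$call == "up", calls$gene_id, sum)[genes]
  down <- tapply(calls$call == "down", calls$gene_id, sum)[genes]
  mfc <- tapply(ifelse(calls$call == "ns", NA, calls$log2fc),
                calls$gene_id, mean, na.rm = TRUE)[genes]
  data.frame(gene_id = genes, n_up = as.integer(up),
             n_down = as.integer(down), mean_sig_log2fc = as.numeric(mfc),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Select putatively adaptive genes
#'
#' Genes with significant expression changes in the same direction in at
#' least `min_populations` evolved populations (inclusive threshold). The
#' majority direction is recorded; an exact tie is resolved by the sign of
#' the mean significant log2 fold change.
#'
#' @param calls a `de_calls` table (see [de_test_all()]).
#' @param min_populations minimum number of same-direction populations
#'   (default 3).
#' @return Data frame `gene_id`, `n_up`, `n_down`, `direction`.
#' @export
select_adaptive <- function(calls, min_populations = 3) {
  if (min_populations < 1L) pv_stop("'min_populations' must be >= 1")
  tab <- direction_counts(calls)
  keep <- pmax(tab$n_up, tab$n_down) >= min_populations
  tab <- tab[keep, , drop = FALSE]
  dir <- ifelse(tab$n_up > tab$n_down, "up",
         ifelse(tab$n_down > tab$n_up, "down",
                ifelse(tab$mean_sig_log2fc >= 0, "up", "down")))
  out <- data.frame(gene_id = tab$gene_id, n_up = tab$n_up,
                    n_down = tab$n_down, direction = dir,
                    stringsAsFactors = FALSE, row.names = NULL)
  out
}
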