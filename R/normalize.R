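# Library-size normalization and biological-variance estimation. TMM
# factors and the tagwise negative-binomial dispersion (Cox-Reid adjusted
# profile likelihood with empirical-Bayes shrinkage) come from edgeR, the
# package this workflow is built around; the CPM-with-prior arithmetic is
# spelled out here because the unlogged edgeR CPM does not take a prior.

#' Trimmed-mean-of-M-values normalization factors
#'
#' Computes per-sample TMM scaling factors (edgeR's `calcNormFactors`):
#' a reference sample is chosen by the 75th-percentile rule, per-sample
#' weighted means of gene-wise log2 ratios are taken after trimming the
#' most extreme M- and A-values, and the factors are renormalized to
#' geometric mean 1. Effective library size = library size x factor.
#'
#' @param m a [count_matrix()] with at least two samples.
#' @return An object of class `norm_factors`: list with `factors` and
#'   `effective_lib_size`, both named by sample.
#' @export
tmm_factors <- function(m) {
  if (ncol(m$counts) < 2L) pv_stop("TMM needs at least two samples")
  if (any(m$lib_size <= 0)) pv_stop("library sizes must be positive")
  f <- edgeR::calcNormFactors(m$counts, lib.size = m$lib_size, method = "TMM")
  names(f) <- colnames(m$counts)
  if (any(!is.finite(f)) || any(f <= 0)) {
    pv_stop("TMM failed: a sample shares no co-expressed genes with the reference")
  }
  structure(list(factors = f, effective_lib_size = m$lib_size * f),
            class = "norm_factors")
}

#' @export
print.norm_factors <- function(x, ...) {
  cat("norm_factors:\n"); print(round(x$factors, 4)); invisible(x)
}

#' Counts per million with an optional prior count
#'
#' CPM is `count / effective library size * 1e6`. A positive
#' `prior_count` is first scaled by the relative library size
#' (`r_j = lib_j / mean(lib)`) and added to the counts, with the library
#' size inflated by twice the scaled prior, so that samples of different
#' depth receive comparable damping:
#' `cpm = (y + prior * r_j) / (efflib_j + 2 * prior * r_j) * 1e6`.
#' With `prior_count = 0` this is the standard (edgeR) CPM.
#'
#' @param m a [count_matrix()].
#' @param f optional [tmm_factors()] result; factors default to 1.
#' @param prior_count non-negative damping count (default 0). Use a
#'   positive prior when the CPM feed a log fold change, so that a zero
#'   ancestral mean cannot produce infinities.
#' @return Numeric gene x sample matrix.
#' @export
cpm_matrix <- function(m, f = NULL, prior_count = 0) {
  if (!is.numeric(prior_count) || length(prior_count) != 1L || prior_count < 0) {
    pv_stop("'prior_count' must be a single non-negative number")
  }
  factors <- if (is.null(f)) rep(1, ncol(m$counts)) else f$factors[colnames(m$counts)]
  if (any(!is.finite(factors)) || any(factors <= 0)) {
    pv_stop("normalization factors must be positive")
  }
  eff <- m$lib_size * factors
  r <- m$lib_size / mean(m$lib_size)
  t((t(m$counts) + prior_count * r) / (eff + 2 * prior_count * r)) * 1e6
}

#' Filter genes by minimum expression in every sample
#'
#' Keeps genes whose CPM is at least `threshold` in all samples (the
#' boundary is inclusive). The filter is applied to prior-free CPM to
#' match the stated rule literally.
#'
#' @param cpm_table gene x sample CPM matrix (see [cpm_matrix()]).
#' @param threshold positive CPM cutoff (default 0.1).
#' @return Character vector of retained gene ids (empty with a warning if
#'   nothing passes).
#' @export
filter_low_expression <- function(cpm_table, threshold = 0.1) {
  if (!is.numeric(threshold) || threshold <= 0) {
    pv_stop("'threshold' must be positive")
  }
  keep <- rownames(cpm_table)[apply(cpm_table >= threshold, 1L, all)]
  if (length(keep) == 0L) warning("no gene passes the expression filter")
  keep
}

#' Per-gene biological variance (BCV^2) from an individual-level panel
#'
#' Estimates the gene-wise negative-binomial dispersion of a panel of
#' individually sequenced samples drawn from one population, separating
#' biological variability from counting noise. The squared biological
#' coefficient of variation equals the NB dispersion, estimated by
#' Cox-Reid adjusted profile likelihood with empirical-Bayes shrinkage
#' toward the common/trended dispersion (edgeR's tagwise estimator).
#'
#' @param panel a [count_matrix()] of at least 5 individuals.
#' @param f optional [tmm_factors()] for the panel; computed if `NULL`.
#' @param prior_df prior degrees of freedom controlling the shrinkage
#'   weight (default 20, the edgeR default at this design size).
#' @return A `dispersion_estimate` data frame with columns `gene_id`,
#'   `bcv2` (NA for all-zero genes, which are flagged) and `flagged`;
#'   attributes `common_dispersion` and `prior_df`.
#' @export
estimate_bcv2 <- function(panel, f = NULL, prior_df = 20) {
  n <- ncol(panel$counts)
  if (n < 5L) pv_stop("BCV^2 estimation needs at least 5 individuals")
  if (is.null(f)) f <- tmm_factors(panel)
  d <- edgeR::DGEList(counts = panel$counts,
                      lib.size = unname(panel$lib_size),
                      norm.factors = unname(f$factors[colnames(panel$counts)]))
  design <- matrix(1, n, 1L)
  d <- edgeR::estimateDisp(d, design = design, prior.df = prior_df)
  bcv2 <- as.numeric(d$tagwise.dispersion)
  flagged <- rowSums(panel$counts) == 0
  bcv2[flagged] <- NA_real_
  out <- data.frame(gene_id = rownames(panel$counts), bcv2 = bcv2,
                    flagged = unname(flagged), stringsAsFactors = FALSE)
  class(out) <- c("dispersion_estimate", "data.frame")
  attr(out, "common_dispersion") <- d$common.dispersion
  attr(out, "prior_df") <- prior_df
  out
}
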