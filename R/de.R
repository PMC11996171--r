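# Per-population differential-expression testing: each evolved population
# is contrasted against the common ancestral samples with a negative
# binomial log-link GLM (evolution as a two-level factor, offset = log
# effective library size) and a 1-df likelihood-ratio test, followed by
# Benjamini-Hochberg FDR control within the population.

#' Benjamini-Hochberg adjustment with NA propagation
#'
#' Step-up BH with monotonicity enforcement (via [stats::p.adjust()]).
#' `NA` entries are carried through unchanged and do not count toward the
#' number of tests.
#'
#' @param p numeric vector of p-values in `[0, 1]`, possibly with `NA`.
#' @return Adjusted p-values, same length and names as `p`.
#' @export
bh_adjust <- function(p) {
  if (!is.numeric(p)) pv_stop("'p' must be numeric")
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) pv_stop("p-values must lie in [0, 1]")
  out <- p
  out[ok] <- p.adjust(p[ok], method = "BH")
  out
}

#' Differential-expression test for one evolved population
#'
#' Fits, per gene, a negative-binomial GLM of the ancestral plus the focal
#' population's samples on a two-level evolution factor and tests the
#' evolution effect with a likelihood-ratio test (edgeR `glmFit`/`glmLRT`).
#' The dispersion is either supplied (e.g. a panel-based
#' [estimate_bcv2()] result or a known simulation value) or estimated once
#' from the samples of the contrast. Genes with all-zero counts in the
#' contrast get `p = NA` and call `ns`.
#'
#' @param m a [count_matrix()] (typically already expression-filtered).
#' @param design a [sample_design()] covering the samples of `m`.
#' @param pop evolved population id (>= 1) with at least 2 replicates.
#' @param dispersion `NULL` (estimate from the contrast), a single value,
#'   a per-gene vector named by gene, or a `dispersion_estimate`.
#' @param fdr_level BH-adjusted significance level for the up/down calls
#'   (default 0.05).
#' @param f optional [tmm_factors()] computed on `m`; computed if `NULL`.
#' @return A `de_calls` data frame with one row per gene: `gene_id`,
#'   `population_id`, `log2fc`, `pvalue`, `fdr`, `call` (up/down/ns).
#' @export
de_test_population <- function(m, design, pop, dispersion = NULL,
                               fdr_level = 0.05, f = NULL) {
  validate_study(m, design)
  if (!pop %in% design$population_id[design$role == "evolved"]) {
    pv_stop(sprintf("population %s not present among evolved samples", format(pop)))
  }
  if (fdr_level <= 0 || fdr_level > 1) pv_stop("'fdr_level' must be in (0, 1]")
  anc <- design$sample_id[design$role == "ancestral"]
  evo <- design$sample_id[design$population_id == pop]
  if (length(evo) < 2L) pv_stop("the focal population needs >= 2 replicates")
  if (length(anc) < 2L) pv_stop("at least 2 ancestral samples are required")
  if (is.null(f)) f <- tmm_factors(m)
  sel <- c(anc, evo)
  y <- m$counts[, sel, drop = FALSE]
  lib <- m$lib_size[sel]
  nf <- f$factors[sel]
  grp <- factor(rep(c("ancestral", "evolved"), c(length(anc), length(evo))),
                levels = c("ancestral", "evolved"))
  X <- model.matrix(~grp)

  zero <- rowSums(y) == 0
  if (is.null(dispersion)) {
    d <- edgeR::DGEList(counts = y, lib.size = unname(lib * nf))
    d <- edgeR::estimateDisp(d, design = X)
    disp <- d$tagwise.dispersion
  } else if (inherits(dispersion, "dispersion_estimate")) {
    disp <- dispersion$bcv2[match(rownames(y), dispersion$gene_id)]
    if (anyNA(disp[!zero])) pv_stop("dispersion missing for some non-zero genes")
    disp[is.na(disp)] <- attr(dispersion, "common_dispersion")
  } else {
    disp <- rep_len(as.numeric(dispersion), nrow(y))
    if (!is.null(names(dispersion)) && length(dispersion) > 1L) {
      disp <- as.numeric(dispersion[rownames(y)])
    }
    if (anyNA(disp) || any(disp < 0)) pv_stop("invalid dispersion values")
  }
  disp <- pmax(disp, 1e-6)  # glmFit needs a positive dispersion

  fit <- edgeR::glmFit(y, design = X, dispersion = disp,
                       lib.size = unname(lib * nf))
  lrt <- edgeR::glmLRT(fit, coef = 2L)
  tab <- lrt$table
  pval <- tab$PValue
  lfc <- tab$logFC
  pval[zero] <- NA_real_
  lfc[zero] <- NA_real_
  fdr <- bh_adjust(pval)
  call <- ifelse(!is.na(fdr) & fdr <= fdr_level,
                 ifelse(lfc > 0, "up", "down"), "ns")
  out <- data.frame(gene_id = rownames(y),
                    population_id = as.integer(pop),
                    log2fc = lfc, pvalue = pval, fdr = fdr, call = call,
                    stringsAsFactors = FALSE)
  class(out) <- c("de_calls", "data.frame")
  attr(out, "fdr_level") <- fdr_level
  out
}

#' Differential-expression tests for all evolved populations
#'
#' Runs [de_test_population()] separately for every evolved population
#' against the shared ancestral samples (the ancestral samples are reused
#' across tests; BH correction is applied within each population).
#'
#' @inheritParams de_test_population
#' @return A `de_calls` data frame stacking all populations.
#' @export
de_test_all <- function(m, design, dispersion = NULL, fdr_level = 0.05,
                        f = NULL) {
  if (is.null(f)) f <- tmm_factors(m)
  pops <- sort(unique(design$population_id[design$role == "evolved"]))
  out <- do.call(rbind, lapply(pops, function(p) {
    de_test_population(m, design, p, dispersion = dispersion,
                       fdr_level = fdr_level, f = f)
  }))
  rownames(out) <- NULL
  class(out) <- c("de_calls", "data.frame")
  attr(out, "fdr_level") <- fdr_level
  out
}
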