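#' Run the full parallelism analysis on a study
#'
#' Chains the pipeline end to end: TMM normalization, the minimum-CPM
#' expression filter, per-population differential-expression tests,
#' replicate frequency spectrum and putatively-adaptive gene selection,
#' per-sample log2 fold changes and the per-gene parallelism statistic
#' 1/F, ancestral BCV^2 from an individual panel, pleiotropy proxies,
#' causal-model selection by BIC and the path-analysis effect
#' decomposition.
#'
#' @param counts a [count_matrix()] of pooled ancestral + evolved samples.
#' @param design the matching [sample_design()].
#' @param panel a [count_matrix()] of individually profiled ancestral
#'   samples (for BCV^2).
#' @param tissues optional [tissue_profile()]; @param network optional
#'   [network_edges()]. At least the source matching `proxy` is required.
#' @param proxy pleiotropy proxy for the causal stage: `"tissue"`
#'   (1 - tau, default) or `"connectivity"`.
#' @param cpm_threshold minimum prior-free CPM required in every sample
#'   (default 0.1).
#' @param cpm_prior prior count used for the log2 fold-change CPM
#'   (default 0.5, so a zero ancestral mean cannot produce infinities).
#' @param fdr_level per-population BH level for the up/down calls
#'   (default 0.05).
#' @param min_populations same-direction populations required for a gene
#'   to count as putatively adaptive (default 3).
#' @param dispersion optional dispersion passed to the DE tests
#'   (default `NULL`: estimated per contrast).
#' @param n_boot bootstrap resamples for the indirect-effect CI.
#' @param seed RNG seed (bootstrap only; the analysis itself is
#'   deterministic).
#' @return A list with elements `norm`, `kept_genes`, `de`, `rfs`,
#'   `adaptive`, `log2fc`, `stats`, `bcv2`, `pleiotropy`, `causal_data`,
#'   `causal`, `path`.
#' @export
analyze_study <- function(counts, design, panel, tissues = NULL,
                          network = NULL, proxy = c("tissue", "connectivity"),
                          cpm_threshold = 0.1, cpm_prior = 0.5,
                          fdr_level = 0.05, min_populations = 3,
                          dispersion = NULL, n_boot = 1000, seed = 1) {
  proxy <- match.arg(proxy)
  validate_study(counts, design)
  f0 <- tmm_factors(counts)
  keep <- filter_low_expression(cpm_matrix(counts, f0, prior_count = 0),
                                threshold = cpm_threshold)
  m <- counts[keep, ]
  f <- tmm_factors(m)
  de <- de_test_all(m, design, dispersion = dispersion,
                    fdr_level = fdr_level, f = f)
  rfs <- build_rfs(de)
  adaptive <- select_adaptive(de, min_populations = min_populations)
  cpmP <- cpm_matrix(m, f, prior_count = cpm_prior)
  X <- log2fc_per_sample(cpmP, design)
  stats <- evo_stats(X)
  panel_f <- tmm_factors(panel[keep, ])
  bcv2 <- estimate_bcv2(panel[keep, ], panel_f)
  pt <- pleiotropy_table(tissues = tissues, network = network, genes = keep)
  cd <- build_causal_data(stats, bcv2, pt, genes = adaptive$gene_id,
                          proxy = proxy)
  causal <- select_causal_model(cd)
  path <- path_analysis(cd, n_boot = n_boot, seed = seed)
  list(norm = f, kept_genes = keep, de = de, rfs = rfs,
       adaptive = adaptive, log2fc = X, stats = stats, bcv2 = bcv2,
       pleiotropy = pt, causal_data = cd, causal = causal, path = path)
}
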