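# Forward Wright-Fisher simulation of replicated polygenic adaptation
# after a shift in trait optimum. A fitness-related trait is the additive
# sum of four redundant gene-level phenotypes; each gene is controlled by
# a different number of unlinked, equal-effect diploid loci, so genes
# differ in their ancestral phenotypic variance. Replicate populations
# founded from the same haplotype panel evolve under Gaussian stabilizing
# selection around the shifted optimum; after the run the per-gene
# parallelism of the evolved change is quantified with the same 1/F
# statistic as for empirical expression data.

#' Genetic architecture of the simulated trait
#'
#' @param n_loci loci per gene (default `c(5, 15, 30, 50)`, four genes).
#' @param effect per-locus allelic effect; equal within and across genes
#'   (a single value, default 1), so ancestral variance grows with the
#'   number of segregating loci.
#' @return An `architecture` list: `genes` (data frame of gene id,
#'   n_loci, effect), `loci` (per-gene column indices), `n_loci_total`,
#'   `alpha` (per-locus effects).
#' @export
architecture <- function(n_loci = c(5, 15, 30, 50), effect = 1) {
  if (any(n_loci < 1L)) pv_stop("every gene needs at least one locus")
  if (!is.numeric(effect) || any(effect <= 0)) pv_stop("'effect' must be positive")
  effect <- rep_len(effect, length(n_loci))
  ends <- cumsum(n_loci)
  starts <- c(1L, head(ends, -1L) + 1L)
  loci <- Map(seq, starts, ends)
  genes <- data.frame(gene_id = sprintf("gene_%dloci", n_loci),
                      n_loci = as.integer(n_loci), effect = effect,
                      stringsAsFactors = FALSE)
  names(loci) <- genes$gene_id
  structure(list(genes = genes, loci = loci,
                 n_loci_total = sum(n_loci),
                 alpha = rep(effect, n_loci)),
            class = "architecture")
}

#' Simulation configuration
#'
#' @param N diploid population size (default 300).
#' @param n_replicates replicate populations per run (default 10).
#' @param generations generations of evolution (default 100).
#' @param optimum_shift optimum displacement in units of the ancestral
#'   trait SD (default 1).
#' @param selection_width SD of the Gaussian fitness function in
#'   ancestral-trait-SD units (default 2, moderate stabilizing
#'   selection); `Inf` gives neutral evolution.
#' @param n_runs independent simulation runs (default 100).
#' @param measurement_replicates noisy measurements per evolved
#'   population (default 3, mirroring the biological replicates of the
#'   empirical design).
#' @param measurement_noise SD of measurement noise in ancestral
#'   trait-SD units (default 0.1).
#' @return A `sim_config` list.
#' @export
sim_config <- function(N = 300, n_replicates = 10, generations = 100,
                       optimum_shift = 1, selection_width = 2,
                       n_runs = 100, measurement_replicates = 3,
                       measurement_noise = 0.1) {
  cfg <- list(N = N, n_replicates = n_replicates, generations = generations,
              optimum_shift = optimum_shift,
              selection_width = selection_width, n_runs = n_runs,
              measurement_replicates = measurement_replicates,
              measurement_noise = measurement_noise)
  num <- unlist(cfg[c("N", "n_replicates", "generations",
                      "measurement_replicates")])
  if (any(num < 1)) pv_stop("population sizes, replicates and generations must be >= 1")
  if (cfg$selection_width <= 0) pv_stop("'selection_width' must be positive")
  if (cfg$measurement_noise < 0) pv_stop("'measurement_noise' must be >= 0")
  structure(cfg, class = "sim_config")
}

# one Wright-Fisher generation cycle on a 2N x L haplotype matrix:
# Gaussian stabilizing viability selection, then 2N gametes with free
# recombination (each gamete locus drawn independently from the chosen
# parent's two haplotypes)
wf_generation <- function(H, alpha, opt, omega) {
  twoN <- nrow(H); L <- ncol(H)
  odd <- seq(1L, twoN, by = 2L)
  z <- as.vector((H[odd, , drop = FALSE] + H[odd + 1L, , drop = FALSE]) %*% alpha)
  w <- if (is.finite(omega)) exp(-((z - opt)^2) / (2 * omega^2)) else
    rep(1, length(z))
  if (sum(w) <= 0) w <- rep(1, length(z))
  par <- sample.int(length(z), twoN, replace = TRUE, prob = w)
  P1 <- H[2L * par - 1L, , drop = FALSE]
  P2 <- H[2L * par, , drop = FALSE]
  swap <- matrix(runif(twoN * L) < 0.5, twoN, L)
  P1[swap] <- P2[swap]
  P1
}

# per-individual gene phenotypes (N x n_genes) of a haplotype matrix
gene_phenotypes <- function(H, arch) {
  odd <- seq(1L, nrow(H), by = 2L)
  G <- H[odd, , drop = FALSE] + H[odd + 1L, , drop = FALSE]
  vapply(seq_len(nrow(arch$genes)), function(g) {
    idx <- arch$loci[[g]]
    as.vector(G[, idx, drop = FALSE] %*% arch$alpha[idx])
  }, numeric(length(odd)))
}

#' Evolve one replicate population
#'
#' Initializes `2N` haplotypes by sampling founders with replacement and
#' runs `generations` Wright-Fisher cycles of Gaussian stabilizing
#' selection around `optimum` with fitness-function SD `omega` (absolute
#' trait units). Fixation of all loci is not an error; the variance is
#' simply 0 from then on.
#'
#' @param founders 0/1 founder haplotype matrix
#'   (see [gen_founder_haplotypes()]); columns must cover the
#'   architecture's loci.
#' @param arch an [architecture()].
#' @param cfg a [sim_config()].
#' @param optimum,omega absolute trait optimum and selection width; if
#'   `NULL` they are derived from this replicate's initial population
#'   (`mean + optimum_shift * SD`, `selection_width * SD`).
#' @param record `"summary"` (default) or `"freq"` to also return the
#'   per-generation allele-frequency matrix.
#' @param seed optional RNG seed.
#' @return List with `gene_means_start`, `gene_means_end` (per-gene mean
#'   phenotypes), `trait_mean_start`, `trait_mean_end`, `optimum`, and
#'   optionally `freq` (generations+1 x loci).
#' @export
run_replicate <- function(founders, arch, cfg, optimum = NULL, omega = NULL,
                          record = c("summary", "freq"), seed = NULL) {
  record <- match.arg(record)
  if (ncol(founders) < arch$n_loci_total) {
    pv_stop("founder matrix has fewer loci than the architecture")
  }
  with_seed(seed, {
    L <- arch$n_loci_total
    H <- founders[sample.int(nrow(founders), 2L * cfg$N, replace = TRUE),
                  seq_len(L), drop = FALSE]
    ph0 <- gene_phenotypes(H, arch)
    z0 <- rowSums(ph0)
    if (is.null(optimum)) optimum <- mean(z0) + cfg$optimum_shift * sd(z0)
    if (is.null(omega)) omega <- cfg$selection_width * sd(z0)
    freq <- if (record == "freq") matrix(NA_real_, cfg$generations + 1L, L)
    if (record == "freq") freq[1L, ] <- colMeans(H)
    for (g in seq_len(cfg$generations)) {
      H <- wf_generation(H, arch$alpha, optimum, omega)
      if (record == "freq") freq[g + 1L, ] <- colMeans(H)
    }
    ph1 <- gene_phenotypes(H, arch)
    out <- list(gene_means_start = colMeans(ph0),
                gene_means_end = colMeans(ph1),
                gene_vars_start = apply(ph0, 2L, var),
                trait_mean_start = mean(z0),
                trait_mean_end = mean(rowSums(ph1)),
                optimum = optimum, omega = omega)
    names(out$gene_means_start) <- names(out$gene_means_end) <-
      names(out$gene_vars_start) <- arch$genes$gene_id
    if (record == "freq") out$freq <- freq
    out
  })
}

#' Parallelism of the evolved change across replicate populations
#'
#' Mirrors the empirical analysis: per gene, each evolved population
#' contributes `measurement_replicates` noisy measurements of its mean
#' expression phenotype, and the evolutionary response of each
#' measurement is its log2 fold change relative to the ancestral mean —
#' the same statistic as for empirical CPM data. The resulting `X_ij`
#' matrix feeds [f_statistic()] to give `F` and `1/F`. Measurements that
#' come out non-positive (possible when the noise exceeds a small
#' phenotype) make the log undefined and flag the gene for that run.
#'
#' @param final_means gene x replicate matrix of evolved mean phenotypes.
#' @param ancestral_mean per-gene ancestral means (must be positive for a
#'   gene to be scored).
#' @param noise_sd measurement-noise SD (absolute trait units).
#' @param measurement_replicates noisy draws per population.
#' @param seed optional RNG seed.
#' @return Data frame per gene: `gene_id`, `ms_pop`, `ms_e`, `f`,
#'   `parallelism`, `ln_parallelism`, `flagged`.
#' @export
evaluate_parallelism <- function(final_means, ancestral_mean, noise_sd,
                                 measurement_replicates = 3, seed = NULL) {
  with_seed(seed, {
    n_genes <- nrow(final_means); R <- measurement_replicates
    P <- ncol(final_means)
    meas <- final_means[, rep(seq_len(P), each = R), drop = FALSE] +
      matrix(rnorm(n_genes * P * R, 0, noise_sd), n_genes, P * R)
    meas[meas <= 0] <- NA_real_
    X <- log2(meas / ifelse(ancestral_mean > 0, ancestral_mean, NA_real_))
    X[!is.finite(X)] <- NA_real_
    rownames(X) <- rownames(final_means) %||% sprintf("gene%d", seq_len(n_genes))
    evo_stats(X, population_id = rep(seq_len(P), each = R))
  })
}

#' Replicated optimum-shift experiment
#'
#' Runs `cfg$n_runs` independent simulation runs. Each run founds
#' `cfg$n_replicates` populations from the same haplotype panel, derives
#' the shared optimum and selection width from the run's pooled initial
#' individuals, evolves every replicate, and evaluates each gene's
#' ancestral phenotypic variance and the parallelism `1/F` of its evolved
#' change. One of the genes is sampled uniformly per run, and the
#' experiment summary is the Spearman correlation between ancestral
#' variance and `ln(1/F)` over the sampled genes.
#'
#' @param cfg a [sim_config()].
#' @param arch an [architecture()] (default: four genes of 5/15/30/50
#'   equal-effect loci).
#' @param founders optional founder haplotypes; by default 189 synthetic
#'   haplotypes are generated once and shared by all runs.
#' @param seed RNG seed for the whole experiment (default 1).
#' @return A `sim_experiment` list: `results` (per run x gene data
#'   frame with `sampled` flag), `rho`, `p_value`, `n_used`, `cfg`.
#' @export
run_experiment <- function(cfg = sim_config(), arch = architecture(),
                           founders = NULL, seed = 1) {
  with_seed(seed, {
    if (is.null(founders)) {
      founders <- gen_founder_haplotypes(189, arch$n_loci_total)
    }
    n_genes <- nrow(arch$genes)
    rows <- vector("list", cfg$n_runs)
    for (r in seq_len(cfg$n_runs)) {
      # found all replicates first so ancestral statistics and the shared
      # optimum come from the pooled generation-0 individuals
      H0 <- lapply(seq_len(cfg$n_replicates), function(i) {
        founders[sample.int(nrow(founders), 2L * cfg$N, replace = TRUE),
                 seq_len(arch$n_loci_total), drop = FALSE]
      })
      ph0 <- do.call(rbind, lapply(H0, gene_phenotypes, arch = arch))
      anc_mean <- colMeans(ph0)
      anc_var <- apply(ph0, 2L, var)
      z0 <- rowSums(ph0)
      sd_anc <- sd(z0)
      opt <- mean(z0) + cfg$optimum_shift * sd_anc
      omega <- cfg$selection_width * sd_anc
      finals <- vapply(H0, function(H) {
        for (g in seq_len(cfg$generations)) {
          H <- wf_generation(H, arch$alpha, opt, omega)
        }
        colMeans(gene_phenotypes(H, arch))
      }, numeric(n_genes))
      rownames(finals) <- arch$genes$gene_id
      st <- evaluate_parallelism(finals, anc_mean,
                                 noise_sd = cfg$measurement_noise * sd_anc,
                                 measurement_replicates = cfg$measurement_replicates)
      st$run <- r
      st$ancestral_variance <- unname(anc_var)
      st$sampled <- seq_len(n_genes) == sample.int(n_genes, 1L)
      rows[[r]] <- st
    }
    results <- do.call(rbind, rows)
    sampled <- results[results$sampled & !results$flagged &
                         is.finite(results$ln_parallelism), , drop = FALSE]
    dropped <- cfg$n_runs - nrow(sampled)
    if (dropped > 0) {
      message(sprintf("excluded %d run(s) with a degenerate sampled gene", dropped))
    }
    ct <- suppressWarnings(cor.test(sampled$ancestral_variance,
                                    sampled$ln_parallelism,
                                    method = "spearman", exact = FALSE))
    structure(list(results = results, rho = unname(ct$estimate),
                   p_value = ct$p.value, n_used = nrow(sampled), cfg = cfg,
                   seed = seed),
              class = "sim_experiment")
  })
}

#' @export
print.sim_experiment <- function(x, ...) {
  cat(sprintf(paste0("replicated optimum-shift experiment: %d runs, ",
                     "Spearman rho(ancestral variance, ln 1/F) = %.3f ",
                     "(p = %.3g, n = %d)\n"),
              x$cfg$n_runs, x$rho, x$p_value, x$n_used))
  invisible(x)
}
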