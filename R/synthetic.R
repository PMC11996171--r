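# Synthetic-data generators with known ground truth. The generator
# emulates the structure of the study the pipeline targets: 5 pooled
# ancestral samples plus 10 evolved populations x 3 biological replicates
# of RNA-seq counts, two panels of 20 individually profiled ancestral
# flies, a FlyAtlas2-like tissue table and a regulatory-network edge
# list, with a configurable causal structure among pleiotropy (Pl),
# ancestral variation (A = ln BCV^2) and parallelism (Pa = ln 1/F).

#' Build the standard study design
#'
#' @param n_populations evolved populations (default 10).
#' @param n_replicates biological replicates per evolved population
#'   (default 3).
#' @param n_ancestral pooled ancestral samples (default 5).
#' @return A [sample_design()].
#' @export
study_design <- function(n_populations = 10, n_replicates = 3,
                         n_ancestral = 5) {
  anc <- data.frame(sample_id = sprintf("anc_r%d", seq_len(n_ancestral)),
                    role = "ancestral", population_id = 0L,
                    replicate_id = seq_len(n_ancestral))
  evo <- expand.grid(replicate_id = seq_len(n_replicates),
                     population_id = seq_len(n_populations))
  evo <- data.frame(sample_id = sprintf("evo_p%02d_r%d", evo$population_id,
                                        evo$replicate_id),
                    role = "evolved", population_id = evo$population_id,
                    replicate_id = evo$replicate_id)
  sample_design(rbind(anc, evo))
}

#' Generate gene-level causal ground truth
#'
#' Draws `(Pl, A, Pa)` triples from one of the five causal graphs (see
#' [fit_causal_model()]). Root nodes are standard normal; every child is
#' the stated linear combination of its parents plus Gaussian noise with
#' SD `noise_sd`:
#' model I `A = a Pl + e, Pa = b A + e'`; II `A = a Pl + e, Pa = c Pl +
#' e'`; III `A = a Pl + e, Pa = b A + c Pl + e'`; IV `Pa = b A + c Pl +
#' e` with `A` independent of `Pl`; V all mutually independent.
#'
#' The default slopes are a strong-link regime in which every arrow is
#' individually detectable at the study's gene numbers.
#'
#' @param model `"I"`..`"V"`.
#' @param n_genes number of genes (>= 10).
#' @param coefficients list with slopes `a` (Pl -> A), `b` (A -> Pa),
#'   `c` (Pl -> Pa); only those used by `model` matter.
#' @param noise_sd residual SD of child nodes (positive).
#' @param seed optional RNG seed.
#' @return A `causal_truth` data frame: `gene_id`, `Pl`, `A`, `Pa`,
#'   `generating_model`; the coefficients are stored as an attribute.
#' @export
gen_causal_truth <- function(model, n_genes,
                             coefficients = list(a = -0.5, b = -0.4, c = 0.3),
                             noise_sd = 1, seed = NULL) {
  model <- match.arg(model, CAUSAL_MODELS)
  if (n_genes < 10L) pv_stop("'n_genes' must be at least 10")
  co <- coefficients
  if (!all(vapply(co[c("a", "b", "c")], function(x)
        is.null(x) || (is.numeric(x) && is.finite(x)), TRUE))) {
    pv_stop("causal coefficients must be finite numbers")
  }
  a <- co$a %||% 0; b <- co$b %||% 0; cc <- co$c %||% 0
  if (!is.numeric(noise_sd) || noise_sd <= 0) pv_stop("'noise_sd' must be positive")
  with_seed(seed, {
    Pl <- rnorm(n_genes)
    e1 <- rnorm(n_genes, sd = noise_sd)
    e2 <- rnorm(n_genes, sd = noise_sd)
    A <- switch(model,
      I = , II = , III = a * Pl + e1,
      IV = , V = rnorm(n_genes))
    Pa <- switch(model,
      I   = b * A + e2,
      II  = cc * Pl + e2,
      III = b * A + cc * Pl + e2,
      IV  = b * A + cc * Pl + e2,
      V   = rnorm(n_genes))
    out <- data.frame(gene_id = sprintf("g%05d", seq_len(n_genes)),
                      Pl = Pl, A = A, Pa = Pa, generating_model = model,
                      stringsAsFactors = FALSE)
    class(out) <- c("causal_truth", "data.frame")
    attr(out, "coefficients") <- list(a = a, b = b, c = cc)
    attr(out, "noise_sd") <- noise_sd
    out
  })
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# negative-binomial draw that degrades gracefully to Poisson at phi = 0
rnb <- function(n, mu, phi) {
  if (length(phi) == 1L) phi <- rep(phi, length.out = n)
  out <- numeric(n)
  pois <- phi == 0
  if (any(pois)) out[pois] <- rpois(sum(pois), rep_len(mu, n)[pois])
  if (any(!pois)) {
    mu <- rep_len(mu, n)
    out[!pois] <- rnbinom(sum(!pois), mu = mu[!pois], size = 1 / phi[!pois])
  }
  out
}

#' Generate a pooled-sample count matrix from causal ground truth
#'
#' Ancestral samples draw negative-binomial counts around each gene's mean
#' expression with dispersion `bcv2_center * exp(A)` (so that the latent
#' `A` is the log dispersion up to a constant). Each evolved population
#' receives one true log2 fold change, shared by its replicates: a
#' gene-level adaptive shift of magnitude `lfc_mean` (random sign) plus a
#' population-specific deviation with SD `lfc_sd_scale * exp(-Pa/2)` —
#' monotonically decreasing in the parallelism latent, so high-`Pa` genes
#' respond alike in all populations. Replicate noise comes from the same
#' NB measurement model.
#'
#' @param truth a [gen_causal_truth()] table.
#' @param design a [sample_design()]; defaults to [study_design()].
#' @param mean_expression per-gene positive mean counts; default
#'   log-normal(log 100, 1.25).
#' @param bcv2_center dispersion at `A = 0` (default 0.09, a typical
#'   outbred-panel BCV of 0.3).
#' @param lfc_mean magnitude of the shared adaptive log2 shift
#'   (default 1).
#' @param lfc_sd_scale scale of the across-population log2 fold-change SD
#'   (default 1, i.e. `SD = exp(-Pa/2)`).
#' @param seed optional RNG seed.
#' @return A [count_matrix()] with attributes `true_log2fc` (gene x
#'   population), `dispersion` (per gene) and `mean_expression`.
#' @export
gen_counts_from_truth <- function(truth, design = study_design(),
                                  mean_expression = NULL,
                                  bcv2_center = 0.09, lfc_mean = 1,
                                  lfc_sd_scale = 1, seed = NULL) {
  n_genes <- nrow(truth)
  with_seed(seed, {
    if (is.null(mean_expression)) {
      mean_expression <- exp(rnorm(n_genes, log(100), 1.25))
    }
    if (any(!is.finite(mean_expression)) || any(mean_expression <= 0)) {
      pv_stop("'mean_expression' must be positive and finite")
    }
    phi <- bcv2_center * exp(truth$A)
    pops <- sort(unique(design$population_id[design$role == "evolved"]))
    P <- length(pops)
    delta <- lfc_mean * sample(c(-1, 1), n_genes, replace = TRUE)
    sd_pop <- lfc_sd_scale * exp(-truth$Pa / 2)
    lfc <- delta + matrix(rnorm(n_genes * P, 0, sd_pop), n_genes, P)
    colnames(lfc) <- paste0("pop", pops); rownames(lfc) <- truth$gene_id
    counts <- matrix(0, n_genes, nrow(design),
                     dimnames = list(truth$gene_id, design$sample_id))
    for (j in seq_len(nrow(design))) {
      p <- design$population_id[j]
      mu <- if (p == 0L) mean_expression else
        mean_expression * 2^lfc[, match(p, pops)]
      counts[, j] <- rnb(n_genes, mu, phi)
    }
    cm <- count_matrix(counts)
    attr(cm, "true_log2fc") <- lfc
    attr(cm, "dispersion") <- setNames(phi, truth$gene_id)
    attr(cm, "mean_expression") <- setNames(mean_expression, truth$gene_id)
    cm
  })
}

#' Generate an individual-level ancestral panel
#'
#' Negative-binomial counts for individually profiled ancestral samples,
#' with the same per-gene mean and dispersion model as
#' [gen_counts_from_truth()]; used to estimate BCV^2.
#'
#' @inheritParams gen_counts_from_truth
#' @param n_individuals panel size (default 20).
#' @param panel_id label used in the sample names.
#' @return A [count_matrix()] of `n_individuals` samples.
#' @export
gen_individual_panel <- function(truth, n_individuals = 20,
                                 mean_expression = NULL,
                                 bcv2_center = 0.09, panel_id = 1,
                                 seed = NULL) {
  n_genes <- nrow(truth)
  with_seed(seed, {
    if (is.null(mean_expression)) {
      mean_expression <- exp(rnorm(n_genes, log(100), 1.25))
    }
    phi <- bcv2_center * exp(truth$A)
    counts <- vapply(seq_len(n_individuals),
                     function(i) rnb(n_genes, mean_expression, phi),
                     numeric(n_genes))
    dimnames(counts) <- list(truth$gene_id,
                             sprintf("panel%s_ind%02d", panel_id,
                                     seq_len(n_individuals)))
    count_matrix(counts)
  })
}

#' Generate a tissue profile with prescribed tau
#'
#' One tissue (chosen at random) is set to 1 and all others to
#' `1 - target_tau`, so the computed tissue-specificity index equals the
#' target exactly.
#'
#' @param target_tau per-gene values in `[0, 1]` (names become gene ids).
#' @param n_tissues number of tissues (>= 2).
#' @param seed optional RNG seed (position of the maximal tissue).
#' @return A [tissue_profile()].
#' @export
gen_tissue_profile <- function(target_tau, n_tissues = 10, seed = NULL) {
  if (n_tissues < 2L) pv_stop("'n_tissues' must be at least 2")
  if (any(!is.finite(target_tau)) || any(target_tau < 0 | target_tau > 1)) {
    pv_stop("'target_tau' values must lie in [0, 1]")
  }
  n <- length(target_tau)
  genes <- names(target_tau) %||% sprintf("g%05d", seq_len(n))
  with_seed(seed, {
    m <- matrix(rep(1 - target_tau, n_tissues), n, n_tissues)
    m[cbind(seq_len(n), sample.int(n_tissues, n, replace = TRUE))] <- 1
    dimnames(m) <- list(genes, sprintf("tissue%02d", seq_len(n_tissues)))
    tissue_profile(m)
  })
}

#' Generate a network with prescribed per-gene connectivity
#'
#' Greedy pairing: repeatedly joins the two genes with the largest
#' remaining connectivity deficit by an edge carrying the smaller of the
#' two deficits. The achieved sums are exact whenever the targets are
#' jointly feasible (at most one gene can be left with an unmet
#' remainder, reported in the `unmet` attribute).
#'
#' @param target_connectivity named non-negative per-gene targets.
#' @param seed optional RNG seed (tie-breaking shuffle).
#' @return A [network_edges()] edge list.
#' @export
gen_network <- function(target_connectivity, seed = NULL) {
  if (any(!is.finite(target_connectivity)) || any(target_connectivity < 0)) {
    pv_stop("'target_connectivity' must be non-negative and finite")
  }
  genes <- names(target_connectivity) %||%
    sprintf("g%05d", seq_along(target_connectivity))
  with_seed(seed, {
    rem <- setNames(as.numeric(target_connectivity), genes)
    rem <- rem[sample.int(length(rem))]  # random tie order
    ea <- eb <- character(0); ew <- numeric(0)
    tol <- 1e-12
    repeat {
      ord <- order(rem, decreasing = TRUE)
      if (length(ord) < 2L || rem[ord[2L]] <= tol) break
      a <- ord[1L]; b <- ord[2L]
      w <- min(rem[a], rem[b])
      ea <- c(ea, names(rem)[a]); eb <- c(eb, names(rem)[b]); ew <- c(ew, w)
      rem[a] <- rem[a] - w; rem[b] <- rem[b] - w
    }
    net <- if (length(ew)) network_edges(ea, eb, ew) else
      network_edges(character(0), character(0), numeric(0))
    attr(net, "unmet") <- rem[rem > tol]
    net
  })
}

#' Generate founder haplotypes
#'
#' Draws each locus's founder allele frequency from `freq_law` and the
#' haplotype alleles independently per locus (linkage equilibrium),
#' conditioning on both alleles being present in the sample (monomorphic
#' loci are redrawn, with bounded retries).
#'
#' @param n_haplotypes number of haplotypes (>= 2); the emulated natural
#'   founder panel has 189.
#' @param n_loci number of loci.
#' @param freq_law function of `n` returning allele frequencies; default
#'   `Beta(0.2, 0.2)`, a U-shaped law mimicking a natural site-frequency
#'   spectrum.
#' @param max_rounds bound on redraw rounds for monomorphic loci.
#' @param seed optional RNG seed.
#' @return 0/1 matrix, `n_haplotypes` x `n_loci`.
#' @export
gen_founder_haplotypes <- function(n_haplotypes = 189, n_loci = 100,
                                   freq_law = function(n) rbeta(n, 0.2, 0.2),
                                   max_rounds = 1000, seed = NULL) {
  if (n_haplotypes < 2L) pv_stop("'n_haplotypes' must be at least 2")
  with_seed(seed, {
    H <- matrix(NA_integer_, n_haplotypes, n_loci)
    todo <- seq_len(n_loci)
    for (round in seq_len(max_rounds)) {
      p <- freq_law(length(todo))
      draw <- matrix(rbinom(n_haplotypes * length(todo), 1L,
                            rep(p, each = n_haplotypes)),
                     n_haplotypes, length(todo))
      H[, todo] <- draw
      mono <- colSums(H[, todo, drop = FALSE]) %in% c(0L, n_haplotypes)
      todo <- todo[mono]
      if (!length(todo)) break
    }
    if (length(todo)) {
      pv_stop("monomorphic loci persisted after the retry bound; check 'freq_law'")
    }
    dimnames(H) <- list(sprintf("hap%03d", seq_len(n_haplotypes)),
                        sprintf("locus%04d", seq_len(n_loci)))
    H
  })
}

#' Generate a complete synthetic study
#'
#' One call produces every input of the pipeline with a shared causal
#' ground truth: the pooled count matrix (ancestral + evolved samples),
#' individual-level ancestral panels, a tissue profile whose expression
#' breadth is linear in the pleiotropy latent
#' (`tau = clamp(0.5 - 0.2 Pl)`), a network whose connectivity is
#' `exp(0.5 Pl)`, and the truth table itself. With `dir` set, all tables
#' are also written as TSV.
#'
#' @inheritParams gen_causal_truth
#' @inheritParams gen_counts_from_truth
#' @param n_populations,n_replicates,n_ancestral study layout (defaults
#'   10 x 3 evolved + 5 ancestral).
#' @param panel_size,n_panels ancestral individual panels (default 2
#'   panels of 20).
#' @param n_tissues tissue count of the generated profile (default 20).
#' @param dir optional output directory for TSV files.
#' @param seed RNG seed for the whole study (default 1).
#' @return List with `truth`, `design`, `counts`, `panels` (list),
#'   `tissues`, `network`, and the generator settings.
#' @export
simulate_study <- function(n_genes = 2000, model = "III",
                           coefficients = list(a = -0.5, b = -0.4, c = 0.3),
                           noise_sd = 1, n_populations = 10,
                           n_replicates = 3, n_ancestral = 5,
                           panel_size = 20, n_panels = 2, n_tissues = 20,
                           bcv2_center = 0.09, lfc_mean = 1,
                           lfc_sd_scale = 1, dir = NULL, seed = 1) {
  with_seed(seed, {
    truth <- gen_causal_truth(model, n_genes, coefficients, noise_sd)
    design <- study_design(n_populations, n_replicates, n_ancestral)
    mean_expression <- exp(rnorm(n_genes, log(100), 1.25))
    counts <- gen_counts_from_truth(truth, design, mean_expression,
                                    bcv2_center, lfc_mean, lfc_sd_scale)
    panels <- lapply(seq_len(n_panels), function(i) {
      gen_individual_panel(truth, panel_size, mean_expression,
                           bcv2_center, panel_id = i)
    })
    tau_target <- setNames(pmin(pmax(0.5 - 0.2 * truth$Pl, 0), 1),
                           truth$gene_id)
    tissues <- gen_tissue_profile(tau_target, n_tissues)
    network <- gen_network(setNames(exp(0.5 * truth$Pl), truth$gene_id))
    out <- list(truth = truth, design = design, counts = counts,
                panels = panels, tissues = tissues, network = network,
                settings = list(model = model, coefficients = coefficients,
                                noise_sd = noise_sd, seed = seed,
                                bcv2_center = bcv2_center,
                                lfc_mean = lfc_mean,
                                lfc_sd_scale = lfc_sd_scale))
    if (!is.null(dir)) {
      dir.create(dir, showWarnings = FALSE, recursive = TRUE)
      write_count_matrix(counts, file.path(dir, "counts.tsv"),
                         design = design,
                         design_path = file.path(dir, "design.tsv"),
                         seed = seed)
      for (i in seq_along(panels)) {
        write_count_matrix(panels[[i]],
                           file.path(dir, sprintf("panel%d.tsv", i)),
                           seed = seed)
      }
      write_tissue_profile(tissues, file.path(dir, "tissues.tsv"), seed = seed)
      write_network(network, file.path(dir, "network.tsv"), seed = seed)
      pv_write_tsv(truth, file.path(dir, "truth.tsv"), seed = seed)
    }
    out
  })
}
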