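# Shared fixtures: small count matrices and designs built in code.

toy_counts <- function(n_genes = 3, n_samples = 4, seed = 1, lambda = 50) {
  set.seed(seed)
  m <- matrix(rpois(n_genes * n_samples, lambda), n_genes, n_samples,
              dimnames = list(paste0("g", seq_len(n_genes)),
                              paste0("s", seq_len(n_samples))))
  count_matrix(m)
}

# NB count matrix for a two-group contrast: `anc` ancestral + `evo` evolved
# samples of one population, gene means `mu`, per-gene log2 shift `lfc`
contrast_counts <- function(n_genes, mu = 500, phi = 0.05, lfc = 0,
                            anc = 5, evo = 3, seed = 1) {
  set.seed(seed)
  mu <- rep_len(mu, n_genes); lfc <- rep_len(lfc, n_genes)
  ya <- sapply(seq_len(anc), function(i) rnbinom(n_genes, mu = mu, size = 1 / phi))
  ye <- sapply(seq_len(evo), function(i)
    rnbinom(n_genes, mu = mu * 2^lfc, size = 1 / phi))
  m <- cbind(ya, ye)
  dimnames(m) <- list(sprintf("g%04d", seq_len(n_genes)),
                      c(sprintf("anc_r%d", seq_len(anc)),
                        sprintf("evo_p01_r%d", seq_len(evo))))
  list(counts = count_matrix(m),
       design = sample_design(data.frame(
         sample_id = colnames(m),
         role = rep(c("ancestral", "evolved"), c(anc, evo)),
         population_id = rep(c(0L, 1L), c(anc, evo)),
         replicate_id = c(seq_len(anc), seq_len(evo)))))
}
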