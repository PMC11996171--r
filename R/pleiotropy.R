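# Two proxies of gene pleiotropy: expression breadth across tissues
# (1 - tau, where tau is the tissue-specificity index) and connectivity in
# a regulatory network (sum of incident adjacency weights).

#' Tissue-specificity index tau
#'
#' For a gene with expression `x_i` across `N >= 2` tissues,
#' `tau = sum_i (1 - x_i / max(x)) / (N - 1)`. It equals 1 for a gene
#' expressed in a single tissue and 0 for a gene expressed uniformly, and
#' is invariant to rescaling the profile. `1 - tau` is the expression
#' breadth used as a pleiotropy proxy.
#'
#' @param profile a [tissue_profile()].
#' @return Named numeric vector of tau values in `[0, 1]`; all-zero
#'   (unscorable) genes are `NA`.
#' @examples
#' p <- tissue_profile(matrix(c(1, 0, 0, 5, 5, 5), 2, 3, byrow = TRUE,
#'        dimnames = list(c("single", "uniform"), c("t1", "t2", "t3"))))
#' tau(p)  # 1 and 0
#' @export
tau <- function(profile) {
  if (!inherits(profile, "tissue_profile")) profile <- tissue_profile(profile)
  x <- unclass(profile)
  N <- ncol(x)
  xmax <- apply(x, 1L, max)
  out <- rowSums(1 - x / xmax) / (N - 1L)
  out[xmax == 0] <- NA_real_
  names(out) <- rownames(x)
  out
}

#' Network connectivity of genes
#'
#' The sum of adjacency weights of edges incident to each gene
#' (self-loops are already excluded by [network_edges()]). Genes absent
#' from the node set score 0 and are flagged.
#'
#' @param net a [network_edges()] edge list.
#' @param genes optional gene ids to score; defaults to the node set.
#' @return Named numeric vector of connectivities, with attribute
#'   `flagged_absent` listing requested genes absent from the network.
#' @export
connectivity <- function(net, genes = NULL) {
  nodes <- unique(c(net$gene_a, net$gene_b))
  if (is.null(genes)) genes <- sort(nodes)
  w <- tapply(c(net$weight, net$weight), c(net$gene_a, net$gene_b), sum)
  out <- setNames(as.numeric(w[genes]), genes)
  absent <- !(genes %in% nodes)
  out[is.na(out)] <- 0
  attr(out, "flagged_absent") <- genes[absent]
  out
}

#' Per-gene pleiotropy table
#'
#' Combines the two proxies over a gene set: `tau`, `pleiotropy_tissue =
#' 1 - tau`, `connectivity`, plus standardized versions (mean 0, SD 1 over
#' scored genes). Genes missing from either source are `NA` in that
#' column and excluded pairwise downstream.
#'
#' @param tissues optional [tissue_profile()].
#' @param network optional [network_edges()].
#' @param genes gene ids to score (default: union of sources).
#' @return A `pleiotropy_table` data frame.
#' @export
pleiotropy_table <- function(tissues = NULL, network = NULL, genes = NULL) {
  if (is.null(tissues) && is.null(network)) {
    pv_stop("provide a tissue profile and/or a network")
  }
  if (is.null(genes)) {
    genes <- unique(c(if (!is.null(tissues)) rownames(tissues),
                      if (!is.null(network)) unique(c(network$gene_a, network$gene_b))))
  }
  tv <- rep(NA_real_, length(genes))
  if (!is.null(tissues)) {
    tt <- tau(tissues)
    tv <- as.numeric(tt[match(genes, names(tt))])
  }
  cv <- rep(NA_real_, length(genes))
  if (!is.null(network)) {
    cc <- connectivity(network, genes = genes)
    cv <- as.numeric(cc)
  }
  std <- function(x) (x - mean(x, na.rm = TRUE)) / sd(x, na.rm = TRUE)
  out <- data.frame(gene_id = genes, tau = tv, pleiotropy_tissue = 1 - tv,
                    connectivity = cv,
                    pleiotropy_tissue_std = std(1 - tv),
                    connectivity_std = std(cv),
                    stringsAsFactors = FALSE)
  class(out) <- c("pleiotropy_table", "data.frame")
  out
}

#' Concordance of the two pleiotropy proxies
#'
#' Spearman rank correlation (average ranks for ties) between expression
#' breadth (1 - tau) and network connectivity over genes scored on both;
#' a diagnostic of whether the proxies capture a shared signal.
#'
#' @param pt a [pleiotropy_table()] with at least 3 genes scored on both.
#' @return List with `rho`, `p_value`, `n`.
#' @export
pleiotropy_concordance <- function(pt) {
  ok <- !is.na(pt$pleiotropy_tissue) & !is.na(pt$connectivity)
  if (sum(ok) < 3L) pv_stop("need >= 3 genes scored on both proxies")
  x <- pt$pleiotropy_tissue[ok]; y <- pt$connectivity[ok]
  if (sd(x) == 0 || sd(y) == 0) {
    warning("constant proxy column; concordance undefined")
    return(list(rho = NA_real_, p_value = NA_real_, n = sum(ok)))
  }
  ct <- suppressWarnings(cor.test(x, y, method = "spearman", exact = FALSE))
  list(rho = unname(ct$estimate), p_value = ct$p.value, n = sum(ok))
}
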