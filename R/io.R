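# TSV readers/writers for every table the pipeline touches. The canonical
# dialect is tab-separated with a header row and '.' decimals; lines
# starting with '#' carry provenance metadata (version, seed, config) and
# are skipped on read. Files ending in .gz are compressed transparently.

pv_read_tsv <- function(path) {
  if (!file.exists(path)) pv_stop(sprintf("file not found: %s", path))
  read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
             check.names = FALSE, stringsAsFactors = FALSE)
}

pv_write_tsv <- function(x, path, seed = NULL, config = NULL,
                         row_label = NULL) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  hdr <- sprintf("# parallevo %s", as.character(packageVersion("parallevo")))
  if (!is.null(seed)) hdr <- c(hdr, sprintf("# seed=%s", format(seed)))
  if (!is.null(config)) {
    kv <- paste(names(config), vapply(config, format, ""), sep = "=")
    hdr <- c(hdr, paste("#", paste(kv, collapse = " ")))
  }
  writeLines(hdr, con)
  if (!is.null(row_label)) {
    x <- cbind(stats::setNames(data.frame(rownames(x), stringsAsFactors = FALSE),
                               row_label),
               as.data.frame(x, stringsAsFactors = FALSE))
  }
  write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE)
  invisible(path)
}

#' Read a count table and its sample design
#'
#' The count file is a TSV with gene ids in the first column and one column
#' per sample; the design file has columns `sample_id`, `role`,
#' `population_id`, `replicate_id`. The two files are cross-referenced and
#' validation failures name the offending gene or sample.
#'
#' @param path path to the count TSV (optionally gzipped).
#' @param design_path path to the design TSV.
#' @return A list with elements `counts` (a [count_matrix()]) and `design`
#'   (a [sample_design()]).
#' @export
read_count_matrix <- function(path, design_path) {
  tab <- pv_read_tsv(path)
  if (ncol(tab) < 2L) pv_stop("count table needs a gene column plus >=1 sample")
  genes <- as.character(tab[[1L]])
  m <- as.matrix(tab[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  dimnames(m) <- list(genes, colnames(tab)[-1L])
  cm <- count_matrix(m)
  design <- sample_design(pv_read_tsv(design_path))
  validate_study(cm, design)
  list(counts = cm, design = design)
}

#' Write a count matrix (and optionally its design) to TSV
#'
#' @param m a [count_matrix()].
#' @param path output TSV path (`.gz` for compression).
#' @param design optional [sample_design()] written alongside.
#' @param design_path path for the design TSV (required with `design`).
#' @param seed,config optional provenance recorded in the commented header.
#' @return `path`, invisibly.
#' @export
write_count_matrix <- function(m, path, design = NULL, design_path = NULL,
                               seed = NULL, config = NULL) {
  pv_write_tsv(m$counts, path, seed = seed, config = config,
               row_label = "gene_id")
  if (!is.null(design)) {
    if (is.null(design_path)) pv_stop("'design_path' required when writing a design")
    pv_write_tsv(as.data.frame(design), design_path, seed = seed)
  }
  invisible(path)
}

#' Read a gene x tissue expression profile
#'
#' @param path TSV with gene ids in the first column and one numeric column
#'   per tissue; at least two tissues are required (the tissue-specificity
#'   index divides by N - 1).
#' @return A [tissue_profile()]; genes with an all-zero row are flagged in
#'   its `unscorable` attribute rather than dropped.
#' @export
read_tissue_profile <- function(path) {
  tab <- pv_read_tsv(path)
  if (ncol(tab) < 3L) pv_stop("a tissue profile needs at least 2 tissues")
  m <- as.matrix(tab[, -1L, drop = FALSE])
  if (!is.numeric(m)) pv_stop("tissue expression must be numeric")
  dimnames(m) <- list(as.character(tab[[1L]]), colnames(tab)[-1L])
  tissue_profile(m)
}

#' Write a tissue profile to TSV
#' @param profile a [tissue_profile()]; @param path output path.
#' @param seed,config optional provenance header fields.
#' @return `path`, invisibly.
#' @export
write_tissue_profile <- function(profile, path, seed = NULL, config = NULL) {
  pv_write_tsv(unclass(profile), path, seed = seed, config = config,
               row_label = "gene_id")
}

#' Read a network edge list
#'
#' @param path TSV with two gene columns and a non-negative weight column.
#' @return A [network_edges()] data frame (undirected; self-loops dropped
#'   with a warning, duplicate pairs merged by summing).
#' @export
read_network <- function(path) {
  tab <- pv_read_tsv(path)
  if (ncol(tab) < 3L) pv_stop("network file needs gene_a, gene_b, weight columns")
  network_edges(tab[[1L]], tab[[2L]], tab[[3L]])
}

#' Write a network edge list to TSV
#' @param net a [network_edges()]; @param path output path.
#' @param seed,config optional provenance header fields.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path, seed = NULL, config = NULL) {
  pv_write_tsv(as.data.frame(net), path, seed = seed, config = config)
}
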