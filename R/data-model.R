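#' Count matrix container
#'
#' A gene x sample table of non-negative integer RNA-seq counts together
#' with per-sample library sizes. Library sizes default to column sums and
#' may only be overridden explicitly.
#'
#' @param counts numeric matrix of non-negative whole numbers with unique,
#'   non-empty row names (gene ids) and column names (sample ids).
#' @param lib_size optional named numeric vector of per-sample library
#'   sizes; defaults to the column sums of `counts`.
#' @return An object of class `count_matrix`: a list with elements
#'   `counts` and `lib_size`.
#' @examples
#' m <- matrix(rpois(12, 50), 3, 4,
#'             dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
#' cm <- count_matrix(m)
#' cm$lib_size
#' @export
count_matrix <- function(counts, lib_size = NULL) {
  if (!is.matrix(counts) || !is.numeric(counts)) {
    pv_stop("'counts' must be a numeric matrix")
  }
  gn <- rownames(counts); sn <- colnames(counts)
  if (is.null(gn) || is.null(sn) || any(!nzchar(gn)) || any(!nzchar(sn))) {
    pv_stop("'counts' must have non-empty gene (row) and sample (column) names")
  }
  if (anyDuplicated(gn)) {
    pv_stop(sprintf("duplicate gene id: %s", gn[duplicated(gn)][1L]))
  }
  if (anyDuplicated(sn)) {
    pv_stop(sprintf("duplicate sample id: %s", sn[duplicated(sn)][1L]))
  }
  if (anyNA(counts) || any(!is.finite(counts))) {
    pv_stop("counts must be finite and non-missing")
  }
  bad <- which(counts < 0, arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    pv_stop(sprintf("negative count for gene '%s' in sample '%s'",
                    gn[bad[1L, 1L]], sn[bad[1L, 2L]]))
  }
  if (any(abs(counts - round(counts)) > 1e-8)) {
    pv_stop("counts must be whole numbers")
  }
  if (is.null(lib_size)) {
    lib_size <- colSums(counts)
  } else {
    if (is.null(names(lib_size))) names(lib_size) <- sn
    if (!identical(sort(names(lib_size)), sort(sn))) {
      pv_stop("'lib_size' names must match the sample ids")
    }
    lib_size <- lib_size[sn]
    if (any(!is.finite(lib_size)) || any(lib_size <= 0)) {
      pv_stop("library sizes must be positive and finite")
    }
  }
  structure(list(counts = counts, lib_size = lib_size), class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d genes x %d samples (median library size %s)\n",
              nrow(x$counts), ncol(x$counts),
              format(stats::median(x$lib_size), big.mark = ",")))
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' Subset a count matrix by genes and/or samples
#'
#' @param x a [count_matrix()].
#' @param i gene ids or indices; @param j sample ids or indices.
#' @param ... ignored.
#' @return A `count_matrix` restricted to the selection; overridden library
#'   sizes are carried over, default ones are recomputed as column sums.
#' @export
`[.count_matrix` <- function(x, i, j, ...) {
  counts <- x$counts
  if (!missing(i)) counts <- counts[i, , drop = FALSE]
  if (!missing(j)) counts <- counts[, j, drop = FALSE]
  lib <- x$lib_size[colnames(counts)]
  # keep original library sizes: subsetting genes must not change depth
  count_matrix(counts, lib_size = lib)
}

#' Sample design table
#'
#' Maps every sample to its role (ancestral or evolved), its population id
#' (0 for the ancestral pool, 1..P for evolved populations) and its
#' biological-replicate id.
#'
#' @param x data frame with columns `sample_id`, `role`, `population_id`,
#'   `replicate_id`.
#' @return A validated `sample_design` data frame.
#' @export
sample_design <- function(x) {
  need <- c("sample_id", "role", "population_id", "replicate_id")
  if (!is.data.frame(x) || !all(need %in% names(x))) {
    pv_stop(sprintf("design must have columns %s", paste(need, collapse = ", ")))
  }
  x <- as.data.frame(x)[need]
  x$sample_id <- as.character(x$sample_id)
  x$role <- as.character(x$role)
  x$population_id <- as.integer(x$population_id)
  x$replicate_id <- as.integer(x$replicate_id)
  if (anyDuplicated(x$sample_id)) {
    pv_stop(sprintf("duplicate sample id in design: %s",
                    x$sample_id[duplicated(x$sample_id)][1L]))
  }
  if (!all(x$role %in% c("ancestral", "evolved"))) {
    pv_stop("role must be 'ancestral' or 'evolved'")
  }
  if (anyNA(x$population_id) || anyNA(x$replicate_id)) {
    pv_stop("population_id and replicate_id must be integers")
  }
  if (any(x$population_id[x$role == "ancestral"] != 0L)) {
    pv_stop("ancestral samples must have population_id 0")
  }
  if (any(x$population_id[x$role == "evolved"] < 1L)) {
    pv_stop("evolved samples must have population_id >= 1")
  }
  if (sum(x$role == "ancestral") < 1L) {
    pv_stop("design needs at least one ancestral sample")
  }
  if (sum(x$role == "evolved") < 1L) {
    pv_stop("design needs at least one evolved sample")
  }
  class(x) <- c("sample_design", "data.frame")
  x
}

#' Check that a count matrix and a design describe the same samples
#'
#' @param m a [count_matrix()]; @param design a [sample_design()].
#' @return `TRUE`, invisibly; otherwise a validation error naming the
#'   offending sample.
#' @export
validate_study <- function(m, design) {
  sn <- colnames(m$counts)
  miss <- setdiff(design$sample_id, sn)
  if (length(miss)) {
    pv_stop(sprintf("design sample '%s' not present in the count matrix", miss[1L]))
  }
  miss <- setdiff(sn, design$sample_id)
  if (length(miss)) {
    pv_stop(sprintf("count-matrix sample '%s' not present in the design", miss[1L]))
  }
  invisible(TRUE)
}

#' Gene x tissue expression profile
#'
#' @param expression numeric non-negative matrix, genes in rows, at least
#'   two tissue columns. Genes whose whole row is zero cannot be scored for
#'   tissue specificity; they are kept but flagged.
#' @return A `tissue_profile`: the matrix with an `unscorable` attribute
#'   (named logical vector).
#' @export
tissue_profile <- function(expression) {
  if (!is.matrix(expression) || !is.numeric(expression)) {
    pv_stop("'expression' must be a numeric matrix")
  }
  if (ncol(expression) < 2L) {
    pv_stop("a tissue profile needs at least 2 tissues")
  }
  if (is.null(rownames(expression)) || is.null(colnames(expression))) {
    pv_stop("tissue profile needs gene row names and tissue column names")
  }
  if (anyDuplicated(rownames(expression))) {
    pv_stop("duplicate gene id in tissue profile")
  }
  if (anyNA(expression) || any(expression < 0)) {
    pv_stop("tissue expression must be non-negative and non-missing")
  }
  unscorable <- apply(expression, 1L, function(r) all(r == 0))
  structure(expression, class = c("tissue_profile", "matrix", "array"),
            unscorable = unscorable)
}

#' Undirected weighted network edge list
#'
#' Edges are interpreted as undirected. Self-loops are dropped with a
#' warning (they never count toward connectivity); duplicated pairs,
#' including reversed ones, are merged by summing their weights.
#'
#' @param gene_a,gene_b character vectors of gene ids.
#' @param weight non-negative numeric adjacency weights.
#' @return A `network_edges` data frame with one row per unordered pair.
#' @export
network_edges <- function(gene_a, gene_b, weight) {
  gene_a <- as.character(gene_a); gene_b <- as.character(gene_b)
  weight <- as.numeric(weight)
  if (length(gene_a) != length(gene_b) || length(gene_a) != length(weight)) {
    pv_stop("edge columns must have equal length")
  }
  if (anyNA(weight) || any(!is.finite(weight)) || any(weight < 0)) {
    pv_stop("edge weights must be non-negative and finite")
  }
  loop <- gene_a == gene_b
  if (any(loop)) {
    warning(sprintf("dropping %d self-loop(s); self-loops do not count toward connectivity",
                    sum(loop)))
    gene_a <- gene_a[!loop]; gene_b <- gene_b[!loop]; weight <- weight[!loop]
  }
  a <- pmin(gene_a, gene_b); b <- pmax(gene_a, gene_b)
  key <- paste(a, b, sep = "\r")
  w <- tapply(weight, key, sum)
  parts <- strsplit(names(w), "\r", fixed = TRUE)
  out <- data.frame(gene_a = vapply(parts, `[`, "", 1L),
                    gene_b = vapply(parts, `[`, "", 2L),
                    weight = as.numeric(w),
                    row.names = NULL, stringsAsFactors = FALSE)
  out <- out[order(out$gene_a, out$gene_b), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("network_edges", "data.frame")
  out
}
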