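#' Library-size normalize to log(CPM + 1)
#'
#' Scales each cell to counts per million and applies `log(x + 1)`. The log
#' base is configurable because the downstream statistics (ranks, Spearman and
#' Pearson correlations) are invariant to it; natural log is the default.
#' All-zero cells stay all-zero and trigger a warning.
#'
#' @param ds An [expression_dataset()].
#' @param log_base Positive log base; `exp(1)` by default.
#' @return A `normalized_view`: list with `values` (sparse genes x cells matrix
#'   of log-CPM values), `dataset_id`, `log_base`, and `cells` metadata carried
#'   over from the parent dataset.
#' @export
normalize_log_cpm <- function(ds, log_base = exp(1)) {
  stopifnot(inherits(ds, "expression_dataset"), log_base > 0)
  totals <- Matrix::colSums(ds$counts)
  zero <- totals == 0
  if (any(zero)) {
    warning(sprintf("%d all-zero cell(s) left as zeros", sum(zero)))
    totals[zero] <- 1
  }
  cpm <- ds$counts %*% Matrix::Diagonal(x = 1e6 / totals)
  cpm@x <- log1p(cpm@x) / log(log_base)
  dimnames(cpm) <- dimnames(ds$counts)
  structure(list(values = cpm, dataset_id = ds$dataset_id,
                 log_base = log_base, cells = ds$cells),
            class = "normalized_view")
}

#' @export
print.normalized_view <- function(x, ...) {
  cat(sprintf("<normalized_view '%s'>: %d genes x %d cells, log base %.4g\n",
              x$dataset_id, nrow(x$values), ncol(x$values), x$log_base))
  invisible(x)
}

#' Per-cluster expression centroids
#'
#' Arithmetic mean of the normalized expression values over the cells of each
#' cluster, in log-CPM space. Centroids are the reference profiles used for
#' spatial cell calling and coordinated-expression analysis.
#'
#' @param nv A `normalized_view`.
#' @return Dense clusters x genes matrix with cluster row names.
#' @export
compute_centroids <- function(nv) {
  stopifnot(inherits(nv, "normalized_view"))
  cl <- nv$cells$cluster
  lev <- sort(unique(cl))
  # indicator matrix (cells x clusters) scaled to cluster means
  ind <- Matrix::sparseMatrix(i = seq_along(cl), j = match(cl, lev),
                              x = 1 / tabulate(match(cl, lev))[match(cl, lev)],
                              dims = c(length(cl), length(lev)))
  cent <- Matrix::t(nv$values %*% ind)
  cent <- as.matrix(cent)
  dimnames(cent) <- list(lev, rownames(nv$values))
  cent
}

#' Z-score expression per gene across cells
#'
#' Centers and scales each gene over all cells using the sample standard
#' deviation (ddof 1). Zero-variance genes map to all-zero rows rather than
#' `NaN` so marker-score averages stay finite.
#'
#' @param nv A `normalized_view`.
#' @return Dense genes x cells matrix.
#' @export
zscore_genes <- function(nv) {
  stopifnot(inherits(nv, "normalized_view"))
  v <- as.matrix(nv$values)
  mu <- rowMeans(v)
  n <- ncol(v)
  sd <- sqrt(pmax(0, (rowSums(v^2) - n * mu^2) / (n - 1)))
  z <- (v - mu) / ifelse(sd > 0, sd, 1)
  z[sd == 0, ] <- 0
  z
}

#' Select highly variable genes jointly across datasets
#'
#' Genes are first intersected across the contributing datasets. Within each
#' dataset, genes are ordered by mean normalized expression and cut into
#' `n_bins` equal-size bins; a gene is flagged when its variance exceeds the
#' bin's `quantile` variance quantile. The returned set is the intersection of
#' the per-dataset flags, ordered by gene id, with the selection parameters
#' recorded as provenance.
#'
#' @param views List of `normalized_view` objects (>= 1).
#' @param n_bins Number of mean-expression bins (default 10).
#' @param quantile Variance quantile within bins (default 0.75).
#' @return An `hvg_set`: list with `gene_ids` and `provenance`.
#' @export
select_hvgs <- function(views, n_bins = 10L, quantile = 0.75) {
  stopifnot(length(views) >= 1L, n_bins >= 1L, quantile >= 0, quantile < 1)
  shared <- Reduce(intersect, lapply(views, function(v) rownames(v$values)))
  if (!length(shared)) abort_atlasrep("select_hvgs(): empty gene intersection")
  flagged <- lapply(views, function(v) {
    m <- v$values[shared, , drop = FALSE]
    mu <- Matrix::rowMeans(m)
    n <- ncol(m)
    va <- (Matrix::rowSums(m^2) - n * mu^2) / (n - 1)
    bin <- dplyr::ntile(mu, n_bins)
    keep <- unlist(lapply(split(seq_along(va), bin), function(idx) {
      thr <- stats::quantile(va[idx], quantile, names = FALSE)
      idx[va[idx] > thr]
    }), use.names = FALSE)
    shared[sort(keep)]
  })
  sel <- sort(Reduce(intersect, flagged))
  structure(list(gene_ids = sel,
                 provenance = list(n_bins = n_bins, quantile = quantile,
                                   datasets = vapply(views, `[[`, "", "dataset_id"),
                                   n_shared = length(shared))),
            class = "hvg_set")
}

#' @export
print.hvg_set <- function(x, ...) {
  cat(sprintf("<hvg_set>: %d genes (bins=%d, quantile=%.2f, datasets: %s)\n",
              length(x$gene_ids), x$provenance$n_bins, x$provenance$quantile,
              paste(x$provenance$datasets, collapse = ", ")))
  invisible(x)
}

#' Write / read a highly-variable-gene set as TSV
#'
#' One `gene_id` column; selection parameters are stored in `#`-prefixed
#' header comment lines.
#'
#' @param hvg An `hvg_set`.
#' @param path TSV path.
#' @return `write_hvgs()` returns the path invisibly; `read_hvgs()` an
#'   `hvg_set`.
#' @export
write_hvgs <- function(hvg, path) {
  header <- sprintf("# hvg_set n_bins=%d quantile=%g datasets=%s",
                    hvg$provenance$n_bins, hvg$provenance$quantile,
                    paste(hvg$provenance$datasets, collapse = ","))
  writeLines(c(header, "gene_id", hvg$gene_ids), path)
  invisible(path)
}

#' @rdname write_hvgs
#' @export
read_hvgs <- function(path) {
  lines <- readLines(path)
  header <- lines[startsWith(lines, "#")]
  genes <- setdiff(lines[!startsWith(lines, "#")], "gene_id")
  prov <- list(raw_header = header)
  structure(list(gene_ids = genes, provenance = prov), class = "hvg_set")
}
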