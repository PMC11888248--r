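#' Construct an expression dataset
#'
#' Bundles a sparse genes-by-cells count matrix with per-cell metadata. This is
#' the atlas container used throughout the package: both reference atlases and
#' spatial panels are `expression_dataset` objects.
#'
#' @param dataset_id Character label identifying the dataset.
#' @param counts Genes x cells matrix of nonnegative integer counts (coerced to
#'   `Matrix::dgCMatrix`). Row names are gene ids, column names cell ids; if
#'   absent they are taken from `cells`/`gene_ids`.
#' @param cells Tibble with one row per cell: `cell_id`, `cluster`, and
#'   optionally `region`, `slice`, `x`, `y` (coordinates in mm).
#' @param gene_ids Optional character vector of gene ids (defaults to
#'   `rownames(counts)`).
#' @return An object of class `expression_dataset`: a list with elements
#'   `dataset_id`, `counts`, `cells`.
#' @export
expression_dataset <- function(dataset_id, counts, cells, gene_ids = NULL) {
  counts <- methods::as(methods::as(methods::as(counts, "dMatrix"),
                                    "generalMatrix"), "CsparseMatrix")
  if (!is.null(gene_ids)) rownames(counts) <- gene_ids
  cells <- tibble::as_tibble(cells)
  if (!all(c("cell_id", "cluster") %in% names(cells))) {
    abort_atlasrep("cells metadata needs at least cell_id and cluster columns")
  }
  for (col in c("region", "slice", "x", "y")) {
    if (!col %in% names(cells)) cells[[col]] <- NA
  }
  cells$cell_id <- as.character(cells$cell_id)
  cells$cluster <- as.character(cells$cluster)
  if (is.null(colnames(counts))) colnames(counts) <- cells$cell_id
  if (is.null(rownames(counts))) {
    abort_atlasrep("counts needs gene ids (rownames or gene_ids argument)")
  }
  ds <- structure(list(dataset_id = dataset_id, counts = counts, cells = cells),
                  class = "expression_dataset")
  validate_dataset(ds)
  ds
}

validate_dataset <- function(ds) {
  counts <- ds$counts
  cells <- ds$cells
  if (ncol(counts) != nrow(cells)) {
    abort_atlasrep("dimension mismatch: %d matrix columns vs %d cell rows",
                   ncol(counts), nrow(cells))
  }
  if (anyDuplicated(rownames(counts))) {
    dup <- rownames(counts)[duplicated(rownames(counts))][1]
    abort_atlasrep("duplicate gene id: %s", dup)
  }
  if (anyDuplicated(cells$cell_id)) {
    dup <- cells$cell_id[duplicated(cells$cell_id)][1]
    abort_atlasrep("duplicate cell id: %s", dup)
  }
  x <- counts@x
  if (length(x)) {
    bad <- which(!is.finite(x) | x < 0 | x != round(x))
    if (length(bad)) {
      abort_atlasrep("counts must be finite nonnegative integers (offending stored entry %d, value %g)",
                     bad[1], x[bad[1]])
    }
  }
  if (any(is.na(cells$cluster))) abort_atlasrep("every cell needs a cluster label")
  invisible(ds)
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat(sprintf("<expression_dataset '%s'>: %d genes x %d cells, %d clusters\n",
              x$dataset_id, nrow(x$counts), ncol(x$counts),
              dplyr::n_distinct(x$cells$cluster)))
  if (!all(is.na(x$cells$region))) {
    cat(sprintf("  regions: %s\n",
                paste(sort(unique(stats::na.omit(x$cells$region))), collapse = ", ")))
  }
  invisible(x)
}

#' Gene ids, cell ids and cluster labels of a dataset
#' @param ds An `expression_dataset`.
#' @return Character vector.
#' @export
gene_ids <- function(ds) rownames(ds$counts)

#' @rdname gene_ids
#' @export
cell_ids <- function(ds) ds$cells$cell_id

#' @rdname gene_ids
#' @export
cluster_labels <- function(ds) sort(unique(ds$cells$cluster))

#' Read an expression dataset from Matrix Market + TSV sidecars
#'
#' Expects `matrix_path` in Matrix Market coordinate format (genes as rows,
#' 1-based indices per the standard), `genes_path` a TSV with a `gene_id`
#' column, and `cells_path` a TSV with `cell_id`, `cluster` and optionally
#' `region`, `slice`, `x`, `y`. Metadata is joined to matrix columns by
#' position.
#'
#' @param matrix_path,genes_path,cells_path File paths.
#' @param dataset_id Dataset label (defaults to the matrix file stem).
#' @return An [expression_dataset()].
#' @export
read_dataset <- function(matrix_path, genes_path, cells_path,
                         dataset_id = sub("\\.mtx$", "", basename(matrix_path))) {
  m <- Matrix::readMM(matrix_path)
  genes <- readr::read_tsv(genes_path, show_col_types = FALSE, comment = "#")
  cells <- readr::read_tsv(cells_path, show_col_types = FALSE, comment = "#")
  if (nrow(genes) != nrow(m)) {
    abort_atlasrep("dimension mismatch: %d matrix rows vs %d gene rows (%s)",
                   nrow(m), nrow(genes), genes_path)
  }
  if (nrow(cells) != ncol(m)) {
    abort_atlasrep("dimension mismatch: %d matrix columns vs %d cell rows (%s)",
                   ncol(m), nrow(cells), cells_path)
  }
  expression_dataset(dataset_id, m, cells, gene_ids = genes$gene_id)
}

#' Write an expression dataset as Matrix Market + TSV sidecars
#'
#' Inverse of [read_dataset()]; writes `<stem>.mtx`, `<stem>_genes.tsv`,
#' `<stem>_cells.tsv` under `dir`.
#'
#' @param ds An `expression_dataset`.
#' @param dir Output directory (created if needed).
#' @param stem File stem; defaults to the dataset id.
#' @return Invisibly, the three paths written.
#' @export
write_dataset <- function(ds, dir, stem = ds$dataset_id) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, paste0(stem, c(".mtx", "_genes.tsv", "_cells.tsv")))
  Matrix::writeMM(ds$counts, paths[1])
  readr::write_tsv(tibble::tibble(gene_id = gene_ids(ds)), paths[2])
  readr::write_tsv(ds$cells, paths[3])
  invisible(paths)
}

#' Read a region-alignment map
#'
#' Two-column TSV (`source`, `aligned`) mapping dataset-specific dissection
#' region labels onto a common region vocabulary (many-to-one).
#'
#' @param path TSV path.
#' @return Tibble with columns `source`, `aligned`.
#' @export
read_region_map <- function(path) {
  rm <- readr::read_tsv(path, show_col_types = FALSE, comment = "#")
  stopifnot(all(c("source", "aligned") %in% names(rm)))
  if (anyDuplicated(rm$source)) abort_atlasrep("region map has duplicate source labels")
  rm
}

#' Align dissection-region labels through a region map
#'
#' Relabels each cell's `region` through the map. Labels listed in
#' `pass_through` are kept as-is; any other unmapped label is an error. Cells
#' whose region is `NA` stay `NA` and are excluded from region-level
#' statistics downstream.
#'
#' @param ds An `expression_dataset`.
#' @param region_map Tibble with columns `source`, `aligned`
#'   (see [read_region_map()]).
#' @param pass_through Character vector of labels to keep unchanged.
#' @return The dataset with relabelled regions.
#' @export
align_regions <- function(ds, region_map, pass_through = character()) {
  reg <- ds$cells$region
  present <- unique(stats::na.omit(reg))
  unmapped <- setdiff(present, c(region_map$source, pass_through))
  if (length(unmapped)) {
    abort_atlasrep("unmapped region label(s): %s", paste(unmapped, collapse = ", "))
  }
  lookup <- stats::setNames(region_map$aligned, region_map$source)
  hit <- !is.na(reg) & reg %in% names(lookup)
  reg[hit] <- unname(lookup[reg[hit]])
  ds$cells$region <- reg
  ds
}
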