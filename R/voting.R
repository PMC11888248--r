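#' Rank-normalize cells over a highly-variable-gene set
#'
#' Represents each cell by the within-cell mid-ranks of its HVG expression,
#' mean-centered and scaled to unit Euclidean norm. The inner product of two
#' such vectors equals the Spearman correlation of the two cells' HVG
#' expression exactly, so the cell-cell similarity network weighted by
#' Spearman correlation reduces to plain matrix products. Absent genes (zero
#' counts) tie at the shared minimum mid-rank. Cells with constant expression
#' across the HVGs are degenerate: they get all-zero vectors and are excluded
#' from downstream AUROCs.
#'
#' @param nv A [normalize_log_cpm()] view.
#' @param hvg An `hvg_set` or character vector of gene ids (>= 3 present).
#' @return A `rank_normalized_cells` object: list with `vectors` (cells x HVG
#'   dense matrix), `hvg` (genes used), `dataset_id`, `cells` metadata, and
#'   `degenerate` (logical per cell).
#' @export
rank_normalize <- function(nv, hvg) {
  genes <- if (inherits(hvg, "hvg_set")) hvg$gene_ids else as.character(hvg)
  genes <- intersect(genes, rownames(nv$values))
  if (length(genes) < 3L) {
    abort_atlasrep("rank_normalize(): fewer than 3 HVGs present (%d)", length(genes))
  }
  m <- as.matrix(nv$values[genes, , drop = FALSE])
  v <- apply(m, 2, midrank)           # genes x cells mid-ranks within cell
  v <- sweep(v, 2, colMeans(v))
  norms <- sqrt(colSums(v^2))
  degenerate <- norms == 0
  norms[degenerate] <- 1
  v <- sweep(v, 2, norms, "/")
  v[, degenerate] <- 0
  structure(list(vectors = t(v), hvg = genes, dataset_id = nv$dataset_id,
                 cells = nv$cells, degenerate = degenerate),
            class = "rank_normalized_cells")
}

#' @export
print.rank_normalized_cells <- function(x, ...) {
  cat(sprintf("<rank_normalized_cells '%s'>: %d cells x %d HVGs (%d degenerate)\n",
              x$dataset_id, nrow(x$vectors), length(x$hvg), sum(x$degenerate)))
  invisible(x)
}

#' Neighbor votes from reference clusters into target cells
#'
#' The vote of reference cluster `c` for target cell `j` is the mean Spearman
#' correlation between cell `j` and the cells of cluster `c`. Because the
#' rank-normalized vectors turn Spearman correlations into inner products,
#' this equals the inner product of cell `j` with the cluster's centroid of
#' normalized vectors — the fast formulation, which is an exact identity, not
#' an approximation.
#'
#' @param reference A `rank_normalized_cells` with cluster labels in its
#'   metadata.
#' @param target A `rank_normalized_cells` over the same HVG list.
#' @return Target-cells x reference-clusters matrix of votes in `[-1, 1]`.
#' @export
nv_votes <- function(reference, target) {
  if (!identical(reference$hvg, target$hvg)) {
    abort_atlasrep("nv_votes(): HVG lists differ between reference and target")
  }
  cent <- cluster_rank_centroids(reference)
  v <- target$vectors %*% t(cent)
  rownames(v) <- target$cells$cell_id
  v
}

# clusters x HVG matrix of mean rank-normalized vectors.
cluster_rank_centroids <- function(rnc) {
  cl <- rnc$cells$cluster
  lev <- sort(unique(cl))
  cent <- t(vapply(lev, function(k) {
    colMeans(rnc$vectors[cl == k, , drop = FALSE])
  }, numeric(ncol(rnc$vectors))))
  rownames(cent) <- lev
  cent
}

#' Directional one-vs-all replicability AUROCs
#'
#' For every reference cluster, target cells are scored by their neighbor
#' votes and each target cluster's cells are tested for ranking above all
#' other cells of the target dataset. Degenerate (constant-expression) cells
#' are excluded. Target clusters containing all or none of the usable cells
#' are flagged `NA`.
#'
#' @param nv_ref,nv_target [normalize_log_cpm()] views of the two datasets.
#' @param hvg Shared HVG set (`hvg_set` or character vector).
#' @return An `auroc_table`: reference-clusters x target-clusters matrix with
#'   attributes `reference`, `target`, `direction`.
#' @export
one_vs_all_auroc <- function(nv_ref, nv_target, hvg) {
  ref <- rank_normalize(nv_ref, hvg)
  tgt <- rank_normalize(nv_target, hvg)
  votes <- nv_votes(ref, tgt)
  auroc_from_votes(votes, tgt, nv_ref$dataset_id, nv_target$dataset_id)
}

# Shared tail of one_vs_all_auroc / apply_pretrained.
auroc_from_votes <- function(votes, tgt, ref_id, target_id) {
  usable <- !tgt$degenerate
  if (sum(tgt$degenerate)) {
    message(sprintf("excluding %d degenerate target cell(s)", sum(tgt$degenerate)))
  }
  labels <- tgt$cells$cluster[usable]
  lev <- sort(unique(tgt$cells$cluster))
  vals <- t(apply(votes[usable, , drop = FALSE], 2, function(s) {
    auroc_grouped(s, labels)[lev]
  }))
  colnames(vals) <- lev
  new_auroc_table(vals, ref_id, target_id,
                  direction = paste(ref_id, "->", target_id))
}

new_auroc_table <- function(vals, reference, target, direction) {
  structure(vals, class = c("auroc_table", "matrix", "array"),
            reference = reference, target = target, direction = direction)
}

#' @export
print.auroc_table <- function(x, ...) {
  cat(sprintf("<auroc_table %s>: %d x %d clusters, mean %.3f\n",
              attr(x, "direction"), nrow(x), ncol(x), mean(x, na.rm = TRUE)))
  invisible(x)
}

#' Symmetric replicability AUROCs
#'
#' Element-wise mean of the two directional tables:
#' `value(c, d) = (ab(c, d) + ba(d, c)) / 2`. The symmetric table is what
#' reciprocal best hits are read from.
#'
#' @param ab `auroc_table` with direction A -> B.
#' @param ba `auroc_table` with direction B -> A.
#' @return An `auroc_table` with direction `"symmetric"`, rows = A clusters,
#'   columns = B clusters.
#' @export
symmetric_auroc <- function(ab, ba) {
  if (!identical(sort(rownames(ab)), sort(colnames(ba))) ||
      !identical(sort(colnames(ab)), sort(rownames(ba)))) {
    abort_atlasrep("symmetric_auroc(): cluster index mismatch between directions")
  }
  # orient so rows always belong to ab's reference
  if (identical(attr(ab, "reference"), attr(ba, "target"))) {
    vals <- (ab + t(ba)[rownames(ab), colnames(ab)]) / 2
  } else {
    abort_atlasrep("symmetric_auroc(): tables are not opposite directions")
  }
  new_auroc_table(vals, attr(ab, "reference"), attr(ab, "target"), "symmetric")
}

#' Tidy an AUROC table into long format
#'
#' @param x An `auroc_table`.
#' @param ... Unused.
#' @return Tibble: `reference_cluster`, `target_cluster`, `auroc`.
#' @export
tidy.auroc_table <- function(x, ...) {
  tibble::as_tibble(as.table(unclass(x)), .name_repair = "minimal") |>
    stats::setNames(c("reference_cluster", "target_cluster", "auroc")) |>
    tibble::as_tibble()
}

#' Write / read an AUROC table (TSV matrix + JSON sidecar)
#'
#' @param x An `auroc_table`.
#' @param path TSV path; the sidecar is `<path>.json`.
#' @return `write_auroc_table()` the path invisibly; `read_auroc_table()` an
#'   `auroc_table`.
#' @export
write_auroc_table <- function(x, path) {
  tab <- tibble::as_tibble(as.data.frame(unclass(x)), rownames = "cluster")
  readr::write_tsv(tab, path)
  jsonlite::write_json(list(reference = attr(x, "reference"),
                            target = attr(x, "target"),
                            direction = attr(x, "direction")),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_auroc_table
#' @export
read_auroc_table <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  m <- as.matrix(tab[, -1])
  rownames(m) <- tab$cluster
  new_auroc_table(m, meta$reference, meta$target, meta$direction)
}
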