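#' Marker catalog
#'
#' A named collection of ordered marker-gene lists, one per cluster, as
#' provided by atlas authors or planted by the synthetic generator.
#'
#' @param sets Named list of character vectors (cluster -> ordered genes).
#' @param source Label for provenance.
#' @return A `marker_catalog` object.
#' @export
marker_catalog <- function(sets, source = "unknown") {
  stopifnot(is.list(sets), !is.null(names(sets)))
  if (any(lengths(sets) == 0)) abort_atlasrep("marker catalog has an empty gene list")
  structure(list(markers = lapply(sets, as.character), source = source),
            class = "marker_catalog")
}

#' @export
print.marker_catalog <- function(x, ...) {
  cat(sprintf("<marker_catalog '%s'>: %d clusters, median %d markers\n",
              x$source, length(x$markers),
              as.integer(stats::median(lengths(x$markers)))))
  invisible(x)
}

#' @export
as_tibble.marker_catalog <- function(x, ...) {
  tibble::tibble(cluster = rep(names(x$markers), lengths(x$markers)),
                 gene = unlist(x$markers, use.names = FALSE),
                 rank = unlist(lapply(lengths(x$markers), seq_len)))
}

#' Read / write a marker catalog as TSV (`cluster`, `gene`, `rank`)
#' @param path TSV path.
#' @param source Provenance label for the read catalog.
#' @param catalog A `marker_catalog`.
#' @return `read_marker_catalog()` returns a `marker_catalog`;
#'   `write_marker_catalog()` the path, invisibly.
#' @export
read_marker_catalog <- function(path, source = basename(path)) {
  tab <- readr::read_tsv(path, show_col_types = FALSE, comment = "#")
  tab <- dplyr::arrange(tab, .data$cluster, .data$rank)
  marker_catalog(split(tab$gene, tab$cluster), source = source)
}

#' @rdname read_marker_catalog
#' @export
write_marker_catalog <- function(catalog, path) {
  readr::write_tsv(as_tibble.marker_catalog(catalog), path)
  invisible(path)
}

#' Average z-scored expression of a marker set per cell
#'
#' Markers absent from the dataset are dropped with a warning; an entirely
#' absent set is an error.
#'
#' @param z Genes x cells z-score matrix from [zscore_genes()].
#' @param genes Character vector of marker genes.
#' @param set_name Label used in messages.
#' @return Numeric per-cell score vector.
#' @export
marker_score_cells <- function(z, genes, set_name = "marker set") {
  present <- intersect(genes, rownames(z))
  if (!length(present)) abort_atlasrep("no marker of %s present in the dataset", set_name)
  if (length(present) < length(genes)) {
    warning(sprintf("%s: dropped %d absent marker(s)",
                    set_name, length(genes) - length(present)))
  }
  colMeans(z[present, , drop = FALSE])
}

#' Marker-set by cluster AUROC matrix
#'
#' For every marker set, cells are ranked by the set's average z-scored
#' expression and a one-vs-all AUROC is computed for every cluster of the
#' dataset. The diagonal (set's own cluster) holds the on-target scores;
#' off-diagonal entries reveal marker sets that are more specific to another
#' cluster.
#'
#' @param ds An [expression_dataset()].
#' @param catalog A [marker_catalog()]. With `drop_absent_sets = TRUE` (the
#'   default for within-atlas evaluation, where the diagonal holds on-target
#'   scores), sets for clusters absent from the dataset are skipped with a
#'   warning; cross-atlas callers keep all sets.
#' @param nv Optional pre-computed [normalize_log_cpm()] view.
#' @param drop_absent_sets Drop sets named after clusters the dataset lacks.
#' @return A `marker_auroc_matrix`: sets x clusters matrix with attributes
#'   `dataset_id` and `scores` (the per-cell score matrix, sets x cells).
#' @export
marker_auroc_matrix <- function(ds, catalog, nv = normalize_log_cpm(ds),
                                drop_absent_sets = TRUE) {
  z <- zscore_genes(nv)
  cl <- ds$cells$cluster
  lev <- sort(unique(cl))
  sets <- catalog$markers
  missing <- setdiff(names(sets), lev)
  if (length(missing) && drop_absent_sets) {
    warning(sprintf("skipping %d marker set(s) for clusters absent from the dataset",
                    length(missing)))
    sets <- sets[setdiff(names(sets), missing)]
    if (!length(sets)) abort_atlasrep("no marker set matches a dataset cluster")
  }
  scores <- t(vapply(names(sets), function(s) {
    marker_score_cells(z, sets[[s]], set_name = s)
  }, numeric(ncol(z))))
  vals <- t(vapply(rownames(scores), function(s) {
    auroc_grouped(scores[s, ], cl)[lev]
  }, numeric(length(lev))))
  colnames(vals) <- lev
  structure(vals, class = c("marker_auroc_matrix", "matrix", "array"),
            dataset_id = ds$dataset_id, scores = scores)
}

#' @export
print.marker_auroc_matrix <- function(x, ...) {
  d <- diag_scores(x)
  cat(sprintf("<marker_auroc_matrix '%s'>: %d sets x %d clusters, mean on-target %.3f\n",
              attr(x, "dataset_id"), nrow(x), ncol(x), mean(d, na.rm = TRUE)))
  invisible(x)
}

# On-target (diagonal) scores of a marker AUROC matrix.
diag_scores <- function(mam) {
  own <- intersect(rownames(mam), colnames(mam))
  vapply(own, function(s) mam[s, s], numeric(1))
}

#' Local (best-vs-next) marker AUROC for one marker set
#'
#' Identifies the best off-target cluster of the set (highest off-diagonal
#' AUROC; ties broken by smallest cluster label) and recomputes the AUROC with
#' cells restricted to the target cluster and that best off-target cluster.
#' Values near 0.5 mean the markers cannot separate the two clusters; values
#' below 0.5 mean the off-target cluster ranks higher.
#'
#' @param ds An [expression_dataset()].
#' @param mam A [marker_auroc_matrix()] for `ds`.
#' @param set Marker-set (cluster) name; must be a row of `mam`.
#' @return One-row tibble: `set`, `best_off_target`, `local_auroc`,
#'   `global_auroc`.
#' @export
marker_local_auroc <- function(ds, mam, set) {
  stopifnot(set %in% rownames(mam))
  cl <- ds$cells$cluster
  row <- mam[set, ]
  off <- row[setdiff(names(row), set)]
  best <- names(off)[argmax_tiebreak(off, names(off))]
  keep <- cl %in% c(set, best)
  scores <- attr(mam, "scores")[set, keep]
  loc <- auroc(scores, cl[keep] == set)
  tibble::tibble(set = set, best_off_target = best, local_auroc = loc,
                 global_auroc = if (set %in% names(row)) row[[set]] else NA_real_)
}

#' Local marker AUROCs for every set of a catalog
#'
#' @inheritParams marker_local_auroc
#' @return Tibble, one row per marker set (see [marker_local_auroc()]).
#' @export
marker_local_aurocs <- function(ds, mam) {
  dplyr::bind_rows(lapply(rownames(mam), function(s) marker_local_auroc(ds, mam, s)))
}

#' Cross-atlas marker-overlap tests
#'
#' Tests every cross-catalog cluster pair for a larger-than-chance
#' intersection of marker genes (upper-tail hypergeometric test over a shared
#' gene universe), with Bonferroni correction. `"all-pairs"` corrects for
#' every pairwise comparison (`|A| * |B|`); `"per-atlas"` uses the relaxed
#' denominator `max(|A|, |B|)`, correcting for the cluster count of each
#' dataset.
#'
#' @param cat_a,cat_b [marker_catalog()]s.
#' @param universe_size Size of the shared gene universe.
#' @param alpha Significance level before correction (default 0.05).
#' @param correction `"all-pairs"` or `"per-atlas"`.
#' @return Tibble of significant pairs: `cluster_a`, `cluster_b`, `k`, `p`,
#'   `p_adj`.
#' @export
marker_overlap_pairs <- function(cat_a, cat_b, universe_size, alpha = 0.05,
                                 correction = c("all-pairs", "per-atlas")) {
  correction <- match.arg(correction)
  if (universe_size < max(lengths(cat_a$markers), lengths(cat_b$markers))) {
    abort_atlasrep("universe_size smaller than a marker list")
  }
  grid <- tidyr::expand_grid(cluster_a = names(cat_a$markers),
                             cluster_b = names(cat_b$markers))
  res <- purrr::pmap_dfr(grid, function(cluster_a, cluster_b) {
    ga <- unique(cat_a$markers[[cluster_a]])
    gb <- unique(cat_b$markers[[cluster_b]])
    k <- length(intersect(ga, gb))
    p <- hypergeom_overlap_test(k, length(ga), length(gb), universe_size)$p_value
    tibble::tibble(cluster_a = cluster_a, cluster_b = cluster_b, k = k, p = p)
  })
  m <- switch(correction,
              "all-pairs" = nrow(grid),
              "per-atlas" = max(length(cat_a$markers), length(cat_b$markers)))
  res$p_adj <- pmin(1, res$p * m)
  dplyr::filter(res, .data$p_adj < alpha)
}

#' Marker-based cluster pairing
#'
#' Pairs each marker set of one atlas with the cluster of the other atlas
#' scoring the highest marker AUROC. When several sets best-match the same
#' cluster, only the pairing with the highest AUROC is kept, so paired
#' clusters are unique.
#'
#' @param catalog_a [marker_catalog()] from atlas A.
#' @param ds_b Target [expression_dataset()] (atlas B).
#' @param nv_b Optional pre-computed normalized view of `ds_b`.
#' @return Tibble: `cluster_a`, `cluster_b`, `auroc`.
#' @export
marker_based_pairing <- function(catalog_a, ds_b, nv_b = normalize_log_cpm(ds_b)) {
  mam <- marker_auroc_matrix(ds_b, catalog_a, nv = nv_b, drop_absent_sets = FALSE)
  hits <- purrr::map_dfr(rownames(mam), function(s) {
    j <- argmax_tiebreak(mam[s, ], colnames(mam))
    tibble::tibble(cluster_a = s, cluster_b = colnames(mam)[j], auroc = mam[s, j])
  })
  hits |>
    dplyr::group_by(.data$cluster_b) |>
    dplyr::slice_max(.data$auroc, n = 1, with_ties = FALSE) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$cluster_a)
}
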