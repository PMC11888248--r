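#' Reciprocal top hits from a symmetric AUROC table
#'
#' A pair `(c, d)` is a reciprocal top hit when `d` is the best-scoring target
#' for `c` (row argmax) and `c` is the best-scoring reference for `d` (column
#' argmax). Ties are broken by smallest cluster label and flagged. With the
#' `directional` option, reciprocity is additionally required in both
#' directional tables.
#'
#' @param sym Symmetric `auroc_table` (rows = atlas A clusters, columns =
#'   atlas B clusters).
#' @param directional Optional list of the two directional tables
#'   (`list(ab, ba)`); if given, both must agree on the mutual argmax.
#' @return Tibble: `cluster_a`, `cluster_b`, `symmetric_auroc`, `tie`
#'   (logical). Reciprocal rows form a one-to-one partial matching.
#' @export
top_hits <- function(sym, directional = NULL) {
  stopifnot(nrow(sym) > 0, ncol(sym) > 0)
  best_b <- vapply(rownames(sym), function(a) {
    j <- argmax_tiebreak(sym[a, ], colnames(sym))
    colnames(sym)[j]
  }, character(1))
  tie_a <- vapply(rownames(sym), function(a)
    attr(argmax_tiebreak(sym[a, ], colnames(sym)), "tie"), logical(1))
  best_a <- vapply(colnames(sym), function(b) {
    i <- argmax_tiebreak(sym[, b], rownames(sym))
    rownames(sym)[i]
  }, character(1))
  rec <- names(best_b)[best_a[best_b] == names(best_b)]
  if (!is.null(directional)) {
    ok <- vapply(rec, function(a) {
      b <- best_b[[a]]
      ab <- directional[[1]]; ba <- directional[[2]]
      colnames(ab)[argmax_tiebreak(ab[a, ], colnames(ab))] == b &&
        colnames(ba)[argmax_tiebreak(ba[b, ], colnames(ba))] == a
    }, logical(1))
    rec <- rec[ok]
  }
  tibble::tibble(cluster_a = rec, cluster_b = unname(best_b[rec]),
                 symmetric_auroc = vapply(rec, function(a) sym[a, best_b[[a]]],
                                          numeric(1)),
                 tie = unname(tie_a[rec])) |>
    dplyr::arrange(.data$cluster_a)
}

#' Best-vs-next discrimination for one reference cluster
#'
#' Takes the two most similar target clusters of a reference cluster (by its
#' one-vs-all AUROC row), restricts the reference cluster's votes to the cells
#' of those two clusters, and asks whether the best cluster's cells can be
#' discriminated from the runner-up's: an AUROC near 1 means the local split
#' is real from this reference's viewpoint, near 0.5 means the two clusters
#' are locally indistinguishable. A Wilcoxon rank-sum test on the same two
#' vote samples supplies significance; callers apply Bonferroni across the
#' reference clusters of one atlas.
#'
#' @param ref_cluster Reference cluster label.
#' @param votes Target-cells x reference-clusters vote matrix from
#'   [nv_votes()].
#' @param ova Directional `auroc_table` (reference -> target).
#' @param target_labels Cluster label per target cell (rows of `votes`).
#' @return One-row tibble: `reference_cluster`, `best`, `next_best`,
#'   `best_vs_next_auroc`, `p_value`.
#' @export
best_vs_next <- function(ref_cluster, votes, ova, target_labels) {
  row <- ova[ref_cluster, ]
  row <- row[!is.na(row)]
  if (length(row) < 2L) {
    return(tibble::tibble(reference_cluster = ref_cluster, best = NA_character_,
                          next_best = NA_character_,
                          best_vs_next_auroc = NA_real_, p_value = NA_real_))
  }
  d1 <- names(row)[argmax_tiebreak(row, names(row))]
  rest <- row[setdiff(names(row), d1)]
  d2 <- names(rest)[argmax_tiebreak(rest, names(rest))]
  s <- votes[, ref_cluster]
  in1 <- target_labels == d1
  in2 <- target_labels == d2
  a <- auroc(s[in1 | in2], in1[in1 | in2])
  p <- rank_sum_test(s[in1], s[in2], tail = "two-sided")$p_value
  tibble::tibble(reference_cluster = ref_cluster, best = d1, next_best = d2,
                 best_vs_next_auroc = a, p_value = p)
}

#' Assemble the reciprocal-pair table with best-vs-next statistics
#'
#' Runs [top_hits()] on the symmetric table and annotates every pair with
#' best-vs-next AUROCs and Bonferroni-corrected Wilcoxon p-values from both
#' reference directions, plus cluster sizes.
#'
#' @param sym Symmetric `auroc_table`.
#' @param ab,ba Directional `auroc_table`s (A -> B and B -> A).
#' @param votes_ab Votes of A clusters into B cells (B-cells x A-clusters).
#' @param votes_ba Votes of B clusters into A cells.
#' @param labels_a,labels_b Cluster label per cell of each atlas, aligned with
#'   the vote matrices' rows.
#' @param alpha Significance level after Bonferroni (default 0.05).
#' @return A `reciprocal_pairs` tibble: `cluster_a`, `cluster_b`,
#'   `symmetric_auroc`, `best_vs_next_a`, `bvn_p_a`, `bvn_sig_a`,
#'   `best_vs_next_b`, `bvn_p_b`, `bvn_sig_b`, `size_a`, `size_b`, `tie`.
#' @export
reciprocal_pair_table <- function(sym, ab, ba, votes_ab, votes_ba,
                                  labels_a, labels_b, alpha = 0.05) {
  pairs <- top_hits(sym)
  m_a <- nrow(ab); m_b <- nrow(ba)
  bvn_a <- purrr::map_dfr(pairs$cluster_a, best_vs_next,
                          votes = votes_ab, ova = ab, target_labels = labels_b)
  bvn_b <- purrr::map_dfr(pairs$cluster_b, best_vs_next,
                          votes = votes_ba, ova = ba, target_labels = labels_a)
  out <- pairs |>
    dplyr::mutate(best_vs_next_a = bvn_a$best_vs_next_auroc,
                  bvn_p_a = pmin(1, bvn_a$p_value * m_a),
                  bvn_sig_a = .data$bvn_p_a < alpha,
                  best_vs_next_b = bvn_b$best_vs_next_auroc,
                  bvn_p_b = pmin(1, bvn_b$p_value * m_b),
                  bvn_sig_b = .data$bvn_p_b < alpha,
                  size_a = as.integer(table(labels_a)[.data$cluster_a]),
                  size_b = as.integer(table(labels_b)[.data$cluster_b]))
  class(out) <- c("reciprocal_pairs", class(out))
  out
}

#' @export
glance.reciprocal_pairs <- function(x, ...) {
  tibble::tibble(n_pairs = nrow(x),
                 mean_symmetric_auroc = mean(x$symmetric_auroc),
                 mean_best_vs_next = mean(c(x$best_vs_next_a, x$best_vs_next_b),
                                          na.rm = TRUE),
                 prop_sig_a = mean(x$bvn_sig_a, na.rm = TRUE),
                 prop_sig_b = mean(x$bvn_sig_b, na.rm = TRUE))
}

#' Build a portable pretrained matching model
#'
#' Stores, per cluster, the mean rank-normalized expression vector over a
#' named gene list, plus cluster sizes. The model can be applied to any new
#' dataset sharing part of the gene list, without access to the training
#' cells.
#'
#' @param nv A [normalize_log_cpm()] view of the training dataset.
#' @param hvg `hvg_set` or character vector of feature genes.
#' @return A `pretrained_model`: list with `gene_ids`, `centroids`
#'   (clusters x genes), `cluster_sizes`, `dataset_id`.
#' @export
build_pretrained <- function(nv, hvg) {
  rnc <- rank_normalize(nv, hvg)
  cent <- cluster_rank_centroids(rnc)
  structure(list(gene_ids = rnc$hvg, centroids = cent,
                 cluster_sizes = table(rnc$cells$cluster),
                 dataset_id = nv$dataset_id),
            class = "pretrained_model")
}

#' @export
print.pretrained_model <- function(x, ...) {
  cat(sprintf("<pretrained_model '%s'>: %d clusters x %d genes\n",
              x$dataset_id, nrow(x$centroids), length(x$gene_ids)))
  invisible(x)
}

#' Apply a pretrained model to an independent dataset
#'
#' Restricts the model centroids and the target cells to the shared genes,
#' re-centers and re-normalizes both over that subset, computes votes as inner
#' products, and scores every target cluster against every model cluster with
#' one-vs-all AUROCs. Each target cluster is assigned the model cluster with
#' the highest AUROC.
#'
#' @param model A [build_pretrained()] model.
#' @param nv_target [normalize_log_cpm()] view of the target dataset.
#' @return List with `auroc` (an `auroc_table`, model clusters x target
#'   clusters), `best_match` (tibble: `target_cluster`, `model_cluster`,
#'   `auroc`), and `n_shared_genes`.
#' @export
apply_pretrained <- function(model, nv_target) {
  shared <- intersect(model$gene_ids, rownames(nv_target$values))
  if (length(shared) < 3L) {
    abort_atlasrep("apply_pretrained(): only %d of %d model genes found in target",
                   length(shared), length(model$gene_ids))
  }
  cent <- model$centroids[, shared, drop = FALSE]
  cent <- cent - rowMeans(cent)
  nrm <- sqrt(rowSums(cent^2))
  nrm[nrm == 0] <- 1
  cent <- cent / nrm
  tgt <- rank_normalize(nv_target, shared)
  votes <- tgt$vectors %*% t(cent)
  rownames(votes) <- tgt$cells$cell_id
  tab <- auroc_from_votes(votes, tgt, model$dataset_id, nv_target$dataset_id)
  best <- purrr::map_dfr(colnames(tab), function(d) {
    col <- tab[, d]
    i <- argmax_tiebreak(col, names(col))
    tibble::tibble(target_cluster = d, model_cluster = rownames(tab)[i],
                   auroc = tab[i, d])
  })
  list(auroc = tab, best_match = best, n_shared_genes = length(shared))
}

#' Write / read a pretrained model (TSV matrix + JSON sidecar)
#'
#' @param model A `pretrained_model`.
#' @param path TSV path for the clusters x genes centroid matrix; sizes and
#'   provenance go to `<path>.json`.
#' @return `write_pretrained()` the path invisibly; `read_pretrained()` a
#'   `pretrained_model`.
#' @export
write_pretrained <- function(model, path) {
  tab <- tibble::as_tibble(as.data.frame(model$centroids), rownames = "cluster")
  readr::write_tsv(tab, path)
  jsonlite::write_json(list(dataset_id = model$dataset_id,
                            gene_ids = model$gene_ids,
                            cluster_sizes = as.list(model$cluster_sizes)),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_pretrained
#' @export
read_pretrained <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  cent <- as.matrix(tab[, -1])
  rownames(cent) <- tab$cluster
  structure(list(gene_ids = meta$gene_ids, centroids = cent,
                 cluster_sizes = unlist(meta$cluster_sizes),
                 dataset_id = meta$dataset_id),
            class = "pretrained_model")
}

#' Enrichment of reciprocal clusters among best matches
#'
#' Tests whether the best matches assigned to an independent dataset's
#' clusters land on reciprocal-hit model clusters more often than the model's
#' own composition would suggest. The 2x2 table crosses (best matches on
#' reciprocal / non-reciprocal model clusters) against (model clusters that
#' are reciprocal / not) — a standard enrichment against availability.
#'
#' @param best_match Tibble from [apply_pretrained()] (`model_cluster` column).
#' @param reciprocal_set Character vector of model clusters that belong to a
#'   reciprocal pair.
#' @param model_clusters All model cluster labels.
#' @return One-row tibble from [fisher_exact_2x2()] (includes `odds_ratio`).
#' @export
reciprocal_enrichment <- function(best_match, reciprocal_set, model_clusters) {
  hit <- best_match$model_cluster %in% reciprocal_set
  avail <- model_clusters %in% reciprocal_set
  tab <- matrix(c(sum(hit), sum(!hit), sum(avail), sum(!avail)), nrow = 2,
                dimnames = list(c("reciprocal", "other"),
                                c("best_matches", "model_clusters")))
  fisher_exact_2x2(tab, tail = "two-sided")
}

#' Combine best matches from two pretrained models
#'
#' Counts, per target cluster, how many of its two best matches (one per
#' model) land on a member of a reciprocal pair, and summarizes best-match
#' AUROCs stratified by that count.
#'
#' @param best_a,best_b Best-match tibbles from the two models.
#' @param pairs `reciprocal_pairs` table (or any tibble with `cluster_a`,
#'   `cluster_b`).
#' @return List with `per_cluster` (tibble: `target_cluster`, `n_reciprocal`
#'   in 0:2, `mean_auroc`) and `summary` (median AUROC by count).
#' @export
two_model_summary <- function(best_a, best_b, pairs) {
  if (!setequal(best_a$target_cluster, best_b$target_cluster)) {
    abort_atlasrep("two_model_summary(): target clusters differ between models")
  }
  rec <- c(pairs$cluster_a, pairs$cluster_b)
  joined <- dplyr::inner_join(best_a, best_b, by = "target_cluster",
                              suffix = c("_a", "_b"))
  per <- joined |>
    dplyr::mutate(n_reciprocal = (.data$model_cluster_a %in% rec) +
                    (.data$model_cluster_b %in% rec),
                  mean_auroc = (.data$auroc_a + .data$auroc_b) / 2) |>
    dplyr::select("target_cluster", "n_reciprocal", "mean_auroc",
                  "auroc_a", "auroc_b")
  summ <- per |>
    dplyr::group_by(.data$n_reciprocal) |>
    dplyr::summarise(n = dplyr::n(),
                     median_auroc = stats::median(.data$mean_auroc),
                     .groups = "drop")
  list(per_cluster = per, summary = summ)
}

#' Select markers that distinguish both sides of a reciprocal pair
#'
#' Scores every shared gene by the smaller of its two within-atlas AUROCs for
#' separating the pair cluster from that atlas's next-nearest cluster (taken
#' from the symmetric AUROC profile), using log-CPM expression. The top `m`
#' genes by this min score are returned together with the local AUROC their
#' average z-score achieves in each atlas.
#'
#' @param pair Length-2 character vector `c(cluster_a, cluster_b)`.
#' @param nv_a,nv_b Normalized views of the two atlases.
#' @param sym Symmetric `auroc_table`.
#' @param m Number of markers to select (default 4).
#' @return List with `genes` (ordered), `local_auroc_a`, `local_auroc_b`,
#'   `next_a`, `next_b`.
#' @export
select_pair_markers <- function(pair, nv_a, nv_b, sym, m = 4L) {
  ca <- pair[[1]]; cb <- pair[[2]]
  row <- sym[ca, setdiff(colnames(sym), cb)]
  col <- sym[setdiff(rownames(sym), ca), cb]
  # next-nearest competitor within each atlas's own profile
  next_b <- names(row)[argmax_tiebreak(row, names(row))]   # rival in atlas B
  next_a <- names(col)[argmax_tiebreak(col, names(col))]   # rival in atlas A
  shared <- intersect(rownames(nv_a$values), rownames(nv_b$values))
  if (m > length(shared)) {
    warning("m exceeds shared gene count; returning all genes")
    m <- length(shared)
  }
  gene_auc <- function(nv, pos_cluster, neg_cluster) {
    keep <- nv$cells$cluster %in% c(pos_cluster, neg_cluster)
    mm <- as.matrix(nv$values[shared, keep, drop = FALSE])
    pos <- nv$cells$cluster[keep] == pos_cluster
    apply(mm, 1, function(v) auroc(v, pos))
  }
  sc_a <- gene_auc(nv_a, ca, next_a)
  sc_b <- gene_auc(nv_b, cb, next_b)
  score <- pmin(sc_a, sc_b)
  genes <- shared[order(score, decreasing = TRUE)[seq_len(m)]]
  local_auc <- function(nv, pos_cluster, neg_cluster) {
    keep <- nv$cells$cluster %in% c(pos_cluster, neg_cluster)
    sub <- nv
    sub$values <- nv$values[, keep, drop = FALSE]
    sub$cells <- nv$cells[keep, ]
    z <- zscore_genes(sub)
    s <- marker_score_cells(z, genes)
    auroc(s, sub$cells$cluster == pos_cluster)
  }
  list(genes = genes,
       local_auroc_a = local_auc(nv_a, ca, next_a),
       local_auroc_b = local_auc(nv_b, cb, next_b),
       next_a = next_a, next_b = next_b)
}
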