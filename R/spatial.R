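#' Centroid-correlation cell calling with gene subsampling
#'
#' Assigns each spatial cell to the reference cluster whose log-CPM centroid
#' it correlates with best (Pearson), repeating the assignment `n_rounds`
#' times on random gene subsets. The final call is the modal round winner
#' (ties broken by higher mean winning correlation, then smallest label); the
#' confidence score is the mean winning correlation over rounds, and a cell
#' passes when that mean reaches `threshold`.
#'
#' @param nv_spatial [normalize_log_cpm()] view of the spatial dataset
#'   (coordinates in its metadata).
#' @param centroids Clusters x genes log-CPM centroid matrix from
#'   [compute_centroids()] on the reference atlas.
#' @param n_rounds Subsampling rounds (default 100).
#' @param subsample_frac Fraction of shared genes drawn per round
#'   (default 0.8).
#' @param threshold Minimum mean correlation to accept a call (default 0.5;
#'   cells below it are flagged `passed = FALSE`).
#' @param seed Integer seed.
#' @param reference_id Label for the reference atlas.
#' @return A `spatial_calls` tibble: `cell_id`, `reference_id`,
#'   `best_cluster`, `mean_correlation`, `passed`, `slice`, `region`, `x`,
#'   `y`.
#' @export
call_cells <- function(nv_spatial, centroids, n_rounds = 100L,
                       subsample_frac = 0.8, threshold = 0.5, seed = 1L,
                       reference_id = "reference") {
  shared <- intersect(colnames(centroids), rownames(nv_spatial$values))
  if (length(shared) < 10L) {
    abort_atlasrep("call_cells(): only %d genes shared with the centroids", length(shared))
  }
  cellm <- as.matrix(nv_spatial$values[shared, , drop = FALSE])
  centm <- t(centroids[, shared, drop = FALSE])
  n_cells <- ncol(cellm)
  clusters <- colnames(centm)
  k_draw <- max(2L, ceiling(subsample_frac * length(shared)))
  wins <- matrix(0L, n_cells, length(clusters), dimnames = list(NULL, clusters))
  win_cor_sum <- matrix(0, n_cells, length(clusters), dimnames = list(NULL, clusters))
  mean_cor <- numeric(n_cells)
  with_seed(seed, {
    for (r in seq_len(n_rounds)) {
      idx <- sample.int(length(shared), k_draw)
      cc <- suppressWarnings(stats::cor(cellm[idx, , drop = FALSE],
                                        centm[idx, , drop = FALSE]))
      cc[is.na(cc)] <- -2
      w <- max.col(cc, ties.method = "first")
      best_cor <- cc[cbind(seq_len(n_cells), w)]
      wins[cbind(seq_len(n_cells), w)] <- wins[cbind(seq_len(n_cells), w)] + 1L
      win_cor_sum[cbind(seq_len(n_cells), w)] <-
        win_cor_sum[cbind(seq_len(n_cells), w)] + best_cor
      mean_cor <- mean_cor + best_cor
    }
  })
  mean_cor <- mean_cor / n_rounds
  best <- vapply(seq_len(n_cells), function(i) {
    w <- wins[i, ]
    cand <- which(w == max(w))
    if (length(cand) > 1L) {
      mc <- win_cor_sum[i, cand] / w[cand]
      cand <- cand[mc >= max(mc) - 1e-12]
      cand <- cand[order(clusters[cand])][1L]
    }
    clusters[cand[1L]]
  }, character(1))
  meta <- nv_spatial$cells
  out <- tibble::tibble(cell_id = meta$cell_id, reference_id = reference_id,
                        best_cluster = best, mean_correlation = mean_cor,
                        passed = mean_cor >= threshold,
                        slice = meta$slice, region = meta$region,
                        x = meta$x, y = meta$y)
  class(out) <- c("spatial_calls", class(out))
  attr(out, "params") <- list(n_rounds = n_rounds, subsample_frac = subsample_frac,
                              threshold = threshold, seed = seed)
  out
}

#' Per-cell concordance of calls from two references
#'
#' A cell is concordant when its calls under reference A and reference B both
#' pass the threshold and land on the two sides of one reciprocal pair. Also
#' reports per-slice concordance proportions (among cells passed under both
#' references) and per-slice counts of distinct clusters detected (union of
#' passed calls from both references).
#'
#' @param calls_a,calls_b `spatial_calls` tables for the same cells.
#' @param pairs Tibble with `cluster_a`, `cluster_b` (reciprocal pairs; A-side
#'   labels must match `calls_a`'s reference clusters).
#' @return List with `cells` (tibble: `cell_id`, `concordant`, per-reference
#'   call columns, `slice`, `region`) and `slices` (tibble: `slice`,
#'   `n_both_passed`, `prop_concordant`, `n_clusters_detected`).
#' @export
pair_concordance <- function(calls_a, calls_b, pairs) {
  if (!setequal(calls_a$cell_id, calls_b$cell_id)) {
    abort_atlasrep("pair_concordance(): cell ids differ between call tables")
  }
  key <- paste(pairs$cluster_a, pairs$cluster_b, sep = "\r")
  cells <- dplyr::inner_join(calls_a, calls_b, by = "cell_id",
                             suffix = c("_a", "_b")) |>
    dplyr::mutate(
      both_passed = .data$passed_a & .data$passed_b,
      concordant = .data$both_passed &
        paste(.data$best_cluster_a, .data$best_cluster_b, sep = "\r") %in% key) |>
    dplyr::select("cell_id", "concordant", "both_passed",
                  "best_cluster_a", "passed_a", "best_cluster_b", "passed_b",
                  slice = "slice_a", region = "region_a", x = "x_a", y = "y_a")
  slices <- cells |>
    dplyr::group_by(.data$slice) |>
    dplyr::summarise(
      n_both_passed = sum(.data$both_passed),
      prop_concordant = ifelse(n_both_passed > 0,
                               sum(.data$concordant) / n_both_passed, NA_real_),
      n_clusters_detected = dplyr::n_distinct(
        c(.data$best_cluster_a[.data$passed_a], .data$best_cluster_b[.data$passed_b])),
      .groups = "drop")
  list(cells = cells, slices = slices)
}

#' Per-slice diversity mismatch between two references
#'
#' For each slice, repeatedly subsamples the passed calls of the richer
#' reference down to the other reference's passed count and reports the mean
#' excess of distinct clusters detected:
#' `mean(distinct clusters in subsampled A) - distinct clusters in B`. When B
#' has more passed calls than A the sides are swapped and the sign flipped.
#'
#' @param calls_a,calls_b `spatial_calls` tables.
#' @param n_rep Subsampling replicates (default 50).
#' @param seed Integer seed.
#' @return Tibble: `slice`, `n_a`, `n_b`, `mismatch`, `swapped`.
#' @export
diversity_mismatch <- function(calls_a, calls_b, n_rep = 50L, seed = 1L) {
  slices <- sort(unique(c(calls_a$slice, calls_b$slice)))
  with_seed(seed, purrr::map_dfr(slices, function(s) {
    pa <- calls_a$best_cluster[calls_a$passed & calls_a$slice == s]
    pb <- calls_b$best_cluster[calls_b$passed & calls_b$slice == s]
    swapped <- length(pa) < length(pb)
    if (swapped) { tmp <- pa; pa <- pb; pb <- tmp }
    if (!length(pb)) {
      return(tibble::tibble(slice = s, n_a = length(pa), n_b = length(pb),
                            mismatch = NA_real_, swapped = swapped))
    }
    sub <- vapply(seq_len(n_rep), function(i) {
      dplyr::n_distinct(sample(pa, length(pb)))
    }, numeric(1))
    mm <- (mean(sub) - dplyr::n_distinct(pb)) * (if (swapped) -1 else 1)
    tibble::tibble(slice = s,
                   n_a = if (swapped) length(pb) else length(pa),
                   n_b = if (swapped) length(pa) else length(pb),
                   mismatch = mm, swapped = swapped)
  }))
}

#' Regional enrichment of concordant cells
#'
#' `log2` ratio of the per-region concordant fraction to the overall
#' concordant fraction. Regions with fewer than `min_cells` cells are
#' suppressed.
#'
#' @param cells The `cells` tibble from [pair_concordance()] (needs `region`
#'   and `concordant`).
#' @param min_cells Minimum cells per region (default 50).
#' @return Tibble: `region`, `n_cells`, `prop_concordant`, `log2_enrichment`.
#' @export
region_enrichment <- function(cells, min_cells = 50L) {
  cells <- dplyr::filter(cells, !is.na(.data$region))
  overall <- mean(cells$concordant)
  cells |>
    dplyr::group_by(.data$region) |>
    dplyr::summarise(n_cells = dplyr::n(),
                     prop_concordant = mean(.data$concordant), .groups = "drop") |>
    dplyr::filter(.data$n_cells >= min_cells) |>
    dplyr::mutate(log2_enrichment = log2(.data$prop_concordant / overall))
}

#' Spatial distances between paired cluster centroids
#'
#' The spatial centroid of a cluster is the mean of `(x, y, slice *
#' slice_spacing)` over its passed calls; the slice index supplies the third
#' coordinate. Distances are Euclidean in mm. Pairs with an unlocated side
#' are skipped with a flag.
#'
#' @param calls_a,calls_b `spatial_calls` tables (cluster labels of each
#'   reference).
#' @param pairs Tibble with `cluster_a`, `cluster_b`.
#' @param slice_spacing Inter-slice spacing in mm (default 0.2).
#' @return Tibble: `cluster_a`, `cluster_b`, `distance_mm`, `located`.
#' @export
paired_centroid_distance <- function(calls_a, calls_b, pairs,
                                     slice_spacing = 0.2) {
  centroid <- function(calls, k) {
    sub <- calls[calls$passed & calls$best_cluster == k &
                   !is.na(calls$x) & !is.na(calls$y), ]
    if (!nrow(sub)) return(NULL)
    c(mean(sub$x), mean(sub$y), mean(sub$slice * slice_spacing))
  }
  purrr::map2_dfr(pairs$cluster_a, pairs$cluster_b, function(a, b) {
    ca <- centroid(calls_a, a); cb <- centroid(calls_b, b)
    if (is.null(ca) || is.null(cb)) {
      tibble::tibble(cluster_a = a, cluster_b = b,
                     distance_mm = NA_real_, located = FALSE)
    } else {
      tibble::tibble(cluster_a = a, cluster_b = b,
                     distance_mm = sqrt(sum((ca - cb)^2)), located = TRUE)
    }
  })
}

#' Dissection-region agreement of paired clusters
#'
#' For each cluster pair, compares the dissection-region composition of the
#' two clusters' cells: `top1_match` flags equal modal regions (ties broken
#' by smallest label), and `top2_match` — defined only when both clusters
#' span at least two regions — flags equal unordered top-two region sets.
#'
#' @param ds_a,ds_b [expression_dataset()]s with aligned region labels.
#' @param pairs Tibble with `cluster_a`, `cluster_b`.
#' @return Tibble: `cluster_a`, `cluster_b`, `top_region_a`, `top_region_b`,
#'   `top1_match`, `top2_match` (NA when undefined).
#' @export
top_region_match <- function(ds_a, ds_b, pairs) {
  region_profile <- function(ds, k) {
    reg <- ds$cells$region[ds$cells$cluster == k]
    reg <- reg[!is.na(reg)]
    sort(table(reg), decreasing = TRUE)
  }
  top_of <- function(pr) {
    mx <- names(pr)[pr == max(pr)]
    sort(mx)[1]
  }
  top2_of <- function(pr) {
    # unordered top-2 set; deterministic under ties by label order
    ord <- order(-as.numeric(pr), names(pr))
    sort(names(pr)[ord][1:2])
  }
  purrr::map2_dfr(pairs$cluster_a, pairs$cluster_b, function(a, b) {
    pa <- region_profile(ds_a, a); pb <- region_profile(ds_b, b)
    t1a <- top_of(pa); t1b <- top_of(pb)
    t2 <- if (length(pa) >= 2 && length(pb) >= 2) {
      identical(top2_of(pa), top2_of(pb))
    } else NA
    tibble::tibble(cluster_a = a, cluster_b = b,
                   top_region_a = t1a, top_region_b = t1b,
                   top1_match = t1a == t1b, top2_match = t2)
  })
}
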