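#' Paired centroid matrices over matched clusters
#'
#' Builds, for each atlas, a genes x pairs matrix whose column `j` is the
#' log-CPM centroid of pair `j`'s cluster in that atlas. Genes are restricted
#' to those shared by both atlases, minus an exclusion set (typically the
#' HVGs that were used to determine the pairs, so the coordinated-expression
#' signal is independent of the matching features).
#'
#' @param nv_a,nv_b Normalized views of the two atlases.
#' @param pairs Tibble with `cluster_a`, `cluster_b` (>= 3 rows).
#' @param exclude `hvg_set`, character vector, or `NULL`.
#' @return List with `a`, `b` (genes x pairs matrices, same row order, columns
#'   in pair order) and `excluded` (genes removed).
#' @export
paired_centroid_matrices <- function(nv_a, nv_b, pairs, exclude = NULL) {
  if (nrow(pairs) < 3L) abort_atlasrep("need at least 3 pairs, got %d", nrow(pairs))
  ex <- if (inherits(exclude, "hvg_set")) exclude$gene_ids else as.character(exclude %||% character())
  shared <- setdiff(intersect(rownames(nv_a$values), rownames(nv_b$values)), ex)
  cent_a <- compute_centroids(nv_a)
  cent_b <- compute_centroids(nv_b)
  mat_a <- t(cent_a[pairs$cluster_a, shared, drop = FALSE])
  mat_b <- t(cent_b[pairs$cluster_b, shared, drop = FALSE])
  colnames(mat_a) <- colnames(mat_b) <- paste(pairs$cluster_a, pairs$cluster_b, sep = "|")
  list(a = mat_a, b = mat_b, excluded = intersect(ex, rownames(nv_a$values)))
}

#' Per-gene coordinated expression across matched clusters
#'
#' Spearman correlation between a gene's centroid profile across the pairs in
#' atlas A and the same gene's profile in atlas B. Genes constant in either
#' atlas are undefined (`NA`).
#'
#' @param mat_a,mat_b Genes x pairs matrices from
#'   [paired_centroid_matrices()].
#' @return Named numeric vector of per-gene Spearman correlations.
#' @export
coordinated_rho <- function(mat_a, mat_b) {
  stopifnot(identical(dim(mat_a), dim(mat_b)))
  r <- row_spearman_all(mat_a, mat_b)
  stats::setNames(r$same, rownames(mat_a))
}

# Rank rows, center, unit-normalize; constant rows -> zero with flag.
row_rank_standardize <- function(m) {
  r <- t(apply(m, 1, midrank))
  r <- r - rowMeans(r)
  nrm <- sqrt(rowSums(r^2))
  constant <- nrm == 0
  nrm[constant] <- 1
  list(v = r / nrm, constant = constant)
}

# All gene-gene Spearman correlations between two centroid matrices via one
# matrix product on rank-standardized rows. Returns the same-gene diagonal
# and the full cross matrix.
row_spearman_all <- function(mat_a, mat_b) {
  sa <- row_rank_standardize(mat_a)
  sb <- row_rank_standardize(mat_b)
  cross <- sa$v %*% t(sb$v)
  same <- unname(diag(cross))
  same[sa$constant | sb$constant] <- NA_real_
  list(same = same, cross = cross, constant = sa$constant | sb$constant)
}

#' Specificity of coordinated expression
#'
#' For each gene `g`, compares the same-gene correlation against the
#' comparison set of all cross-gene correlations involving `g` in either
#' direction (`g` in A vs every other gene in B, and every other gene in A vs
#' `g` in B). The percentile is the tie-adjusted fraction of the comparison
#' set below the same-gene value (x100); `is_top` flags genes whose same-gene
#' correlation strictly exceeds every member. Implemented with
#' rank-transformed matrix products; genes with constant centroids in either
#' atlas are excluded from both the scores and the comparison sets.
#'
#' @inheritParams coordinated_rho
#' @return Tibble: `gene`, `same_gene_rho`, `percentile` (0-100), `is_top`,
#'   `n_pairs_used`.
#' @export
specificity <- function(mat_a, mat_b) {
  stopifnot(identical(dim(mat_a), dim(mat_b)))
  r <- row_spearman_all(mat_a, mat_b)
  keep <- !r$constant
  cross <- r$cross[keep, keep, drop = FALSE]
  same <- r$same[keep]
  g <- length(same)
  pct <- numeric(g); top <- logical(g)
  for (i in seq_len(g)) {
    comp <- c(cross[i, -i], cross[-i, i])
    below <- sum(comp < same[i] - 1e-12)
    ties <- sum(abs(comp - same[i]) <= 1e-12)
    pct[i] <- 100 * (below + ties / 2) / length(comp)
    top[i] <- same[i] > max(comp) + 1e-12
  }
  out <- tibble::tibble(gene = rownames(mat_a), same_gene_rho = r$same,
                        percentile = NA_real_, is_top = NA,
                        n_pairs_used = ncol(mat_a))
  out$percentile[keep] <- pct
  out$is_top[keep] <- top
  out
}

#' Coordinated-expression table for a matched atlas pair
#'
#' Convenience wrapper: builds the paired centroid matrices, computes
#' per-gene coordinated correlations and specificity, and flags excluded
#' matching genes.
#'
#' @inheritParams paired_centroid_matrices
#' @return A `coord_expr` tibble: `gene`, `same_gene_rho`, `percentile`,
#'   `is_top`, `n_pairs_used`, `excluded_hvg`.
#' @export
coordinated_expression <- function(nv_a, nv_b, pairs, exclude = NULL) {
  mats <- paired_centroid_matrices(nv_a, nv_b, pairs, exclude)
  out <- specificity(mats$a, mats$b)
  out$excluded_hvg <- FALSE
  if (length(mats$excluded)) {
    out <- dplyr::bind_rows(out, tibble::tibble(
      gene = mats$excluded, same_gene_rho = NA_real_, percentile = NA_real_,
      is_top = NA, n_pairs_used = ncol(mats$a), excluded_hvg = TRUE))
  }
  class(out) <- c("coord_expr", class(out))
  out
}

#' @export
glance.coord_expr <- function(x, ...) {
  scored <- dplyr::filter(x, !.data$excluded_hvg, !is.na(.data$same_gene_rho))
  tibble::tibble(n_genes = nrow(scored),
                 mean_rho = mean(scored$same_gene_rho),
                 mean_percentile = mean(scored$percentile),
                 prop_top = mean(scored$is_top))
}

#' Stability of coordinated expression under pair subsampling
#'
#' For each fraction, repeatedly subsamples the pair columns without
#' replacement and recomputes mean coordinated correlation, mean percentile
#' and the proportion of top-ranked genes. Fractions yielding fewer than 3
#' pairs are skipped with a flag.
#'
#' @inheritParams coordinated_rho
#' @param fractions Numeric vector in (0, 1].
#' @param n_rep Replicates per fraction (default 20).
#' @param seed Integer seed.
#' @return Tibble: `fraction`, `n_pairs`, `skipped`, `mean_rho`,
#'   `mean_percentile`, `prop_top`, `sd_rho` (means and spread over
#'   replicates; exact full-data values at fraction 1).
#' @export
subsample_curves <- function(mat_a, mat_b, fractions = c(0.1, 0.25, 0.5, 1),
                             n_rep = 20L, seed = 1L) {
  stopifnot(all(fractions > 0), all(fractions <= 1))
  n <- ncol(mat_a)
  with_seed(seed, purrr::map_dfr(fractions, function(f) {
    k <- ceiling(f * n)
    if (k < 3L) {
      return(tibble::tibble(fraction = f, n_pairs = k, skipped = TRUE,
                            mean_rho = NA_real_, mean_percentile = NA_real_,
                            prop_top = NA_real_, sd_rho = NA_real_))
    }
    reps <- if (k == n) 1L else n_rep
    stats_rep <- vapply(seq_len(reps), function(i) {
      idx <- if (k == n) seq_len(n) else sample.int(n, k)
      sp <- specificity(mat_a[, idx, drop = FALSE], mat_b[, idx, drop = FALSE])
      ok <- !is.na(sp$same_gene_rho)
      c(mean(sp$same_gene_rho[ok]), mean(sp$percentile[ok]), mean(sp$is_top[ok]))
    }, numeric(3))
    tibble::tibble(fraction = f, n_pairs = k, skipped = FALSE,
                   mean_rho = mean(stats_rep[1, ]),
                   mean_percentile = mean(stats_rep[2, ]),
                   prop_top = mean(stats_rep[3, ]),
                   sd_rho = if (reps > 1) stats::sd(stats_rep[1, ]) else 0)
  }))
}

#' Read gene sets from a GMT file
#'
#' @param path GMT path (one set per line: name, description, genes).
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  if (requireNamespace("fgsea", quietly = TRUE)) {
    fgsea::gmtPathways(path)
  } else {
    lines <- strsplit(readLines(path), "\t")
    stats::setNames(lapply(lines, function(l) unique(l[-(1:2)])),
                    vapply(lines, `[`, "", 1))
  }
}

#' Gene-set summaries of coordinated expression
#'
#' Intersects each set with the scored genes, drops sets outside
#' `[min_size, max_size]` after intersection, and reports per-set mean
#' coordinated correlation and mean percentile plus a Wilcoxon rank-sum test
#' of in-set versus out-of-set percentiles, BH-adjusted across sets.
#'
#' @param coord A [coordinated_expression()] table.
#' @param sets Named list of gene vectors (e.g. [read_gmt()]).
#' @param min_size,max_size Post-intersection size bounds (defaults 15, 150).
#' @return Tibble: `set`, `n_genes`, `mean_rho`, `mean_percentile`,
#'   `p_value`, `p_adj`.
#' @export
gene_set_summary <- function(coord, sets, min_size = 15L, max_size = 150L) {
  if (!length(sets)) abort_atlasrep("gene_set_summary(): empty collection")
  scored <- dplyr::filter(coord, !.data$excluded_hvg, !is.na(.data$percentile))
  res <- purrr::imap_dfr(sets, function(genes, name) {
    genes <- unique(genes)
    inset <- scored$gene %in% genes
    n <- sum(inset)
    if (n < min_size || n > max_size) return(NULL)
    p <- rank_sum_test(scored$percentile[inset], scored$percentile[!inset],
                       tail = "two-sided")$p_value
    tibble::tibble(set = name, n_genes = n,
                   mean_rho = mean(scored$same_gene_rho[inset]),
                   mean_percentile = mean(scored$percentile[inset]),
                   p_value = p)
  })
  if (!nrow(res)) return(dplyr::mutate(res, p_adj = numeric(0)))
  res$p_adj <- adjust_p(res$p_value, "bh")
  res
}
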