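test_that("cell calling limit cases behave as the procedure dictates", {
  sp <- default_spatial()
  # threshold above 1 passes nothing; threshold -1 passes everything
  none <- call_cells(sp$nv, sp$cent_b, n_rounds = 3, threshold = 1 + 1e-9, seed = 2)
  expect_false(any(none$passed))
  all_in <- call_cells(sp$nv, sp$cent_b, n_rounds = 3, threshold = -1, seed = 2)
  expect_true(all(all_in$passed))

  # one round at full gene fraction equals the plain argmax assignment
  one <- call_cells(sp$nv, sp$cent_b, n_rounds = 1, subsample_frac = 1, seed = 5)
  shared <- intersect(colnames(sp$cent_b), rownames(sp$nv$values))
  cc <- stats::cor(as.matrix(sp$nv$values[shared, ]), t(sp$cent_b[, shared]))
  plain <- colnames(cc)[max.col(cc, ties.method = "first")]
  expect_equal(one$best_cluster, plain)
  expect_equal(one$mean_correlation, cc[cbind(seq_len(nrow(cc)),
                                              max.col(cc, ties.method = "first"))],
               tolerance = 1e-12)

  # a cell exactly equal to a centroid is called with correlation 1 every round
  cent_nv <- structure(list(
    values = Matrix::Matrix(t(sp$cent_b[1:2, shared]), sparse = TRUE),
    dataset_id = "cents", log_base = exp(1),
    cells = tibble::tibble(cell_id = c("cc1", "cc2"),
                           cluster = rownames(sp$cent_b)[1:2],
                           region = NA, slice = 1L, x = 0, y = 0)),
    class = "normalized_view")
  cc_calls <- call_cells(cent_nv, sp$cent_b[, shared], n_rounds = 10, seed = 3)
  expect_equal(cc_calls$best_cluster, rownames(sp$cent_b)[1:2])
  expect_equal(cc_calls$mean_correlation, c(1, 1), tolerance = 1e-12)
  expect_true(all(cc_calls$passed))

  # determinism
  r1 <- call_cells(sp$nv, sp$cent_b, n_rounds = 5, seed = 11)
  r2 <- call_cells(sp$nv, sp$cent_b, n_rounds = 5, seed = 11)
  expect_identical(r1, r2)
})

test_that("more subsampling rounds stabilize the confidence score", {
  sp <- default_spatial()
  one_cell <- sp$nv
  one_cell$values <- sp$nv$values[, 1, drop = FALSE]
  one_cell$cells <- sp$nv$cells[1, ]
  mc <- function(n_rounds, seed) {
    call_cells(one_cell, sp$cent_b, n_rounds = n_rounds, seed = seed)$mean_correlation
  }
  v10 <- var(vapply(1:30, function(s) mc(10, s), numeric(1)))
  v100 <- var(vapply(1:30, function(s) mc(100, s + 1000), numeric(1)))
  expect_lt(v100, v10)
})

test_that("pair concordance flags cells matching a reciprocal pair", {
  mk_calls <- function(best, passed, ref) {
    out <- tibble::tibble(cell_id = paste0("c", seq_along(best)), reference_id = ref,
                          best_cluster = best, mean_correlation = 0.9,
                          passed = passed, slice = c(1L, 1L, 2L, 2L),
                          region = c("R1", "R1", "R2", "R2"), x = 0, y = 0)
    class(out) <- c("spatial_calls", class(out))
    out
  }
  pairs <- tibble::tibble(cluster_a = "P", cluster_b = "Q")
  ca <- mk_calls(c("P", "P", "P", "Z"), c(TRUE, TRUE, FALSE, TRUE), "a")
  cb <- mk_calls(c("Q", "Z", "Q", "Q"), c(TRUE, TRUE, TRUE, TRUE), "b")
  pc <- pair_concordance(ca, cb, pairs)
  expect_equal(pc$cells$concordant, c(TRUE, FALSE, FALSE, FALSE))
  sl1 <- pc$slices[pc$slices$slice == 1, ]
  expect_equal(sl1$prop_concordant, 0.5)
  expect_true(all(pc$slices$prop_concordant >= 0 & pc$slices$prop_concordant <= 1,
                  na.rm = TRUE))
  cb_bad <- cb; cb_bad$cell_id[1] <- "zz"
  expect_error(pair_concordance(ca, cb_bad, pairs), "cell ids")
})

test_that("diversity mismatch is zero for identical calls and positive for richer ones", {
  mk <- function(clusters) {
    n <- length(clusters)
    out <- tibble::tibble(cell_id = paste0("c", 1:n), reference_id = "r",
                          best_cluster = clusters, mean_correlation = 0.9,
                          passed = TRUE, slice = 1L, region = "R1", x = 0, y = 0)
    class(out) <- c("spatial_calls", class(out))
    out
  }
  same <- mk(rep(letters[1:5], each = 20))
  expect_equal(diversity_mismatch(same, same, n_rep = 20, seed = 1)$mismatch, 0)

  rich <- mk(rep(letters[1:10], each = 10))   # 100 calls over 10 clusters
  poor <- mk(rep(letters[1:5], each = 20))    # 100 calls over 5 clusters
  mm <- diversity_mismatch(rich, poor, n_rep = 50, seed = 2)
  expect_gt(mm$mismatch, 2)
  mm2 <- diversity_mismatch(rich, poor, n_rep = 50, seed = 2)
  expect_identical(mm, mm2)
  # reversing the arguments flips the sign (equal counts: no side swap needed)
  mm3 <- diversity_mismatch(poor, rich, n_rep = 50, seed = 2)
  expect_lt(mm3$mismatch, -2)
  expect_false(mm3$swapped)
  # genuinely unbalanced counts trigger the swap-and-flip path
  mm4 <- diversity_mismatch(mk(rep(letters[1:5], each = 10)), rich,
                            n_rep = 50, seed = 3)
  expect_true(mm4$swapped)
  expect_lt(mm4$mismatch, 0)
})

test_that("region enrichment is a log2 ratio with the weighted-mean identity", {
  cells <- tibble::tibble(
    region = rep(c("R1", "R2"), each = 100),
    concordant = c(rep(c(TRUE, FALSE), c(80, 20)), rep(c(TRUE, FALSE), c(40, 60))))
  re <- region_enrichment(cells, min_cells = 50)
  overall <- 120 / 200
  expect_equal(re$log2_enrichment[re$region == "R1"], log2(0.8 / overall))
  # a region with twice the global concordant fraction maps to exactly 1
  cells2 <- tibble::tibble(region = rep(c("R1", "R2"), each = 100),
                           concordant = c(rep(c(TRUE, FALSE), c(80, 20)),
                                          rep(FALSE, 100)))
  re2 <- region_enrichment(cells2, min_cells = 10)
  expect_equal(re2$log2_enrichment[re2$region == "R1"], 1)
  # cell-count-weighted mean of 2^enrichment equals 1
  w <- re$n_cells / sum(re$n_cells)
  expect_equal(sum(w * 2^re$log2_enrichment), 1, tolerance = 1e-12)
  # a small region is suppressed
  cells3 <- dplyr::bind_rows(cells, tibble::tibble(region = "R3", concordant = TRUE))
  expect_false("R3" %in% region_enrichment(cells3, min_cells = 50)$region)
})

test_that("paired centroid distances are Euclidean in slice-extended space", {
  mk <- function(x, y, slice, cluster) {
    out <- tibble::tibble(cell_id = paste0(cluster, "_", seq_along(x)),
                          reference_id = "r", best_cluster = cluster,
                          mean_correlation = 0.9, passed = TRUE,
                          slice = slice, region = "R1", x = x, y = y)
    class(out) <- c("spatial_calls", class(out))
    out
  }
  ca <- mk(c(0, 0), c(0, 0), c(0L, 0L), "P")
  cb <- mk(c(3, 3), c(4, 4), c(0L, 0L), "Q")
  pairs <- tibble::tibble(cluster_a = "P", cluster_b = "Q")
  d <- paired_centroid_distance(ca, cb, pairs)
  expect_equal(d$distance_mm, 5)
  # coincident centroids
  d0 <- paired_centroid_distance(ca, mk(c(0, 0), c(0, 0), c(0L, 0L), "Q"), pairs)
  expect_equal(d0$distance_mm, 0)
  # slice spacing enters the third coordinate
  cb2 <- mk(c(0, 0), c(0, 0), c(5L, 5L), "Q")
  d2 <- paired_centroid_distance(ca, cb2, pairs, slice_spacing = 0.2)
  expect_equal(d2$distance_mm, 1)
  # unlocated cluster is skipped with a flag
  dna <- paired_centroid_distance(ca, cb, tibble::tibble(cluster_a = "P",
                                                         cluster_b = "missing"))
  expect_false(dna$located)
})

test_that("top-region matching compares modal and top-two region sets", {
  mk_ds <- function(regions, cluster) {
    n <- length(regions)
    counts <- matrix(1, 2, n, dimnames = list(c("g1", "g2"), NULL))
    expression_dataset(cluster, counts,
                       tibble::tibble(cell_id = paste0(cluster, 1:n),
                                      cluster = cluster, region = regions))
  }
  a <- mk_ds(rep("X", 4), "ka")
  b <- mk_ds(rep("X", 3), "kb")
  pairs <- tibble::tibble(cluster_a = "ka", cluster_b = "kb")
  tm <- top_region_match(a, b, pairs)
  expect_true(tm$top1_match)
  expect_true(is.na(tm$top2_match))  # single-region clusters: top-2 undefined

  a2 <- mk_ds(c("X", "X", "Y"), "ka")
  b2 <- mk_ds(c("Y", "Y", "X"), "kb")
  tm2 <- top_region_match(a2, b2, pairs)
  expect_false(tm2$top1_match)   # X vs Y modal regions
  expect_true(tm2$top2_match)    # unordered {X, Y} on both sides
})
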