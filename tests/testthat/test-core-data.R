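test_that("dataset construction validates counts and metadata", {
  ds <- tiny_dataset()
  expect_s3_class(ds, "expression_dataset")
  expect_equal(gene_ids(ds), c("g1", "g2", "g3"))
  expect_equal(cluster_labels(ds), c("k1", "k2"))

  bad_cells <- tibble::tibble(cell_id = c("c1", "c1"), cluster = c("k", "k"))
  expect_error(expression_dataset("x", matrix(1:2, 1, dimnames = list("g", NULL)),
                                  bad_cells), "duplicate cell id")
  expect_error(expression_dataset("x", matrix(c(1, -1), 1, 2,
                                              dimnames = list("g", NULL)),
                                  tibble::tibble(cell_id = c("a", "b"),
                                                 cluster = "k")),
               "nonnegative")
  expect_error(expression_dataset("x", matrix(c(1, 0.5), 1, 2,
                                              dimnames = list("g", NULL)),
                                  tibble::tibble(cell_id = c("a", "b"),
                                                 cluster = "k")),
               "integers")
})

test_that("matrix-market round trip preserves counts and metadata", {
  dir <- withr::local_tempdir()
  ds <- tiny_dataset()
  paths <- write_dataset(ds, dir)
  back <- read_dataset(paths[1], paths[2], paths[3], dataset_id = "tiny")
  expect_equal(as.matrix(back$counts), as.matrix(ds$counts))
  expect_equal(back$cells$cluster, ds$cells$cluster)
  expect_equal(gene_ids(back), gene_ids(ds))

  # random sparse fixture
  set.seed(10)
  m <- Matrix::rsparsematrix(30, 12, density = 0.2,
                             rand.x = function(n) rpois(n, 4))
  rownames(m) <- sprintf("g%02d", 1:30)
  ds2 <- expression_dataset("rand", abs(m),
                            tibble::tibble(cell_id = sprintf("c%02d", 1:12),
                                           cluster = rep(c("a", "b"), 6)))
  p2 <- write_dataset(ds2, dir, stem = "rand")
  back2 <- read_dataset(p2[1], p2[2], p2[3])
  expect_equal(as.matrix(back2$counts), as.matrix(ds2$counts))

  # sidecar with wrong row count
  cells_bad <- file.path(dir, "bad_cells.tsv")
  readr::write_tsv(ds$cells[1:3, ], cells_bad)
  expect_error(read_dataset(paths[1], paths[2], cells_bad), "dimension mismatch")
})

test_that("log-CPM normalization matches hand arithmetic and its invariances", {
  counts <- matrix(c(1, 0, 3), 3, 1, dimnames = list(c("g1", "g2", "g3"), NULL))
  ds <- expression_dataset("h", counts,
                           tibble::tibble(cell_id = "c1", cluster = "k"))
  nv <- normalize_log_cpm(ds)
  expect_equal(as.numeric(nv$values),
               c(log(250000 + 1), 0, log(750000 + 1)), tolerance = 1e-12)
  expect_equal(as.numeric(nv$values), c(12.4292, 0, 13.5278), tolerance = 1e-4)

  # doubling all counts of a cell leaves its column unchanged (CPM scale-free)
  ds2 <- ds; ds2$counts <- ds$counts * 2
  expect_equal(as.matrix(normalize_log_cpm(ds2)$values), as.matrix(nv$values),
               tolerance = 1e-12)

  # all-zero cell stays zero, with a warning
  z <- expression_dataset("z", matrix(0, 2, 1, dimnames = list(c("a", "b"), NULL)),
                          tibble::tibble(cell_id = "c", cluster = "k"))
  expect_warning(nz <- normalize_log_cpm(z), "all-zero")
  expect_true(all(nz$values == 0))

  # recomputing a column from parent counts reproduces the view
  ds3 <- tiny_dataset()
  nv3 <- normalize_log_cpm(ds3)
  col2 <- log1p(ds3$counts[, 2] / sum(ds3$counts[, 2]) * 1e6)
  expect_equal(as.numeric(nv3$values[, 2]), as.numeric(col2), tolerance = 1e-12)
})

test_that("log base only rescales values and leaves rank statistics unchanged", {
  ds <- tiny_dataset()
  nat <- normalize_log_cpm(ds)
  two <- normalize_log_cpm(ds, log_base = 2)
  ratio <- as.matrix(two$values) / as.matrix(nat$values)
  expect_equal(unique(round(ratio[as.matrix(nat$values) > 0], 10)),
               round(1 / log(2), 10))
  r1 <- rank_normalize(nat, gene_ids(ds))
  r2 <- rank_normalize(two, gene_ids(ds))
  expect_equal(r1$vectors, r2$vectors, tolerance = 1e-12)
})

test_that("centroids are per-cluster means in normalized space", {
  vals <- matrix(c(1, 3, 3, 5), nrow = 2,
                 dimnames = list(c("g1", "g2"), c("c1", "c2")))
  nv <- structure(list(values = Matrix::Matrix(vals, sparse = TRUE),
                       dataset_id = "m", log_base = exp(1),
                       cells = tibble::tibble(cell_id = c("c1", "c2"),
                                              cluster = c("k", "k"))),
                  class = "normalized_view")
  expect_equal(compute_centroids(nv)["k", ], c(g1 = 2, g2 = 4))

  ds <- tiny_dataset()
  nv2 <- normalize_log_cpm(ds)
  cent <- compute_centroids(nv2)
  # singleton check via a one-cell cluster
  nv2$cells$cluster <- c("k1", "k2", "k3", "k3")
  cent2 <- compute_centroids(nv2)
  expect_equal(cent2["k1", ], as.numeric(nv2$values[, 1]), ignore_attr = TRUE)
  # permuting cells leaves centroids unchanged
  perm <- c(3, 1, 4, 2)
  nv3 <- nv2
  nv3$values <- nv2$values[, perm]
  nv3$cells <- nv2$cells[perm, ]
  expect_equal(compute_centroids(nv3), cent2, tolerance = 1e-12)
})

test_that("gene z-scoring uses sample SD and zeroes constant genes", {
  vals <- matrix(c(1, 5, 2, 5, 3, 5), nrow = 2,
                 dimnames = list(c("g1", "g2"), c("c1", "c2", "c3")))
  nv <- structure(list(values = Matrix::Matrix(vals, sparse = TRUE),
                       dataset_id = "m", log_base = exp(1),
                       cells = tibble::tibble(cell_id = c("c1", "c2", "c3"),
                                              cluster = "k")),
                  class = "normalized_view")
  z <- zscore_genes(nv)
  expect_equal(z["g1", ], c(c1 = -1, c2 = 0, c3 = 1))
  expect_equal(z["g2", ], c(c1 = 0, c2 = 0, c3 = 0))
  nvr <- default_views()$a
  zr <- zscore_genes(nvr)
  expect_true(max(abs(rowMeans(zr))) < 1e-10)
})

test_that("HVG selection flags high-variance genes within mean bins", {
  # four genes with variances 1, 2, 3, 4: quantile 0.5 keeps the top two
  a <- sqrt(c(1, 2, 3, 4))
  vals <- rbind(c(-a[1], a[1], 0), c(-a[2], a[2], 0),
                c(-a[3], a[3], 0), c(-a[4], a[4], 0)) + 5
  rownames(vals) <- paste0("g", 1:4)
  nv <- structure(list(values = Matrix::Matrix(vals, sparse = TRUE),
                       dataset_id = "m", log_base = exp(1),
                       cells = tibble::tibble(cell_id = paste0("c", 1:3),
                                              cluster = "k")),
                  class = "normalized_view")
  hvg <- select_hvgs(list(nv), n_bins = 1, quantile = 0.5)
  expect_equal(hvg$gene_ids, c("g3", "g4"))

  # a constant gene is never selected and the set stays within shared genes
  v <- default_views()
  hvg2 <- default_hvg()
  expect_true(all(hvg2$gene_ids %in%
                    intersect(rownames(v$a$values), rownames(v$b$values))))
  const_gene <- rownames(v$a$values)[1]
  va <- v$a
  va$values[const_gene, ] <- 0
  hvg3 <- select_hvgs(list(va, v$b))
  expect_false(const_gene %in% hvg3$gene_ids)

  # round trip
  dir <- withr::local_tempdir()
  p <- write_hvgs(hvg2, file.path(dir, "hvg.tsv"))
  expect_equal(read_hvgs(p)$gene_ids, hvg2$gene_ids)
})

test_that("region alignment maps labels and rejects unmapped ones", {
  ds <- tiny_dataset()
  rm <- tibble::tibble(source = c("HIP", "CTX"), aligned = c("HPF", "Isocortex"))
  out <- align_regions(ds, rm)
  expect_equal(unique(out$cells$region[out$cells$cluster == "k1"]), "HPF")
  ident <- align_regions(ds, tibble::tibble(source = c("HIP", "CTX"),
                                            aligned = c("HIP", "CTX")))
  expect_equal(ident$cells, ds$cells)
  expect_error(align_regions(ds, tibble::tibble(source = "HIP", aligned = "HPF")),
               "CTX")
  passed <- align_regions(ds, tibble::tibble(source = "HIP", aligned = "HPF"),
                          pass_through = "CTX")
  expect_equal(sort(unique(passed$cells$region)), c("CTX", "HPF"))
})
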