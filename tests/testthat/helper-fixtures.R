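# Shared fixtures, built once per test session and cached.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, build(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# Tiny hand-checkable dataset: 3 genes x 4 cells, 2 clusters.
tiny_dataset <- function() {
  counts <- matrix(c(1, 0, 3,
                     2, 0, 6,
                     0, 5, 1,
                     0, 4, 2), nrow = 3,
                   dimnames = list(c("g1", "g2", "g3"), NULL))
  expression_dataset("tiny", counts,
                     tibble::tibble(cell_id = paste0("c", 1:4),
                                    cluster = c("k1", "k1", "k2", "k2"),
                                    region = c("HIP", "HIP", "CTX", "CTX")))
}

# Default study conditions: 40 shared types, 60 cells/type, 1500 genes.
default_sim <- function() fixture("default_sim", function() {
  simulate_pair(generator_config())
})

default_views <- function() fixture("default_views", function() {
  s <- default_sim()
  list(a = normalize_log_cpm(s$a), b = normalize_log_cpm(s$b))
})

default_hvg <- function() fixture("default_hvg", function() {
  v <- default_views()
  select_hvgs(list(v$a, v$b))
})

# Full neighbor-voting results on the default pair.
default_match <- function() fixture("default_match", function() {
  s <- default_sim(); v <- default_views(); hvg <- default_hvg()
  rnc_a <- rank_normalize(v$a, hvg)
  rnc_b <- rank_normalize(v$b, hvg)
  votes_ab <- nv_votes(rnc_a, rnc_b)
  votes_ba <- nv_votes(rnc_b, rnc_a)
  ab <- atlasrep:::auroc_from_votes(votes_ab, rnc_b, "atlas_a", "atlas_b")
  ba <- atlasrep:::auroc_from_votes(votes_ba, rnc_a, "atlas_b", "atlas_a")
  sym <- symmetric_auroc(ab, ba)
  pairs <- reciprocal_pair_table(sym, ab, ba, votes_ab, votes_ba,
                                 s$a$cells$cluster, s$b$cells$cluster)
  list(rnc_a = rnc_a, rnc_b = rnc_b, votes_ab = votes_ab, votes_ba = votes_ba,
       ab = ab, ba = ba, sym = sym, pairs = pairs)
})

# Split fixture: every replicable type split into two subclusters in B, plus
# unique clusters on both sides (the similar-clusters regime).
split_config <- function(seed = 1L) {
  generator_config(n_types = 20L, n_split_types = 14L, n_unique_a = 4L,
                   n_unique_b = 2L, n_genes = 1200L,
                   cells_per_type_a = c(50L, 50L),
                   cells_per_type_b = c(50L, 50L), seed = seed)
}

split_sim <- function() fixture("split_sim", function() {
  suppressMessages(simulate_pair(split_config()))
})

split_views <- function() fixture("split_views", function() {
  s <- split_sim()
  list(a = normalize_log_cpm(s$a), b = normalize_log_cpm(s$b))
})

split_match <- function() fixture("split_match", function() {
  s <- split_sim(); v <- split_views()
  hvg <- select_hvgs(list(v$a, v$b))
  rnc_a <- rank_normalize(v$a, hvg)
  rnc_b <- rank_normalize(v$b, hvg)
  votes_ab <- nv_votes(rnc_a, rnc_b)
  votes_ba <- nv_votes(rnc_b, rnc_a)
  ab <- atlasrep:::auroc_from_votes(votes_ab, rnc_b, "atlas_a", "atlas_b")
  ba <- atlasrep:::auroc_from_votes(votes_ba, rnc_a, "atlas_b", "atlas_a")
  sym <- symmetric_auroc(ab, ba)
  pairs <- reciprocal_pair_table(sym, ab, ba, votes_ab, votes_ba,
                                 s$a$cells$cluster, s$b$cells$cluster)
  list(hvg = hvg, ab = ab, ba = ba, sym = sym, pairs = pairs,
       votes_ab = votes_ab, votes_ba = votes_ba)
})

# Default conditions plus planted unique clusters on both sides.
unique_sim <- function() fixture("unique_sim", function() {
  simulate_pair(generator_config(n_unique_a = 2L, n_unique_b = 2L))
})

# Small oracle fixture for brute-force vote checks: ~100 cells per atlas.
small_sim <- function() fixture("small_sim", function() {
  simulate_pair(generator_config(n_types = 5L, n_genes = 300L,
                                 cells_per_type_a = c(20L, 20L),
                                 cells_per_type_b = c(20L, 20L), seed = 3L))
})

# Spatial panel generated from atlas B of the default pair.
default_spatial <- function() fixture("default_spatial", function() {
  s <- default_sim()
  sp <- simulate_spatial_panel(s$b, s$truth, panel_size = 250L, seed = 7L,
                               cells_per_cluster = 20L)
  list(sp = sp, nv = normalize_log_cpm(sp),
       cent_b = compute_centroids(default_views()$b),
       cent_a = compute_centroids(default_views()$a))
})

# Gene-wise permuted copies of the spatial cells: pure noise with matched
# library sizes and marginal count distribution.
noise_spatial <- function() fixture("noise_spatial", function() {
  sp <- default_spatial()$sp
  m <- as.matrix(sp$counts)
  set.seed(424242)
  for (j in seq_len(ncol(m))) m[, j] <- m[sample(nrow(m)), j]
  noise <- sp
  noise$counts <- Matrix::Matrix(m, sparse = TRUE)
  rownames(noise$counts) <- rownames(sp$counts)
  noise
})

expect_tie_free_equal <- function(x, y, tol = 1e-12) {
  expect_true(max(abs(x - y)) <= tol)
}
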