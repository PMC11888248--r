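#' Configuration for the paired synthetic-atlas generator
#'
#' Defines the study conditions for the simulated pair of atlases: two datasets
#' sharing latent cell types, with protocol-specific distortion (per-gene
#' nuclear transcript retention and lower depth in atlas B, emulating
#' single-nucleus profiling), optional types split into two subclusters in B,
#' and optional types unique to one atlas. All randomness fans out from `seed`
#' through named substreams so stages can be regenerated independently.
#'
#' @param n_types Total latent cell types.
#' @param n_genes Number of genes.
#' @param cells_per_type_a,cells_per_type_b Integer range `c(lo, hi)` of cells
#'   per cluster in each atlas.
#' @param depth_a,depth_b Mean library size (total counts) per cell.
#' @param nb_dispersion Negative-binomial dispersion (variance
#'   `mu + dispersion * mu^2`).
#' @param program_effect_sd SD of the per-type log-scale expression effect;
#'   controls how distinct types are.
#' @param retention_range Range `c(lo, hi)` of per-gene nuclear retention
#'   factors applied to atlas B.
#' @param retention_frac Fraction of genes subject to retention loss.
#' @param n_split_types Types represented by two perturbed subclusters in B.
#' @param split_effect_sd SD of the log-scale perturbation separating the two
#'   subclusters of a split type.
#' @param n_unique_a,n_unique_b Types present in only one atlas.
#' @param n_regions,n_slices Number of dissection regions and coronal slices.
#' @param spatial_sd Gaussian scatter (mm) of cells around their type center.
#' @param field_mm Side of the square spatial field (mm).
#' @param n_markers Markers per cluster in the generated catalogs.
#' @param seed Integer master seed.
#' @return A `generator_config` list.
#' @export
generator_config <- function(n_types = 40L, n_genes = 1500L,
                             cells_per_type_a = c(60L, 60L),
                             cells_per_type_b = c(60L, 60L),
                             depth_a = 8000, depth_b = 4000,
                             nb_dispersion = 0.3, program_effect_sd = 1.0,
                             retention_range = c(0.1, 0.7),
                             retention_frac = 0.3,
                             n_split_types = 0L, split_effect_sd = 0.3,
                             n_unique_a = 0L, n_unique_b = 0L,
                             n_regions = 5L, n_slices = 8L,
                             spatial_sd = 0.3, field_mm = 10,
                             n_markers = 4L, seed = 1L) {
  cfg <- as.list(environment())
  if (n_split_types + n_unique_a + n_unique_b > n_types) {
    abort_atlasrep("infeasible config: %d split + %d + %d unique types exceed %d total",
                   n_split_types, n_unique_a, n_unique_b, n_types)
  }
  stopifnot(n_genes > 10, nb_dispersion > 0, program_effect_sd > 0,
            all(retention_range > 0), all(retention_range <= 1),
            retention_frac >= 0, retention_frac <= 1,
            cells_per_type_a[1] >= 1, cells_per_type_b[1] >= 1)
  structure(cfg, class = "generator_config")
}

# Type layout: shared first, then split, then unique-A, then unique-B.
type_layout <- function(cfg) {
  n_shared <- cfg$n_types - cfg$n_split_types - cfg$n_unique_a - cfg$n_unique_b
  types <- sprintf("T%02d", seq_len(cfg$n_types))
  role <- rep(c("shared", "split", "unique_a", "unique_b"),
              c(n_shared, cfg$n_split_types, cfg$n_unique_a, cfg$n_unique_b))
  tibble::tibble(type = types, role = role)
}

#' Simulate a pair of atlases with planted ground truth
#'
#' Generates two expression datasets sharing latent cell-type programs.
#' Per type and gene, a log-normal program mean is drawn; cells draw
#' negative-binomial counts at that mean scaled by a log-normal library size.
#' Atlas B additionally applies per-gene retention factors (a random subset of
#' genes is depleted, emulating the loss of cytoplasmic transcripts in nuclei)
#' and a lower mean depth. Split types appear as one cluster in A and two
#' perturbed subclusters in B. Each type carries a dissection region, a slice
#' and a spatial center; non-replicable types (splits, uniques) are placed in
#' later slices so that slice-level cluster diversity rises where
#' replicability falls.
#'
#' Marker catalogs are generated per atlas: the top `n_markers` genes by
#' log-fold change of the cluster's expected expression against the maximum
#' over all *non-sibling* clusters of the same atlas. Sibling subclusters of a
#' split type therefore share markers, recreating the regime in which markers
#' identify a cluster globally but cannot separate it from its closest
#' neighbor.
#'
#' @param cfg A [generator_config()].
#' @return List with elements `a`, `b` ([expression_dataset()]s, each carrying
#'   the generating programs as an attribute), `truth` (list: `shared_pairs`,
#'   `split_map`, `unique_a`, `unique_b`, `type_table` with per-cluster region,
#'   slice and spatial center), `markers_a`, `markers_b`
#'   ([marker_catalog()]s).
#' @export
simulate_pair <- function(cfg = generator_config()) {
  stopifnot(inherits(cfg, "generator_config"))
  layout <- type_layout(cfg)
  genes <- sprintf("G%04d", seq_len(cfg$n_genes))

  # latent programs (relative expression per type)
  # planted-unique types get twice the between-type spread: a type labelled
  # unique must be unambiguously distinct for the truth table to be true
  prog_t <- with_seed(substream_seed(cfg$seed, "programs"), {
    base <- stats::rnorm(cfg$n_genes, 0, 1)
    vapply(seq_len(cfg$n_types), function(t) {
      sd_t <- cfg$program_effect_sd *
        (if (grepl("unique", layout$role[t])) 2 else 1)
      exp(base + stats::rnorm(cfg$n_genes, 0, sd_t))
    }, numeric(cfg$n_genes))
  })
  colnames(prog_t) <- layout$type
  rownames(prog_t) <- genes
  prog_t <- sweep(prog_t, 2, colSums(prog_t), "/")

  # split children: perturbed copies of the parent program
  split_types <- layout$type[layout$role == "split"]
  child_of <- function(tp, k) sprintf("%s.%d", tp, k)
  prog_children <- with_seed(substream_seed(cfg$seed, "splits"), {
    out <- list()
    for (tp in split_types) {
      for (k in 1:2) {
        p <- prog_t[, tp] * exp(stats::rnorm(cfg$n_genes, 0, cfg$split_effect_sd))
        out[[child_of(tp, k)]] <- p / sum(p)
      }
    }
    out
  })

  # retention factors for atlas B
  retention <- with_seed(substream_seed(cfg$seed, "retention"), {
    r <- rep(1, cfg$n_genes)
    n_aff <- round(cfg$retention_frac * cfg$n_genes)
    if (n_aff > 0) {
      aff <- sample.int(cfg$n_genes, n_aff)
      r[aff] <- stats::runif(n_aff, cfg$retention_range[1], cfg$retention_range[2])
    }
    r
  })
  names(retention) <- genes

  # cluster composition per atlas
  a_clusters <- layout$type[layout$role %in% c("shared", "split", "unique_a")]
  b_parent <- layout$type[layout$role %in% c("shared", "unique_b")]
  b_children <- unlist(lapply(split_types, function(tp) child_of(tp, 1:2)))
  b_clusters <- c(b_parent, b_children %||% character())

  prog_a <- prog_t[, a_clusters, drop = FALSE]
  prog_b_raw <- cbind(prog_t[, b_parent, drop = FALSE],
                      do.call(cbind, prog_children) %||% NULL)
  colnames(prog_b_raw) <- b_clusters
  prog_b <- prog_b_raw * retention  # observed (distorted) B expression, not renormalized

  # spatial layout: later slices accumulate more (and less replicable) types
  type_tab <- with_seed(substream_seed(cfg$seed, "spatial"), {
    i <- seq_len(cfg$n_types)
    tibble::tibble(
      type = layout$type, role = layout$role,
      region = sprintf("R%d", 1L + (i - 1L) %% cfg$n_regions),
      slice = pmax(1L, as.integer(ceiling(cfg$n_slices * sqrt(i / cfg$n_types)))),
      x = stats::runif(cfg$n_types, 0, cfg$field_mm),
      y = stats::runif(cfg$n_types, 0, cfg$field_mm))
  })
  cluster_tab <- dplyr::bind_rows(
    dplyr::mutate(type_tab, cluster = type),
    dplyr::inner_join(tibble::tibble(type = rep(split_types, each = 2),
                                     cluster = b_children %||% character()),
                      type_tab, by = "type"))

  sample_atlas <- function(id, progs, depth, range, stream) {
    with_seed(substream_seed(cfg$seed, stream), {
      mats <- list(); meta <- list()
      for (k in colnames(progs)) {
        n_k <- if (range[1] == range[2]) range[1] else
          sample(seq(range[1], range[2]), 1)
        libs <- stats::rlnorm(n_k, log(depth) - 0.3^2 / 2, 0.3)
        mu <- outer(progs[, k], libs)
        cnt <- matrix(stats::rnbinom(length(mu), mu = as.vector(mu),
                                     size = 1 / cfg$nb_dispersion),
                      nrow = cfg$n_genes)
        mats[[k]] <- cnt
        info <- cluster_tab[cluster_tab$cluster == k, ]
        meta[[k]] <- tibble::tibble(cluster = k, region = info$region,
                                    slice = info$slice)[rep(1, n_k), ]
      }
      counts <- do.call(cbind, mats)
      meta <- dplyr::bind_rows(meta)
      meta$cell_id <- sprintf("%s_c%05d", id, seq_len(nrow(meta)))
      meta$x <- NA_real_; meta$y <- NA_real_
      ds <- expression_dataset(id, Matrix::Matrix(counts, sparse = TRUE),
                               meta[, c("cell_id", "cluster", "region", "slice", "x", "y")],
                               gene_ids = genes)
      ds
    })
  }

  ds_a <- sample_atlas("atlas_a", prog_a, cfg$depth_a, cfg$cells_per_type_a, "cells_a")
  ds_b <- sample_atlas("atlas_b", prog_b, cfg$depth_b, cfg$cells_per_type_b, "cells_b")
  attr(ds_a, "programs") <- prog_a
  attr(ds_b, "programs") <- prog_b
  attr(ds_a, "config") <- cfg
  attr(ds_b, "config") <- cfg

  shared_types <- layout$type[layout$role == "shared"]
  truth <- list(
    shared_pairs = tibble::tibble(cluster_a = shared_types, cluster_b = shared_types),
    split_map = tibble::tibble(cluster_a = rep(split_types, each = 2),
                               cluster_b = b_children %||% character()),
    unique_a = layout$type[layout$role == "unique_a"],
    unique_b = layout$type[layout$role == "unique_b"],
    type_table = cluster_tab[, c("cluster", "type", "role", "region", "slice", "x", "y")],
    retention = retention)

  siblings_b <- stats::setNames(
    lapply(b_clusters, function(k) {
      tp <- sub("\\.\\d$", "", k)
      setdiff(grep(paste0("^", tp, "\\."), b_clusters, value = TRUE), k)
    }), b_clusters)
  # markers describe the latent type, not the subcluster: children of a split
  # type get markers selected from the parent program, so siblings share them
  prog_b_marker <- vapply(b_clusters, function(k) {
    prog_t[, sub("\\.\\d$", "", k)] * retention
  }, numeric(cfg$n_genes))
  rownames(prog_b_marker) <- genes
  markers_a <- plant_markers(prog_a, cfg$n_markers, siblings = NULL, source = "atlas_a")
  markers_b <- plant_markers(prog_b_marker, cfg$n_markers, siblings = siblings_b,
                             source = "atlas_b")

  list(a = ds_a, b = ds_b, truth = truth, markers_a = markers_a, markers_b = markers_b)
}

# Top-m genes per cluster by log fold change against the maximum over
# non-sibling clusters of the same atlas.
plant_markers <- function(progs, m, siblings = NULL, source = "synthetic") {
  eps <- 1e-12
  sets <- lapply(colnames(progs), function(k) {
    rivals <- setdiff(colnames(progs), c(k, siblings[[k]]))
    fc <- log(progs[, k] + eps) - log(apply(progs[, rivals, drop = FALSE], 1, max) + eps)
    rownames(progs)[order(fc, decreasing = TRUE)[seq_len(m)]]
  })
  names(sets) <- colnames(progs)
  marker_catalog(sets, source = source)
}

#' Simulate a reduced-gene-panel spatial dataset
#'
#' Emulates an imaging-based spatial transcriptomics experiment: cells of each
#' cluster are scattered around the cluster's planted spatial center, and
#' expression is drawn from the cluster's generating program restricted to a
#' random gene panel, with per-cell-per-gene log-normal noise on the mean.
#' Cluster labels are retained as ground truth.
#'
#' @param ds An atlas produced by [simulate_pair()] (carries its programs).
#' @param truth The matching truth list.
#' @param panel_size Number of genes in the panel.
#' @param noise_sd Log-scale SD of the multiplicative mean noise.
#' @param seed Integer seed.
#' @param cells_per_cluster Spatial cells per cluster.
#' @param depth Mean panel counts per cell.
#' @return An [expression_dataset()] with coordinates, restricted to the panel.
#' @export
simulate_spatial_panel <- function(ds, truth, panel_size, noise_sd = 0.2,
                                   seed = 1L, cells_per_cluster = 30L,
                                   depth = 2000) {
  progs <- attr(ds, "programs")
  cfg <- attr(ds, "config")
  if (is.null(progs)) abort_atlasrep("dataset carries no generating programs")
  if (panel_size > nrow(progs)) abort_atlasrep("panel_size exceeds gene count")
  with_seed(seed, {
    panel <- sort(sample(rownames(progs), panel_size))
    mats <- list(); meta <- list()
    disp <- cfg$nb_dispersion
    for (k in colnames(progs)) {
      q <- progs[panel, k]
      q <- q / sum(q)
      noise <- if (noise_sd > 0) {
        matrix(exp(stats::rnorm(length(q) * cells_per_cluster,
                                -noise_sd^2 / 2, noise_sd)),
               nrow = length(q))
      } else 1
      mu <- q * depth * noise
      if (!is.matrix(mu)) mu <- matrix(mu, nrow = length(q), ncol = cells_per_cluster)
      cnt <- matrix(stats::rnbinom(length(mu), mu = as.vector(mu), size = 1 / disp),
                    nrow = length(q))
      info <- truth$type_table[truth$type_table$cluster == k, ]
      meta[[k]] <- tibble::tibble(
        cluster = k, region = info$region, slice = info$slice,
        x = stats::rnorm(cells_per_cluster, info$x, cfg$spatial_sd),
        y = stats::rnorm(cells_per_cluster, info$y, cfg$spatial_sd))
      mats[[k]] <- cnt
    }
    counts <- do.call(cbind, mats)
    meta <- dplyr::bind_rows(meta)
    meta$cell_id <- sprintf("sp_%s_c%05d", ds$dataset_id, seq_len(nrow(meta)))
    sp <- expression_dataset(paste0("spatial_", ds$dataset_id),
                             Matrix::Matrix(counts, sparse = TRUE),
                             meta[, c("cell_id", "cluster", "region", "slice", "x", "y")],
                             gene_ids = panel)
    attr(sp, "panel") <- panel
    sp
  })
}

#' Shuffle cluster labels to create a null dataset
#'
#' Permutes the cluster labels uniformly at random across cells, leaving
#' expression untouched. Used for calibration: every replicability statistic
#' should fall to chance level on the result.
#'
#' @param ds An [expression_dataset()].
#' @param seed Integer seed.
#' @return The dataset with permuted cluster labels.
#' @export
degrade_to_null <- function(ds, seed = 1L) {
  ds$cells$cluster <- with_seed(seed, sample(ds$cells$cluster))
  ds
}
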