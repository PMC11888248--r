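# End-to-end orchestration: simulate -> prepare -> match -> markers ->
# map_cells -> coexpr -> enrich, with a manifest and resumable stages.

# 32-bit FNV-1a over serialized R objects; cheap content hash for the manifest.
hash_obj <- function(x) {
  bytes <- serialize(x, NULL, version = 2)
  h <- 2166136261
  for (b in as.integer(bytes)) {
    h <- bitwXor(h, b)
    h <- (h * 16777619) %% 4294967296
  }
  sprintf("%08x", h)
}

write_tsv_prov <- function(x, path, run_hash, seed) {
  header <- sprintf("# atlasrep %s run=%s seed=%d",
                    as.character(utils::packageVersion("atlasrep")), run_hash, seed)
  writeLines(header, path)
  readr::write_tsv(x, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' Default pipeline configuration
#'
#' Assembles the full run configuration with one master seed fanned out to
#' named substreams. Any element can be overridden; [read_pipeline_config()]
#' loads the same structure from a YAML file.
#'
#' @param out_dir Output directory for all stage artifacts.
#' @param seed Master integer seed.
#' @param simulate Named list of [generator_config()] overrides.
#' @param hvg List: `n_bins`, `quantile`.
#' @param calling List: `panel_size`, `noise_sd`, `cells_per_cluster`,
#'   `n_rounds`, `subsample_frac`, `threshold`.
#' @param coexpr List: `fractions`, `n_rep`.
#' @param enrich List: `min_clusters`.
#' @return A `run_config` list.
#' @export
pipeline_config <- function(out_dir, seed = 1L, simulate = list(),
                            hvg = list(), calling = list(), coexpr = list(),
                            enrich = list()) {
  merge_list <- function(base, extra) utils::modifyList(base, extra)
  cfg <- list(
    out_dir = out_dir, seed = as.integer(seed),
    simulate = simulate,
    hvg = merge_list(list(n_bins = 10L, quantile = 0.75), hvg),
    calling = merge_list(list(panel_size = 250L, noise_sd = 0.2,
                              cells_per_cluster = 20L, n_rounds = 25L,
                              subsample_frac = 0.8, threshold = 0.5), calling),
    coexpr = merge_list(list(fractions = c(0.25, 0.5, 1), n_rep = 20L), coexpr),
    enrich = merge_list(list(min_clusters = 5L), enrich))
  structure(cfg, class = "run_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file; keys mirror [pipeline_config()] arguments.
#' @param out_dir Optional override of the configured output directory.
#' @return A `run_config` list.
#' @export
read_pipeline_config <- function(path, out_dir = NULL) {
  y <- yaml::read_yaml(path)
  cfg <- pipeline_config(out_dir %||% y$out_dir %||% "atlasrep_run",
                         seed = y$seed %||% 1L,
                         simulate = y$simulate %||% list(),
                         hvg = y$hvg %||% list(),
                         calling = y$calling %||% list(),
                         coexpr = y$coexpr %||% list(),
                         enrich = y$enrich %||% list())
  cfg
}

pipeline_stages <- c("simulate", "prepare", "match", "markers",
                     "map_cells", "coexpr", "enrich")

stage_outputs <- function(cfg, stage) {
  d <- file.path(cfg$out_dir, stage)
  file.path(d, switch(stage,
    simulate = c("atlas_a.mtx", "atlas_a_genes.tsv", "atlas_a_cells.tsv",
                 "atlas_b.mtx", "atlas_b_genes.tsv", "atlas_b_cells.tsv",
                 "spatial.mtx", "spatial_genes.tsv", "spatial_cells.tsv",
                 "truth.tsv", "type_table.tsv", "markers_a.tsv", "markers_b.tsv"),
    prepare = "hvgs.tsv",
    match = c("auroc_ab.tsv", "auroc_ba.tsv", "auroc_sym.tsv",
              "reciprocal_pairs.tsv"),
    markers = c("marker_stats_a.tsv", "marker_stats_b.tsv",
                "marker_pairing.tsv", "marker_overlap.tsv"),
    map_cells = c("calls_a.tsv", "calls_b.tsv", "concordance_slices.tsv",
                  "region_enrichment.tsv", "centroid_distances.tsv",
                  "top_region_match.tsv", "diversity_mismatch.tsv"),
    coexpr = c("coord_expr.tsv", "subsample_curves.tsv"),
    enrich = "class_enrichment.tsv"))
}

read_stage_datasets <- function(cfg) {
  d <- file.path(cfg$out_dir, "simulate")
  list(a = read_dataset(file.path(d, "atlas_a.mtx"), file.path(d, "atlas_a_genes.tsv"),
                        file.path(d, "atlas_a_cells.tsv"), dataset_id = "atlas_a"),
       b = read_dataset(file.path(d, "atlas_b.mtx"), file.path(d, "atlas_b_genes.tsv"),
                        file.path(d, "atlas_b_cells.tsv"), dataset_id = "atlas_b"))
}

read_stage_pairs <- function(cfg) {
  readr::read_tsv(file.path(cfg$out_dir, "match", "reciprocal_pairs.tsv"),
                  show_col_types = FALSE, comment = "#")
}

run_stage <- function(cfg, stage, run_hash) {
  d <- file.path(cfg$out_dir, stage)
  dir.create(d, showWarnings = FALSE, recursive = TRUE)
  seed <- cfg$seed
  wt <- function(x, f) write_tsv_prov(x, file.path(d, f), run_hash, seed)

  if (stage == "simulate") {
    gcfg <- do.call(generator_config,
                    utils::modifyList(cfg$simulate, list(seed = substream_seed(seed, "generator"))))
    sim <- simulate_pair(gcfg)
    write_dataset(sim$a, d); write_dataset(sim$b, d)
    sp <- simulate_spatial_panel(sim$b, sim$truth,
                                 panel_size = cfg$calling$panel_size,
                                 noise_sd = cfg$calling$noise_sd,
                                 seed = substream_seed(seed, "spatial_panel"),
                                 cells_per_cluster = cfg$calling$cells_per_cluster)
    write_dataset(sp, d, stem = "spatial")
    truth_tab <- dplyr::bind_rows(
      dplyr::mutate(sim$truth$shared_pairs, pair_type = "shared"),
      dplyr::mutate(sim$truth$split_map, pair_type = "split"),
      tibble::tibble(cluster_a = sim$truth$unique_a, cluster_b = NA_character_,
                     pair_type = "unique_a"),
      tibble::tibble(cluster_a = NA_character_, cluster_b = sim$truth$unique_b,
                     pair_type = "unique_b"))
    wt(truth_tab, "truth.tsv")
    wt(sim$truth$type_table, "type_table.tsv")
    write_marker_catalog(sim$markers_a, file.path(d, "markers_a.tsv"))
    write_marker_catalog(sim$markers_b, file.path(d, "markers_b.tsv"))
  } else if (stage == "prepare") {
    ds <- read_stage_datasets(cfg)
    hvg <- select_hvgs(list(normalize_log_cpm(ds$a), normalize_log_cpm(ds$b)),
                       n_bins = cfg$hvg$n_bins, quantile = cfg$hvg$quantile)
    write_hvgs(hvg, file.path(cfg$out_dir, "prepare", "hvgs.tsv"))
  } else if (stage == "match") {
    ds <- read_stage_datasets(cfg)
    hvg <- read_hvgs(file.path(cfg$out_dir, "prepare", "hvgs.tsv"))
    nv_a <- normalize_log_cpm(ds$a); nv_b <- normalize_log_cpm(ds$b)
    rnc_a <- rank_normalize(nv_a, hvg); rnc_b <- rank_normalize(nv_b, hvg)
    votes_ab <- nv_votes(rnc_a, rnc_b)  # B cells x A clusters
    votes_ba <- nv_votes(rnc_b, rnc_a)
    ab <- auroc_from_votes(votes_ab, rnc_b, "atlas_a", "atlas_b")
    ba <- auroc_from_votes(votes_ba, rnc_a, "atlas_b", "atlas_a")
    sym <- symmetric_auroc(ab, ba)
    pairs <- reciprocal_pair_table(sym, ab, ba, votes_ab, votes_ba,
                                   labels_a = ds$a$cells$cluster,
                                   labels_b = ds$b$cells$cluster)
    write_auroc_table(ab, file.path(d, "auroc_ab.tsv"))
    write_auroc_table(ba, file.path(d, "auroc_ba.tsv"))
    write_auroc_table(sym, file.path(d, "auroc_sym.tsv"))
    wt(pairs, "reciprocal_pairs.tsv")
  } else if (stage == "markers") {
    ds <- read_stage_datasets(cfg)
    sim_d <- file.path(cfg$out_dir, "simulate")
    cat_a <- read_marker_catalog(file.path(sim_d, "markers_a.tsv"), "atlas_a")
    cat_b <- read_marker_catalog(file.path(sim_d, "markers_b.tsv"), "atlas_b")
    nv_a <- normalize_log_cpm(ds$a); nv_b <- normalize_log_cpm(ds$b)
    for (side in c("a", "b")) {
      dsx <- ds[[side]]
      nvx <- if (side == "a") nv_a else nv_b
      catx <- if (side == "a") cat_a else cat_b
      mam <- marker_auroc_matrix(dsx, catx, nv = nvx)
      wt(marker_local_aurocs(dsx, mam), sprintf("marker_stats_%s.tsv", side))
    }
    wt(marker_based_pairing(cat_a, ds$b, nv_b = nv_b), "marker_pairing.tsv")
    overlap <- marker_overlap_pairs(cat_a, cat_b,
                                    universe_size = length(intersect(gene_ids(ds$a),
                                                                     gene_ids(ds$b))),
                                    correction = "per-atlas")
    wt(overlap, "marker_overlap.tsv")
  } else if (stage == "map_cells") {
    ds <- read_stage_datasets(cfg)
    sim_d <- file.path(cfg$out_dir, "simulate")
    sp <- read_dataset(file.path(sim_d, "spatial.mtx"),
                       file.path(sim_d, "spatial_genes.tsv"),
                       file.path(sim_d, "spatial_cells.tsv"), dataset_id = "spatial")
    nv_sp <- normalize_log_cpm(sp)
    pairs <- read_stage_pairs(cfg)
    calls <- lapply(c(a = "a", b = "b"), function(side) {
      cents <- compute_centroids(normalize_log_cpm(ds[[side]]))
      call_cells(nv_sp, cents, n_rounds = cfg$calling$n_rounds,
                 subsample_frac = cfg$calling$subsample_frac,
                 threshold = cfg$calling$threshold,
                 seed = substream_seed(cfg$seed, paste0("calling_", side)),
                 reference_id = ds[[side]]$dataset_id)
    })
    conc <- pair_concordance(calls$a, calls$b, pairs)
    wt(calls$a, "calls_a.tsv"); wt(calls$b, "calls_b.tsv")
    wt(conc$slices, "concordance_slices.tsv")
    wt(region_enrichment(conc$cells, min_cells = 20L), "region_enrichment.tsv")
    wt(paired_centroid_distance(calls$a, calls$b, pairs), "centroid_distances.tsv")
    wt(top_region_match(ds$a, ds$b, pairs), "top_region_match.tsv")
    wt(diversity_mismatch(calls$a, calls$b,
                          seed = substream_seed(cfg$seed, "diversity")),
       "diversity_mismatch.tsv")
  } else if (stage == "coexpr") {
    ds <- read_stage_datasets(cfg)
    hvg <- read_hvgs(file.path(cfg$out_dir, "prepare", "hvgs.tsv"))
    pairs <- read_stage_pairs(cfg)
    nv_a <- normalize_log_cpm(ds$a); nv_b <- normalize_log_cpm(ds$b)
    coord <- coordinated_expression(nv_a, nv_b, pairs, exclude = hvg)
    mats <- paired_centroid_matrices(nv_a, nv_b, pairs, exclude = hvg)
    curves <- subsample_curves(mats$a, mats$b, fractions = cfg$coexpr$fractions,
                               n_rep = cfg$coexpr$n_rep,
                               seed = substream_seed(cfg$seed, "subsample"))
    wt(coord, "coord_expr.tsv")
    wt(curves, "subsample_curves.tsv")
  } else if (stage == "enrich") {
    sim_d <- file.path(cfg$out_dir, "simulate")
    type_tab <- readr::read_tsv(file.path(sim_d, "type_table.tsv"),
                                show_col_types = FALSE, comment = "#")
    pairs <- read_stage_pairs(cfg)
    ann <- type_tab |>
      dplyr::filter(!grepl("\\.", .data$cluster)) |>  # atlas A clusters
      dplyr::transmute(cluster = .data$cluster, class = .data$region)
    wt(class_enrichment(pairs, ann, min_clusters = cfg$enrich$min_clusters),
       "class_enrichment.tsv")
  }
  invisible(TRUE)
}

#' Run the full replicability pipeline
#'
#' Executes the stages simulate, prepare, match, markers, map_cells, coexpr
#' and enrich in order, writing TSV/JSON artifacts plus a manifest
#' (`manifest.json`) recording parameters, seeds, content hashes and which
#' stages were executed. With `resume = TRUE`, stages whose outputs exist and
#' whose input hash is unchanged are skipped, so deleting an intermediate
#' recomputes only that stage and everything downstream. A rerun with the
#' same configuration reproduces all outputs.
#'
#' @param cfg A [pipeline_config()] (or [read_pipeline_config()]) object.
#' @param resume Skip up-to-date stages (default `FALSE`).
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(cfg, resume = FALSE) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest_path <- file.path(cfg$out_dir, "manifest.json")
  old <- if (resume && file.exists(manifest_path)) {
    jsonlite::read_json(manifest_path, simplifyVector = FALSE)
  } else NULL
  stages <- list()
  upstream_hash <- hash_obj(list(seed = cfg$seed))
  upstream_executed <- FALSE
  for (stage in pipeline_stages) {
    params <- cfg[[stage]] %||% list()
    stage_hash <- hash_obj(list(stage = stage, params = params,
                                upstream = upstream_hash))
    outputs <- stage_outputs(cfg, stage)
    old_hash <- if (!is.null(old)) {
      rec <- Filter(function(s) s$name == stage, old$stages)
      if (length(rec)) rec[[1]]$hash else NULL
    } else NULL
    up_to_date <- resume && !upstream_executed &&
      identical(old_hash, stage_hash) && all(file.exists(outputs))
    if (!up_to_date) {
      ok <- tryCatch(run_stage(cfg, stage, stage_hash), error = function(e) e)
      if (inherits(ok, "error")) {
        stages[[stage]] <- list(name = stage, hash = stage_hash,
                                executed = TRUE, status = "failed",
                                error = conditionMessage(ok))
        manifest <- list(config_hash = hash_obj(unclass(cfg)), seed = cfg$seed,
                         stages = unname(stages))
        jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, pretty = TRUE)
        abort_atlasrep("pipeline stage '%s' failed: %s", stage, conditionMessage(ok))
      }
    }
    stages[[stage]] <- list(name = stage, hash = stage_hash,
                            executed = !up_to_date, status = "complete",
                            outputs = basename(outputs))
    upstream_hash <- stage_hash
    upstream_executed <- upstream_executed || !up_to_date
  }
  manifest <- list(package_version = as.character(utils::packageVersion("atlasrep")),
                   config_hash = hash_obj(unclass(cfg)), seed = cfg$seed,
                   stages = unname(stages))
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

#' Class enrichment of reciprocal clusters
#'
#' Given a cluster-to-class annotation for one atlas, tests each class for
#' over-representation of reciprocal clusters with an upper-tail
#' hypergeometric test, BH-adjusted across classes. Classes with fewer than
#' `min_clusters` clusters are dropped.
#'
#' @param pairs Reciprocal-pair tibble (uses `cluster_a`; pass a renamed
#'   table to annotate the other atlas).
#' @param annotation Tibble: `cluster`, `class`, covering the atlas clusters.
#' @param min_clusters Minimum class size (default 10).
#' @return Tibble: `class`, `n_clusters`, `n_reciprocal`, `p_value`, `p_adj`.
#' @export
class_enrichment <- function(pairs, annotation, min_clusters = 10L) {
  rec <- unique(pairs$cluster_a)
  n_total <- nrow(annotation)
  n_rec <- sum(annotation$cluster %in% rec)
  res <- annotation |>
    dplyr::group_by(.data$class) |>
    dplyr::summarise(n_clusters = dplyr::n(),
                     n_reciprocal = sum(.data$cluster %in% rec),
                     .groups = "drop") |>
    dplyr::filter(.data$n_clusters >= min_clusters)
  if (!nrow(res)) return(dplyr::mutate(res, p_value = numeric(0), p_adj = numeric(0)))
  res$p_value <- purrr::pmap_dbl(res, function(class, n_clusters, n_reciprocal) {
    hypergeom_overlap_test(n_reciprocal, n_clusters, n_rec, n_total)$p_value
  })
  res$p_adj <- adjust_p(res$p_value, "bh")
  res
}
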