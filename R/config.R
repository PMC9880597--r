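#' Pipeline configuration
#'
#' Bundles every tunable threshold of the processing pipeline in one
#' validated list.  Defaults follow the filtering and feature-selection
#' choices used throughout the package: cells with fewer than 2,000 UMIs or
#' more than 15% mitochondrial UMIs are removed, the top 2,000 variable
#' genes feed the 20-component PCA, clustering uses a k = 15 neighbour graph
#' at resolution 1, cluster annotations require a 2% label share, large
#' groups are subsampled to 2,000 cells before differential testing, and
#' differentially expressed genes need a fold change above 2 at adjusted
#' p below 0.05.
#'
#' @param min_umis Minimum UMI count; cells with strictly fewer are removed.
#' @param max_mito_frac Maximum mitochondrial UMI fraction; cells strictly
#'   above are removed.
#' @param n_hvg Number of highly variable genes to select.
#' @param n_pcs Number of principal components for the cell representation.
#' @param knn_k Neighbours per cell in the kNN graph.
#' @param cluster_resolution Louvain resolution parameter.
#' @param anchor_k Genes taken per anchor per direction when building the
#'   marker panel.
#' @param min_label_frac Minimum fraction of a cluster a reference label
#'   must cover to be transferred.
#' @param de_subsample Maximum cells per group in differential testing;
#'   larger groups are downsampled (seeded).
#' @param fc_threshold Fold-change threshold (ratio scale) for the DEG flag.
#' @param alpha Adjusted-p significance level.
#' @param cpt_scale Per-cell normalisation target (counts per thousand).
#' @param n_perm Permutations for enrichment-score and localization p values.
#' @param rng_seed Integer seed for every stochastic step.
#'
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(min_umis = 2000,
                            max_mito_frac = 0.15,
                            n_hvg = 2000,
                            n_pcs = 20,
                            knn_k = 15,
                            cluster_resolution = 1.0,
                            anchor_k = 10,
                            min_label_frac = 0.02,
                            de_subsample = 2000,
                            fc_threshold = 2.0,
                            alpha = 0.05,
                            cpt_scale = 1000,
                            n_perm = 1000,
                            rng_seed = 0L) {
  cfg <- list(min_umis = min_umis, max_mito_frac = max_mito_frac,
              n_hvg = n_hvg, n_pcs = n_pcs, knn_k = knn_k,
              cluster_resolution = cluster_resolution, anchor_k = anchor_k,
              min_label_frac = min_label_frac, de_subsample = de_subsample,
              fc_threshold = fc_threshold, alpha = alpha,
              cpt_scale = cpt_scale, n_perm = n_perm,
              rng_seed = as.integer(rng_seed))
  validate_config(cfg)
  class(cfg) <- "pipeline_config"
  cfg
}

validate_config <- function(cfg) {
  pos <- c("min_umis", "n_hvg", "n_pcs", "knn_k", "cluster_resolution",
           "anchor_k", "de_subsample", "fc_threshold", "cpt_scale", "n_perm")
  for (f in pos) {
    assert_that(is.numeric(cfg[[f]]) && length(cfg[[f]]) == 1 && cfg[[f]] > 0,
                sprintf("config field '%s' must be a positive scalar", f))
  }
  for (f in c("max_mito_frac", "min_label_frac", "alpha")) {
    assert_that(is.numeric(cfg[[f]]) && cfg[[f]] > 0 && cfg[[f]] < 1,
                sprintf("config field '%s' must lie in (0, 1)", f))
  }
  invisible(cfg)
}

#' Read or write a pipeline configuration as YAML
#'
#' @param path File path.
#' @return `read_config` returns a `pipeline_config`; `write_config` returns
#'   the path invisibly.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0) {
    warning("ignoring unknown config fields: ", paste(unknown, collapse = ", "))
  }
  do.call(pipeline_config, raw[intersect(names(raw), known)])
}

#' @rdname read_config
#' @param config A `pipeline_config`.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}
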