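#' The fixed Shh-responsive gene panel
#'
#' Nine genes whose expression responds to Shh signalling in the
#' developing diencephalon; their collective position in a fold-change
#' ranking is the Shh response score.
#'
#' @return Character vector of 9 gene symbols.
#' @export
shh_panel <- function() {
  c("Gli1", "Ptch1", "Olig2", "Nkx2-2", "Pdlim3", "Fst", "Zdbf2",
    "Hs3st1", "Slc38a11")
}

#' PCA cell representation
#'
#' The low-dimensional representation used for neighbour graphs and
#' clustering: log-CPT of the top variable genes, per-gene centred and
#' scaled, projected on the top principal components.
#'
#' @param counts Gene-by-cell raw count matrix (QC-filtered).
#' @param config A [pipeline_config()].
#' @return A cells x `n_pcs` numeric matrix with barcode rownames.
#' @export
pca_representation <- function(counts, config = pipeline_config()) {
  n_hvg <- min(config$n_hvg, nrow(counts))
  hvg <- select_variable_genes(counts, n_hvg = n_hvg)
  logcpt <- normalize_cpt(counts, config, log1p = TRUE)
  m <- t(as.matrix(logcpt[hvg, , drop = FALSE]))
  keep <- apply(m, 2, sd) > 0
  m <- scale(m[, keep, drop = FALSE])
  n_pcs <- min(config$n_pcs, ncol(m), nrow(m) - 1)
  pr <- prcomp(m, center = FALSE, scale. = FALSE, rank. = n_pcs)
  emb <- pr$x
  rownames(emb) <- colnames(counts)
  emb
}

#' Symmetrised k-nearest-neighbour graph
#'
#' Euclidean kNN in the supplied representation; an undirected edge joins
#' two cells when either is among the other's k nearest.  Ties at the k-th
#' neighbour are broken by cell index.
#'
#' @param representation Cells x dims numeric matrix.
#' @param k Neighbours per cell; must be positive and below the cell count.
#' @return An undirected `igraph` graph whose vertex names are the
#'   representation's rownames.
#' @export
build_knn_graph <- function(representation, k) {
  n <- nrow(representation)
  assert_that(is_count(k) && k > 0, "k must be a positive integer")
  assert_that(k < n, "k must be smaller than the number of cells")
  assert_that(all(is.finite(representation)),
              "representation must be finite")
  d <- as.matrix(stats::dist(representation))
  edges <- integer(0)
  for (i in seq_len(n)) {
    ord <- order(d[i, -i], seq_len(n)[-i])  # index breaks distance ties
    nb <- (seq_len(n)[-i])[ord][seq_len(k)]
    edges <- c(edges, rbind(i, nb))
  }
  g <- igraph::graph_from_edgelist(matrix(edges, ncol = 2, byrow = TRUE),
                                   directed = FALSE)
  g <- igraph::simplify(g)
  if (igraph::vcount(g) < n) {
    g <- igraph::add_vertices(g, n - igraph::vcount(g))
  }
  igraph::V(g)$name <- rownames(representation) %||% as.character(seq_len(n))
  g
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Louvain clustering of the cell graph
#'
#' Modularity-maximising Louvain partition at the given resolution; the
#' seed pins the stochastic refinement so a partition is reproducible.
#'
#' @param graph An undirected `igraph` graph over cells.
#' @param resolution Louvain resolution parameter.
#' @param seed Integer seed.
#' @return A list of class `cluster_partition`: `membership` (named
#'   integer vector, dense cluster ids from 0), `modularity`, and the
#'   parameters used.
#' @export
cluster_cells <- function(graph, resolution = 1.0, seed = 0L) {
  assert_that(igraph::vcount(graph) > 0, "empty graph")
  cl <- with_rng(seed,
                 igraph::cluster_louvain(graph, resolution = resolution))
  memb <- igraph::membership(cl)
  memb <- as.integer(factor(memb)) - 1L   # dense ids from 0
  names(memb) <- igraph::V(graph)$name
  structure(list(membership = memb,
                 modularity = max(igraph::modularity(cl)),
                 resolution = resolution, seed = as.integer(seed)),
            class = "cluster_partition")
}

#' Transfer reference annotations through a joint clustering
#'
#' Each cluster collects every reference label carried by at least
#' `min_frac` of its cells (2% by default); cells without a reference
#' label inherit their cluster's label set.  Clusters where no label
#' reaches the bar are `"unlabeled"`.
#'
#' @param partition A [cluster_cells()] partition over all cells.
#' @param reference Named character vector, barcode -> reference label,
#'   covering a subset of the partitioned cells.
#' @param min_frac Minimum fraction of a cluster a label must cover.
#' @return A list: `cluster_labels` (data.frame cluster, label, frac) and
#'   `cell_labels` (named list, barcode -> character vector of labels).
#' @export
transfer_labels <- function(partition, reference, min_frac = 0.02) {
  assert_that(min_frac > 0 && min_frac < 1,
              "min_frac must lie in (0, 1)")
  memb <- partition$membership
  rows <- list()
  sets <- list()
  for (cl in sort(unique(memb))) {
    bcs <- names(memb)[memb == cl]
    labs <- reference[intersect(bcs, names(reference))]
    keep <- character(0)
    if (length(labs) > 0) {
      frac <- table(labs) / length(bcs)
      frac <- sort(frac, decreasing = TRUE)
      keep <- names(frac)[frac >= min_frac]
      if (length(keep) > 0) {
        rows[[as.character(cl)]] <- data.frame(
          cluster = cl, label = keep, frac = as.numeric(frac[keep]),
          stringsAsFactors = FALSE)
      }
    }
    sets[[as.character(cl)]] <- if (length(keep) > 0) keep else "unlabeled"
  }
  cluster_labels <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(cluster = integer(0), label = character(0),
               frac = numeric(0))
  rownames(cluster_labels) <- NULL
  cell_labels <- lapply(memb, function(cl) sets[[as.character(cl)]])
  # annotated cells keep their own reference label
  unannot <- setdiff(names(memb), names(reference))
  for (bc in intersect(names(memb), names(reference))) {
    cell_labels[[bc]] <- unname(reference[bc])
  }
  list(cluster_labels = cluster_labels, cell_labels = cell_labels,
       unannotated = unannot)
}

# Unweighted running-sum enrichment statistic from hit positions: walking
# the ranked list, hits add 1/Nh, misses subtract 1/(N - Nh); the score is
# the running sum's most extreme excursion (signed).
es_from_positions <- function(pos, n_total) {
  nh <- length(pos)
  pos <- sort(pos)
  step_hit <- 1 / nh
  step_miss <- 1 / (n_total - nh)
  idx <- seq_len(nh)
  # value just after each hit, and just before each hit
  after <- idx * step_hit - (pos - idx) * step_miss
  before <- (idx - 1) * step_hit - (pos - idx) * step_miss
  hi <- max(after, 0)
  lo <- min(before, 0)
  if (hi >= -lo) hi else lo
}

#' Shh response score of a fold-change ranking
#'
#' Ranks all genes by decreasing log fold change and computes the classic
#' unweighted running-sum enrichment score of the Shh-responsive panel:
#' panel hits increment the running sum by `1/Nh`, misses decrement it by
#' `1/(N - Nh)`, and the score is the most extreme excursion (so it lies
#' in `[-1, 1]`, +1 when all panel genes lead the ranking and -1 when they
#' all trail).  The p value is the one-sided fraction of seeded random
#' panel placements whose score reaches the observed one.
#'
#' @param de_table data.frame with columns `gene` and `log2fc` (control vs
#'   mutant fold changes).
#' @param panel Character vector of panel genes (default [shh_panel()]).
#' @param n_perm Number of label permutations for the p value.
#' @param seed Integer seed for the permutations.
#' @return A list: `es`, `p`, `n_hits`, `n_genes`, `n_perm`, `seed`.
#' @export
shh_response_score <- function(de_table, panel = shh_panel(),
                               n_perm = 1000, seed = 0L) {
  assert_that(all(c("gene", "log2fc") %in% colnames(de_table)),
              "de_table needs columns 'gene' and 'log2fc'")
  assert_that(all(is.finite(de_table$log2fc)),
              "fold changes must be finite")
  ranked <- de_table$gene[order(-de_table$log2fc)]
  n <- length(ranked)
  hits <- which(ranked %in% panel)
  assert_that(length(hits) > 0, "no panel gene present in de_table")
  assert_that(n > length(hits), "de_table must contain non-panel genes")
  es <- es_from_positions(hits, n)
  perm_es <- with_rng(seed, vapply(seq_len(n_perm), function(i) {
    es_from_positions(sample.int(n, length(hits)), n)
  }, numeric(1)))
  p <- (1 + sum(perm_es >= es)) / (n_perm + 1)
  list(es = es, p = p, n_hits = length(hits), n_genes = n,
       n_perm = n_perm, seed = as.integer(seed))
}
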