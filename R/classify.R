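#' Feature panel for semi-supervised progenitor classification
#'
#' A panel of genes selected by correlation with a small set of anchor
#' markers, partitioned into per-subpopulation gene sets, together with
#' the rostro-caudal order of the subpopulation labels used to break ties.
#'
#' @param gene_sets Named list mapping subpopulation label -> character
#'   vector of genes.
#' @param subpop_order Label order from rostral to caudal; ties in cell
#'   assignment go to the most rostral label.
#' @param panel_table Optional data.frame (anchor, direction, gene, r)
#'   recording how the panel was derived.
#' @return A list of class `feature_panel`.
#' @export
feature_panel <- function(gene_sets, subpop_order = names(gene_sets),
                         panel_table = NULL) {
  assert_that(length(gene_sets) > 0 && !is.null(names(gene_sets)),
              "gene_sets must be a named list")
  assert_that(all(lengths(gene_sets) > 0), "gene sets must be non-empty")
  assert_that(!anyDuplicated(names(gene_sets)),
              "subpopulation labels must be unique")
  assert_that(setequal(subpop_order, names(gene_sets)),
              "subpop_order must be a permutation of the gene-set labels")
  structure(list(gene_sets = gene_sets, subpop_order = subpop_order,
                 panel_genes = unique(unlist(gene_sets, use.names = FALSE)),
                 panel_table = panel_table),
            class = "feature_panel")
}

#' Default progenitor panel matching the simulator's domains
#'
#' Gene sets are the anchor-plus-marker blocks of [default_domains()], in
#' rostro-caudal order.
#'
#' @return A `feature_panel`.
#' @export
default_feature_panel <- function() {
  doms <- default_domains()
  sets <- lapply(doms, function(d) c(d$anchor_gene, d$marker_genes))
  names(sets) <- vapply(doms, `[[`, "", "name")
  feature_panel(sets)
}

#' Anchors of the rostro-caudal progenitor axis
#' @return Character vector `c("Nkx2-2", "Olig2", "Dbx1", "Rspo3")`.
#' @export
default_anchors <- function() c("Nkx2-2", "Olig2", "Dbx1", "Rspo3")

#' Anchor-correlated feature selection
#'
#' For each anchor gene, computes the Pearson correlation of every gene
#' with that anchor across cells (on the supplied, typically log-CPT,
#' expression matrix) and keeps the `k` most positively and `k` most
#' negatively correlated genes.  The panel is the deduplicated union in
#' first-seen order (anchors in the given order; positives by decreasing
#' r, then negatives by increasing r).  Each anchor correlates perfectly
#' with itself and therefore leads its own positive list unless
#' `include_anchors = FALSE`.
#'
#' @param expression Gene-by-cell expression matrix (log-CPT recommended).
#' @param anchors Character vector of anchor symbols present in the matrix.
#' @param k Genes per anchor per direction.
#' @param include_anchors Keep each anchor inside its own top-k positives.
#' @return A list: `panel_genes` (character) and `panel_table`
#'   (anchor, direction, gene, r).
#' @export
anchor_correlated_features <- function(expression, anchors, k = 10,
                                       include_anchors = TRUE) {
  missing <- setdiff(anchors, rownames(expression))
  assert_that(length(missing) == 0,
              paste0("anchor(s) absent from the gene universe: ",
                     paste(missing, collapse = ", ")))
  m <- as.matrix(expression)
  a <- t(m[anchors, , drop = FALSE])
  sd_a <- apply(a, 2, sd)
  assert_that(all(sd_a > 0),
              paste0("anchor(s) with zero variance: ",
                     paste(anchors[sd_a == 0], collapse = ", ")))
  r <- suppressWarnings(cor(t(m), a))   # genes x anchors; NA for constants
  rows <- list()
  for (anc in anchors) {
    ri <- r[, anc]
    ri <- ri[!is.na(ri)]
    if (!include_anchors) ri <- ri[names(ri) != anc]
    pos <- head(names(sort(ri, decreasing = TRUE)), k)
    neg <- head(names(sort(ri, decreasing = FALSE)), k)
    if (k > 0) {
      rows[[anc]] <- data.frame(
        anchor = anc,
        direction = rep(c("positive", "negative"),
                        c(length(pos), length(neg))),
        gene = c(pos, neg),
        r = unname(ri[c(pos, neg)]),
        stringsAsFactors = FALSE)
    }
  }
  tab <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(anchor = character(0), direction = character(0),
               gene = character(0), r = numeric(0))
  rownames(tab) <- NULL
  list(panel_genes = unique(tab$gene), panel_table = tab)
}

#' Correlation-based hierarchical grouping of panel genes
#'
#' Average-linkage agglomerative clustering of genes under the distance
#' `1 - Pearson r` between their expression profiles, cut to `n_groups`.
#' Constant genes (undefined correlation) are dropped with a warning.
#'
#' @param expression Gene-by-cell expression matrix.
#' @param panel_genes Character vector of genes to group.
#' @param n_groups Number of groups to cut the tree into.
#' @return A named list of gene character vectors, one per group, ordered
#'   by first occurrence of their genes in `panel_genes`; names are
#'   `"group1"`, `"group2"`, ...
#' @export
cluster_feature_genes <- function(expression, panel_genes, n_groups) {
  panel_genes <- intersect(panel_genes, rownames(expression))
  m <- as.matrix(expression[panel_genes, , drop = FALSE])
  sds <- apply(m, 1, sd)
  if (any(sds == 0)) {
    warning("dropping constant gene(s) from the panel: ",
            paste(panel_genes[sds == 0], collapse = ", "))
    m <- m[sds > 0, , drop = FALSE]
  }
  # lexicographic gene order fixes hclust tie-breaks
  m <- m[order(rownames(m)), , drop = FALSE]
  assert_that(n_groups >= 1 && n_groups <= nrow(m),
              "n_groups must lie between 1 and the usable panel size")
  d <- as.dist(1 - cor(t(m)))
  memb <- cutree(hclust(d, method = "average"), k = n_groups)
  first_seen <- memb[intersect(panel_genes, names(memb))]
  ids <- unique(first_seen)
  groups <- lapply(ids, function(g) names(memb)[memb == g])
  names(groups) <- paste0("group", seq_along(groups))
  groups
}

#' Assign cells to subpopulations by marker-set totals
#'
#' Each cell scores every subpopulation by the total CPT over that
#' subpopulation's gene set, divided by set size (the default size
#' normalisation; `normalize = FALSE` keeps plain totals).  The label is
#' the argmax; exact ties go to the most rostral label in `subpop_order`
#' and are flagged, and cells scoring zero on every set are labelled
#' `"unassigned"`.
#'
#' @param cpt Gene-by-cell CPT matrix (or raw counts with
#'   `normalize_cells = TRUE` applied upstream).
#' @param panel A [feature_panel()].
#' @param normalize Divide each set score by its gene-set size.
#' @return A data.frame with `barcode`, `label`, `tie` and one score column
#'   per subpopulation (named `score.<label>`).
#' @export
assign_cells <- function(cpt, panel, normalize = TRUE) {
  assert_that(ncol(cpt) >= 1, "at least one cell is required")
  labels <- panel$subpop_order
  scores <- sapply(labels, function(lab) {
    genes <- intersect(panel$gene_sets[[lab]], rownames(cpt))
    assert_that(length(genes) > 0,
                paste0("gene set '", lab, "' has no genes in the matrix"))
    s <- Matrix::colSums(cpt[genes, , drop = FALSE])
    if (normalize) s / length(panel$gene_sets[[lab]]) else s
  })
  scores <- matrix(scores, ncol = length(labels),
                   dimnames = list(colnames(cpt), labels))
  best <- max.col(scores, ties.method = "first")  # first = most rostral
  top <- scores[cbind(seq_len(nrow(scores)), best)]
  n_at_top <- rowSums(scores == top)
  label <- labels[best]
  label[top == 0] <- "unassigned"
  out <- data.frame(barcode = colnames(cpt), label = label,
                    tie = n_at_top > 1 & top > 0,
                    stringsAsFactors = FALSE)
  colnames(scores) <- paste0("score.", labels)
  cbind(out, as.data.frame(scores, row.names = NULL))
}

#' Binary marker gating
#'
#' A cell is marker-positive when its raw count is at least 1 (default), or
#' when its CPT value reaches `threshold` if one is given.
#'
#' @param counts Gene-by-cell raw count matrix.
#' @param gene Marker symbol.
#' @param threshold Optional CPT threshold; `NULL` uses the raw-count rule.
#' @param cpt CPT matrix, required when `threshold` is set.
#' @return Named logical vector over cells.
#' @export
gate_binary_marker <- function(counts, gene, threshold = NULL, cpt = NULL) {
  assert_that(gene %in% rownames(counts),
              paste0("gene not found: ", gene))
  if (is.null(threshold)) {
    x <- counts[gene, ] >= 1
  } else {
    assert_that(!is.null(cpt), "cpt matrix required with a CPT threshold")
    x <- cpt[gene, ] >= threshold
  }
  setNames(as.logical(x), colnames(counts))
}
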