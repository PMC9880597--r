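# Small in-code fixtures shared across test files.

# Downscaled simulation spec: same structure as the defaults, fewer cells.
tiny_spec <- function(n = 200, softness = 0.05, ...) {
  simulation_spec(domains = default_domains(softness),
                  n_cells_control = n, n_cells_mutant = n, ...)
}

# Random small sparse count matrix with gene/barcode names.
random_counts <- function(n_genes = 8, n_cells = 5, seed = 1) {
  set.seed(seed)
  m <- matrix(rpois(n_genes * n_cells, 2), n_genes, n_cells)
  rownames(m) <- paste0("g", seq_len(n_genes))
  colnames(m) <- paste0("bc", seq_len(n_cells))
  methods::as(Matrix::Matrix(m, sparse = TRUE), "CsparseMatrix")
}

# Write a Matrix Market triplet file plus sidecars by hand.
write_triplet_fixture <- function(dir, n_genes, n_cells, entries, genes,
                                  barcodes) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  lines <- c("%%MatrixMarket matrix coordinate integer general",
             paste(n_genes, n_cells, nrow(entries)))
  if (nrow(entries) > 0) {
    lines <- c(lines, apply(entries, 1, paste, collapse = " "))
  }
  writeLines(lines, file.path(dir, "matrix.mtx"))
  writeLines(genes, file.path(dir, "genes.tsv"))
  writeLines(barcodes, file.path(dir, "barcodes.tsv"))
  dir
}

# Independent Fisher oracle: table probabilities from binomial coefficients,
# two-sided p as the mass of tables no more probable than the observed one.
fisher_oracle_p <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c; n <- r1 + r2
  support <- max(0, c1 - r2):min(r1, c1)
  pr <- choose(r1, support) * choose(r2, c1 - support) / choose(n, c1)
  sum(pr[pr <= pr[support == a] * (1 + 1e-7)])
}

# Two-gene matrix (one nuclear, one mitochondrial) with exact UMI totals
# and mito percentages.
make_qc_matrix <- function(umis, mito_pct) {
  n <- length(umis)
  mito <- round(umis * mito_pct / 100)
  m <- rbind(umis - mito, mito)
  rownames(m) <- c("Actb", "mt-Nd1")
  colnames(m) <- paste0("c", seq_len(n))
  Matrix::Matrix(m, sparse = TRUE)
}

# A de_table with the panel genes planted at given ranks (1 = top).
ranked_de_table <- function(panel, panel_ranks, n_genes = 100) {
  genes <- paste0("null", seq_len(n_genes))
  genes[panel_ranks] <- panel
  data.frame(gene = genes, log2fc = seq(n_genes, 1), # already ordered
             stringsAsFactors = FALSE)
}
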