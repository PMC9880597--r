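#' Read a 10x-style sparse count matrix
#'
#' Loads a Matrix Market coordinate file together with its gene and barcode
#' sidecar TSVs into a sparse gene-by-cell integer matrix.  Row/column
#' counts are checked against the sidecar files, duplicate gene symbols are
#' disambiguated deterministically by appending `.1`, `.2`, ... in file
#' order (with a warning), and duplicate barcodes within one sample are an
#' error.
#'
#' @param matrix_path Path to the `.mtx` coordinate file.
#' @param genes_path Path to a TSV whose first column holds gene symbols
#'   (an optional second column holds the chromosome).
#' @param barcodes_path Path to a one-column TSV of cell barcodes.
#' @return A `dgCMatrix` with genes as rows and barcodes as columns.
#' @export
read_counts <- function(matrix_path, genes_path, barcodes_path) {
  for (p in c(matrix_path, genes_path, barcodes_path)) {
    assert_that(file.exists(p), paste0("input file not found: ", p))
  }
  m <- tryCatch(Matrix::readMM(matrix_path),
                error = function(e) stop("malformed Matrix Market file '",
                                         matrix_path, "': ",
                                         conditionMessage(e), call. = FALSE))
  vals <- if (methods::is(m, "nMatrix")) rep(1, Matrix::nnzero(m)) else m@x
  assert_that(all(vals >= 0), "count matrix contains negative entries")
  assert_that(all(vals == floor(vals)),
              "count matrix contains non-integer entries")
  genes_tab <- read.delim(genes_path, header = FALSE,
                          colClasses = "character")
  barcodes <- read.delim(barcodes_path, header = FALSE,
                         colClasses = "character")[, 1]
  assert_that(nrow(genes_tab) == nrow(m),
              sprintf("gene file lists %d genes but matrix has %d rows",
                      nrow(genes_tab), nrow(m)))
  assert_that(length(barcodes) == ncol(m),
              sprintf("barcode file lists %d barcodes but matrix has %d columns",
                      length(barcodes), ncol(m)))
  if (anyDuplicated(barcodes)) {
    stop("duplicate barcodes within one sample: ",
         paste(unique(barcodes[duplicated(barcodes)]), collapse = ", "),
         call. = FALSE)
  }
  symbols <- dedup_symbols(genes_tab[, 1])
  out <- methods::as(m, "CsparseMatrix")
  out <- methods::as(out, "dMatrix")
  dimnames(out) <- list(symbols, barcodes)
  out
}

# Append ".1", ".2", ... to repeated symbols, in file order.
dedup_symbols <- function(symbols) {
  dup <- duplicated(symbols)
  if (any(dup)) {
    warning("renaming ", sum(dup), " duplicate gene symbol(s): ",
            paste(unique(symbols[dup]), collapse = ", "))
    symbols <- make.unique(symbols, sep = ".")
  }
  symbols
}

#' Write a count matrix in the 10x triplet format
#'
#' @param counts Gene-by-cell sparse matrix with dimnames.
#' @param dir Output directory (created if absent).
#' @param gene_chromosomes Optional named map symbol -> chromosome written as
#'   a second column of `genes.tsv`.
#' @return The directory path, invisibly.
#' @export
write_counts <- function(counts, dir, gene_chromosomes = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(methods::as(counts, "CsparseMatrix"),
                  file.path(dir, "matrix.mtx"))
  genes <- data.frame(symbol = rownames(counts))
  if (!is.null(gene_chromosomes)) {
    genes$chromosome <- unname(gene_chromosomes[rownames(counts)])
  }
  write.table(genes, file.path(dir, "genes.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  writeLines(colnames(counts), file.path(dir, "barcodes.tsv"))
  invisible(dir)
}

#' Merge per-sample count matrices and cell tables
#'
#' Concatenates samples column-wise after checking that they share one gene
#' universe.  Every barcode is suffixed with `-<sample_id>` so merged
#' barcodes are unique even when samples reuse raw barcodes.
#'
#' @param samples A list; each element is a list with components `counts`
#'   (gene-by-cell matrix) and `cells` (per-cell metadata with columns
#'   `barcode` and `sample_id`).
#' @return A list with merged `counts` and `cells`; metadata rows align 1:1
#'   with matrix columns.
#' @export
merge_samples <- function(samples) {
  assert_that(length(samples) >= 1, "no samples supplied")
  ref_genes <- rownames(samples[[1]]$counts)
  for (i in seq_along(samples)) {
    g <- rownames(samples[[i]]$counts)
    if (!setequal(g, ref_genes)) {
      bad <- union(setdiff(g, ref_genes), setdiff(ref_genes, g))
      stop("gene universe mismatch in sample ", i, ": ",
           paste(head(bad, 10), collapse = ", "),
           if (length(bad) > 10) " ..." else "", call. = FALSE)
    }
  }
  pieces <- lapply(samples, function(s) {
    cts <- s$counts[ref_genes, , drop = FALSE]
    cells <- s$cells
    assert_that(nrow(cells) == ncol(cts),
                "cell table rows do not match matrix columns")
    assert_that(all(cells$barcode == colnames(cts)),
                "cell table barcodes do not match matrix column names")
    sid <- unique(cells$sample_id)
    assert_that(length(sid) == 1, "each sample must have one sample_id")
    new_bc <- paste0(cells$barcode, "-", sid)
    colnames(cts) <- new_bc
    cells$barcode <- new_bc
    list(counts = cts, cells = cells)
  })
  counts <- do.call(cbind, lapply(pieces, `[[`, "counts"))
  cells <- do.call(rbind, lapply(pieces, `[[`, "cells"))
  rownames(cells) <- NULL
  assert_that(!anyDuplicated(colnames(counts)),
              "merged barcodes are not unique; sample_ids must differ")
  list(counts = counts, cells = cells)
}

#' Per-cell metadata table constructor
#'
#' Validates and assembles the standard per-cell metadata used throughout
#' the pipeline.
#'
#' @param barcode,sample_id Character vectors.
#' @param genotype `"control"` or `"mutant"`.
#' @param timepoint One of `"E12.5"`, `"E14.5"`, `"E16.5"`, `"E18.5"`.
#' @param replicate Integer replicate index.
#' @return A `data.frame` with one row per cell.
#' @export
cell_table <- function(barcode, sample_id, genotype, timepoint,
                       replicate = 1L) {
  genotype <- as.character(genotype)
  timepoint <- as.character(timepoint)
  assert_that(all(genotype %in% c("control", "mutant")),
              "genotype must be 'control' or 'mutant'")
  assert_that(all(timepoint %in% c("E12.5", "E14.5", "E16.5", "E18.5")),
              "timepoint must be one of E12.5, E14.5, E16.5, E18.5")
  n <- length(barcode)
  data.frame(barcode = as.character(barcode),
             sample_id = rep_len(as.character(sample_id), n),
             genotype = rep_len(genotype, n),
             timepoint = rep_len(timepoint, n),
             replicate = rep_len(as.integer(replicate), n),
             stringsAsFactors = FALSE)
}
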