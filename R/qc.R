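#' Mitochondrial UMI fraction per cell
#'
#' Mitochondrial genes are recognised by a case-insensitive `mt-` symbol
#' prefix (mouse convention); an explicit gene list can override this.
#'
#' @param counts Gene-by-cell count matrix.
#' @param mito_genes Optional explicit character vector of mitochondrial
#'   gene symbols.
#' @return Numeric vector of per-cell mitochondrial fractions in `[0, 1]`.
#' @export
mito_fraction <- function(counts, mito_genes = NULL) {
  if (is.null(mito_genes)) {
    mito_genes <- grep("^mt-", rownames(counts), ignore.case = TRUE,
                       value = TRUE)
  } else {
    mito_genes <- intersect(mito_genes, rownames(counts))
  }
  tot <- Matrix::colSums(counts)
  mito <- if (length(mito_genes) > 0) {
    Matrix::colSums(counts[mito_genes, , drop = FALSE])
  } else rep(0, ncol(counts))
  frac <- ifelse(tot > 0, mito / tot, 0)
  unname(frac)
}

#' Knee point of the log barcode-rank curve
#'
#' Sorts barcodes by UMI count descending, smooths `log10(count)` against
#' `log10(rank)` with a rolling median, and places the knee at the rank
#' where the numerical derivative of the smoothed curve is most negative —
#' the cliff that separates real cells from the ambient tail.  The
#' suggested UMI threshold is the count at that rank.
#'
#' Confidence is graded by how much steeper the cliff is than the typical
#' slope of the curve: a dip at least 3x the median downward slope (and not
#' in the terminal 5% of ranks, where every distribution plunges) is
#' `"high"`, 1.5-3x is `"low"`, and below that the curve is treated as
#' unimodal and `"none"` is reported.  Whenever confidence is not high the
#' threshold falls back to `fallback` (the configured minimum UMI count).
#'
#' @param umis Numeric vector of UMI counts per barcode (zeros ignored).
#' @param window Rolling-median window, in ranks.
#' @param fallback Threshold returned when no confident knee is found.
#' @param n_grid Resolution of the uniform log-rank grid on which the
#'   derivative is evaluated (a uniform grid keeps the per-rank spacing of
#'   the deep tail from dominating the finite differences).
#' @return A list: `threshold` (suggested UMI cutoff), `confidence`
#'   (`"high"`, `"low"`, or `"none"`), `knee_rank`, `knee_count`.
#' @export
barcode_rank_inflection <- function(umis, window = 15, fallback = 2000,
                                    n_grid = 256) {
  umis <- umis[umis > 0]
  assert_that(length(umis) >= 10,
              "at least 10 nonzero barcodes are required")
  cts <- sort(umis, decreasing = TRUE)
  n <- length(cts)
  # thin to the first and last rank of each distinct count so integer
  # plateaus become single steps rather than long flat runs
  idx <- sort(unique(c(which(!duplicated(cts)),
                       which(!duplicated(cts, fromLast = TRUE)))))
  x <- log10(idx)
  y_s <- if (length(idx) >= 3 * window) {
    rolling_median(log10(cts[idx]), window)
  } else log10(cts[idx])
  xg <- seq(0, log10(n), length.out = n_grid)
  yg <- stats::approx(x, y_s, xout = xg, rule = 2)$y
  dy <- (yg[-(1:2)] - yg[1:(n_grid - 2)]) / (xg[-(1:2)] - xg[1:(n_grid - 2)])
  i_min <- which.min(dy)
  mid <- 2:(n_grid - 1)
  knee_rank <- min(n, max(1, round(10^xg[mid[i_min]])))
  min_slope <- dy[i_min]
  knee_count <- 10^yg[mid[i_min]]
  # a knee is a deep dip the derivative climbs back out of: require a
  # markedly flatter stretch after the cliff (ruling out curves that merely
  # accelerate into their tail) and measure the count drop across the
  # contiguous steep region around the minimum
  after <- dy[seq_along(dy) > i_min + 2]
  recovers <- length(after) > 0 && any(after >= min_slope / 3)
  steep <- dy <= min_slope / 3
  run_start <- i_min
  while (run_start > 1 && steep[run_start - 1]) run_start <- run_start - 1
  run_end <- i_min
  while (run_end < length(dy) && steep[run_end + 1]) run_end <- run_end + 1
  gridstep <- xg[2] - xg[1]
  depth <- yg[mid[run_start]] - yg[mid[run_end]] + abs(min_slope) * gridstep
  width <- xg[mid[run_end]] - xg[mid[run_start]] + gridstep
  run_slope <- -depth / width
  confidence <- if (min_slope > -1e-9 || !recovers) "none"
                else if (run_slope <= -10 && depth >= 0.5) "high"
                else if (min_slope <= -1) "low"
                else "none"
  threshold <- if (confidence == "high") knee_count else fallback
  list(threshold = threshold, confidence = confidence,
       knee_rank = knee_rank, knee_count = knee_count)
}

rolling_median <- function(y, window) {
  n <- length(y)
  if (window <= 1 || n < window) return(y)
  half <- floor(window / 2)
  vapply(seq_len(n), function(i) {
    median(y[max(1, i - half):min(n, i + half)])
  }, numeric(1))
}

#' Filter cells on UMI count and mitochondrial fraction
#'
#' Removes cells with strictly fewer than `min_umis` UMIs or a
#' mitochondrial fraction strictly above `max_mito_frac`; cells sitting
#' exactly on either boundary are retained.  QC fields (`n_umis`,
#' `n_genes`, `mito_frac`) are (re)computed on the cell table.
#'
#' @param counts Gene-by-cell count matrix.
#' @param cells Per-cell metadata aligned with the matrix columns.
#' @param config A [pipeline_config()].
#' @return A list with the filtered `counts` and `cells`.
#' @export
filter_cells <- function(counts, cells = NULL, config = pipeline_config()) {
  n_umis <- Matrix::colSums(counts)
  mito <- mito_fraction(counts)
  keep <- n_umis >= config$min_umis & mito <= config$max_mito_frac
  out_counts <- counts[, keep, drop = FALSE]
  if (is.null(cells)) {
    cells <- data.frame(barcode = colnames(counts),
                        stringsAsFactors = FALSE)
  }
  assert_that(nrow(cells) == ncol(counts),
              "cell table rows must match matrix columns")
  cells$n_umis <- as.integer(n_umis)
  cells$n_genes <- as.integer(Matrix::colSums(counts > 0))
  cells$mito_frac <- mito
  cells$qc_pass <- keep
  list(counts = out_counts, cells = cells[keep, , drop = FALSE],
       qc = cells)
}

#' Drop X- and Y-chromosome genes
#'
#' Removes sex-chromosome genes so unequal male/female replicate balance
#' between conditions cannot drive downstream contrasts.  Genes missing
#' from the chromosome map are retained with a warning.
#'
#' @param counts Gene-by-cell count matrix.
#' @param gene_chromosomes Named character vector, symbol -> chromosome.
#' @return The count matrix without X/Y genes.
#' @export
remove_sex_genes <- function(counts, gene_chromosomes) {
  mapped <- intersect(rownames(counts), names(gene_chromosomes))
  unmapped <- setdiff(rownames(counts), mapped)
  if (length(unmapped) > 0) {
    warning(length(unmapped),
            " gene(s) missing from the chromosome map were retained")
  }
  sex <- mapped[gene_chromosomes[mapped] %in% c("X", "Y", "chrX", "chrY")]
  counts[setdiff(rownames(counts), sex), , drop = FALSE]
}

#' Counts-per-thousand normalisation
#'
#' Scales each cell to a fixed total of `cpt_scale` (1,000 by default),
#' optionally followed by `log1p`.
#'
#' @param counts Gene-by-cell count matrix with no all-zero cell.
#' @param config A [pipeline_config()].
#' @param log1p If `TRUE`, return `log1p(CPT)`.
#' @return A sparse matrix of (log-)CPT values with the input dimnames.
#' @export
normalize_cpt <- function(counts, config = pipeline_config(),
                          log1p = FALSE) {
  tot <- Matrix::colSums(counts)
  if (any(tot == 0)) {
    stop("zero-total cell(s): ",
         paste(head(colnames(counts)[tot == 0], 5), collapse = ", "),
         call. = FALSE)
  }
  cpt <- counts %*% Matrix::Diagonal(x = config$cpt_scale / tot)
  dimnames(cpt) <- dimnames(counts)
  if (log1p) cpt@x <- log1p(cpt@x)
  methods::as(cpt, "CsparseMatrix")
}

#' Select highly variable genes
#'
#' Ranks genes by the variance of standardised counts: per-gene variance is
#' compared against a loess trend of `log10(variance)` on `log10(mean)`,
#' values are standardised by the trend's expected standard deviation,
#' clipped at `sqrt(n_cells)`, and the variance of the clipped values is
#' the ranking statistic.  Constant genes score zero.
#'
#' @param counts Gene-by-cell count matrix (raw counts).
#' @param n_hvg Number of genes to return.
#' @param span Loess span for the mean-variance trend.
#' @return Character vector of the top `n_hvg` gene symbols, by decreasing
#'   standardised variance (ties broken by symbol).
#' @export
select_variable_genes <- function(counts, n_hvg = 2000, span = 0.5) {
  m <- as.matrix(counts)
  n_cells <- ncol(m)
  mu <- rowMeans(m)
  v <- apply(m, 1, var)
  score <- setNames(rep(0, nrow(m)), rownames(m))
  use <- mu > 0 & v > 0
  if (sum(use) >= 5) {
    lm10 <- log10(mu[use]); lv10 <- log10(v[use])
    fit <- tryCatch(loess(lv10 ~ lm10, span = span, degree = 2),
                    error = function(e) NULL)
    exp_sd <- if (!is.null(fit)) sqrt(10^predict(fit)) else sqrt(v[use])
    z <- (m[use, , drop = FALSE] - mu[use]) / exp_sd
    clip <- sqrt(n_cells)
    z <- pmin(pmax(z, -clip), clip)
    score[use] <- apply(z, 1, var)
  } else if (any(use)) {
    score[use] <- v[use]
  }
  if (n_hvg > nrow(m)) {
    warning("fewer genes than n_hvg; returning all ", nrow(m), " genes")
    n_hvg <- nrow(m)
  }
  ord <- order(-score, rownames(m))
  rownames(m)[ord][seq_len(n_hvg)]
}

#' Summarise per-cell QC metrics
#'
#' @param cells Cell table with populated `n_umis`, `n_genes`, `mito_frac`.
#' @return A list: `n_cells`, `median_umis`, `iqr_umis` (25th/75th
#'   percentiles), `median_genes`, `iqr_genes`, `median_mito_frac`,
#'   `iqr_mito_frac`.  Medians use the midpoint convention for even n.
#' @export
qc_summary <- function(cells) {
  if (nrow(cells) == 0) return(list(n_cells = 0L))
  iqr2 <- function(x) unname(quantile(x, c(0.25, 0.75)))
  list(n_cells = nrow(cells),
       median_umis = median(cells$n_umis),
       iqr_umis = iqr2(cells$n_umis),
       median_genes = median(cells$n_genes),
       iqr_genes = iqr2(cells$n_genes),
       median_mito_frac = median(cells$mito_frac),
       iqr_mito_frac = iqr2(cells$mito_frac))
}
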