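#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Exact two-sided p by hypergeometric enumeration: with margins fixed,
#' the p value is the sum of the probabilities of all tables whose
#' probability does not exceed that of the observed table (up to a 1e-7
#' relative tolerance for floating-point ties).  The reported odds ratio
#' is the sample odds ratio `(a*d)/(b*c)` — not the conditional MLE —
#' with `x/0 = Inf` and `0/0` reported as `NaN` (undefined).
#'
#' @param table A 2x2 matrix (or length-4 vector `a, c, b, d` filled
#'   column-wise) of nonnegative integers.
#' @return A list with `odds_ratio` and `p`.
#' @export
fisher_exact_2x2 <- function(table) {
  tab <- matrix(as.numeric(table), 2, 2)
  assert_that(all(tab >= 0) && all(tab == floor(tab)),
              "table entries must be nonnegative integers")
  a <- tab[1, 1]; b <- tab[1, 2]; c_ <- tab[2, 1]; d <- tab[2, 2]
  or <- (a * d) / (b * c_)
  r1 <- a + b; r2 <- c_ + d; c1 <- a + c_
  if (r1 == 0 || r2 == 0 || c1 == 0 || b + d == 0) {
    return(list(odds_ratio = or, p = 1))
  }
  support <- max(0, c1 - r2):min(r1, c1)
  probs <- dhyper(support, r1, r2, c1)
  p_obs <- probs[support == a]
  p <- sum(probs[probs <= p_obs * (1 + 1e-7)])
  list(odds_ratio = or, p = min(1, p))
}

#' Genotype-by-population composition enrichment
#'
#' For every population label, tests the 2x2 table of (label vs all other
#' labels) x (control vs mutant) with the two-sided Fisher test, reporting
#' the sample odds ratio oriented so that OR > 1 means the label is
#' enriched in controls, i.e. depleted in mutants.  P values are BH
#' adjusted across labels.
#'
#' @param labels Character vector of per-cell population labels.
#' @param genotype Character vector (`"control"`/`"mutant"`) aligned with
#'   `labels`.
#' @param label_universe Labels to test (default: all observed).
#' @return A data.frame with columns `label`, `a`, `b`, `c`, `d` (label
#'   control, label mutant, other control, other mutant), `odds_ratio`,
#'   `p`, `q`.
#' @export
composition_enrichment <- function(labels, genotype,
                                   label_universe = sort(unique(labels))) {
  assert_that(length(labels) == length(genotype),
              "labels and genotype must align")
  assert_that(all(genotype %in% c("control", "mutant")),
              "genotype must be 'control' or 'mutant'")
  assert_that(all(c("control", "mutant") %in% genotype),
              "both genotypes must be present")
  ctrl <- genotype == "control"
  rows <- lapply(label_universe, function(lab) {
    in_lab <- labels == lab
    a <- sum(in_lab & ctrl); b <- sum(in_lab & !ctrl)
    c_ <- sum(!in_lab & ctrl); d <- sum(!in_lab & !ctrl)
    fi <- fisher_exact_2x2(matrix(c(a, c_, b, d), 2, 2))
    data.frame(label = lab, a = a, b = b, c = c_, d = d,
               odds_ratio = fi$odds_ratio, p = fi$p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- bh_adjust(out$p)
  out
}

# Two-sided Wilcoxon rank-sum p via the normal approximation with tie
# correction and continuity correction; vector-friendly workhorse for the
# per-gene DE scan.
ranksum_approx_p <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  w <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  ties <- table(r)
  sigma2 <- (n1 * n2 / 12) *
    ((n1 + n2 + 1) - sum(ties^3 - ties) / ((n1 + n2) * (n1 + n2 - 1)))
  if (sigma2 <= 0) return(1)
  z <- (w - mu - sign(w - mu) * 0.5) / sqrt(sigma2)
  min(1, 2 * pnorm(-abs(z)))
}

#' Rank-based differential expression between two cell groups
#'
#' A per-gene two-sided Wilcoxon rank-sum test on CPT values, with the
#' decision rule used throughout the package: a gene is differentially
#' expressed when its fold change exceeds `fc_threshold` (in either
#' direction) and its BH-adjusted p falls below `alpha`.  Fold change is
#' the ratio of group mean CPT with a pseudocount of 1 CPT; groups larger
#' than `de_subsample` are downsampled (seeded) before testing.
#'
#' @param counts Gene-by-cell raw count matrix.
#' @param group_a,group_b Barcodes of the two groups (columns of `counts`).
#' @param config A [pipeline_config()].
#' @param seed Seed for the subsampling (default `config$rng_seed`).
#' @return A data.frame with `gene`, `mean_cpt_a`, `mean_cpt_b`, `log2fc`
#'   (a over b), `p`, `q`, `deg`; attribute `n_used` records group sizes
#'   after subsampling.
#' @export
de_rank_test <- function(counts, group_a, group_b,
                         config = pipeline_config(),
                         seed = config$rng_seed) {
  assert_that(length(group_a) > 0 && length(group_b) > 0,
              "both groups must be non-empty")
  assert_that(all(c(group_a, group_b) %in% colnames(counts)),
              "group barcodes must be matrix columns")
  sub <- function(g, off) {
    if (length(g) > config$de_subsample) {
      with_rng(offset_seed(seed, off),
               sample(g, config$de_subsample))
    } else g
  }
  ga <- sub(group_a, 0L); gb <- sub(group_b, 1L)
  cpt <- as.matrix(normalize_cpt(counts[, c(ga, gb), drop = FALSE], config))
  ia <- seq_along(ga); ib <- length(ga) + seq_along(gb)
  mean_a <- rowMeans(cpt[, ia, drop = FALSE])
  mean_b <- rowMeans(cpt[, ib, drop = FALSE])
  log2fc <- log2((mean_a + 1) / (mean_b + 1))
  p <- vapply(seq_len(nrow(cpt)), function(i) {
    xa <- cpt[i, ia]; xb <- cpt[i, ib]
    if (all(xa == xa[1]) && all(xb == xa[1])) return(1)
    if (length(xa) <= 50 && length(xb) <= 50) {
      suppressWarnings(wilcox.test(xa, xb, exact = TRUE)$p.value)
    } else {
      ranksum_approx_p(xa, xb)
    }
  }, numeric(1))
  q <- bh_adjust(p)
  out <- data.frame(gene = rownames(cpt), mean_cpt_a = mean_a,
                    mean_cpt_b = mean_b, log2fc = log2fc, p = p, q = q,
                    deg = abs(log2fc) > log2(config$fc_threshold) &
                          q < config$alpha,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "n_used") <- c(a = length(ga), b = length(gb))
  out
}

#' Cell-cycle scoring with expression-matched control bins
#'
#' For each phase gene set, the score of a cell is the mean expression of
#' the set minus the mean expression of a control set: genes are binned by
#' their average expression across cells (`n_bins` bins) and, for each set
#' gene, `n_ctrl` control genes are drawn (seeded) from its bin.  Phase is
#' the argmax of (S, G2M) when the winning score is positive, else G1.
#'
#' @param expression Gene-by-cell expression matrix (log-CPT recommended).
#' @param s_genes,g2m_genes Phase gene sets (>= 5 genes each after
#'   intersection with the matrix).
#' @param n_bins Expression bins for control matching.
#' @param n_ctrl Control genes drawn per set gene.
#' @param seed Integer seed for the control draws.
#' @return A data.frame with `barcode`, `s_score`, `g2m_score`, `phase`.
#' @export
cell_cycle_score <- function(expression, s_genes, g2m_genes, n_bins = 25,
                             n_ctrl = 50, seed = 0L) {
  m <- as.matrix(expression)
  s_genes <- intersect(s_genes, rownames(m))
  g2m_genes <- intersect(g2m_genes, rownames(m))
  assert_that(length(s_genes) >= 5 && length(g2m_genes) >= 5,
              "each phase set needs >= 5 genes present in the matrix")
  avg <- rowMeans(m)
  n_bins <- min(n_bins, length(unique(avg)))
  bin <- cut(rank(avg, ties.method = "first"), breaks = n_bins,
             labels = FALSE)
  names(bin) <- rownames(m)
  score_set <- function(set, off) {
    ctrl <- with_rng(offset_seed(seed, off), {
      unique(unlist(lapply(set, function(g) {
        pool <- setdiff(names(bin)[bin == bin[g]], set)
        if (length(pool) == 0) pool <- setdiff(names(bin), set)
        sample(pool, min(n_ctrl, length(pool)))
      })))
    })
    colMeans(m[set, , drop = FALSE]) -
      colMeans(m[ctrl, , drop = FALSE])
  }
  s <- score_set(s_genes, 0L)
  g2m <- score_set(g2m_genes, 1L)
  phase <- ifelse(pmax(s, g2m) <= 0, "G1",
                  ifelse(g2m >= s, "G2M", "S"))
  data.frame(barcode = colnames(m), s_score = unname(s),
             g2m_score = unname(g2m), phase = unname(phase),
             stringsAsFactors = FALSE)
}

#' Genotype shift in G2/M scores
#'
#' Two-sided Wilcoxon rank-sum test of G2/M scores between control and
#' mutant cells of one cluster; exact enumeration for small tie-free
#' samples, normal approximation with tie correction otherwise.
#'
#' @param scores Numeric per-cell G2/M scores.
#' @param genotype Character vector aligned with `scores`.
#' @param exact Force the exact (`TRUE`) or approximate (`FALSE`) p value;
#'   `NULL` (default) selects exact enumeration for tie-free samples of at
#'   most 50 per group.
#' @return A list: `delta_median` (mutant minus control) and `p`.
#' @export
g2m_shift_test <- function(scores, genotype, exact = NULL) {
  assert_that(all(c("control", "mutant") %in% genotype),
              "both genotypes must be present")
  x <- scores[genotype == "control"]
  y <- scores[genotype == "mutant"]
  if (is.null(exact)) {
    exact <- length(x) <= 50 && length(y) <= 50 &&
      !anyDuplicated(c(x, y))
  }
  p <- if (exact) {
    wilcox.test(x, y, exact = TRUE)$p.value
  } else {
    ranksum_approx_p(x, y)
  }
  list(delta_median = median(y) - median(x), p = p)
}

#' Spearman rank correlation
#'
#' Rho is the Pearson correlation of midranks; the p value uses the
#' t-distribution approximation with `n - 2` degrees of freedom.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return A list with `rho` and `p`.
#' @export
spearman <- function(x, y) {
  assert_that(length(x) == length(y) && length(x) >= 3,
              "x and y must have equal length >= 3")
  assert_that(sd(x) > 0 && sd(y) > 0,
              "spearman correlation undefined for constant input")
  rho <- cor(rank(x), rank(y))
  n <- length(x)
  p <- if (abs(rho) >= 1) 0 else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * pt(-abs(tstat), n - 2)
  }
  list(rho = rho, p = p)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment with monotonicity enforcement; order-invariant
#' and elementwise at least the raw p.
#'
#' @param p Numeric vector of p values in `[0, 1]`.
#' @return Adjusted q values in input order.
#' @export
bh_adjust <- function(p) {
  assert_that(all(p >= 0 & p <= 1, na.rm = FALSE),
              "p values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}
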