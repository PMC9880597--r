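test_that("Fisher p values match enumeration and R's implementation", {
  bal <- fisher_exact_2x2(matrix(c(10, 10, 10, 10), 2, 2))
  expect_equal(bal$odds_ratio, 1)
  expect_equal(bal$p, 1)

  diag5 <- fisher_exact_2x2(matrix(c(5, 0, 0, 5), 2, 2))
  expect_equal(diag5$odds_ratio, Inf)
  expect_equal(diag5$p, 2 / 252, tolerance = 1e-12)

  set.seed(42)
  for (i in 1:50) {
    tab <- matrix(rmultinom(1, sample(4:30, 1), rep(0.25, 4)), 2, 2)
    mine <- fisher_exact_2x2(tab)
    expect_equal(mine$p, fisher_oracle_p(tab[1, 1], tab[1, 2],
                                         tab[2, 1], tab[2, 2]),
                 tolerance = 1e-12)
    expect_equal(mine$p, stats::fisher.test(tab)$p.value, tolerance = 1e-9)
  }
  expect_error(fisher_exact_2x2(matrix(c(-1, 1, 1, 1), 2, 2)),
               "nonnegative")
})

test_that("Fisher test is symmetric under joint swaps; OR inverts on row swap", {
  set.seed(8)
  for (i in 1:10) {
    tab <- matrix(sample(0:12, 4, TRUE), 2, 2)
    a <- fisher_exact_2x2(tab)
    b <- fisher_exact_2x2(tab[2:1, 2:1])
    expect_equal(a$p, b$p, tolerance = 1e-12)
    expect_equal(a$odds_ratio, b$odds_ratio)
    c_ <- fisher_exact_2x2(tab[2:1, ])
    if (is.finite(a$odds_ratio) && a$odds_ratio > 0) {
      expect_equal(c_$odds_ratio, 1 / a$odds_ratio)
    }
  }
})

test_that("composition enrichment orients OR as control-enrichment", {
  labels <- rep(c("A", "B"), each = 100)
  genotype <- rep(c("control", "mutant"), 100)
  enr <- composition_enrichment(labels, genotype)
  expect_equal(enr$odds_ratio, c(1, 1))
  expect_equal(enr$p, c(1, 1))
  expect_true(all(enr$q >= enr$p))
  expect_equal(enr$a + enr$b + enr$c + enr$d, rep(200L, 2))

  # a label wholly absent from mutants: infinite OR, finite p
  labels2 <- c(rep("gone", 10), rep("other", 190))
  genotype2 <- c(rep("control", 10), rep(c("control", "mutant"), 95))
  enr2 <- composition_enrichment(labels2, genotype2)
  gone <- enr2[enr2$label == "gone", ]
  expect_equal(gone$odds_ratio, Inf)
  expect_lt(gone$p, 1)
  expect_error(composition_enrichment(c("A", "B"), c("control", "control")),
               "both genotypes")
})

test_that("depleted-domain odds ratio is recovered from a simulated pair", {
  spec <- simulation_spec()   # defaults: 1,800 cells/genotype, 10x depletion
  labs <- simulate_genotype_labels(spec, seed = 0)
  grp <- labs$domain %in% c("rTh.Pro", "cTh.Pro1")
  tab <- table(factor(grp, c(TRUE, FALSE)),
               factor(labs$genotype, c("control", "mutant")))
  or <- fisher_exact_2x2(tab)$odds_ratio
  expect_gt(or, 7); expect_lt(or, 14)
})

test_that("rank DE flags planted fold changes and nothing on identical groups", {
  sim <- simulate_progenitor_field(tiny_spec(n = 60), seed = 2)
  same <- de_rank_test(sim$counts, colnames(sim$counts)[1:30],
                       colnames(sim$counts)[1:30])
  expect_equal(sum(same$deg), 0)

  # planted 10-fold gene in an otherwise-null NB simulation
  for (seed in 1:3) {
    set.seed(seed)
    n <- 300
    mu <- runif(60, 2, 20)
    a <- matrix(rnbinom(60 * n, size = 2, mu = mu), 60, n)
    b <- matrix(rnbinom(60 * n, size = 2, mu = mu), 60, n)
    b[1, ] <- rnbinom(n, size = 2, mu = mu[1] * 10)
    m <- cbind(a, b)
    rownames(m) <- paste0("g", 1:60)
    colnames(m) <- paste0("c", 1:(2 * n))
    de <- de_rank_test(Matrix::Matrix(m, sparse = TRUE),
                       paste0("c", (n + 1):(2 * n)), paste0("c", 1:n))
    expect_true(de$deg[de$gene == "g1"])
    expect_gt(de$log2fc[de$gene == "g1"], 1)
  }
  expect_error(de_rank_test(sim$counts, character(0), "BC000001"),
               "non-empty")
})

test_that("oversized groups are subsampled to the configured ceiling", {
  sim <- simulate_progenitor_field(tiny_spec(n = 120), seed = 4)
  cfg <- pipeline_config(de_subsample = 40)
  de <- de_rank_test(sim$counts, colnames(sim$counts)[1:70],
                     colnames(sim$counts)[71:120], config = cfg)
  expect_equal(unname(attr(de, "n_used")), c(40, 40))
  # subsampling is seeded: same seed, same result
  de2 <- de_rank_test(sim$counts, colnames(sim$counts)[1:70],
                      colnames(sim$counts)[71:120], config = cfg)
  expect_identical(de$p, de2$p)
})

test_that("cell-cycle scores separate cycling cells and are seeded", {
  spec <- tiny_spec(n = 400, cycling_frac = 0.5)
  sim <- simulate_progenitor_field(spec, seed = 6)
  logcpt <- as.matrix(normalize_cpt(sim$counts, log1p = TRUE))
  s_ref <- grep("^Hk", rownames(logcpt), value = TRUE)[1:10]
  cc <- cell_cycle_score(logcpt, s_ref, spec$g2m_genes, seed = 1)
  cyc <- sim$truth$cycling
  expect_gt(sum(cyc), 50); expect_gt(sum(!cyc), 50)
  w <- g2m_shift_test(cc$g2m_score,
                      ifelse(cyc, "mutant", "control"))
  expect_lt(w$p, 0.01)
  expect_gt(median(cc$g2m_score[cyc]), median(cc$g2m_score[!cyc]))
  expect_true(all(cc$phase[cyc & cc$g2m_score > 0] %in% c("G2M", "S")))
  # determinism of the control-set draw
  cc2 <- cell_cycle_score(logcpt, s_ref, spec$g2m_genes, seed = 1)
  expect_identical(cc$g2m_score, cc2$g2m_score)

  # an all-zero cell scores 0 on both programs and is called G1
  zeroed <- cbind(logcpt, zero = 0)
  cz <- cell_cycle_score(zeroed, s_ref, spec$g2m_genes, seed = 1)
  last <- nrow(cz)
  expect_equal(cz$s_score[last], 0)
  expect_equal(cz$g2m_score[last], 0)
  expect_equal(cz$phase[last], "G1")
})

test_that("G2/M shift test handles exact and approximate regimes", {
  sym <- g2m_shift_test(c(1, 4, 2, 3),
                        c("control", "control", "mutant", "mutant"))
  expect_equal(sym$p, 1)

  set.seed(12)
  scores <- c(rnorm(100, 0, 0.15), rnorm(100, 0, 0.15) - 0.3)
  gt <- rep(c("control", "mutant"), each = 100)
  res <- g2m_shift_test(scores, gt)
  expect_lt(res$p, 0.01)
  expect_lt(res$delta_median, 0)

  # normal approximation tracks exact enumeration at n = 20/20
  for (i in 1:5) {
    x <- rnorm(20); y <- rnorm(20)
    gt20 <- rep(c("control", "mutant"), each = 20)
    exact_p <- g2m_shift_test(c(x, y), gt20, exact = TRUE)$p
    approx_p <- g2m_shift_test(c(x, y), gt20, exact = FALSE)$p
    expect_equal(exact_p, wilcox.test(x, y, exact = TRUE)$p.value)
    expect_lt(abs(approx_p - exact_p), 0.02)
  }
  expect_error(g2m_shift_test(1:4, rep("control", 4)), "both genotypes")
})

test_that("spearman correlation is rank-invariant with a t-approximate p", {
  x <- c(0.3, 1.2, -0.5, 2.2, 0.9, -1.4)
  expect_equal(spearman(x, x)$rho, 1)
  expect_equal(spearman(x, -x)$rho, -1)
  expect_equal(spearman(x, exp(x))$rho, 1)
  expect_equal(spearman(x, x)$p, 0)
  set.seed(3)
  a <- rnorm(40); b <- a + rnorm(40)
  ref <- suppressWarnings(stats::cor.test(a, b, method = "spearman"))
  mine <- spearman(a, b)
  expect_equal(mine$rho, unname(ref$estimate), tolerance = 1e-12)
  expect_error(spearman(rep(1, 5), rnorm(5)), "constant")
})

test_that("BH adjustment follows the step-up rule and its invariants", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(rep(1, 4)), rep(1, 4))
  expect_equal(bh_adjust(0.2), 0.2)
  set.seed(2)
  p <- runif(30)
  q <- bh_adjust(p)
  expect_true(all(q >= p))
  ord <- order(p)
  expect_true(all(diff(q[ord]) >= -1e-15))
  shuffle <- sample(30)
  expect_equal(bh_adjust(p[shuffle]), q[shuffle])
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
})
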