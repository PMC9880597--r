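# Block-structured expression: each anchor drives its own gene block.
block_expression <- function(n_cells = 120, block_size = 20, n_noise = 40,
                             seed = 5) {
  set.seed(seed)
  anchors <- c("Nkx2-2", "Olig2", "Dbx1", "Rspo3")
  rows <- list()
  for (a in anchors) {
    z <- rnorm(n_cells)
    block <- t(sapply(seq_len(block_size), function(i) {
      z + rnorm(n_cells, sd = 0.4)
    }))
    rownames(block) <- c(a, paste0(a, ".blk", seq_len(block_size - 1)))
    rows[[a]] <- block
  }
  noise <- matrix(rnorm(n_noise * n_cells), n_noise, n_cells,
                  dimnames = list(paste0("noise", seq_len(n_noise)), NULL))
  m <- rbind(do.call(rbind, rows), noise)
  colnames(m) <- paste0("c", seq_len(n_cells))
  m
}

test_that("anchor-correlated panel matches a brute-force correlation oracle", {
  m <- block_expression()
  anchors <- c("Nkx2-2", "Olig2", "Dbx1", "Rspo3")
  res <- anchor_correlated_features(m, anchors, k = 10)
  expect_lte(length(res$panel_genes), 80)
  for (a in anchors) {
    sel <- res$panel_table
    pos <- sel$gene[sel$anchor == a & sel$direction == "positive"]
    # brute force: correlate every gene with the anchor by hand
    r <- apply(m, 1, function(g) cor(g, m[a, ]))
    oracle <- names(sort(r, decreasing = TRUE))[1:10]
    expect_setequal(pos, oracle)
    expect_equal(pos[1], a)                 # self-correlation r = 1 leads
    expect_true(all(startsWith(pos, a) | pos == a))  # all from own block
  }
  # k = 0 gives an empty panel; absent/constant anchors error
  expect_equal(length(anchor_correlated_features(m, anchors, k = 0)$panel_genes), 0)
  expect_error(anchor_correlated_features(m, "Missing"), "absent")
  m2 <- m; m2["Olig2", ] <- 1
  expect_error(anchor_correlated_features(m2, anchors), "zero variance")
})

test_that("the panel is invariant to cell order", {
  m <- block_expression(seed = 8)
  anchors <- c("Nkx2-2", "Olig2")
  a1 <- anchor_correlated_features(m, anchors, k = 5)
  set.seed(2)
  a2 <- anchor_correlated_features(m[, sample(ncol(m))], anchors, k = 5)
  expect_identical(a1$panel_genes, a2$panel_genes)
})

test_that("correlation-distance clustering recovers planted gene blocks", {
  # perfectly correlated within, anti-correlated across: exact split
  set.seed(3)
  v <- rnorm(50)
  m <- rbind(v, 2 * v + 1, 3 * v, -v, -2 * v + 5, -0.5 * v)
  rownames(m) <- paste0("g", 1:6)
  groups <- cluster_feature_genes(m, rownames(m), 2)
  expect_setequal(groups[[1]], c("g1", "g2", "g3"))
  expect_setequal(groups[[2]], c("g4", "g5", "g6"))
  # singleton cut
  expect_equal(lengths(cluster_feature_genes(m, rownames(m), 6)),
               setNames(rep(1L, 6), paste0("group", 1:6)))

  # three noisy blocks, within-correlation 0.9, across 0: exact recovery
  set.seed(4)
  n <- 400
  blocks <- lapply(1:3, function(b) {
    z <- rnorm(n)
    t(sapply(1:6, function(i) sqrt(0.9) * z + sqrt(0.1) * rnorm(n)))
  })
  m3 <- do.call(rbind, blocks)
  rownames(m3) <- paste0("b", rep(1:3, each = 6), ".", rep(1:6, 3))
  g3 <- cluster_feature_genes(m3, rownames(m3), 3)
  for (grp in g3) {
    expect_equal(length(unique(substr(grp, 1, 2))), 1)
    expect_equal(length(grp), 6)
  }
  # constant genes are dropped with a warning
  m4 <- rbind(m, const = rep(1, 50))
  expect_warning(cluster_feature_genes(m4, rownames(m4), 2), "constant")
})

test_that("cells are assigned by size-normalised set totals with rostral ties", {
  sets <- list(A = c("a1", "a2"), B = c("b1", "b2", "b3"))
  panel <- feature_panel(sets, subpop_order = c("A", "B"))
  cpt <- matrix(0, 5, 3,
                dimnames = list(c("a1", "a2", "b1", "b2", "b3"),
                                c("cellA", "cellTie", "cellZero")))
  cpt[c("a1", "a2"), "cellA"] <- 10
  cpt[, "cellTie"] <- c(3, 3, 2, 2, 2)   # A: 6/2 = 3; B: 6/3 = 2 -> A wins
  res <- assign_cells(cpt, panel)
  expect_equal(res$label, c("A", "A", "unassigned"))
  expect_false(any(res$tie))
  # exact tie: most rostral label wins and the tie is flagged
  cpt[, "cellTie"] <- c(2, 2, 2, 2, 2)   # A: 2, B: 2
  res2 <- assign_cells(cpt, panel)
  expect_equal(res2$label[2], "A")
  expect_true(res2$tie[2])
  # unnormalised mode favours the larger set on equal per-gene signal
  res3 <- assign_cells(cpt, panel, normalize = FALSE)
  expect_equal(res3$label[2], "B")
  expect_error(assign_cells(cpt, feature_panel(list(A = "zzz"))), "no genes")
})

test_that("labels are invariant to per-cell count scaling", {
  sim <- simulate_progenitor_field(tiny_spec(n = 150), seed = 3)
  cpt1 <- normalize_cpt(sim$counts)
  scaled <- sim$counts %*% Matrix::Diagonal(x = sample(1:5, 150, TRUE))
  dimnames(scaled) <- dimnames(sim$counts)
  cpt2 <- normalize_cpt(scaled)
  panel <- default_feature_panel()
  expect_equal(assign_cells(cpt1, panel)$label,
               assign_cells(cpt2, panel)$label)
})

test_that("hard-boundary simulations are classified nearly perfectly", {
  spec <- tiny_spec(n = 400, softness = 0)
  sim <- simulate_progenitor_field(spec, seed = 0)
  res <- assign_cells(normalize_cpt(sim$counts), default_feature_panel())
  expect_gte(mean(res$label == sim$truth$domain), 0.95)
  # label frequencies match truth frequencies within 2 SE
  nm <- vapply(spec$domains, `[[`, "", "name")
  f_hat <- table(factor(res$label, nm)) / 400
  f_true <- table(factor(sim$truth$domain, nm)) / 400
  se <- sqrt(as.numeric(f_true) * (1 - as.numeric(f_true)) / 400)
  expect_true(all(abs(as.numeric(f_hat) - as.numeric(f_true)) <=
                    2 * se + 1e-12))
})

test_that("binary marker gating follows the raw-count and CPT rules", {
  m <- Matrix::Matrix(matrix(c(0, 1, 5, 0), 2, 2,
                             dimnames = list(c("Sox2", "Foxp2"),
                                             c("c1", "c2"))), sparse = TRUE)
  g <- gate_binary_marker(m, "Sox2")
  expect_equal(unname(g), c(FALSE, TRUE))
  cpt <- normalize_cpt(m)
  g2 <- gate_binary_marker(m, "Foxp2", threshold = 500, cpt = cpt)
  expect_equal(unname(g2), c(TRUE, FALSE))
  expect_error(gate_binary_marker(m, "Olig3"), "not found")

  # lineage: late double-positive cells are rare
  sim <- simulate_lineage(tiny_spec(n = 500), seed = 1)
  late <- sim$truth$pseudotime > 0.5
  dp <- gate_binary_marker(sim$counts, "Sox2") &
        gate_binary_marker(sim$counts, "Foxp2")
  expect_lt(mean(dp[late]), 0.05)
})
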