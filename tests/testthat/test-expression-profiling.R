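test_that("TPM normalisation matches hand arithmetic and its invariances", {
  m <- matrix(c(10, 20), 2, 1, dimnames = list(c("a", "b"), "s1"))
  tpm <- counts_to_tpm(m, gene_lengths = c(a = 1000, b = 2000))
  expect_equal(unname(tpm[, 1]), c(5e5, 5e5))

  one <- counts_to_tpm(matrix(7, 1, 1, dimnames = list("g", "s")),
                       gene_lengths = c(g = 1234))
  expect_equal(unname(one[1, 1]), 1e6)

  es <- generate_expression_matrix(seed = 2)
  tpm <- counts_to_tpm(es)
  expect_true(all(abs(colSums(tpm) - 1e6) < 1e-6 * 1e6))
  # depth invariance
  doubled <- counts_to_tpm(es$counts * 2, gene_lengths = es$gene_lengths)
  expect_equal(tpm, doubled)

  zero <- es$counts; zero[, 1] <- 0
  expect_error(counts_to_tpm(zero, gene_lengths = es$gene_lengths),
               colnames(zero)[1])
})

test_that("gene Z-scores standardise rows and drop flat genes", {
  m <- matrix(c(1, 2, 3), 1, 3, dimnames = list("g", paste0("s", 1:3)))
  expect_equal(unname(zscore_genes(m)[1, ]), c(-1, 0, 1))

  es <- generate_expression_matrix(seed = 3)
  z <- zscore_genes(counts_to_tpm(es))
  expect_true(all(abs(rowMeans(z)) < 1e-12))
  expect_true(all(abs(apply(z, 1, sd) - 1) < 1e-12))

  flat <- rbind(m, flat_gene = c(2, 2, 2))
  expect_message(z2 <- zscore_genes(flat), "zero-variance")
  expect_identical(attr(z2, "dropped"), "flat_gene")
  expect_error(zscore_genes(m[, 1, drop = FALSE]), "2 samples")
})

test_that("correlation clustering uses 1 - Pearson r and matches brute force", {
  withr::with_seed(5, {
    m <- matrix(rnorm(80), 8, 10,
                dimnames = list(paste0("g", 1:8), paste0("s", 1:10)))
    cl <- correlation_cluster(m, top_n = Inf)
    for (i in 1:9) for (j in (i + 1):10) {
      expect_equal(cl$cor_matrix[i, j], brute_pearson(m[, i], m[, j]),
                   tolerance = 1e-12)
      expect_equal(cl$dist_matrix[i, j], 1 - brute_pearson(m[, i], m[, j]),
                   tolerance = 1e-12)
    }
    expect_equal(unname(diag(cl$cor_matrix)), rep(1, 10))
    expect_true(isSymmetric(cl$cor_matrix))
    expect_true(all(diff(cl$hclust$height) >= -1e-12))

    # identical samples at distance zero merge first
    m2 <- cbind(m, s11 = m[, 1])
    cl2 <- correlation_cluster(m2, top_n = Inf)
    first <- sort(cl2$hclust$labels[-cl2$hclust$merge[1, ]])
    expect_identical(first, c("s1", "s11"))

    # anti-correlated pair at distance 2
    m3 <- cbind(a = m[, 1], b = -m[, 1])
    cl3 <- correlation_cluster(m3, top_n = Inf)
    expect_equal(cl3$dist_matrix["a", "b"], 2)

    # sample clustering is invariant to gene (row) order; gene clustering is
    # invariant to a positive affine rescaling of any single gene
    perm <- sample(nrow(m))
    expect_equal(correlation_cluster(m[perm, ], top_n = Inf)$cor_matrix,
                 cl$cor_matrix)
    clg <- correlation_cluster(m, axis = "genes")
    m4 <- m; m4[3, ] <- 5 * m4[3, ] + 2
    expect_equal(correlation_cluster(m4, axis = "genes")$cor_matrix,
                 clg$cor_matrix, tolerance = 1e-12)

    m5 <- rbind(m, flat = rep(1, 10))
    expect_error(correlation_cluster(m5, axis = "genes"), "flat")
  })
})

test_that("synthetic four-group design clusters deactivated with quiescent samples", {
  es <- generate_expression_matrix(seed = 1)
  z <- zscore_genes(counts_to_tpm(es))
  cl <- correlation_cluster(z)
  grp <- es$sample_groups

  # on mean correlations, daHSC sits with qHSC and aHSC_d7 with aHSC_d10
  mean_r <- function(g1, g2) {
    r <- cl$cor_matrix[names(grp)[grp == g1], names(grp)[grp == g2]]
    mean(r[r < 1])
  }
  expect_gt(mean_r("daHSC_d10", "qHSC_d0"), mean_r("daHSC_d10", "aHSC_d7"))
  expect_gt(mean_r("daHSC_d10", "qHSC_d0"), mean_r("daHSC_d10", "aHSC_d10"))
  expect_gt(mean_r("aHSC_d7", "aHSC_d10"), mean_r("aHSC_d7", "qHSC_d0"))

  # dendrogram: the tightest super-group containing all daHSC leaves also
  # contains the qHSC leaves but no activated sample
  merged_groups <- stats::cutree(cl$hclust, k = 2)
  expect_equal(length(unique(merged_groups[grp %in% c("daHSC_d10", "qHSC_d0")])), 1)
  expect_equal(length(unique(merged_groups[grp %in% c("aHSC_d7", "aHSC_d10")])), 1)
  expect_false(merged_groups[[which(grp == "daHSC_d10")[1]]] ==
                 merged_groups[[which(grp == "aHSC_d7")[1]]])

  expect_match(cluster_newick(cl), "^\\(")
})

test_that("PCA behaves on degenerate and structured input", {
  # one direction of variation -> PC1 explains everything
  base <- matrix(rep(c(1, 2, 3, 4), each = 5), 5, 4,
                 dimnames = list(paste0("g", 1:5), paste0("s", 1:4)))
  pc <- pca_samples(base, log_transform = FALSE)
  expect_equal(pc$var_explained[1], 1)
  expect_true(all(diff(pc$var_explained) <= 1e-12))
  expect_lte(sum(pc$var_explained), 1 + 1e-12)

  # duplicated samples score identically
  es <- generate_expression_matrix(seed = 4)
  tpm <- counts_to_tpm(es)
  dup <- cbind(tpm, dup1 = tpm[, 1])
  pdup <- pca_samples(dup)
  s <- pdup$scores
  expect_equal(unlist(s[s$sample == "dup1", -(1:2)]),
               unlist(s[s$sample == colnames(tpm)[1], -(1:2)]))

  # activated day-7 and day-10 samples sit together in PC1-2 space
  pc2 <- pca_samples(tpm, es$sample_groups)
  cent <- function(g) {
    colMeans(pc2$scores[pc2$scores$group == g, c("PC1", "PC2")])
  }
  d <- function(u, v) sqrt(sum((u - v)^2))
  expect_lt(d(cent("aHSC_d7"), cent("aHSC_d10")),
            d(cent("aHSC_d7"), cent("qHSC_d0")))
  expect_lt(d(cent("aHSC_d7"), cent("aHSC_d10")),
            d(cent("aHSC_d10"), cent("daHSC_d10")))

  expect_error(pca_samples(tpm[, 1, drop = FALSE]), "2 samples")
})

test_that("volcano statistics recover programmed effects and rank fibrosis genes down", {
  # a noise-free 4-fold drop is recovered exactly (epsilon = 0):
  # the compensating gene keeps per-sample totals, hence TPM scaling, fixed
  tpm0 <- matrix(
    c(400, 600, 401, 599, 399, 601,   # group a: gene down ~400, filler ~600
      100, 900, 101, 899, 99, 901),   # group b: gene down ~100
    nrow = 2,
    dimnames = list(c("down4", "filler"), paste0("s", 1:6))
  ) * 1000
  g0 <- setNames(rep(c("a", "b"), each = 3), paste0("s", 1:6))
  v0 <- volcano_stats(tpm0, g0, "a", "b", epsilon = 0)
  expect_equal(v0$log2_fc[v0$gene == "down4"], -2)

  # identical groups give log2FC 0
  same <- matrix(rep(c(5, 6, 7, 5, 6, 7), 2), 2, 6, byrow = TRUE,
                 dimnames = list(c("g1", "g2"), paste0("s", 1:6)))
  gsame <- setNames(rep(c("A", "B"), each = 3), paste0("s", c(1:3, 1:3 + 3)))
  vsame <- volcano_stats(same, gsame, "A", "B")
  expect_equal(vsame$log2_fc, c(0, 0))

  # stochastic defaults: fibrosis markers fall in the down-in-daHSC quadrant
  es <- generate_expression_matrix(seed = 1)
  v <- volcano_stats(counts_to_tpm(es), es$sample_groups,
                     "aHSC_d10", "daHSC_d10")
  fib <- tidy(v)[tidy(v)$gene %in% c("COL1A1", "TGFB1"), ]
  expect_true(all(fib$log2_fc < -1))
  expect_true(all(fib$p_value < 0.05))
  expect_false(is.unsorted(v$p_value, na.rm = TRUE))

  expect_error(volcano_stats(counts_to_tpm(es), es$sample_groups,
                             "aHSC_d10", "missing_group"), "at least 2")
})
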