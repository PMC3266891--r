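test_that("genotype table deduplicates rows and counts subjects", {
  g <- rbind(c(0, 1, 2), c(1, 0, 0), c(0, 1, 2), c(0, 1, 2))
  tab <- genotype_table(g)
  expect_equal(nrow(tab$codes), 2L)
  expect_equal(sort(tab$counts), c(1L, 3L))
  expect_equal(sum(tab$counts), 4L)
  expect_equal(tab$codes[tab$subject_index[1L], ], g[1L, ])

  # all-identical subjects collapse to H = 1 (keep one varying SNP valid)
  g1 <- rbind(c(0, 1), c(0, 1), c(1, 0))
  tab1 <- genotype_table(g1)
  expect_equal(nrow(tab1$codes), 2L)

  # brute-force row-uniqueness oracle on a random matrix
  gr <- rand_genotypes(50, 5, seed = 7)
  H_oracle <- length(unique(apply(gr, 1L, paste, collapse = "-")))
  expect_equal(nrow(genotype_table(gr)$codes), H_oracle)
})

test_that("genotype table validates input", {
  expect_error(genotype_table(rbind(c(0, 3), c(1, 0))), "0, 1 or 2")
  expect_error(genotype_table(rbind(c(0, NA), c(1, 0))), "missing")
  # monomorphic SNP named in the error
  g <- cbind(c(0, 1, 2), c(1, 1, 1))
  colnames(g) <- c("rs1", "rs2")
  expect_error(genotype_table(g), "rs2")
})

test_that("snp variance is the population variance over subjects", {
  g <- cbind(c(0, 1, 2, 1), c(0, 0, 1, 1))
  tab <- genotype_table(g)
  expect_equal(tab$snp_variance,
               c(mean(g[, 1]^2) - mean(g[, 1])^2,
                 mean(g[, 2]^2) - mean(g[, 2])^2))
})

test_that("genotype distance is a variance-standardized semimetric", {
  # column 1 has population variance 0.5; rows differing by one unit there
  g <- rbind(c(0, 0), c(1, 0), c(2, 1), c(1, 1))
  tab <- genotype_table(g)
  expect_equal(tab$snp_variance[1L], 0.5)
  d <- genotype_distance(tab)
  expect_equal(diag(d), rep(0, nrow(d)))
  expect_equal(d, t(d))
  expect_true(all(d[upper.tri(d)] > 0))
  i <- tab$subject_index
  expect_equal(d[i[1L], i[2L]], 1 / 0.5)   # one-unit difference at SNP 1 only

  # naive double-loop oracle on a random table
  gr <- rand_genotypes(40, 6, seed = 11)
  tabr <- genotype_table(gr)
  expect_equal(genotype_distance(tabr), oracle_distance(tabr),
               tolerance = 1e-10)
})

test_that("neighbour graph implements mutual/one-way k-NN weights", {
  # k >= H - 1: everyone is in everyone's neighbour set, all weights 2
  g3 <- rbind(c(0, 0), c(1, 1), c(2, 0), c(0, 1))
  tab3 <- genotype_table(g3)
  gr3 <- neighbor_graph(genotype_distance(tab3), n_neighbors = 4)
  w <- gr3$weights
  expect_true(all(w[upper.tri(w)] == 2L))

  # asymmetric one-way relation: points on a line at 0, 1, 3 with k = 1
  d <- as.matrix(dist(c(0, 1, 3)))^2
  gr1 <- neighbor_graph(d, n_neighbors = 1)
  expect_equal(gr1$weights[1L, 2L], 2L)   # mutual nearest
  expect_equal(gr1$weights[2L, 3L], 1L)   # 2 is 3's nearest, not vice versa
  expect_equal(gr1$weights[1L, 3L], 0L)

  expect_error(neighbor_graph(d, n_neighbors = 0), ">= 1")

  # brute-force oracle on a random instance
  gr <- rand_genotypes(60, 5, seed = 3)
  tab <- genotype_table(gr)
  d <- genotype_distance(tab)
  ng <- neighbor_graph(d, n_neighbors = 4)
  expect_equal(ng$weights, oracle_knn_weights(d, 4))
  # every row touches at least n_neighbors positive entries
  expect_true(all(rowSums(ng$weights > 0) >= 4))
})

test_that("neighbour graph is invariant to subject order", {
  g <- rand_genotypes(50, 5, seed = 19)
  set.seed(1)
  perm <- sample(nrow(g))
  w1 <- neighbor_graph(genotype_distance(genotype_table(g)))$weights
  tab2 <- genotype_table(g[perm, ])
  w2 <- neighbor_graph(genotype_distance(tab2))$weights
  # map genotype ids of the permuted table onto the original ordering
  key1 <- apply(genotype_table(g)$codes, 1L, paste, collapse = "")
  key2 <- apply(tab2$codes, 1L, paste, collapse = "")
  m <- match(key1, key2)
  expect_equal(w2[m, m], w1, ignore_attr = TRUE)
})

test_that("regrouping merges genotypes through k-medoids on the distance", {
  g <- rand_genotypes(30, 4, seed = 5)
  tab <- genotype_table(g)
  H <- nrow(tab$codes)
  expect_warning(out <- regroup_genotypes(tab, H), "unchanged")
  expect_identical(out$codes, tab$codes)

  # two exact duplicate blocks: zero within-block distance recovers blocks
  rows <- rbind(c(0, 0, 1), c(0, 1, 1), c(2, 2, 0), c(2, 1, 0))
  gdup <- rows[rep(1:4, times = c(5, 5, 5, 5)), ]
  # genotypes 1,2 close; 3,4 close (differ at middle SNP only)
  tabd <- genotype_table(gdup)
  red <- regroup_genotypes(tabd, 2L)
  expect_equal(nrow(red$codes), 2L)
  lab <- red$subject_index
  expect_equal(length(unique(lab[1:10])), 1L)
  expect_equal(length(unique(lab[11:20])), 1L)
  expect_true(lab[1L] != lab[11L])
  expect_equal(sum(red$counts), 20L)
})

test_that("imputation and r2 pruning helpers behave", {
  g <- rbind(c(0, NA), c(1, 1), c(1, 1), c(NA, 0))
  gi <- impute_genotypes(g)
  expect_false(anyNA(gi))
  expect_equal(gi[4L, 1L], 1)           # rounded mean of (0,1,1)
  # duplicated column is pruned at r2 = 1
  gg <- cbind(c(0, 1, 2, 0, 1), c(0, 1, 2, 0, 1), c(2, 0, 1, 1, 0))
  expect_equal(prune_r2(gg, 0.8), c(1L, 3L))
})
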