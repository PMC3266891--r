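test_that("haplotype-pool genotypes satisfy HWE composition and target MAFs", {
  # single haplotype with frequency 1: all subjects identical homozygotes
  pop1 <- population_model(haplotypes = rbind(c(1, 0, 1)), hap_freq = 1)
  g1 <- simulate_genotypes(pop1, 30, seed = 1)
  expect_true(all(g1 == rep(c(2, 0, 2), each = 30)))
  expect_equal(nrow(unique(g1)), 1L)

  # independent SNPs at the reference frequencies: empirical MAFs within
  # 3 binomial SE of the target (2n draws per SNP)
  pop <- population_model(maf = tag_snp_maf)
  n <- 4000
  g <- simulate_genotypes(pop, n, seed = 2)
  se <- sqrt(tag_snp_maf * (1 - tag_snp_maf) / (2 * n))
  expect_true(all(abs(colMeans(g) / 2 - tag_snp_maf) < 3 * se))
  expect_equal(tag_snp_maf[1], 0.32)
  expect_equal(tag_snp_maf[15], 0.24)

  # explicit two-block pool: within-block r2 matches the pool's analytic
  # value, between-block r2 near zero
  hap <- cbind(c(1, 1, 0, 0), c(1, 0, 1, 0))     # block 1: 2 SNPs? build 2 blocks
  # block A: SNPs 1-2 perfectly coupled in the pool; block B: SNP 3 free
  hapA <- rbind(c(1, 1), c(0, 0), c(1, 1), c(0, 0))
  hapB <- rbind(1, 0, 0, 1)
  pool <- cbind(hapA, hapB)
  fr <- c(0.3, 0.3, 0.2, 0.2)
  pop2 <- population_model(haplotypes = pool, hap_freq = fr)
  # analytic allele-level correlation in the pool
  p1 <- sum(fr * pool[, 1]); p3 <- sum(fr * pool[, 3])
  c13 <- sum(fr * pool[, 1] * pool[, 3]) - p1 * p3
  r2_13 <- c13^2 / (p1 * (1 - p1) * p3 * (1 - p3))
  g2 <- simulate_genotypes(pop2, 6000, seed = 3)
  r2_emp <- cor(g2)^2
  expect_equal(r2_emp[1, 2], 1, tolerance = 1e-9)      # coupled block
  expect_equal(r2_emp[1, 3], r2_13, tolerance = 0.05)  # cross-block
})

test_that("the default population has realistic genotype-space diversity", {
  pop <- default_population()
  expect_s3_class(pop, "population_model")
  # deterministic construction
  pop2 <- default_population()
  expect_identical(pop$haplotypes, pop2$haplotypes)
  expect_identical(pop$hap_freq, pop2$hap_freq)
  g <- simulate_genotypes(pop, 3000, seed = 4)
  H <- nrow(unique(g))
  expect_gt(H, 300); expect_lt(H, 1200)
  expect_lt(max(abs(colMeans(g) / 2 - tag_snp_maf)), 0.08)
})

test_that("cluster rules count risk alleles as specified", {
  rule3 <- region_rule(snps = c(2, 6, 10), cuts = c(1, 2))
  g0 <- matrix(0L, 3, 15)
  expect_equal(assign_true_clusters(g0, rule3), rep(1L, 3))   # region I
  g2 <- g0; g2[, 2] <- 1L; g2[, 6] <- 1L                      # exactly 2
  expect_equal(assign_true_clusters(g2, rule3), rep(2L, 3))
  g3 <- g2; g3[, 10] <- 2L                                    # more than 2
  expect_equal(assign_true_clusters(g3, rule3), rep(3L, 3))

  # brute-force allele-count oracle on a random matrix
  g <- rand_genotypes(80, 15, seed = 5)
  lab <- assign_true_clusters(g, rule3)
  tot <- g[, 2] + g[, 6] + g[, 10]
  expect_equal(lab, ifelse(tot <= 1, 1L, ifelse(tot == 2, 2L, 3L)))

  rule2 <- two_cluster_rule(snps = c(1, 3), threshold = 2)
  expect_equal(assign_true_clusters(g, rule2),
               1L + as.integer(g[, 1] + g[, 3] >= 2))
  ruleS <- single_snp_rule(4, mode = "dominant")
  expect_equal(assign_true_clusters(g, ruleS), 1L + as.integer(g[, 4] > 0))
  expect_error(assign_true_clusters(g[, 1:3], rule3), "beyond")
})

test_that("exposure depends on the genotype cluster as designed", {
  set.seed(6)
  lab <- sample(1:3, 6000, replace = TRUE)
  E <- simulate_exposure(lab, seed = 7)
  expect_true(all(E %in% 0:1))
  p1 <- mean(E[lab == 1]); p23 <- mean(E[lab != 1])
  n1 <- sum(lab == 1); n23 <- sum(lab != 1)
  expect_lt(abs(p1 - 0.3), 3 * sqrt(0.3 * 0.7 / n1))
  expect_lt(abs(p23 - 0.6), 3 * sqrt(0.6 * 0.4 / n23))
  expect_true(all(simulate_exposure(lab, p_exposed = 1, seed = 8) == 1L))
})

test_that("case-control sampling fills exact quotas reproducibly", {
  pop <- population_model(maf = tag_snp_maf[1:8])
  rule <- two_cluster_rule(snps = c(2, 4, 6), threshold = 2)
  spec <- risk_model_spec(rule, alpha = c(0, 1), beta = c(0.3, 1.2),
                          p_exposed = c(0.3, 0.6))
  d1 <- simulate_case_control(pop, spec, 130, 170, seed = 9)
  expect_equal(sum(d1$D), 130L)
  expect_equal(sum(1 - d1$D), 170L)
  d2 <- simulate_case_control(pop, spec, 130, 170, seed = 9)
  expect_identical(d1$D, d2$D)
  expect_identical(d1$table$codes, d2$table$codes)
  expect_equal(length(attr(d1, "truth")$cluster), 300L)

  # degenerate risk model aborts with a diagnostic
  bad <- risk_model_spec(rule, alpha = c(0, 0), beta = c(0, 0),
                         baseline = -40)
  expect_error(simulate_case_control(pop, bad, 50, 50, seed = 10,
                                     max_batches = 3), "quota")
})

test_that("a null risk model leaves covariate distributions undistorted", {
  pop <- population_model(maf = tag_snp_maf[1:6])
  rule <- two_cluster_rule(snps = c(2, 4, 6), threshold = 2)
  m0 <- risk_model_spec(rule, alpha = c(0, 0), beta = c(0, 0),
                        p_exposed = c(0.3, 0.6))
  dat <- simulate_case_control(pop, m0, 700, 700, seed = 11)
  G <- dat$table$codes[dat$genotype_id, ]
  se <- sqrt(tag_snp_maf[1:6] * (1 - tag_snp_maf[1:6]) / (2 * 1400))
  expect_true(all(abs(colMeans(G) / 2 - tag_snp_maf[1:6]) < 4 * se))
  truth <- attr(dat, "truth")$cluster
  expect_lt(abs(mean(dat$E[truth == 1]) - 0.3), 0.05)
  expect_lt(abs(mean(dat$E[truth == 2]) - 0.6), 0.05)
})

test_that("refits on simulated studies recover the generating odds ratios", {
  pop <- default_population()
  rule <- two_cluster_rule(snps = c(2, 6, 10), threshold = 2)

  # main effects: G OR = 4 (cluster 2 vs 1) and E OR = 4, no interaction
  null_spec <- risk_model_spec(rule, alpha = c(0, log(4)), beta = log(4),
                               p_exposed = c(0.3, 0.6))
  dat <- simulate_case_control(pop, null_spec, 1500, 1500, seed = 12)
  truth <- attr(dat, "truth")$cluster
  L2 <- as.numeric(truth == 2)
  fit <- oracle_logistic(dat$D, cbind(1, L2, dat$E))
  se <- sqrt(diag(fit$vcov))
  expect_lt(abs(fit$coef[2] - log(4)), 2 * se[2])
  expect_lt(abs(fit$coef[3] - log(4)), 2 * se[3])

  # interaction contrast log 2 recovered from a known-label fit
  int_spec <- risk_model_spec(rule, alpha = c(0, 0.7),
                              beta = c(0.5, 0.5 + log(2)),
                              p_exposed = c(0.3, 0.6))
  dat2 <- simulate_case_control(pop, int_spec, 1500, 1500, seed = 13)
  t2 <- as.numeric(attr(dat2, "truth")$cluster == 2)
  f2 <- oracle_logistic(dat2$D, cbind(1, t2, dat2$E, t2 * dat2$E))
  se2 <- sqrt(diag(f2$vcov))
  expect_lt(abs(f2$coef[4] - log(2)), 2 * se2[4])
})
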