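test_that("model log-likelihood matches collapse cases and a naive loop", {
  dat <- small_study(60, 60, J = 5, seed = 2)
  H <- nrow(dat$table$codes)
  n <- length(dat$D)

  # all coefficients zero: every p_i = 1/2
  expect_equal(gep_log_likelihood(dat, rep(1L, H), alpha = 0, beta = 0),
               n * log(0.5))

  # K = 1 equals plain logistic regression log-likelihood
  eta <- -0.4 + 0.8 * dat$E
  expect_equal(gep_log_likelihood(dat, rep(1L, H), alpha = -0.4, beta = 0.8),
               sum(dat$D * eta - log1p(exp(eta))))

  # random instance vs explicit per-subject sigmoid loop
  set.seed(3)
  z <- sample.int(3, H, replace = TRUE)
  alpha <- rnorm(3); beta <- rnorm(3)
  ll <- 0
  for (i in seq_len(n)) {
    k <- z[dat$genotype_id[i]]
    p <- 1 / (1 + exp(-(alpha[k] + beta[k] * dat$E[i])))
    ll <- ll + dat$D[i] * log(p) + (1 - dat$D[i]) * log(1 - p)
  }
  expect_equal(gep_log_likelihood(dat, z, alpha, beta), ll)

  expect_error(gep_log_likelihood(dat, z, alpha, beta[1:2]), "slope")
})

test_that("chains are reproducible and honour the storage contract", {
  dat <- small_study(50, 50, J = 4, seed = 5)
  ctl <- gep_control(iterations = 301, burn_in = 300, thinning = 1, seed = 1,
                     psi_update_every = 5)
  f <- gep_fit(dat, K = 2, control = ctl)
  expect_equal(length(f$samples$psi), 1L)      # exactly one stored draw

  ctl2 <- short_control(seed = 7)
  f1 <- gep_fit(dat, K = 2, control = ctl2)
  f2 <- gep_fit(dat, K = 2, control = ctl2)
  expect_identical(f1$samples, f2$samples)     # bit-identical given the seed
})

test_that("K = 1 posterior agrees with an independent logistic MLE", {
  set.seed(31)
  n <- 1200
  E <- rbinom(n, 1, 0.4)
  X <- cbind(rnorm(n))
  D <- rbinom(n, 1, plogis(-0.5 + 0.9 * E + 0.4 * X))
  dat <- case_control_data(D, E, rand_genotypes(n, 4, seed = 32),
                           covariates = X)
  fit <- gep_fit(dat, K = 1, control = gep_control(
    iterations = 6000, burn_in = 2000, thinning = 4, seed = 33))
  ml <- oracle_logistic(D, cbind(1, E, X))
  se <- sqrt(diag(ml$vcov))
  post <- c(mean(fit$samples$alpha), mean(fit$samples$beta),
            mean(fit$samples$gamma))
  expect_true(all(abs(post - ml$coef) < 2 * se))
})

test_that("allocation chain has the enumerated stationary distribution", {
  # tiny instance, coefficients frozen (zero proposal scale), psi fixed at 0:
  # the z-chain must converge to p(z) proportional to the likelihood
  set.seed(41)
  base <- rbind(c(0, 0, 1), c(1, 0, 1), c(2, 1, 0), c(0, 2, 2))
  g <- base[sample(1:4, 24, replace = TRUE), ]
  while (nrow(unique(g)) < 4) g <- base[sample(1:4, 24, replace = TRUE), ]
  E <- rbinom(24, 1, 0.5)
  D <- rbinom(24, 1, plogis(-0.3 + 0.9 * E))
  dat <- case_control_data(D, E, g, n_neighbors = 2)
  H <- nrow(dat$table$codes)
  K <- 2

  z0 <- pam_cluster(genotype_distance(dat$table), k = K)$labels
  st <- gepotts:::start_coefficients(dat, z0, K, "interaction")
  ctl <- gep_control(iterations = 42000, burn_in = 2000, thinning = 2,
                     prop_sd = c(alpha = 0, beta = 0, gamma = 0, psi = 0),
                     adapt = FALSE, psi_max = 0, seed = 42)
  fit <- gep_fit(dat, K = K, control = ctl)
  # frozen coefficients as expected
  expect_true(all(fit$samples$alpha[, 1] == fit$samples$alpha[1, 1]))

  states <- as.matrix(expand.grid(rep(list(1:K), H)))
  lp <- apply(states, 1L, function(z)
    gep_log_likelihood(dat, z, st$alpha, st$beta, model = "interaction"))
  pr <- exp(lp - max(lp)); pr <- pr / sum(pr)
  key <- apply(states, 1L, paste, collapse = "")
  emp <- table(factor(apply(fit$samples$z, 1L, paste, collapse = ""),
                      levels = key)) / nrow(fit$samples$z)
  # correlated draws: allow generous Monte-Carlo slack
  expect_lt(max(abs(as.numeric(emp) - pr)), 0.03)
})

test_that("likelihood dominance pins a genotype's allocation", {
  # two genotype groups with opposite case loads and strong effects: the
  # posterior must separate them into different clusters essentially always
  set.seed(51)
  gA <- c(0, 0, 0); gB <- c(2, 2, 2)
  g <- rbind(matrix(gA, 60, 3, byrow = TRUE), matrix(gB, 60, 3, byrow = TRUE))
  D <- c(rbinom(60, 1, 0.95), rbinom(60, 1, 0.05))
  E <- rbinom(120, 1, 0.5)
  dat <- case_control_data(D, E, g)
  fit <- gep_fit(dat, K = 2, control = short_control(seed = 52))
  pi_ab <- coassignment_matrix(fit)[1, 2]
  expect_lt(pi_ab, 0.05)
})

test_that("MCMH coupling update matches the exact-normalizer sampler", {
  # H = 5 genotypes: run the packaged MCMH chain and an independent R
  # sampler that uses the enumerated normalizing constant; their psi
  # posteriors must agree within Monte-Carlo error
  set.seed(61)
  base <- rbind(c(0, 0, 1), c(1, 0, 1), c(2, 1, 0), c(0, 2, 2), c(1, 1, 1))
  g <- base[sample(1:5, 40, replace = TRUE), ]
  while (nrow(unique(g)) < 5) g <- base[sample(1:5, 40, replace = TRUE), ]
  E <- rbinom(40, 1, 0.5)
  D <- rbinom(40, 1, plogis(-0.3 + 0.8 * E))
  dat <- case_control_data(D, E, g, n_neighbors = 2)

  fit <- gep_fit(dat, K = 2, control = gep_control(
    iterations = 40000, burn_in = 8000, thinning = 8,
    m_auxiliary = 50, aux_sweeps = 5, psi_update_every = 1, seed = 62))

  # independent oracle: same blocks but psi updated with the exact ratio
  oracle_psi <- local({
    set.seed(63)
    K <- 2; H <- 5
    W <- dat$graph$weights
    z <- sample.int(K, H, TRUE); psi <- 0.6
    alpha <- rep(0, K); beta <- rep(0, K)
    ll <- function(z, a, b) gep_log_likelihood(dat, z, a, b)
    keep <- numeric(0)
    # precompute exact normalizer on a fine grid for speed
    grid <- seq(0, 1.2, by = 0.01)
    lz <- vapply(grid, function(p) potts_log_norm_exact(p, dat$graph, K), 0)
    lZ <- function(p) lz[[which.min(abs(grid - p))]]
    for (it in 1:6000) {
      for (k in 1:K) {
        a2 <- alpha; a2[k] <- a2[k] + rnorm(1, 0, 0.4)
        if (log(runif(1)) < ll(z, a2, beta) - ll(z, alpha, beta) +
            dnorm(a2[k], 0, 2, TRUE) - dnorm(alpha[k], 0, 2, TRUE)) alpha <- a2
        b2 <- beta; b2[k] <- b2[k] + rnorm(1, 0, 0.4)
        if (log(runif(1)) < ll(z, alpha, b2) - ll(z, alpha, beta) +
            dnorm(b2[k], 0, 2, TRUE) - dnorm(beta[k], 0, 2, TRUE)) beta <- b2
      }
      for (h in 1:H) {
        lp <- vapply(1:K, function(k) {
          zz <- z; zz[h] <- k
          psi * potts_suff_stat(zz, dat$graph) + ll(zz, alpha, beta)
        }, 0)
        z[h] <- sample.int(K, 1, prob = exp(lp - max(lp)))
      }
      U <- potts_suff_stat(z, dat$graph)
      prop <- psi + rnorm(1, 0, 0.15)
      while (prop < 0 || prop > 1.2) {
        if (prop < 0) prop <- -prop
        if (prop > 1.2) prop <- 2 * 1.2 - prop
      }
      if (log(runif(1)) < (prop - psi) * U - (lZ(prop) - lZ(psi))) psi <- prop
      if (it > 1000) keep <- c(keep, psi)
    }
    keep
  })
  # compare posterior means; SE from thinned oracle draws
  m_or <- mean(oracle_psi)
  se <- sd(oracle_psi[seq(1, length(oracle_psi), by = 10)]) /
    sqrt(length(oracle_psi) / 10)
  expect_lt(abs(mean(fit$samples$psi) - m_or), 3 * se + 0.03)
})
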