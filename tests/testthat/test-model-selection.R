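# build a synthetic gep_fit with prescribed draws, so DIC pieces can be
# checked without running a chain
fake_fit <- function(dat, zdraws, alpha, beta, model = "interaction") {
  ll <- vapply(seq_len(nrow(zdraws)), function(t)
    gep_log_likelihood(dat, zdraws[t, ], alpha[t, ],
                       if (model == "interaction") beta[t, ] else beta[t, 1],
                       model = model), 0)
  structure(list(
    samples = list(z = zdraws, alpha = alpha, beta = beta,
                   gamma = matrix(0, nrow(zdraws), 0),
                   psi = rep(0.5, nrow(zdraws)), loglik = ll),
    acceptance = c(alpha = 0.3, beta = 0.3, gamma = NA, z = 0.3, psi = 0.3),
    K = ncol(alpha), model = model,
    control = gep_control(iterations = 2, burn_in = 1, thinning = 1),
    data = dat), class = "gep_fit")
}

test_that("a degenerate chain gives D_bar = D_hat and zero pD", {
  dat <- small_study(40, 40, J = 4, seed = 3)
  H <- nrow(dat$table$codes)
  z <- matrix(rep(rep(1:2, length.out = H), each = 10), nrow = 10)
  a <- matrix(rep(c(-0.2, 0.4), each = 10), 10)
  b <- matrix(rep(c(0.1, 0.9), each = 10), 10)
  f <- fake_fit(dat, z, a, b)
  d <- dic(f)
  expect_equal(d$pD, 0, tolerance = 1e-10)
  expect_equal(d$DIC, d$D_bar)
  expect_equal(d$D_bar, -2 * f$samples$loglik[1L])
})

test_that("DIC is invariant under per-draw cluster relabelling", {
  dat <- small_study(60, 60, J = 5, seed = 4)
  fit <- gep_fit(dat, K = 2, control = short_control(seed = 5))
  d0 <- dic(fit)

  flip <- fit
  T_ <- nrow(fit$samples$z)
  set.seed(6)
  swap <- sample(c(TRUE, FALSE), T_, replace = TRUE)
  flip$samples$z[swap, ] <- 3L - fit$samples$z[swap, , drop = FALSE]
  flip$samples$alpha[swap, ] <- fit$samples$alpha[swap, 2:1, drop = FALSE]
  flip$samples$beta[swap, ] <- fit$samples$beta[swap, 2:1, drop = FALSE]
  d1 <- dic(flip)
  expect_equal(d1$DIC, d0$DIC, tolerance = 1e-10)
  expect_equal(d1$pD, d0$pD, tolerance = 1e-10)
})

test_that("K = 1 DIC matches an independent Bayesian logistic sampler", {
  set.seed(7)
  n <- 400
  E <- rbinom(n, 1, 0.5)
  D <- rbinom(n, 1, plogis(-0.2 + 0.7 * E))
  dat <- case_control_data(D, E, rand_genotypes(n, 4, seed = 8))
  fit <- gep_fit(dat, K = 1, control = gep_control(
    iterations = 20000, burn_in = 5000, thinning = 10, seed = 9))
  d <- dic(fit)

  # independent random-walk MH for plain Bayesian logistic regression
  ind <- local({
    set.seed(10)
    th <- c(0, 0); keep <- matrix(0, 0, 2); lls <- numeric(0)
    ll <- function(th) {
      eta <- th[1] + th[2] * E
      sum(D * eta - log1p(exp(eta)))
    }
    cur <- ll(th)
    for (it in 1:30000) {
      pr <- th + rnorm(2, 0, 0.1)
      new <- ll(pr)
      if (log(runif(1)) < new - cur +
          sum(dnorm(pr, 0, 2, TRUE)) - sum(dnorm(th, 0, 2, TRUE))) {
        th <- pr; cur <- new
      }
      if (it > 5000 && it %% 10 == 0) {
        keep <- rbind(keep, th); lls <- c(lls, cur)
      }
    }
    D_bar <- mean(-2 * lls)
    mhat <- colMeans(keep)
    list(D_bar = D_bar, D_hat = -2 * ll(mhat),
         DIC = 2 * D_bar + 2 * ll(mhat))
  })
  expect_lt(abs(d$DIC - ind$DIC), 1.5)
  expect_lt(abs(d$D_bar - ind$D_bar), 1.5)
})

test_that("+1 rule picks the smallest K within one unit of the minimum", {
  expect_equal(select_k_plus_one(c(`1` = 96.2, `2` = 94.5, `3` = 94.4)), 2L)
  # a K within one unit of the minimum is preferred over the minimizer
  expect_equal(select_k_plus_one(c(`1` = 95.2, `2` = 94.5, `3` = 94.4)), 1L)
  expect_equal(select_k_plus_one(c(`1` = 90, `2` = 93, `3` = 96)), 1L)
  expect_error(select_k_plus_one(numeric(0)), "no DIC")

  # brute-force re-evaluation oracle on random tables
  set.seed(11)
  for (r in 1:20) {
    v <- rnorm(5, 100, 3)
    names(v) <- 1:5
    sel <- select_k_plus_one(v)
    ok <- which(v <= min(v) + 1)
    expect_equal(sel, min(ok))
    expect_lte(sel, which.min(v))          # never larger than the argmin
    expect_equal(select_k_plus_one(v + 17.3), sel)  # shift invariance
  }
})

test_that("+1 SE rule uses the Monte-Carlo SE at the minimizing K", {
  runs <- list(`1` = c(100, 100), `2` = c(90.5, 89.5), `3` = c(89.4, 89.6))
  # means 100 / 90 / 89.5; SE at minimizer (K=3) = 0.1/sqrt(2) ~ 0.0707
  expect_equal(select_k_one_se(runs), 3L)
  runs2 <- list(`1` = c(100, 100), `2` = c(91, 89), `3` = c(88.5, 90.5))
  # means 100 / 90 / 89.5, SE at K=3 = 1/sqrt(2) ~ 0.707: K = 2 qualifies
  expect_equal(select_k_one_se(runs2), 2L)
  expect_error(select_k_one_se(list(`1` = 100, `2` = 90)), "runs per K")

  set.seed(12)
  for (r in 1:20) {
    runs <- lapply(1:4, function(k) rnorm(5, 100 - k, 2))
    names(runs) <- 1:4
    sel <- select_k_one_se(runs)
    means <- vapply(runs, mean, 0)
    i <- which.min(means)
    se <- sd(runs[[i]]) / sqrt(5)
    expect_equal(sel, min(which(means <= means[i] + se)))
    expect_lte(sel, i)
  }
})
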