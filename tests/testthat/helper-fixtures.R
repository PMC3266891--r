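# shared fixtures and independent oracles, all built in code at test time

# random genotype matrix guaranteed polymorphic in every column
rand_genotypes <- function(n, J, seed) {
  set.seed(seed)
  repeat {
    g <- matrix(sample(0:2, n * J, replace = TRUE), n, J)
    v <- apply(g, 2L, function(x) length(unique(x)) > 1L)
    if (all(v)) return(g)
  }
}

# small simulated case-control study with a two-cluster risk structure
small_study <- function(n_cases = 150, n_controls = 150, J = 8, seed = 1,
                        alpha = c(0, 1.2), beta = c(0.2, 1.4),
                        snps = c(2, 4, 6)[c(2, 4, 6) <= J], regroup = NULL) {
  pop <- population_model(maf = tag_snp_maf[seq_len(J)])
  rule <- two_cluster_rule(snps = snps, threshold = 2)
  spec <- risk_model_spec(rule, alpha = alpha, beta = beta,
                          p_exposed = c(0.3, 0.6))
  simulate_case_control(pop, spec, n_cases, n_controls, seed = seed,
                        regroup = regroup)
}

# short chain configuration used across tests
short_control <- function(seed = 1, ...) {
  gep_control(iterations = 1500L, burn_in = 700L, thinning = 4L,
              psi_update_every = 5L, aux_sweeps = 5L, seed = seed, ...)
}

## ---- independent oracles -------------------------------------------------

# brute-force pairwise distance: explicit double loop over SNPs
oracle_distance <- function(tab) {
  H <- nrow(tab$codes); J <- ncol(tab$codes)
  d <- matrix(0, H, H)
  for (a in seq_len(H)) for (b in seq_len(H)) {
    s <- 0
    for (j in seq_len(J))
      s <- s + (tab$codes[a, j] - tab$codes[b, j])^2 / tab$snp_variance[j]
    d[a, b] <- s
  }
  d
}

# brute-force k-NN weights from sorted distance lists
oracle_knn_weights <- function(d, k) {
  H <- nrow(d)
  kk <- min(k, H - 1L)
  nn <- lapply(seq_len(H), function(h) {
    o <- order(d[h, ], seq_len(H))
    setdiff(o, h)[seq_len(kk)]
  })
  w <- matrix(0L, H, H)
  for (a in seq_len(H)) for (b in seq_len(H)) {
    if (a == b) next
    w[a, b] <- (b %in% nn[[a]]) + (a %in% nn[[b]])
  }
  w
}

# naive U(z): double loop over all pairs
oracle_suff_stat <- function(z, W) {
  H <- length(z); u <- 0
  for (a in seq_len(H - 1L)) for (b in (a + 1L):H)
    if (z[a] == z[b]) u <- u + W[a, b]
  u
}

# second, independently coded enumeration of the Potts normalizer:
# iterates integer encodings rather than expand.grid
oracle_log_norm <- function(psi, W, K) {
  H <- nrow(W)
  tot <- 0
  for (code in 0:(K^H - 1)) {
    z <- integer(H); c0 <- code
    for (h in seq_len(H)) { z[h] <- c0 %% K; c0 <- c0 %/% K }
    tot <- tot + exp(psi * oracle_suff_stat(z, W))
  }
  log(tot)
}

# enumeration of exact Potts state probabilities
oracle_potts_probs <- function(psi, W, K) {
  H <- nrow(W)
  states <- as.matrix(expand.grid(rep(list(seq_len(K)), H)))
  lu <- apply(states, 1L, function(z) psi * oracle_suff_stat(z, W))
  p <- exp(lu - max(lu)); p <- p / sum(p)
  list(states = states, probs = p)
}

# independent Newton-Raphson logistic regression (MLE oracle)
oracle_logistic <- function(y, Xd, maxit = 50, tol = 1e-10) {
  b <- rep(0, ncol(Xd))
  for (it in seq_len(maxit)) {
    eta <- drop(Xd %*% b)
    p <- 1 / (1 + exp(-eta))
    wgt <- p * (1 - p)
    score <- crossprod(Xd, y - p)
    info <- crossprod(Xd * wgt, Xd)
    step <- solve(info, score)
    b <- b + step
    if (max(abs(step)) < tol) break
  }
  eta <- drop(Xd %*% b)
  list(coef = drop(b),
       loglik = sum(y * eta - log1p(exp(eta))),
       vcov = solve(info))
}

# exhaustive k-medoids: best objective over all medoid subsets (small H)
oracle_pam_objective <- function(d, k) {
  H <- nrow(d)
  combs <- utils::combn(H, k)
  best <- Inf
  for (i in seq_len(ncol(combs))) {
    m <- combs[, i]
    obj <- sum(apply(d[, m, drop = FALSE], 1L, min))
    if (obj < best) best <- obj
  }
  best
}
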