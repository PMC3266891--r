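#' Minor allele frequencies of the 15 tagging SNPs used as the default
#' simulated region
#'
#' Control-sample minor allele frequencies for the 15 tag SNPs of the
#' 15q25.1 candidate region (in genomic order) that define the default
#' [population_model()].
#'
#' @format numeric vector of length 15, values in (0, 0.5].
#' @export
tag_snp_maf <- c(0.32, 0.22, 0.38, 0.23, 0.39, 0.17, 0.12, 0.24,
                 0.36, 0.37, 0.29, 0.41, 0.30, 0.35, 0.24)

#' Haplotype population model for simulated genotypes
#'
#' Describes the haplotype distribution from which simulated subjects draw
#' two independent haplotypes (Hardy-Weinberg equilibrium at the haplotype
#' level). Two parameterizations are supported:
#' \itemize{
#'   \item an explicit haplotype pool (`haplotypes` 0/1 matrix plus
#'     `hap_freq`), for which linkage disequilibrium is fully determined by
#'     the pool; or
#'   \item per-SNP minor allele frequencies with optional LD blocks: within
#'     each block, haplotype alleles are generated through a Gaussian
#'     copula with first-order autoregressive latent correlation `rho`, so
#'     marginal frequencies are exact and correlation decays along the
#'     block; SNPs in different blocks are independent.
#' }
#'
#' @param maf per-SNP minor allele frequencies in (0, 0.5] (default: the
#'   15 tag-SNP frequencies in [tag_snp_maf]).
#' @param blocks optional integer vector (length J) of block ids.
#' @param rho latent within-block AR(1) correlation (default 0:
#'   independent SNPs).
#' @param haplotypes optional explicit pool: rows are haplotypes (0/1).
#' @param hap_freq frequencies of the pool rows (summing to 1).
#' @return object of class `population_model`.
#' @export
population_model <- function(maf = tag_snp_maf, blocks = NULL, rho = 0,
                             haplotypes = NULL, hap_freq = NULL) {
  if (!is.null(haplotypes)) {
    haplotypes <- as.matrix(haplotypes)
    if (!all(haplotypes %in% 0:1)) stop("haplotypes must be 0/1")
    if (is.null(hap_freq)) hap_freq <- rep(1 / nrow(haplotypes), nrow(haplotypes))
    if (length(hap_freq) != nrow(haplotypes) ||
        abs(sum(hap_freq) - 1) > 1e-8 || any(hap_freq < 0))
      stop("hap_freq must be a probability vector over haplotype rows")
    J <- ncol(haplotypes)
    maf <- as.numeric(crossprod(hap_freq, haplotypes))
  } else {
    if (any(maf <= 0 | maf > 0.5)) stop("maf must lie in (0, 0.5]")
    J <- length(maf)
    if (is.null(blocks)) blocks <- seq_len(J)
    if (length(blocks) != J) stop("blocks must have one entry per SNP")
    if (abs(rho) >= 1) stop("rho must lie in (-1, 1)")
  }
  structure(list(J = J, maf = maf, blocks = blocks, rho = rho,
                 haplotypes = haplotypes, hap_freq = hap_freq),
            class = "population_model")
}

r_haplotypes <- function(pop, n_hap) {
  if (!is.null(pop$haplotypes)) {
    idx <- sample.int(nrow(pop$haplotypes), n_hap, replace = TRUE,
                      prob = pop$hap_freq)
    h <- pop$haplotypes[idx, , drop = FALSE]
    if (!is.null(pop$rare_model) && pop$rare_eps > 0) {
      mix <- stats::rbinom(n_hap, 1L, pop$rare_eps) == 1L
      if (any(mix)) h[mix, ] <- r_haplotypes(pop$rare_model, sum(mix))
    }
    return(h)
  }
  J <- pop$J
  z <- matrix(stats::rnorm(n_hap * J), n_hap, J)
  if (pop$rho != 0) {
    for (j in 2:J) if (pop$blocks[j] == pop$blocks[j - 1L])
      z[, j] <- pop$rho * z[, j - 1L] + sqrt(1 - pop$rho^2) * z[, j]
  }
  h <- matrix(0L, n_hap, J)
  for (j in seq_len(J)) h[, j] <- as.integer(z[, j] < stats::qnorm(pop$maf[j]))
  h
}

#' Default study population: LD-blocked haplotype pool over 15 tag SNPs
#'
#' The reference population used throughout the simulation studies. The 15
#' SNPs form three 5-SNP LD blocks. Within each block a pool of
#' `haps_per_block` common haplotypes is constructed (patterns drawn from a
#' latent AR(1) Gaussian copula at correlation `rho`, frequencies then
#' fitted so the pool's allele frequencies match [tag_snp_maf]); blocks
#' combine independently. A small fraction `rare_eps` of haplotypes is
#' drawn fresh from the underlying copula, mimicking the tail of rare
#' haplotypes seen in real data. The construction is deterministic, so two
#' calls give the identical population.
#'
#' With these defaults a sample of 3,000 subjects carries roughly a
#' thousand distinct multilocus genotypes -- the same order of diversity as
#' a real candidate-region case-control panel -- rather than the
#' one-genotype-per-subject saturation that independent SNPs would give.
#'
#' @param maf target minor allele frequencies (default [tag_snp_maf]).
#' @param blocks block ids per SNP (default three blocks of five).
#' @param rho latent within-block correlation of the copula (default 0.9).
#' @param haps_per_block common haplotypes retained per block (default 5).
#' @param rare_eps fraction of fresh copula haplotypes (default 0.05).
#' @return a [population_model()] with an explicit haplotype pool.
#' @export
default_population <- function(maf = tag_snp_maf,
                               blocks = rep(seq_len(ceiling(length(maf) / 5)),
                                            each = 5L)[seq_along(maf)],
                               rho = 0.9, haps_per_block = 5L,
                               rare_eps = 0.05) {
  # deterministic internal RNG, isolated from the caller's stream
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(20120126L)

  fit_freq <- function(hap, target, iters = 2000L, lr = 0.5) {
    f <- rep(1 / nrow(hap), nrow(hap))
    for (it in seq_len(iters)) {
      cur <- drop(crossprod(hap, f))
      f <- f * exp(-lr * drop(hap %*% (cur - target)))
      f <- pmax(f, 1e-4)
      f <- f / sum(f)
    }
    f
  }
  pools <- lapply(unique(blocks), function(b) {
    j <- which(blocks == b)
    sub <- population_model(maf = maf[j], blocks = rep(1L, length(j)),
                            rho = rho)
    h <- r_haplotypes(sub, 6000L)
    key <- apply(h, 1L, paste, collapse = "")
    tb <- sort(table(key), decreasing = TRUE)
    pat <- do.call(rbind, lapply(strsplit(names(utils::head(tb, haps_per_block)),
                                          ""), as.integer))
    list(h = pat, f = fit_freq(pat, maf[j]))
  })
  hap <- pools[[1L]]$h; f <- pools[[1L]]$f
  for (b in pools[-1L]) {
    idx <- expand.grid(a = seq_along(f), c = seq_along(b$f))
    hap <- cbind(hap[idx$a, , drop = FALSE], b$h[idx$c, , drop = FALSE])
    f <- f[idx$a] * b$f[idx$c]
  }
  pop <- population_model(haplotypes = hap, hap_freq = f)
  pop$rare_eps <- rare_eps
  pop$rare_model <- population_model(maf = maf, blocks = blocks, rho = rho)
  pop
}

#' Simulate genotype matrices from a population model
#'
#' Each subject is the sum of two independent haplotypes from the
#' population model, so genotypes satisfy Hardy-Weinberg equilibrium at
#' the haplotype level and empirical minor allele frequencies converge to
#' the model's.
#'
#' @param pop a [population_model()].
#' @param n number of subjects.
#' @param seed optional integer seed.
#' @return n x J integer matrix of codes 0/1/2.
#' @export
simulate_genotypes <- function(pop, n, seed = NULL) {
  stopifnot(inherits(pop, "population_model"))
  if (!is.null(seed)) set.seed(seed)
  r_haplotypes(pop, n) + r_haplotypes(pop, n)
}

#' Risk-allele-count partition rules for the genotype space
#'
#' `region_rule()` builds the three-region partition driven by the total
#' number of risk alleles (minor alleles treated as high-risk) at a set of
#' functional SNPs: region 1 for totals at or below `cuts[1]`, region 2 for
#' totals above `cuts[1]` and at or below `cuts[2]`, region 3 otherwise.
#' With the defaults (`cuts = c(1, 2)`) this is: at most 1 allele, exactly
#' 2, more than 2. `two_cluster_rule()` is the binary version (below vs at
#' or above `threshold` risk alleles). `single_snp_rule()` clusters on one
#' SNP, either dominant (0 vs 1/2) or additive (three clusters).
#' Any function mapping a genotype matrix to positive integer labels can
#' also be used directly wherever a rule is accepted.
#'
#' @param snps functional SNP column indices (default `c(2, 6, 10)`).
#' @param cuts increasing integer cut points for the allele total.
#' @param threshold minimum allele total assigned to cluster 2.
#' @param snp single functional SNP index.
#' @param mode `"dominant"` or `"additive"`.
#' @return object of class `cluster_rule` (a function with metadata).
#' @name cluster_rules
#' @export
region_rule <- function(snps = c(2L, 6L, 10L), cuts = c(1L, 2L)) {
  force(snps); force(cuts)
  f <- function(g) {
    if (max(snps) > ncol(g)) stop("rule references SNP index beyond the matrix")
    tot <- rowSums(g[, snps, drop = FALSE])
    1L + findInterval(tot, cuts + 0.5)
  }
  structure(f, class = c("cluster_rule", "function"),
            n_clusters = length(cuts) + 1L, label = "risk-allele regions")
}

#' @rdname cluster_rules
#' @export
two_cluster_rule <- function(snps = c(2L, 6L, 10L), threshold = 2L) {
  force(snps); force(threshold)
  f <- function(g) {
    if (max(snps) > ncol(g)) stop("rule references SNP index beyond the matrix")
    1L + as.integer(rowSums(g[, snps, drop = FALSE]) >= threshold)
  }
  structure(f, class = c("cluster_rule", "function"),
            n_clusters = 2L, label = "risk-allele threshold")
}

#' @rdname cluster_rules
#' @export
single_snp_rule <- function(snp, mode = c("dominant", "additive")) {
  mode <- match.arg(mode); force(snp)
  f <- function(g) {
    if (snp > ncol(g)) stop("rule references SNP index beyond the matrix")
    if (mode == "dominant") 1L + as.integer(g[, snp] > 0) else g[, snp] + 1L
  }
  structure(f, class = c("cluster_rule", "function"),
            n_clusters = if (mode == "dominant") 2L else 3L,
            label = paste0("single SNP (", mode, ")"))
}

#' Assign genotypes to their true risk clusters under a rule
#'
#' @param genotypes n x J matrix of codes 0/1/2.
#' @param rule a rule from [cluster_rules] or any function mapping the
#'   genotype matrix to integer labels starting at 1.
#' @return integer vector of cluster labels.
#' @export
assign_true_clusters <- function(genotypes, rule) {
  lab <- rule(as.matrix(genotypes))
  if (any(lab < 1L)) stop("rule produced labels below 1")
  as.integer(lab)
}

#' Draw genotype-dependent exposure
#'
#' Exposure is Bernoulli given the subject's true cluster; the default
#' probabilities reproduce the study design in which subjects in region 1
#' are exposed with probability 0.3 and all others with probability 0.6.
#'
#' @param cluster_labels per-subject true cluster labels.
#' @param p_exposed per-cluster exposure probabilities (recycled to the
#'   number of clusters; default `c(0.3, 0.6, 0.6)`).
#' @param seed optional integer seed.
#' @return integer 0/1 exposure vector.
#' @export
simulate_exposure <- function(cluster_labels, p_exposed = c(0.3, 0.6, 0.6),
                              seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  K <- max(cluster_labels)
  p <- rep_len(p_exposed, K)
  if (any(p < 0 | p > 1)) stop("exposure probabilities must lie in [0, 1]")
  stats::rbinom(length(cluster_labels), 1L, p[cluster_labels])
}

#' Cluster-structured disease risk model for simulation
#'
#' Packages a partition rule with per-cluster intercepts and exposure log
#' odds ratios (model form: logit P(D=1) = baseline + alpha_k + beta_k E).
#' Because case-control sampling does not identify the absolute baseline,
#' only contrasts of `alpha` matter; the working `baseline` merely sets the
#' population prevalence used during rejection sampling.
#'
#' @param rule a [cluster_rules] rule (or plain labelling function with an
#'   `n_clusters` attribute or matching `alpha` length).
#' @param alpha per-cluster intercept offsets (log odds).
#' @param beta per-cluster exposure log odds ratios (length 1 = shared, no
#'   interaction).
#' @param p_exposed per-cluster exposure probabilities.
#' @param baseline working baseline log odds (default places an unexposed
#'   cluster-1 subject at 5% risk).
#' @return object of class `risk_model_spec`.
#' @export
risk_model_spec <- function(rule, alpha, beta,
                            p_exposed = c(0.3, 0.6, 0.6),
                            baseline = NULL) {
  nc <- attr(rule, "n_clusters")
  if (is.null(nc)) nc <- length(alpha)
  if (length(alpha) != nc) stop("alpha must have one entry per cluster")
  if (!length(beta) %in% c(1L, nc))
    stop("beta must be shared (length 1) or per-cluster")
  if (is.null(baseline)) baseline <- stats::qlogis(0.05) - alpha[1L]
  structure(list(rule = rule, alpha = alpha,
                 beta = rep_len(beta, nc), shared_beta = length(beta) == 1L,
                 p_exposed = rep_len(p_exposed, nc), baseline = baseline,
                 n_clusters = nc),
            class = "risk_model_spec")
}

#' Simulate a case-control study under a cluster-structured risk model
#'
#' Retrospective (quota) sampling by rejection: subjects are drawn from the
#' population (genotype, then genotype-dependent exposure, then disease
#' status from the logistic risk model with the working baseline) and kept
#' as cases or controls until both quotas are filled. The working baseline
#' is absorbed into the non-identified intercept level, so its choice only
#' affects sampling efficiency.
#'
#' @param pop a [population_model()].
#' @param risk a [risk_model_spec()].
#' @param n_cases,n_controls quotas.
#' @param seed optional integer seed.
#' @param n_neighbors,regroup passed to [case_control_data()].
#' @param max_batches abort guard on the rejection loop.
#' @return a [case_control_data()] with attribute `truth`: list holding
#'   the per-subject true cluster labels, the generating coefficients and
#'   the rule.
#' @export
simulate_case_control <- function(pop, risk, n_cases, n_controls,
                                  seed = NULL, n_neighbors = 4L,
                                  regroup = NULL, max_batches = 2000L) {
  stopifnot(inherits(pop, "population_model"),
            inherits(risk, "risk_model_spec"))
  if (!is.null(seed)) set.seed(seed)
  need <- c(n_controls, n_cases)            # indexed by D + 1
  got <- c(0L, 0L)
  batch <- max(1000L, 2L * (n_cases + n_controls))
  Gs <- list(); Es <- list(); Ds <- list(); Ls <- list()
  for (iter in seq_len(max_batches)) {
    g <- simulate_genotypes(pop, batch)
    lab <- assign_true_clusters(g, risk$rule)
    if (max(lab) > risk$n_clusters)
      stop("rule produced more clusters than the risk model specifies")
    e <- simulate_exposure(lab, risk$p_exposed)
    eta <- risk$baseline + risk$alpha[lab] + risk$beta[lab] * e
    d <- stats::rbinom(batch, 1L, stats::plogis(eta))
    keep <- logical(batch)
    for (s in 0:1) {
      want <- need[s + 1L] - got[s + 1L]
      if (want > 0L) {
        idx <- which(d == s)
        keep[idx[seq_len(min(want, length(idx)))]] <- TRUE
      }
    }
    if (any(keep)) {
      Gs[[length(Gs) + 1L]] <- g[keep, , drop = FALSE]
      Es[[length(Es) + 1L]] <- e[keep]
      Ds[[length(Ds) + 1L]] <- d[keep]
      Ls[[length(Ls) + 1L]] <- lab[keep]
      got <- got + c(sum(d[keep] == 0L), sum(d[keep] == 1L))
    }
    if (all(got >= need)) break
  }
  if (!all(got >= need))
    stop("case/control quotas unreachable within the draw budget; ",
         "check that the risk model's probabilities are not degenerate")
  G <- do.call(rbind, Gs); E <- unlist(Es); D <- unlist(Ds); L <- unlist(Ls)
  o <- order(D, decreasing = TRUE)          # cases first, stable
  dat <- case_control_data(D[o], E[o], G[o, , drop = FALSE],
                           n_neighbors = n_neighbors, regroup = regroup)
  attr(dat, "truth") <- list(cluster = L[o], alpha = risk$alpha,
                             beta = risk$beta, rule = risk$rule)
  dat
}
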