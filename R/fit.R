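#' Chain configuration for the latent-profile sampler
#'
#' Collects every tunable of the MCMC sampler. The defaults mirror a
#' full-length analysis run (200,000 iterations, first half discarded,
#' thinning 10); the `"bootstrap"` preset shortens nothing but shifts to the
#' 300,000/200,000 schedule used for bootstrap replicate fits, and the
#' `"desk"` preset is a deliberately small configuration for interactive
#' exploration and examples.
#'
#' @param iterations,burn_in,thinning chain schedule; `burn_in < iterations`
#'   and stored draws number `(iterations - burn_in)/thinning`.
#' @param m_auxiliary auxiliary Potts draws per coupling update (default 50;
#'   values between 50 and 100 work well).
#' @param aux_sweeps Gibbs sweeps between consecutive auxiliary draws
#'   (default 5). The auxiliary chain starts at the current allocation
#'   state, which keeps the importance-sampling estimate of the
#'   normalizing-constant ratio usable in the strongly coupled regime,
#'   where short chains from uniform starts cannot equilibrate.
#' @param psi_update_every update the coupling every this many iterations
#'   (default 1). The auxiliary sampling dominates the per-iteration cost on
#'   large genotype spaces, so thinning this block buys speed at no cost to
#'   the invariant distribution.
#' @param prop_sd named numeric: Gaussian random-walk proposal SDs for
#'   `alpha`, `beta`, `gamma` and `psi`.
#' @param adapt logical: tune proposal scales during burn-in toward a
#'   20-45% acceptance window (frozen after burn-in).
#' @param prior `"normal"` (mean 0, variance 4) or `"uniform"` (symmetric
#'   interval) prior for every risk-model coefficient.
#' @param prior_sd SD of the normal coefficient prior (default 2).
#' @param prior_bound half-width of the uniform coefficient prior
#'   (default 10).
#' @param psi_max upper end of the uniform prior for the Potts coupling
#'   (default 1.2, past which the co-assignment probability is essentially
#'   saturated and the model approaches its phase-transition regime).
#' @param init `"pam"` starts the allocation at a k-medoids partition of the
#'   genotype distance matrix; `"random"` starts uniform.
#' @param seed optional integer seed applied at the start of [gep_fit()].
#' @param preset optional shorthand: `"paper"`, `"bootstrap"` or `"desk"`.
#' @return a list of class `gep_control`.
#' @export
gep_control <- function(iterations = 200000L, burn_in = 100000L,
                        thinning = 10L, m_auxiliary = 50L, aux_sweeps = 5L,
                        psi_update_every = 1L,
                        prop_sd = c(alpha = 0.1, beta = 0.1, gamma = 0.1,
                                    psi = 0.05),
                        adapt = TRUE,
                        prior = c("normal", "uniform"), prior_sd = 2,
                        prior_bound = 10, psi_max = 1.2,
                        init = c("pam", "random"), seed = NULL,
                        preset = NULL) {
  if (!is.null(preset)) {
    preset <- match.arg(preset, c("paper", "bootstrap", "desk"))
    if (preset == "bootstrap") { iterations <- 300000L; burn_in <- 200000L }
    if (preset == "desk") {
      iterations <- 3000L; burn_in <- 1500L; thinning <- 5L
      psi_update_every <- 5L; aux_sweeps <- 5L
    }
  }
  prior <- match.arg(prior)
  init <- match.arg(init)
  if (burn_in >= iterations) stop("burn_in must be smaller than iterations")
  if (m_auxiliary < 1L) stop("m_auxiliary must be >= 1")
  ps <- c(alpha = 0.1, beta = 0.1, gamma = 0.1, psi = 0.05)
  ps[names(prop_sd)] <- prop_sd
  structure(list(iterations = as.integer(iterations),
                 burn_in = as.integer(burn_in),
                 thinning = as.integer(thinning),
                 m_auxiliary = as.integer(m_auxiliary),
                 aux_sweeps = as.integer(aux_sweeps),
                 psi_update_every = as.integer(psi_update_every),
                 prop_sd = ps, adapt = isTRUE(adapt),
                 prior = prior, prior_sd = prior_sd,
                 prior_bound = prior_bound, psi_max = psi_max,
                 init = init, seed = seed),
            class = "gep_control")
}

# informative starting coefficients: maximum-likelihood logistic fit of the
# risk model at the initial partition, so cluster labels are
# likelihood-meaningful from the first sweep (a zero start leaves the labels
# exchangeable and lets the Potts prior collapse them before the
# coefficients can differentiate)
start_coefficients <- function(data, z0, K, model) {
  k_sub <- factor(z0[data$genotype_id], levels = seq_len(K))
  p <- ncol(data$X)
  df0 <- data.frame(D = data$D, E = data$E, L = k_sub)
  if (p > 0L) {
    X <- data$X; colnames(X) <- paste0("X", seq_len(p)); df0 <- cbind(df0, X)
  }
  xterm <- if (p > 0L) paste("+", paste(paste0("X", seq_len(p)), collapse = " + ")) else ""
  fml <- if (K == 1L) paste("D ~ E", xterm)
         else if (model == "interaction") paste("D ~ 0 + L + L:E", xterm)
         else paste("D ~ 0 + L + E", xterm)
  out <- list(alpha = numeric(K),
              beta = numeric(if (model == "interaction") K else 1L),
              gamma = numeric(p))
  fit <- tryCatch(suppressWarnings(
    stats::glm(stats::as.formula(fml), stats::binomial(), data = df0)),
    error = function(e) NULL)
  if (is.null(fit)) return(out)
  cf <- stats::coef(fit)
  cf[is.na(cf)] <- 0
  if (K == 1L) {
    out$alpha <- unname(cf["(Intercept)"])
    out$beta <- unname(cf["E"])
  } else {
    out$alpha <- unname(cf[paste0("L", seq_len(K))])
    out$beta <- if (model == "interaction")
      unname(cf[paste0("L", seq_len(K), ":E")]) else unname(cf["E"])
  }
  if (p > 0L) out$gamma <- unname(cf[paste0("X", seq_len(p))])
  out$alpha[!is.finite(out$alpha)] <- 0
  out$beta[!is.finite(out$beta)] <- 0
  out$gamma[!is.finite(out$gamma)] <- 0
  # keep the start inside plausible prior range
  out$alpha <- pmax(pmin(out$alpha, 8), -8)
  out$beta <- pmax(pmin(out$beta, 8), -8)
  out$gamma <- pmax(pmin(out$gamma, 8), -8)
  out
}

#' Fit the Bayesian latent genetic-profile risk model
#'
#' Runs the joint posterior sampler for the cluster-specific logistic risk
#' model with a Potts prior over the allocation of distinct multilocus
#' genotypes to `K` risk clusters. Each sweep updates (i) the risk-model
#' coefficients by Gaussian random-walk Metropolis-Hastings, (ii) each
#' genotype's cluster label by a Metropolized Gibbs step, and (iii) the
#' Potts coupling by Monte Carlo Metropolis-Hastings, in which the
#' intractable normalizing-constant ratio is replaced by an importance-
#' sampling estimate from auxiliary prior draws.
#'
#' Under the `"interaction"` form every cluster carries its own exposure
#' log odds ratio; under `"no_interaction"` a single slope is shared, which
#' is the null model of the interaction test. The prospective logistic
#' likelihood is used for the retrospectively sampled case-control data, so
#' intercept levels are identified only up to a common shift; contrasts of
#' intercepts, exposure slopes and covariate effects are the estimands.
#'
#' @param data a [case_control_data()].
#' @param K number of latent clusters (>= 1).
#' @param model `"interaction"` (cluster-specific exposure effect) or
#'   `"no_interaction"` (shared exposure effect).
#' @param control a [gep_control()].
#' @return An object of class `gep_fit` holding the thinned posterior draws
#'   (`samples$z`, `$alpha`, `$beta`, `$gamma`, `$psi`, `$loglik`),
#'   acceptance rates, and the data/configuration needed by downstream
#'   summaries. Methods: `print`, `summary`, `coef`, `plot`.
#' @examples
#' pop <- population_model(maf = c(0.3, 0.2, 0.4, 0.25, 0.35))
#' rule <- two_cluster_rule(snps = 1:3, threshold = 2)
#' spec <- risk_model_spec(rule, alpha = c(0, 1.2), beta = c(0.2, 1.4),
#'                         p_exposed = c(0.3, 0.6))
#' dat <- simulate_case_control(pop, spec, n_cases = 120, n_controls = 120,
#'                              seed = 7)
#' fit <- gep_fit(dat, K = 2,
#'                control = gep_control(preset = "desk", seed = 1))
#' fit
#' @export
gep_fit <- function(data, K, model = c("interaction", "no_interaction"),
                    control = gep_control()) {
  model <- match.arg(model)
  stopifnot(inherits(data, "case_control_data"), inherits(control, "gep_control"))
  K <- as.integer(K)
  if (K < 1L) stop("K must be >= 1")
  if (!is.null(control$seed)) set.seed(control$seed)
  H <- nrow(data$table$codes)
  e <- data$graph$edges

  z0 <- if (K == 1L) rep(1L, H)
        else if (K >= H) ((seq_len(H) - 1L) %% K) + 1L
        else if (control$init == "pam")
          pam_cluster(genotype_distance(data$table), k = K)$labels
        else sample.int(K, H, replace = TRUE)
  st <- start_coefficients(data, z0, K, model)

  res <- run_chain_cpp(
    D = data$D, E = data$E, X = data$X, cid = data$genotype_id, H = H,
    ei = e$i, ej = e$j, ew = as.numeric(e$w),
    K = K, interaction = (model == "interaction"),
    iterations = control$iterations, burn_in = control$burn_in,
    thinning = control$thinning, m_aux = control$m_auxiliary,
    aux_sweeps = control$aux_sweeps, psi_every = control$psi_update_every,
    sd_alpha = control$prop_sd[["alpha"]], sd_beta = control$prop_sd[["beta"]],
    sd_gamma = control$prop_sd[["gamma"]], sd_psi = control$prop_sd[["psi"]],
    prior_type = if (control$prior == "normal") 0L else 1L,
    prior_sd = control$prior_sd, prior_bound = control$prior_bound,
    psi_max = control$psi_max, adapt = control$adapt,
    z_init = z0, psi_init = control$psi_max / 2,
    alpha_init = st$alpha, beta_init = st$beta, gamma_init = st$gamma)

  if (!all(is.finite(res$loglik)))
    stop("non-finite log-likelihood encountered in stored draws")
  structure(
    list(samples = res[c("z", "alpha", "beta", "gamma", "psi", "loglik")],
         acceptance = res$acceptance,
         K = K, model = model, control = control, data = data),
    class = "gep_fit")
}

#' @export
print.gep_fit <- function(x, ...) {
  n_draws <- length(x$samples$psi)
  cat("Bayesian latent genetic-profile fit (",
      if (x$model == "interaction") "with" else "without",
      " G-E interaction)\n", sep = "")
  cat("  K =", x$K, "clusters,", n_draws, "stored draws\n")
  cat("  acceptance:",
      paste(names(x$acceptance),
            sprintf("%.2f", x$acceptance), collapse = ", "), "\n")
  cat("  posterior median psi:", signif(stats::median(x$samples$psi), 3), "\n")
  invisible(x)
}

# per-genotype draws of the assigned intercept / exposure slope; subjects
# sharing a genotype share these, so genotype-level matrices are enough
genotype_draws <- function(fit) {
  z <- fit$samples$z
  T_ <- nrow(z); H <- ncol(z)
  a <- fit$samples$alpha
  idx <- cbind(rep(seq_len(T_), H), as.vector(z))
  alpha_hd <- matrix(a[idx], T_, H)
  beta_hd <- if (fit$model == "interaction")
    matrix(fit$samples$beta[idx], T_, H)
  else matrix(fit$samples$beta[, 1L], T_, H)
  list(alpha = alpha_hd, beta = beta_hd)
}

#' Per-genotype posterior effect summaries
#'
#' Posterior medians, per distinct genotype, of the assigned intercept and
#' exposure log odds ratio. Because intercept levels are not identified
#' under case-control sampling, the genetic effect is reported as an odds
#' ratio against a reference genotype, chosen as the one with the lowest
#' posterior median intercept.
#'
#' @param fit a [gep_fit()].
#' @return data frame with one row per distinct genotype: subject count,
#'   posterior median intercept and exposure log-OR, the exposure OR, and
#'   the genetic OR relative to the reference genotype.
#' @export
genotype_summary <- function(fit) {
  gd <- genotype_draws(fit)
  med_a <- apply(gd$alpha, 2L, stats::median)
  med_b <- apply(gd$beta, 2L, stats::median)
  ref <- which.min(med_a)
  data.frame(genotype = seq_along(med_a),
             n_subjects = fit$data$table$counts,
             median_alpha = med_a,
             median_beta = med_b,
             exposure_or = exp(med_b),
             genetic_or_vs_ref = exp(med_a - med_a[ref]))
}

#' @export
summary.gep_fit <- function(object, ...) {
  gs <- genotype_summary(object)
  d <- dic(object)
  out <- list(K = object$K, model = object$model,
              n_draws = length(object$samples$psi),
              acceptance = object$acceptance,
              psi = stats::quantile(object$samples$psi, c(0.25, 0.5, 0.75)),
              dic = d, genotype_summary = gs)
  class(out) <- "summary.gep_fit"
  out
}

#' @export
print.summary.gep_fit <- function(x, ...) {
  cat("Latent genetic-profile model,", x$model, "form, K =", x$K, "\n")
  cat(sprintf("  DIC %.1f (Dbar %.1f, pD %.1f)\n", x$dic$DIC, x$dic$D_bar,
              x$dic$pD))
  cat("  psi quartiles:", paste(signif(x$psi, 3), collapse = " / "), "\n")
  cat("  exposure OR across genotypes: median",
      signif(stats::median(x$genotype_summary$exposure_or), 3),
      "range", paste(signif(range(x$genotype_summary$exposure_or), 3),
                     collapse = " - "), "\n")
  cat("  genetic OR vs reference genotype: range",
      paste(signif(range(x$genotype_summary$genetic_or_vs_ref), 3),
            collapse = " - "), "\n")
  invisible(x)
}

#' @export
coef.gep_fit <- function(object, ...) {
  b <- object$samples$beta
  g <- object$samples$gamma
  out <- list(alpha = apply(object$samples$alpha, 2L, stats::median),
              beta = apply(b, 2L, stats::median),
              psi = stats::median(object$samples$psi))
  if (ncol(g) > 0L) out$gamma <- apply(g, 2L, stats::median)
  out
}

#' Trace plots for a fitted latent-profile model
#'
#' @param x a [gep_fit()].
#' @param ... passed to [plot()].
#' @export
plot.gep_fit <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  plot(x$samples$loglik, type = "l", xlab = "stored draw",
       ylab = "log-likelihood", main = "Trace: log-likelihood", ...)
  plot(x$samples$psi, type = "l", xlab = "stored draw",
       ylab = expression(psi), main = "Trace: Potts coupling", ...)
  invisible(x)
}
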