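#' Likelihood-ratio test of cluster-by-exposure interaction
#'
#' Given a (consensual) cluster assignment of subjects, fits by maximum
#' likelihood the logistic model with cluster (categorical), exposure,
#' covariates and the cluster-by-exposure interaction, against the same
#' model without the interaction terms. The statistic is twice the
#' log-likelihood difference, referred to a chi-squared distribution with
#' `K* - 1` degrees of freedom.
#'
#' Because the cluster variable is itself estimated from the data, the
#' nominal p-value overstates significance; it serves as the test statistic
#' of the parametric-bootstrap procedure in [gep_interaction_test()].
#'
#' @param data a [case_control_data()].
#' @param labels per-subject cluster assignment with at least 2 observed
#'   levels (e.g. `subject_labels` of a [consensus_partition()]).
#' @return list with `statistic`, `df`, `p` and `converged`.
#' @export
lrt_interaction <- function(data, labels) {
  L <- factor(labels)
  if (nlevels(L) < 2L) stop("need at least 2 cluster levels")
  if (any(tabulate(L) == 0L)) stop("empty cluster level")
  df0 <- data.frame(D = data$D, E = data$E, L = L)
  X <- data$X
  xterm <- if (ncol(X) > 0L) {
    colnames(X) <- paste0("X", seq_len(ncol(X)))
    df0 <- cbind(df0, X)
    paste("+", paste(colnames(X), collapse = " + "))
  } else ""
  full <- stats::glm(stats::as.formula(paste("D ~ L * E", xterm)),
                     family = stats::binomial(), data = df0)
  red <- stats::glm(stats::as.formula(paste("D ~ L + E", xterm)),
                    family = stats::binomial(), data = df0)
  stat <- max(0, 2 * (stats::logLik(full)[1L] - stats::logLik(red)[1L]))
  df <- nlevels(L) - 1L
  list(statistic = stat, df = df,
       p = stats::pchisq(stat, df = df, lower.tail = FALSE),
       converged = full$converged && red$converged)
}

#' Maximum-likelihood null (no-interaction) logistic model
#'
#' Fits by MLE the logistic model with cluster main effect (from the
#' no-interaction Bayesian fit's consensus labels), exposure and
#' covariates -- the model whose fitted probabilities drive the parametric
#' bootstrap. A single-cluster assignment collapses to plain logistic
#' regression on exposure and covariates.
#'
#' @param data a [case_control_data()].
#' @param labels0 per-subject cluster labels under the null fit.
#' @return list with the `glm` object, `fitted` probabilities and
#'   `converged`.
#' @export
fit_null_logistic <- function(data, labels0) {
  L <- factor(labels0)
  df0 <- data.frame(D = data$D, E = data$E)
  rhs <- "E"
  if (nlevels(L) >= 2L) { df0$L <- L; rhs <- "L + E" }
  if (ncol(data$X) > 0L) {
    X <- data$X; colnames(X) <- paste0("X", seq_len(ncol(X)))
    df0 <- cbind(df0, X)
    rhs <- paste(rhs, "+", paste(colnames(X), collapse = " + "))
  }
  m <- stats::glm(stats::as.formula(paste("D ~", rhs)),
                  family = stats::binomial(), data = df0)
  list(model = m, fitted = as.numeric(stats::fitted(m)),
       converged = m$converged)
}

#' Regenerate outcomes from a fitted null model
#'
#' Produces one parametric-bootstrap dataset: a copy of the observed data
#' in which every subject's outcome is redrawn as an independent Bernoulli
#' variable with that subject's fitted null probability. Genotypes,
#' exposure and covariates are untouched, so the genotype space and its
#' neighbour graph are reused as-is.
#'
#' @param null_model result of [fit_null_logistic()] (or a numeric vector
#'   of per-subject probabilities).
#' @param data a [case_control_data()].
#' @return a `case_control_data` with regenerated outcomes.
#' @export
bootstrap_null_dataset <- function(null_model, data) {
  p <- if (is.numeric(null_model)) null_model else null_model$fitted
  if (length(p) != length(data$D)) stop("fitted probabilities length mismatch")
  replace_outcome(data, stats::rbinom(length(p), 1L, p))
}

# observed-data arm of the test: fit interaction model over the grid,
# select K* (restricted to >= 2), build the consensus labels, return the
# nominal LRT p-value
interaction_arm <- function(data, k_grid, control, seed_offset = 0L) {
  ctl <- control
  if (!is.null(control$seed)) ctl$seed <- control$seed + seed_offset
  k_grid <- sort(unique(as.integer(k_grid)))
  if (any(k_grid < 2L)) stop("interaction-arm grid must start at K >= 2")
  kg <- gep_k_grid(data, k_grid, model = "interaction", control = ctl,
                   runs = 1L, keep_fits = TRUE)
  k_star <- max(2L, kg$selected)
  fit <- kg$fits[[paste0("K", k_star, ".r1")]]
  cons <- consensus_partition(fit, k_star)
  lrt <- lrt_interaction(data, cons$labels[data$genotype_id])
  list(k_star = k_star, p = lrt$p, statistic = lrt$statistic,
       df = lrt$df, converged = lrt$converged, consensus = cons)
}

#' Parametric-bootstrap test of gene-environment interaction
#'
#' The full resampling-based test:
#' \enumerate{
#'   \item Fit the Bayesian risk model with interaction over `k_grid`
#'     (restricted to `K >= 2`), select `K1*` by the +1 rule, build the
#'     consensus assignment and compute the nominal interaction LRT
#'     p-value `p_obs` -- the test statistic.
#'   \item Fit the no-interaction Bayesian model over `null_k_grid`,
#'     select `K0*`, build its consensus assignment, and fit the
#'     maximum-likelihood logistic null (cluster main effect + exposure +
#'     covariates).
#'   \item Generate `B` bootstrap datasets by regenerating every outcome
#'     from the fitted null probabilities, rerun step 1 on each, and
#'     collect the replicate statistics `T_b`.
#'   \item Report `p_value = (1 + #\{T_b <= p_obs\}) / (B + 1)` --
#'     replicate evidence is compared on the p-value scale, where smaller
#'     means more extreme.
#' }
#' By default `K1*` is re-selected on every bootstrap replicate, mirroring
#' the use of the identical procedure on observed and replicate data; set
#' `reselect_k = FALSE` to freeze the replicate grid at the observed `K1*`.
#'
#' @param data a [case_control_data()].
#' @param k_grid candidate cluster counts for the interaction fits
#'   (default `2:5`).
#' @param B number of bootstrap replicates.
#' @param control chain configuration for the observed-data fits.
#' @param boot_control chain configuration for replicate fits (defaults to
#'   `control`; a shortened preset is customary since replicates only feed
#'   the null distribution of the statistic).
#' @param null_k_grid candidate cluster counts for the no-interaction null
#'   fit (default `1:max(k_grid)`).
#' @param reselect_k re-select the number of clusters on each replicate.
#' @param seed integer seed governing the whole procedure.
#' @return object of class `gep_interaction_test`: `p_obs`, `df`,
#'   `K1_star`, `K0_star`, `bootstrap_stats`, `p_value`, `B`,
#'   `B_effective` (replicates whose fits converged) and the consensus
#'   partitions of both arms.
#' @export
gep_interaction_test <- function(data, k_grid = 2:5, B = 199L,
                                 control = gep_control(),
                                 boot_control = NULL,
                                 null_k_grid = NULL,
                                 reselect_k = TRUE, seed = NULL) {
  if (B < 1L) stop("B must be >= 1")
  if (is.null(boot_control)) boot_control <- control
  if (is.null(null_k_grid)) null_k_grid <- seq_len(max(k_grid))
  if (!is.null(seed)) { control$seed <- seed; boot_control$seed <- seed }

  obs <- interaction_arm(data, k_grid, control, seed_offset = 0L)

  ctl0 <- control
  if (!is.null(ctl0$seed)) ctl0$seed <- ctl0$seed + 500000L
  kg0 <- gep_k_grid(data, null_k_grid, model = "no_interaction",
                    control = ctl0, runs = 1L, keep_fits = TRUE)
  k0 <- kg0$selected
  cons0 <- consensus_partition(kg0$fits[[paste0("K", k0, ".r1")]], k0)
  null_fit <- fit_null_logistic(data, cons0$labels[data$genotype_id])

  rep_grid <- if (reselect_k) k_grid else obs$k_star
  stats_b <- rep(NA_real_, B)
  ok <- logical(B)
  for (b in seq_len(B)) {
    if (!is.null(seed)) set.seed(seed + 7000000L + b)
    db <- bootstrap_null_dataset(null_fit, data)
    arm <- tryCatch(
      interaction_arm(db, rep_grid, boot_control,
                      seed_offset = 1000000L + 37L * b),
      error = function(e) NULL)
    if (!is.null(arm)) { stats_b[b] <- arm$p; ok[b] <- arm$converged }
  }
  used <- !is.na(stats_b)
  p_value <- (1 + sum(stats_b[used] <= obs$p)) / (sum(used) + 1)

  structure(
    list(p_obs = obs$p, statistic = obs$statistic, df = obs$df,
         K1_star = obs$k_star, K0_star = k0,
         bootstrap_stats = stats_b, p_value = p_value,
         B = B, B_effective = sum(used), n_flagged = sum(used & !ok),
         consensus = obs$consensus, null_consensus = cons0),
    class = "gep_interaction_test")
}

#' @export
print.gep_interaction_test <- function(x, ...) {
  cat("Parametric-bootstrap test of G-E interaction\n")
  cat(sprintf("  K1* = %d (interaction fit), K0* = %d (null fit)\n",
              x$K1_star, x$K0_star))
  cat(sprintf("  nominal LRT p_obs = %.4g (chi-squared, %d df)\n",
              x$p_obs, x$df))
  cat(sprintf("  bootstrap p-value = %.4g (%d of %d replicates usable)\n",
              x$p_value, x$B_effective, x$B))
  invisible(x)
}
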