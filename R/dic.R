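#' Deviance information criterion for a fitted latent-profile model
#'
#' Computes \eqn{\bar D}, the posterior mean deviance over stored draws
#' (deviance = -2 log-likelihood), and \eqn{\hat D}, the deviance at the
#' plug-in: per-subject posterior means of the assigned intercept and
#' exposure slope together with the posterior mean covariate coefficients.
#' The per-subject plug-in makes the criterion invariant to cluster
#' relabelling across draws, so no relabelling post-processing is needed.
#' The criterion is \eqn{\mathrm{DIC} = 2\bar D - \hat D = \bar D + p_D}
#' with effective parameter count \eqn{p_D = \bar D - \hat D}.
#'
#' @param fit a [gep_fit()].
#' @return list with `D_bar`, `D_hat`, `DIC`, `pD` (negative `pD` is
#'   reported as-is but flagged with a warning).
#' @export
dic <- function(fit) {
  stopifnot(inherits(fit, "gep_fit"))
  if (length(fit$samples$loglik) == 0L) stop("fit holds no stored draws")
  D_bar <- mean(-2 * fit$samples$loglik)
  gd <- genotype_draws(fit)
  abar <- colMeans(gd$alpha)[fit$data$genotype_id]
  bbar <- colMeans(gd$beta)[fit$data$genotype_id]
  gbar <- if (ncol(fit$samples$gamma) > 0L) colMeans(fit$samples$gamma)
          else numeric(0)
  eta <- abar + bbar * fit$data$E +
    if (length(gbar)) drop(fit$data$X %*% gbar) else 0
  ll_hat <- sum(fit$data$D * eta -
                  ifelse(eta > 0, eta + log1p(exp(-eta)), log1p(exp(eta))))
  D_hat <- -2 * ll_hat
  pD <- D_bar - D_hat
  if (pD < 0) warning("negative effective parameter count pD = ",
                      signif(pD, 3))
  list(D_bar = D_bar, D_hat = D_hat, DIC = 2 * D_bar - D_hat, pD = pD)
}

#' Choose the number of clusters by the +1 rule
#'
#' Given one DIC value per candidate K, returns the smallest K whose DIC is
#' within 1 of the minimum. This single-run shortcut reflects the fact that
#' the Monte Carlo standard error of a converged chain's DIC is typically
#' below 1.
#'
#' @param dic_by_k named numeric vector of DIC values; names (or, failing
#'   that, positions) are interpreted as K.
#' @return the selected K (integer).
#' @export
select_k_plus_one <- function(dic_by_k) {
  if (length(dic_by_k) == 0L) stop("no DIC values supplied")
  ks <- if (!is.null(names(dic_by_k))) as.integer(names(dic_by_k))
        else seq_along(dic_by_k)
  o <- order(ks); ks <- ks[o]; v <- as.numeric(dic_by_k)[o]
  ks[which(v <= min(v) + 1)[1L]]
}

#' Choose the number of clusters by the +1 standard-error rule
#'
#' Given repeated-run DIC values per candidate K, returns the smallest K
#' whose mean DIC lies within one Monte Carlo standard error (of the
#' minimizing K's mean) of the minimum mean DIC.
#'
#' @param dic_runs named list (names = K) of numeric vectors of DIC values
#'   from independent chains, at least 2 runs per K.
#' @return the selected K (integer).
#' @export
select_k_one_se <- function(dic_runs) {
  if (length(dic_runs) == 0L) stop("no DIC values supplied")
  if (any(lengths(dic_runs) < 2L))
    stop("need >= 2 runs per K for a standard error; use select_k_plus_one()")
  ks <- if (!is.null(names(dic_runs))) as.integer(names(dic_runs))
        else seq_along(dic_runs)
  o <- order(ks); ks <- ks[o]; dic_runs <- dic_runs[o]
  means <- vapply(dic_runs, mean, 0)
  i_min <- which.min(means)
  se_min <- stats::sd(dic_runs[[i_min]]) / sqrt(length(dic_runs[[i_min]]))
  ks[which(means <= means[i_min] + se_min)[1L]]
}

#' Fit the model over a grid of cluster counts
#'
#' Convenience driver: fits [gep_fit()] for each K in `k_grid` (optionally
#' several independent runs per K), tabulates DIC, and applies the +1 rule
#' (single runs) or the +1 SE rule (repeated runs).
#'
#' @param data a [case_control_data()].
#' @param k_grid integer vector of candidate cluster counts.
#' @param model passed to [gep_fit()].
#' @param control a [gep_control()]; its seed, when set, seeds run r of K
#'   deterministically.
#' @param runs independent chains per K (default 1).
#' @param keep_fits return the fitted objects as well (memory permitting).
#' @return list of class `gep_kgrid`: `table` (data frame of K, run, DIC
#'   components), `selected` (chosen K), `rule`, and optionally `fits`.
#' @export
gep_k_grid <- function(data, k_grid, model = c("interaction", "no_interaction"),
                       control = gep_control(), runs = 1L, keep_fits = FALSE) {
  model <- match.arg(model)
  rows <- list(); fits <- list()
  for (K in k_grid) {
    for (r in seq_len(runs)) {
      ctl <- control
      if (!is.null(control$seed))
        ctl$seed <- control$seed + 1000L * r + K
      f <- gep_fit(data, K = K, model = model, control = ctl)
      d <- dic(f)
      rows[[length(rows) + 1L]] <-
        data.frame(K = K, run = r, D_bar = d$D_bar, D_hat = d$D_hat,
                   DIC = d$DIC, pD = d$pD)
      if (keep_fits) fits[[paste0("K", K, ".r", r)]] <- f
    }
  }
  tab <- do.call(rbind, rows)
  if (runs >= 2L) {
    by_k <- split(tab$DIC, tab$K)
    sel <- select_k_one_se(by_k); rule <- "+1 SE"
  } else {
    v <- tab$DIC; names(v) <- tab$K
    sel <- select_k_plus_one(v); rule <- "+1"
  }
  out <- list(table = tab, selected = sel, rule = rule)
  if (keep_fits) out$fits <- fits
  class(out) <- "gep_kgrid"
  out
}

#' @export
print.gep_kgrid <- function(x, ...) {
  agg <- stats::aggregate(DIC ~ K, data = x$table, FUN = mean)
  cat("DIC over K grid (", x$rule, " rule):\n", sep = "")
  print(agg, row.names = FALSE)
  cat("selected K =", x$selected, "\n")
  invisible(x)
}
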