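# half-deviance of a logistic fit on a fixed design matrix
fit_ll <- function(Xd, y) {
  f <- suppressWarnings(stats::glm.fit(Xd, y, family = stats::binomial()))
  -f$deviance / 2
}

# per-unit interaction LRT machinery on precomputed design matrices: for
# each unit (SNP or PC) a reduced design [1, unit-main, E, X] and a full
# design adding unit x E columns; the nominal p-value is the chi-squared
# LRT between them
build_unit_designs <- function(E, units, X, categorical) {
  lapply(seq_len(ncol(units)), function(j) {
    Um <- if (categorical) {
      f <- factor(units[, j])
      stats::model.matrix(~f)[, -1L, drop = FALSE]
    } else cbind(units[, j])
    red <- cbind(1, Um, E, X)
    full <- cbind(red, Um * E)
    list(red = red, full = full, df = ncol(Um))
  })
}

min_p_over_units <- function(designs, D) {
  p <- vapply(designs, function(d) {
    stat <- max(0, 2 * (fit_ll(d$full, D) - fit_ll(d$red, D)))
    stats::pchisq(stat, df = d$df, lower.tail = FALSE)
  }, 0)
  list(p = p, min_p = min(p))
}

calibrate_min_p <- function(D, designs, null_design, B) {
  obs <- min_p_over_units(designs, D)
  null_fit <- suppressWarnings(
    stats::glm.fit(null_design, D, family = stats::binomial()))
  probs <- as.numeric(null_fit$fitted.values)
  mins <- vapply(seq_len(B), function(b) {
    Db <- stats::rbinom(length(D), 1L, probs)
    min_p_over_units(designs, Db)$min_p
  }, 0)
  list(nominal_p = obs$p, min_p = obs$min_p,
       p_value = (1 + sum(mins <= obs$min_p)) / (B + 1), B = B)
}

#' minP single-SNP interaction test
#'
#' The standard single-marker comparator: for each SNP, a 2-df likelihood
#' ratio test of the SNP-by-exposure interaction in a logistic model with
#' the SNP as a three-level categorical variable (levels absent from the
#' data are dropped, with the degrees of freedom reduced accordingly),
#' exposure and covariates. The test statistic is the minimum nominal
#' p-value over SNPs, and its significance is calibrated by a parametric
#' bootstrap under the fitted main-effects null (additive SNP main effects
#' plus exposure and covariates), which accounts for the min-p selection
#' effect.
#'
#' @param data a [case_control_data()].
#' @param B number of bootstrap replicates (default 999).
#' @param seed optional integer seed.
#' @return object of class `minp_test` with per-SNP nominal p-values, the
#'   minimum, and the calibrated p-value.
#' @export
minp_snp_test <- function(data, B = 999L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  G <- data$table$codes[data$genotype_id, , drop = FALSE]
  poly <- apply(G, 2L, function(g) length(unique(g)) >= 2L)
  if (!all(poly)) warning("excluding ", sum(!poly), " monomorphic SNP(s)")
  G <- G[, poly, drop = FALSE]
  if (ncol(G) == 0L) stop("no polymorphic SNPs")
  designs <- build_unit_designs(data$E, G, data$X, categorical = TRUE)
  null_design <- cbind(1, G, data$E, data$X)   # additive SNP main effects
  res <- calibrate_min_p(data$D, designs, null_design, B = B)
  structure(c(res, list(unit = "SNP", n_units = ncol(G))),
            class = "minp_test")
}

#' minP principal-component interaction test
#'
#' The principal-component comparator: PCs are computed from the centred
#' (not scaled) subjects-by-SNP code matrix, each loading vector's sign
#' fixed so its largest-absolute entry is positive. For each PC, a 1-df
#' likelihood ratio test of the PC-by-exposure interaction (PC treated as a
#' continuous variable) in a logistic model with the PC, exposure and
#' covariates; the minimum nominal p-value is calibrated by the same
#' parametric bootstrap, under a null with all PC main effects.
#'
#' @inheritParams minp_snp_test
#' @param n_pc number of leading PCs to test (default: all with positive
#'   variance).
#' @export
minp_pc_test <- function(data, B = 999L, n_pc = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  G <- data$table$codes[data$genotype_id, , drop = FALSE]
  Gc <- scale(G, center = TRUE, scale = FALSE)
  if (all(abs(Gc) < 1e-12)) stop("genotype matrix has zero variance")
  sv <- svd(Gc)
  pos <- sv$d > 1e-8 * sv$d[1L]
  scores <- sv$u[, pos, drop = FALSE] %*% diag(sv$d[pos], sum(pos))
  # sign convention: largest-absolute loading positive
  for (j in seq_len(ncol(scores))) {
    l <- sv$v[, j]
    if (l[which.max(abs(l))] < 0) scores[, j] <- -scores[, j]
  }
  if (!is.null(n_pc)) scores <- scores[, seq_len(min(n_pc, ncol(scores))),
                                       drop = FALSE]
  designs <- build_unit_designs(data$E, scores, data$X, categorical = FALSE)
  null_design <- cbind(1, scores, data$E, data$X)
  res <- calibrate_min_p(data$D, designs, null_design, B = B)
  structure(c(res, list(unit = "PC", n_units = ncol(scores))),
            class = "minp_test")
}

#' @export
print.minp_test <- function(x, ...) {
  cat(sprintf("minP-%s interaction test over %d units\n", x$unit, x$n_units))
  cat(sprintf("  min nominal p = %.4g; calibrated p = %.4g (B = %d)\n",
              x$min_p, x$p_value, x$B))
  invisible(x)
}
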