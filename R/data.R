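#' Assemble a case-control dataset for latent-profile modelling
#'
#' Bundles the per-subject outcome, exposure, optional covariates and the
#' region's genotypes into the container consumed by [gep_fit()] and the
#' interaction test. The genotype matrix is collapsed to its distinct
#' multilocus genotypes, and the nearest-neighbour similarity graph over
#' those genotypes is built once and stored.
#'
#' @param disease length-n 0/1 vector (1 = case).
#' @param exposure length-n numeric exposure (binary or continuous).
#' @param genotypes n x J matrix of minor-allele counts 0/1/2, or an
#'   existing [genotype_table()] (whose `subject_index` must have length n).
#' @param covariates optional n x p numeric matrix or data frame of
#'   adjustment covariates.
#' @param n_neighbors neighbourhood size for the genotype graph (default 4).
#' @param regroup optional number of pseudo-genotype subgroups; when the
#'   number of distinct genotypes is very large, [regroup_genotypes()] is
#'   applied first to cap the Potts lattice size.
#' @return object of class `case_control_data` with elements `D`, `E`, `X`,
#'   `genotype_id`, `table` (the genotype table) and `graph`.
#' @export
case_control_data <- function(disease, exposure, genotypes, covariates = NULL,
                              n_neighbors = 4L, regroup = NULL) {
  D <- as.integer(disease)
  if (!all(D %in% 0:1)) stop("disease must be coded 0/1")
  E <- as.numeric(exposure)
  n <- length(D)
  if (length(E) != n) stop("exposure length does not match disease")
  if (anyNA(E)) stop("missing exposure values")
  if (sum(D) == 0L || sum(D) == n) stop("need at least one case and one control")

  tab <- if (inherits(genotypes, "genotype_table")) genotypes
         else genotype_table(genotypes)
  if (length(tab$subject_index) != n)
    stop("genotype rows do not match the number of subjects")
  if (!is.null(regroup) && regroup < nrow(tab$codes))
    tab <- regroup_genotypes(tab, regroup)

  X <- if (is.null(covariates)) matrix(0, n, 0L) else {
    X <- as.matrix(covariates)
    storage.mode(X) <- "double"
    if (nrow(X) != n) stop("covariate rows do not match the number of subjects")
    if (anyNA(X)) stop("missing covariate values")
    X
  }
  graph <- neighbor_graph(genotype_distance(tab), n_neighbors = n_neighbors)
  structure(
    list(D = D, E = E, X = X,
         genotype_id = tab$subject_index,
         table = tab, graph = graph),
    class = "case_control_data")
}

#' @export
print.case_control_data <- function(x, ...) {
  cat("Case-control data:", sum(x$D), "cases,", sum(1 - x$D), "controls;",
      nrow(x$table$codes), "distinct genotypes at", ncol(x$table$codes),
      "SNPs;", ncol(x$X), "covariate(s)\n")
  invisible(x)
}

# replace the outcome vector, keeping genotype/graph machinery (used by the
# parametric bootstrap, where only D is regenerated)
replace_outcome <- function(data, new_D) {
  stopifnot(inherits(data, "case_control_data"))
  new_D <- as.integer(new_D)
  if (length(new_D) != length(data$D)) stop("outcome length mismatch")
  data$D <- new_D
  data
}

#' Stable Bernoulli log-likelihood of the cluster-specific logistic model
#'
#' Evaluates \eqn{\sum_i D_i \log p_i + (1-D_i)\log(1-p_i)} with
#' \eqn{\mathrm{logit}\, p_i = \alpha_{z(c_i)} + \beta_{z(c_i)} E_i +
#' \gamma' X_i} (interaction form) or with a single shared \eqn{\beta}
#' (no-interaction form), computed stably for extreme linear predictors.
#'
#' @param data a [case_control_data()].
#' @param z allocation vector over distinct genotypes.
#' @param alpha,beta,gamma coefficient vectors; `beta` has length K for the
#'   interaction form and length 1 otherwise.
#' @param model `"interaction"` or `"no_interaction"`.
#' @return scalar log-likelihood.
#' @export
gep_log_likelihood <- function(data, z, alpha, beta, gamma = numeric(0),
                               model = c("interaction", "no_interaction")) {
  model <- match.arg(model)
  stopifnot(inherits(data, "case_control_data"))
  H <- nrow(data$table$codes)
  if (length(z) != H) stop("allocation vector length must equal H")
  K <- length(alpha)
  if (!all(z %in% seq_len(K))) stop("allocation labels exceed the number of intercepts")
  if (model == "interaction" && length(beta) != K)
    stop("interaction form needs one exposure slope per cluster")
  if (model == "no_interaction" && length(beta) != 1L)
    stop("no-interaction form needs a single shared exposure slope")
  if (length(gamma) != ncol(data$X)) stop("gamma length must match covariates")
  k <- z[data$genotype_id]
  b <- if (model == "interaction") beta[k] else beta
  eta <- alpha[k] + b * data$E +
    if (ncol(data$X) > 0L) drop(data$X %*% gamma) else 0
  sum(data$D * eta - ifelse(eta > 0, eta + log1p(exp(-eta)), log1p(exp(eta))))
}
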