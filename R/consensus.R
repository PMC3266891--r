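#' Posterior co-assignment proportion matrix
#'
#' For every pair of distinct genotypes, the proportion of stored MCMC
#' draws in which the two carried the same cluster label. The matrix is
#' symmetric with unit diagonal and is invariant to relabelling of clusters
#' within any draw, which makes it the natural label-switching-proof
#' summary of the posterior clustering.
#'
#' @param samples a [gep_fit()] or an integer matrix of allocation draws
#'   (one row per draw).
#' @return H x H numeric matrix of proportions.
#' @export
coassignment_matrix <- function(samples) {
  z <- if (inherits(samples, "gep_fit")) samples$samples$z else as.matrix(samples)
  if (nrow(z) == 0L) stop("need at least one stored draw")
  storage.mode(z) <- "integer"
  coassign_cpp(z)
}

#' Partitioning around medoids on a precomputed dissimilarity
#'
#' In-package k-medoids (BUILD then SWAP) on an arbitrary symmetric
#' dissimilarity matrix. BUILD greedily seeds `k` medoids minimizing total
#' dissimilarity; SWAP repeatedly applies the best medoid/non-medoid
#' exchange (standard nearest/second-nearest delta computation) until no
#' exchange lowers the objective. All ties are broken by the lowest index,
#' so the result is fully deterministic; the `seed` argument is accepted
#' for interface stability but has no effect on the deterministic
#' implementation.
#'
#' @param dissimilarity symmetric nonnegative matrix with zero diagonal.
#' @param k number of clusters (1 <= k < nrow).
#' @param seed ignored (deterministic algorithm); kept for call
#'   compatibility.
#' @return list with `medoids` (indices), `labels` (nearest-medoid
#'   assignment, labelled in medoid order) and `objective` (total
#'   dissimilarity to assigned medoids).
#' @export
pam_cluster <- function(dissimilarity, k, seed = NULL) {
  d <- as.matrix(dissimilarity)
  H <- nrow(d)
  if (k <= 0L || k >= H) stop("k must satisfy 1 <= k < number of objects")
  storage.mode(d) <- "double"
  out <- pam_cpp(d, as.integer(k))
  list(medoids = as.integer(out$medoids), labels = as.integer(out$labels),
       objective = out$objective)
}

#' Consensus partition from posterior allocation draws
#'
#' Ensemble-averages the MCMC clusterings: computes the co-assignment
#' proportion matrix, then partitions genotypes into `k_star` clusters by
#' k-medoids with one minus the co-assignment proportion as dissimilarity.
#' Labels are propagated to subjects through their genotype ids.
#'
#' @param samples a [gep_fit()] or matrix of allocation draws.
#' @param k_star number of consensus clusters.
#' @param data the [case_control_data()] (taken from the fit when omitted);
#'   needed to map genotype labels to subjects.
#' @param seed optional seed for the k-medoids swap scan.
#' @return object of class `gep_consensus`: `coassign`, `labels` (per
#'   genotype), `subject_labels`, `medoids`.
#' @export
consensus_partition <- function(samples, k_star, data = NULL, seed = NULL) {
  if (inherits(samples, "gep_fit") && is.null(data)) data <- samples$data
  pi_mat <- coassignment_matrix(samples)
  if (k_star == 1L) {
    labels <- rep(1L, nrow(pi_mat)); medoids <- which.min(rowSums(1 - pi_mat))[1L]
  } else {
    fit <- pam_cluster(1 - pi_mat, k = k_star, seed = seed)
    labels <- fit$labels; medoids <- fit$medoids
  }
  structure(
    list(coassign = pi_mat, labels = labels,
         subject_labels = if (!is.null(data)) labels[data$genotype_id] else NULL,
         medoids = medoids, k = as.integer(k_star)),
    class = "gep_consensus")
}

#' @export
print.gep_consensus <- function(x, ...) {
  cat("Consensus partition into", x$k, "clusters; genotype cluster sizes:",
      paste(tabulate(x$labels, x$k), collapse = ", "), "\n")
  invisible(x)
}
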