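graph_edges <- function(graph) {
  stopifnot(inherits(graph, "neighbor_graph"))
  graph$edges
}

#' Potts sufficient statistic
#'
#' Computes \eqn{U(z) = \sum_{h < h'} w_{hh'} I(z_h = z_{h'})}, the weighted
#' number of neighbour pairs sharing a cluster label. The unnormalized Potts
#' density is \eqn{\exp\{\psi U(z)\}}.
#'
#' @param z integer allocation vector (one label per distinct genotype).
#' @param graph a [neighbor_graph()].
#' @return nonnegative scalar.
#' @export
potts_suff_stat <- function(z, graph) {
  e <- graph_edges(graph)
  H <- nrow(graph$weights)
  if (length(z) != H) stop("allocation vector length must equal graph size")
  potts_suff_stat_cpp(as.integer(z), H, e$i, e$j, as.numeric(e$w))
}

#' Log unnormalized Potts density
#'
#' Returns \eqn{\psi U(z)}; see [potts_suff_stat()].
#'
#' @inheritParams potts_suff_stat
#' @param psi nonnegative coupling (regulating) parameter.
#' @export
potts_log_unnorm <- function(z, psi, graph) {
  if (psi < 0) stop("psi must be nonnegative")
  psi * potts_suff_stat(z, graph)
}

#' Gibbs draws from the Potts prior
#'
#' Draws allocation vectors approximately from the Potts distribution with
#' coupling `psi` on the given neighbour graph, using single-site Gibbs
#' sweeps from a fresh uniform random start for every draw. These are the
#' auxiliary draws used by the Monte Carlo Metropolis-Hastings update of
#' `psi`, and are also useful on their own for calibrating the coupling
#' against the induced neighbour co-assignment probability.
#'
#' @inheritParams potts_log_unnorm
#' @param K number of cluster labels.
#' @param n_samples number of draws.
#' @param sweeps_per_sample full Gibbs sweeps per draw (default 20).
#' @param seed optional integer seed.
#' @return `n_samples` x H integer matrix of labels in `1:K`.
#' @export
sample_potts <- function(psi, graph, K, n_samples, sweeps_per_sample = 20L,
                         seed = NULL) {
  if (psi < 0) stop("psi must be nonnegative")
  if (K < 1) stop("K must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  e <- graph_edges(graph)
  sample_potts_cpp(psi, nrow(graph$weights), e$i, e$j, as.numeric(e$w),
                   as.integer(K), as.integer(n_samples),
                   as.integer(sweeps_per_sample))
}

#' Exact log normalizing constant of the Potts model by enumeration
#'
#' Enumerates all \eqn{K^H} allocation vectors and returns
#' \eqn{\log \sum_z \exp\{\psi U(z)\}}. Only feasible for tiny graphs; used
#' as an independent oracle for the Monte Carlo machinery.
#'
#' @inheritParams sample_potts
#' @param max_states guard on the enumeration size (default 1e6).
#' @export
potts_log_norm_exact <- function(psi, graph, K, max_states = 1e6) {
  H <- nrow(graph$weights)
  if (K^H > max_states) stop("state space K^H too large to enumerate")
  states <- as.matrix(expand.grid(rep(list(seq_len(K)), H)))
  e <- graph_edges(graph)
  lu <- apply(states, 1L, function(z)
    psi * sum(e$w * (z[e$i] == z[e$j])))
  m <- max(lu)
  m + log(sum(exp(lu - m)))
}

#' Average neighbour co-assignment probability
#'
#' For a set of allocation draws, the proportion of (neighbour pair, draw)
#' combinations in which both genotypes carry the same cluster label. Under
#' independence (`psi = 0`) this equals `1/K`; it increases towards 1 with
#' the coupling, which is how a usable upper bound for `psi` is chosen.
#'
#' @param samples matrix of allocation draws (one row per draw), e.g. from
#'   [sample_potts()].
#' @param graph a [neighbor_graph()].
#' @return scalar in `[0, 1]`.
#' @export
coassignment_probability <- function(samples, graph) {
  samples <- rbind(samples)
  if (nrow(samples) == 0L) stop("need at least one sample")
  e <- graph_edges(graph)
  if (nrow(e) == 0L) stop("graph has no positive-weight edges")
  mean(apply(samples, 1L, function(z) mean(z[e$i] == z[e$j])))
}
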