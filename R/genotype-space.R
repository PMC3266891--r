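#' Tabulate the distinct multilocus genotypes in a sample
#'
#' Collapses an \eqn{n \times J} matrix of minor-allele counts (coded 0/1/2)
#' into the set of distinct multilocus genotypes observed in the sample.
#' Each distinct joint genotype acts as one "site" for the Potts prior, so
#' all downstream machinery (distances, neighbour graph, allocation vectors)
#' works on the \eqn{H} distinct rows rather than on the \eqn{n} subjects.
#'
#' @param genotype_matrix numeric or integer matrix with one row per subject
#'   and one column per SNP; entries must be 0, 1 or 2 (no missing values --
#'   see [impute_genotypes()] for a simple pre-processing helper).
#' @return An object of class `genotype_table` with components
#'   \describe{
#'     \item{codes}{\eqn{H \times J} matrix of distinct genotype rows, in
#'       canonical (lexicographic) order so genotype ids are intrinsic to
#'       the genotype set rather than to subject order;}
#'     \item{subject_index}{length-\eqn{n} map from subject to genotype id;}
#'     \item{counts}{number of subjects carrying each distinct genotype;}
#'     \item{snp_variance}{per-SNP population variance (divide-by-\eqn{n})
#'       of the codes over all subjects, used to standardize distances.}
#'   }
#' @details Monomorphic SNPs (zero variance over subjects) are rejected:
#'   they carry no information and would make the standardized distance
#'   undefined. Remove or impute them upstream.
#' @seealso [genotype_distance()], [neighbor_graph()]
#' @export
genotype_table <- function(genotype_matrix) {
  g <- as.matrix(genotype_matrix)
  storage.mode(g) <- "integer"
  if (nrow(g) < 2L) stop("need at least 2 subjects")
  if (ncol(g) < 1L) stop("need at least 1 SNP")
  if (anyNA(g)) stop("missing genotype codes are not allowed; impute or drop upstream")
  if (!all(g %in% 0:2)) stop("genotype codes must be 0, 1 or 2")
  n <- nrow(g)
  # population (divide-by-n) variance over all subjects, per SNP
  v <- colMeans(g^2) - colMeans(g)^2
  if (any(v <= 0)) {
    bad <- which(v <= 0)
    nm <- colnames(g)
    lab <- if (is.null(nm)) paste0("SNP", bad) else nm[bad]
    stop("monomorphic SNP(s) with zero variance: ", paste(lab, collapse = ", "))
  }
  key <- apply(g, 1L, paste, collapse = ",")
  first <- !duplicated(key)
  codes <- g[first, , drop = FALSE]
  # canonical (lexicographic) ordering of distinct genotypes, so genotype
  # ids -- and the id-based tie-breaks downstream -- do not depend on the
  # order subjects happen to appear in
  o <- do.call(order, as.data.frame(codes))
  codes <- codes[o, , drop = FALSE]
  id <- match(key, apply(codes, 1L, paste, collapse = ","))
  structure(
    list(codes = codes,
         subject_index = id,
         counts = as.integer(tabulate(id, nbins = nrow(codes))),
         snp_variance = v),
    class = "genotype_table")
}

#' @export
print.genotype_table <- function(x, ...) {
  cat("Genotype table:", nrow(x$codes), "distinct multilocus genotypes,",
      ncol(x$codes), "SNPs,", length(x$subject_index), "subjects\n")
  invisible(x)
}

#' Variance-standardized squared distance between multilocus genotypes
#'
#' For distinct genotypes \eqn{h, h'} with codes \eqn{g_{hj}} the distance is
#' \deqn{d(h, h') = \sum_j (g_{hj} - g_{h'j})^2 / s_j^2,}
#' where \eqn{s_j^2} is the sample variance of SNP \eqn{j}'s code over all
#' subjects. Standardizing by the per-SNP variance prevents common SNPs from
#' dominating the geometry of the genotype space.
#'
#' @param table a [genotype_table()].
#' @return symmetric nonnegative \eqn{H \times H} matrix with zero diagonal.
#' @export
genotype_distance <- function(table) {
  stopifnot(inherits(table, "genotype_table"))
  g <- sweep(table$codes, 2L, sqrt(table$snp_variance), "/")
  sq <- rowSums(g^2)
  d <- outer(sq, sq, "+") - 2 * tcrossprod(g)
  d[d < 0] <- 0           # numerical noise
  diag(d) <- 0
  d
}

#' Nearest-neighbour similarity graph over distinct genotypes
#'
#' Builds the symmetric weight matrix used by the Potts prior. Genotype
#' \eqn{h'} receives weight 2 from \eqn{h} when each is among the other's
#' `n_neighbors` closest distinct genotypes (mutual k-nearest-neighbour
#' relation), weight 1 when the relation holds in one direction only, and 0
#' otherwise. Ties at the k-th nearest distance are broken by ascending
#' genotype id so the graph is reproducible without any random seed.
#'
#' @param distance symmetric nonnegative matrix with zero diagonal, e.g.
#'   from [genotype_distance()].
#' @param n_neighbors number of nearest distinct genotypes defining each
#'   neighbourhood (default 4).
#' @return object of class `neighbor_graph`: list with `weights` (dense
#'   symmetric integer matrix with entries 0/1/2), `n_neighbors`, and
#'   `edges`, a data frame of the positive-weight pairs (i < j).
#' @export
neighbor_graph <- function(distance, n_neighbors = 4L) {
  d <- as.matrix(distance)
  H <- nrow(d)
  if (n_neighbors < 1L) stop("n_neighbors must be >= 1")
  if (!isTRUE(all.equal(d, t(d), tolerance = 1e-8)))
    stop("distance matrix must be symmetric")
  k <- min(n_neighbors, H - 1L)
  # in_knn[h, h'] = 1 if h' is among the k nearest (distinct) genotypes of h
  in_knn <- matrix(0L, H, H)
  for (h in seq_len(H)) {
    o <- order(d[h, ], seq_len(H))   # stable: ties broken by ascending id
    o <- o[o != h][seq_len(k)]
    in_knn[h, o] <- 1L
  }
  w <- in_knn + t(in_knn)
  diag(w) <- 0L
  up <- which(upper.tri(w) & w > 0L, arr.ind = TRUE)
  structure(
    list(weights = w,
         n_neighbors = as.integer(n_neighbors),
         edges = data.frame(i = up[, 1L], j = up[, 2L],
                            w = w[cbind(up[, 1L], up[, 2L])])),
    class = "neighbor_graph")
}

#' @export
print.neighbor_graph <- function(x, ...) {
  cat("Neighbour graph:", nrow(x$weights), "genotypes,",
      nrow(x$edges), "weighted edges (k =", x$n_neighbors, ")\n")
  invisible(x)
}

#' Merge distinct genotypes into pseudo-genotype subgroups
#'
#' For samples with very many distinct multilocus genotypes the MCMC cost can
#' be reduced by first partitioning the genotype space into a smaller number
#' of subgroups (by k-medoids on the standardized genotype distance) and then
#' treating each subgroup as a single pseudo-genotype. Each pseudo-genotype
#' takes its medoid's codes; subject indices and counts are remapped.
#'
#' @param table a [genotype_table()].
#' @param target_groups desired number of pseudo-genotypes (< H).
#' @return a `genotype_table` with `target_groups` rows (or the input,
#'   with a warning, when `target_groups >= H`).
#' @export
regroup_genotypes <- function(table, target_groups) {
  stopifnot(inherits(table, "genotype_table"))
  H <- nrow(table$codes)
  if (target_groups >= H) {
    warning("target_groups >= number of distinct genotypes; returning input unchanged")
    return(table)
  }
  d <- genotype_distance(table)
  fit <- pam_cluster(d, k = as.integer(target_groups))
  new_id <- fit$labels[table$subject_index]
  out <- table
  out$codes <- table$codes[fit$medoids, , drop = FALSE]
  out$subject_index <- new_id
  out$counts <- as.integer(tabulate(new_id, nbins = target_groups))
  out
}

#' Impute missing genotype codes to the rounded per-SNP mean
#'
#' Minimal pre-processing helper: replaces `NA` codes by the per-SNP mean
#' code over observed subjects, rounded to the nearest of 0/1/2. The model
#' itself never sees missing data.
#'
#' @param genotype_matrix matrix of codes 0/1/2 possibly containing `NA`.
#' @return matrix of the same shape with no missing values.
#' @export
impute_genotypes <- function(genotype_matrix) {
  g <- as.matrix(genotype_matrix)
  for (j in seq_len(ncol(g))) {
    miss <- is.na(g[, j])
    if (any(miss)) {
      if (all(miss)) stop("SNP column ", j, " has no observed genotypes")
      g[miss, j] <- max(0, min(2, round(mean(g[!miss, j]))))
    }
  }
  g
}

#' Greedy r-squared pruning of SNPs
#'
#' Convenience pre-processing: walks SNPs left to right and drops any SNP
#' whose squared allelic correlation with an already-kept SNP is at or above
#' `threshold`. Mirrors the common tag-SNP thinning used before building the
#' genotype space, so that no pair of retained SNPs is nearly redundant.
#'
#' @param genotype_matrix subjects-by-SNP matrix of codes 0/1/2.
#' @param threshold r-squared cutoff (default 0.8).
#' @return integer vector of retained column indices.
#' @export
prune_r2 <- function(genotype_matrix, threshold = 0.8) {
  g <- as.matrix(genotype_matrix)
  keep <- integer(0)
  for (j in seq_len(ncol(g))) {
    if (length(keep) == 0L) { keep <- j; next }
    r2 <- suppressWarnings(stats::cor(g[, j], g[, keep, drop = FALSE]))^2
    if (all(is.na(r2)) || max(r2, na.rm = TRUE) < threshold) keep <- c(keep, j)
  }
  keep
}
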