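#' Load a case-control study from delimited text files
#'
#' Reads a genotype file (first column subject id, remaining columns SNP
#' codes 0/1/2 with a header of SNP names; PLINK `.raw`-style additive
#' files work once their leading pedigree columns are reduced to an id
#' column) and a phenotype file (subject id, disease 0/1, exposure,
#' optional covariates), joins them on subject id, validates, and returns
#' the assembled dataset. Rows with missing required fields are rejected
#' with a per-row report.
#'
#' @param genotype_path,phenotype_path paths to whitespace- or
#'   tab-delimited text files with headers.
#' @param disease_col,exposure_col column names in the phenotype file.
#' @param covariate_cols optional character vector of covariate columns.
#' @param id_col subject-id column name shared by both files (default:
#'   first column of each).
#' @param n_neighbors,regroup passed to [case_control_data()].
#' @return a [case_control_data()]; rejected rows (if any) are reported in
#'   a warning and recorded in the `rejected` attribute.
#' @export
load_study <- function(genotype_path, phenotype_path,
                       disease_col = "disease", exposure_col = "exposure",
                       covariate_cols = NULL, id_col = NULL,
                       n_neighbors = 4L, regroup = NULL) {
  if (!file.exists(genotype_path)) stop("genotype file not found: ", genotype_path)
  if (!file.exists(phenotype_path)) stop("phenotype file not found: ", phenotype_path)
  gt <- utils::read.table(genotype_path, header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE)
  ph <- utils::read.table(phenotype_path, header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE)
  gid <- if (is.null(id_col)) names(gt)[1L] else id_col
  pid <- if (is.null(id_col)) names(ph)[1L] else id_col
  if (!pid %in% names(ph)) stop("id column not found in phenotype file")
  if (!disease_col %in% names(ph))
    stop("unknown disease column: ", disease_col)
  if (!exposure_col %in% names(ph))
    stop("unknown exposure column: ", exposure_col)
  for (v in covariate_cols) if (!v %in% names(ph))
    stop("unknown covariate column: ", v)

  common <- intersect(gt[[gid]], ph[[pid]])
  if (length(common) == 0L) stop("no subject ids shared between the two files")
  gt <- gt[match(common, gt[[gid]]), , drop = FALSE]
  ph <- ph[match(common, ph[[pid]]), , drop = FALSE]

  need <- ph[, c(disease_col, exposure_col, covariate_cols), drop = FALSE]
  gmat <- as.matrix(gt[, setdiff(names(gt), gid), drop = FALSE])
  bad <- !stats::complete.cases(need) | apply(gmat, 1L, anyNA)
  if (any(bad)) {
    warning(sum(bad), " row(s) rejected for missing required fields: ",
            paste(utils::head(common[bad], 10L), collapse = ", "),
            if (sum(bad) > 10L) ", ...")
    gt <- gt[!bad, , drop = FALSE]; ph <- ph[!bad, , drop = FALSE]
    need <- need[!bad, , drop = FALSE]; gmat <- gmat[!bad, , drop = FALSE]
  }
  D <- need[[disease_col]]
  if (!all(D %in% 0:1)) stop("disease column must be coded 0/1")
  storage.mode(gmat) <- "integer"
  out <- case_control_data(
    D, need[[exposure_col]], gmat,
    covariates = if (length(covariate_cols))
      as.matrix(need[, covariate_cols, drop = FALSE]) else NULL,
    n_neighbors = n_neighbors, regroup = regroup)
  attr(out, "subject_id") <- ph[[pid]]
  attr(out, "rejected") <- common[bad]
  out
}

#' Write a case-control study to delimited text files
#'
#' Inverse of [load_study()]: emits a tab-delimited genotype file and a
#' phenotype file that round-trip through [load_study()].
#'
#' @param data a [case_control_data()].
#' @param genotype_path,phenotype_path output paths.
#' @export
write_study <- function(data, genotype_path, phenotype_path) {
  stopifnot(inherits(data, "case_control_data"))
  n <- length(data$D)
  ids <- attr(data, "subject_id")
  if (is.null(ids)) ids <- sprintf("S%05d", seq_len(n))
  G <- data$table$codes[data$genotype_id, , drop = FALSE]
  if (is.null(colnames(G))) colnames(G) <- paste0("snp", seq_len(ncol(G)))
  utils::write.table(data.frame(id = ids, G, check.names = FALSE),
                     genotype_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  ph <- data.frame(id = ids, disease = data$D, exposure = data$E)
  if (ncol(data$X) > 0L) {
    X <- data$X
    if (is.null(colnames(X))) colnames(X) <- paste0("X", seq_len(ncol(X)))
    ph <- cbind(ph, X)
  }
  utils::write.table(ph, phenotype_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(genotype_path, phenotype_path))
}

#' Run the full latent-profile analysis workflow
#'
#' Orchestrates the end-to-end analysis on an assembled dataset: fits the
#' interaction model over a grid of cluster counts (optionally with
#' repeated chains per K), selects the number of clusters by the +1 rule
#' (single runs) or the +1 SE rule (repeated runs), extracts the consensus
#' partition, summarizes per-genotype posterior effects, and (optionally)
#' runs the parametric-bootstrap interaction test. All artifacts can be
#' written to an output directory as delimited text plus a JSON manifest
#' echoing the configuration and seed.
#'
#' @param data a [case_control_data()] (e.g. from [load_study()] or
#'   [simulate_case_control()]).
#' @param k_grid candidate cluster counts (default `1:5`).
#' @param runs chains per K for the +1 SE rule (default 1: +1 rule).
#' @param control a [gep_control()].
#' @param test run the bootstrap interaction test (needs a grid with
#'   K >= 2; skipped with a message otherwise).
#' @param B bootstrap replicates for the test.
#' @param boot_control chain configuration for bootstrap replicates.
#' @param seed master seed for the whole workflow.
#' @param out_dir optional directory for artifacts (DIC table, consensus
#'   labels, genotype summaries, test result, manifest).
#' @return list of class `gep_analysis` with `kgrid`, `selected_k`,
#'   `consensus`, `genotype_summary`, `interaction_test` (or `NULL`).
#' @export
run_full_analysis <- function(data, k_grid = 1:5, runs = 1L,
                              control = gep_control(), test = TRUE,
                              B = 199L, boot_control = NULL, seed = 1L,
                              out_dir = NULL) {
  stopifnot(inherits(data, "case_control_data"))
  control$seed <- seed
  kg <- gep_k_grid(data, k_grid, model = "interaction", control = control,
                   runs = runs, keep_fits = TRUE)
  k_star <- kg$selected
  fit <- kg$fits[[paste0("K", k_star, ".r1")]]
  cons <- consensus_partition(fit, k_star)
  gsum <- genotype_summary(fit)

  it <- NULL
  if (test) {
    tg <- k_grid[k_grid >= 2L]
    if (length(tg) == 0L) {
      message("interaction test needs candidate K >= 2; skipped")
    } else {
      it <- gep_interaction_test(data, k_grid = tg, B = B, control = control,
                                 boot_control = boot_control,
                                 seed = seed + 1L)
    }
  }

  out <- structure(list(kgrid = kg[c("table", "selected", "rule")],
                        selected_k = k_star, consensus = cons,
                        genotype_summary = gsum, interaction_test = it,
                        seed = seed),
                   class = "gep_analysis")

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.table(kg$table, file.path(out_dir, "dic_table.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(gsum, file.path(out_dir, "genotype_summary.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(
      data.frame(subject = seq_along(cons$subject_labels),
                 cluster = cons$subject_labels),
      file.path(out_dir, "subject_clusters.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    manifest <- list(
      package_version = as.character(utils::packageVersion("gepotts")),
      seed = seed, k_grid = k_grid, runs = runs, rule = kg$rule,
      selected_k = k_star,
      control = control[setdiff(names(control), "seed")],
      interaction_test = if (!is.null(it))
        list(p_obs = it$p_obs, p_value = it$p_value, B = it$B,
             K1_star = it$K1_star, K0_star = it$K0_star) else NULL)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  out
}

#' @export
print.gep_analysis <- function(x, ...) {
  cat("Latent genetic-profile workflow (seed ", x$seed, ")\n", sep = "")
  cat("  selected K =", x$selected_k, "by the", x$kgrid$rule, "rule\n")
  print(x$consensus)
  if (!is.null(x$interaction_test)) print(x$interaction_test)
  invisible(x)
}
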