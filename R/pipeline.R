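#' Fit the full cross-individual marker-gene consensus
#'
#' The package's main entry point. For every individual d in the cohort it
#' (1) discretizes d's expression and computes the MaxRel and mRMR feature
#' lists, (2) runs incremental feature selection: prefix models trained on
#' d and scored on every other individual, (3) locates the inflection point
#' of each accuracy curve, (4) intersects the selected prefix sets into d's
#' important-feature set; finally the important sets of all training
#' individuals are combined into one consensus frequency table ranking
#' genes by cross-individual robustness.
#'
#' @param datasets List of [expression_dataset()] objects (distinct
#'   individuals, shared gene universe), e.g. from [generate_cohort()].
#' @param n_features Length of the mRMR/MaxRel rankings (default 500).
#' @param n_curve Number of IFS curve points computed per test dataset
#'   (default `k_max + 1`): the consensus depends only on curve points up
#'   to `k_max + 1`, because inflection search is confined to
#'   `[k_min, k_max]` and greedy mRMR prefixes are nested, so computing
#'   longer curves cannot change the result. Raise it to inspect fuller
#'   curves.
#' @param criterion mRMR criterion, `"difference"` or `"quotient"`.
#' @param threshold_sd Discretization threshold in per-gene sd units.
#' @param C,tol Classifier settings, see [smo_fit()].
#' @param k_min,k_max Inflection search range (default \[4, 50\]).
#' @param verbose Print progress per training individual.
#' @return An object of class `ifs_consensus` with elements `summary`
#'   (cohort counts), `rankings` (per individual: `maxrel`, `mrmr`),
#'   `curves` (per training individual: list of `ifs_curve`),
#'   `inflections` (data frame train/test/k/total_acc/fallback),
#'   `important_sets`, `consensus` (the [consensus_frequency()] table) and
#'   `params`.
#' @seealso [run_all()] for the file-writing orchestration.
#' @export
ifs_consensus <- function(datasets, n_features = 500L,
                          n_curve = k_max + 1L,
                          criterion = c("difference", "quotient"),
                          threshold_sd = 1, C = 1, tol = 1e-3,
                          k_min = 4L, k_max = 50L, verbose = FALSE) {
  criterion <- match.arg(criterion)
  stopifnot(length(datasets) >= 2L)
  ids <- vapply(datasets, function(d) d$individual_id, character(1L))
  names(datasets) <- ids
  summary <- summarize_cohort(datasets)
  n_curve <- as.integer(n_curve)
  n_features <- as.integer(n_features)
  n_rank <- min(max(n_features, n_curve), nrow(datasets[[1L]]$values))
  if (n_curve > n_rank)
    stop("'n_curve' exceeds the number of available genes")

  rankings <- list(); curves <- list(); important_sets <- list()
  infl_rows <- list()
  for (id in ids) {
    if (verbose) message("training individual ", id)
    disc <- discretize_expression(datasets[[id]], threshold = threshold_sd)
    rankings[[id]] <- list(
      maxrel = maxrel_ranking(disc, n_features = n_rank),
      mrmr = mrmr_ranking(disc, n_features = n_rank, criterion = criterion))
    tests <- datasets[ids != id]
    cv <- run_ifs(datasets[[id]], tests, rankings[[id]]$mrmr,
                  n_max = n_curve, C = C, tol = tol)
    curves[[id]] <- cv
    infl <- lapply(cv, find_inflection, k_min = k_min, k_max = k_max)
    infl_rows[[id]] <- data.frame(
      train = id, test = names(cv),
      k = vapply(infl, function(p) p$k, integer(1L)),
      total_acc = vapply(infl, function(p) p$total_acc, numeric(1L)),
      fallback = vapply(infl, function(p) p$fallback_used, logical(1L)),
      stringsAsFactors = FALSE)
    important_sets[[id]] <- important_features(rankings[[id]]$mrmr, infl)
  }
  inflections <- do.call(rbind, infl_rows)
  rownames(inflections) <- NULL
  structure(
    list(summary = summary, rankings = rankings, curves = curves,
         inflections = inflections, important_sets = important_sets,
         consensus = consensus_frequency(important_sets),
         params = list(n_features = n_features, n_curve = n_curve,
                       criterion = criterion, threshold_sd = threshold_sd,
                       C = C, tol = tol, k_min = k_min, k_max = k_max),
         call = match.call()),
    class = "ifs_consensus")
}

#' @export
print.ifs_consensus <- function(x, ...) {
  cat("Cross-individual marker-gene consensus\n",
      "  ", nrow(x$summary), " individuals, ", sum(x$summary$total),
      " samples; mRMR criterion '", x$params$criterion,
      "', inflection range [", x$params$k_min, ", ", x$params$k_max, "]\n",
      sep = "")
  sizes <- vapply(x$important_sets, length, integer(1L))
  cat("  important-set sizes: ",
      paste(sprintf("%s=%d", names(sizes), sizes), collapse = ", "), "\n",
      sep = "")
  cat("  consensus genes: ", nrow(x$consensus), " (",
      sum(x$consensus$frequency == length(x$important_sets)),
      " in every set)\n", sep = "")
  invisible(x)
}

#' @export
summary.ifs_consensus <- function(object, ...) {
  cat("Cohort:\n")
  print(object$summary)
  cat("\nInflection points (k, total accuracy per train/test pair):\n")
  print.data.frame(object$inflections, row.names = FALSE, digits = 4)
  cat("\nTop consensus genes:\n")
  print(object$consensus, n = 15L)
  invisible(object)
}

#' Plot the IFS accuracy curves of one training individual
#'
#' Draws total prediction accuracy against the number of top-ranked
#' features for every test individual, marking each curve's inflection
#' point with a triangle.
#'
#' @param x An `ifs_consensus` fit.
#' @param train Training individual id (default: the first).
#' @param ... Passed to [graphics::matplot()].
#' @return Invisibly, `x`.
#' @importFrom graphics matplot points legend
#' @export
plot.ifs_consensus <- function(x, train = names(x$curves)[1L], ...) {
  cv <- x$curves[[train]]
  if (is.null(cv)) stop("no curves for training individual '", train, "'")
  acc <- sapply(cv, function(cur) cur$total_acc)
  matplot(cv[[1L]]$k, acc, type = "l", lty = 1L, col = seq_along(cv),
          xlab = "number of top mRMR features",
          ylab = "total prediction accuracy",
          main = paste("IFS curves, training individual", train), ...)
  inf <- x$inflections[x$inflections$train == train, ]
  points(inf$k, inf$total_acc, pch = 17L, col = seq_along(cv), cex = 1.3)
  legend("bottomright", legend = names(cv), lty = 1L, col = seq_along(cv),
         bty = "n", cex = 0.8)
  invisible(x)
}

#' Configuration of a file-writing pipeline run
#'
#' Either a generator configuration (synthetic cohort) or paths to existing
#' matrix/annotation TSVs must be supplied, not neither.
#'
#' @param out_dir Output directory (created if needed).
#' @param generator A [cohort_config()], or `NULL` when reading files.
#' @param matrix_paths Named character vector individual id -> matrix TSV.
#' @param annotation_path Annotation TSV covering all individuals.
#' @param n_features,n_curve,criterion,threshold_sd,C,tol,k_min,k_max As in
#'   [ifs_consensus()].
#' @return A list of class `run_config`.
#' @export
run_config <- function(out_dir, generator = NULL, matrix_paths = NULL,
                       annotation_path = NULL, n_features = 500L,
                       n_curve = k_max + 1L,
                       criterion = "difference", threshold_sd = 1,
                       C = 1, tol = 1e-3, k_min = 4L, k_max = 50L) {
  if (is.null(generator) && (is.null(matrix_paths) || is.null(annotation_path)))
    stop("supply either 'generator' or 'matrix_paths' + 'annotation_path'")
  if (!is.null(generator) && !inherits(generator, "cohort_config"))
    stop("'generator' must be a cohort_config")
  structure(list(out_dir = out_dir, generator = generator,
                 matrix_paths = matrix_paths,
                 annotation_path = annotation_path,
                 n_features = as.integer(n_features),
                 n_curve = as.integer(n_curve), criterion = criterion,
                 threshold_sd = threshold_sd, C = C, tol = tol,
                 k_min = as.integer(k_min), k_max = as.integer(k_max)),
            class = "run_config")
}

#' Run the whole pipeline and persist every artifact
#'
#' Orchestrates simulate (or load) -> rank -> incremental feature selection
#' -> inflection -> consensus, writing per-individual matrices and
#' annotations (when simulating), ground truth, feature lists, one curve
#' TSV per train/test pair, an inflection table, per-individual important
#' sets and the consensus table under `config$out_dir`, plus a
#' `manifest.tsv` listing every artifact with its MD5 digest. Reruns with
#' the same configuration produce byte-identical artifacts and manifest.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with the `ifs_consensus` fit, the manifest
#'   data frame and the manifest path.
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(...) file.path(config$out_dir, ...)
  written <- character(0)
  emit <- function(path) written <<- c(written, path)

  if (!is.null(config$generator)) {
    cohort <- generate_cohort(config$generator)
    datasets <- cohort$datasets
    for (id in names(datasets)) {
      mp <- out(paste0(id, ".matrix.tsv"))
      ap <- out(paste0(id, ".annotation.tsv"))
      write_expression_dataset(datasets[[id]], mp, ap)
      emit(mp); emit(ap)
    }
    gt <- out("ground_truth.tsv")
    .write_tsv(cohort$truth, gt)
    emit(gt)
  } else {
    datasets <- lapply(names(config$matrix_paths), function(id)
      read_expression_dataset(config$matrix_paths[[id]],
                              config$annotation_path, id))
    names(datasets) <- names(config$matrix_paths)
  }

  fit <- ifs_consensus(datasets, n_features = config$n_features,
                       n_curve = config$n_curve,
                       criterion = config$criterion,
                       threshold_sd = config$threshold_sd,
                       C = config$C, tol = config$tol,
                       k_min = config$k_min, k_max = config$k_max)

  for (id in names(fit$rankings)) {
    p1 <- out(paste0(id, ".maxrel.tsv"))
    p2 <- out(paste0(id, ".mrmr.tsv"))
    write_feature_list(fit$rankings[[id]]$maxrel, p1); emit(p1)
    write_feature_list(fit$rankings[[id]]$mrmr, p2); emit(p2)
    for (test_id in names(fit$curves[[id]])) {
      pc <- out(paste0("curve_", id, "_vs_", test_id, ".tsv"))
      write_ifs_curve(fit$curves[[id]][[test_id]], pc); emit(pc)
    }
    pi_ <- out(paste0("important_", id, ".tsv"))
    .write_tsv(data.frame(rank = seq_along(fit$important_sets[[id]]),
                          gene_id = fit$important_sets[[id]],
                          stringsAsFactors = FALSE), pi_)
    emit(pi_)
  }
  pinf <- out("inflections.tsv")
  .write_tsv(fit$inflections, pinf); emit(pinf)
  pcons <- out("consensus.tsv")
  .write_tsv(as.data.frame(fit$consensus), pcons); emit(pcons)

  written <- sort(written)
  manifest <- data.frame(path = basename(written),
                         md5 = unname(tools::md5sum(written)),
                         stringsAsFactors = FALSE)
  mpath <- out("manifest.tsv")
  .write_tsv(manifest, mpath)
  invisible(list(fit = fit, manifest = manifest, manifest_path = mpath))
}
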