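#' Cross-individual incremental feature selection curves
#'
#' For each prefix length k = 1..`n_max` of a ranked feature list, trains a
#' one-vs-one SMO SVM on the training individual's samples restricted to
#' the first k genes and scores it on every test individual's samples,
#' producing one accuracy-vs-k curve per test dataset. Raw expression
#' values feed the classifier; discretization is used only for the
#' mutual-information ranking upstream.
#'
#' @param training An [expression_dataset()] used to fit every prefix model.
#' @param tests List of `expr_dataset` objects to score; an empty list
#'   yields an empty curve list.
#' @param flist A [feature_list()] (ordinarily flavor mRMR) with at least
#'   `n_max` entries.
#' @param n_max Number of nested prefix sets to evaluate.
#' @param C,tol,max_steps Classifier settings, see [smo_fit()].
#' @return A list of `ifs_curve` objects, one per test dataset, each a data
#'   frame with columns `k`, `total_acc`, `acc_BS`, `acc_CB`, `acc_CC`,
#'   `correct`, `n` and attributes `train` / `test`. Any listed gene absent
#'   from a dataset raises an error naming the gene.
#' @export
run_ifs <- function(training, tests, flist, n_max, C = 1, tol = 1e-3,
                    max_steps = 1e7) {
  stopifnot(inherits(training, "expr_dataset"), inherits(flist, "feature_list"))
  n_max <- as.integer(n_max)
  if (n_max < 1L || n_max > nrow(flist))
    stop("'n_max' must be in 1..", nrow(flist), " (feature list length)")
  genes <- flist$gene_id[seq_len(n_max)]
  for (d in c(list(training), tests)) {
    miss <- setdiff(genes, rownames(d$values))
    if (length(miss))
      stop("gene '", miss[1L], "' of the feature list is absent from ",
           "dataset '", d$individual_id, "'")
  }
  if (length(tests) == 0L) return(list())

  xtr_full <- t(training$values[genes, , drop = FALSE])
  xte_full <- lapply(tests, function(d) t(d$values[genes, , drop = FALSE]))
  rows <- lapply(tests, function(d) vector("list", n_max))
  for (k in seq_len(n_max)) {
    model <- smo_multiclass(xtr_full[, seq_len(k), drop = FALSE],
                            training$regions, C = C, tol = tol,
                            max_steps = max_steps)
    for (j in seq_along(tests)) {
      pred <- predict(model, xte_full[[j]][, seq_len(k), drop = FALSE])
      sc <- score_predictions(tests[[j]]$regions, pred)
      rows[[j]][[k]] <- data.frame(
        k = k, total_acc = sc$total,
        acc_BS = sc$per_class[["BS"]], acc_CB = sc$per_class[["CB"]],
        acc_CC = sc$per_class[["CC"]],
        correct = sc$correct, n = sc$n)
    }
  }
  curves <- lapply(seq_along(tests), function(j) {
    cur <- do.call(rbind, rows[[j]])
    attr(cur, "train") <- training$individual_id
    attr(cur, "test") <- tests[[j]]$individual_id
    class(cur) <- c("ifs_curve", "data.frame")
    cur
  })
  names(curves) <- vapply(tests, function(d) d$individual_id, character(1L))
  curves
}

# accuracy sequence used for the exact >=/> comparisons of the inflection
# rule: integer correct counts when the curve carries them (same n at every
# k of one curve), the stored accuracies otherwise (fixture curves)
.curve_acc_key <- function(curve) {
  if (!is.null(curve$correct)) curve$correct else curve$total_acc
}

#' Locate the inflection point of an IFS curve
#'
#' The inflection point is the first k in `[k_min, k_max]` whose total
#' accuracy is greater than or equal to the accuracy at k-1 and strictly
#' greater than the accuracy at k+1 — the earliest point where the curve
#' stops improving, marking a compact informative feature set. When no k in
#' range satisfies the rule (e.g. a strictly increasing curve), the
#' smallest k attaining the maximum accuracy in range is returned with
#' `fallback_used = TRUE`. Comparisons use exact correct-sample counts when
#' the curve carries them, so the >= / > conditions are unambiguous.
#'
#' @param curve An `ifs_curve` with at least 3 points.
#' @param k_min,k_max Search range, `2 <= k_min <= k_max <= N - 1`. The
#'   default \[4, 50\] focuses on compact feature sets.
#' @return A list of class `ifs_inflection`: `k`, `total_acc`,
#'   `fallback_used`, plus the curve's `train`/`test` ids.
#' @export
find_inflection <- function(curve, k_min = 4L, k_max = 50L) {
  stopifnot(inherits(curve, "data.frame"))
  N <- nrow(curve)
  if (N < 3L)
    stop("curve must have at least 3 points")
  k_min <- as.integer(k_min); k_max <- as.integer(k_max)
  if (!(2L <= k_min && k_min <= k_max && k_max <= N - 1L))
    stop("need 2 <= k_min <= k_max <= N - 1 (N = ", N, ")")
  acc <- .curve_acc_key(curve)
  ks <- k_min:k_max
  hit <- acc[ks] >= acc[ks - 1L] & acc[ks] > acc[ks + 1L]
  if (any(hit)) {
    k <- ks[which(hit)[1L]]
    fallback <- FALSE
  } else {
    k <- ks[which.max(acc[ks])]
    fallback <- TRUE
  }
  structure(list(k = k, total_acc = curve$total_acc[k],
                 fallback_used = fallback,
                 train = attr(curve, "train"), test = attr(curve, "test")),
            class = "ifs_inflection")
}

#' @export
print.ifs_inflection <- function(x, ...) {
  cat("Inflection point: k = ", x$k, ", total accuracy ",
      format(x$total_acc, digits = 4),
      if (x$fallback_used) " (fallback: argmax in range)", "\n", sep = "")
  invisible(x)
}

#' First feature count attaining the maximum accuracy of a curve
#'
#' @param curve A non-empty `ifs_curve`.
#' @return List with `k` (smallest k at the maximum) and `total_acc`.
#' @export
max_accuracy_point <- function(curve) {
  stopifnot(inherits(curve, "data.frame"), nrow(curve) >= 1L)
  acc <- .curve_acc_key(curve)
  k <- curve$k[which.max(acc)]
  list(k = k, total_acc = curve$total_acc[curve$k == k][1L])
}

#' Important features of one training individual
#'
#' Intersects the prefix sets selected by the inflection points of the
#' training individual's curves against every test individual. Because the
#' prefixes of one ranked list are nested, the intersection equals the
#' prefix of length `min(k)`; both computations are performed and asserted
#' equal before returning.
#'
#' @param flist The [feature_list()] the curves were built from.
#' @param inflections Non-empty list of [find_inflection()] results for
#'   curves sharing this training dataset.
#' @return Character vector of gene ids, in list order.
#' @export
important_features <- function(flist, inflections) {
  stopifnot(inherits(flist, "feature_list"))
  if (length(inflections) == 0L)
    stop("'inflections' must be non-empty")
  ks <- vapply(inflections, function(p) as.integer(p$k), integer(1L))
  if (any(ks < 1L) || any(ks > nrow(flist)))
    stop("inflection k outside the feature list")
  prefix_sets <- lapply(ks, function(k) flist$gene_id[seq_len(k)])
  literal <- Reduce(intersect, prefix_sets)
  by_min <- flist$gene_id[seq_len(min(ks))]
  stopifnot(identical(sort(literal), sort(by_min)))
  by_min
}

#' Consensus frequency of important genes across training individuals
#'
#' Counts, for every gene, in how many training individuals' important
#' feature sets it occurs — the cross-individual robustness statistic that
#' ranks the final marker genes.
#'
#' @param important_sets Named list: training individual id -> character
#'   vector of important gene ids. Ids must be distinct.
#' @return A `consensus_table`: data frame `gene_id`, `frequency`,
#'   `training_ids` (comma-separated contributing individuals), sorted by
#'   frequency descending then gene id ascending.
#' @export
consensus_frequency <- function(important_sets) {
  ids <- names(important_sets)
  if (is.null(ids) || anyDuplicated(ids))
    stop("'important_sets' must be a named list with distinct training ids")
  genes <- sort(unique(unlist(important_sets, use.names = FALSE)))
  contrib <- lapply(genes, function(g)
    ids[vapply(important_sets, function(s) g %in% s, logical(1L))])
  out <- data.frame(
    gene_id = genes,
    frequency = vapply(contrib, length, integer(1L)),
    training_ids = vapply(contrib, paste, character(1L), collapse = ","),
    stringsAsFactors = FALSE)
  out <- out[order(-out$frequency, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_sets") <- length(important_sets)
  class(out) <- c("consensus_table", "data.frame")
  out
}

#' @export
print.consensus_table <- function(x, n = 20L, ...) {
  cat("Consensus gene table over ", attr(x, "n_sets"),
      " training individuals (", nrow(x), " genes)\n", sep = "")
  print.data.frame(utils::head(x, n), row.names = FALSE)
  if (nrow(x) > n) cat("... ", nrow(x) - n, " more\n", sep = "")
  invisible(x)
}

#' Write / read an IFS curve as TSV
#'
#' Columns `k`, `total_acc`, `acc_BS`, `acc_CB`, `acc_CC`, `correct`, `n`
#' preceded by a comment line recording the train/test individual ids.
#'
#' @param curve An `ifs_curve`.
#' @param path File path.
#' @return `write_ifs_curve` returns `path` invisibly; `read_ifs_curve`
#'   returns an `ifs_curve`.
#' @export
write_ifs_curve <- function(curve, path) {
  stopifnot(inherits(curve, "ifs_curve"))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("# train: %s\ttest: %s",
                     attr(curve, "train"), attr(curve, "test")), con)
  df <- as.data.frame(curve)
  if (is.null(df$correct)) { df$correct <- NA_integer_; df$n <- NA_integer_ }
  writeLines(paste(c("k", "total_acc", "acc_BS", "acc_CB", "acc_CC",
                     "correct", "n"), collapse = "\t"), con)
  writeLines(sprintf("%d\t%.12g\t%.12g\t%.12g\t%.12g\t%s\t%s",
                     df$k, df$total_acc, df$acc_BS, df$acc_CB, df$acc_CC,
                     ifelse(is.na(df$correct), "NA", df$correct),
                     ifelse(is.na(df$n), "NA", df$n)), con)
  invisible(path)
}

#' @rdname write_ifs_curve
#' @export
read_ifs_curve <- function(path) {
  first <- readLines(path, n = 1L)
  train <- test <- NA_character_
  skip <- 0L
  if (startsWith(first, "# train:")) {
    parts <- strsplit(sub("^# ", "", first), "\t")[[1L]]
    train <- trimws(sub("train:", "", parts[1L]))
    test <- trimws(sub("test:", "", parts[2L]))
    skip <- 1L
  }
  df <- .read_tsv(path, skip = skip)
  if (df$k[1L] != 1L || any(df$k != seq_len(nrow(df))))
    stop("curve k values must be exactly 1..N")
  attr(df, "train") <- train
  attr(df, "test") <- test
  class(df) <- c("ifs_curve", "data.frame")
  df
}
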