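#' @useDynLib regmarker, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm predict
#' @importFrom utils read.delim write.table
NULL

#' Admissible brain-region class labels
#'
#' The three sample classes used throughout the package: brain stem (BS),
#' cerebellum (CB) and cerebral cortex (CC). The label vocabulary is fixed;
#' configurable class sets are out of scope.
#'
#' @return Character vector `c("BS", "CB", "CC")`.
#' @export
region_labels <- function() c("BS", "CB", "CC")

#' Construct an expression dataset for one individual
#'
#' An `expr_dataset` holds one individual's genes-by-samples expression
#' matrix together with the brain-region label of every sample. It is the
#' unit on which feature ranking and classification operate: the study
#' design keeps each individual's samples together so that classifiers can
#' be trained on one person and tested on the others.
#'
#' @param individual_id Single character label for the individual.
#' @param values Numeric matrix, genes in rows, samples in columns, with
#'   unique rownames (gene ids) and colnames (sample ids). All values must
#'   be finite.
#' @param regions Character vector of per-sample region labels, one of
#'   `"BS"`, `"CB"`, `"CC"`, in column order of `values`.
#' @return An object of class `expr_dataset` with elements `individual_id`,
#'   `values` and `regions`.
#' @seealso [read_expression_dataset()], [summarize_cohort()]
#' @export
expression_dataset <- function(individual_id, values, regions) {
  stopifnot(is.character(individual_id), length(individual_id) == 1L)
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix (genes x samples)")
  gene_ids <- rownames(values)
  sample_ids <- colnames(values)
  if (is.null(gene_ids) || is.null(sample_ids))
    stop("'values' must carry gene ids as rownames and sample ids as colnames")
  if (anyDuplicated(gene_ids))
    stop("duplicate gene ids: ", paste(unique(gene_ids[duplicated(gene_ids)]),
                                       collapse = ", "))
  if (anyDuplicated(sample_ids))
    stop("duplicate sample ids: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  if (!all(is.finite(values)))
    stop("non-finite expression values in dataset '", individual_id, "'")
  regions <- as.character(regions)
  if (length(regions) != ncol(values))
    stop("length of 'regions' (", length(regions),
         ") does not match sample count (", ncol(values), ")")
  bad <- !regions %in% region_labels()
  if (any(bad))
    stop("unknown region label '", regions[which(bad)[1L]],
         "' for sample '", sample_ids[which(bad)[1L]], "'")
  structure(
    list(individual_id = individual_id, values = values, regions = regions),
    class = "expr_dataset"
  )
}

#' @export
print.expr_dataset <- function(x, ...) {
  cnt <- table(factor(x$regions, levels = region_labels()))
  cat("Expression dataset: individual ", x$individual_id, "\n",
      "  ", nrow(x$values), " genes x ", ncol(x$values), " samples",
      " (BS ", cnt[["BS"]], ", CB ", cnt[["CB"]], ", CC ", cnt[["CC"]], ")\n",
      sep = "")
  invisible(x)
}

#' @export
dim.expr_dataset <- function(x) dim(x$values)

# Shared TSV reading conventions: UTF-8, tab separators, '.' decimal, no
# quoting. Matrices are wide-and-short (many genes, few samples), genes in
# rows.
.read_tsv <- function(path, ...) {
  read.delim(path, sep = "\t", quote = "", check.names = FALSE,
             stringsAsFactors = FALSE, ...)
}

.write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE, fileEncoding = "UTF-8")
}

#' Read one individual's expression dataset from TSV files
#'
#' Reads an expression matrix (header row of sample ids, first column
#' `gene_id`) and a sample annotation table (columns `sample_id`,
#' `individual_id`, `region`) and assembles a validated [expression_dataset()]
#' for one individual. Columns are ordered as the annotation file lists the
#' individual's samples.
#'
#' @param matrix_path Path to the expression matrix TSV.
#' @param annotation_path Path to the annotation TSV.
#' @param individual_id Which individual's samples to extract.
#' @return An `expr_dataset`.
#' @details Samples present in the matrix but missing from the annotation
#'   (or vice versa) raise a consistency error; a non-numeric cell raises a
#'   parse error naming the gene row and sample column; a region label other
#'   than BS/CB/CC raises a format error naming the offending sample.
#' @export
read_expression_dataset <- function(matrix_path, annotation_path,
                                    individual_id) {
  ann <- .read_tsv(annotation_path)
  need <- c("sample_id", "individual_id", "region")
  if (!all(need %in% names(ann)))
    stop("annotation file must have columns ", paste(need, collapse = ", "))
  bad <- !ann$region %in% region_labels()
  if (any(bad))
    stop("unknown region label '", ann$region[which(bad)[1L]],
         "' for sample '", ann$sample_id[which(bad)[1L]], "'")
  ann <- ann[ann$individual_id == individual_id, , drop = FALSE]
  if (nrow(ann) == 0L)
    stop("no annotated samples for individual '", individual_id, "'")

  raw <- .read_tsv(matrix_path, colClasses = "character")
  if (names(raw)[1L] != "gene_id")
    stop("expression matrix must start with a 'gene_id' column")
  gene_ids <- raw[[1L]]
  mat_samples <- names(raw)[-1L]

  missing_in_matrix <- setdiff(ann$sample_id, mat_samples)
  if (length(missing_in_matrix))
    stop("annotated sample(s) missing from matrix: ",
         paste(missing_in_matrix, collapse = ", "))
  # samples of *this* individual found in the matrix but not annotated can
  # not be detected (the matrix may legitimately hold other individuals);
  # a matrix column annotated to this individual is checked above, and any
  # matrix column with no annotation row at all is a consistency error.
  all_ann <- .read_tsv(annotation_path)
  unannotated <- setdiff(mat_samples, all_ann$sample_id)
  if (length(unannotated))
    stop("matrix sample(s) missing from annotation: ",
         paste(unannotated, collapse = ", "))

  sub <- raw[, ann$sample_id, drop = FALSE]
  values <- matrix(NA_real_, nrow = nrow(sub), ncol = ncol(sub),
                   dimnames = list(gene_ids, ann$sample_id))
  for (j in seq_len(ncol(sub))) {
    v <- suppressWarnings(as.numeric(sub[[j]]))
    if (anyNA(v)) {
      i <- which(is.na(v))[1L]
      stop("non-numeric expression value '", sub[[j]][i], "' at gene '",
           gene_ids[i], "', sample '", ann$sample_id[j], "'")
    }
    values[, j] <- v
  }
  expression_dataset(individual_id, values, ann$region)
}

#' Write an expression dataset and its annotation to TSV files
#'
#' Inverse of [read_expression_dataset()]: emits the genes-by-samples matrix
#' with a `gene_id` first column, and an annotation table with columns
#' `sample_id`, `individual_id`, `region`.
#'
#' @param dataset An `expr_dataset`.
#' @param matrix_path,annotation_path Output file paths.
#' @return Invisibly, the two paths.
#' @export
write_expression_dataset <- function(dataset, matrix_path, annotation_path) {
  stopifnot(inherits(dataset, "expr_dataset"))
  df <- data.frame(gene_id = rownames(dataset$values),
                   dataset$values, check.names = FALSE,
                   stringsAsFactors = FALSE)
  .write_tsv(format(df, digits = 12, trim = TRUE, scientific = FALSE),
             matrix_path)
  ann <- data.frame(sample_id = colnames(dataset$values),
                    individual_id = dataset$individual_id,
                    region = dataset$regions, stringsAsFactors = FALSE)
  .write_tsv(ann, annotation_path)
  invisible(c(matrix_path, annotation_path))
}

#' Tally per-region sample counts across a cohort
#'
#' Counts BS/CB/CC samples per individual and the per-individual totals,
#' mirroring the standard cohort-description table of a multi-donor brain
#' expression study.
#'
#' @param datasets List of `expr_dataset` objects with distinct individual
#'   ids. An empty list yields an empty (zero-row) summary.
#' @return A `cohort_summary`: data frame with columns `individual_id`,
#'   `BS`, `CB`, `CC`, `total`.
#' @export
summarize_cohort <- function(datasets) {
  ids <- vapply(datasets, function(d) d$individual_id, character(1L))
  if (anyDuplicated(ids))
    stop("duplicate individual ids in cohort: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  rows <- lapply(datasets, function(d) {
    cnt <- table(factor(d$regions, levels = region_labels()))
    data.frame(individual_id = d$individual_id,
               BS = as.integer(cnt[["BS"]]), CB = as.integer(cnt[["CB"]]),
               CC = as.integer(cnt[["CC"]]),
               total = length(d$regions), stringsAsFactors = FALSE)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(individual_id = character(0), BS = integer(0), CB = integer(0),
               CC = integer(0), total = integer(0), stringsAsFactors = FALSE)
  class(out) <- c("cohort_summary", "data.frame")
  out
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat("Cohort summary (", nrow(x), " individual",
      if (nrow(x) != 1L) "s", ", ", sum(x$total), " samples)\n", sep = "")
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

#' Construct a ranked feature list
#'
#' A `feature_list` is an ordered gene ranking with scores, in one of two
#' flavors: `"MaxRel"` (genes sorted by mutual information with the region
#' label alone; scores non-increasing) or `"mRMR"` (greedy
#' minimum-redundancy maximum-relevance order; scores are the greedy
#' objective at selection time and need not be monotone). Its length-k
#' prefixes are the nested feature sets evaluated by incremental feature
#' selection.
#'
#' @param gene_ids Character vector of unique gene ids, in rank order.
#' @param scores Numeric scores, same length.
#' @param flavor `"MaxRel"` or `"mRMR"`.
#' @return A `feature_list`: data frame with columns `rank`, `gene_id`,
#'   `score` and attribute `flavor`.
#' @export
feature_list <- function(gene_ids, scores, flavor = c("mRMR", "MaxRel")) {
  flavor <- match.arg(flavor)
  gene_ids <- as.character(gene_ids)
  scores <- as.numeric(scores)
  stopifnot(length(gene_ids) == length(scores))
  if (anyDuplicated(gene_ids))
    stop("duplicate gene in feature list: ",
         paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "))
  if (length(scores) && anyNA(scores))
    stop("feature list scores must not be NA")
  if (flavor == "MaxRel" && length(scores) > 1L &&
      any(diff(scores) > 1e-12))
    stop("MaxRel scores must be non-increasing")
  out <- data.frame(rank = seq_along(gene_ids), gene_id = gene_ids,
                    score = scores, stringsAsFactors = FALSE)
  attr(out, "flavor") <- flavor
  class(out) <- c("feature_list", "data.frame")
  out
}

#' @export
print.feature_list <- function(x, n = 10L, ...) {
  cat(attr(x, "flavor"), " feature list, ", nrow(x), " entries\n", sep = "")
  print.data.frame(utils::head(x, n), row.names = FALSE)
  if (nrow(x) > n) cat("... ", nrow(x) - n, " more\n", sep = "")
  invisible(x)
}

#' Write / read a feature list as TSV
#'
#' The file has a `# flavor: <MaxRel|mRMR>` comment line followed by a
#' header `rank`, `gene_id`, `score`. Scores survive a round trip to 12
#' significant digits.
#'
#' @param x A `feature_list`.
#' @param path File path.
#' @return `write_feature_list` returns `path` invisibly;
#'   `read_feature_list` returns a `feature_list`.
#' @export
write_feature_list <- function(x, path) {
  stopifnot(inherits(x, "feature_list"))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste0("# flavor: ", attr(x, "flavor")), con)
  writeLines("rank\tgene_id\tscore", con)
  if (nrow(x))
    writeLines(sprintf("%d\t%s\t%.12g", x$rank, x$gene_id, x$score), con)
  invisible(path)
}

#' @rdname write_feature_list
#' @export
read_feature_list <- function(path) {
  first <- readLines(path, n = 1L)
  flavor <- "mRMR"
  skip <- 0L
  if (startsWith(first, "# flavor:")) {
    flavor <- trimws(sub("# flavor:", "", first, fixed = TRUE))
    skip <- 1L
  }
  df <- .read_tsv(path, skip = skip)
  if (!all(c("rank", "gene_id", "score") %in% names(df)))
    stop("feature list file must have columns rank, gene_id, score")
  if (nrow(df) && any(df$rank != seq_len(nrow(df))))
    stop("feature list ranks must be 1..N in order")
  feature_list(as.character(df$gene_id), df$score, flavor = flavor)
}
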