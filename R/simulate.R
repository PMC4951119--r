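#' Default per-individual region sample counts
#'
#' The six-donor cohort shape the generator emulates: per-individual
#' (BS, CB, CC) sample counts of a published six-individual brain
#' expression cohort, totalling 363, 529, 470, 501, 946 and 893 samples.
#'
#' @return Named list of length-3 integer vectors `c(BS, CB, CC)`.
#' @export
default_cohort_counts <- function() {
  list(
    "H0351.1009" = c(BS = 26L,  CB = 42L, CC = 295L),
    "H0351.1012" = c(BS = 80L,  CB = 48L, CC = 401L),
    "H0351.1015" = c(BS = 79L,  CB = 62L, CC = 329L),
    "H0351.1016" = c(BS = 59L,  CB = 80L, CC = 362L),
    "H0351.2001" = c(BS = 154L, CB = 53L, CC = 739L),
    "H0351.2002" = c(BS = 188L, CB = 83L, CC = 622L)
  )
}

#' Configuration for the synthetic cohort generator
#'
#' Describes a multi-individual expression cohort with a small set of
#' planted region-discriminative genes. Gene g has a baseline level
#' `mu_g ~ N(0, 1)` shared by all individuals; individual d adds a
#' gene-specific batch offset `b_dg ~ N(0, batch_sd^2)`; a sample from
#' region r adds `delta_gr = effect_size * noise_sd` when g is planted for
#' r (else 0) plus measurement noise `N(0, noise_sd^2)`. Planted genes are
#' shared across individuals unless `private_planting` is set, in which
#' case each individual receives its own planted sets.
#'
#' @param n_genes Number of gene features (default 2000, a test-scale
#'   stand-in for the ~20782 genes of a full microarray profile).
#' @param per_individual_counts Named list of `c(BS, CB, CC)` sample counts;
#'   default [default_cohort_counts()].
#' @param n_planted_per_region Planted genes per region (default 10).
#' @param effect_size Region mean shift of a planted gene, in units of the
#'   measurement-noise standard deviation (default 2).
#' @param batch_sd Standard deviation of the per-individual, per-gene batch
#'   offset (default 0.5).
#' @param noise_sd Measurement noise standard deviation (default 1).
#' @param seed Integer seed; fixed seed gives bit-identical cohorts.
#' @param private_planting If `TRUE`, plant individual-private gene sets
#'   instead of one shared set (default `FALSE`).
#' @return A validated list of class `cohort_config`.
#' @export
cohort_config <- function(n_genes = 2000L,
                          per_individual_counts = default_cohort_counts(),
                          n_planted_per_region = 10L,
                          effect_size = 2,
                          batch_sd = 0.5,
                          noise_sd = 1,
                          seed = 1L,
                          private_planting = FALSE) {
  n_genes <- as.integer(n_genes)
  n_planted_per_region <- as.integer(n_planted_per_region)
  stopifnot(length(n_genes) == 1L, n_genes >= 1L,
            length(n_planted_per_region) == 1L, n_planted_per_region >= 0L,
            is.numeric(effect_size), effect_size >= 0,
            is.numeric(batch_sd), batch_sd >= 0,
            is.numeric(noise_sd), noise_sd > 0,
            is.logical(private_planting))
  if (3L * n_planted_per_region > n_genes)
    stop("3 * n_planted_per_region must not exceed n_genes")
  if (!is.list(per_individual_counts) || is.null(names(per_individual_counts)))
    stop("'per_individual_counts' must be a named list of c(BS, CB, CC)")
  if (anyDuplicated(names(per_individual_counts)))
    stop("duplicate individual ids in 'per_individual_counts'")
  for (id in names(per_individual_counts)) {
    cnt <- per_individual_counts[[id]]
    if (length(cnt) != 3L || any(cnt < 0L))
      stop("counts for '", id, "' must be three non-negative integers")
    if (sum(cnt) == 0L)
      stop("individual '", id, "' has no samples")
    per_individual_counts[[id]] <- as.integer(cnt)
  }
  structure(
    list(n_genes = n_genes, per_individual_counts = per_individual_counts,
         n_planted_per_region = n_planted_per_region,
         effect_size = as.numeric(effect_size),
         batch_sd = as.numeric(batch_sd), noise_sd = as.numeric(noise_sd),
         seed = as.integer(seed), private_planting = private_planting),
    class = "cohort_config"
  )
}

# deterministic per-individual sub-seed so cohorts are identical no matter
# the order in which individuals are materialized
.individual_seed <- function(seed, idx) {
  as.integer((as.numeric(seed) + 104729 * idx) %% 2147483647)
}

#' Generate a synthetic multi-individual expression cohort
#'
#' Draws a cohort under the Gaussian planted-shift model of
#' [cohort_config()] and returns both the per-individual datasets and the
#' ground truth of which genes were planted for which region.
#'
#' @param config A `cohort_config`.
#' @return A list with elements:
#'   \describe{
#'     \item{datasets}{named list of [expression_dataset()] objects, one per
#'       individual, samples grouped BS then CB then CC;}
#'     \item{truth}{data frame `gene_id`, `region`, `delta` (and
#'       `individual_id` under private planting) listing the planted genes
#'       and their mean shifts.}
#'   }
#' @examples
#' cohort <- generate_cohort(cohort_config(n_genes = 100, seed = 7,
#'   per_individual_counts = list(A = c(5, 5, 5), B = c(4, 6, 8))))
#' summarize_cohort(cohort$datasets)
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "cohort_config"))
    config <- do.call(cohort_config, config)
  G <- config$n_genes
  gene_ids <- sprintf("g%05d", seq_len(G))
  ids <- names(config$per_individual_counts)
  delta <- config$effect_size * config$noise_sd

  plant_regions <- function() {
    idx <- sample.int(G, 3L * config$n_planted_per_region)
    split(gene_ids[idx], rep(region_labels(),
                             each = config$n_planted_per_region))[region_labels()]
  }

  set.seed(config$seed)
  mu <- rnorm(G)
  names(mu) <- gene_ids
  shared_planted <- if (config$n_planted_per_region > 0L && !config$private_planting)
    plant_regions() else NULL
  private_planted <- if (config$n_planted_per_region > 0L && config$private_planting)
    lapply(ids, function(i) plant_regions()) else NULL
  if (!is.null(private_planted)) names(private_planted) <- ids

  datasets <- vector("list", length(ids))
  names(datasets) <- ids
  for (i in seq_along(ids)) {
    id <- ids[i]
    cnt <- config$per_individual_counts[[id]]
    S <- sum(cnt)
    regions <- rep(region_labels(), times = cnt)
    set.seed(.individual_seed(config$seed, i))
    b <- rnorm(G, 0, config$batch_sd)
    eps <- matrix(rnorm(G * S, 0, config$noise_sd), nrow = G)
    values <- mu + b + eps   # recycles down columns: per-gene constants
    planted <- if (!is.null(private_planted)) private_planted[[id]] else shared_planted
    if (!is.null(planted)) {
      for (r in region_labels()) {
        gi <- match(planted[[r]], gene_ids)
        values[gi, regions == r] <- values[gi, regions == r] + delta
      }
    }
    dimnames(values) <- list(gene_ids,
                             sprintf("%s_s%04d", id, seq_len(S)))
    datasets[[i]] <- expression_dataset(id, values, regions)
  }

  truth <- if (config$n_planted_per_region == 0L) {
    data.frame(gene_id = character(0), region = character(0),
               delta = numeric(0), stringsAsFactors = FALSE)
  } else if (!config$private_planting) {
    data.frame(gene_id = unlist(shared_planted, use.names = FALSE),
               region = rep(region_labels(),
                            each = config$n_planted_per_region),
               delta = delta, stringsAsFactors = FALSE)
  } else {
    do.call(rbind, lapply(ids, function(id) {
      data.frame(individual_id = id,
                 gene_id = unlist(private_planted[[id]], use.names = FALSE),
                 region = rep(region_labels(),
                              each = config$n_planted_per_region),
                 delta = delta, stringsAsFactors = FALSE)
    }))
  }
  list(datasets = datasets, truth = truth)
}

#' Wrap a vector of accuracies as an IFS curve
#'
#' Test/plotting helper: turns a plain accuracy vector into an `ifs_curve`
#' with feature counts k = 1..length and per-class accuracies set equal to
#' the total.
#'
#' @param accuracies Non-empty numeric vector with values in `[0, 1]`.
#' @param train,test Individual ids recorded on the curve (defaults
#'   `"fixture"`).
#' @return An `ifs_curve` data frame.
#' @export
make_curve_fixture <- function(accuracies, train = "fixture",
                               test = "fixture") {
  if (length(accuracies) == 0L)
    stop("'accuracies' must be non-empty")
  if (!is.numeric(accuracies) || anyNA(accuracies) ||
      any(accuracies < 0 | accuracies > 1))
    stop("'accuracies' must lie in [0, 1]")
  out <- data.frame(k = seq_along(accuracies),
                    total_acc = as.numeric(accuracies),
                    acc_BS = as.numeric(accuracies),
                    acc_CB = as.numeric(accuracies),
                    acc_CC = as.numeric(accuracies))
  attr(out, "train") <- train
  attr(out, "test") <- test
  class(out) <- c("ifs_curve", "data.frame")
  out
}
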