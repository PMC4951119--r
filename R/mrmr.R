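#' Discretize expression values into three states
#'
#' Maps each gene's continuous intensities to states -1/0/+1 around its own
#' mean: -1 below `mean - threshold*sd`, +1 above `mean + threshold*sd`,
#' 0 otherwise. Mean and (sample) standard deviation are computed on this
#' dataset only; a constant gene (sd = 0, or a single sample) maps to all
#' zeros. This three-state coding is the standard companion of
#' mutual-information feature ranking for microarray intensities.
#'
#' @param dataset An [expression_dataset()].
#' @param threshold Positive threshold in units of per-gene sd (default 1).
#' @return A `disc_dataset`: list with `states` (genes x samples integer
#'   matrix in \{-1, 0, 1\}), `regions`, `individual_id`, and `thresholds`
#'   (per-gene mean and sd used).
#' @export
discretize_expression <- function(dataset, threshold = 1) {
  stopifnot(inherits(dataset, "expr_dataset"),
            is.numeric(threshold), length(threshold) == 1L, threshold > 0)
  v <- dataset$values
  S <- ncol(v)
  m <- rowMeans(v)
  s <- if (S > 1L) sqrt(rowSums((v - m)^2) / (S - 1L)) else rep(0, nrow(v))
  lo <- m - threshold * s
  hi <- m + threshold * s
  states <- matrix(0L, nrow(v), ncol(v), dimnames = dimnames(v))
  states[v < lo] <- -1L
  states[v > hi] <- 1L
  structure(
    list(individual_id = dataset$individual_id, states = states,
         regions = dataset$regions,
         thresholds = data.frame(gene_id = rownames(v), mean = m, sd = s,
                                 row.names = NULL, stringsAsFactors = FALSE)),
    class = "disc_dataset"
  )
}

#' Plug-in mutual information of two discrete vectors
#'
#' Empirical mutual information in bits from the joint contingency table:
#' `I = sum p(a,b) log2( p(a,b) / (p(a) p(b)) )`, with `0 * log` terms taken
#' as 0. Non-negative up to floating-point rounding; `I(x, x)` equals the
#' plug-in entropy of `x`.
#'
#' @param x,y Vectors of equal length (any discrete values).
#' @return Mutual information estimate in bits.
#' @export
mutual_information <- function(x, y) {
  if (length(x) != length(y))
    stop("'x' and 'y' must have equal length")
  if (length(x) == 0L)
    stop("'x' and 'y' must be non-empty")
  tab <- table(x, y)
  n <- sum(tab)
  pxy <- tab / n
  px <- rowSums(pxy)
  py <- colSums(pxy)
  nz <- pxy > 0
  sum(pxy[nz] * log2(pxy[nz] / outer(px, py)[nz]))
}

# Vectorized per-row mutual information (bits) between each row of an
# integer state matrix (values in {-1,0,1}) and one discrete vector y.
# This is the workhorse of the rankings: 9 masked row-sums instead of G
# contingency tables.
.mi_rows <- function(states, y) {
  G <- nrow(states)
  S <- ncol(states)
  ylev <- sort(unique(y))
  L <- length(ylev)
  cnt <- matrix(0, G, 3L * L)
  for (ai in 1:3) {
    Sa <- states == c(-1L, 0L, 1L)[ai]
    for (bi in seq_len(L)) {
      cnt[, (ai - 1L) * L + bi] <- rowSums(Sa[, y == ylev[bi], drop = FALSE])
    }
  }
  pxy <- cnt / S
  # px: G x 3 (sum over y states); py: length L, same for all genes
  px <- sapply(1:3, function(ai)
    rowSums(pxy[, (ai - 1L) * L + seq_len(L), drop = FALSE]))
  px <- matrix(px, nrow = G)
  py <- vapply(ylev, function(b) mean(y == b), numeric(1))
  denom <- px[, rep(1:3, each = L), drop = FALSE] *
    rep(py, times = 3)[col(pxy)]
  term <- pxy * log2(pxy / denom)
  term[pxy == 0] <- 0
  rowSums(term)
}

.check_ranking_args <- function(data, n_features) {
  stopifnot(inherits(data, "disc_dataset"))
  n_features <- as.integer(n_features)
  if (length(n_features) != 1L || n_features < 1L ||
      n_features > nrow(data$states))
    stop("'n_features' must be in 1..G (G = ", nrow(data$states), ")")
  if (length(unique(data$regions)) < 2L)
    warning("all samples share one region label; every relevance is 0")
  n_features
}

#' Rank genes by relevance alone (MaxRel list)
#'
#' Sorts genes by the mutual information between their discretized states
#' and the region label, descending; ties are broken by ascending gene id
#' so lists are reproducible across platforms.
#'
#' @param data A `disc_dataset` from [discretize_expression()].
#' @param n_features How many top genes to keep (default 500).
#' @return A [feature_list()] of flavor `"MaxRel"` whose scores are the
#'   relevance values in bits.
#' @export
maxrel_ranking <- function(data, n_features = 500L) {
  n_features <- .check_ranking_args(data, n_features)
  rel <- .mi_rows(data$states, data$regions)
  ids <- rownames(data$states)
  ord <- order(-rel, ids)
  keep <- ord[seq_len(n_features)]
  feature_list(ids[keep], rel[keep], flavor = "MaxRel")
}

#' Greedy minimum-redundancy maximum-relevance ranking (mRMR list)
#'
#' The first gene maximizes relevance `I(g; class)`. Thereafter, with
#' selected set `S`, the next gene maximizes
#' `I(g; class) - mean_{s in S} I(g; s)` (difference criterion) or
#' `I(g; class) / max(mean_s I(g; s), eps)` (quotient criterion). Ties are
#' broken by ascending gene id. The first entry always coincides with the
#' MaxRel rank-1 gene.
#'
#' @inheritParams maxrel_ranking
#' @param criterion `"difference"` (default) or `"quotient"`.
#' @return A [feature_list()] of flavor `"mRMR"` whose scores are the greedy
#'   objective values at selection time.
#' @export
mrmr_ranking <- function(data, n_features = 500L,
                         criterion = c("difference", "quotient")) {
  criterion <- match.arg(criterion)
  n_features <- .check_ranking_args(data, n_features)
  states <- data$states
  ids <- rownames(states)
  G <- nrow(states)
  rel <- .mi_rows(states, data$regions)

  selected <- integer(n_features)
  sel_score <- numeric(n_features)
  red_sum <- numeric(G)            # sum of MI with already-selected genes
  active <- rep(TRUE, G)
  eps <- 1e-12
  for (t in seq_len(n_features)) {
    score <- if (t == 1L) rel else if (criterion == "difference")
      rel - red_sum / (t - 1L)
    else
      rel / pmax(red_sum / (t - 1L), eps)
    score[!active] <- -Inf
    cand <- which(active)
    best <- cand[order(-score[cand], ids[cand])[1L]]
    selected[t] <- best
    sel_score[t] <- score[best]
    active[best] <- FALSE
    if (t < n_features)
      red_sum <- red_sum + .mi_rows(states, states[best, ])
  }
  feature_list(ids[selected], sel_score, flavor = "mRMR")
}
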