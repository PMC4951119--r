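# Independent oracles used to cross-check the implementation. Each one
# deliberately takes a different computational route than the package code.

# mutual information via the entropy identity I = H(X) + H(Y) - H(X,Y)
# (the package computes the joint-table sum directly)
oracle_mi <- function(x, y) {
  H <- function(v) {
    p <- as.numeric(table(v)) / length(v)
    -sum(p * log2(p))
  }
  H(x) + H(y) - H(paste(x, y, sep = "\r"))
}

# exhaustive per-step greedy mRMR using oracle_mi pairwise
oracle_mrmr <- function(states, regions, n, criterion = "difference") {
  ids <- rownames(states)
  G <- nrow(states)
  rel <- vapply(seq_len(G), function(i) oracle_mi(states[i, ], regions),
                numeric(1))
  sel <- integer(0)
  for (t in seq_len(n)) {
    cand <- setdiff(seq_len(G), sel)
    sc <- vapply(cand, function(i) {
      if (!length(sel)) return(rel[i])
      red <- mean(vapply(sel, function(j) oracle_mi(states[i, ], states[j, ]),
                         numeric(1)))
      if (criterion == "difference") rel[i] - red
      else rel[i] / max(red, 1e-12)
    }, numeric(1))
    sel <- c(sel, cand[order(-sc, ids[cand])[1L]])
  }
  ids[sel]
}

# population-sd standardization matching the SVM's internal contract
std_pop <- function(X) {
  ctr <- colMeans(X)
  scl <- sqrt(colMeans(sweep(X, 2L, ctr)^2))
  scl[scl == 0] <- 1
  sweep(sweep(X, 2L, ctr), 2L, scl, "/")
}

dual_objective <- function(alpha, X, y) {
  ay <- alpha * y
  sum(alpha) - 0.5 * drop(crossprod(ay, (X %*% t(X)) %*% ay))
}

# projection of v onto {0 <= a <= C, sum(a * y) = 0} via bisection on the
# hyperplane multiplier (y entries are +-1, so the constraint residual is
# monotone in the multiplier)
.project_box_hyperplane <- function(v, y, C) {
  g <- function(t) sum(pmin(pmax(v - t * y, 0), C) * y)
  lo <- -(max(abs(v)) + C + 1)
  hi <- -lo
  for (it in 1:100) {
    mid <- (lo + hi) / 2
    if (g(mid) > 0) lo <- mid else hi <- mid
  }
  pmin(pmax(v - ((lo + hi) / 2) * y, 0), C)
}

# accelerated projected-gradient solve of the C-SVM dual: an entirely
# different generic-QP route than the decomposition under test
oracle_qp_pg <- function(K, y, C, iters = 20000L) {
  n <- length(y)
  Q <- outer(y, y) * K
  L <- max(abs(eigen(Q, symmetric = TRUE, only.values = TRUE)$values), 1e-8)
  obj <- function(a) sum(a) - 0.5 * drop(crossprod(a, Q %*% a))
  a <- rep(0, n); z <- a; tk <- 1
  best <- a; best_obj <- 0
  for (it in seq_len(iters)) {
    grad <- 1 - drop(Q %*% z)
    a_new <- .project_box_hyperplane(z + grad / L, y, C)
    t_new <- (1 + sqrt(1 + 4 * tk^2)) / 2
    z <- a_new + ((tk - 1) / t_new) * (a_new - a)
    a <- a_new; tk <- t_new
    if (it %% 100L == 0L) {
      o <- obj(a)
      if (o > best_obj) { best_obj <- o; best <- a }
    }
  }
  if (obj(a) > best_obj) best <- a
  best
}

# generic QP solve of the C-SVM dual: kernlab's interior-point solver when
# its factorization tolerates the (often rank-deficient) Hessian, the
# projected-gradient solver otherwise
oracle_svm_dual <- function(X, y, C) {
  n <- nrow(X)
  K <- X %*% t(X)
  alpha <- NULL
  for (ridge in c(1e-8, 1e-6)) {
    sol <- tryCatch(
      kernlab::ipop(c = matrix(-1, n), H = outer(y, y) * K + diag(ridge, n),
                    A = matrix(y, 1L), b = 0, l = matrix(0, n),
                    u = matrix(C, n), r = 0, sigf = 9, maxiter = 200),
      error = function(e) NULL)
    if (!is.null(sol)) { alpha <- as.numeric(kernlab::primal(sol)); break }
  }
  if (is.null(alpha)) alpha <- oracle_qp_pg(K, y, C)
  list(alpha = alpha, objective = dual_objective(alpha, X, y))
}

# KKT conditions of the dual at tolerance tol, bounds at eps
kkt_satisfied <- function(alpha, y, f, C, tol, eps = 1e-8) {
  r <- (f - y) * y                       # y*f - 1
  at0 <- alpha <= eps
  atC <- alpha >= C - eps
  interior <- !at0 & !atC
  all(r[at0] >= -tol - 1e-9) &&
    all(r[atC] <= tol + 1e-9) &&
    all(abs(r[interior]) <= tol + 1e-9)
}

# literal scan of the verbal inflection definition
oracle_inflection <- function(acc, k_min, k_max) {
  for (k in k_min:k_max)
    if (acc[k] >= acc[k - 1L] && acc[k] > acc[k + 1L])
      return(list(k = k, fallback = FALSE))
  rng <- k_min:k_max
  list(k = rng[which.max(acc[rng])], fallback = TRUE)
}

# random separable/overlapping binary problems for SMO property tests
random_binary_problem <- function(seed, n = NULL, p = NULL, sep = NULL) {
  set.seed(seed)
  if (is.null(n)) n <- sample(6:30, 1L)
  if (is.null(p)) p <- sample(1:5, 1L)
  if (is.null(sep)) sep <- runif(1, 0, 3)
  n1 <- sample(2:(n - 2L), 1L)
  y <- c(rep(1, n1), rep(-1, n - n1))
  X <- matrix(rnorm(n * p), n, p)
  X[y == 1, 1L] <- X[y == 1, 1L] + sep
  list(X = X, y = y)
}
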