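test_that("the symmetric two-point problem has its closed-form solution", {
  m <- smo_fit(matrix(c(-1, 1), ncol = 1L), c(-1, 1), C = 100)
  expect_equal(m$alpha, c(0.5, 0.5), tolerance = 1e-6)
  expect_equal(m$b, 0, tolerance = 1e-9)
  # decision function is the identity on the original scale
  grid <- matrix(c(-2, -1, 0, 1, 2), ncol = 1L)
  expect_equal(predict(m, grid, type = "decision"), c(-2, -1, 0, 1, 2),
               tolerance = 1e-6)
  # training margins are +-1; the zero decision maps to the first label
  expect_equal(predict(m, matrix(0), type = "class"), "+1")
})

test_that("input validation rejects degenerate training problems", {
  X <- matrix(rnorm(10), 5L, 2L)
  expect_error(smo_fit(X, rep(1, 5L)), "single class")
  expect_error(smo_fit(X, c(1, 2, 1, -1, -1)), "-1 and \\+1")
  X[2L, 1L] <- NA
  expect_error(smo_fit(X, c(1, 1, -1, -1, -1)), "finite")
  m <- smo_fit(matrix(rnorm(8), 4L, 2L), c(1, 1, -1, -1))
  expect_error(predict(m, matrix(rnorm(3), 1L, 3L)), "features")
})

test_that("dual objective matches the generic QP oracle on small problems", {
  skip_if_not_installed("kernlab")
  for (seed in 1:50) {
    prob <- random_binary_problem(seed)
    C <- c(0.01, 0.1, 1, 10)[1L + seed %% 4L]
    m <- smo_fit(prob$X, prob$y, C = C, tol = 1e-4)
    Xs <- std_pop(prob$X)
    obj_smo <- dual_objective(m$alpha, Xs, prob$y)
    qp <- oracle_svm_dual(Xs, prob$y, C)
    # SMO must reach the QP optimum to 1e-4 relative
    expect_equal(obj_smo, qp$objective,
                 tolerance = 1e-4 * max(1, abs(qp$objective)),
                 info = paste("seed", seed))
    # feasibility: box and equality constraints
    expect_true(all(m$alpha >= -1e-10 & m$alpha <= C + 1e-10))
    expect_lt(abs(sum(m$alpha * prob$y)), 1e-8)
    # KKT at the training tolerance
    f <- predict(m, prob$X, type = "decision")
    expect_true(kkt_satisfied(m$alpha, prob$y, f, C, 1e-4),
                info = paste("KKT seed", seed))
  }
})

test_that("hard overlap with tiny C keeps every alpha in its box", {
  set.seed(77)
  X <- matrix(rnorm(40), 20L, 2L)     # pure noise: heavily overlapping
  y <- rep(c(1, -1), 10L)
  m <- smo_fit(X, y, C = 0.01, tol = 1e-4)
  eps <- 1e-8
  at_bound <- m$alpha < eps | m$alpha > 0.01 - eps
  f <- predict(m, X, type = "decision")
  expect_true(kkt_satisfied(m$alpha, y, f, 0.01, 1e-4))
  expect_true(all(m$alpha >= -1e-12 & m$alpha <= 0.01 + 1e-12))
  # interior alphas must sit on the margin
  r <- (f - y) * y
  expect_true(all(abs(r[!at_bound]) <= 1e-4 + 1e-9))
})

test_that("predictions agree with the QP-oracle model off the margin", {
  skip_if_not_installed("kernlab")
  set.seed(88)
  prob <- random_binary_problem(88, n = 24L, p = 2L, sep = 2)
  m <- smo_fit(prob$X, prob$y, C = 1, tol = 1e-5)
  Xs <- std_pop(prob$X)
  qp <- oracle_svm_dual(Xs, prob$y, 1)
  # oracle bias from an interior support vector
  interior <- which(qp$alpha > 1e-4 & qp$alpha < 1 - 1e-4)
  K <- Xs %*% t(Xs)
  b_qp <- mean(prob$y[interior] - (K %*% (qp$alpha * prob$y))[interior])
  grid <- matrix(rnorm(100), 50L, 2L)
  gs <- sweep(sweep(grid, 2L, colMeans(prob$X)), 2L,
              sqrt(colMeans(sweep(prob$X, 2L, colMeans(prob$X))^2)), "/")
  f_qp <- drop(gs %*% crossprod(Xs, qp$alpha * prob$y)) + b_qp
  f_smo <- predict(m, grid, type = "decision")
  off <- abs(f_qp) > 1e-2
  expect_true(all(sign(f_smo[off]) == sign(f_qp[off])))
})

test_that("predictions are invariant to affine rescaling of a feature", {
  set.seed(99)
  prob <- random_binary_problem(99, n = 26L, p = 3L, sep = 1.5)
  m1 <- smo_fit(prob$X, prob$y, C = 1)
  X2 <- prob$X
  X2[, 2L] <- 1000 * X2[, 2L] - 37
  m2 <- smo_fit(X2, prob$y, C = 1)
  grid <- matrix(rnorm(60), 20L, 3L)
  grid2 <- grid
  grid2[, 2L] <- 1000 * grid2[, 2L] - 37
  # decision values agree up to the KKT stopping tolerance; labels agree
  # everywhere the decision is not hair-thin
  f1 <- predict(m1, grid, type = "decision")
  f2 <- predict(m2, grid2, type = "decision")
  expect_equal(f1, f2, tolerance = 0.02)
  off <- abs(f1) > 1e-2
  expect_equal(sign(f1[off]), sign(f2[off]))
  # constant features pass through without rescaling and change nothing
  X3 <- cbind(prob$X, 5)
  m3 <- smo_fit(X3, prob$y, C = 1)
  expect_equal(predict(m3, cbind(grid, 5), type = "decision"),
               predict(m1, grid, type = "decision"), tolerance = 1e-6)
})

test_that("three separable blobs are classified perfectly one-vs-one", {
  set.seed(111)
  centers <- rbind(BS = c(0, 8), CB = c(8, 0), CC = c(-8, -4))
  y <- rep(c("BS", "CB", "CC"), each = 15L)
  X <- centers[y, ] + matrix(rnorm(90, sd = 0.4), 45L, 2L)
  m <- smo_multiclass(X, y)
  expect_equal(predict(m, X), y)
  # deep inside a blob: two of three pairwise votes
  far <- matrix(c(0, 8), 1L, 2L)
  expect_equal(predict(m, far), "BS")
  expect_equal(predict(m, X[0L, , drop = FALSE]), character(0))
})

test_that("an absent class degrades gracefully to two-class behaviour", {
  set.seed(121)
  y <- rep(c("BS", "CC"), each = 10L)
  X <- matrix(rnorm(40), 20L, 2L)
  X[y == "BS", 1L] <- X[y == "BS", 1L] + 5
  m <- smo_multiclass(X, y)
  expect_s3_class(m$models[["BS|CB"]], "smo_constant")
  expect_s3_class(m$models[["CB|CC"]], "smo_constant")
  expect_true(all(predict(m, X) %in% c("BS", "CC")))
  expect_equal(predict(m, X), ifelse(X[, 1L] > 2.5, "BS", "CC"))
  expect_error(smo_multiclass(X, rep("BS", 20L)), "single class")
  expect_error(smo_multiclass(X, rep(c("BS", "XX"), 10L)), "labels")
})

test_that("a rock-paper-scissors vote resolves by the margin-sum rule", {
  # synthesize a model whose three members vote for three different
  # classes, then check the hand-computed winner
  cp <- function(p, w, b, nf = 1L) structure(
    list(class_pair = p, alpha = numeric(0), y = numeric(0), b = b,
         w = w, center = 0, scale = 1, C = 1, tol = 1e-3,
         objective = 0, steps = 0, converged = TRUE, n_features = nf),
    class = "smo_binary")
  model <- structure(list(models = list(
    "BS|CB" = cp(c("BS", "CB"), w = 1, b = 0),      # x>0 -> BS, margin |x|
    "BS|CC" = cp(c("BS", "CC"), w = -1, b = 0),     # x>0 -> CC, margin |x|
    "CB|CC" = cp(c("CB", "CC"), w = 0, b = 0.3)     # always CB, margin 0.3
  ), C = 1, tol = 1e-3, n_features = 1L), class = "smo_model")
  # at x = 1: votes BS (margin 1), CC (margin 1), CB (margin 0.3) -> BS/CC
  # tie on votes is broken by margin sum (1 vs 1), then label order -> BS
  expect_equal(predict(model, matrix(1)), "BS")
  # at x = 0.1 margins: BS 0.1, CC 0.1, CB 0.3 -> CB wins on margin sum
  expect_equal(predict(model, matrix(0.1)), "CB")
})

test_that("accuracy scoring tallies totals and per-class fractions", {
  perfect <- score_predictions(c("BS", "CB", "CC"), c("BS", "CB", "CC"))
  expect_equal(perfect$total, 1)
  expect_equal(unname(perfect$per_class), c(1, 1, 1))
  allcc <- score_predictions(c("BS", "CB", "CC", "CC"), rep("CC", 4L))
  expect_equal(allcc$total, 0.5)
  expect_equal(unname(allcc$per_class), c(0, 0, 1))
  # absent class reported as NA, counts exposed for exact comparisons
  two <- score_predictions(c("BS", "CC"), c("BS", "BS"))
  expect_true(is.na(two$per_class[["CB"]]))
  expect_equal(two$correct, 1L)
  expect_equal(two$n, 2L)
  expect_error(score_predictions("BS", c("BS", "CB")), "equal length")
  # random fixture vs direct tally
  set.seed(131)
  tr <- sample(c("BS", "CB", "CC"), 60L, replace = TRUE)
  pr <- sample(c("BS", "CB", "CC"), 60L, replace = TRUE)
  sc <- score_predictions(tr, pr)
  expect_equal(sc$total, sum(tr == pr) / 60)
  expect_equal(sc$per_class[["CB"]],
               sum(tr == "CB" & pr == "CB") / sum(tr == "CB"))
})

test_that("multiclass on a planted cohort beats the majority baseline
           across individuals", {
  cohort <- generate_cohort(small_cohort_config(seed = 61L, effect = 2))
  train <- cohort$datasets$A
  test <- cohort$datasets$B
  disc <- discretize_expression(train)
  genes <- mrmr_ranking(disc, 20L)$gene_id
  m <- smo_multiclass(t(train$values[genes, ]), train$regions)
  acc <- score_predictions(test$regions,
                           predict(m, t(test$values[genes, ])))$total
  baseline <- max(table(test$regions)) / ncol(test$values)
  expect_gt(acc, baseline)
})

test_that("SMO models survive TSV serialization with identical predictions", {
  set.seed(141)
  prob <- random_binary_problem(141, n = 20L, p = 3L, sep = 1)
  m <- smo_fit(prob$X, prob$y, C = 1)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_smo_model(m, path)
  back <- read_smo_model(path)
  grid <- matrix(rnorm(30), 10L, 3L)
  expect_identical(predict(back, grid, type = "decision"),
                   predict(m, grid, type = "decision"))
  expect_identical(back$alpha, m$alpha)

  y3 <- rep(c("BS", "CB", "CC"), each = 8L)
  X3 <- matrix(rnorm(48), 24L, 2L) + cbind(c(3, 0, -3)[as.integer(factor(y3))], 0)
  mm <- smo_multiclass(X3, y3)
  write_smo_model(mm, path)
  back3 <- read_smo_model(path)
  grid3 <- matrix(rnorm(40), 20L, 2L)
  expect_identical(predict(back3, grid3), predict(mm, grid3))
})
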