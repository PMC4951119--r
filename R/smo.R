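#' Train a binary linear soft-margin SVM by sequential minimal optimization
#'
#' Solves the C-SVM dual `max sum(alpha) - 1/2 alpha' (yy' .* K) alpha`
#' subject to `0 <= alpha_i <= C` and `sum(alpha_i y_i) = 0` with a linear
#' kernel, using the SMO decomposition: the smallest possible working set of
#' two dual variables is optimized analytically per step until no
#' Karush-Kuhn-Tucker violator beyond `tol` remains. Features are
#' standardized internally with the training mean and population standard
#' deviation; constant features pass through unscaled.
#'
#' @param x Numeric matrix, samples in rows, features in columns.
#' @param y Labels: either numeric -1/+1, or a character/factor with
#'   exactly two levels, the first of `class_pair` mapping to +1.
#' @param C Regularization constant (default 1, the common toolkit default).
#' @param tol KKT violation tolerance (default 1e-3).
#' @param class_pair Optional length-2 character vector naming the classes
#'   (first label corresponds to +1 and wins zero-valued decisions). Derived
#'   from `y` when omitted.
#' @param max_steps Safety cap on two-variable updates (default 1e7).
#' @return An object of class `smo_binary` with dual coefficients `alpha`,
#'   bias `b`, primal weight vector `w` (standardized coordinates),
#'   standardization vectors `center`/`scale`, the achieved dual
#'   `objective`, and bookkeeping fields.
#' @examples
#' m <- smo_fit(matrix(c(-1, 1), ncol = 1), c(-1, 1), C = 100)
#' m$alpha          # 0.5 0.5
#' predict(m, matrix(c(-2, 0, 2), ncol = 1), type = "decision")
#' @export
smo_fit <- function(x, y, C = 1, tol = 1e-3, class_pair = NULL,
                    max_steps = 1e7) {
  x <- as.matrix(x)
  if (!is.numeric(x) || !all(is.finite(x)))
    stop("'x' must be a finite numeric matrix")
  stopifnot(is.numeric(C), C > 0, is.numeric(tol), tol > 0)
  if (is.numeric(y)) {
    if (!all(y %in% c(-1, 1)))
      stop("numeric 'y' must contain only -1 and +1")
    if (is.null(class_pair)) class_pair <- c("+1", "-1")
    ynum <- as.numeric(y)
  } else {
    y <- as.character(y)
    if (is.null(class_pair)) class_pair <- sort(unique(y))
    if (length(class_pair) != 2L || !all(y %in% class_pair))
      stop("'y' must take exactly the two values of 'class_pair'")
    ynum <- ifelse(y == class_pair[1L], 1, -1)
  }
  if (length(ynum) != nrow(x))
    stop("length(y) must equal nrow(x)")
  if (length(unique(ynum)) < 2L)
    stop("training data contain a single class")

  center <- colMeans(x)
  scale <- sqrt(colMeans(sweep(x, 2L, center)^2))  # population sd
  scale[scale == 0] <- 1                            # constant features
  xs <- sweep(sweep(x, 2L, center), 2L, scale, "/")

  fit <- .smo_train_cpp(xs, ynum, C, tol, max_steps)
  if (!fit$converged)
    warning("SMO hit the step cap before clearing all KKT violations")
  alpha <- drop(fit$alpha)
  structure(
    list(class_pair = class_pair, alpha = alpha, y = ynum, b = fit$b,
         w = drop(crossprod(xs, alpha * ynum)), center = center,
         scale = scale, C = C, tol = tol, objective = fit$objective,
         steps = fit$steps, converged = fit$converged,
         n_features = ncol(x)),
    class = "smo_binary"
  )
}

#' @export
print.smo_binary <- function(x, ...) {
  nb <- sum(x$alpha > 1e-8)
  cat("Binary SMO-trained linear SVM: ", x$class_pair[1L], " (+1) vs ",
      x$class_pair[2L], " (-1)\n  ", length(x$alpha), " training samples, ",
      x$n_features, " features, C = ", x$C, ", ", nb,
      " support vectors\n", sep = "")
  invisible(x)
}

#' Predict with a binary SMO model
#'
#' Decision values are `f(x) = <w, standardized x> + b`; the predicted label
#' is the first element of `class_pair` when `f >= 0` (a zero decision value
#' maps to the pair's first label), the second otherwise.
#'
#' @param object An `smo_binary` model.
#' @param newdata Numeric matrix with the training feature count.
#' @param type `"class"` (default) or `"decision"`.
#' @param ... Unused.
#' @return Character labels or numeric decision values.
#' @export
predict.smo_binary <- function(object, newdata,
                               type = c("class", "decision"), ...) {
  type <- match.arg(type)
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != object$n_features)
    stop("newdata has ", ncol(newdata), " features; model expects ",
         object$n_features)
  xs <- sweep(sweep(newdata, 2L, object$center), 2L, object$scale, "/")
  f <- drop(xs %*% object$w) + object$b
  if (type == "decision") return(f)
  ifelse(f >= 0, object$class_pair[1L], object$class_pair[2L])
}

# degenerate one-vs-one member used when a class pair has no samples of one
# class in the training data: always predicts the present class
.smo_constant <- function(class_pair, present, n_features) {
  structure(list(class_pair = class_pair, present = present,
                 n_features = n_features),
            class = "smo_constant")
}

#' @export
predict.smo_constant <- function(object, newdata,
                                 type = c("class", "decision"), ...) {
  type <- match.arg(type)
  n <- nrow(as.matrix(newdata))
  if (type == "class") return(rep(object$present, n))
  rep(if (object$present == object$class_pair[1L]) 1 else -1, n)
}

#' Train the three-region one-vs-one SVM
#'
#' Fits one binary SMO model per unordered pair of region classes
#' (BS|CB, BS|CC, CB|CC), each on the samples of that pair only. A pair
#' with an absent class becomes a constant predictor for the present class;
#' with only two classes in `y`, the multiclass model therefore reduces to
#' the single informative binary model.
#'
#' @param x Numeric matrix, samples x features.
#' @param y Region labels in `{BS, CB, CC}`; at least two classes present.
#' @param C,tol,max_steps Passed to [smo_fit()].
#' @return An object of class `smo_model` holding the three pair models.
#' @export
smo_multiclass <- function(x, y, C = 1, tol = 1e-3, max_steps = 1e7) {
  x <- as.matrix(x)
  y <- as.character(y)
  if (!all(y %in% region_labels()))
    stop("labels must be in {", paste(region_labels(), collapse = ", "), "}")
  present <- intersect(region_labels(), unique(y))
  if (length(present) < 2L)
    stop("training data contain a single class")
  pairs <- utils::combn(region_labels(), 2L, simplify = FALSE)
  models <- lapply(pairs, function(p) {
    idx <- y %in% p
    have <- intersect(p, unique(y[idx]))
    if (length(have) < 2L)
      return(.smo_constant(p, have[1L], ncol(x)))
    smo_fit(x[idx, , drop = FALSE], y[idx], C = C, tol = tol,
            class_pair = p, max_steps = max_steps)
  })
  names(models) <- vapply(pairs, paste, character(1L), collapse = "|")
  structure(list(models = models, C = C, tol = tol,
                 n_features = ncol(x)),
            class = "smo_model")
}

#' @export
print.smo_model <- function(x, ...) {
  cat("One-vs-one SMO SVM over regions ",
      paste(region_labels(), collapse = "/"), " (C = ", x$C, ")\n", sep = "")
  for (nm in names(x$models))
    cat("  ", nm, ": ",
        if (inherits(x$models[[nm]], "smo_constant")) "constant" else
          paste0(length(x$models[[nm]]$alpha), " samples"), "\n", sep = "")
  invisible(x)
}

#' Predict region labels by pairwise voting
#'
#' Each of the three binary models casts one vote; the majority class wins.
#' Ties among top-voted classes (including the three-way
#' rock-paper-scissors case) are broken by the larger sum of absolute
#' decision values collected by the tied classes, then by label order
#' BS < CB < CC.
#'
#' @param object An `smo_model`.
#' @param newdata Numeric matrix with the training feature count. Zero rows
#'   yield a zero-length label vector.
#' @param ... Unused.
#' @return Character vector of predicted region labels.
#' @export
predict.smo_model <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  n <- nrow(newdata)
  labs <- region_labels()
  if (n == 0L) return(character(0))
  votes <- matrix(0L, n, 3L, dimnames = list(NULL, labs))
  margin <- matrix(0, n, 3L, dimnames = list(NULL, labs))
  for (m in object$models) {
    f <- predict(m, newdata, type = "decision")
    lab <- ifelse(f >= 0, m$class_pair[1L], m$class_pair[2L])
    for (cl in m$class_pair) {
      hit <- lab == cl
      votes[hit, cl] <- votes[hit, cl] + 1L
      margin[hit, cl] <- margin[hit, cl] + abs(f[hit])
    }
  }
  vapply(seq_len(n), function(i) {
    top <- which(votes[i, ] == max(votes[i, ]))
    if (length(top) > 1L) {
      best <- max(margin[i, top])
      top <- top[margin[i, top] == best]   # label order breaks exact ties
    }
    labs[top[1L]]
  }, character(1L))
}

#' Total and per-class prediction accuracy
#'
#' @param true_labels,predicted_labels Equal-length label vectors.
#' @return A list with `total` (fraction correct), `per_class` (named
#'   BS/CB/CC accuracies, `NA` for a class absent from `true_labels`),
#'   `correct` and `n` (integer counts behind `total`, so downstream
#'   comparisons of accuracies can be made on exact rational counts).
#' @export
score_predictions <- function(true_labels, predicted_labels) {
  true_labels <- as.character(true_labels)
  predicted_labels <- as.character(predicted_labels)
  if (length(true_labels) != length(predicted_labels))
    stop("label vectors must have equal length")
  if (length(true_labels) == 0L)
    stop("label vectors must be non-empty")
  ok <- true_labels == predicted_labels
  per_class <- vapply(region_labels(), function(cl) {
    idx <- true_labels == cl
    if (!any(idx)) NA_real_ else mean(ok[idx])
  }, numeric(1))
  list(total = mean(ok), per_class = per_class,
       correct = sum(ok), n = length(ok))
}

#' Serialize / restore an SMO model as TSV
#'
#' Writes a long-format TSV (`pair`, `part`, `index`, `value`) holding dual
#' coefficients, bias, class pair, C and the standardization vectors of a
#' binary or one-vs-one model, sufficient to reproduce predictions exactly.
#'
#' @param model An `smo_binary` or `smo_model`.
#' @param path File path.
#' @return `write_smo_model` returns `path` invisibly; `read_smo_model`
#'   returns the restored model.
#' @export
write_smo_model <- function(model, path) {
  rows_binary <- function(m, pair_id) {
    meta <- data.frame(
      pair = pair_id, part = "meta",
      index = c("label_pos", "label_neg", "C", "tol", "b", "objective"),
      value = c(m$class_pair, sprintf("%.17g", c(m$C, m$tol, m$b,
                                                 m$objective))),
      stringsAsFactors = FALSE)
    vec <- function(part, v)
      data.frame(pair = pair_id, part = part,
                 index = as.character(seq_along(v)),
                 value = sprintf("%.17g", v), stringsAsFactors = FALSE)
    rbind(meta, vec("alpha", m$alpha), vec("y", m$y), vec("w", m$w),
          vec("center", m$center), vec("scale", m$scale))
  }
  rows_constant <- function(m, pair_id) {
    data.frame(pair = pair_id, part = "meta",
               index = c("label_pos", "label_neg", "constant",
                         "n_features"),
               value = c(m$class_pair, m$present,
                         as.character(m$n_features)),
               stringsAsFactors = FALSE)
  }
  rows <- if (inherits(model, "smo_binary")) {
    rows_binary(model, paste(model$class_pair, collapse = "|"))
  } else if (inherits(model, "smo_model")) {
    do.call(rbind, lapply(names(model$models), function(nm) {
      m <- model$models[[nm]]
      if (inherits(m, "smo_constant")) rows_constant(m, nm)
      else rows_binary(m, nm)
    }))
  } else stop("not an SMO model")
  .write_tsv(rows, path)
  invisible(path)
}

#' @rdname write_smo_model
#' @export
read_smo_model <- function(path) {
  df <- .read_tsv(path, colClasses = "character")
  build_binary <- function(d) {
    meta <- d[d$part == "meta", ]
    getm <- function(k) meta$value[meta$index == k]
    if (length(getm("constant")))
      return(.smo_constant(c(getm("label_pos"), getm("label_neg")),
                           getm("constant"),
                           as.integer(getm("n_features"))))
    vec <- function(part) {
      v <- d[d$part == part, ]
      as.numeric(v$value[order(as.integer(v$index))])
    }
    alpha <- vec("alpha"); ynum <- vec("y")
    center <- vec("center"); scale <- vec("scale")
    w <- vec("w")
    structure(
      list(class_pair = c(getm("label_pos"), getm("label_neg")),
           alpha = alpha, y = ynum, b = as.numeric(getm("b")),
           w = w, center = center, scale = scale,
           C = as.numeric(getm("C")), tol = as.numeric(getm("tol")),
           objective = as.numeric(getm("objective")),
           steps = NA_real_, converged = TRUE,
           n_features = length(center)),
      class = "smo_binary")
  }
  pairs <- unique(df$pair)
  models <- lapply(pairs, function(p) build_binary(df[df$pair == p, ]))
  names(models) <- pairs
  if (length(models) == 1L) return(models[[1L]])
  structure(list(models = models, C = models[[1L]]$C, tol = models[[1L]]$tol,
                 n_features = models[[1L]]$n_features),
            class = "smo_model")
}
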