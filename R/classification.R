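# Linear one-against-one SVM classification with leave-one-out
# evaluation. No SVM library ships with the runtime, so the binary
# subproblem is solved in C++ by deterministic dual coordinate descent on
# the L1 hinge loss (cyclic sweeps, fixed order), which makes every
# accuracy and confusion matrix bit-reproducible.

#' Train a linear one-against-one SVM
#'
#' Features are standardised to zero mean and unit deviation per dimension
#' using the training data only (zero-deviation dimensions pass through
#' unscaled), then one soft-margin linear SVM is fitted per unordered
#' class pair.
#'
#' @param x numeric matrix, samples in rows.
#' @param labels class labels (character or factor), one per row.
#' @param C soft-margin cost (> 0).
#' @param tol,max_epochs optimiser stopping controls.
#' @return object of class `herb_svm` with per-pair weight vectors, the
#'   ordered class labels and the standardisation parameters.
#' @export
svm_train <- function(x, labels, C = 1.0, tol = 1e-6, max_epochs = 2000L) {
  x <- as.matrix(x)
  labels <- as.character(labels)
  stopifnot(nrow(x) == length(labels), C > 0)
  if (any(!is.finite(x))) {
    bad <- which(rowSums(!is.finite(x)) > 0)
    stop("non-finite feature value(s) in sample(s): ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  classes <- sort(unique(labels))
  if (length(classes) < 2L) stop("need at least 2 classes to train")
  mu <- colMeans(x)
  sdv <- apply(x, 2, stats::sd)
  scale_ <- ifelse(is.na(sdv) | sdv == 0, 1, sdv)
  xs <- sweep(sweep(x, 2, mu), 2, scale_, "/")
  pairs <- utils::combn(classes, 2L)
  W <- matrix(0, nrow = ncol(pairs), ncol = ncol(x) + 1L)
  for (p in seq_len(ncol(pairs))) {
    a <- pairs[1, p]; b <- pairs[2, p]
    sel <- labels %in% c(a, b)
    y <- ifelse(labels[sel] == a, 1, -1)
    Xp <- cbind(xs[sel, , drop = FALSE], 1)  # bias feature
    W[p, ] <- .svm_dcd_cpp(Xp, y, C, tol, as.integer(max_epochs))
  }
  structure(list(weights = W, pairs = pairs, classes = classes,
                 center = mu, scale = scale_, C = C),
            class = "herb_svm")
}

#' @export
print.herb_svm <- function(x, ...) {
  cat(sprintf("herbleaf linear SVM: %d classes, %d pairwise classifiers, C = %g\n",
              length(x$classes), nrow(x$weights), x$C))
  invisible(x)
}

#' Predict classes by one-against-one voting
#'
#' Every pairwise classifier votes for one of its two classes; the label
#' with most votes wins. Ties are broken by the largest sum of signed
#' decision values among the tied labels, then by label order.
#'
#' @param model a `herb_svm`.
#' @param x numeric matrix (or vector) of samples to classify.
#' @return character vector of predicted labels.
#' @export
svm_predict <- function(model, x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  x <- as.matrix(x)
  if (ncol(x) != length(model$center))
    stop("feature dimension mismatch: model expects ", length(model$center),
         ", got ", ncol(x))
  xs <- sweep(sweep(x, 2, model$center), 2, model$scale, "/")
  Xa <- cbind(xs, 1)
  dec <- Xa %*% t(model$weights)       # n x n_pairs
  cls <- model$classes
  out <- character(nrow(x))
  for (i in seq_len(nrow(x))) {
    votes <- stats::setNames(numeric(length(cls)), cls)
    score <- votes
    for (p in seq_len(ncol(dec))) {
      a <- model$pairs[1, p]; b <- model$pairs[2, p]
      d <- dec[i, p]
      if (d >= 0) votes[a] <- votes[a] + 1 else votes[b] <- votes[b] + 1
      score[a] <- score[a] + d
      score[b] <- score[b] - d
    }
    best <- which(votes == max(votes))
    if (length(best) > 1L) {
      s <- score[best]
      best <- best[which(s == max(s))]
    }
    out[i] <- cls[best[1L]]              # residual ties: label order
  }
  out
}

new_confusion <- function(true, pred, classes) {
  m <- table(factor(true, levels = classes), factor(pred, levels = classes))
  counts <- matrix(as.integer(m), nrow = length(classes),
                   dimnames = list(classes, classes))
  structure(list(counts = counts,
                 accuracy = sum(diag(counts)) / max(sum(counts), 1L)),
            class = "herb_confusion")
}

#' @export
print.herb_confusion <- function(x, ...) {
  cat(sprintf("herbleaf confusion matrix: %d classes, accuracy %.4f\n",
              nrow(x$counts), x$accuracy))
  invisible(x)
}

#' Leave-one-out evaluation
#'
#' For each sample the model (including the feature standardisation) is
#' refitted on all remaining samples and the held-out sample predicted;
#' folds that lose a class entirely (n = 1 for that class) are allowed --
#' that class simply cannot be predicted for its own sample.
#'
#' @inheritParams svm_train
#' @return list with `accuracy`, `confusion` (a `herb_confusion`), and
#'   the vector of per-sample `predictions`.
#' @export
loo_evaluate <- function(x, labels, C = 1.0) {
  x <- as.matrix(x)
  labels <- as.character(labels)
  n <- nrow(x)
  stopifnot(n >= 2L)
  preds <- character(n)
  for (i in seq_len(n)) {
    m <- svm_train(x[-i, , drop = FALSE], labels[-i], C = C)
    preds[i] <- svm_predict(m, x[i, , drop = FALSE])
  }
  cm <- new_confusion(labels, preds, sort(unique(labels)))
  list(accuracy = cm$accuracy, confusion = cm, predictions = preds)
}

#' Leave-one-out accuracy per feature subset
#'
#' Runs [loo_evaluate()] restricted to each requested combination of
#' feature blocks (columns are selected by their `fs1_`/`fs2_`/`fs3_`
#' name prefixes).
#'
#' @param x numeric feature matrix with block-prefixed column names.
#' @param labels class labels.
#' @param subsets list of character vectors of block names, e.g.
#'   `list("fs1", c("fs1", "fs2", "fs3"))`.
#' @param C soft-margin cost.
#' @return data frame with columns `subset` and `accuracy`.
#' @export
evaluate_feature_subsets <- function(x, labels, subsets, C = 1.0) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) stop("feature matrix must have block-prefixed column names")
  res <- lapply(subsets, function(bl) {
    cols <- feature_block_columns(colnames(x), bl)
    if (!length(cols)) stop("no feature columns for subset: ", paste(bl, collapse = "+"))
    loo_evaluate(x[, cols, drop = FALSE], labels, C = C)$accuracy
  })
  data.frame(subset = vapply(subsets, paste, "", collapse = "+"),
             accuracy = unlist(res), stringsAsFactors = FALSE)
}
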