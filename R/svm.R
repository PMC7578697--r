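# Linear soft-margin SVM, confusion-matrix metrics and repeated stratified
# k-fold cross-validation. The quadratic program is solved by a sequential
# minimal optimisation routine in C++ (see src/svm_smo.cpp); the R layer
# validates inputs and reports fold-level metrics.

#' Train a linear soft-margin SVM
#'
#' Minimises `0.5 * ||w||^2 + C * sum(hinge)` over separating hyperplanes
#' `w . x + b = 0`. Solved in the dual by sequential minimal optimisation
#' with maximal-violating-pair selection; the reported `objective` is the
#' primal value at the solution.
#'
#' @param x Numeric matrix, n samples x d features.
#' @param y Labels in `{+1, -1}`; both classes must be present.
#' @param C Soft-margin penalty (> 0, default 1).
#' @param tol Convergence tolerance on the dual KKT violation
#'   (default 1e-6).
#' @param max_iter Iteration cap (default 1e5).
#' @return An object of class `linear_svm`: list with `w`, `b`, `C`,
#'   `alpha`, `objective`, `iterations`.
#' @export
train_linear_svm <- function(x, y, C = 1, tol = 1e-6, max_iter = 100000L) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  y <- as.numeric(y)
  if (!all(y %in% c(-1, 1))) stop("labels must be +1/-1", call. = FALSE)
  if (length(unique(y)) < 2) {
    stop("training data contain a single class", call. = FALSE)
  }
  if (!all(is.finite(x))) stop("non-finite feature values", call. = FALSE)
  if (length(y) != nrow(x)) stop("x/y length mismatch", call. = FALSE)
  if (C <= 0) stop("C must be positive", call. = FALSE)
  fit <- .smo_fit_cpp(x, y, C, tol, as.integer(max_iter))
  structure(list(w = setNames(fit$w, colnames(x)), b = fit$b, C = C,
                 alpha = fit$alpha, objective = fit$objective,
                 iterations = fit$iterations),
            class = "linear_svm")
}

#' @export
print.linear_svm <- function(x, ...) {
  cat("<linear_svm> d =", length(x$w), " C =", x$C,
      " objective =", signif(x$objective, 6), "\n")
  invisible(x)
}

#' Decision values of a linear SVM
#'
#' @param model A `linear_svm`.
#' @param x Feature matrix (or vector) with the training dimensionality.
#' @return Numeric vector `x %*% w + b`.
#' @export
svm_decision <- function(model, x) {
  x <- if (is.null(dim(x))) matrix(x, nrow = 1) else as.matrix(x)
  if (ncol(x) != length(model$w)) {
    stop("feature dimension mismatch: model has ", length(model$w),
         ", input has ", ncol(x), call. = FALSE)
  }
  drop(x %*% model$w + model$b)
}

#' Predict class labels
#'
#' Classifies by the sign of the decision value `w . x + b`; a value of
#' exactly zero is assigned to the positive class.
#'
#' @param object A `linear_svm`.
#' @param x Feature matrix (or vector) with the training dimensionality.
#' @param ... Unused.
#' @return Vector of labels in `{+1, -1}`.
#' @export
predict.linear_svm <- function(object, x, ...) {
  ifelse(svm_decision(object, x) >= 0, 1, -1)
}

#' Confusion matrix of a binary prediction
#'
#' Counts true/false positives/negatives with the patient class (CL, +1)
#' as positive.
#'
#' @param predicted,actual Label vectors in `{+1, -1}` of equal length.
#' @return An object of class `confusion_matrix`: named list
#'   `TP, FN, FP, TN`.
#' @export
confusion <- function(predicted, actual) {
  if (length(predicted) != length(actual)) {
    stop("length mismatch", call. = FALSE)
  }
  if (!all(c(predicted, actual) %in% c(-1, 1))) {
    stop("labels must be +1/-1", call. = FALSE)
  }
  structure(list(TP = sum(predicted == 1 & actual == 1),
                 FN = sum(predicted == -1 & actual == 1),
                 FP = sum(predicted == 1 & actual == -1),
                 TN = sum(predicted == -1 & actual == -1)),
            class = "confusion_matrix")
}

#' Classification metrics from a confusion matrix
#'
#' Sensitivity `TP/(TP+FN)`, specificity `TN/(TN+FP)`, accuracy
#' `(TP+TN)/n`, the Matthews correlation coefficient
#' `(TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))` and balanced
#' accuracy `(sensitivity + specificity)/2`. If any factor of the MCC
#' denominator is zero the MCC is defined as 0 (standard convention for
#' degenerate cells).
#'
#' @param cm A [confusion()] result, or any list with `TP, FN, FP, TN`.
#' @return A tibble row with `sensitivity`, `specificity`, `accuracy`,
#'   `mcc`, `bacc` (bacc as a proportion in `[0, 1]`).
#' @export
classification_metrics <- function(cm) {
  tp <- cm$TP; fn <- cm$FN; fp <- cm$FP; tn <- cm$TN
  n <- tp + fn + fp + tn
  if (n < 1) stop("empty confusion matrix", call. = FALSE)
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  den <- as.numeric(tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  mcc <- if (den > 0) (as.numeric(tp) * tn - as.numeric(fp) * fn) /
    sqrt(den) else 0
  tibble::tibble(sensitivity = sens, specificity = spec,
                 accuracy = (tp + tn) / n, mcc = mcc,
                 bacc = (sens + spec) / 2)
}

# derive a per-repeat RNG seed from the master seed; kept < 2^31
fold_seed <- function(seed, r) {
  (as.integer(seed) %% 1000003L) * 1009L + as.integer(r)
}

#' Build repeated (stratified) k-fold partitions
#'
#' For each repeat a fresh seeded shuffle partitions the samples into k
#' folds; stratification balances class counts per fold. The assignment of
#' sample `i` in repeat `r` is a pure function of `(seed, r)`, so distinct
#' channel subsets evaluated under the same master seed share identical
#' partitions.
#'
#' @param y Label vector (any type; classes taken as distinct values).
#' @param k Number of folds (default 5).
#' @param repeats Number of repeats (default 20).
#' @param seed Master seed.
#' @param stratified Stratify folds by class (default TRUE).
#' @return Integer matrix, `length(y)` x `repeats`, entries in `1..k`.
#' @export
make_folds <- function(y, k = 5, repeats = 20, seed = 1,
                       stratified = TRUE) {
  n <- length(y)
  stopifnot(k >= 2, repeats >= 1, n >= k)
  out <- matrix(NA_integer_, n, repeats)
  for (r in seq_len(repeats)) {
    withr::with_seed(fold_seed(seed, r), {
      if (stratified) {
        for (cls in sort(unique(y))) {
          idx <- which(y == cls)
          out[idx, r] <- sample(rep_len(seq_len(k), length(idx)))
        }
      } else {
        out[, r] <- sample(rep_len(seq_len(k), n))
      }
    })
  }
  out
}

#' Subject-grouped fold partitions
#'
#' Like [make_folds()], but all rows of one subject are assigned to the
#' same fold (stratifying subjects by their class). Sample-level folding
#' lets the multiple task rows of one subject fall into train and test
#' of the same split; when those rows are strongly correlated this leaks
#' subject identity into the test fold, which inflates cross-validated
#' metrics — including under a permutation null. Grouped folds restore
#' exchangeability.
#'
#' @param subjects Vector of subject identifiers, one per row.
#' @param y Label vector, one per row (constant within subject).
#' @param k,repeats,seed As in [make_folds()].
#' @return Integer matrix, `length(y)` x `repeats`, entries in `1..k`.
#' @export
make_subject_folds <- function(subjects, y, k = 5, repeats = 20,
                               seed = 1) {
  subj <- unique(subjects)
  ysub <- y[match(subj, subjects)]
  if (any(tapply(y, subjects, function(v) length(unique(v))) > 1)) {
    stop("labels must be constant within subject", call. = FALSE)
  }
  fsub <- make_folds(ysub, k = k, repeats = repeats, seed = seed)
  fsub[match(subjects, subj), , drop = FALSE]
}

#' Repeated k-fold cross-validation of a linear SVM
#'
#' For each repeat, a seeded shuffle partitions the rows into k folds
#' (stratified by class by default); each fold serves once as the test
#' set. Metrics are computed per test fold and averaged over all
#' `k * repeats` folds.
#'
#' @param features Feature table from [build_dataset()] (columns
#'   `group`, `ch1..ch16`), or a plain numeric matrix if `y` is given.
#' @param channels Integer channel numbers to use (default: all 16).
#' @param y Optional label vector in `{+1, -1}` when `features` is a
#'   matrix.
#' @param k,repeats,seed,stratified Cross-validation design; see
#'   [make_folds()].
#' @param C Soft-margin penalty, fixed across folds.
#' @param folds Optional precomputed fold matrix (overrides
#'   `k/repeats/seed`).
#' @param tol,max_iter Solver controls (defaults are looser than
#'   [train_linear_svm()] since fold-level metrics are insensitive to the
#'   last digits of `w`).
#' @return A list with `folds` (tibble of per-fold confusion cells and
#'   metrics), `mean_mcc`, `mean_bacc`, and the `fold_matrix` used.
#' @export
repeated_kfold <- function(features, channels = 1:16, y = NULL,
                           k = 5, repeats = 20, seed = 1,
                           stratified = TRUE, C = 1, folds = NULL,
                           tol = 1e-4, max_iter = 20000L) {
  if (is.data.frame(features)) {
    x <- as.matrix(features[FEATURE_COLS])
    y <- label_to_y(features$group)
  } else {
    x <- as.matrix(features)
    if (is.null(y)) stop("`y` required with a matrix input", call. = FALSE)
  }
  storage.mode(x) <- "double"
  if (ncol(x) < max(channels)) stop("channel index out of range",
                                    call. = FALSE)
  if (length(unique(y)) < 2) {
    stop("cross-validation requires both classes", call. = FALSE)
  }
  if (min(table(y)) < k && stratified) {
    stop("too few samples per class for ", k, " stratified folds",
         call. = FALSE)
  }
  if (is.null(folds)) {
    folds <- make_folds(y, k = k, repeats = repeats, seed = seed,
                        stratified = stratified)
  }
  cells <- .cv_confusion_cpp(x, as.numeric(y), folds,
                             as.integer(channels), C, tol,
                             as.integer(max_iter))
  tab <- tibble::as_tibble(cells)
  names(tab)[1] <- "rep"
  met <- purrr::pmap_dfr(tab[c("TP", "FN", "FP", "TN")],
                         function(TP, FN, FP, TN) {
    classification_metrics(list(TP = TP, FN = FN, FP = FP, TN = TN))
  })
  fold_tab <- dplyr::bind_cols(tab, met)
  degenerate <- (fold_tab$TP + fold_tab$FN == 0) |
    (fold_tab$TN + fold_tab$FP == 0)
  if (any(degenerate)) {
    warning(sum(degenerate), " fold(s) missing a class; their MCC is 0",
            call. = FALSE)
  }
  list(folds = fold_tab,
       mean_mcc = mean(fold_tab$mcc),
       mean_bacc = mean(fold_tab$bacc, na.rm = any(degenerate)),
       fold_matrix = folds)
}

#' Compare two fold-level metric distributions
#'
#' Welch two-sample t-test on fold-level metric values (e.g. MCCs of two
#' channel groupings); the statistic's sign indicates the direction of the
#' difference (`a` minus `b`).
#'
#' @param a,b Numeric vectors of fold-level metrics, length >= 2 each.
#' @return A list with `statistic`, `p_value`, `df`, `mean_a`, `mean_b`.
#' @export
compare_metric_distributions <- function(a, b) {
  stopifnot(length(a) >= 2, length(b) >= 2)
  if (sd(a) == 0 && sd(b) == 0) {
    stop("both samples have zero variance; t-test undefined",
         call. = FALSE)
  }
  tt <- t.test(a, b, var.equal = FALSE)
  list(statistic = unname(tt$statistic), p_value = tt$p.value,
       df = unname(tt$parameter), mean_a = mean(a), mean_b = mean(b))
}
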