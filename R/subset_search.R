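# Exhaustive channel-subset evaluation: enumerate every non-empty subset
# of a hemisphere grouping, cross-validate each on shared fold partitions,
# rank by mean MCC and report Table-style summaries and weight-sign
# matrices.

#' Channel groupings by hemisphere
#'
#' The probe band samples the prefrontal cortex with CH1-CH8 over the
#' right hemisphere and CH9-CH16 over the left.
#'
#' @param name One of `"right"`, `"left"`, `"bilateral"`.
#' @return A list with `name` and integer `channels`.
#' @export
channel_grouping <- function(name = c("right", "left", "bilateral")) {
  name <- match.arg(name)
  channels <- switch(name, right = 1:8, left = 9:16, bilateral = 1:16)
  list(name = name, channels = channels)
}

#' Enumerate all non-empty channel subsets of a grouping
#'
#' Subsets are returned in a deterministic order: by size, then
#' lexicographically within each size. An n-channel grouping yields
#' `2^n - 1` subsets.
#'
#' @param grouping A [channel_grouping()] or integer vector of channels.
#' @param max_size Optional cap on subset size (for capped searches).
#' @return List of integer vectors.
#' @export
enumerate_subsets <- function(grouping, max_size = NULL) {
  channels <- if (is.list(grouping)) grouping$channels else
    as.integer(grouping)
  stopifnot(length(channels) >= 1, !anyDuplicated(channels))
  sizes <- seq_len(if (is.null(max_size)) length(channels) else
    min(max_size, length(channels)))
  out <- list()
  for (s in sizes) {
    # combn over positions: combn(x, m) would read a scalar x as 1:x
    idx <- combn(seq_along(channels), s, simplify = FALSE)
    out <- c(out, lapply(idx, function(i) channels[i]))
  }
  out
}

subset_key <- function(subset) paste(subset, collapse = ",")

#' Cross-validate one channel subset
#'
#' Restricts the feature table to the given channels and runs
#' [repeated_kfold()]; the result is invariant to the order in which the
#' channels are listed.
#'
#' @param features Feature table from [build_dataset()].
#' @param subset Integer channel numbers (non-empty).
#' @param k,repeats,seed,C,folds As in [repeated_kfold()].
#' @return A list of class `subset_result` with `subset`, `mean_mcc`,
#'   `mean_bacc` (percent) and the per-fold metric tibble.
#' @export
evaluate_subset <- function(features, subset, k = 5, repeats = 20,
                            seed = 1, C = 1, folds = NULL) {
  if (length(subset) == 0) stop("subset must be non-empty", call. = FALSE)
  subset <- sort(unique(as.integer(subset)))
  cv <- repeated_kfold(features, channels = subset, k = k,
                       repeats = repeats, seed = seed, C = C,
                       folds = folds)
  structure(list(subset = subset, mean_mcc = cv$mean_mcc,
                 mean_bacc = 100 * cv$mean_bacc, folds = cv$folds),
            class = "subset_result")
}

#' Exhaustive channel-subset search
#'
#' Evaluates every non-empty subset of the grouping with repeated
#' stratified k-fold cross-validation. All subsets share the same fold
#' partitions (derived from the master seed), so they are compared on
#' identical train/test splits. Results are ranked by mean MCC
#' (descending), with ties broken by mean bACC (descending), then smaller
#' subset size, then lexicographic subset order.
#'
#' @param features Feature table from [build_dataset()].
#' @param grouping `"right"`, `"left"`, `"bilateral"`, or a
#'   [channel_grouping()].
#' @param k,repeats,seed,C Cross-validation design and penalty.
#' @param max_size Optional cap on subset size; the full bilateral search
#'   (65,535 subsets x k*repeats fits) takes a few minutes on one core at
#'   `tol = 1e-2`, a cap of 6 runs in about half a minute.
#' @param tol,max_iter Solver controls per fold.
#' @return A `search_report` tibble with columns `subset` (string),
#'   `size`, `mean_mcc`, `mean_bacc` (percent), ranked; attributes carry
#'   the grouping, CV design, seed and fold matrix.
#' @export
exhaustive_search <- function(features, grouping = "bilateral", k = 5,
                              repeats = 20, seed = 1, C = 1,
                              max_size = NULL, tol = 1e-4,
                              max_iter = 20000L) {
  if (is.character(grouping)) grouping <- channel_grouping(grouping)
  x <- as.matrix(features[FEATURE_COLS])
  storage.mode(x) <- "double"
  y <- label_to_y(features$group)
  if (length(unique(y)) < 2) stop("feature table is single-class",
                                  call. = FALSE)
  subsets <- enumerate_subsets(grouping, max_size = max_size)
  folds <- make_folds(y, k = k, repeats = repeats, seed = seed)
  # evaluate in prefix (preorder) order so each subset can warm-start its
  # fold solves from the parent subset's solutions; report order is
  # unaffected
  keys <- vapply(subsets,
                 function(s) paste(sprintf("%02d", s), collapse = ""),
                 character(1))
  ord_eval <- order(keys, method = "radix")
  res_eval <- .cv_search_cpp(x, y, folds,
                             lapply(subsets[ord_eval], as.integer), C,
                             tol, as.integer(max_iter))
  res <- matrix(NA_real_, length(subsets), 2)
  res[ord_eval, ] <- res_eval
  report <- tibble::tibble(
    subset = vapply(subsets, subset_key, character(1)),
    size = lengths(subsets),
    mean_mcc = res[, 1],
    mean_bacc = 100 * res[, 2]
  )
  ord <- order(-report$mean_mcc, -report$mean_bacc, report$size,
               report$subset)
  report <- report[ord, ]
  attr(report, "grouping") <- grouping$name
  attr(report, "cv") <- list(k = k, repeats = repeats, C = C, seed = seed,
                             max_size = max_size)
  attr(report, "fold_matrix") <- folds
  class(report) <- c("search_report", class(report))
  report
}

#' Top-ranked subsets of a search report
#'
#' @param report A `search_report` (or list of reports, which are bound
#'   with their grouping names).
#' @param k Rows per grouping (default 5).
#' @return Tibble of the first `k` rows (per grouping), in non-increasing
#'   mean-MCC order, with a `grouping` column.
#' @export
top_k <- function(report, k = 5) {
  if (!is.data.frame(report) && is.list(report)) {
    return(dplyr::bind_rows(lapply(report, top_k, k = k)))
  }
  if (k > nrow(report)) {
    warning("k = ", k, " exceeds report length ", nrow(report),
            "; truncating", call. = FALSE)
    k <- nrow(report)
  }
  out <- utils::head(report, k)
  out <- tibble::as_tibble(out)
  out$grouping <- attr(report, "grouping") %||% NA_character_
  dplyr::relocate(out, "grouping")
}

#' Signed channel weights of the top-ranked subsets
#'
#' For each of the top `m` subsets the SVM is refit on the full feature
#' table restricted to that subset, and each member channel's signed
#' weight is recorded (positive = higher HbO2 in the patient group under
#' the CL = +1 encoding). Channels absent from a subset are empty (`NA`).
#'
#' @param features Feature table from [build_dataset()].
#' @param report A ranked `search_report`.
#' @param m Number of top subsets (default 50).
#' @param C Soft-margin penalty used for the refits.
#' @return A numeric matrix, `m` x 16, rownames = subset strings; `NA`
#'   where a channel is not in the subset. Rows whose refit failed are
#'   recorded in the `failed` attribute.
#' @export
weight_sign_matrix <- function(features, report, m = 50, C = 1) {
  if (m > nrow(report)) stop("m exceeds report length", call. = FALSE)
  x <- as.matrix(features[FEATURE_COLS])
  y <- label_to_y(features$group)
  out <- matrix(NA_real_, m, 16, dimnames = list(report$subset[seq_len(m)],
                                                 CHANNELS))
  failed <- character(0)
  for (i in seq_len(m)) {
    subset <- as.integer(strsplit(report$subset[i], ",")[[1]])
    fit <- tryCatch(train_linear_svm(x[, subset, drop = FALSE], y, C = C),
                    error = function(e) NULL)
    if (is.null(fit)) {
      failed <- c(failed, report$subset[i])
      next
    }
    out[i, subset] <- fit$w
  }
  attr(out, "failed") <- failed
  if (length(failed) > 0) {
    warning(length(failed), " refit(s) failed; rows flagged", call. = FALSE)
  }
  out
}
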