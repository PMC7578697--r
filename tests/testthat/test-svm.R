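test_that("symmetric two-point problem gives the analytic hyperplane", {
  fit <- train_linear_svm(matrix(c(1, -1)), c(1, -1), C = 100)
  expect_equal(unname(fit$w), 1, tolerance = 1e-6)
  expect_equal(fit$b, 0, tolerance = 1e-6)
})

test_that("solver objective matches the brute-force QP oracle", {
  withr::with_seed(3, {
    for (trial in 1:5) {
      n <- 8
      x <- matrix(rnorm(n * 2), n, 2)
      y <- rep(c(1, -1), each = 4)
      x[y == 1, 1] <- x[y == 1, 1] + 2
      C <- c(0.5, 1, 10)[(trial %% 3) + 1]
      fit <- train_linear_svm(x, y, C = C, tol = 1e-8)
      oracle <- oracle_svm_qp(x, y, C)
      expect_false(is.null(oracle))
      obj_fit <- svm_primal_obj(x, y, fit$w, fit$b, C)
      obj_orc <- svm_primal_obj(x, y, oracle$w, oracle$b, C)
      expect_equal(obj_fit, obj_orc, tolerance = 1e-4)
      expect_equal(unname(fit$w), oracle$w, tolerance = 1e-3)
    }
  })
})

test_that("solver agrees with an independent libsvm implementation", {
  skip_if_not_installed("e1071")
  withr::with_seed(4, {
    n <- 60
    x <- matrix(rnorm(n * 5), n, 5)
    y <- rep(c(1, -1), each = 30)
    x[y == 1, 1] <- x[y == 1, 1] + 1
    for (C in c(0.5, 2)) {
      fit <- train_linear_svm(x, y, C = C, tol = 1e-8)
      m <- e1071::svm(x, factor(y), kernel = "linear", cost = C,
                      scale = FALSE)
      w_e <- drop(t(m$coefs) %*% m$SV)
      b_e <- -m$rho
      if (cor(drop(x %*% w_e) + b_e, svm_decision(fit, x)) < 0) {
        w_e <- -w_e
        b_e <- -b_e
      }
      expect_equal(svm_primal_obj(x, y, fit$w, fit$b, C),
                   svm_primal_obj(x, y, w_e, b_e, C), tolerance = 1e-3)
    }
  })
})

test_that("duplicating every point with C halved leaves the model fixed", {
  withr::with_seed(5, {
    x <- matrix(rnorm(20), 10, 2)
    y <- rep(c(1, -1), each = 5)
    x[y == 1, ] <- x[y == 1, ] + 3  # separable: hard-margin regime
    f1 <- train_linear_svm(x, y, C = 100, tol = 1e-8)
    f2 <- train_linear_svm(rbind(x, x), c(y, y), C = 50, tol = 1e-8)
    expect_equal(f1$w, f2$w, tolerance = 1e-4)
    expect_equal(f1$b, f2$b, tolerance = 1e-4)
    # support vectors satisfy the margin constraints
    expect_true(all(y * svm_decision(f1, x) >= 1 - 1e-6))
  })
})

test_that("training rejects degenerate inputs", {
  expect_error(train_linear_svm(matrix(1:4, 2), c(1, 1)), "single class")
  expect_error(train_linear_svm(matrix(c(1, NA, 3, 4), 2), c(1, -1)),
               "non-finite")
  expect_error(train_linear_svm(matrix(1:4, 2), c(1, 0)), "labels")
  expect_error(train_linear_svm(matrix(1:4, 2), c(1, -1), C = 0),
               "positive")
})

test_that("prediction is the decision sign with ties positive", {
  model <- structure(list(w = c(1, 0), b = 0, C = 1), class = "linear_svm")
  expect_equal(predict(model, c(3, 5)), 1)
  expect_equal(predict(model, c(-2, 9)), -1)
  expect_equal(predict(model, c(0, 0)), 1)  # documented tie rule
  expect_error(predict(model, c(1, 2, 3)), "dimension mismatch")
})

test_that("confusion matrix counts the four cells", {
  cm <- confusion(c(1, 1, 1, -1, -1), c(1, 1, 1, -1, -1))
  expect_equal(unclass(cm)[c("TP", "FN", "FP", "TN")],
               list(TP = 3L, FN = 0L, FP = 0L, TN = 2L))
  cm2 <- confusion(c(-1, -1, -1, 1, 1), c(1, 1, 1, -1, -1))
  expect_equal(unclass(cm2)[c("TP", "FN", "FP", "TN")],
               list(TP = 0L, FN = 3L, FP = 2L, TN = 0L))
  withr::with_seed(6, {
    for (i in 1:5) {
      p <- sample(c(-1, 1), 30, replace = TRUE)
      a <- sample(c(-1, 1), 30, replace = TRUE)
      cm3 <- confusion(p, a)
      expect_equal(cm3$TP + cm3$FN + cm3$FP + cm3$TN, 30)
    }
  })
  expect_error(confusion(c(1, 0), c(1, -1)), "labels")
  expect_error(confusion(1, c(1, -1)), "length")
})

test_that("metrics match the independent implementation on random cells", {
  withr::with_seed(7, {
    for (i in 1:1000) {
      cells <- as.list(rpois(4, 8))
      names(cells) <- c("TP", "FN", "FP", "TN")
      if (sum(unlist(cells)) == 0) cells$TP <- 1
      m <- classification_metrics(cells)
      expect_equal(m$mcc, oracle_mcc(cells$TP, cells$FN, cells$FP,
                                     cells$TN), tolerance = 1e-12)
      expect_true(m$mcc >= -1 && m$mcc <= 1)
      if (cells$TP + cells$FN > 0 && cells$TN + cells$FP > 0) {
        expect_equal(m$bacc, oracle_bacc(cells$TP, cells$FN, cells$FP,
                                         cells$TN), tolerance = 1e-12)
        expect_equal(m$bacc, (m$sensitivity + m$specificity) / 2)
      }
    }
  })
})

test_that("metric identities hold on canonical confusion matrices", {
  perfect <- classification_metrics(list(TP = 25, FN = 0, FP = 0,
                                         TN = 25))
  expect_equal(perfect$mcc, 1)
  expect_equal(perfect$bacc, 1)
  expect_equal(perfect$accuracy, 1)
  chance <- classification_metrics(list(TP = 25, FN = 25, FP = 25,
                                        TN = 25))
  expect_equal(chance$mcc, 0)
  expect_equal(chance$bacc, 0.5)
  hand <- classification_metrics(list(TP = 20, FN = 10, FP = 5, TN = 20))
  expect_equal(hand$sensitivity, 20 / 30)
  expect_equal(hand$specificity, 20 / 25)
  expect_equal(hand$mcc, (20 * 20 - 5 * 10) /
                 sqrt(25 * 30 * 25 * 30))
  expect_equal(hand$bacc, (20 / 30 + 20 / 25) / 2)
})

test_that("MCC and bACC are invariant under class swap", {
  withr::with_seed(8, {
    for (i in 1:50) {
      v <- rpois(4, 6)
      a <- classification_metrics(list(TP = v[1], FN = v[2], FP = v[3],
                                       TN = v[4]))
      b <- classification_metrics(list(TP = v[4], FN = v[3], FP = v[2],
                                       TN = v[1]))
      expect_equal(a$mcc, b$mcc, tolerance = 1e-12)
      if (is.finite(a$bacc) && is.finite(b$bacc)) {
        expect_equal(a$bacc, b$bacc, tolerance = 1e-12)
      }
    }
  })
})

test_that("fold partitions are stratified, exhaustive and seed-pure", {
  y <- rep(c(1, -1), c(60, 50))
  f1 <- make_folds(y, k = 5, repeats = 20, seed = 9)
  f2 <- make_folds(y, k = 5, repeats = 20, seed = 9)
  expect_identical(f1, f2)
  expect_equal(dim(f1), c(110, 20))
  for (r in c(1, 10, 20)) {
    # every sample in exactly one fold; both classes in every fold
    expect_true(all(f1[, r] %in% 1:5))
    for (fd in 1:5) {
      expect_equal(sum(y[f1[, r] == fd] == 1), 12)
      expect_equal(sum(y[f1[, r] == fd] == -1), 10)
    }
  }
  f3 <- make_folds(y, k = 5, repeats = 20, seed = 10)
  expect_false(identical(f1, f3))
})

test_that("subject-grouped folds keep each subject's rows together", {
  subjects <- rep(sprintf("S%02d", 1:20), each = 2)
  y <- rep(rep(c(1, -1), c(12, 8)), each = 2)
  f <- make_subject_folds(subjects, y, k = 4, repeats = 5, seed = 3)
  expect_equal(dim(f), c(40, 5))
  for (r in 1:5) {
    per_subj <- tapply(f[, r], subjects, function(v) length(unique(v)))
    expect_true(all(per_subj == 1))
    for (fd in 1:4) expect_gt(length(unique(y[f[, r] == fd])), 1)
  }
  expect_error(make_subject_folds(subjects, seq_len(40), k = 2),
               "constant within subject")
})

test_that("repeated k-fold returns k x repeats folds and exercises both
           separable and chance regimes", {
  tab <- quick_feature_table(shift = 6, signal = 1:4, seed = 21)
  cv <- repeated_kfold(tab, k = 5, repeats = 20, seed = 1)
  expect_equal(nrow(cv$folds), 100)
  expect_equal(cv$mean_mcc, 1)
  expect_equal(cv$mean_bacc, 1)
  # permuted labels: chance-level MCC
  tabp <- quick_feature_table(shift = 0, seed = 22)
  cvp <- repeated_kfold(tabp, k = 5, repeats = 20, seed = 2)
  expect_lt(abs(cvp$mean_mcc), 0.1)
})

test_that("Welch comparison of fold metric distributions", {
  withr::with_seed(10, {
    a <- rnorm(100, 0.5, 0.1)
    expect_error(compare_metric_distributions(rep(1, 5), rep(1, 5)),
                 "zero variance")
    same <- compare_metric_distributions(a, a)
    expect_equal(same$statistic, 0)
    expect_equal(same$p_value, 1)
    shift <- compare_metric_distributions(a + 10, a)
    expect_gt(shift$statistic, 0)
    expect_lt(shift$p_value, 1e-6)
    flipped <- compare_metric_distributions(a, a + 10)
    expect_equal(flipped$statistic, -shift$statistic, tolerance = 1e-12)
  })
})
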