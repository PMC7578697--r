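# Independent oracles used by the tests. These deliberately avoid the
# package's own code paths.

# Brute-force QP solve of the soft-margin SVM dual by enumerating KKT
# active sets: each point is assigned to {alpha = 0, free, alpha = C};
# free alphas and the bias follow from the linear KKT system, and the
# assignment is kept only if box and complementary-slackness conditions
# hold. Feasible for n <= ~10.
oracle_svm_qp <- function(x, y, C, kkt_tol = 1e-7) {
  x <- as.matrix(x)
  n <- nrow(x)
  stopifnot(n <= 12)
  K <- x %*% t(x)
  best <- NULL
  best_obj <- -Inf
  for (code in 0:(3^n - 1)) {
    assign <- (code %/% 3^(0:(n - 1))) %% 3  # 0 zero, 1 free, 2 at C
    Fr <- which(assign == 1)
    Bd <- which(assign == 2)
    if (length(Fr) == 0) next  # bias undetermined; generic optima have free SVs
    # unknowns: alpha_Fr, b. Equations: margin equalities + balance.
    nf <- length(Fr)
    A <- matrix(0, nf + 1, nf + 1)
    rhs <- numeric(nf + 1)
    for (ii in seq_len(nf)) {
      i <- Fr[ii]
      A[ii, seq_len(nf)] <- y[i] * y[Fr] * K[i, Fr]
      A[ii, nf + 1] <- y[i]
      rhs[ii] <- 1 - y[i] * sum(C * y[Bd] * K[i, Bd])
    }
    A[nf + 1, seq_len(nf)] <- y[Fr]
    rhs[nf + 1] <- -sum(C * y[Bd])
    sol <- tryCatch(solve(A, rhs), error = function(e) NULL)
    if (is.null(sol)) next
    a_fr <- sol[seq_len(nf)]
    b <- sol[nf + 1]
    if (any(a_fr < -kkt_tol) || any(a_fr > C + kkt_tol)) next
    alpha <- numeric(n)
    alpha[Fr] <- pmin(pmax(a_fr, 0), C)
    alpha[Bd] <- C
    w <- drop(t(x) %*% (alpha * y))
    marg <- y * (x %*% w + b)
    if (any(marg[assign == 0] < 1 - kkt_tol)) next
    if (any(marg[Bd] > 1 + kkt_tol)) next
    obj_dual <- sum(alpha) - 0.5 * sum((alpha * y) * (K %*% (alpha * y)))
    if (obj_dual > best_obj) {
      best_obj <- obj_dual
      best <- list(w = w, b = b, alpha = alpha, dual_objective = obj_dual)
    }
  }
  best
}

# primal SVM objective
svm_primal_obj <- function(x, y, w, b, C) {
  0.5 * sum(w^2) + C * sum(pmax(0, 1 - y * (as.matrix(x) %*% w + b)))
}

# MCC as the Pearson correlation of the expanded binary label vectors
# (an algebraically equivalent but independent route); zero-variance
# cases map to the 0 convention.
oracle_mcc <- function(tp, fn, fp, tn) {
  actual <- c(rep(1, tp), rep(1, fn), rep(0, fp), rep(0, tn))
  pred <- c(rep(1, tp), rep(0, fn), rep(1, fp), rep(0, tn))
  if (sd(actual) == 0 || sd(pred) == 0) return(0)
  cor(actual, pred)
}

# balanced accuracy from recalls computed off a 2x2 table
oracle_bacc <- function(tp, fn, fp, tn) {
  (tp / (tp + fn) + tn / (tn + fp)) / 2
}

# Pearson r by explicit sums of products
oracle_pearson <- function(x, y) {
  n <- length(x)
  num <- n * sum(x * y) - sum(x) * sum(y)
  den <- sqrt(n * sum(x^2) - sum(x)^2) * sqrt(n * sum(y^2) - sum(y)^2)
  num / den
}
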