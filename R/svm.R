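# Support-vector classifier on top of the compiled SMO solver: kernels,
# decision values, Platt probability calibration, stratified CV helpers.

rbf_kernel <- function(x, z = x, gamma) {
  x <- as.matrix(x); z <- as.matrix(z)
  d2 <- outer(rowSums(x^2), rowSums(z^2), "+") - 2 * tcrossprod(x, z)
  d2[d2 < 0] <- 0
  exp(-gamma * d2)
}

linear_kernel <- function(x, z = x) tcrossprod(as.matrix(x), as.matrix(z))

#' Train a C-SVC support vector classifier
#'
#' Binary soft-margin SVM solved in the dual by sequential minimal
#' optimization (compiled code). Labels are coerced to -1/+1 with the
#' positive class being 1 / TRUE / the second factor level.
#'
#' @param x Numeric feature matrix (rows = samples).
#' @param y Binary labels (0/1, logical, or factor).
#' @param kernel `"rbf"` or `"linear"`.
#' @param C Soft-margin cost parameter.
#' @param gamma RBF kernel width (ignored for the linear kernel).
#' @param tol SMO stopping tolerance on the KKT violation gap.
#' @return An object of class `hs_svm` with the support-vector expansion
#'   (`coef` = alpha*y, `b`, the retained training rows), kernel settings and
#'   for linear kernels the primal weight vector `w`.
#' @export
svm_fit <- function(x, y, kernel = c("rbf", "linear"), C = 1, gamma = 0.05,
                    tol = 1e-3) {
  kernel <- match.arg(kernel)
  x <- as.matrix(x)
  ypm <- to_pm1(y)
  if (length(unique(ypm)) < 2) stop("svm_fit needs both classes present")
  stopifnot(nrow(x) == length(ypm), C > 0)
  K <- if (kernel == "rbf") rbf_kernel(x, gamma = gamma) else linear_kernel(x)
  sol <- smo_solve(K, ypm, C, tol = tol)
  if (!sol$converged) {
    warning("SMO did not reach tolerance ", tol, " within iteration budget")
  }
  coef <- sol$alpha * ypm
  sv <- which(sol$alpha > 1e-12)
  out <- list(kernel = kernel, C = C, gamma = gamma,
              xsv = x[sv, , drop = FALSE], coef = coef[sv], b = sol$b,
              objective = sol$objective, iterations = sol$iterations)
  if (kernel == "linear") out$w <- drop(crossprod(x, coef))
  structure(out, class = "hs_svm")
}

to_pm1 <- function(y) {
  if (is.factor(y)) y <- as.integer(y) - 1L
  y <- as.numeric(y)
  stopifnot(all(y %in% c(0, 1)))
  ifelse(y > 0, 1, -1)
}

#' Decision values of a fitted SVM
#'
#' @param object An `hs_svm`.
#' @param x New feature matrix.
#' @return Numeric decision values (positive = positive class side).
#' @export
svm_decision <- function(object, x) {
  x <- as.matrix(x)
  if (!nrow(object$xsv)) return(rep(object$b, nrow(x)))
  Kx <- if (object$kernel == "rbf") {
    rbf_kernel(x, object$xsv, gamma = object$gamma)
  } else linear_kernel(x, object$xsv)
  drop(Kx %*% object$coef) + object$b
}

# Platt sigmoid calibration P(y=1|f) = 1/(1+exp(A f + B)), fitted by the
# regularized Newton procedure of Lin, Lin & Weng (2007).
platt_fit <- function(f, y) {
  y01 <- ifelse(to_pm1(y) > 0, 1, 0)
  n_pos <- sum(y01 == 1); n_neg <- sum(y01 == 0)
  t <- ifelse(y01 == 1, (n_pos + 1) / (n_pos + 2), 1 / (n_neg + 2))
  a <- 0
  b <- log((n_neg + 1) / (n_pos + 1))
  fval <- function(a, b) {
    z <- a * f + b
    sum(ifelse(z >= 0, t * z + log1p(exp(-z)), (t - 1) * z + log1p(exp(z))))
  }
  obj <- fval(a, b)
  for (it in 1:100) {
    z <- a * f + b
    p <- ifelse(z >= 0, exp(-z) / (1 + exp(-z)), 1 / (1 + exp(z)))
    d1 <- t - p
    d2 <- p * (1 - p)
    g1 <- sum(f * d1); g2 <- sum(d1)
    if (abs(g1) < 1e-10 && abs(g2) < 1e-10) break
    h11 <- sum(f * f * d2) + 1e-12
    h22 <- sum(d2) + 1e-12
    h21 <- sum(f * d2)
    det <- h11 * h22 - h21^2
    da <- -(h22 * g1 - h21 * g2) / det
    db <- -(-h21 * g1 + h11 * g2) / det
    step <- 1
    repeat {
      na <- a + step * da; nb <- b + step * db
      nobj <- fval(na, nb)
      if (nobj < obj + 1e-4 * step * (g1 * da + g2 * db)) {
        a <- na; b <- nb; obj <- nobj; break
      }
      step <- step / 2
      if (step < 1e-10) break
    }
    if (step < 1e-10) break
  }
  c(A = a, B = b)
}

platt_prob <- function(platt, f) {
  z <- platt[["A"]] * f + platt[["B"]]
  ifelse(z >= 0, exp(-z) / (1 + exp(-z)), 1 / (1 + exp(z)))
}

# Deterministic stratified fold assignment: within each class, shuffled
# round-robin fold labels under the given seed.
stratified_folds <- function(y, k, seed) {
  y01 <- ifelse(to_pm1(y) > 0, 1, 0)
  folds <- integer(length(y01))
  with_seed(seed, {
    for (cls in c(0, 1)) {
      idx <- which(y01 == cls)
      folds[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
  })
  folds
}

# One cross-validation pass for (C, gamma): per-fold held-out decision
# values and AUCs. The CV score is the mean of per-fold AUCs -- pooling
# decision values across folds mixes fold-specific offsets and biases the
# null -- while the pooled out-of-fold decisions are kept for Platt
# calibration (monotone link, offsets absorbed by the sigmoid fit).
cv_rbf <- function(x, y, C, gamma, folds_id) {
  dec <- numeric(nrow(x))
  fold_auc <- c()
  for (k in sort(unique(folds_id))) {
    test <- folds_id == k
    fit <- svm_fit(x[!test, , drop = FALSE], y[!test],
                   kernel = "rbf", C = C, gamma = gamma)
    dec[test] <- svm_decision(fit, x[test, , drop = FALSE])
    fold_auc <- c(fold_auc, roc_auc(dec[test], y[test])$auc)
  }
  list(auc = mean(fold_auc), fold_auc = fold_auc, decisions = dec)
}
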