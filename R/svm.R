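# Soft-margin kernel SVM via sequential minimal optimization (simplified
# SMO, Platt-style working-pair selection). Used both by the classical RBF
# baseline and by the quantum-kernel classifier; the kernels come from the
# caller, only the convex dual solver lives here.

# k: precomputed Gram matrix; y: labels in {-1, +1}.
smo_fit <- function(k, y, cost = 1, tol = 1e-4, max_passes = 20L,
                    max_iter = 5000L) {
  n <- length(y)
  stopifnot(nrow(k) == n, all(y %in% c(-1, 1)))
  alpha <- numeric(n)
  b <- 0
  passes <- 0L
  iter <- 0L
  fcache <- function(i) sum(alpha * y * k[, i]) + b
  while (passes < max_passes && iter < max_iter) {
    changed <- 0L
    for (i in seq_len(n)) {
      ei <- fcache(i) - y[i]
      if ((y[i] * ei < -tol && alpha[i] < cost) ||
          (y[i] * ei > tol && alpha[i] > 0)) {
        j <- if (n > 1L) sample(setdiff(seq_len(n), i), 1L) else i
        if (j == i) next
        ej <- fcache(j) - y[j]
        ai_old <- alpha[i]; aj_old <- alpha[j]
        if (y[i] != y[j]) {
          lo <- max(0, aj_old - ai_old); hi <- min(cost, cost + aj_old - ai_old)
        } else {
          lo <- max(0, ai_old + aj_old - cost); hi <- min(cost, ai_old + aj_old)
        }
        if (lo >= hi) next
        eta <- 2 * k[i, j] - k[i, i] - k[j, j]
        if (eta >= 0) next
        aj <- aj_old - y[j] * (ei - ej) / eta
        aj <- min(max(aj, lo), hi)
        if (abs(aj - aj_old) < 1e-7) next
        ai <- ai_old + y[i] * y[j] * (aj_old - aj)
        alpha[i] <- ai; alpha[j] <- aj
        b1 <- b - ei - y[i] * (ai - ai_old) * k[i, i] -
          y[j] * (aj - aj_old) * k[i, j]
        b2 <- b - ej - y[i] * (ai - ai_old) * k[i, j] -
          y[j] * (aj - aj_old) * k[j, j]
        b <- if (ai > 0 && ai < cost) b1
             else if (aj > 0 && aj < cost) b2
             else (b1 + b2) / 2
        changed <- changed + 1L
      }
    }
    passes <- if (changed == 0L) passes + 1L else 0L
    iter <- iter + 1L
  }
  list(alpha = alpha, b = b)
}

rbf_kernel <- function(a, b, gamma) {
  an <- rowSums(a^2); bn <- rowSums(b^2)
  d2 <- outer(an, bn, `+`) - 2 * tcrossprod(a, b)
  exp(-gamma * pmax(d2, 0))
}

#' Radial-basis-function SVM baseline
#'
#' Classical soft-margin SVM with an RBF kernel, trained by the same SMO
#' solver as the quantum-kernel classifier. `gamma = NULL` uses the
#' scikit-learn "scale" heuristic `1 / (d * var(x))`.
#'
#' @param x Feature matrix (rows = trials).
#' @param y Binary labels (second class by first appearance is positive).
#' @param cost Soft-margin cost C.
#' @param gamma RBF width; `NULL` for the scale heuristic.
#' @param seed Seed for the SMO working-pair randomization.
#' @return An object of class `svm_model`.
#' @export
svm_fit <- function(x, y, cost = 1, gamma = NULL, seed = 1L) {
  if (is.null(dim(x))) x <- matrix(x, nrow = length(y))
  y <- as.character(y)
  classes <- unique(y)
  if (length(classes) != 2L) {
    stop_p300("SVM is binary; got %d class(es)", length(classes),
              class = "class_error")
  }
  ysign <- ifelse(y == classes[2L], 1, -1)
  if (is.null(gamma)) {
    v <- stats::var(as.vector(x))
    gamma <- if (v > 0) 1 / (ncol(x) * v) else 1
  }
  k <- rbf_kernel(x, x, gamma)
  sv <- with_seed(seed, smo_fit(k, ysign, cost = cost))
  structure(list(x = x, ysign = ysign, alpha = sv$alpha, b = sv$b,
                 gamma = gamma, cost = cost, classes = classes),
            class = "svm_model")
}

#' Predict with the RBF SVM baseline
#' @param model An `svm_model`.
#' @param x Feature matrix or single vector.
#' @return Character vector of class labels.
#' @export
svm_predict <- function(model, x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  k <- rbf_kernel(x, model$x, model$gamma)
  f <- as.vector(k %*% (model$alpha * model$ysign)) + model$b
  ifelse(f > 0, model$classes[2L], model$classes[1L])
}
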