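#' Affine-invariant Riemannian distance between SPD matrices
#'
#' `sqrt(sum(log(lambda_i)^2))` over the generalized eigenvalues of the pair
#' `(a, b)`; the geodesic distance of the affine-invariant metric. Symmetric
#' in its arguments and invariant under congruence `a -> G a G'`,
#' `b -> G b G'` for invertible `G`.
#'
#' @param a,b SPD matrices of a common size.
#' @return Nonnegative scalar, zero iff `a == b`.
#' @export
aird <- function(a, b) {
  assert_spd(a, name = "a"); assert_spd(b, name = "b")
  if (!all(dim(a) == dim(b))) {
    stop_p300("size mismatch", class = "dimension_error")
  }
  bis <- sym_power(b, -0.5)
  ev <- eigen(bis %*% a %*% bis, symmetric = TRUE, only.values = TRUE)$values
  sqrt(sum(log(ev)^2))
}

#' Minimum-distance-to-mean classifier on SPD matrices
#'
#' Fits one Karcher mean per class; prediction assigns the class whose mean
#' is nearest in the affine-invariant metric, ties broken toward the first
#' class in training order.
#'
#' @param matrices List of SPD matrices.
#' @param labels Per-matrix class labels (two or more classes, each with at
#'   least one matrix).
#' @param tol,max_iter Karcher-mean settings (shared with [riemann_mean()]).
#' @return An object of class `mdm_model`.
#' @export
mdm_fit <- function(matrices, labels, tol = 1e-8, max_iter = 50L) {
  labels <- as.character(labels)
  classes <- unique(labels)                # training order
  if (length(classes) < 2L) {
    stop_p300("need >= 2 classes", class = "class_error")
  }
  means <- lapply(classes, function(cl) {
    riemann_mean(matrices[labels == cl], tol = tol, max_iter = max_iter)
  })
  names(means) <- classes
  structure(list(class_means = means, classes = classes),
            class = "mdm_model")
}

#' Predict with an MDM model
#' @param model An `mdm_model`.
#' @param m A single SPD matrix or a list of them.
#' @return Character class label(s).
#' @export
mdm_predict <- function(model, m) {
  if (is.list(m)) return(vapply(m, function(x) mdm_predict(model, x), ""))
  if (!all(dim(m) == dim(model$class_means[[1L]]))) {
    stop_p300("matrix size %dx%d does not match training size %dx%d",
              nrow(m), ncol(m), nrow(model$class_means[[1L]]),
              ncol(model$class_means[[1L]]), class = "dimension_error")
  }
  d <- vapply(model$class_means, function(mu) aird(m, mu), 0)
  model$classes[which.min(d)]              # which.min takes the first tie
}
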