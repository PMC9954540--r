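# Symmetric-matrix functional calculus and the super-trial / tangent-space
# feature stack.

# f applied to the spectrum of a symmetric matrix
sym_fun <- function(a, f) {
  e <- eigen((a + t(a)) / 2, symmetric = TRUE)
  e$vectors %*% (f(e$values) * t(e$vectors))
}

sym_power <- function(a, p) sym_fun(a, function(v) {
  if (any(v <= 0) && p < 0) {
    stop_p300("matrix is not positive definite (min eigenvalue %.3g)", min(v),
              class = "domain_error")
  }
  sign(v) * abs(v)^p
})

spd_logm <- function(a) sym_fun(a, function(v) {
  if (any(v <= 0)) {
    stop_p300("matrix logarithm requires positive definiteness (min eigenvalue %.3g)",
              min(v), class = "domain_error")
  }
  log(v)
})

spd_expm <- function(a) sym_fun(a, exp)

assert_spd <- function(a, tol = 1e-10, name = "matrix") {
  if (!is.matrix(a) || nrow(a) != ncol(a)) {
    stop_p300("`%s` must be square", name, class = "dimension_error")
  }
  if (max(abs(a - t(a))) > tol * max(1, max(abs(a)))) {
    stop_p300("`%s` is not symmetric", name, class = "domain_error")
  }
  ev <- eigen((a + t(a)) / 2, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) {
    stop_p300("`%s` is not positive definite (min eigenvalue %.3g)", name,
              min(ev), class = "domain_error")
  }
  invisible(TRUE)
}

#' Build a super-trial from a filtered epoch and a prototype
#'
#' Stacks the (filtered) temporal prototype of the TARGET response on top of
#' the (filtered) epoch: with one xDAWN filter per class both blocks have 2
#' rows and the super-trial is 4 x T, whose correlation matrix is the 4 x 4
#' SPD feature of the pipeline.
#'
#' @param filtered_epoch p x T matrix (virtual channels x samples).
#' @param prototype q x T matrix, same sample count.
#' @return (q + p) x T matrix, prototype rows first.
#' @export
build_supertrial <- function(filtered_epoch, prototype) {
  if (ncol(filtered_epoch) != ncol(prototype)) {
    stop_p300("sample counts differ: epoch %d, prototype %d",
              ncol(filtered_epoch), ncol(prototype),
              class = "dimension_error")
  }
  rbind(prototype, filtered_epoch)
}

#' Shrunk correlation matrix of a super-trial
#'
#' Computes the sample correlation matrix across rows (time courses),
#' optionally mean-centering each row first (the standard definition), then
#' applies shrinkage `(1 - eps) C + eps I` so the result is strictly
#' positive definite. A constant (zero-variance) row is degenerate for
#' correlation; a tiny jitter (1e-12 RMS) is added to such rows with a
#' warning.
#'
#' @param supertrial n x T matrix with T >= 2.
#' @param shrinkage Shrinkage weight toward the identity.
#' @param center Mean-center rows before correlating (default TRUE).
#' @return n x n SPD matrix with unit diagonal.
#' @export
correlation_spd <- function(supertrial, shrinkage = 1e-6, center = TRUE) {
  if (ncol(supertrial) < 2L) {
    stop_p300("need >= 2 samples to correlate", class = "dimension_error")
  }
  x <- supertrial
  if (center) x <- x - rowMeans(x)
  sds <- sqrt(rowSums(x^2))
  if (any(sds == 0)) {
    warning("constant row(s) in super-trial; adding 1e-12 jitter",
            call. = FALSE)
    bad <- which(sds == 0)
    jit <- matrix(stats::rnorm(length(bad) * ncol(x), sd = 1e-12),
                  nrow = length(bad))
    x[bad, ] <- x[bad, ] + if (center) jit - rowMeans(jit) else jit
    sds <- sqrt(rowSums(x^2))
  }
  x <- x / sds
  c0 <- tcrossprod(x)
  c0 <- (c0 + t(c0)) / 2
  diag(c0) <- 1
  (1 - shrinkage) * c0 + shrinkage * diag(nrow(c0))
}

#' Riemannian (Karcher) mean of SPD matrices
#'
#' Fixed point of the affine-invariant gradient iteration
#' `M <- M^{1/2} exp(mean_i log(M^{-1/2} A_i M^{-1/2})) M^{1/2}`,
#' initialized at the arithmetic mean and stopped when the Frobenius norm of
#' the mean log (the Riemannian gradient) falls below `tol`.
#'
#' @param matrices List of SPD matrices of a common size (or a 3D array
#'   n x n x k).
#' @param tol Gradient-norm stopping tolerance.
#' @param max_iter Maximum iterations; non-convergence is an error reporting
#'   the last gradient norm.
#' @return The SPD mean matrix.
#' @export
riemann_mean <- function(matrices, tol = 1e-8, max_iter = 50L) {
  if (is.array(matrices) && length(dim(matrices)) == 3L) {
    matrices <- lapply(seq_len(dim(matrices)[3L]),
                       function(k) matrices[, , k])
  }
  if (length(matrices) == 0L) {
    stop_p300("empty matrix list", class = "parameter_error")
  }
  if (length(matrices) == 1L) return(matrices[[1L]])
  m <- Reduce(`+`, matrices) / length(matrices)
  for (it in seq_len(max_iter)) {
    ms <- sym_power(m, 0.5)
    mis <- sym_power(m, -0.5)
    g <- Reduce(`+`, lapply(matrices,
                            function(a) spd_logm(mis %*% a %*% mis))) /
      length(matrices)
    gnorm <- sqrt(sum(g^2))
    if (gnorm < tol) return(m)
    m <- ms %*% spd_expm(g) %*% ms
    m <- (m + t(m)) / 2
  }
  stop_p300("Karcher mean did not converge in %d iterations (gradient norm %.3g)",
            max_iter, gnorm, class = "convergence_error")
}

# indices of the upper triangle (row-major over i <= j) of an n x n matrix
upper_tri_rowmajor <- function(n, diag = TRUE) {
  idx <- which(upper.tri(matrix(0, n, n), diag = diag), arr.ind = TRUE)
  idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
}

#' Project an SPD matrix into the tangent space at a base point
#'
#' Computes `L = logm(base^{-1/2} %*% m %*% base^{-1/2})` and returns its
#' upper-triangular half-vectorization (row-major, diagonal first within
#' each row) with off-diagonal entries scaled by sqrt(2), so the Euclidean
#' norm of the vector equals the affine-invariant Riemannian distance
#' between `m` and `base`. A 4 x 4 matrix yields a 10-element vector.
#'
#' @param m SPD matrix.
#' @param base SPD base point (typically the [riemann_mean()] of the
#'   training matrices).
#' @return Numeric vector of length `n (n + 1) / 2`.
#' @export
tangent_project <- function(m, base) {
  assert_spd(m, name = "m"); assert_spd(base, name = "base")
  if (!all(dim(m) == dim(base))) {
    stop_p300("size mismatch between matrix and base", class = "dimension_error")
  }
  bis <- sym_power(base, -0.5)
  l <- spd_logm(bis %*% m %*% bis)
  n <- nrow(l)
  idx <- upper_tri_rowmajor(n)
  w <- ifelse(idx[, 1L] == idx[, 2L], 1, sqrt(2))
  w * l[idx]
}

#' Inverse of [tangent_project()]
#'
#' Rebuilds the symmetric log-matrix from the weighted half-vectorization,
#' exponentiates and undoes the base-point congruence.
#'
#' @param v Tangent vector of length `n (n + 1) / 2`.
#' @param base SPD base point used for the projection.
#' @return The SPD matrix whose projection at `base` is `v`.
#' @export
tangent_unproject <- function(v, base) {
  n <- nrow(base)
  if (length(v) != n * (n + 1) / 2) {
    stop_p300("tangent vector length %d does not match base size %d",
              length(v), n, class = "dimension_error")
  }
  idx <- upper_tri_rowmajor(n)
  w <- ifelse(idx[, 1L] == idx[, 2L], 1, sqrt(2))
  l <- matrix(0, n, n)
  l[idx] <- v / w
  l <- l + t(l) - diag(diag(l))
  bs <- sym_power(base, 0.5)
  s <- bs %*% spd_expm(l) %*% bs
  (s + t(s)) / 2
}

#' Reduced flat vector of a super-trial correlation matrix
#'
#' Drops the entries of the correlation matrix that carry no per-trial
#' information: the unit diagonal and the prototype-prototype block, which
#' depends only on the (shared) temporal prototype. What remains is the
#' prototype x epoch cross-block (row-major) followed by the strict upper
#' triangle of the epoch block (row-major). For the canonical n = 4, p = 2
#' this is a 5-element vector.
#'
#' @param corr n x n correlation matrix of a super-trial.
#' @param prototype_rows Number of leading rows occupied by the prototype
#'   block (p); must satisfy p < n.
#' @return Numeric vector of length `n(n+1)/2 - n - p(p-1)/2`.
#' @export
flatten_reduced <- function(corr, prototype_rows) {
  n <- nrow(corr)
  p <- assert_count(prototype_rows, "prototype_rows")
  if (p >= n) {
    stop_p300("prototype_rows (%d) must be < matrix size (%d)", p, n,
              class = "dimension_error")
  }
  cross <- as.vector(t(corr[seq_len(p), (p + 1):n, drop = FALSE]))
  ep <- corr[(p + 1):n, (p + 1):n, drop = FALSE]
  m <- nrow(ep)
  upper <- if (m > 1L) ep[upper_tri_rowmajor(m, diag = FALSE)] else numeric(0)
  c(cross, upper)
}

#' Flatten an epoch to a plain vector
#'
#' Row-major concatenation of the (virtual) channels of one epoch; the
#' "epoch vector" input variant of the case-based classifier.
#'
#' @param epoch channels x samples matrix.
#' @return Numeric vector of length `channels * samples`.
#' @export
flatten_epoch <- function(epoch) as.vector(t(epoch))
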