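# Independent dense-matrix simulator used as the oracle for the fast
# statevector code. Every gate is an explicit 2^n x 2^n complex matrix and
# circuits are plain matrix products; nothing here shares code with the
# package's reshaping/diagonal-fusion implementation.

oracle_gate1 <- function(n, q, u) {
  # qubit 1 is the fastest-varying index: it is the last kron factor
  kronecker(diag(2^(n - q)), kronecker(u, diag(2^(q - 1))))
}

oracle_h <- function(n, q) oracle_gate1(n, q, matrix(c(1, 1, 1, -1), 2) / sqrt(2))
oracle_p <- function(n, q, phi) oracle_gate1(n, q, diag(c(1, exp(1i * phi))))
oracle_ry <- function(n, q, th) {
  oracle_gate1(n, q, matrix(c(cos(th / 2), sin(th / 2),
                              -sin(th / 2), cos(th / 2)), 2))
}
oracle_rz <- function(n, q, th) {
  oracle_gate1(n, q, diag(c(exp(-1i * th / 2), exp(1i * th / 2))))
}

# CX as an explicit permutation of basis states
oracle_cx <- function(n, control, target) {
  m <- matrix(0, 2^n, 2^n)
  for (k in 0:(2^n - 1)) {
    kk <- if (bitwAnd(bitwShiftR(k, control - 1L), 1L) == 1L) {
      bitwXor(k, bitwShiftL(1L, target - 1L))
    } else k
    m[kk + 1L, k + 1L] <- 1
  }
  m
}

oracle_cz <- function(n, q1, q2) {
  d <- rep(1 + 0i, 2^n)
  for (k in 0:(2^n - 1)) {
    if (bitwAnd(bitwShiftR(k, q1 - 1L), 1L) == 1L &&
        bitwAnd(bitwShiftR(k, q2 - 1L), 1L) == 1L) d[k + 1L] <- -1
  }
  diag(d)
}

# ZZ feature map as literal gate products, pair term via CX-P-CX
oracle_zz_feature_map <- function(x, reps = 2, entanglement = "linear") {
  n <- length(x)
  pairs <- if (n < 2) matrix(integer(0), ncol = 2)
           else if (entanglement == "linear") cbind(1:(n - 1), 2:n)
           else t(utils::combn(n, 2))
  u <- diag(2^n)
  for (r in seq_len(reps)) {
    for (q in 1:n) u <- oracle_h(n, q) %*% u
    for (q in 1:n) u <- oracle_p(n, q, 2 * x[q]) %*% u
    if (nrow(pairs)) {
      for (k in seq_len(nrow(pairs))) {
        i <- pairs[k, 1]; j <- pairs[k, 2]
        u <- oracle_cx(n, i, j) %*% u
        u <- oracle_p(n, j, 2 * (pi - x[i]) * (pi - x[j])) %*% u
        u <- oracle_cx(n, i, j) %*% u
      }
    }
  }
  e1 <- rep(0 + 0i, 2^n); e1[1] <- 1
  as.vector(u %*% e1)
}

# two-local ansatz as literal gate products
oracle_ansatz <- function(state, theta, n, reps = 3,
                          rotation_blocks = c("ry", "rz"),
                          entanglement = "full") {
  pairs <- if (n < 2) matrix(integer(0), ncol = 2)
           else if (entanglement == "linear") cbind(1:(n - 1), 2:n)
           else t(utils::combn(n, 2))
  k <- 0
  rot <- function(state) {
    for (g in rotation_blocks) {
      for (q in 1:n) {
        k <<- k + 1
        u <- if (g == "ry") oracle_ry(n, q, theta[k]) else oracle_rz(n, q, theta[k])
        state <- as.vector(u %*% state)
      }
    }
    state
  }
  for (r in seq_len(reps)) {
    state <- rot(state)
    if (nrow(pairs)) {
      for (pk in seq_len(nrow(pairs))) {
        state <- as.vector(oracle_cz(n, pairs[pk, 1], pairs[pk, 2]) %*% state)
      }
    }
  }
  rot(state)
}

oracle_parity_probs <- function(state, n) {
  par <- vapply(0:(2^n - 1), function(k) {
    sum(bitwAnd(bitwShiftR(k, 0:(n - 1)), 1L)) %% 2L
  }, 0L)
  c(pos = sum(Mod(state[par == 0L])^2), neg = sum(Mod(state[par == 1L])^2))
}
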