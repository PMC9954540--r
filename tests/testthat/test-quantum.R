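test_that("the feature map preserves norm; one repetition is phase-only", {
  for (n in 2:4) {
    # a single repetition ends in diagonal phases, so magnitudes stay
    # uniform for any input (including x = 0)
    s0 <- zz_feature_map(rep(0, n), feature_map_spec(n, reps = 1))
    expect_equal(Mod(s0), rep(2^(-n / 2), 2^n), tolerance = 1e-10)
    set.seed(n)
    x <- stats::runif(n, -1, 2)
    s1 <- zz_feature_map(x, feature_map_spec(n, reps = 1))
    expect_equal(Mod(s1), rep(2^(-n / 2), 2^n), tolerance = 1e-10)
    # at the canonical reps = 2 the second Hadamard layer interferes the
    # pair phases, so only the norm is preserved
    s2 <- zz_feature_map(x, feature_map_spec(n))
    expect_equal(sum(Mod(s2)^2), 1, tolerance = 1e-10)
  }
  expect_error(zz_feature_map(c(1, 2), feature_map_spec(3)),
               class = "dimension_error")
})

test_that("feature map and ansatz agree with the dense-matrix oracle", {
  # feature map, n = 2, the canonical reps = 2 linear entanglement
  x <- c(0.5, 1.0)
  expect_equal(zz_feature_map(x, feature_map_spec(2)),
               oracle_zz_feature_map(x, reps = 2), tolerance = 1e-10)
  # larger instances, both entanglement patterns
  set.seed(21)
  for (n in 2:4) {
    for (ent in c("linear", "full")) {
      xx <- stats::runif(n, -2, 2)
      expect_equal(zz_feature_map(xx, feature_map_spec(n, entanglement = ent)),
                   oracle_zz_feature_map(xx, reps = 2, entanglement = ent),
                   tolerance = 1e-10)
    }
  }
  # ansatz + parity readout on random parameters
  for (n in 2:4) {
    an <- ansatz_spec(n)
    th <- stats::runif(n_ansatz_params(an), -pi, pi)
    psi <- zz_feature_map(rep(0.3, n), feature_map_spec(n))
    fast <- apply_ansatz(psi, th, an)
    dense <- oracle_ansatz(psi, th, n, reps = 3)
    expect_equal(fast, dense, tolerance = 1e-10)
    expect_equal(sum(Mod(fast)^2), 1, tolerance = 1e-10)
    p <- vqc_forward(rep(0.3, n), th, feature_map_spec(n), an)
    expect_equal(unname(p), unname(oracle_parity_probs(dense, n)),
                 tolerance = 1e-10)
  }
})

test_that("kernel values behave as fidelities", {
  set.seed(5)
  x <- stats::runif(3); y <- stats::runif(3)
  spec <- feature_map_spec(3)
  expect_equal(quantum_kernel(x, x, spec), 1, tolerance = 1e-10)
  expect_identical(quantum_kernel(x, y, spec), quantum_kernel(y, x, spec))
  expect_error(quantum_kernel(x, y, spec, shots = -1),
               class = "parameter_error")

  # shot estimates at R = 1024 land within 0.05 of exact for >= 95/100 pairs
  hits <- vapply(1:100, function(i) {
    set.seed(i)
    a <- stats::runif(2, -1, 1); b <- stats::runif(2, -1, 1)
    sp <- feature_map_spec(2)
    abs(quantum_kernel(a, b, sp, shots = 1024, seed = i) -
          quantum_kernel(a, b, sp)) < 0.05
  }, TRUE)
  expect_gte(mean(hits), 0.95)
})

test_that("exact Gram matrices are unit-diagonal and PSD", {
  expect_equal(kernel_matrix(matrix(0.7, 1, 1), feature_map_spec(1)),
               matrix(1, 1, 1), tolerance = 1e-12)
  set.seed(12)
  x <- matrix(stats::runif(50 * 10, -1, 1), 50)   # the 10-qubit case
  g <- kernel_matrix(x)
  expect_equal(diag(g), rep(1, 50), tolerance = 1e-12)
  ev <- eigen((g + t(g)) / 2, symmetric = TRUE, only.values = TRUE)$values
  expect_gte(min(ev), -1e-8)

  # duplicated input rows give identical Gram rows
  xd <- rbind(x[1:5, ], x[2, ])
  gd <- kernel_matrix(xd)
  expect_equal(gd[6, ], gd[2, ], tolerance = 1e-12)
})

test_that("shot-mode Gram error shrinks as shots grow", {
  set.seed(30)
  x <- matrix(stats::runif(8 * 3, -1, 1), 8)
  g_exact <- kernel_matrix(x)
  err <- function(shots) {
    e <- vapply(1:10, function(i) {
      max(abs(kernel_matrix(x, shots = shots, seed = 100 + i) - g_exact))
    }, 0)
    mean(e)
  }
  expect_gt(err(256), 1.5 * err(4096))      # ~halves when R quadruples
})

test_that("QSVC separates kernel-orthogonal clusters and degenerates at C -> 0", {
  # seeded search for two anchors with tiny cross-kernel, then tight clusters
  spec <- feature_map_spec(2)
  set.seed(17)
  u <- stats::runif(2, -1, 1)
  repeat {
    v <- stats::runif(2, -3, 3)
    if (quantum_kernel(u, v, spec) < 0.1) break
  }
  xs <- rbind(t(replicate(6, u + stats::rnorm(2, sd = 0.01))),
              t(replicate(6, v + stats::rnorm(2, sd = 0.01))))
  within_ok <- min(kernel_matrix(xs[1:6, ], spec)) > 0.9 &&
    min(kernel_matrix(xs[7:12, ], spec)) > 0.9
  expect_true(within_ok)
  y <- rep(c("A", "B"), each = 6)
  m <- qsvc_fit(xs, y, spec)
  expect_identical(qsvc_predict(m, xs), y)

  m0 <- qsvc_fit(xs, y, spec, cost = 1e-6)
  expect_true(all(m0$alpha <= 1e-6 + 1e-12))          # all duals at bound
  # the kernel term is bounded by n * C, so the decision collapses onto the
  # bias as C -> 0
  k0 <- kernel_matrix(xs, spec)
  f0 <- as.vector(k0 %*% (m0$alpha * m0$ysign)) + m0$b
  expect_true(all(abs(f0 - m0$b) <= length(y) * 1e-6))

  # exact kernel vs high-shot kernel agree on a 12-point toy
  mshot <- qsvc_fit(xs, y, spec, shots = 1e5, seed = 3)
  expect_identical(qsvc_predict(mshot, xs), qsvc_predict(m, xs))
  expect_error(qsvc_fit(xs, rep("A", 12), spec), class = "class_error")
})

test_that("zero rotations leave the feature-map parity distribution alone", {
  n <- 3
  an <- ansatz_spec(n)
  x0 <- rep(0, n)
  p <- vqc_forward(x0, rep(0, n_ansatz_params(an)), feature_map_spec(n), an)
  bare <- oracle_parity_probs(zz_feature_map(x0, feature_map_spec(n)), n)
  expect_equal(unname(p), unname(bare), tolerance = 1e-10)
  expect_equal(sum(p), 1, tolerance = 1e-10)
})

test_that("SPSA recovers a quadratic minimum and is seed-deterministic", {
  target <- c(1, -2, 0.5, 3, -1)
  obj <- function(th) sum((th - target)^2)
  th0 <- target + c(1, -1, 1, -1, 1) / sqrt(5)
  expect_identical(spsa_minimize(obj, th0, maxiter = 0), th0)
  expect_identical(spsa_minimize(obj, th0, maxiter = 50, seed = 4),
                   spsa_minimize(obj, th0, maxiter = 50, seed = 4))
  ok <- vapply(1:50, function(seed) {
    th <- spsa_minimize(obj, th0, c0 = 4, maxiter = 500, seed = seed)
    sqrt(sum((th - target)^2)) < 0.1
  }, TRUE)
  expect_gte(mean(ok), 0.9)
  expect_error(spsa_minimize(obj, th0, maxiter = -1), class = "parameter_error")
})

test_that("VQC learns labels drawn from its own circuit family", {
  n <- 2
  set.seed(33)
  x <- matrix(stats::runif(24 * n, -1, 1), 24)
  fm <- feature_map_spec(n)
  an <- ansatz_spec(n)
  # labels from the untrained (seed-initialized) circuit itself
  seed <- 5
  theta0 <- with_seed(seed, stats::runif(n_ansatz_params(an), -pi, pi))
  p0 <- vapply(seq_len(nrow(x)),
               function(j) vqc_forward(x[j, ], theta0, fm, an)["pos"], 0)
  y <- ifelse(p0 > 0.5, "pos", "neg")
  if (length(unique(y)) == 2) {
    m <- vqc_fit(x, y, fm, an, maxiter = 30, seed = seed)
    acc <- mean(vqc_predict(m, x) == y)
    expect_gte(acc, 0.95)
    expect_gte(m$bias, -1); expect_lte(m$bias, 1)
  }

  # label-shuffled data shows no structure
  set.seed(1)
  xx <- matrix(stats::runif(40 * n, -1, 1), 40)
  baccs <- vapply(1:5, function(s) {
    set.seed(s)
    ys <- sample(rep(c("pos", "neg"), 20))
    m <- vqc_fit(xx, ys, fm, an, maxiter = 20, seed = s)
    balanced_accuracy(ys, vqc_predict(m, xx))
  }, 0)
  expect_true(all(baccs >= 0.4 & baccs <= 0.7))
  expect_error(vqc_fit(x, rep("pos", 24), fm, an), class = "class_error")
})

test_that("a 20 x 20 exact kernel on 10 qubits completes quickly", {
  set.seed(44)
  x <- matrix(stats::runif(20 * 10, -1, 1), 20)
  t0 <- proc.time()["elapsed"]
  g <- kernel_matrix(x)
  expect_lt(proc.time()["elapsed"] - t0, 60)
  expect_identical(dim(g), c(20L, 20L))
})
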