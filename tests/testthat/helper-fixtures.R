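# Shared fixtures, built in code at test time.

# A session small enough for fast CV: n_targets x reps x 12 flashes.
small_session <- function(amplitude = 8, noise_scale = 2, seed = 1,
                          n_targets = 1, reps = 5) {
  d <- session_design(n_targets = n_targets,
                      n_repetitions_per_target = reps)
  generate_session(d, p300_params(amplitude = amplitude),
                   noise_scale = noise_scale, seed = seed)
}

small_epochs <- function(...) preprocess_session(small_session(...))

# Moore-Penrose pseudo-inverse via SVD (no extra dependencies)
MASS_ginv <- function(x, tol = 1e-10) {
  s <- svd(x)
  keep <- s$d > tol * max(s$d)
  s$v[, keep, drop = FALSE] %*% (t(s$u[, keep, drop = FALSE]) / s$d[keep])
}

# Random SPD matrix with log-spectrum sd `spread`
random_spd <- function(n, spread = 1) {
  q <- qr.Q(qr(matrix(stats::rnorm(n * n), n)))
  q %*% diag(exp(stats::rnorm(n, sd = spread))) %*% t(q)
}

# SPD matrices scattered around `center` with dispersion `disp`
spd_cluster <- function(center, k, disp = 0.1) {
  cs <- sym_power(center, 0.5)
  lapply(seq_len(k), function(i) {
    v <- matrix(stats::rnorm(nrow(center)^2, sd = disp), nrow(center))
    v <- (v + t(v)) / 2
    m <- cs %*% spd_expm(v) %*% cs
    (m + t(m)) / 2
  })
}

# Separable HCBR toy: token "1:<digits>" carries the class, remaining
# tokens are unique per case, so training support has the true sign by
# construction.
separable_cases <- function(n_cases = 20, digits = 4) {
  labels <- rep(c("A", "B"), length.out = n_cases)
  cases <- lapply(seq_len(n_cases), function(j) {
    x <- c(if (labels[j] == "B") 1 else 0,   # discriminative feature
           j + c(0.1, 0.2, 0.3))             # unique filler per case
    hcbr_discretize(x, digits = digits)
  })
  list(cases = cases, labels = labels)
}

# Overlapping-token toy (small value alphabet) for label-shuffle nulls:
# cases share tokens heavily so memorization is impossible.
overlapping_cases <- function(n_cases = 60, n_features = 8) {
  cases <- lapply(seq_len(n_cases), function(j) {
    hcbr_discretize(sample(c(0, 0.1, 0.2), n_features, replace = TRUE),
                    digits = 4)
  })
  cases
}
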