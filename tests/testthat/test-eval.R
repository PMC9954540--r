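test_that("balanced accuracy matches its defining formula", {
  expect_equal(balanced_accuracy(c("T", "N", "T", "N"), c("T", "N", "T", "N")),
               1.0)
  # constant predictor is exactly 0.5 whatever the imbalance
  yt <- c(rep("N", 90), rep("T", 10))
  expect_equal(balanced_accuracy(yt, rep("N", 100)), 0.5)
  # A = 600 correct NON-TARGET, B = 40, C = 32 correct TARGET, D = 96:
  # 0.5 * (600/640 + 32/128) = 0.59375
  y_true <- c(rep("NON-TARGET", 640), rep("TARGET", 128))
  y_pred <- c(rep("NON-TARGET", 600), rep("TARGET", 40),
              rep("TARGET", 32), rep("NON-TARGET", 96))
  expect_equal(balanced_accuracy(y_true, y_pred), 0.59375)
  expect_error(balanced_accuracy(rep("T", 5), rep("T", 5)),
               class = "class_error")
  expect_error(balanced_accuracy(c("T", "N"), "T"), class = "parameter_error")
})

test_that("stratified folds keep per-fold class balance within one trial", {
  labels <- c(rep("NON-TARGET", 640), rep("TARGET", 128))
  f <- stratified_kfold(labels, k = 5, seed = 3)
  for (i in 1:5) {
    expect_identical(sum(f == i & labels == "NON-TARGET"), 128L)
    expect_true(sum(f == i & labels == "TARGET") %in% c(25L, 26L))
  }
  expect_identical(f, stratified_kfold(labels, k = 5, seed = 3))
  expect_false(identical(f, stratified_kfold(labels, k = 5, seed = 4)))

  # leave-one-out per class at the boundary
  lab2 <- rep(c("A", "B"), each = 4)
  f2 <- stratified_kfold(lab2, k = 4, seed = 1)
  for (i in 1:4) expect_identical(sum(f2 == i), 2L)
  expect_error(stratified_kfold(lab2, k = 5), class = "stratification_error")
})

test_that("cv_evaluate reports per-fold scores with strict train/test split", {
  ep <- small_epochs(seed = 6)
  r <- cv_evaluate(ep, "mdm", seed = 2, return_models = TRUE)
  expect_s3_class(r, "cv_report")
  expect_identical(nrow(r$folds), 5L)
  expect_true(all(r$folds$train_bacc >= 0 & r$folds$train_bacc <= 1))
  expect_true(all(r$folds$test_bacc >= 0 & r$folds$test_bacc <= 1))

  # leakage check: junk in the test trials of fold 1 cannot change the
  # pipeline or classifier fitted for fold 1
  folds <- stratified_kfold(ep$labels, k = 5, seed = 2)
  ep_junk <- ep
  ep_junk$data[folds == 1, , ] <- 1e3 * array(
    stats::rnorm(sum(folds == 1) * prod(dim(ep$data)[2:3])),
    dim = c(sum(folds == 1), dim(ep$data)[2], dim(ep$data)[3]))
  r2 <- cv_evaluate(ep_junk, "mdm", seed = 2, return_models = TRUE)
  expect_identical(r2$models[[1]]$pipeline, r$models[[1]]$pipeline)
  expect_identical(r2$models[[1]]$model, r$models[[1]]$model)
  expect_identical(r2$folds$train_bacc[1], r$folds$train_bacc[1])

  expect_error(cv_evaluate(ep, "nonesuch"), class = "config_error")
})

test_that("high-SNR sessions are recovered by the baselines", {
  ep <- small_epochs(amplitude = 10, noise_scale = 1, seed = 3)
  expect_gte(cv_evaluate(ep, "mdm", seed = 1)$mean_test, 0.8)
  expect_gte(cv_evaluate(ep, "svm", seed = 1)$mean_test, 0.8)
})

test_that("the permutation threshold is seeded and handles degenerates", {
  ep <- small_epochs(amplitude = 0, seed = 10, n_targets = 1, reps = 3)
  pt <- permutation_threshold(ep, classifier = "constant", n_perm = 6,
                              seed = 5)
  expect_equal(pt$scores, rep(0.5, 6))
  expect_equal(pt$threshold, 0.5)
  pt2 <- permutation_threshold(ep, classifier = "constant", n_perm = 6,
                               seed = 5)
  expect_identical(pt, pt2)
  expect_error(permutation_threshold(ep, n_perm = 0), class = "parameter_error")
})

test_that("the null permutation threshold matches a fresh-data Monte-Carlo oracle", {
  # Dual route: the label-permutation threshold on one null session should
  # estimate the same 0.975 quantile as direct simulation of the null
  # (fresh zero-amplitude sessions, true labels). 100 draws per route.
  d <- session_design(n_targets = 1, n_repetitions_per_target = 5)
  null_ep <- function(seed) {
    preprocess_session(generate_session(d, p300_params(amplitude = 0),
                                        noise_scale = 4, seed = seed))
  }
  perm <- permutation_threshold(null_ep(1), classifier = "mdm",
                                n_perm = 100, seed = 1)$threshold
  oracle_scores <- vapply(1:100, function(s) {
    cv_evaluate(null_ep(100 + s), "mdm", seed = s)$mean_test
  }, 0)
  oracle <- sort(oracle_scores)[ceiling(0.975 * 100)]
  # The permutation route is conservative here: epochs overlap in time and
  # the noise is autocorrelated, so permuted labels that clump in time are
  # genuinely more predictable than the evenly spread true labels. The
  # threshold must therefore sit at or above the marginal null quantile,
  # close to it, and inside the chance neighbourhood.
  expect_gte(perm, oracle - 0.02)
  expect_lt(perm - oracle, 0.15)
  expect_gt(perm, 0.5)      # strictly above chance
  expect_lt(perm, 0.7)      # but well below a real effect
})

test_that("run_experiment assembles all five classifiers end to end", {
  cfg <- list(design = list(n_targets = 1, n_repetitions_per_target = 3),
              amplitude = 6, noise_scale = 2, seed = 4, k = 3,
              classifiers = c("mdm", "svm", "hcbr", "vqc", "qsvc"),
              maxiter = 4)               # scaled-down SPSA for test speed
  res <- run_experiment(cfg)
  expect_length(res$reports, 5L)
  for (r in res$reports) expect_identical(nrow(r$folds), 3L)
  expect_identical(nrow(res$table), 5L)
  expect_true(all(res$table$mean_test >= 0 & res$table$mean_test <= 1))
  expect_error(run_experiment(list(classifiers = "lda")),
               class = "config_error")
})

test_that("the digits x nfilter sweep emits the full 3 x 3 grid", {
  ep <- small_epochs(seed = 12, n_targets = 1, reps = 3)
  grid <- sweep_digits_filters(ep, k = 3, seed = 2)
  expect_identical(nrow(grid), 9L)
  expect_setequal(unique(grid$digits), c(4L, 6L, 8L))
  expect_setequal(unique(grid$nfilter), c(1L, 2L, 4L))
  expect_true(all(is.finite(grid$test_bacc)))
})

test_that("feature CSVs put one trial per row with the label last", {
  ep <- small_epochs(seed = 13, n_targets = 1, reps = 2)
  pipe <- feature_pipeline_fit(ep, mode = "tangent")
  ft <- feature_transform(pipe, ep)
  path <- withr::local_tempfile(fileext = ".csv")
  write_features_csv(ft, ep$labels, path)
  back <- utils::read.csv(path, check.names = FALSE)
  expect_identical(nrow(back), n_trials(ep))
  expect_identical(names(back)[ncol(back)], "label")
  expect_equal(as.matrix(back[, -ncol(back)]), ft, ignore_attr = TRUE,
               tolerance = 1e-12)
})
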