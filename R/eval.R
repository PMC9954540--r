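#' Balanced accuracy
#'
#' Mean of the per-class recalls: with A and B the correctly and
#' incorrectly classified NON-TARGET epochs and C and D the correctly and
#' incorrectly classified TARGET epochs, this is
#' `0.5 * (A / (A + B) + C / (C + D))`. Robust to the 640:128 class
#' imbalance; a constant predictor scores exactly 0.5.
#'
#' @param y_true True labels containing both classes.
#' @param y_pred Predicted labels, same length.
#' @return Scalar in [0, 1].
#' @export
balanced_accuracy <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) {
    stop_p300("length mismatch: %d true vs %d predicted", length(y_true),
              length(y_pred), class = "parameter_error")
  }
  y_true <- as.character(y_true); y_pred <- as.character(y_pred)
  classes <- unique(y_true)
  if (length(classes) < 2L) {
    stop_p300("y_true must contain both classes", class = "class_error")
  }
  recalls <- vapply(classes, function(cl) {
    mean(y_pred[y_true == cl] == cl)
  }, 0)
  mean(recalls)
}

#' Stratified k-fold assignment
#'
#' Shuffles each class independently (seeded) and deals its trials
#' round-robin over the folds, so per-fold class counts differ from the
#' ideal proportion by at most one trial. Deterministic given the seed.
#'
#' @param labels Trial labels.
#' @param k Number of folds.
#' @param seed RNG seed.
#' @return Integer vector of fold ids in `1..k`.
#' @export
stratified_kfold <- function(labels, k = 5L, seed = 1L) {
  k <- assert_count(k, "k")
  labels <- as.character(labels)
  counts <- table(labels)
  if (any(counts < k)) {
    stop_p300("class `%s` has %d trials, fewer than k = %d",
              names(counts)[which.min(counts)], min(counts), k,
              class = "stratification_error")
  }
  folds <- integer(length(labels))
  with_seed(seed, {
    for (cl in names(counts)) {
      idx <- sample(which(labels == cl))
      folds[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  folds
}

# ---- feature pipeline ---------------------------------------------------

#' Fit the feature-extraction pipeline on training epochs
#'
#' Estimates per-class xDAWN filters, the filtered TARGET prototype, and —
#' for tangent features — the Riemannian mean of the training super-trial
#' correlation matrices (the tangent base point). Everything is fitted on
#' the training epochs only, so the transform can be applied to held-out
#' trials without leakage.
#'
#' @param epochs Training [epoch_set()].
#' @param mode `"matrices"` (SPD correlation matrices), `"tangent"`
#'   (tangent-space vectors), `"reduced"` (flat correlation vectors with
#'   redundant entries removed) or `"epochvec"` (flattened filtered
#'   epochs).
#' @param nfilter xDAWN filters per class.
#' @param shrinkage Correlation shrinkage passed to [correlation_spd()].
#' @param target_class Class whose evoked response is the prototype.
#' @return An object of class `feature_pipeline`.
#' @export
feature_pipeline_fit <- function(epochs, mode = c("tangent", "matrices",
                                                  "reduced", "epochvec"),
                                 nfilter = 1L, shrinkage = 1e-6,
                                 target_class = "TARGET") {
  mode <- match.arg(mode)
  xd <- fit_xdawn(epochs, nfilter = nfilter)
  if (!target_class %in% xd$classes) {
    stop_p300("target class `%s` absent from training data", target_class,
              class = "class_error")
  }
  proto <- apply_filters(xd, xd$prototypes[[target_class]])
  pipe <- list(mode = mode, xdawn = xd, prototype = proto,
               prototype_rows = nrow(proto), shrinkage = shrinkage,
               base = NULL)
  if (mode == "tangent") {
    mats <- supertrial_correlations(pipe, epochs)
    pipe$base <- riemann_mean(mats)
  }
  structure(pipe, class = "feature_pipeline")
}

supertrial_correlations <- function(pipe, epochs) {
  lapply(seq_len(n_trials(epochs)), function(j) {
    filt <- apply_filters(pipe$xdawn, epochs$data[j, , ])
    correlation_spd(build_supertrial(filt, pipe$prototype),
                    shrinkage = pipe$shrinkage)
  })
}

#' Apply a fitted feature pipeline to epochs
#'
#' @param pipe A `feature_pipeline`.
#' @param epochs An [epoch_set()] (train or held-out).
#' @return For mode `"matrices"` a list of SPD matrices; otherwise a
#'   numeric matrix with one feature row per trial.
#' @export
feature_transform <- function(pipe, epochs) {
  if (pipe$mode == "epochvec") {
    return(t(vapply(seq_len(n_trials(epochs)), function(j) {
      flatten_epoch(apply_filters(pipe$xdawn, epochs$data[j, , ]))
    }, numeric(pipe$prototype_rows * dim(epochs$data)[3L]))))
  }
  mats <- supertrial_correlations(pipe, epochs)
  switch(pipe$mode,
         matrices = mats,
         tangent = t(vapply(mats, tangent_project, base = pipe$base,
                            numeric(nrow(pipe$base) * (nrow(pipe$base) + 1) / 2))),
         reduced = t(vapply(mats, flatten_reduced,
                            prototype_rows = pipe$prototype_rows,
                            numeric(length(flatten_reduced(mats[[1L]],
                                                           pipe$prototype_rows))))))
}

# ---- classifier registry ------------------------------------------------

classifier_names <- function() c("mdm", "svm", "hcbr", "vqc", "qsvc")

default_mode <- function(classifier) {
  if (classifier == "mdm") "matrices" else "tangent"
}

fit_classifier <- function(classifier, feats, labels, opts, seed) {
  switch(classifier,
    mdm = mdm_fit(feats, labels),
    svm = svm_fit(feats, labels, cost = opts$cost %||% 1,
                  gamma = opts$gamma %||% NULL, seed = seed),
    hcbr = {
      digits <- opts$digits %||% 4L
      cases <- lapply(seq_len(nrow(feats)), function(j) {
        hcbr_discretize(feats[j, ], digits = digits)
      })
      hcbr_fit(cases, labels, l0 = opts$l0 %||% 1L, eta = opts$eta %||% 0.1)
    },
    vqc = vqc_fit(feats, labels, shots = opts$shots %||% 0L,
                  c0 = opts$c0 %||% 4, maxiter = opts$maxiter %||% 40L,
                  seed = seed),
    qsvc = qsvc_fit(feats, labels, shots = opts$shots %||% 0L,
                    cost = opts$cost %||% 1, seed = seed),
    constant = {                           # degenerate pipeline for nulls
      tab <- table(as.character(labels))
      structure(list(class = names(tab)[which.max(tab)]),
                class = "constant_model")
    },
    stop_p300("unknown classifier `%s`; valid names: %s", classifier,
              paste(classifier_names(), collapse = ", "),
              class = "config_error"))
}

predict_classifier <- function(classifier, model, feats, opts) {
  switch(classifier,
    mdm = mdm_predict(model, feats),
    svm = svm_predict(model, feats),
    hcbr = {
      digits <- opts$digits %||% 4L
      cases <- lapply(seq_len(nrow(feats)), function(j) {
        hcbr_discretize(feats[j, ], digits = digits)
      })
      hcbr_predict(model, cases)$class
    },
    vqc = vqc_predict(model, feats),
    qsvc = qsvc_predict(model, feats),
    constant = rep(model$class,
                   if (is.list(feats)) length(feats) else nrow(feats)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- cross-validated evaluation ----------------------------------------

#' Cross-validated evaluation of one classifier
#'
#' Stratified, shuffled k-fold cross-validation. The feature pipeline
#' (xDAWN filters, prototype, tangent base) and the classifier are fitted
#' on the training folds only; held-out trials are only ever transformed
#' and scored.
#'
#' @param epochs An [epoch_set()].
#' @param classifier One of `"mdm"`, `"svm"`, `"hcbr"`, `"vqc"`, `"qsvc"`.
#' @param mode Feature mode (default: `"matrices"` for MDM, `"tangent"`
#'   otherwise).
#' @param k Number of folds.
#' @param seed Seed for fold assignment and any classifier randomness.
#' @param opts Named list of classifier options (`digits`, `l0`, `shots`,
#'   `maxiter`, `c0`, `cost`, `gamma`, `nfilter`, `shrinkage`).
#' @param return_models Also return the per-fold fitted pipelines and
#'   classifiers (for inspection/leakage checks).
#' @return An object of class `cv_report`: per-fold train/test balanced
#'   accuracies, their mean and standard deviation, the classifier name, a
#'   config fingerprint and the seed.
#' @export
cv_evaluate <- function(epochs, classifier, mode = NULL, k = 5L, seed = 1L,
                        opts = list(), return_models = FALSE) {
  if (!classifier %in% c(classifier_names(), "constant")) {
    stop_p300("unknown classifier `%s`; valid names: %s", classifier,
              paste(classifier_names(), collapse = ", "),
              class = "config_error")
  }
  if (is.null(mode)) mode <- default_mode(classifier)
  folds <- stratified_kfold(epochs$labels, k = k, seed = seed)
  rows <- vector("list", k)
  models <- if (return_models) vector("list", k) else NULL
  for (f in seq_len(k)) {
    tr <- epochs[folds != f]
    te <- epochs[folds == f]
    pipe <- feature_pipeline_fit(tr, mode = mode,
                                 nfilter = opts$nfilter %||% 1L,
                                 shrinkage = opts$shrinkage %||% 1e-6)
    ftr <- feature_transform(pipe, tr)
    fte <- feature_transform(pipe, te)
    model <- fit_classifier(classifier, ftr, tr$labels, opts, seed + f)
    pr_tr <- predict_classifier(classifier, model, ftr, opts)
    pr_te <- predict_classifier(classifier, model, fte, opts)
    rows[[f]] <- data.frame(fold = f,
                            train_bacc = balanced_accuracy(tr$labels, pr_tr),
                            test_bacc = balanced_accuracy(te$labels, pr_te))
    if (return_models) models[[f]] <- list(pipeline = pipe, model = model)
  }
  folds_df <- do.call(rbind, rows)
  fingerprint <- paste0(classifier, "/", mode, "/k", k, "/",
                        paste(sprintf("%s=%s", names(opts),
                                      vapply(opts, function(v)
                                        paste(format(v), collapse = ";"), "")),
                              collapse = ","))
  structure(list(classifier = classifier, mode = mode, folds = folds_df,
                 mean_train = mean(folds_df$train_bacc),
                 sd_train = stats::sd(folds_df$train_bacc),
                 mean_test = mean(folds_df$test_bacc),
                 sd_test = stats::sd(folds_df$test_bacc),
                 config = fingerprint, seed = seed,
                 models = models),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("<cv_report> %s (%s): train %.4f (sd %.4f), test %.4f (sd %.4f) over %d folds\n",
              x$classifier, x$mode, x$mean_train, x$sd_train, x$mean_test,
              x$sd_test, nrow(x$folds)))
  invisible(x)
}

#' Permutation significance threshold of cross-validated accuracy
#'
#' Permutes the trial labels `n_perm` times (seeded); for each permutation
#' the full pipeline is refitted and its cross-validated mean test balanced
#' accuracy recorded. The significance threshold is the empirical
#' nearest-rank `1 - alpha/2` quantile (0.975 for the canonical
#' `alpha = 0.05`) of that null distribution.
#'
#' @param epochs An [epoch_set()].
#' @param classifier Pipeline classifier (canonically `"mdm"`).
#' @param mode Feature mode (default per classifier).
#' @param n_perm Number of permutations (>= 1; the canonical full-scale run
#'   uses 10000, the reduced default is 200).
#' @param alpha Two-sided significance level.
#' @param k Folds.
#' @param seed RNG seed.
#' @param opts Classifier options as in [cv_evaluate()].
#' @return List with `threshold`, the vector of permuted `scores`, `alpha`
#'   and `n_perm`.
#' @export
permutation_threshold <- function(epochs, classifier = "mdm", mode = NULL,
                                  n_perm = 200L, alpha = 0.05, k = 5L,
                                  seed = 1L, opts = list()) {
  if (length(n_perm) != 1L || !is.finite(n_perm) || n_perm < 1) {
    stop_p300("n_perm must be >= 1", class = "parameter_error")
  }
  n_perm <- as.integer(n_perm)
  perms <- with_seed(seed, {
    lapply(seq_len(n_perm), function(i) sample(seq_along(epochs$labels)))
  })
  scores <- vapply(seq_len(n_perm), function(i) {
    ep <- epochs
    ep$labels <- epochs$labels[perms[[i]]]
    cv_evaluate(ep, classifier, mode = mode, k = k, seed = seed + i,
                opts = opts)$mean_test
  }, 0)
  q <- 1 - alpha / 2
  sorted <- sort(scores)
  threshold <- sorted[min(max(ceiling(q * n_perm), 1L), n_perm)]
  list(threshold = threshold, scores = scores, alpha = alpha,
       n_perm = n_perm)
}

# ---- experiment runner --------------------------------------------------

#' Run an end-to-end classification experiment
#'
#' Generates (or accepts) a session, band-pass filters and epochs it, and
#' evaluates each requested classifier with stratified k-fold
#' cross-validation. Optionally runs the decimal-digits x filter-count
#' hyperparameter sweep and/or a permutation significance threshold, and
#' writes CSV/JSON reports.
#'
#' @param config Named list (or path to a JSON file). Recognized keys:
#'   `classifiers` (default `c("mdm", "svm")`), `mode` (named list of
#'   per-classifier feature modes), `design` (list of [session_design()]
#'   overrides), `amplitude`, `noise_scale`, `seed`, `k`, `low`, `high`,
#'   `tmin`, `tmax`, classifier options (`nfilter`, `digits`, `l0`,
#'   `shots`, `maxiter`, `c0`, `cost`), `sweep` (logical: run the
#'   digits {4,6,8} x nfilter {1,2,4} grid with HCBR), `n_perm` (0 skips
#'   the permutation threshold), `out_dir`.
#' @param session Optional pre-built `bci_session`, bypassing generation.
#' @param epochs Optional pre-built [epoch_set()], bypassing preprocessing.
#' @return List of class `experiment_result`: `reports` (per-classifier
#'   `cv_report`s), `table` (comparison data.frame), optional `sweep` grid
#'   and `permutation` result.
#' @export
run_experiment <- function(config = list(), session = NULL, epochs = NULL) {
  if (is.character(config)) config <- jsonlite::fromJSON(config)
  cfg <- config
  classifiers <- cfg$classifiers %||% c("mdm", "svm")
  bad <- setdiff(classifiers, classifier_names())
  if (length(bad)) {
    stop_p300("unknown classifier(s) %s; valid names: %s",
              paste(bad, collapse = ", "),
              paste(classifier_names(), collapse = ", "),
              class = "config_error")
  }
  seed <- cfg$seed %||% 1L
  k <- cfg$k %||% 5L
  opts <- cfg[intersect(names(cfg), c("nfilter", "digits", "l0", "eta",
                                      "shots", "maxiter", "c0", "cost",
                                      "gamma", "shrinkage"))]
  if (is.null(epochs)) {
    if (is.null(session)) {
      design <- do.call(session_design, cfg$design %||% list())
      p300 <- p300_params(amplitude = cfg$amplitude %||% 5.0,
                          n_channels = design$n_channels)
      session <- generate_session(design, p300,
                                  noise_scale = cfg$noise_scale %||% 4.0,
                                  seed = seed)
    }
    epochs <- preprocess_session(session,
                                 filter_spec(low = cfg$low %||% 1,
                                             high = cfg$high %||% 24),
                                 tmin = cfg$tmin %||% 0.1,
                                 tmax = cfg$tmax %||% 0.7)
  }
  reports <- lapply(classifiers, function(cl) {
    cv_evaluate(epochs, cl, mode = cfg$mode[[cl]], k = k, seed = seed,
                opts = opts)
  })
  names(reports) <- classifiers
  tab <- do.call(rbind, lapply(reports, function(r) {
    data.frame(classifier = r$classifier, mode = r$mode,
               mean_train = r$mean_train, sd_train = r$sd_train,
               mean_test = r$mean_test, sd_test = r$sd_test)
  }))
  rownames(tab) <- NULL
  out <- list(reports = reports, table = tab, epochs_summary = dim(epochs$data))
  if (isTRUE(cfg$sweep)) {
    out$sweep <- sweep_digits_filters(epochs, k = k, seed = seed,
                                      l0 = opts$l0 %||% 1L)
  }
  if ((cfg$n_perm %||% 0) > 0) {
    out$permutation <- permutation_threshold(epochs, classifier = "mdm",
                                             n_perm = cfg$n_perm, k = k,
                                             seed = seed)
  }
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(tab, file.path(cfg$out_dir, "report.csv"),
                     row.names = FALSE)
    jsonlite::write_json(list(table = tab, sweep = out$sweep,
                              threshold = out$permutation$threshold),
                         file.path(cfg$out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  structure(out, class = "experiment_result")
}

#' @export
print.experiment_result <- function(x, ...) {
  cat("<experiment_result>\n")
  print(x$table, row.names = FALSE)
  if (!is.null(x$permutation)) {
    cat(sprintf("permutation threshold (%d perms): %.4f\n",
                x$permutation$n_perm, x$permutation$threshold))
  }
  if (!is.null(x$sweep)) {
    cat("hyperparameter sweep:\n")
    print(x$sweep, row.names = FALSE)
  }
  invisible(x)
}

#' Decimal-digits x filter-count sweep for the case-based classifier
#'
#' Reproduces the hyperparameter grid of the dry-run protocol: HCBR test
#' balanced accuracy for rounding digits {4, 6, 8} crossed with xDAWN
#' filter counts {1, 2, 4}.
#'
#' @param epochs An [epoch_set()].
#' @param digits,nfilters Grid axes.
#' @param k Folds.
#' @param seed RNG seed.
#' @param l0 HCBR correction passes.
#' @return Data frame with one row per grid cell: `digits`, `nfilter`,
#'   `test_bacc`.
#' @export
sweep_digits_filters <- function(epochs, digits = c(4L, 6L, 8L),
                                 nfilters = c(1L, 2L, 4L), k = 5L,
                                 seed = 1L, l0 = 1L) {
  grid <- expand.grid(digits = digits, nfilter = nfilters)
  grid$test_bacc <- vapply(seq_len(nrow(grid)), function(i) {
    cv_evaluate(epochs, "hcbr", mode = "tangent", k = k, seed = seed,
                opts = list(digits = grid$digits[i],
                            nfilter = grid$nfilter[i],
                            l0 = l0))$mean_test
  }, 0)
  grid
}

#' Write per-trial feature vectors to CSV
#'
#' One row per trial, feature columns first, the label column last —
#' the interchange format consumed by the classifier CLIs.
#'
#' @param feats Numeric feature matrix (rows = trials).
#' @param labels Trial labels.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_features_csv <- function(feats, labels, path) {
  df <- as.data.frame(feats)
  names(df) <- sprintf("f%d", seq_len(ncol(df)))
  df$label <- as.character(labels)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
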