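#' Fit per-class xDAWN spatial filters
#'
#' For each class, xDAWN solves the generalized eigenproblem maximizing the
#' ratio of evoked-response power to overall signal power,
#' `(w' S_evoked w) / (w' S_signal w)`, where `S_evoked` is the covariance
#' (over time) of the class-average evoked response and `S_signal` the
#' covariance of the concatenated epochs. The top `nfilter` generalized
#' eigenvectors per class are returned in descending eigenvalue order, rows
#' normalized to unit norm, sign fixed so each filter's largest-magnitude
#' coefficient is positive.
#'
#' @param epochs An [epoch_set()] with at least two epochs per class.
#' @param nfilter Filters per class (1 reproduces the canonical 4 x 4
#'   super-trial pipeline).
#' @param loading Diagonal loading added to `S_signal` for conditioning.
#' @return An object of class `xdawn_model` with `filters` (per-class list
#'   of nfilter x channels matrices), `prototypes` (per-class mean evoked
#'   responses, channels x samples), `eigenvalues` and `classes`.
#' @export
fit_xdawn <- function(epochs, nfilter = 1L, loading = 1e-8) {
  nfilter <- assert_count(nfilter, "nfilter")
  d <- dim(epochs$data)
  nch <- d[2L]
  if (nfilter > nch) {
    stop_p300("nfilter (%d) exceeds channel count (%d)", nfilter, nch,
              class = "dimension_error")
  }
  classes <- levels(droplevels(epochs$labels))
  if (length(classes) < 2L) {
    stop_p300("need at least 2 classes, got %d", length(classes),
              class = "class_error")
  }
  counts <- table(droplevels(epochs$labels))
  if (any(counts < 2L)) {
    stop_p300("every class needs >= 2 epochs (got %s)",
              paste(sprintf("%s=%d", names(counts), as.integer(counts)),
                    collapse = ", "), class = "class_error")
  }
  # signal covariance from all concatenated epochs
  allmat <- matrix(aperm(epochs$data, c(2L, 3L, 1L)), nrow = nch)
  allmat <- allmat - rowMeans(allmat)
  s_signal <- tcrossprod(allmat) / ncol(allmat) + diag(loading, nch)
  w_inv_sqrt <- sym_power(s_signal, -0.5)

  filters <- list(); prototypes <- list(); eigenvalues <- list()
  for (cl in classes) {
    idx <- which(epochs$labels == cl)
    evoked <- apply(epochs$data[idx, , , drop = FALSE], c(2L, 3L), mean)
    evc <- evoked - rowMeans(evoked)
    s_evoked <- tcrossprod(evc) / ncol(evc)
    # whiten then ordinary symmetric eigenproblem
    e <- eigen(w_inv_sqrt %*% s_evoked %*% w_inv_sqrt, symmetric = TRUE)
    v <- w_inv_sqrt %*% e$vectors[, seq_len(nfilter), drop = FALSE]
    w <- t(v)
    for (i in seq_len(nrow(w))) {
      w[i, ] <- w[i, ] / sqrt(sum(w[i, ]^2))
      if (w[i, which.max(abs(w[i, ]))] < 0) w[i, ] <- -w[i, ]
    }
    filters[[cl]] <- w
    prototypes[[cl]] <- evoked
    eigenvalues[[cl]] <- e$values[seq_len(nfilter)]
  }
  structure(list(filters = filters, prototypes = prototypes,
                 eigenvalues = eigenvalues, classes = classes,
                 nfilter = nfilter),
            class = "xdawn_model")
}

#' Apply fitted xDAWN filters to an epoch
#'
#' Stacks every class's filters (training-class order) and projects the
#' epoch onto them, yielding `nfilter * n_classes` virtual channels.
#'
#' @param model An `xdawn_model`.
#' @param epoch channels x samples matrix.
#' @return (nfilter * n_classes) x samples matrix.
#' @export
apply_filters <- function(model, epoch) {
  w <- do.call(rbind, model$filters)
  if (ncol(w) != nrow(epoch)) {
    stop_p300("epoch has %d channels, filters expect %d", nrow(epoch), ncol(w),
              class = "dimension_error")
  }
  w %*% epoch
}

#' Write an xDAWN model to a single-file archive
#'
#' Same JSON + base64-double container as [write_epochs()].
#'
#' @param model An `xdawn_model`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_xdawn <- function(model, path) {
  if (!inherits(model, "xdawn_model")) {
    stop_p300("`model` must be an xdawn_model", class = "format_error")
  }
  doc <- list(format = "p300bci-xdawn", version = 1L,
              classes = model$classes, nfilter = model$nfilter,
              filter_dims = lapply(model$filters, dim),
              filters = lapply(model$filters, encode_doubles),
              prototype_dims = lapply(model$prototypes, dim),
              prototypes = lapply(model$prototypes, encode_doubles),
              eigenvalues = model$eigenvalues)
  writeLines(jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA), path)
  invisible(path)
}

#' Read an xDAWN model archive
#' @param path File written by [write_xdawn()].
#' @return An `xdawn_model`, bit-identical to the one written.
#' @export
read_xdawn <- function(path) {
  doc <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                  error = function(e) {
                    stop_p300("not a readable xdawn archive: %s",
                              conditionMessage(e), class = "format_error")
                  })
  for (field in c("format", "classes", "nfilter", "filters", "prototypes")) {
    if (is.null(doc[[field]])) {
      stop_p300("xdawn archive missing field `%s`", field,
                class = "format_error")
    }
  }
  unpack <- function(vals, dims) {
    out <- lapply(seq_along(vals), function(i) {
      d <- as.integer(unlist(dims[[i]]))
      matrix(decode_doubles(vals[[i]], prod(d)), d[1L], d[2L])
    })
    names(out) <- names(vals)
    out
  }
  structure(list(filters = unpack(doc$filters, doc$filter_dims),
                 prototypes = unpack(doc$prototypes, doc$prototype_dims),
                 eigenvalues = lapply(doc$eigenvalues, unlist),
                 classes = unlist(doc$classes),
                 nfilter = as.integer(doc$nfilter)),
            class = "xdawn_model")
}

#' Apply xDAWN filters to every epoch of a set
#' @param model An `xdawn_model`.
#' @param epochs An [epoch_set()].
#' @return An [epoch_set()] of virtual-channel epochs.
#' @export
apply_filters_set <- function(model, epochs) {
  w <- do.call(rbind, model$filters)
  d <- dim(epochs$data)
  out <- array(0, dim = c(d[1L], nrow(w), d[3L]))
  for (j in seq_len(d[1L])) out[j, , ] <- w %*% epochs$data[j, , ]
  epoch_set(out, epochs$labels, epochs$sfreq, epochs$window)
}
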