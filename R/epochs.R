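#' Labelled epoch container
#'
#' An `epoch_set` holds fixed-length windows of multichannel EEG cut around
#' stimulus onsets, with their TARGET / NON-TARGET labels, the sampling rate
#' and the epoch window relative to onset.
#'
#' @param data trials x channels x samples numeric array (microvolts). An
#'   empty set (0 trials) is allowed.
#' @param labels Per-trial labels, coerced to a factor with levels
#'   `NON-TARGET`, `TARGET` (extra levels are kept if present).
#' @param sfreq Sampling frequency, Hz.
#' @param window Numeric `c(tmin, tmax)` in seconds relative to onset.
#' @return An object of class `epoch_set`.
#' @export
epoch_set <- function(data, labels, sfreq, window) {
  if (!is.array(data) || length(dim(data)) != 3L) {
    stop_p300("`data` must be a trials x channels x samples array",
              class = "format_error")
  }
  if (length(labels) != dim(data)[1L]) {
    stop_p300("labels length (%d) != number of trials (%d)",
              length(labels), dim(data)[1L], class = "format_error")
  }
  if (!is.factor(labels)) {
    lev <- union(c("NON-TARGET", "TARGET"), unique(as.character(labels)))
    labels <- factor(as.character(labels), levels = lev)
  }
  sfreq <- assert_positive(sfreq, "sfreq")
  if (length(window) != 2L || window[1L] >= window[2L]) {
    stop_p300("`window` must be c(tmin, tmax) with tmin < tmax",
              class = "format_error")
  }
  structure(list(data = data, labels = labels, sfreq = sfreq,
                 window = as.numeric(window)),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$data)
  tab <- table(x$labels)
  cat(sprintf("<epoch_set> %d trials x %d channels x %d samples @ %g Hz, window [%g, %g] s (%s)\n",
              d[1L], d[2L], d[3L], x$sfreq, x$window[1L], x$window[2L],
              paste(sprintf("%s=%d", names(tab), as.integer(tab)),
                    collapse = ", ")))
  invisible(x)
}

#' Number of trials in an epoch set
#' @param x An `epoch_set`.
#' @export
n_trials <- function(x) dim(x$data)[1L]

#' Subset an epoch set by trial index
#' @param x An `epoch_set`.
#' @param i Trial indices (integer or logical).
#' @param ... Ignored.
#' @export
`[.epoch_set` <- function(x, i, ...) {
  epoch_set(x$data[i, , , drop = FALSE], x$labels[i], x$sfreq, x$window)
}

# ---- single-file archive -----------------------------------------------
# Canonical on-disk format: one JSON document holding the metadata plus the
# sample data as base64-encoded IEEE 754 little-endian doubles (column-major
# order of the trials x channels x samples array). The encoding round-trips
# bit-identically.

encode_doubles <- function(x) jsonlite::base64_enc(writeBin(as.numeric(x),
                                                            raw(),
                                                            size = 8,
                                                            endian = "little"))

decode_doubles <- function(s, n) {
  readBin(jsonlite::base64_dec(s), what = "double", n = n, size = 8,
          endian = "little")
}

#' Write an epoch set to a single-file archive
#'
#' @param epochs An [epoch_set()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @seealso [read_epochs()]
#' @export
write_epochs <- function(epochs, path) {
  if (!inherits(epochs, "epoch_set")) {
    stop_p300("`epochs` must be an epoch_set", class = "format_error")
  }
  d <- dim(epochs$data)
  doc <- list(format = "p300bci-epochs", version = 1L,
              dims = d,
              labels = as.character(epochs$labels),
              label_levels = levels(epochs$labels),
              sfreq = epochs$sfreq, window = epochs$window,
              data = encode_doubles(epochs$data))
  writeLines(jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA), path)
  invisible(path)
}

#' Read an epoch set from a single-file archive
#'
#' @param path File written by [write_epochs()].
#' @return An [epoch_set()], bit-identical to the one written.
#' @export
read_epochs <- function(path) {
  doc <- tryCatch(jsonlite::fromJSON(path),
                  error = function(e) {
                    stop_p300("not a readable epoch archive: %s",
                              conditionMessage(e), class = "format_error")
                  })
  for (field in c("format", "dims", "labels", "sfreq", "window", "data")) {
    if (is.null(doc[[field]])) {
      stop_p300("epoch archive missing field `%s`", field,
                class = "format_error")
    }
  }
  if (!identical(doc$format, "p300bci-epochs")) {
    stop_p300("unexpected archive format `%s` in field `format`", doc$format,
              class = "format_error")
  }
  d <- as.integer(doc$dims)
  vals <- decode_doubles(doc$data, prod(d))
  if (length(vals) != prod(d)) {
    stop_p300("epoch archive field `data` truncated: %d values, expected %d",
              length(vals), prod(d), class = "format_error")
  }
  labels <- factor(as.character(doc$labels), levels = doc$label_levels)
  epoch_set(array(vals, dim = d), labels, doc$sfreq, doc$window)
}

#' Write a continuous session to a single-file archive
#'
#' Same JSON + base64 container as [write_epochs()], holding the continuous
#' record and the flash onset list of a [generate_session()] result.
#'
#' @param session A `bci_session`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_session <- function(session, path) {
  if (!inherits(session, "bci_session")) {
    stop_p300("`session` must be a bci_session", class = "format_error")
  }
  doc <- list(format = "p300bci-session", version = 1L,
              dims = dim(session$record),
              sfreq = session$sfreq,
              onset_sample = session$onsets$sample,
              onset_time = session$onsets$time,
              onset_label = as.character(session$onsets$label),
              record = encode_doubles(session$record))
  writeLines(jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA), path)
  invisible(path)
}

#' Read a continuous session archive
#' @param path File written by [write_session()].
#' @return A list with `record`, `onsets`, `sfreq` (a partial `bci_session`).
#' @export
read_session <- function(path) {
  doc <- tryCatch(jsonlite::fromJSON(path),
                  error = function(e) {
                    stop_p300("not a readable session archive: %s",
                              conditionMessage(e), class = "format_error")
                  })
  for (field in c("format", "dims", "sfreq", "onset_sample", "onset_label",
                  "record")) {
    if (is.null(doc[[field]])) {
      stop_p300("session archive missing field `%s`", field,
                class = "format_error")
    }
  }
  d <- as.integer(doc$dims)
  vals <- decode_doubles(doc$record, prod(d))
  if (length(vals) != prod(d)) {
    stop_p300("session archive field `record` truncated",
              class = "format_error")
  }
  structure(list(record = matrix(vals, nrow = d[1L], ncol = d[2L]),
                 onsets = data.frame(sample = as.integer(doc$onset_sample),
                                     time = if (is.null(doc$onset_time))
                                       doc$onset_sample / doc$sfreq
                                     else as.numeric(doc$onset_time),
                                     label = factor(doc$onset_label,
                                                    levels = c("NON-TARGET",
                                                               "TARGET"))),
                 sfreq = doc$sfreq),
            class = "bci_session")
}
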