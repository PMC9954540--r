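#' Band-pass filter specification
#'
#' Describes the Hamming-window FIR band-pass used to isolate the 1--24 Hz
#' band that carries the P300. The number of taps, when not given, is
#' derived from the transition width by the standard Hamming approximation
#' `n_taps ~= 3.3 * sfreq / transition_width` (rounded up to an odd count so
#' the filter is symmetric around a centre tap).
#'
#' @param low Lower pass-band edge, Hz.
#' @param high Upper pass-band edge, Hz.
#' @param window Taper name; only `"hamming"` is implemented.
#' @param order Number of taps; `NULL` derives it from the transition width.
#' @return An object of class `filter_spec`.
#' @export
filter_spec <- function(low = 1, high = 24, window = "hamming", order = NULL) {
  low <- assert_positive(low, "low")
  high <- assert_positive(high, "high")
  if (low >= high) {
    stop_p300("need 0 < low < high (got %g, %g)", low, high,
              class = "parameter_error")
  }
  if (!identical(window, "hamming")) {
    stop_p300("only the hamming window is implemented", class = "parameter_error")
  }
  if (!is.null(order)) order <- assert_count(order, "order", min = 3L)
  structure(list(low = low, high = high, window = window, order = order),
            class = "filter_spec")
}

# Windowed-sinc band-pass taps (symmetric, odd length, Hamming taper).
# Edges sit at `low` and `high` (gain ~0.5 at the edges).
fir_bandpass_taps <- function(spec, sfreq) {
  nyq <- sfreq / 2
  if (spec$high >= nyq) {
    stop_p300("high edge (%g Hz) must be below Nyquist (%g Hz)", spec$high,
              nyq, class = "parameter_error")
  }
  n <- spec$order
  if (is.null(n)) {
    # transition width: a quarter of the edge frequency, clamped to stay
    # physical at both edges (standard EEG filter-design heuristic)
    tw_low <- min(max(spec$low * 0.25, 2), spec$low)
    tw_high <- min(max(spec$high * 0.25, 2), nyq - spec$high)
    tw <- min(tw_low, tw_high)
    n <- ceiling(3.3 * sfreq / tw)
  }
  if (n %% 2 == 0) n <- n + 1L
  m <- (n - 1) / 2
  k <- seq_len(n) - 1 - m                  # centred tap index
  sinc <- function(f, k) ifelse(k == 0, 2 * f / sfreq,
                                sin(2 * pi * f * k / sfreq) / (pi * k))
  h <- sinc(spec$high, k) - sinc(spec$low, k)
  w <- 0.54 - 0.46 * cos(2 * pi * (seq_len(n) - 1) / (n - 1))
  h * w
}

# Frequency response (complex gain, single pass) of the taps at `freq` Hz.
fir_response <- function(taps, sfreq, freq) {
  n <- length(taps)
  m <- (n - 1) / 2
  k <- seq_len(n) - 1 - m
  vapply(freq, function(f) sum(taps * exp(-2i * pi * f * k / sfreq)),
         complex(1))
}

# Centred FFT convolution of one channel with symmetric taps ("same" size).
conv_same <- function(x, taps) {
  n <- length(x)
  m <- (length(taps) - 1) / 2
  full <- stats::convolve(x, rev(taps), type = "open")
  full[(m + 1):(m + n)]
}

#' Zero-phase band-pass filtering of a continuous record
#'
#' Applies the Hamming-window FIR band-pass forward and backward (two
#' centred passes of the symmetric kernel) after reflect-padding, so the net
#' group delay is zero and the effective magnitude response is the squared
#' single-pass response.
#'
#' @param record channels x samples numeric matrix (a plain vector is
#'   treated as one channel).
#' @param sfreq Sampling frequency, Hz.
#' @param spec A [filter_spec()].
#' @return Filtered record with the same shape as the input.
#' @export
bandpass <- function(record, sfreq, spec = filter_spec()) {
  vec <- is.null(dim(record))
  if (vec) record <- matrix(record, nrow = 1)
  taps <- fir_bandpass_taps(spec, sfreq)
  n <- ncol(record)
  if (n <= 3 * length(taps)) {
    stop_p300("record (%d samples) must be longer than 3x the filter order (%d taps)",
              n, length(taps), class = "length_error")
  }
  pad <- length(taps)
  out <- record
  for (ch in seq_len(nrow(record))) {
    x <- record[ch, ]
    # reflect padding around the end points
    xp <- c(2 * x[1] - x[(pad + 1):2], x, 2 * x[n] - x[(n - 1):(n - pad)])
    y <- conv_same(xp, taps)               # forward pass
    y <- rev(conv_same(rev(y), taps))      # backward pass
    out[ch, ] <- y[(pad + 1):(pad + n)]
  }
  if (vec) out <- out[1, ]
  out
}

#' Cut stimulus-locked epochs from a continuous record
#'
#' The epoch window is the half-open sample range
#' `[floor(tmin * sfreq), floor(tmax * sfreq))` relative to each onset
#' sample, giving `floor(tmax * sfreq) - floor(tmin * sfreq)` samples per
#' epoch (77 samples for the default 100--700 ms window at 128 Hz). This
#' convention is fixed; any onset whose window leaves the record raises a
#' bounds error naming the onset index.
#'
#' @param record channels x samples matrix.
#' @param onsets 1-based onset sample indices, or a data.frame with columns
#'   `sample` and `label` (as produced by [generate_session()]).
#' @param labels Per-onset labels; ignored when `onsets` is a data.frame.
#' @param sfreq Sampling frequency, Hz.
#' @param tmin,tmax Epoch window in seconds relative to onset.
#' @return An [epoch_set()].
#' @export
extract_epochs <- function(record, onsets, labels = NULL, sfreq,
                           tmin = 0.1, tmax = 0.7) {
  if (is.data.frame(onsets)) {
    labels <- onsets$label
    onsets <- onsets$sample
  }
  if (is.null(labels) || length(labels) != length(onsets)) {
    stop_p300("labels must match onsets (%d onsets)", length(onsets),
              class = "parameter_error")
  }
  if (tmin >= tmax) {
    stop_p300("need tmin < tmax", class = "parameter_error")
  }
  s0 <- floor(tmin * sfreq)
  s1 <- floor(tmax * sfreq) - 1L           # half-open end
  nsamp <- s1 - s0 + 1L
  nch <- nrow(record)
  ntr <- length(onsets)
  dat <- array(0, dim = c(ntr, nch, nsamp))
  for (j in seq_len(ntr)) {
    a <- onsets[j] + s0
    b <- onsets[j] + s1
    if (a < 1L || b > ncol(record)) {
      stop_p300("onset %d: window [%d, %d] exceeds record bounds [1, %d]",
                j, a, b, ncol(record), class = "bounds_error")
    }
    dat[j, , ] <- record[, a:b]
  }
  epoch_set(dat, labels, sfreq, c(tmin, tmax))
}

#' Filter and epoch a session in one call
#'
#' @param session A `bci_session` (from [generate_session()] or
#'   [read_session()]).
#' @param spec A [filter_spec()].
#' @param tmin,tmax Epoch window, seconds.
#' @return An [epoch_set()].
#' @export
preprocess_session <- function(session, spec = filter_spec(),
                               tmin = 0.1, tmax = 0.7) {
  filtered <- bandpass(session$record, session$sfreq, spec)
  extract_epochs(filtered, session$onsets, sfreq = session$sfreq,
                 tmin = tmin, tmax = tmax)
}
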