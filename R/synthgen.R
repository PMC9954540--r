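#' Session design for a synthetic Brain Invaders style oddball experiment
#'
#' Describes the stimulation schedule of a visual P300 oddball session: a
#' 6 x 6 symbol matrix, a set of TARGET symbols each presented over several
#' repetitions, and within every repetition a fixed number of flashes of
#' which a small minority contain the TARGET. The defaults reproduce the
#' canonical design: 8 TARGET symbols x 8 repetitions x 12 flashes with 2
#' TARGET flashes per repetition, i.e. 128 TARGET and 640 NON-TARGET trials,
#' recorded on 16 channels at 128 Hz.
#'
#' @param n_symbols_total Total symbols on screen (the 6 x 6 matrix).
#' @param n_targets Number of designated TARGET symbols per session.
#' @param n_repetitions_per_target Repetitions for each TARGET symbol.
#' @param flashes_per_repetition Flashes composing one repetition.
#' @param target_flashes_per_repetition Flashes of a repetition that contain
#'   the TARGET symbol; must be less than `flashes_per_repetition`.
#' @param n_channels Number of EEG channels.
#' @param sfreq Sampling frequency in Hz.
#' @param isi Inter-stimulus interval between flash onsets, in seconds.
#' @return An object of class `session_design`.
#' @export
session_design <- function(n_symbols_total = 36L, n_targets = 8L,
                           n_repetitions_per_target = 8L,
                           flashes_per_repetition = 12L,
                           target_flashes_per_repetition = 2L,
                           n_channels = 16L, sfreq = 128, isi = 0.4) {
  d <- list(
    n_symbols_total = assert_count(n_symbols_total, "n_symbols_total"),
    n_targets = assert_count(n_targets, "n_targets"),
    n_repetitions_per_target = assert_count(n_repetitions_per_target,
                                            "n_repetitions_per_target"),
    flashes_per_repetition = assert_count(flashes_per_repetition,
                                          "flashes_per_repetition"),
    target_flashes_per_repetition =
      assert_count(target_flashes_per_repetition,
                   "target_flashes_per_repetition"),
    n_channels = assert_count(n_channels, "n_channels"),
    sfreq = assert_positive(sfreq, "sfreq"),
    isi = assert_positive(isi, "isi")
  )
  if (d$target_flashes_per_repetition >= d$flashes_per_repetition) {
    stop_p300("target_flashes_per_repetition (%d) must be < flashes_per_repetition (%d)",
              d$target_flashes_per_repetition, d$flashes_per_repetition,
              class = "parameter_error")
  }
  structure(d, class = "session_design")
}

#' Parameters of the simulated P300 deflection
#'
#' The P300 is modelled as a smooth positive Gaussian-windowed bump added to
#' TARGET epochs, peaking `peak_latency` seconds after stimulus onset (the
#' physiological window is 240--600 ms), with full width at half maximum
#' `width` and peak amplitude `amplitude` microvolts. The deflection is
#' scaled per channel by `spatial_profile`, which defaults to a
#' parieto-central topography on the standard 16-channel montage
#' (largest weights on Pz and Cz, intermediate on P3/P4/P7/P8 and the
#' occipital row, near zero frontally).
#'
#' @param peak_latency Peak latency in seconds after stimulus onset.
#' @param width Full width at half maximum of the bump, seconds.
#' @param amplitude Peak amplitude in microvolts; 0 yields null (no ERP) data.
#' @param spatial_profile Per-channel weights, length `n_channels`; the
#'   template added to channel c is `amplitude * spatial_profile[c]` at peak.
#' @param n_channels Used to build the default profile.
#' @return An object of class `p300_params`.
#' @export
p300_params <- function(peak_latency = 0.35, width = 0.2, amplitude = 5.0,
                        spatial_profile = NULL, n_channels = 16L) {
  peak_latency <- assert_positive(peak_latency, "peak_latency")
  width <- assert_positive(width, "width")
  if (length(amplitude) != 1L || !is.finite(amplitude) || amplitude < 0) {
    stop_p300("`amplitude` must be a single nonnegative number",
              class = "parameter_error")
  }
  n_channels <- assert_count(n_channels, "n_channels")
  if (is.null(spatial_profile)) {
    spatial_profile <- default_spatial_profile(n_channels)
  }
  if (length(spatial_profile) != n_channels) {
    stop_p300("`spatial_profile` must have %d entries (got %d)", n_channels,
              length(spatial_profile), class = "parameter_error")
  }
  structure(list(peak_latency = peak_latency, width = width,
                 amplitude = as.numeric(amplitude),
                 spatial_profile = as.numeric(spatial_profile)),
            class = "p300_params")
}

# Parieto-central topography for the 16-channel montage
# (Fp1 Fp2 F5 AFz F6 T7 Cz T8 P7 P3 Pz P4 P8 O1 Oz O2); other channel
# counts fall back to a smooth posterior-weighted ramp.
default_spatial_profile <- function(n_channels) {
  if (n_channels == 16L) {
    c(Fp1 = 0.05, Fp2 = 0.05, F5 = 0.10, AFz = 0.15, F6 = 0.10,
      T7 = 0.10, Cz = 0.80, T8 = 0.10, P7 = 0.45, P3 = 0.70,
      Pz = 1.00, P4 = 0.70, P8 = 0.45, O1 = 0.40, Oz = 0.45, O2 = 0.40)
  } else {
    x <- seq(0, 1, length.out = n_channels)
    0.05 + 0.95 * x^2
  }
}

#' Single-channel P300 template waveform
#'
#' Evaluates the Gaussian bump on a regular sample grid. The maximum falls
#' on the sample nearest `params$peak_latency` and the waveform decays to
#' below 1% of the peak at the window edges for the default parameters.
#'
#' @param params A [p300_params()] object.
#' @param sfreq Sampling frequency, Hz.
#' @param duration Template duration in seconds; must cover
#'   `peak_latency + width`.
#' @return Numeric vector of `round(duration * sfreq)` samples (microvolts).
#' @export
p300_template <- function(params, sfreq, duration = 0.7) {
  sfreq <- assert_positive(sfreq, "sfreq")
  duration <- assert_positive(duration, "duration")
  if (duration < params$peak_latency + params$width) {
    stop_p300("duration (%.3f s) must be >= peak_latency + width (%.3f s)",
              duration, params$peak_latency + params$width,
              class = "parameter_error")
  }
  n <- round(duration * sfreq)
  t <- (seq_len(n) - 1) / sfreq
  sigma <- params$width / (2 * sqrt(2 * log(2)))  # FWHM -> sd
  params$amplitude * exp(-(t - params$peak_latency)^2 / (2 * sigma^2))
}

# 1/f ("pink") Gaussian noise via spectral shaping; unit RMS.
pink_noise <- function(n) {
  white <- stats::rnorm(n)
  spec <- stats::fft(white)
  f <- c(1, seq_len(n - 1))                # avoid the DC singularity
  f <- pmin(f, n - f + 1)                  # two-sided frequency index
  spec <- spec / sqrt(f)
  x <- Re(stats::fft(spec, inverse = TRUE)) / n
  x / stats::sd(x)
}

#' Generate a synthetic oddball EEG session
#'
#' Produces a continuous multichannel record together with the flash onset
#' list. Each repetition consists of `flashes_per_repetition` flashes of
#' which exactly `target_flashes_per_repetition` (chosen at random within
#' the repetition) are TARGET flashes; the P300 template, scaled by the
#' spatial profile, is added to the record after every TARGET onset. The
#' noise floor is pink (1/f) Gaussian noise per channel plus a small
#' common-mode pink component, identical in distribution for both classes.
#'
#' @param design A [session_design()].
#' @param p300 A [p300_params()]; its spatial profile must match
#'   `design$n_channels`.
#' @param noise_scale Per-channel noise RMS in microvolts.
#' @param seed Integer seed fixing all randomness.
#' @return A list of class `bci_session` with elements `record`
#'   (channels x samples matrix, microvolts), `onsets` (data.frame with
#'   `sample` — 1-based onset sample index — `time` in seconds and `label`,
#'   a factor with levels `NON-TARGET`, `TARGET`), `sfreq`, `design`,
#'   `p300`, `noise_scale`, `seed`.
#' @export
generate_session <- function(design = session_design(),
                             p300 = p300_params(n_channels = design$n_channels),
                             noise_scale = 4.0, seed = 1L) {
  if (!inherits(design, "session_design")) {
    stop_p300("`design` must be a session_design object", class = "parameter_error")
  }
  if (length(p300$spatial_profile) != design$n_channels) {
    stop_p300("spatial_profile length (%d) != n_channels (%d)",
              length(p300$spatial_profile), design$n_channels,
              class = "parameter_error")
  }
  if (noise_scale < 0) {
    stop_p300("`noise_scale` must be nonnegative", class = "parameter_error")
  }
  n_rep <- design$n_targets * design$n_repetitions_per_target
  n_flash <- n_rep * design$flashes_per_repetition
  sfreq <- design$sfreq
  pad <- 1.0                               # head/tail padding, seconds
  n_samples <- ceiling((2 * pad + n_flash * design$isi) * sfreq)

  with_seed(seed, {
    record <- matrix(0, nrow = design$n_channels, ncol = n_samples)
    if (noise_scale > 0) {
      common <- pink_noise(n_samples)
      for (ch in seq_len(design$n_channels)) {
        record[ch, ] <- noise_scale * (pink_noise(n_samples) + 0.3 * common)
      }
    }
    # flash schedule: one flash every isi seconds
    onset_time <- pad + (seq_len(n_flash) - 1) * design$isi
    onset_sample <- as.integer(floor(onset_time * sfreq)) + 1L
    label <- rep("NON-TARGET", n_flash)
    for (r in seq_len(n_rep)) {
      pos <- sample.int(design$flashes_per_repetition,
                        design$target_flashes_per_repetition)
      label[(r - 1L) * design$flashes_per_repetition + pos] <- "TARGET"
    }
    if (p300$amplitude > 0) {
      tpl <- p300_template(p300, sfreq,
                           duration = max(0.7, p300$peak_latency + 2 * p300$width))
      bump <- outer(p300$spatial_profile, tpl)   # channels x template samples
      for (s0 in onset_sample[label == "TARGET"]) {
        idx <- s0:min(s0 + ncol(bump) - 1L, n_samples)
        record[, idx] <- record[, idx] + bump[, seq_along(idx)]
      }
    }
    structure(list(record = record,
                   onsets = data.frame(sample = onset_sample,
                                       time = onset_time,
                                       label = factor(label,
                                                      levels = c("NON-TARGET",
                                                                 "TARGET"))),
                   sfreq = sfreq, design = design, p300 = p300,
                   noise_scale = noise_scale, seed = as.integer(seed)),
              class = "bci_session")
  })
}

#' @export
print.bci_session <- function(x, ...) {
  tab <- table(x$onsets$label)
  cat(sprintf("<bci_session> %d channels x %d samples @ %g Hz; %d flashes (%s)\n",
              nrow(x$record), ncol(x$record), x$sfreq, nrow(x$onsets),
              paste(sprintf("%s=%d", names(tab), as.integer(tab)),
                    collapse = ", ")))
  invisible(x)
}
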