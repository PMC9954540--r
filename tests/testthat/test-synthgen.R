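test_that("p300_template places and shapes the bump correctly", {
  p0 <- p300_params(amplitude = 0)
  expect_equal(p300_template(p0, 128), rep(0, round(0.7 * 128)))

  p <- p300_params()
  tpl <- p300_template(p, 128)
  expect_equal(which.max(tpl), round(0.35 * 128) + 1L)  # 1-based sample 45+1
  # unimodal: increases to the peak, decreases after
  pk <- which.max(tpl)
  expect_true(all(diff(tpl[1:pk]) > 0))
  expect_true(all(diff(tpl[pk:length(tpl)]) < 0))
  # edge decay below 1% of peak: frozen from the Gaussian at the window
  # edges, exp(-0.35^2 / (2 * (0.2 / 2.3548)^2)) = 2.07e-4
  edge <- exp(-p$peak_latency^2 / (2 * (p$width / (2 * sqrt(2 * log(2))))^2))
  expect_equal(tpl[1], p$amplitude * edge, tolerance = 1e-10)
  expect_lt(tpl[1], 0.01 * max(tpl))
  expect_lt(tpl[length(tpl)], 0.01 * max(tpl))

  expect_error(p300_params(width = 0), class = "parameter_error")
  expect_error(p300_template(p, 128, duration = 0.3), class = "parameter_error")
})

test_that("default session reproduces the 128/640 oddball trial counts", {
  s <- generate_session(seed = 7)
  tab <- table(s$onsets$label)
  expect_identical(as.integer(tab[["TARGET"]]), 128L)
  expect_identical(as.integer(tab[["NON-TARGET"]]), 640L)
  d <- s$design
  expect_identical(nrow(s$onsets),
                   d$n_targets * d$n_repetitions_per_target *
                     d$flashes_per_repetition)
  # exactly 2 TARGET flashes inside every repetition block of 12
  blocks <- split(s$onsets$label,
                  rep(seq_len(64), each = d$flashes_per_repetition))
  expect_true(all(vapply(blocks, function(b) sum(b == "TARGET"), 0L) == 2L))
})

test_that("sessions are seed-deterministic and seed-sensitive", {
  d <- session_design(n_targets = 2, n_repetitions_per_target = 2)
  s1 <- generate_session(d, seed = 11)
  s2 <- generate_session(d, seed = 11)
  s3 <- generate_session(d, seed = 12)
  expect_identical(s1$record, s2$record)
  expect_identical(s1$onsets, s2$onsets)
  expect_false(identical(s1$record, s3$record))
})

test_that("high-SNR class difference peaks in the physiological window", {
  s <- small_session(amplitude = 20, noise_scale = 2, seed = 3,
                     n_targets = 2, reps = 4)
  ep <- extract_epochs(s$record, s$onsets, sfreq = s$sfreq,
                       tmin = 0, tmax = 0.7)
  diff_ev <- apply(ep$data[ep$labels == "TARGET", , , drop = FALSE],
                   c(2, 3), mean) -
    apply(ep$data[ep$labels == "NON-TARGET", , , drop = FALSE],
          c(2, 3), mean)
  top_ch <- order(s$p300$spatial_profile, decreasing = TRUE)[1:3]
  for (ch in top_ch) {
    pk_t <- (which.max(diff_ev[ch, ]) - 1) / s$sfreq
    expect_gte(pk_t, 0.24)
    expect_lte(pk_t, 0.60)
  }
})

test_that("zero-amplitude sessions carry no class signal (null MC)", {
  d <- session_design(n_targets = 2, n_repetitions_per_target = 3)
  p0 <- p300_params(amplitude = 0)
  win <- function(sfreq) seq(floor(0.24 * sfreq), floor(0.60 * sfreq))
  pvals <- vapply(1:100, function(seed) {
    s <- generate_session(d, p0, noise_scale = 2, seed = 1000 + seed)
    ep <- extract_epochs(s$record, s$onsets, sfreq = s$sfreq,
                         tmin = 0, tmax = 0.7)
    m <- rowMeans(ep$data[, 11, win(s$sfreq)])  # Pz window mean per trial
    stats::t.test(m[ep$labels == "TARGET"],
                  m[ep$labels == "NON-TARGET"])$p.value
  }, 0)
  expect_gte(mean(pvals > 0.01), 0.95)
})

test_that("design validation catches inconsistent parameters", {
  expect_error(session_design(target_flashes_per_repetition = 12),
               class = "parameter_error")
  expect_error(session_design(sfreq = -1), class = "parameter_error")
  expect_error(session_design(n_targets = 0), class = "parameter_error")
  expect_error(generate_session(p300 = p300_params(n_channels = 4)),
               class = "parameter_error")
})

test_that("epoch archives round-trip bit-identically", {
  ep <- small_epochs(seed = 2, n_targets = 1, reps = 2)
  path <- withr::local_tempfile(fileext = ".json")
  write_epochs(ep, path)
  back <- read_epochs(path)
  expect_identical(back$data, ep$data)
  expect_identical(back$labels, ep$labels)
  expect_identical(back$sfreq, ep$sfreq)
  expect_identical(back$window, ep$window)

  # empty set round-trips
  ep0 <- ep[integer(0)]
  write_epochs(ep0, path)
  expect_identical(n_trials(read_epochs(path)), 0L)

  # truncated / corrupt archives raise format errors
  txt <- readLines(path)
  writeLines(substr(txt, 1, nchar(txt) %/% 2), path)
  expect_error(read_epochs(path), class = "format_error")
  writeLines('{"format": "p300bci-epochs", "dims": [1, 2, 3]}', path)
  expect_error(read_epochs(path), class = "format_error")
})

test_that("session archives round-trip", {
  s <- small_session(seed = 4, n_targets = 1, reps = 2)
  path <- withr::local_tempfile(fileext = ".json")
  write_session(s, path)
  back <- read_session(path)
  expect_identical(back$record, s$record)
  expect_identical(back$onsets$sample, s$onsets$sample)
  expect_identical(back$onsets$label, s$onsets$label)
})
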