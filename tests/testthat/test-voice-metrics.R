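test_that("the envelope pipeline obeys its exact rate law", {
  tr <- audio_track(rep(0.25, 8000 * 2), 8000)
  env <- envelope(tr)
  expect_equal(env$fs_env, 1000 / 60)
  expect_equal(round(env$fs_env), 17)
  expect_equal(env$values, rep(0.25, length(env$values)), tolerance = 1e-12)

  # a 60 s magnitude series at 1000 Hz in blocks of 60 -> 1000 points
  tr60 <- audio_track(abs(rnorm(60000)), 1000)
  expect_length(envelope(tr60)$values, 1000)

  expect_error(envelope(audio_track(rep(0.1, 16000), 8000), block = 1e6),
               class = "mgce_parameter_error")
  expect_error(envelope(audio_track(rep(0.1, 100), 8000)),
               class = "mgce_input_error")
})

test_that("speech segments cover silence, continuous voicing and bursts correctly", {
  silent <- envelope(audio_track(rep(0, 8000 * 3), 8000))
  s0 <- detect_speech_segments(silent)
  expect_equal(nrow(s0), 0)
  expect_equal(attr(s0, "voiced_fraction"), 0)

  tone <- envelope(sine_track(220, 0.3, 3, fs = 8000))
  s1 <- detect_speech_segments(tone)
  expect_equal(nrow(s1), 1)
  expect_lt(s1$start, 0.1)
  expect_gt(s1$end, 2.9)

  g <- gen_counting_audio(audio_scenario(n_bursts = 10, snr_db = 20, seed = 3))
  segs <- detect_speech_segments(envelope(g$track))
  expect_equal(nrow(segs), 10)
  env_dt <- 60 / 1000
  expect_lte(max(abs(segs$start - g$truth$start)), env_dt)
  expect_lte(max(abs(segs$end - g$truth$end)), env_dt)
})

test_that("the 50 longest counting segments are retained in time order", {
  g50 <- gen_counting_audio(audio_scenario(n_bursts = 50, seed = 4))
  s50 <- count50_segments(detect_speech_segments(envelope(g50$track)))
  expect_equal(nrow(s50), 50)

  g47 <- gen_counting_audio(audio_scenario(n_bursts = 47, seed = 5))
  expect_equal(nrow(count50_segments(detect_speech_segments(envelope(g47$track)))), 47)

  # 55 segments of known durations: selection against a sort oracle
  withr::with_seed(11, dur <- runif(55, 0.1, 0.9))
  starts <- cumsum(c(0, head(dur, -1) + 0.3))
  segs <- speech_segments(starts, starts + dur, max(starts + dur))
  kept <- count50_segments(segs)
  expect_equal(nrow(kept), 50)
  oracle <- sort(dur, decreasing = TRUE)[1:50]
  expect_equal(sort(kept$end - kept$start), sort(oracle), tolerance = 1e-12)
  expect_true(all(diff(kept$start) > 0))
})

test_that("integrated loudness matches the BS.1770 calibration point and gain laws", {
  ref <- sine_track(997, 0.1, 10)
  l <- integrated_loudness(ref)
  expect_true(l$defined)
  expect_lt(abs(l$lufs - (-23.0)), 0.2)

  l2 <- integrated_loudness(sine_track(997, 0.2, 10))
  expect_lt(abs((l2$lufs - l$lufs) - 6.02), 0.05)

  l20 <- integrated_loudness(sine_track(997, 1.0, 10))
  expect_lt(abs((l20$lufs - l$lufs) - 20), 0.1)

  silence <- audio_track(rep(0, 48000 * 2), 48000)
  expect_false(integrated_loudness(silence)$defined)
  expect_error(integrated_loudness(audio_track(rep(0.1, 1000), 48000)),
               class = "mgce_input_error")
  expect_error(integrated_loudness(audio_track(rep(0.1, 8000), 4000)),
               class = "mgce_parameter_error")
})

test_that("pitch is recovered for tonal bursts and undefined for noise", {
  for (f0 in c(220, 110)) {
    g <- gen_counting_audio(audio_scenario(n_bursts = 6, f0 = f0, snr_db = 25,
                                           seed = 6))
    segs <- detect_speech_segments(envelope(g$track))
    p <- pitch_series(g$track, segs)
    expect_true(p$defined)
    expect_lt(abs(p$median - f0), 1)
  }
  withr::with_seed(8, noise <- rnorm(8000 * 4, 0, 0.2))
  burst <- numeric(8000 * 4)
  idx <- rep(seq_len(4000), 3) + rep(c(8000, 16000, 24000), each = 4000)
  burst[idx] <- noise[idx]
  tr <- audio_track(burst, 8000)
  segs <- speech_segments(c(1, 2, 3), c(1.5, 2.5, 3.5), 4)
  expect_false(pitch_series(tr, segs)$defined)
})

test_that("breathing-band energy captures in-band lines and is linear", {
  fs <- 1000; t <- (0:(fs * 10 - 1)) / fs
  x <- 1 + 0.5 * sin(2 * pi * 10 * t)
  be <- band_energy(x, fs = fs)
  expect_equal(be$ratio, 1, tolerance = 1e-9)       # all non-DC energy at 10 Hz
  expect_equal(be$band_l2, 0.5 / sqrt(2), tolerance = 1e-9)

  x40 <- 1 + 0.5 * sin(2 * pi * 40 * t)
  expect_lt(band_energy(x40, fs = fs)$band_l2, 1e-9)

  expect_equal(band_energy(2 * x, fs = fs)$band_l2, 2 * be$band_l2,
               tolerance = 1e-9)
  expect_error(band_energy(x, fs = 40), class = "mgce_parameter_error")
})

test_that("Teager-Kaiser energy matches closed forms", {
  expect_true(all(teager_kaiser(rep(3.7, 100))$series == 0))
  expect_true(all(teager_kaiser(as.numeric(1:100))$series == 1))

  A <- 0.4; w <- 0.3
  psi <- teager_kaiser(A * sin(w * (1:5000)))$series
  expect_lt(max(abs(psi - A^2 * sin(w)^2)) / (A^2 * sin(w)^2), 1e-6)

  expect_error(teager_kaiser(c(1, 2)), class = "mgce_input_error")
})

test_that("spectral entropy is a bounded flatness measure", {
  fs <- 8000
  tone <- sine_track(1000, 0.5, 2, fs = fs)   # bin-centred at frame 512
  et <- spectral_entropy(tone)
  expect_lt(et$entropy_mean, 0.01)

  withr::with_seed(9, wn <- audio_track(rnorm(fs * 5, 0, 0.1), fs))
  en <- spectral_entropy(wn)
  expect_gte(en$entropy_mean, 0.9)
  expect_true(all(en$entropy[is.finite(en$entropy)] >= 0))
  expect_true(all(en$entropy[is.finite(en$entropy)] <= 1))

  # monotone under spectral flattening: tone < tone + noise < noise
  withr::with_seed(10, mix <- audio_track(tone$samples[1:(fs * 2)] +
                                            rnorm(fs * 2, 0, 0.1), fs))
  em <- spectral_entropy(mix)
  expect_lt(et$entropy_mean, em$entropy_mean)
  expect_lt(em$entropy_mean, en$entropy_mean)

  # two equal bins among N: entropy = log(2) / log(N)
  t2 <- (0:(fs * 2 - 1)) / fs
  two <- audio_track(0.3 * sin(2 * pi * 1000 * t2) + 0.3 * sin(2 * pi * 2000 * t2), fs)
  e2 <- spectral_entropy(two)
  expect_equal(e2$entropy_mean, log(2) / log(256), tolerance = 1e-6)

  expect_error(spectral_entropy(wn, frame_s = 0.01),
               class = "mgce_parameter_error")
})

test_that("single-breath features integrate energy over speech", {
  fs <- 8000; A <- 0.4
  starts <- seq(0, by = 0.7, length.out = 14)
  x <- numeric(fs * 10.2)
  tt <- (seq_along(x) - 1) / fs
  for (st in starts) {
    idx <- which(tt >= st & tt < st + 0.5)
    x[idx] <- A * sin(2 * pi * 200 * (tt[idx] - st))
  }
  tr <- audio_track(x, fs)
  segs <- speech_segments(starts, starts + 0.5, tr$duration)
  sb <- single_breath_features(tr, segs)
  expect_equal(sb$sb_duration, max(starts) + 0.5 - 0, tolerance = 1e-9)
  expect_equal(sb$sb_energy_integral, 14 * 0.5 * A^2 / 2, tolerance = 1e-3)
  expect_equal(sb$voiced_fraction, 14 * 0.5 / tr$duration, tolerance = 1e-9)

  single <- single_breath_features(tr, speech_segments(1, 2, tr$duration))
  expect_equal(single$sb_duration, 1)

  none <- single_breath_features(tr, speech_segments(numeric(0), numeric(0),
                                                     tr$duration))
  expect_false(none$defined)
})

test_that("the full voice-feature chain runs on synthetic counting audio", {
  g <- gen_counting_audio(audio_scenario(n_bursts = 20, seed = 13))
  vf <- voice_features(g$track, "count50")
  expect_equal(vf$n_segments, 20)
  expect_true(vf$loudness_defined)
  expect_lt(abs(vf$pitch_median - 220), 2)
  expect_true(vf$entropy_mean > 0 && vf$entropy_mean < 1)
  expect_gt(vf$sb_duration, 15)
})
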