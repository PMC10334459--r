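# Voice-feature suite for the counting-to-50 and single-breath exercises.
#
# The segmentation chain works on a rectified, block-averaged envelope: the
# raw audio is reduced to a ~1000 Hz magnitude series (RMS over sample
# blocks), then block-averaged by 60 to an ~17 Hz envelope that is smooth
# enough for a simple noise threshold to separate speech from silence
# without fragmenting into many small gaps. Spectral features that need
# bandwidth above the envelope Nyquist (the 5-25 Hz breathing band) are
# computed on the 1000 Hz magnitude series; loudness, pitch,
# Teager-Kaiser energy and spectral entropy are computed on the raw audio
# restricted to speech.

#' Reduce audio to an intermediate magnitude series
#'
#' RMS magnitude over non-overlapping sample blocks, giving a magnitude
#' series at `intermediate_fs` (default 1000 Hz).
#'
#' @param track an [audio_track()]
#' @param intermediate_fs target rate, Hz
#' @return numeric vector with attribute `fs = intermediate_fs`
#' @export
magnitude_series <- function(track, intermediate_fs = 1000) {
  stopifnot(inherits(track, "audio_track"))
  n <- length(track$samples)
  bins <- floor((seq_len(n) - 1) * intermediate_fs / track$fs)
  ms <- rowsum(track$samples^2, bins)
  cnt <- rowsum(rep(1, n), bins)
  v <- sqrt(ms[, 1] / cnt[, 1])
  attr(v, "fs") <- intermediate_fs
  v
}

#' Block-averaged speech envelope
#'
#' Rectifies and resamples the audio to an `intermediate_fs` magnitude
#' series, then averages non-overlapping blocks of `block` samples; the
#' envelope rate is exactly `intermediate_fs / block` (~17 Hz with the
#' defaults).
#'
#' @param track an [audio_track()] of duration >= 1 s
#' @param intermediate_fs intermediate magnitude-series rate, Hz (default 1000)
#' @param block block size in intermediate samples (default 60)
#' @return object of class `mgce_envelope` with `values`, `fs_env`, `t`
#'   (block-centre times), `block`, `intermediate_fs`, `track_duration`
#' @export
envelope <- function(track, intermediate_fs = 1000, block = 60) {
  stopifnot(inherits(track, "audio_track"))
  if (track$duration < 1) {
    abort_mgce("envelope needs at least 1 s of audio", "mgce_input_error")
  }
  mag <- magnitude_series(track, intermediate_fs)
  if (block > length(mag)) {
    abort_mgce("block exceeds magnitude-series length", "mgce_parameter_error")
  }
  n_blk <- floor(length(mag) / block)
  v <- colMeans(matrix(mag[seq_len(n_blk * block)], nrow = block))
  fs_env <- intermediate_fs / block
  structure(
    list(values = v, fs_env = fs_env,
         t = (seq_len(n_blk) - 0.5) / fs_env,
         block = block, intermediate_fs = intermediate_fs,
         track_duration = track$duration),
    class = "mgce_envelope"
  )
}

#' Speech segments container
#'
#' @param start,end segment boundaries, seconds (non-overlapping,
#'   increasing)
#' @param track_duration total track duration, seconds (for the voiced
#'   fraction)
#' @return data.frame of class `speech_segments` with attribute
#'   `voiced_fraction`
#' @export
speech_segments <- function(start, end, track_duration) {
  stopifnot(length(start) == length(end), all(end >= start))
  if (length(start) > 1L && any(start[-1] < end[-length(end)])) {
    abort_mgce("segments must be non-overlapping and increasing", "mgce_input_error")
  }
  structure(
    data.frame(start = start, end = end),
    class = c("speech_segments", "data.frame"),
    voiced_fraction = if (track_duration > 0) sum(end - start) / track_duration else 0,
    track_duration = track_duration
  )
}

#' Detect speech segments by envelope thresholding
#'
#' The threshold is `noise_k` times the envelope median, capped at the
#' midpoint between median and maximum so that a track that is voiced
#' throughout is still detected. Runs above threshold become segments;
#' gaps shorter than `bridge_s` are bridged and segments shorter than
#' `min_seg_s` dropped.
#'
#' @param env an [mgce_envelope()]
#' @param noise_k noise-threshold multiplier on the envelope median
#'   (default 3)
#' @param bridge_s bridge gaps shorter than this, seconds (default 0.15)
#' @param min_seg_s drop segments shorter than this, seconds (default 0.05)
#' @return a [speech_segments()]
#' @export
detect_speech_segments <- function(env, noise_k = 3, bridge_s = 0.15,
                                   min_seg_s = 0.05) {
  stopifnot(inherits(env, "mgce_envelope"))
  v <- env$values
  if (!length(v)) abort_mgce("empty envelope", "mgce_input_error")
  med <- stats::median(v)
  thr <- min(noise_k * med, (med + max(v)) / 2)
  above <- v >= thr & v > 0
  dt <- 1 / env$fs_env
  r <- rle(above)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  seg <- data.frame(i0 = starts[r$values], i1 = ends[r$values])
  if (nrow(seg) > 1L) {
    keep <- seg[1, , drop = FALSE]
    for (i in 2:nrow(seg)) {
      gap <- (seg$i0[i] - keep$i1[nrow(keep)] - 1L) * dt
      if (gap < bridge_s) keep$i1[nrow(keep)] <- seg$i1[i]
      else keep <- rbind(keep, seg[i, ])
    }
    seg <- keep
  }
  if (nrow(seg)) {
    dur <- (seg$i1 - seg$i0 + 1L) * dt
    seg <- seg[dur >= min_seg_s, , drop = FALSE]
  }
  speech_segments((seg$i0 - 1L) * dt, seg$i1 * dt, env$track_duration)
}

#' Keep the 50 longest speech segments of a counting exercise
#'
#' The counting-to-50 exercise yields one sound interval per spoken
#' number; the 50 longest intervals above noise are retained (all, when
#' fewer), ties broken by earlier start, and returned in time order.
#'
#' @param segments a [speech_segments()]
#' @param n number to keep (default 50)
#' @return a [speech_segments()] with at most `n` rows
#' @export
count50_segments <- function(segments, n = 50L) {
  seg <- as.data.frame(segments)
  if (nrow(seg) > n) {
    dur <- seg$end - seg$start
    ord <- order(-dur, seg$start)
    seg <- seg[sort(ord[seq_len(n)]), ]
  }
  speech_segments(seg$start, seg$end, attr(segments, "track_duration"))
}

# sample indices covered by segments
segment_sample_index <- function(segments, fs, n_total) {
  seg <- as.data.frame(segments)
  unlist(lapply(seq_len(nrow(seg)), function(i) {
    i0 <- max(1L, floor(seg$start[i] * fs) + 1L)
    i1 <- min(n_total, ceiling(seg$end[i] * fs))
    if (i1 >= i0) seq(i0, i1) else integer(0)
  }))
}

#' Per-segment fundamental frequency statistics
#'
#' f0 per speech segment by normalized autocorrelation over a 50-400 Hz
#' search range (spanning typical adult male, 85-155 Hz, and female,
#' 165-255 Hz, speech); a segment is voiced when its peak normalized
#' autocorrelation reaches `voiced_min_corr`. Median and IQR are taken
#' over voiced segments.
#'
#' @param track an [audio_track()]
#' @param segments a [speech_segments()] (non-empty)
#' @param f_min,f_max search range, Hz
#' @param voiced_min_corr voicing threshold on the autocorrelation peak
#'   (default 0.5)
#' @return list with `per_segment` (data.frame segment/f0/voiced),
#'   `median`, `iqr`, `defined`
#' @export
pitch_series <- function(track, segments, f_min = 50, f_max = 400,
                         voiced_min_corr = 0.5) {
  stopifnot(inherits(track, "audio_track"))
  seg <- as.data.frame(segments)
  if (!nrow(seg)) abort_mgce("no segments to analyze", "mgce_input_error")
  fs <- track$fs
  lag_min <- max(2L, floor(fs / f_max))
  lag_max <- ceiling(fs / f_min)
  f0 <- rep(NA_real_, nrow(seg)); voiced <- rep(FALSE, nrow(seg))
  for (i in seq_len(nrow(seg))) {
    idx <- segment_sample_index(seg[i, , drop = FALSE], fs, length(track$samples))
    x <- track$samples[idx]
    x <- x - mean(x)
    if (length(x) < 2L * lag_max || sum(x^2) == 0) next
    # FFT autocorrelation
    nfft <- stats::nextn(2L * length(x), 2)
    X <- stats::fft(c(x, rep(0, nfft - length(x))))
    r <- Re(stats::fft(Mod(X)^2, inverse = TRUE)) / nfft
    r <- r / r[1]
    lags <- lag_min:min(lag_max, length(r) - 1L)
    pk <- which.max(r[lags + 1L])
    if (r[lags[pk] + 1L] >= voiced_min_corr) {
      lag <- lags[pk] + refine_parabolic(r, lags[pk] + 1L)
      f0[i] <- fs / lag
      voiced[i] <- TRUE
    }
  }
  defined <- any(voiced)
  list(
    per_segment = data.frame(segment = seq_len(nrow(seg)), f0 = f0,
                             voiced = voiced),
    median = if (defined) stats::median(f0[voiced]) else NA_real_,
    iqr = if (defined) stats::IQR(f0[voiced]) else NA_real_,
    defined = defined
  )
}

#' Spectral energy in the breathing band
#'
#' L2 norm of the Fourier coefficients of the whole-exercise magnitude
#' series restricted to the breathing-rate window (5-25 Hz by default).
#' Both counting exercises engage respiration, and low-frequency amplitude
#' modulation of the voice carries the breathing rhythm; the band energy
#' must therefore be computed on a series whose Nyquist rate exceeds the
#' band (the ~1000 Hz magnitude series, not the ~17 Hz envelope).
#'
#' @param x an [audio_track()] (reduced internally to its magnitude
#'   series), or a numeric series with `fs` given
#' @param fs sampling rate of `x` when numeric, Hz
#' @param f_lo,f_hi band bounds, Hz (defaults 5 and 25)
#' @param intermediate_fs magnitude-series rate used for an audio track
#' @return list with `band_l2`, `total_l2` (DC excluded), `ratio`
#' @export
band_energy <- function(x, fs = NULL, f_lo = 5, f_hi = 25,
                        intermediate_fs = 1000) {
  if (inherits(x, "audio_track")) {
    x <- magnitude_series(x, intermediate_fs)
    fs <- attr(x, "fs")
  }
  if (is.null(fs)) abort_mgce("fs required for a plain numeric series",
                              "mgce_parameter_error")
  if (fs / 2 <= f_hi) {
    abort_mgce(sprintf("series Nyquist (%.3g Hz) must exceed f_hi (%g Hz)",
                       fs / 2, f_hi), "mgce_parameter_error")
  }
  n <- length(x)
  co <- stats::fft(x) / n
  k <- seq(2L, floor(n / 2) + 1L)       # one-sided, DC excluded
  f <- (k - 1L) * fs / n
  amp2 <- 2 * Mod(co[k])^2              # fold negative frequencies
  in_band <- f >= f_lo & f <= f_hi
  band <- sqrt(sum(amp2[in_band]))
  total <- sqrt(sum(amp2))
  list(band_l2 = band, total_l2 = total,
       ratio = if (total > 0) band / total else NA_real_)
}

#' Teager-Kaiser energy operator
#'
#' `psi(n) = x(n)^2 - x(n-1) x(n+1)`, an instantaneous-energy estimate
#' used for tone detection; for a sinusoid `A sin(w n)` it is the constant
#' `A^2 sin(w)^2`.
#'
#' @param x an [audio_track()] or numeric vector (>= 3 samples)
#' @param segments optional [speech_segments()]; the mean is then taken
#'   over speech samples only
#' @return list with `series` (length `n - 2`) and `mean`
#' @export
teager_kaiser <- function(x, segments = NULL) {
  fs <- NULL
  if (inherits(x, "audio_track")) { fs <- x$fs; x <- x$samples }
  n <- length(x)
  if (n < 3L) abort_mgce("need at least 3 samples", "mgce_input_error")
  psi <- x[2:(n - 1L)]^2 - x[1:(n - 2L)] * x[3:n]
  m <- if (!is.null(segments) && !is.null(fs)) {
    idx <- segment_sample_index(segments, fs, n)
    idx <- idx[idx >= 2L & idx <= n - 1L]
    if (length(idx)) mean(psi[idx - 1L]) else NA_real_
  } else {
    mean(psi)
  }
  list(series = psi, mean = m)
}

# peak prominence on a series: height above the higher of the two minima
# separating the peak from the nearest higher point on each side
peak_prominences <- function(v) {
  n <- length(v)
  is_peak <- which(diff(sign(diff(v))) < 0) + 1L
  prom <- vapply(is_peak, function(i) {
    lm <- v[i]; j <- i
    while (j > 1L && v[j - 1L] <= v[i]) { j <- j - 1L; lm <- min(lm, v[j]) }
    rm_ <- v[i]; j <- i
    while (j < n && v[j + 1L] <= v[i]) { j <- j + 1L; rm_ <- min(rm_, v[j]) }
    v[i] - max(lm, rm_)
  }, numeric(1))
  data.frame(index = is_peak, prominence = prom)
}

#' Frame-wise spectral entropy of the voice signal
#'
#' Per frame the normalized power spectrum is treated as a probability
#' distribution and its Shannon entropy, divided by `log(n_bins)`, gives a
#' flatness measure in `[0, 1]` (a pure tone concentrates on one bin,
#' entropy ~ 0; white noise is flat, entropy near 1). Silent frames are
#' excluded from the mean. Entropy peaks - local maxima with prominence at
#' least `peak_prominence` - are counted; intermittent prosody modulation
#' raises the count, a monotonic voice lowers it.
#'
#' @param track an [audio_track()]
#' @param frame_s analysis frame, seconds (frame must be >= 256 samples)
#' @param hop_s hop between frames, seconds
#' @param peak_prominence prominence threshold for peak counting
#'   (default 0.1)
#' @return list with `t`, `entropy` (per frame, `NA` for silent frames),
#'   `entropy_mean`, `entropy_peaks`
#' @export
spectral_entropy <- function(track, frame_s = 0.064, hop_s = 0.032,
                             peak_prominence = 0.1) {
  stopifnot(inherits(track, "audio_track"))
  n_frame <- round(frame_s * track$fs)
  if (n_frame < 256L) {
    abort_mgce("entropy frame must span at least 256 samples", "mgce_parameter_error")
  }
  hop <- max(1L, round(hop_s * track$fs))
  x <- track$samples
  starts <- seq(1L, length(x) - n_frame + 1L, by = hop)
  nb <- floor(n_frame / 2)
  ent <- vapply(starts, function(s) {
    fr <- x[s:(s + n_frame - 1L)]
    p <- Mod(stats::fft(fr))[2:(nb + 1L)]^2   # one-sided, DC excluded
    tot <- sum(p)
    if (tot <= 0) return(NA_real_)
    p <- p / tot
    p <- p[p > 0]
    -sum(p * log(p)) / log(nb)
  }, numeric(1))
  tt <- (starts - 1L + n_frame / 2) / track$fs
  valid <- is.finite(ent)
  peaks <- if (sum(valid) >= 3L) {
    pr <- peak_prominences(ent[valid])
    sum(pr$prominence >= peak_prominence)
  } else 0L
  list(t = tt, entropy = ent,
       entropy_mean = if (any(valid)) mean(ent[valid]) else NA_real_,
       entropy_peaks = peaks)
}

#' Single-breath counting features
#'
#' The exercise duration (first speech onset to last speech offset) is the
#' primary severity indicator; the energy integral (sum of squared
#' amplitude over speech, times the sample period) approximates expended
#' airflow volume up to microphone calibration; the voiced fraction
#' summarizes diction pacing.
#'
#' @param track an [audio_track()]
#' @param segments a [speech_segments()]
#' @return list with `sb_duration` (s), `sb_energy_integral`
#'   (amplitude^2 s), `voiced_fraction`, `defined`
#' @export
single_breath_features <- function(track, segments) {
  seg <- as.data.frame(segments)
  if (!nrow(seg)) {
    return(list(sb_duration = NA_real_, sb_energy_integral = NA_real_,
                voiced_fraction = attr(segments, "voiced_fraction"),
                defined = FALSE))
  }
  idx <- segment_sample_index(segments, track$fs, length(track$samples))
  list(
    sb_duration = max(seg$end) - min(seg$start),
    sb_energy_integral = sum(track$samples[idx]^2) / track$fs,
    voiced_fraction = attr(segments, "voiced_fraction"),
    defined = TRUE
  )
}

#' Full voice-feature set for one exercise
#'
#' Runs the whole chain: envelope, segment detection (optionally capped at
#' the 50 longest for the counting exercise), loudness, pitch, breathing
#' band energy, Teager-Kaiser energy, spectral entropy and single-breath
#' features.
#'
#' @param track an [audio_track()]
#' @param exercise `"count50"` or `"single_breath"`
#' @param noise_k envelope threshold multiplier
#' @return list of class `voice_feature_set`
#' @export
voice_features <- function(track, exercise = c("count50", "single_breath"),
                           noise_k = 3) {
  exercise <- match.arg(exercise)
  env <- envelope(track)
  segs <- detect_speech_segments(env, noise_k = noise_k)
  if (exercise == "count50") segs <- count50_segments(segs)
  loud <- if (nrow(segs)) integrated_loudness(track, segs) else
    structure(list(lufs = NA_real_, defined = FALSE), class = "mgce_loudness")
  pit <- if (nrow(segs)) pitch_series(track, segs) else
    list(median = NA_real_, iqr = NA_real_, defined = FALSE)
  be <- band_energy(track)
  tke <- teager_kaiser(track, segs)
  ent <- spectral_entropy(track)
  sb <- single_breath_features(track, segs)
  structure(
    list(
      exercise = exercise, segments = segs,
      n_segments = nrow(segs),
      voiced_fraction = attr(segs, "voiced_fraction"),
      loudness_lufs = loud$lufs, loudness_defined = loud$defined,
      pitch_median = pit$median, pitch_iqr = pit$iqr,
      pitch_defined = pit$defined,
      band_energy = be$band_l2, band_ratio = be$ratio,
      tke_mean = tke$mean,
      entropy_mean = ent$entropy_mean, entropy_peaks = ent$entropy_peaks,
      sb_duration = sb$sb_duration,
      sb_energy_integral = sb$sb_energy_integral
    ),
    class = "voice_feature_set"
  )
}
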