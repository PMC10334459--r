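# Session orchestration: run every configured exercise analyzer on its
# time window, isolate failures, grade, and emit a structured JSON report.

#' Load and validate a session configuration
#'
#' The config (YAML or JSON file, or an equivalent named list) declares
#' per-exercise inputs and windows:
#' \preformatted{
#' seed: 1
#' calibration: {known_length_cm: 45, measured_px: 150}
#' exercises:
#'   ptosis:          {measures_csv: ptosis.csv, window: [0, 60]}
#'   diplopia:        {alignment_csv: align.csv, onset_s: none}
#'   cheek_puff:      {landmarks_csv: face.csv, annotation: normal_seal}
#'   tongue_to_cheek: {landmarks_csv: face.csv, annotation: full_deformity}
#'   count50:         {audio_wav: count.wav, dysarthria_onset_count: none}
#'   arm_strength:    {landmarks_csv: body.csv}
#'   single_breath:   {audio_wav: sb.wav, count: 32}
#'   sit_to_stand:    {landmarks_csv: body.csv, annotation: no_difficulty}
#' }
#' `"none"` marks an absent clinical event (no diplopia, no drift, no
#' dysarthria). Paths are resolved relative to the config file.
#'
#' @param config path to a YAML/JSON file, or a named list
#' @return validated config list of class `session_config`
#' @export
session_config <- function(config) {
  base_dir <- "."
  if (is.character(config)) {
    if (!file.exists(config)) {
      abort_mgce(sprintf("config file not found: %s", config), "mgce_config_error")
    }
    base_dir <- dirname(config)
    config <- if (tolower(tools::file_ext(config)) %in% c("yml", "yaml")) {
      yaml::read_yaml(config)
    } else {
      jsonlite::fromJSON(config, simplifyVector = TRUE)
    }
  }
  if (!is.list(config) || is.null(config$exercises) || !length(config$exercises)) {
    abort_mgce("config must declare at least one exercise", "mgce_config_error")
  }
  unknown <- setdiff(names(config$exercises), mgce_items)
  if (length(unknown)) {
    abort_mgce(sprintf("unknown exercises in config: %s",
                       paste(unknown, collapse = ", ")), "mgce_config_error")
  }
  for (item in names(config$exercises)) {
    ex <- config$exercises[[item]]
    # resolve paths relative to the config file; a missing file is not a
    # config error - the exercise is isolated and skipped at run time
    for (field in intersect(names(ex), c("measures_csv", "alignment_csv",
                                         "landmarks_csv", "audio_wav"))) {
      p <- ex[[field]]
      if (!file.exists(p) && file.exists(file.path(base_dir, p))) {
        config$exercises[[item]][[field]] <- file.path(base_dir, p)
      }
    }
    w <- ex$window
    if (!is.null(w) && (length(w) != 2L || w[2] <= w[1])) {
      abort_mgce(sprintf("%s: window must be [t0, t1] with t1 > t0", item),
                 "mgce_config_error")
    }
  }
  config$seed <- config$seed %||% 1L
  structure(config, class = c("session_config", "list"))
}

# "none" / NULL-tolerant scalar extraction for clinical annotations
annot_value <- function(x) {
  if (is.null(x)) return(NULL)
  if (is.character(x) && tolower(x) == "none") return(NA_real_)
  x
}

trim_stream <- function(stream, window) {
  if (is.null(window)) return(stream)
  keep <- stream$t >= window[1] & stream$t <= window[2]
  landmark_stream(stream$frames[keep], conf_floor = stream$conf_floor)
}

trim_track <- function(track, window) {
  if (is.null(window)) return(track)
  i0 <- max(1L, floor(window[1] * track$fs) + 1L)
  i1 <- min(length(track$samples), ceiling(window[2] * track$fs))
  audio_track(track$samples[i0:i1], track$fs)
}

read_measures_csv <- function(path, window = NULL) {
  df <- utils::read.csv(path)
  need <- c("t", "d_lid_pupil", "d_lid_lid", "area")
  if (!all(need %in% names(df))) {
    abort_mgce(sprintf("measures CSV needs columns %s", paste(need, collapse = ", ")),
               "mgce_parse_error")
  }
  if (!is.null(window)) df <- df[df$t >= window[1] & df$t <= window[2], ]
  df$mask <- stats::complete.cases(df[, need])
  structure(df, class = c("ptosis_series", "data.frame"), normalized = FALSE)
}

# per-item analyzers; each returns a metrics list and grading inputs
session_analyzers <- list(
  ptosis = function(ex, config) {
    series <- read_measures_csv(ex$measures_csv, ex$window)
    fit <- fit_linear_decay(series, "d_lid_pupil")
    d_end <- fit$intercept + fit$slope * fit$window[2]
    inputs <- list(d_lid_pupil = d_end)
    if (!is.null(ex$annotation)) {
      inputs <- list(ptosis_category = ex$annotation)
    }
    list(
      metrics = list(slope_px_s = fit$slope, percent_decay = fit$percent_decay,
                     p_value = fit$p_value, d_lid_pupil_end = d_end,
                     n_frames = sum(series$mask)),
      grade_inputs = inputs
    )
  },
  diplopia = function(ex, config) {
    df <- utils::read.csv(ex$alignment_csv)
    if (!all(c("t", "b_left", "b_right") %in% names(df))) {
      abort_mgce("alignment CSV needs columns t, b_left, b_right", "mgce_parse_error")
    }
    if (!is.null(ex$window)) df <- df[df$t >= ex$window[1] & df$t <= ex$window[2], ]
    delta <- df$b_left - df$b_right
    offset <- stats::median(delta[df$t <= df$t[1] + 2])
    series <- structure(
      data.frame(t = df$t, b_left = df$b_left, b_right = df$b_right,
                 misalignment = abs(delta - offset)),
      class = c("alignment_series", "data.frame"), baseline_offset = offset
    )
    summ <- alignment_summary(series)
    onset <- annot_value(ex$onset_s)
    list(
      metrics = list(max_misalignment = summ$max_misalignment,
                     drift_slope = summ$drift_slope, steady = summ$steady),
      grade_inputs = if (is.null(onset)) list() else list(onset_s = onset)
    )
  },
  cheek_puff = function(ex, config) {
    stream <- trim_stream(load_landmark_stream(ex$landmarks_csv, "face68"),
                          ex$window)
    feats <- mouth_feature_series(stream)
    ev <- detect_deformation_events(feats$t, feats$upper_lip_nose_distance,
                                    mask = feats$mask)
    list(
      metrics = list(
        n_events = nrow(ev),
        event_amplitude = if (nrow(ev)) max(abs(ev$amplitude)) else 0,
        event_start = if (nrow(ev)) ev$start[1] else NA,
        event_end = if (nrow(ev)) ev$end[nrow(ev)] else NA,
        seal_fraction = mean(feats$seal[feats$mask])
      ),
      grade_inputs = if (is.null(ex$annotation)) list()
                     else list(annotation = ex$annotation)
    )
  },
  tongue_to_cheek = function(ex, config) {
    stream <- trim_stream(load_landmark_stream(ex$landmarks_csv, "face68"),
                          ex$window)
    feats <- mouth_feature_series(stream)
    switch_t <- side_switch_detector(feats$t, feats$mouth_angle)
    ev <- detect_deformation_events(feats$t, feats$mouth_angle,
                                    mask = feats$mask)
    list(
      metrics = list(switch_time_s = switch_t, n_events = nrow(ev)),
      grade_inputs = if (is.null(ex$annotation)) list()
                     else list(annotation = ex$annotation)
    )
  },
  count50 = function(ex, config) {
    track <- trim_track(read_wav(ex$audio_wav), ex$window)
    vf <- voice_features(track, "count50")
    onset <- annot_value(ex$dysarthria_onset_count)
    list(
      metrics = list(
        n_segments = vf$n_segments, voiced_fraction = vf$voiced_fraction,
        loudness_lufs = vf$loudness_lufs, pitch_median = vf$pitch_median,
        pitch_iqr = vf$pitch_iqr, band_energy = vf$band_energy,
        tke_mean = vf$tke_mean, entropy_mean = vf$entropy_mean,
        entropy_peaks = vf$entropy_peaks
      ),
      grade_inputs = if (is.null(onset)) list()
                     else list(dysarthria_onset_count = onset)
    )
  },
  arm_strength = function(ex, config) {
    stream <- trim_stream(load_landmark_stream(ex$landmarks_csv, "body33"),
                          ex$window)
    series <- arm_angle_series(stream)
    drift <- detect_arm_drift(series,
                              threshold_deg = ex$threshold_deg %||% 5,
                              hold_s = ex$hold_s %||% 1)
    onsets <- c(drift$left, drift$right)
    worst <- if (all(is.na(onsets))) NA_real_ else min(onsets, na.rm = TRUE)
    slope_l <- ols_slope(series$t[series$mask], series$theta_left[series$mask])
    list(
      metrics = list(drift_onset_left = drift$left,
                     drift_onset_right = drift$right,
                     slope_left_deg_s = slope_l$slope),
      grade_inputs = list(drift_onset_s = worst)
    )
  },
  single_breath = function(ex, config) {
    track <- trim_track(read_wav(ex$audio_wav), ex$window)
    vf <- voice_features(track, "single_breath")
    list(
      metrics = list(
        sb_duration = vf$sb_duration,
        sb_energy_integral = vf$sb_energy_integral,
        voiced_fraction = vf$voiced_fraction,
        loudness_lufs = vf$loudness_lufs
      ),
      grade_inputs = if (is.null(ex$count)) list() else list(count = ex$count)
    )
  },
  sit_to_stand = function(ex, config) {
    stream <- trim_stream(load_landmark_stream(ex$landmarks_csv, "body33"),
                          ex$window)
    calib <- if (!is.null(config$calibration)) {
      calibrate_pixels(config$calibration$known_length_cm,
                       config$calibration$measured_px)
    }
    kin <- stand_kinematics(stream, calib = calib)
    list(
      metrics = list(
        rise_start = kin$rise_start, rise_end = kin$rise_end,
        peak_speed_px_s = kin$peak_speed_px_s,
        peak_speed_cm_s = kin$peak_speed_cm_s,
        lateral_sway_px = kin$lateral_sway_px
      ),
      grade_inputs = if (is.null(ex$annotation)) list()
                     else list(annotation = ex$annotation)
    )
  }
)

# short stable polynomial hash of the config for report provenance
config_hash <- function(config) {
  bytes <- utils::head(charToRaw(jsonlite::toJSON(unclass(config),
                                                  auto_unbox = TRUE)), 1e6)
  h <- 0
  for (b in as.integer(bytes)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Run a full examination session
#'
#' Executes every configured exercise analyzer on its window. A failure in
#' one analyzer never aborts the session: the exercise is reported with
#' status `skipped` (input missing/invalid) and its reason, while the rest
#' run normally. Items whose analyzer ran but whose grading inputs are
#' absent are `partial`.
#'
#' @param config a [session_config()] (or path / list accepted by it)
#' @return list of class `session_report`
#' @export
run_session <- function(config) {
  config <- session_config(config)
  set.seed(config$seed)
  exercises <- list()
  grade_bundle <- list()
  for (item in mgce_items) {
    ex <- config$exercises[[item]]
    if (is.null(ex)) {
      exercises[[item]] <- list(status = "skipped", reason = "not configured")
      next
    }
    res <- tryCatch(
      session_analyzers[[item]](ex, config),
      error = function(e) e
    )
    if (inherits(res, "error")) {
      exercises[[item]] <- list(status = "skipped",
                                reason = conditionMessage(res))
      next
    }
    has_grade_input <- length(res$grade_inputs) > 0
    exercises[[item]] <- list(
      status = if (has_grade_input) "ok" else "partial",
      metrics = res$metrics
    )
    if (!has_grade_input) {
      exercises[[item]]$reason <- "metrics computed; grading input not provided"
    }
    grade_bundle[[item]] <- res$grade_inputs
  }
  grades <- if (length(grade_bundle)) {
    lapply(grade_session(grade_bundle), function(g) {
      list(grade = g$grade, basis = g$basis, note = g$note)
    })
  } else {
    list()
  }
  structure(
    list(
      version = as.character(utils::packageVersion("mgcekit")),
      seed = config$seed,
      config_hash = config_hash(config),
      exercises = exercises,
      grades = grades
    ),
    class = c("session_report", "list")
  )
}

#' Write a session report to JSON
#'
#' @param report a `session_report`
#' @param path destination JSON
#' @return `path`, invisibly
#' @export
write_report <- function(report, path) {
  validate_report(report)
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       digits = NA, na = "null", null = "null", pretty = TRUE)
  invisible(path)
}

#' Read and validate a session report
#'
#' @param path JSON report file
#' @return a `session_report`
#' @export
read_report <- function(path) {
  rep <- jsonlite::fromJSON(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  rep <- structure(rep, class = c("session_report", "list"))
  validate_report(rep)
  rep
}

#' Validate the session-report schema
#'
#' Required: `version`, `seed`, `exercises` with every one of the eight
#' exam items present and carrying a status in `ok/partial/skipped`.
#'
#' @param report candidate report
#' @return `TRUE` invisibly; throws a serialization error on violation
#' @export
validate_report <- function(report) {
  need <- c("version", "seed", "exercises", "grades")
  missing_f <- setdiff(need, names(report))
  if (length(missing_f)) {
    abort_mgce(sprintf("report missing fields: %s", paste(missing_f, collapse = ", ")),
               "mgce_serialization_error")
  }
  if (!length(report$exercises)) {
    abort_mgce("report has no exercises", "mgce_serialization_error")
  }
  missing_i <- setdiff(mgce_items, names(report$exercises))
  if (length(missing_i)) {
    abort_mgce(sprintf("report missing exam items: %s",
                       paste(missing_i, collapse = ", ")),
               "mgce_serialization_error")
  }
  for (item in mgce_items) {
    st <- report$exercises[[item]]$status
    if (is.null(st) || !st %in% c("ok", "partial", "skipped")) {
      abort_mgce(sprintf("exercise '%s' has invalid status '%s'", item,
                         if (is.null(st)) "<missing>" else st),
                 "mgce_serialization_error")
    }
  }
  invisible(TRUE)
}

#' @export
print.session_report <- function(x, ...) {
  cat(sprintf("<session_report> v%s seed=%s config=%s\n",
              x$version, x$seed, x$config_hash))
  for (item in names(x$exercises)) {
    ex <- x$exercises[[item]]
    g <- x$grades[[item]]
    gtxt <- if (!is.null(g) && !is.null(g$grade) && !is.na(g$grade)) {
      sprintf(" grade=%d", g$grade)
    } else ""
    cat(sprintf("  %-16s %s%s\n", item, ex$status, gtxt))
  }
  invisible(x)
}
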