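# Ordinal 0-3 severity grading of the eight MG-CE exam items.
#
# The printed grading boundaries are applied verbatim, with inclusive
# interval semantics ("11-60 s" means 11 <= t <= 60). Two items leave a
# seam between printed rows: an arm-drift onset of exactly 120 s (between
# "no drift for >120 s" and "drift at 90-119 s") and a dysarthria onset at
# exactly 50; both resolve to the milder grade. Items whose clinical
# category is visual (cheek seal quality, use of hands when standing) take
# a manual annotation; automated features accompany them as supporting
# evidence only.

#' The eight MG-CE exam items
#' @export
mgce_items <- c("ptosis", "diplopia", "cheek_puff", "tongue_to_cheek",
                "count50", "arm_strength", "single_breath", "sit_to_stand")

grade_labels <- c("normal", "mild", "moderate", "severe")

#' Map a lid-to-pupil distance to a ptosis category
#'
#' @param d_lid_pupil signed vertical distance from the upper lid down to
#'   the pupil centre, px (positive = lid above the pupil)
#' @param at_tol half-width of the "eyelid at the pupil" band, px
#'   (default 1)
#' @return `"above_pupil"`, `"at_pupil"` or `"below_pupil"` (the
#'   distinction between no ptosis and a lid above the pupil is clinical
#'   and must be annotated)
#' @export
ptosis_category <- function(d_lid_pupil, at_tol = 1) {
  if (!is_finite_num(d_lid_pupil)) {
    abort_mgce("d_lid_pupil must be finite", "mgce_input_error")
  }
  if (abs(d_lid_pupil) <= at_tol) "at_pupil"
  else if (d_lid_pupil > at_tol) "above_pupil"
  else "below_pupil"
}

grade_result <- function(item, grade, basis, note = "") {
  structure(
    list(item = item, grade = grade, basis = basis, note = note,
         gradable = !is.na(grade)),
    class = "grade_result"
  )
}

#' @export
print.grade_result <- function(x, ...) {
  if (x$gradable) {
    cat(sprintf("<grade> %s: %d (%s) - %s\n", x$item, x$grade,
                grade_labels[x$grade + 1L], x$basis))
  } else {
    cat(sprintf("<grade> %s: ungradable - %s\n", x$item, x$note))
  }
  invisible(x)
}

cat_grade <- function(value, levels, item) {
  g <- match(value, levels) - 1L
  if (is.na(g)) {
    abort_mgce(sprintf("unknown %s annotation '%s' (expected one of: %s)",
                       item, value, paste(levels, collapse = ", ")),
               "mgce_input_error")
  }
  g
}

#' Grade a single MG-CE item
#'
#' `inputs` is a named list carrying the item's rule inputs:
#' \describe{
#'   \item{ptosis}{`ptosis_category` in `none / above_pupil / at_pupil /
#'     below_pupil` (or `d_lid_pupil` in px, mapped via
#'     [ptosis_category()])}
#'   \item{diplopia}{`onset_s` (seconds to double vision; `NA` = none)}
#'   \item{cheek_puff}{`annotation` in `normal_seal / transverse_pucker /
#'     air_escapes / cannot_perform`}
#'   \item{tongue_to_cheek}{`annotation` in `full_deformity /
#'     partial_deformity / no_deformity / cannot_perform`}
#'   \item{count50}{`dysarthria_onset_count` (number at which dysarthria
#'     appeared; `NA` = none)}
#'   \item{arm_strength}{`drift_onset_s` (`NA` = no drift)}
#'   \item{single_breath}{`count` (highest number reached)}
#'   \item{sit_to_stand}{`annotation` in `no_difficulty / slow_no_hands /
#'     need_hands / unable`}
#' }
#' An optional `exercise_duration_s` is validated against onset inputs.
#'
#' @param item one of [mgce_items]
#' @param inputs named list, see above
#' @return a `grade_result` (grade `NA` with a reason when the required
#'   input is missing)
#' @export
grade_item <- function(item, inputs = list()) {
  item <- match.arg(item, mgce_items)
  need <- function(field) {
    if (is.null(inputs[[field]])) {
      return(grade_result(item, NA_integer_, basis = "",
                          note = sprintf("missing required input '%s'", field)))
    }
    NULL
  }
  check_onset <- function(onset) {
    dur <- inputs$exercise_duration_s
    if (!is.null(dur) && is.finite(onset) && onset > dur) {
      abort_mgce(sprintf("onset %.1f s exceeds exercise duration %.1f s",
                         onset, dur), "mgce_input_error")
    }
  }
  switch(item,
    ptosis = {
      cat_ <- inputs$ptosis_category
      if (is.null(cat_) && !is.null(inputs$d_lid_pupil)) {
        cat_ <- ptosis_category(inputs$d_lid_pupil,
                                at_tol = inputs$at_tol %||% 1)
      }
      if (is.null(cat_)) return(need("ptosis_category"))
      g <- cat_grade(cat_, c("none", "above_pupil", "at_pupil", "below_pupil"),
                     "ptosis")
      grade_result(item, g, basis = sprintf("ptosis_category=%s", cat_))
    },
    diplopia = {
      if (is.null(inputs$onset_s)) return(need("onset_s"))
      onset <- inputs$onset_s
      check_onset(onset)
      g <- if (is.na(onset) || onset >= 61) 0L
      else if (onset >= 11) 1L
      else if (onset >= 1) 2L
      else 3L
      grade_result(item, g, basis = sprintf("diplopia onset %s s",
                                            format(onset)))
    },
    cheek_puff = {
      if (is.null(inputs$annotation)) return(need("annotation"))
      g <- cat_grade(inputs$annotation,
                     c("normal_seal", "transverse_pucker", "air_escapes",
                       "cannot_perform"), "cheek_puff")
      grade_result(item, g, basis = sprintf("annotation=%s", inputs$annotation),
                   note = "visual category; automated features are supporting evidence")
    },
    tongue_to_cheek = {
      if (is.null(inputs$annotation)) return(need("annotation"))
      g <- cat_grade(inputs$annotation,
                     c("full_deformity", "partial_deformity", "no_deformity",
                       "cannot_perform"), "tongue_to_cheek")
      grade_result(item, g, basis = sprintf("annotation=%s", inputs$annotation),
                   note = "visual category; automated features are supporting evidence")
    },
    count50 = {
      if (is.null(inputs$dysarthria_onset_count)) {
        return(need("dysarthria_onset_count"))
      }
      cnt <- inputs$dysarthria_onset_count
      g <- if (is.na(cnt) || cnt >= 50) 0L
      else if (cnt >= 30) 1L
      else if (cnt >= 10) 2L
      else 3L
      grade_result(item, g, basis = sprintf("dysarthria onset at count %s",
                                            format(cnt)))
    },
    arm_strength = {
      if (is.null(inputs$drift_onset_s)) return(need("drift_onset_s"))
      onset <- inputs$drift_onset_s
      check_onset(onset)
      g <- if (is.na(onset) || onset >= 120) 0L
      else if (onset >= 90) 1L
      else if (onset >= 10) 2L
      else 3L
      grade_result(item, g, basis = sprintf("drift onset %s s", format(onset)))
    },
    single_breath = {
      if (is.null(inputs$count)) return(need("count"))
      cnt <- inputs$count
      g <- if (cnt >= 30) 0L else if (cnt >= 25) 1L else if (cnt >= 20) 2L else 3L
      grade_result(item, g, basis = sprintf("single-breath count %d", cnt))
    },
    sit_to_stand = {
      if (is.null(inputs$annotation)) return(need("annotation"))
      g <- cat_grade(inputs$annotation,
                     c("no_difficulty", "slow_no_hands", "need_hands", "unable"),
                     "sit_to_stand")
      grade_result(item, g, basis = sprintf("annotation=%s", inputs$annotation),
                   note = "visual category; automated features are supporting evidence")
    }
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Grade all items of a session
#'
#' @param bundle named list: one entry per item id with that item's
#'   `inputs` (see [grade_item()]); items without an entry are reported
#'   ungradable
#' @return named list of `grade_result`, one per item
#' @export
grade_session <- function(bundle) {
  if (!length(bundle)) abort_mgce("empty metrics bundle", "mgce_input_error")
  unknown <- setdiff(names(bundle), mgce_items)
  if (length(unknown)) {
    abort_mgce(sprintf("unknown exam items: %s", paste(unknown, collapse = ", ")),
               "mgce_input_error")
  }
  res <- lapply(mgce_items, function(item) {
    grade_item(item, bundle[[item]] %||% list())
  })
  names(res) <- mgce_items
  res
}
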