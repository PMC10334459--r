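test_that("printed grading rows are applied verbatim", {
  expect_equal(grade_item("single_breath", list(count = 30))$grade, 0L)
  expect_equal(grade_item("single_breath", list(count = 29))$grade, 1L)
  expect_equal(grade_item("single_breath", list(count = 22))$grade, 2L)
  expect_equal(grade_item("single_breath", list(count = 19))$grade, 3L)

  expect_equal(grade_item("diplopia", list(onset_s = NA))$grade, 0L)
  expect_equal(grade_item("diplopia", list(onset_s = 61))$grade, 0L)
  expect_equal(grade_item("diplopia", list(onset_s = 60))$grade, 1L)
  expect_equal(grade_item("diplopia", list(onset_s = 5))$grade, 2L)
  expect_equal(grade_item("diplopia", list(onset_s = 0))$grade, 3L)

  expect_equal(grade_item("arm_strength", list(drift_onset_s = NA))$grade, 0L)
  expect_equal(grade_item("arm_strength", list(drift_onset_s = 95))$grade, 1L)
  expect_equal(grade_item("arm_strength", list(drift_onset_s = 45))$grade, 2L)
  expect_equal(grade_item("arm_strength", list(drift_onset_s = 5))$grade, 3L)
  # seam: exactly 120 s resolves to the milder grade
  expect_equal(grade_item("arm_strength", list(drift_onset_s = 120))$grade, 0L)

  expect_equal(grade_item("count50", list(dysarthria_onset_count = NA))$grade, 0L)
  expect_equal(grade_item("count50", list(dysarthria_onset_count = 35))$grade, 1L)
  expect_equal(grade_item("count50", list(dysarthria_onset_count = 15))$grade, 2L)
  expect_equal(grade_item("count50", list(dysarthria_onset_count = 5))$grade, 3L)

  expect_equal(grade_item("ptosis", list(ptosis_category = "none"))$grade, 0L)
  expect_equal(grade_item("ptosis", list(ptosis_category = "at_pupil"))$grade, 2L)
  expect_equal(grade_item("ptosis", list(d_lid_pupil = 0.5))$grade, 2L)
  expect_equal(grade_item("ptosis", list(d_lid_pupil = -3))$grade, 3L)
  expect_equal(grade_item("ptosis", list(d_lid_pupil = 4))$grade, 1L)

  expect_equal(grade_item("cheek_puff", list(annotation = "normal_seal"))$grade, 0L)
  expect_equal(grade_item("cheek_puff", list(annotation = "cannot_perform"))$grade, 3L)
  expect_equal(grade_item("tongue_to_cheek",
                          list(annotation = "partial_deformity"))$grade, 1L)
  expect_equal(grade_item("sit_to_stand", list(annotation = "need_hands"))$grade, 2L)
})

test_that("numeric rules are monotone and exhaustive over their domains", {
  for (spec in list(
    list(item = "diplopia", field = "onset_s", domain = 0:180, worse_low = TRUE),
    list(item = "arm_strength", field = "drift_onset_s", domain = 0:180,
         worse_low = TRUE),
    list(item = "count50", field = "dysarthria_onset_count", domain = 0:60,
         worse_low = TRUE),
    list(item = "single_breath", field = "count", domain = 0:60,
         worse_low = TRUE)
  )) {
    grades <- vapply(spec$domain, function(v) {
      inp <- list(); inp[[spec$field]] <- v
      grade_item(spec$item, inp)$grade
    }, integer(1))
    expect_true(all(grades %in% 0:3))          # total over the domain
    expect_true(all(diff(grades) <= 0))        # worsening input never lowers grade
  }
})

test_that("grade boundaries match the printed minima (enumeration audit)", {
  arm <- vapply(0:180, function(v) {
    grade_item("arm_strength", list(drift_onset_s = v))$grade
  }, integer(1))
  expect_equal(min((0:180)[arm == 1L]), 90)

  sb <- vapply(0:60, function(v) {
    grade_item("single_breath", list(count = v))$grade
  }, integer(1))
  expect_equal(min((0:60)[sb == 0L]), 30)

  dip <- vapply(0:180, function(v) {
    grade_item("diplopia", list(onset_s = v))$grade
  }, integer(1))
  expect_equal(min((0:180)[dip == 1L]), 11)

  c50 <- vapply(0:60, function(v) {
    grade_item("count50", list(dysarthria_onset_count = v))$grade
  }, integer(1))
  expect_equal(min((0:60)[c50 == 1L]), 30)
})

test_that("session grading reports every item and isolates missing inputs", {
  full <- list(
    ptosis = list(ptosis_category = "above_pupil"),
    diplopia = list(onset_s = NA),
    cheek_puff = list(annotation = "normal_seal"),
    tongue_to_cheek = list(annotation = "full_deformity"),
    count50 = list(dysarthria_onset_count = NA),
    arm_strength = list(drift_onset_s = 95),
    single_breath = list(count = 32),
    sit_to_stand = list(annotation = "no_difficulty")
  )
  res <- grade_session(full)
  expect_length(res, 8)
  expect_true(all(vapply(res, function(g) g$gradable, logical(1))))

  partial <- full[c("ptosis", "arm_strength")]
  res2 <- grade_session(partial)
  expect_false(res2$count50$gradable)
  expect_match(res2$count50$note, "missing")
  expect_true(res2$ptosis$gradable)

  expect_error(grade_session(list()), class = "mgce_input_error")
  expect_error(grade_item("diplopia", list(onset_s = 70,
                                           exercise_duration_s = 60)),
               class = "mgce_input_error")
  expect_error(grade_item("cheek_puff", list(annotation = "sideways")),
               class = "mgce_input_error")
})
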