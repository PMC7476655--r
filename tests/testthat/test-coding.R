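# Scene-coding schema, task mapping and inter-rater agreement.

valid_code_row <- function(snapshot_id = "s1") {
  data.frame(snapshot_id = snapshot_id, duration = "ad hoc",
             location = "indoors", familiarity = "home",
             light_type = "natural", brightness = "medium",
             object_distance = "within reach", focus_plane = "single",
             periphery = "none", scanning = "no", hands = "1 hand",
             walking = "no", coping_used = "yes", able_alone = "yes",
             time_of_day = "12-18", stringsAsFactors = FALSE)
}

test_that("the shipped schema has the 14 classifiers and validates codes", {
  schema <- default_scene_schema()
  expect_length(schema, 14)
  expect_setequal(
    names(schema),
    c("duration", "location", "familiarity", "light_type", "brightness",
      "object_distance", "focus_plane", "periphery", "scanning", "hands",
      "walking", "coping_used", "able_alone", "time_of_day"))
  expect_true(all(vapply(schema, function(s) length(s$categories) >= 2,
                         logical(1))))

  code <- valid_code_row()
  expect_identical(validate_scene_code(code, schema), code)

  bad <- code; bad$brightness <- "dazzling"
  expect_error(validate_scene_code(bad, schema), regexp = "brightness",
               class = "visdemand_validation_error")

  incomplete <- code[setdiff(names(code), "time_of_day")]
  expect_error(validate_scene_code(incomplete, schema),
               regexp = "time_of_day",
               class = "visdemand_completeness_error")
})

test_that("the shipped schema round-trips through serialization unchanged", {
  schema <- default_scene_schema()
  path <- withr::local_tempfile(fileext = ".json")
  write_scene_schema(schema, path)
  expect_identical(read_scene_schema(path), schema)
})

test_that("time of day bins are lower-inclusive", {
  expect_equal(bin_time_of_day("13:30"), "12-18")
  expect_equal(bin_time_of_day("06:00"), "6-12")
  expect_equal(bin_time_of_day("05:59"), "0-6")
  expect_equal(bin_time_of_day("00:00"), "0-6")
  expect_equal(bin_time_of_day(c(18, 23.99, 11.999)),
               c("18-24", "18-24", "6-12"))
  expect_error(bin_time_of_day("24:00"), class = "visdemand_validation_error")
  expect_error(bin_time_of_day("nope"), class = "visdemand_validation_error")
})

test_that("only 'unable' collapses to unable_alone", {
  expect_equal(simplify_difficulty("unable"), "unable_alone")
  expect_equal(
    simplify_difficulty(c("very easy", "easy", "average", "difficult",
                          "very difficult")),
    rep("able_alone", 5))
  expect_error(simplify_difficulty("impossible"),
               class = "visdemand_validation_error")
})

test_that("task mapping matches the questionnaire vocabulary and flags bespoke labels", {
  voc <- default_task_vocabulary()
  expect_equal(sum(!voc$is_bespoke), 48L)
  expect_equal(sum(voc$adapted), 12L)

  m <- map_task("Read package labels", voc)
  expect_false(m$is_bespoke)
  # case and whitespace folding reach the canonical wording
  m2 <- map_task("  read   PACKAGE labels ", voc)
  expect_false(m2$is_bespoke)
  expect_equal(m2$task_label, "Read package labels")

  expect_true(map_task("Appreciate environment", voc)$is_bespoke)
  expect_true(map_task("Knit a sweater", voc)$is_bespoke)
  expect_error(map_task("", voc), class = "visdemand_validation_error")
  expect_error(map_task("   ", voc), class = "visdemand_validation_error")

  rec <- task_record("P01", "S001", "Watch TV", narrative = "watching tv")
  expect_false(rec$is_bespoke)
  expect_equal(rec$task_label, "Watch TV")
})

test_that("percent agreement is exact, symmetric and fails on unmatched ids", {
  codes_a <- do.call(rbind, lapply(sprintf("s%02d", 1:27), valid_code_row))
  expect_true(all(percent_agreement(codes_a, codes_a)$agreement_pct == 100))

  codes_b <- codes_a
  codes_b$duration[1:7] <- "long"  # 20 of 27 matching
  rep_ab <- percent_agreement(codes_a, codes_b)
  expect_equal(rep_ab$agreement_pct[rep_ab$classifier == "duration"],
               100 * 20 / 27)
  expect_equal(round(rep_ab$agreement_pct[rep_ab$classifier == "duration"], 1),
               74.1)
  expect_equal(attr(rep_ab, "n_items"), 27L)
  rep_ba <- percent_agreement(codes_b, codes_a)
  expect_equal(rep_ab$agreement_pct, rep_ba$agreement_pct)

  # row order must not matter: pairing is by snapshot_id
  shuffled <- codes_b[sample(nrow(codes_b)), ]
  expect_equal(percent_agreement(codes_a, shuffled)$agreement_pct,
               rep_ab$agreement_pct)

  codes_c <- codes_a
  codes_c$snapshot_id[1] <- "other"
  expect_error(percent_agreement(codes_a, codes_c),
               class = "visdemand_pairing_error")
  expect_error(percent_agreement(codes_a, codes_a[1:5, ]),
               class = "visdemand_pairing_error")
})

test_that("independent uniform coders agree at the chance rate 100/k", {
  for (k in c(2L, 4L, 5L)) {
    fx <- gen_dual_coder(10000, 0, k, seed = 100 + k)
    rate <- percent_agreement(fx$coder_a, fx$coder_b)$agreement_pct
    # a fully independent coder B: agreement_rate 0 means B always moves
    # off A's category, so chance agreement is 0 by construction; instead
    # simulate true independence directly
    set.seed(200 + k)
    a <- sample(sprintf("C%d", 1:k), 10000, replace = TRUE)
    b <- sample(sprintf("C%d", 1:k), 10000, replace = TRUE)
    df_a <- data.frame(snapshot_id = seq_along(a), code = a)
    df_b <- data.frame(snapshot_id = seq_along(b), code = b)
    est <- percent_agreement(df_a, df_b)$agreement_pct
    expect_equal(est, 100 / k, tolerance = 2 / (100 / k))
    expect_equal(rate, 0)
  }
})

test_that("kappa is 1 for identity, near 0 for independence", {
  codes <- do.call(rbind, lapply(sprintf("s%02d", 1:20), valid_code_row))
  codes$duration <- rep(c("ad hoc", "short"), 10)
  expect_equal(cohen_kappa(codes, codes)$kappa[1], 1)
  set.seed(9)
  a <- data.frame(snapshot_id = 1:5000,
                  code = sample(c("x", "y"), 5000, TRUE))
  b <- data.frame(snapshot_id = 1:5000,
                  code = sample(c("x", "y"), 5000, TRUE))
  expect_lt(abs(cohen_kappa(a, b)$kappa), 0.05)
  # degenerate: both coders constant -> expected agreement 1, kappa NA
  const <- data.frame(snapshot_id = 1:4, code = "x")
  expect_true(is.na(cohen_kappa(const, const)$kappa))
})
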