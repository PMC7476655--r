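# Task rankings, classifier distributions, metric summaries and word
# frequencies.

test_that("dual ranking counts snapshots and participants by their own rules", {
  # the worked example: one participant reporting the same task three times
  records <- data.frame(
    participant_id = c("P1", "P1", "P1"),
    task_label = rep("Find something on a crowded shelf", 3))
  rt <- rank_tasks(records)
  expect_equal(rt$snapshot_count, 3L)
  expect_equal(rt$participant_count, 1L)
  expect_equal(rt$snapshot_pct, 100)
  expect_equal(rt$participant_pct, 100)

  set.seed(61)
  labels <- c(rep("shared task", 8), sample(letters[1:10], 92, TRUE))
  records2 <- data.frame(
    participant_id = sample(sprintf("P%d", 1:5), 100, TRUE),
    task_label = labels)
  rt2 <- rank_tasks(records2)
  expect_equal(rt2$snapshot_pct[rt2$task_label == "shared task"], 8)
  expect_equal(sum(rt2$snapshot_count), 100L)
  expect_equal(sum(rt2$snapshot_pct), 100)
  expect_true(all(rt2$participant_count <= 5L))
  # permutation invariance
  perm <- records2[sample(nrow(records2)), ]
  expect_identical(as.data.frame(rank_tasks(perm)), as.data.frame(rt2))
  # empty input: empty table, not an error
  empty <- rank_tasks(data.frame(participant_id = character(0),
                                 task_label = character(0)))
  expect_equal(nrow(empty), 0L)
})

test_that("planted task probabilities are recovered in rank order", {
  fx <- gen_coding_dataset(10, 5000,
                           task_probs = c(A = 0.5, B = 0.3, C = 0.2),
                           seed = 71)
  rt <- rank_tasks(fx$records)
  expect_equal(rt$task_label, c("A", "B", "C"))
  expect_equal(rt$rank_snapshot, 1:3)
})

test_that("classifier distributions sum to 100 and recover planted shares", {
  codes <- do.call(rbind, lapply(1:4, function(i) {
    row <- data.frame(snapshot_id = sprintf("s%d", i), duration = "ad hoc",
                      location = if (i <= 3) "indoors" else "outdoors",
                      familiarity = "home", light_type = "natural",
                      brightness = "medium", object_distance = "within reach",
                      focus_plane = "single", periphery = "none",
                      scanning = "no", hands = "none", walking = "no",
                      coping_used = "no", able_alone = "yes",
                      time_of_day = "6-12")
    row
  }))
  dist <- distribution_by_classifier(codes)
  loc <- dist[dist$classifier == "location", ]
  expect_equal(loc$pct[loc$category == "indoors"], 75)
  expect_equal(loc$pct[loc$category == "outdoors"], 25)
  sums <- tapply(dist$pct, dist$classifier, sum)
  expect_true(all(abs(sums - 100) < 0.01))

  fx <- gen_coding_dataset(20, 10000, seed = 81)
  dist2 <- distribution_by_classifier(fx$codes)
  for (cl in names(fx$planted$classifier_probs)) {
    p <- fx$planted$classifier_probs[[cl]]
    sub <- dist2[dist2$classifier == cl, ]
    got <- setNames(sub$pct, sub$category)[names(p)]
    expect_true(all(abs(got - 100 * p) <= 1.5),
                label = sprintf("classifier %s within 1.5 points", cl))
  }
})

test_that("metric summaries use sample SD and proportion histograms", {
  two <- data.frame(contrast_pct = c(40, 60))
  s <- summarize_metric_distributions(two)
  expect_equal(s$contrast_pct$mean, 50)
  expect_equal(s$contrast_pct$sd, sd(c(40, 60)))
  expect_equal(round(s$contrast_pct$sd, 2), 14.14)
  expect_equal(sum(s$contrast_pct$histogram$proportion), 1)

  expect_warning(s1 <- summarize_metric_distributions(
    data.frame(contrast_pct = 40)), regexp = "degenerate")
  expect_equal(s1$contrast_pct$sd, 0)
  expect_error(summarize_metric_distributions(data.frame()),
               class = "visdemand_empty_input_error")
})

test_that("word frequencies tokenize, stem and respect stop words", {
  wf <- word_frequency(c("read mail", "read signs"), stem_map = NULL,
                       stopwords = character(0))
  expect_equal(wf$count[wf$word == "read"], 2L)
  expect_equal(wf$pct[wf$word == "read"], 50)
  expect_equal(attr(wf, "n_tokens"), 4L)

  empty <- word_frequency(character(0))
  expect_equal(nrow(empty), 0L)

  wf2 <- word_frequency(c("Reading the mail", "I read signs"),
                        stem_map = c(reading = "read"),
                        stopwords = c("the", "i"))
  expect_equal(wf2$count[wf2$word == "read"], 2L)
  expect_equal(attr(wf2, "n_tokens"), 4L)

  # planted token mix recovered exactly
  set.seed(91)
  planted <- c(read = 30L, find = 12L, bus = 7L)
  toks <- sample(rep(names(planted), times = planted))
  wf3 <- word_frequency(paste(toks, collapse = " "), stem_map = NULL,
                        stopwords = character(0))
  expect_equal(setNames(wf3$count, wf3$word)[names(planted)], planted)
})

test_that("rendered percentages keep one decimal below 1%", {
  expect_equal(format_table_pct(c(8, 0.5, 0.28, 1.4, 0)),
               c("8%", "0.5%", "0.3%", "1%", "0%"))
})

test_that("the file-level aggregate driver ties the tables together", {
  dir <- withr::local_tempdir()
  fx <- gen_coding_dataset(5, 200, seed = 101)
  fx$records$narrative <- "read the label"
  task_csv <- file.path(dir, "tasks.csv")
  scene_csv <- file.path(dir, "scenes.csv")
  write.csv(fx$records, task_csv, row.names = FALSE)
  write.csv(fx$codes, scene_csv, row.names = FALSE)
  out <- aggregate_report_files(task_csv, scene_csv, out_dir = dir)
  expect_s3_class(out$ranking, "ranking_table")
  expect_equal(attr(out$ranking, "n_records"), 200L)
  expect_true(file.exists(file.path(dir, "report.json")))
  expect_true(file.exists(file.path(dir, "ranking.csv")))
  rep_json <- jsonlite::read_json(file.path(dir, "report.json"))
  expect_equal(rep_json$n_participants, 5L)
})
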