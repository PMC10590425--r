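test_that("transition counts and matrix follow the label sequence", {
  const <- count_transitions(rep("Dissection", 10))
  expect_identical(const$total, 0L)
  expect_true(all(const$matrix == 0L))

  seq4 <- c("Marking", "Idle", "Marking", "Idle")
  ct <- count_transitions(seq4)
  expect_identical(ct$total, 3L)
  expect_identical(ct$matrix["Marking", "Idle"], 2L)
  expect_identical(ct$matrix["Idle", "Marking"], 1L)
  expect_true(all(diag(ct$matrix) == 0L))

  for (seed in 1:50) {
    tr <- random_track(sample(2:200, 1), seed = seed)
    expect_identical(count_transitions(tr$labels)$total,
                     nrow(segments_from_labels(tr)) - 1L)
  }
})

test_that("the NT-index curve is a nondecreasing step curve with exact final value", {
  none <- nt_index_curve(rep("Idle", 20), fps = 1, lesion_size_cm = 3)
  expect_true(all(none$value == 0))

  tr <- random_track(300, seed = 8)
  nt <- nt_index_curve(tr$labels, fps = 1, lesion_size_cm = 2)
  expect_true(all(diff(nt$value) >= 0))
  expect_identical(nt$value[1], 0)
  expect_identical(nt$final * 2, as.numeric(count_transitions(tr$labels)$total))

  five <- c("Marking", "Idle", "Marking", "Idle", "Marking", "Idle")
  expect_equal(nt_index_curve(five, 1, 2)$final, 2.5)
  expect_error(nt_index_curve(five, 1, 0), "lesion_size_cm")

  # per-minute variant normalises by elapsed time as well
  ntm <- nt_index_curve(tr$labels, fps = 1, lesion_size_cm = 2,
                        per_minute = TRUE)
  t_end <- (length(tr$labels) - 1) / 60
  expect_equal(ntm$final, nt$final / t_end)
})

test_that("phase periods and ratios are exact arithmetic", {
  labels <- c(rep("Dissection", 30), rep("Idle", 20), rep("Injection", 10))
  pp <- phase_periods(labels, fps = 1)
  expect_equal(pp$duration_s[pp$phase == "Dissection"], 30)
  expect_equal(pp$ratio[pp$phase == "Idle"], 20 / 60)
  expect_equal(sum(pp$ratio), 1, tolerance = 1e-9)

  all_d <- phase_periods(rep("Dissection", 8), 1)
  expect_equal(all_d$ratio[all_d$phase == "Dissection"], 1)
  expect_error(phase_periods(character(0), 1), "empty")

  # fps scales durations, not ratios
  pp25 <- phase_periods(labels, fps = 25)
  expect_equal(pp25$duration_s[pp25$phase == "Dissection"], 30 / 25)
  expect_equal(pp25$ratio, pp$ratio)
})

test_that("derived scores implement the three printed ratios", {
  labels <- c(rep("Idle", 20), rep("Dissection", 30), rep("Marking", 10))
  pp <- phase_periods(labels, 1)
  ds <- derived_scores(pp, lesion_size_cm = 2)
  expect_equal(ds$idle_per_tumor, 10)
  expect_equal(ds$idle_per_dissection, 2 / 3)
  expect_equal(ds$procedure_per_tumor, 30)

  no_idle <- derived_scores(phase_periods(rep("Dissection", 30), 1), 2)
  expect_equal(no_idle$idle_per_tumor, 0)
  expect_equal(no_idle$idle_per_dissection, 0)
  expect_equal(no_idle$procedure_per_tumor, 15)

  no_diss <- derived_scores(phase_periods(rep("Idle", 30), 1), 2)
  expect_true(is.na(no_diss$idle_per_dissection))
})

test_that("reports assemble every section and round-trip through JSON", {
  cs <- simulate_case("rep-1", seed = 5, duration_s = 200, render = FALSE,
                      training_status = "with help")
  rep1 <- generate_report(cs$metadata, cs$track)
  expect_identical(rep1$color_bar, segments_from_labels(cs$track$labels))
  expect_equal(sum(rep1$pie$ratio), 1, tolerance = 1e-9)
  expect_identical(rep1$basic_info$label_source, "annotation")
  expect_equal(rep1$skill$nt_final * rep1$basic_info$lesion_size_cm,
               as.numeric(rep1$transitions$total))

  back <- report_from_json(report_to_json(rep1))
  expect_equal(back, rep1, tolerance = 0)

  f <- withr::local_tempfile(fileext = ".json")
  report_to_json(rep1, f)
  expect_equal(report_from_json(paste(readLines(f), collapse = "\n")), rep1,
               tolerance = 0)
})

test_that("a report without lesion size still renders, with NT marked unavailable", {
  cs <- simulate_case("rep-2", seed = 6, duration_s = 100, render = FALSE)
  meta <- cs$metadata
  meta$lesion_size_cm <- NULL
  rep2 <- generate_report(meta, cs$track)
  expect_null(rep2$nt_curve)
  expect_true(is.na(rep2$skill$nt_final))
  expect_true(is.na(rep2$skill$idle_per_tumor))
  f <- withr::local_tempfile(fileext = ".html")
  render_report_html(rep2, f)
  html <- paste(readLines(f), collapse = "\n")
  expect_match(html, "NT-index unavailable")
})

test_that("rendered HTML contains all six report sections", {
  cs <- simulate_case("rep-3", seed = 7, duration_s = 150, render = FALSE)
  rep3 <- generate_report(cs$metadata, cs$track)
  f <- withr::local_tempfile(fileext = ".html")
  render_report_html(rep3, f)
  html <- paste(readLines(f), collapse = "\n")
  for (sec in c("basic-info", "color-bar", "duration-pie", "transition-matrix",
                "nt-index", "skill-scores")) {
    expect_match(html, paste0('id="', sec, '"'))
  }
})

test_that("operators rank by ascending final NT-index", {
  mk <- function(id, skill, seed) {
    cs <- simulate_case(id, seed = seed, duration_s = 400, skill = skill,
                        render = FALSE)
    generate_report(cs$metadata, cs$track)
  }
  reps <- list(novice = mk("n", skill_profile("novice"), 3),
               expert = mk("e", skill_profile("expert"), 3))
  rk <- rank_by_nt_index(reps)
  expect_identical(rk$id[order(rk$rank)],
                   rk$id[order(rk$nt_final)])
  expect_identical(rk$rank, 1:2)
})
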