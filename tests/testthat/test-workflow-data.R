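test_that("phase vocabulary and coding form a fixed bijection", {
  expect_identical(esd_phases(),
                   c("Marking", "Injection", "Dissection", "Idle"))
  expect_identical(phase_code(esd_phases()), 0:3)
  expect_identical(phase_from_code(0:3), esd_phases())
  expect_error(phase_code("Cutting"), "unknown phase")
})

test_that("frame and segment annotation files parse, expand and round-trip", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("frame,phase", "0,Marking", "1,Marking", "2,Idle"), f)
  tr <- read_annotation(f, fps = 1)
  expect_identical(tr$labels, c("Marking", "Marking", "Idle"))
  expect_equal(length(tr), 3L)

  s <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("start,end,phase", "0,10,Marking", "10,20,Idle"), s)
  ts <- read_annotation(s, fps = 1)
  expect_length(ts$labels, 20L)
  expect_identical(table(ts$labels)[["Marking"]], 10L)

  # round trip in both dialects
  tr0 <- random_track(80, seed = 5)
  for (fmt in c("frame", "segment")) {
    out <- withr::local_tempfile(fileext = ".csv")
    write_annotation(tr0, out, format = fmt)
    expect_identical(read_annotation(out, fps = 1)$labels, tr0$labels)
  }
})

test_that("malformed annotation files raise informative errors", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("frame,phase", "0,Marking", "1,Cutting"), f)
  expect_error(read_annotation(f, fps = 1), "Cutting")

  g <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("frame,phase", "0,Marking", "2,Idle"), g)
  expect_error(read_annotation(g, fps = 1), "contiguous")

  h <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("start,end,phase", "0,10,Marking", "12,20,Idle"), h)
  expect_error(read_annotation(h, fps = 1), "gap or overlap")
  expect_error(read_annotation("no/such/file.csv", fps = 1), "not found")
})

test_that("run-length segments and label expansion are mutually inverse", {
  expect_identical(
    segments_from_labels(c("Marking", "Marking", "Injection", "Injection",
                           "Dissection")),
    data.frame(start = c(0L, 2L, 4L), end = c(2L, 4L, 5L),
               phase = c("Marking", "Injection", "Dissection")))
  expect_identical(segments_from_labels(rep("Idle", 7)),
                   data.frame(start = 0L, end = 7L, phase = "Idle"))
  expect_identical(nrow(segments_from_labels(character(0))), 0L)

  for (seed in 1:200) {
    tr <- random_track(sample(1:120, 1), seed = seed)
    seg <- segments_from_labels(tr)
    expect_identical(labels_from_segments(seg), tr$labels)
    # adjacent segments differ in phase
    if (nrow(seg) > 1) {
      expect_true(all(seg$phase[-1] != seg$phase[-nrow(seg)]))
    }
  }
})

test_that("downsampling keeps the first frame of each window", {
  tr <- random_track(50, fps = 25, seed = 2)
  dn <- downsample_track(tr, 1)
  expect_equal(length(dn), 2L)
  expect_identical(dn$labels, tr$labels[c(1, 26)])
  expect_equal(dn$fps, 1)

  expect_identical(downsample_track(tr, 25)$labels, tr$labels)
  expect_error(downsample_track(tr, 2), "integer multiple")

  # length is ceil(T * f / fps), kept labels are window-first
  tr2 <- random_track(17, fps = 4, seed = 3)
  dn2 <- downsample_track(tr2, 2)
  expect_equal(length(dn2), ceiling(17 * 2 / 4))
  expect_identical(dn2$labels, tr2$labels[seq(1, 17, by = 2)])
})

test_that("Pearson agreement matches the covariance formula and its invariances", {
  tr <- random_track(60, seed = 9)
  expect_equal(pearson_agreement(tr, tr), 1.0)

  a <- phase_from_code(c(0, 0, 1, 2))
  b <- phase_from_code(c(0, 1, 1, 2))
  expect_equal(pearson_agreement(a, b), 0.8528028654, tolerance = 1e-9)
  expect_equal(pearson_agreement(b, a), pearson_agreement(a, b))

  expect_error(pearson_agreement(a, rep("Idle", 4)), "constant")
  expect_error(pearson_agreement(a, b[1:3]), "length")
})

test_that("case metadata JSON round-trips", {
  meta <- list(case_id = "c1", date = "2026-02-01", surgeon_id = "S2",
               organ = "rectum", lesion_size_cm = 3.2,
               training_status = "with help", fps = 1)
  f <- withr::local_tempfile(fileext = ".json")
  write_case_metadata(meta, f)
  expect_equal(read_case_metadata(f), meta)
})

test_that("annotation_track validates its invariants", {
  expect_error(annotation_track("c", fps = 0, labels = "Idle"), "fps")
  expect_error(annotation_track("c", 1, "Idle",
                                metadata = list(lesion_size_cm = -1)),
               "lesion_size_cm")
  expect_error(annotation_track("c", 1, "Idle",
                                metadata = list(training_status = "solo")),
               "training_status")
  expect_silent(annotation_track("c", 1, character(0)))
})
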