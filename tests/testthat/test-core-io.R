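test_that("builtin montages carry the expected channels and homologous pairs", {
  m14 <- builtin_montage("emotiv14")
  expect_length(m14$channels, 14)
  expect_equal(nrow(m14$pairs), 7)
  expect_setequal(m14$channels,
                  c("AF3", "F7", "F3", "FC5", "T7", "P7", "O1",
                    "O2", "P8", "T8", "FC6", "F4", "F8", "AF4"))

  m32 <- builtin_montage("deap32")
  expect_length(m32$channels, 32)
  expect_equal(nrow(m32$pairs), 14)
  key <- paste(m32$pairs$left, m32$pairs$right)
  expect_true(all(c("F3 F4", "F7 F8") %in% key))

  expect_error(builtin_montage("unknown"), "available montages")
})

test_that("montage pair tables reject self-pairs, unknown and reversed duplicates", {
  expect_error(montage("m", c("F3", "F4"),
                       data.frame(left = "F3", right = "F3")),
               "itself")
  expect_error(montage("m", c("F3", "F4"),
                       data.frame(left = "F3", right = "Cz")),
               "not in montage")
  expect_error(montage("m", c("F3", "F4"),
                       data.frame(left = c("F3", "F4"),
                                  right = c("F4", "F3"))),
               "reversed")
  # no builtin pair appears reversed
  for (name in c("deap32", "emotiv14")) {
    p <- builtin_montage(name)$pairs
    expect_equal(anyDuplicated(
      vapply(seq_len(nrow(p)),
             function(i) paste(sort(c(p$left[i], p$right[i])), collapse = "|"),
             character(1))), 0L)
  }
})

test_that("label normalization is affine, bounded and invertible", {
  expect_equal(affect_label(9, 1, 1, 9)$valence, 1)
  expect_equal(affect_label(5, 5, 1, 9)$valence, 0.5)
  expect_equal(affect_label(1, 9, 1, 9)$valence, 0)
  expect_equal(affect_label(3, 3, 1, 5)$arousal, 0.5)
  expect_error(affect_label(10, 5, 1, 9), "outside")
  # round trip raw -> normalized -> raw
  for (raw in seq(1, 9, by = 0.5)) {
    lab <- affect_label(raw, raw)
    expect_equal(denormalize_label(lab$valence, 1, 9), raw,
                 tolerance = 1e-12)
  }
})

test_that("epoch segmentation matches brute-force window enumeration", {
  m <- builtin_montage("emotiv14")
  rec60 <- random_recording(m, fs = 128, seconds = 60)
  expect_length(segment_epochs(rec60, 4, 0.5), 29)  # floor((60-4)/2)+1
  expect_length(segment_epochs(random_recording(m, seconds = 4), 4, 0.5), 1)
  expect_warning(
    out <- segment_epochs(random_recording(m, seconds = 3), 4, 0.5),
    "shorter")
  expect_length(out, 0)

  # property: count equals brute-force enumeration for random settings
  set.seed(7)
  for (i in 1:12) {
    secs <- sample(3:30, 1)
    ep_s <- sample(2:6, 1)
    ov <- sample(c(0, 0.25, 0.5, 0.75), 1)
    rec <- random_recording(m, fs = 32, seconds = secs, seed = i)
    got <- suppressWarnings(length(segment_epochs(rec, ep_s, ov)))
    win <- round(ep_s * 32)
    hop <- max(1, round(win * (1 - ov)))
    expected <- 0
    s0 <- 0
    while (s0 + win <= secs * 32) {
      expected <- expected + 1
      s0 <- s0 + hop
    }
    expect_equal(got, expected, info = sprintf("secs=%d ep=%d ov=%g",
                                               secs, ep_s, ov))
  }
})

test_that("epochs inherit the trial label and carry window-sized data", {
  rec <- random_recording(seconds = 10, label = affect_label(7, 3))
  eps <- segment_epochs(rec, 4, 0.5)
  expect_length(eps, 4)
  for (ep in eps) {
    expect_equal(ncol(ep$data), 4 * 128)
    expect_equal(ep$label$valence, 0.75)
    expect_equal(ep$label$arousal, 0.25)
  }
  expect_equal(purrr::map_int(eps, "epoch_index"), 0:3)
})

test_that("CSV recordings round-trip with side-car metadata and montage reorder", {
  m <- builtin_montage("emotiv14")
  rec <- random_recording(m, seconds = 5, label = affect_label(9, 1))
  path <- withr::local_tempfile(fileext = ".csv")
  write_recording_csv(rec, path)
  back <- read_recording(path, "csv", m)
  expect_equal(back$data, rec$data, tolerance = 1e-9)
  expect_equal(back$fs, 128)
  expect_equal(back$label$valence, 1)
  expect_equal(back$label$arousal, 0)

  # shuffled channel order in the file is restored to montage order
  tab <- utils::read.csv(path, check.names = FALSE)
  set.seed(1)
  tab <- tab[sample(nrow(tab)), ]
  utils::write.csv(tab, path, row.names = FALSE)
  back2 <- read_recording(path, "csv", m)
  expect_equal(back2$data, rec$data, tolerance = 1e-9)

  # a montage channel missing from the file is an explicit failure
  tab <- tab[tab$channel != "F3", ]
  utils::write.csv(tab, path, row.names = FALSE)
  expect_error(read_recording(path, "csv", m), "channel mismatch.*F3")
})

test_that("labels can come from a label table keyed by subject and trial", {
  m <- builtin_montage("emotiv14")
  rec <- random_recording(m, seconds = 4, label = NULL)
  rec$subject_id <- "s7"; rec$trial_id <- "t2"
  path <- withr::local_tempfile(fileext = ".csv")
  write_recording_csv(rec, path)
  lab_path <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(data.frame(subject_id = c("s7", "s7"),
                              trial_id = c("t1", "t2"),
                              valence_raw = c(2, 8), arousal_raw = c(3, 6)),
                   lab_path, row.names = FALSE)
  labs <- read_label_table(lab_path)
  back <- read_recording(path, "csv", m, labels = labs)
  expect_equal(back$label$valence, 7 / 8)
  expect_equal(back$label$arousal, 5 / 8)
  # missing label row is a labeling failure
  rec$trial_id <- "t9"
  write_recording_csv(rec, path)
  expect_error(read_recording(path, "csv", m, labels = labs),
               "labeling failure")
})

test_that("EDF files round-trip within quantization accuracy", {
  m <- builtin_montage("emotiv14")
  rec <- random_recording(m, seconds = 4, label = affect_label(6, 4))
  path <- withr::local_tempfile(fileext = ".edf")
  write_edf(rec, path)
  back <- read_recording(path, "edf", m, labels = rec$label)
  expect_equal(back$fs, 128)
  expect_equal(dim(back$data), dim(rec$data))
  # 16-bit quantization over the channel range
  span <- max(rec$data) - min(rec$data)
  expect_lt(max(abs(back$data - rec$data)), span / 65536 * 2)
})

test_that("epoch directories persist with a manifest", {
  rec <- random_recording(seconds = 8)
  eps <- segment_epochs(rec, 4, 0.5)
  dir <- withr::local_tempdir()
  write_epochs(eps, dir)
  man <- jsonlite::read_json(file.path(dir, "manifest.json"))
  expect_length(man, length(eps))
  expect_true(all(vapply(man, function(e) file.exists(file.path(dir, e$file)),
                         logical(1))))
})
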