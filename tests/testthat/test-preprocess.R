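test_that("trimming removes exactly the requested stretch", {
  rec <- eeg_recording(matrix(seq_len(200), 2, 100, byrow = TRUE), 10,
                       c("A", "B"))
  tr <- trim_recording(rec, 2, 3)
  expect_equal(ncol(tr$data), 50)                 # (10 - 5) s * 10 Hz
  expect_equal(tr$data[, 1], rec$data[, 21])      # head removed, order kept
  expect_equal(tr$channel_names, rec$channel_names)

  expect_identical(trim_recording(rec, 0, 0)$data, rec$data)
  expect_error(trim_recording(rec, 6, 5), "shorter")
})

test_that("downsampling preserves duration, rate and tone amplitude", {
  n <- 8000
  t <- (seq_len(n) - 1) / 1000
  sine <- sin(2 * pi * 5 * t)
  rec <- eeg_recording(rbind(sine, sine), 1000, c("A", "B"))
  ds <- downsample_recording(rec, 200)
  expect_equal(ds$rate, 200)
  expect_equal(ncol(ds$data), 1600)               # factor-5 decimation

  # interior of the decimated tone matches the analytic sinusoid to < 1%
  ref <- sin(2 * pi * 5 * (seq_len(1600) - 1) / 200)
  mid <- 100:1500
  expect_lt(max(abs(ds$data[1, mid] - ref[mid])), 0.01)

  expect_identical(downsample_recording(rec, 1000), rec)
  expect_error(downsample_recording(rec, 2000), "exceeds")
})

test_that("segmentation is non-overlapping, chronological, remainder-dropping", {
  rec <- eeg_recording(matrix(seq_len(70800), 1), 10, "A")  # 7080 s
  segs <- segment_recording(rec)
  expect_length(segs, 885)                        # floor(7080 / 8)
  expect_equal(attr(segs[[2]], "start_s"), 8)
  expect_equal(segs[[2]][1, 1], segs[[1]][1, 80] + 1)

  rec8 <- eeg_recording(matrix(rnorm(80), 1), 10, "A")
  expect_length(segment_recording(rec8), 1)
  rec79 <- eeg_recording(matrix(rnorm(79), 1), 10, "A")
  expect_length(segment_recording(rec79), 0)

  # sample-count arithmetic on random durations
  for (n in c(83, 160, 555, 1601)) {
    k <- length(segment_recording(eeg_recording(matrix(rnorm(n), 1), 10,
                                                "A")))
    expect_true(k * 80 <= n && n < (k + 1) * 80)
  }
})

test_that("framing yields 2T frames and concatenation is the identity", {
  seg <- matrix(rnorm(2 * 1600), 2)               # 8 s at 200 Hz
  fr <- frame_segment(seg, 200, 0.5)
  expect_equal(dim(fr), c(2, 16, 100))
  rebuilt <- do.call(cbind, lapply(1:16, function(f) fr[, f, ]))
  expect_identical(rebuilt, seg)

  one <- frame_segment(seg, 200, 8)
  expect_equal(dim(one), c(2, 1, 1600))
  expect_identical(one[, 1, ], seg)
  expect_equal(dim(frame_segment(seg, 200, 1)), c(2, 8, 200))
  expect_error(frame_segment(seg, 200, 3), "divide")
})

test_that("perclos is the closure fraction and labels are monotone", {
  expect_equal(perclos(4, 8)$perclos, 0.5)
  expect_equal(perclos(0, 8)$perclos, 0)
  expect_equal(perclos(8, 8)$perclos, 1)
  expect_error(perclos(9, 8), "\\[0, window\\]")
  expect_error(perclos(4, 0), "positive")

  expect_equal(as.character(label_from_perclos(0.34)), "awake")
  expect_equal(as.character(label_from_perclos(0.5, "ternary")), "fatigue")
  expect_equal(as.character(label_from_perclos(0.7, "ternary")), "drowsy")
  # boundary goes to the more fatigued class unless strict
  expect_equal(as.character(label_from_perclos(0.35)), "fatigue")
  expect_equal(as.character(label_from_perclos(0.35, strict = TRUE)),
               "awake")

  p <- sort(runif(50))
  lab <- as.integer(label_from_perclos(p, "ternary"))
  expect_true(all(diff(lab) >= 0))
})

test_that("recording container and label streams round-trip through disk", {
  dir <- withr::local_tempdir()
  rec <- eeg_recording(matrix(rnorm(3 * 50), 3), 25, c("O1", "OZ", "O2"))
  write_recording(rec, dir)
  back <- read_recording(dir)
  expect_equal(back$rate, 25)
  expect_equal(back$channel_names, rec$channel_names)
  expect_equal(back$data, rec$data, tolerance = 1e-12)

  lab_path <- file.path(dir, "labels.csv")
  utils::write.csv(data.frame(window_start_s = c(0, 8),
                              eye_closure_s = c(2, 6)),
                   lab_path, row.names = FALSE)
  ls <- read_label_stream(lab_path)
  expect_equal(ls$perclos, c(0.25, 0.75))
})
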