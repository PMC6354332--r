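test_that("CSV recordings round-trip at full float precision", {
  set.seed(11)
  rec <- eeg_recording(matrix(rnorm(3 * 100), 3), fs = 100,
                       labels = c("A", "B", "C"))
  path <- withr::local_tempfile(fileext = ".csv")
  write_recording_csv(rec, path)
  back <- read_recording(path, format = "csv", fs = 100)
  expect_identical(back$labels, rec$labels)
  expect_identical(unname(back$data), unname(rec$data))
  expect_equal(ncol(back$data), 100)
})

test_that("recording construction validates labels and stages", {
  m <- matrix(rnorm(300), 3)
  expect_error(eeg_recording(m, 100, labels = c("a", "b")), "labels")
  expect_error(eeg_recording(m, 100, labels = c("a", "b", "b")), "unique")
  expect_error(eeg_recording(m, -1), "fs")
  expect_error(
    eeg_recording(m, 100, stages = data.frame(start_s = 0, end_s = 10,
                                              stage = "IS")),
    "within")
  expect_error(
    eeg_recording(m, 100, stages = data.frame(start_s = 0, end_s = 1,
                                              stage = "XX")),
    "stages")
})

test_that("non-numeric cells in a CSV matrix are rejected", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("1,2,bad", "4,5,6"), path)
  expect_error(read_recording(path, format = "csv", fs = 10), "non-numeric")
})

test_that("EDF files round-trip labels exactly and data to 16-bit accuracy", {
  set.seed(12)
  labs <- c("Fp1", "Fp2", "T3")
  rec <- eeg_recording(matrix(rnorm(3 * 500, sd = 40), 3), fs = 250,
                       labels = labs)
  path <- withr::local_tempfile(fileext = ".edf")
  write_edf(rec, path)
  back <- read_recording(path)
  expect_identical(back$labels, labs)          # header passthrough, in order
  expect_equal(back$fs, 250)
  expect_equal(ncol(back$data), 500)
  span <- diff(range(rec$data))
  expect_lt(max(abs(back$data - rec$data)), span / 65000 * 2)
})

test_that("band-pass keeps in-band sines and removes slow drift", {
  fs <- 500
  t <- seq(0, 60, by = 1 / fs)[-1]
  sine50 <- sin(2 * pi * 50 * t)
  drift <- sin(2 * pi * 0.05 * t)
  rec <- eeg_recording(rbind(sine50, drift), fs, labels = c("s", "d"))
  out <- bandpass_filter(rec, 0.3, 75, order = 4)
  expect_equal(dim(out$data), dim(rec$data))
  expect_lt(abs(sd(out$data["s", ]) / sd(sine50) - 1), 0.05)   # preserved
  expect_lt(sd(out$data["d", ]) / sd(drift), 0.10)             # > 90% gone
})

test_that("band edges beyond Nyquist are rejected", {
  rec <- eeg_recording(matrix(rnorm(1000), 2), fs = 500)
  expect_error(bandpass_filter(rec, 0.3, 300), "Nyquist|fs/2")
  expect_error(bandpass_filter(rec, 80, 75), "fs/2")
})

test_that("windowing produces the expected grid and stage tags", {
  fs <- 100
  stages <- data.frame(start_s = c(0, 6), end_s = c(6, 10),
                       stage = c("AS", "IS"))
  rec <- eeg_recording(matrix(rnorm(2 * 1000), 2), fs, stages = stages)
  ws <- segment_windows(rec, window_s = 2, overlap_frac = 0.5)
  expect_length(ws$windows, 9)                     # floor((10-2)/1) + 1
  expect_true(all(diff(ws$starts_s) > 0))
  expect_true(all(vapply(ws$windows, ncol, 0L) == 200))
  # midpoint rule: window starting at 5 s has midpoint 6 s -> IS
  expect_identical(ws$stage_of_window[ws$starts_s == 5], "IS")
  expect_identical(ws$stage_of_window[ws$starts_s == 0], "AS")

  exact <- segment_windows(rec, window_s = 10, overlap_frac = 0)
  expect_length(exact$windows, 1)
  expect_error(segment_windows(rec, window_s = 12), "longer than")
})

test_that("the pipeline order filter-then-window is not interchangeable", {
  set.seed(13)
  fs <- 250
  rec <- eeg_recording(matrix(rnorm(2 * fs * 10), 2), fs)
  filtered_first <- segment_windows(bandpass_filter(rec, 1, 40), 2, 0)
  per_window <- lapply(segment_windows(rec, 2, 0)$windows, function(w)
    bandpass_filter(eeg_recording(w, fs), 1, 40)$data)
  # same shapes, but edge transients differ, so the pipeline must fix the
  # order (filter first, as run_pipeline does)
  expect_false(isTRUE(all.equal(filtered_first$windows[[2]], per_window[[2]],
                                check.attributes = FALSE)))
})
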