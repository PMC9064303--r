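test_that("event files load into recordings with sorted, windowed trains", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("# comment line",
               "a\t0.5", "b,1.2", "a 0.1", "c\t2.0", "b\t0.4", "a\t1.9"),
             path)
  rec <- read_spike_events(path, t_start = 0, t_end = 3600)
  expect_s3_class(rec, "recording")
  expect_equal(sort(names(rec$trains)), c("a", "b", "c"))
  expect_equal(sum(spike_counts(rec)), 6L)
  expect_equal(rec$trains[["a"]]$times, c(0.1, 0.5, 1.9))
})

test_that("out-of-window events are dropped under the half-open rule", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("a\t0.0", "a\t5.0", "a\t10.0", "a\t12.0"), path)
  expect_message(rec <- read_spike_events(path, 0, 10), "dropped 2 events")
  expect_equal(rec$trains[["a"]]$times, c(0, 5))
})

test_that("malformed and empty files raise informative errors", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("a\t1.0", "oops"), path)
  expect_error(read_spike_events(path, 0, 10), "line 2")
  writeLines(c("a\tnot_a_number"), path)
  expect_error(read_spike_events(path, 0, 10), "line 1")
  writeLines("# only a comment", path)
  expect_error(read_spike_events(path, 0, 10), "empty")
})

test_that("write -> read round-trips node ids and times exactly", {
  rec <- poisson_recording(3, 5, 20, seed = 11)
  path <- withr::local_tempfile(fileext = ".txt")
  write_spike_events(rec, path)
  back <- read_spike_events(path, 0, 20)
  expect_equal(sort(names(back$trains)), sort(names(rec$trains)))
  for (id in names(rec$trains)) {
    expect_equal(back$trains[[id]]$times, rec$trains[[id]]$times)
  }
})

test_that("sample-index columns convert with the declared sampling rate", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("a\t25000", "a\t50000"), path)
  rec <- read_spike_events(path, 0, 10, sample_rate = 25000)
  expect_equal(rec$trains[["a"]]$times, c(1, 2))
})

test_that("low-activity filtering is strict at the threshold and idempotent", {
  t99 <- spike_train(seq(0.5, 99.49, length.out = 99), 0, 100, "low")
  t100 <- spike_train(seq(0.5, 99.49, length.out = 100), 0, 100, "edge")
  t500 <- spike_train(seq(0.1, 99.9, length.out = 500), 0, 100, "high")
  rec <- recording(list(t99, t100, t500))
  expect_message(kept <- filter_low_activity(rec, 100), "low")
  expect_equal(sort(names(kept$trains)), c("edge", "high"))
  expect_identical(names(filter_low_activity(kept, 100)$trains),
                   names(kept$trains))
  expect_equal(names(filter_low_activity(rec, 0)$trains), names(rec$trains))
  expect_error(filter_low_activity(rec, 1e6), "nothing to analyse")
})

test_that("jitter bounds offsets, preserves counts, and breaks grid ties", {
  grid <- spike_train(seq(0.0004, 4, by = 0.00004)[1:5000], 0, 5, "g")
  rec <- recording(list(grid))
  jit <- jitter_spike_times(rec, half_width = 2e-5, seed = 42)
  tj <- jit$trains[[1]]$times
  expect_length(tj, 5000)
  expect_true(all(abs(sort(tj) - grid$times) <= 2e-5 + 1e-12))
  expect_equal(anyDuplicated(diff(tj)), 0)
  expect_true(all(diff(tj) > 0))
  expect_identical(jitter_spike_times(rec, 0), rec)
  expect_error(jitter_spike_times(rec, -1), "half_width")
})

test_that("jitter with a fixed seed is reproducible and restores RNG state", {
  rec <- poisson_recording(2, 5, 30, seed = 4)
  set.seed(99)
  before <- .Random.seed
  j1 <- jitter_spike_times(rec, seed = 7)
  expect_identical(.Random.seed, before)
  j2 <- jitter_spike_times(rec, seed = 7)
  expect_identical(j1, j2)
})

test_that("cropping restricts to the half-open sub-window", {
  rec <- recording(list(spike_train(c(1, 2, 3, 4), 0, 10, "a")))
  sub <- crop_recording(rec, 2, 4)
  expect_equal(sub$trains[[1]]$times, c(2, 3))
  expect_equal(sub$t_start, 2)
  expect_error(crop_recording(rec, -1, 4), "within")
})
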