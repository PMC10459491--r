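# Pre-processing pipeline: normalisation, resampling, zero-phase
# filtering, initial-contact detection, segmentation, labelling, padding
# and subject-wise splitting.

flat_rec <- function(gy, rate = 60, range = 1, stages = c("normalize", "filter")) {
  n <- length(gy)
  imu_recording("S1", "T1", rate, matrix(0, n, 3),
                cbind(0, gy, 0), accel_range_g = range, gyro_range_dps = range,
                stages = stages)
}

test_that("normalisation divides by the sensor ranges and is idempotent", {
  rec <- imu_recording("S", "T", 128, cbind(c(16, 0, -16), 0, 0),
                       cbind(c(500, 0, 0), 0, 0))
  nrm <- normalize_recording(rec)
  expect_equal(nrm$accel[, 1], c(1, 0, -1))
  expect_equal(nrm$gyro[1, 1], 0.5)
  expect_equal(normalize_recording(nrm), nrm)
  expect_true("normalize" %in% nrm$stages)
})

test_that("resampling preserves content at the new rate", {
  n <- 256
  t <- (seq_len(n) - 1) / 128
  sine <- sin(2 * pi * 5 * t)
  rec <- imu_recording("S", "T", 128, matrix(0.5, n, 3),
                       cbind(0, sine, 0), gyro_range_dps = 1)
  out <- resample_recording(rec, 60)
  expect_equal(nrow(out$gyro), 120)            # round(256 * 60/128)
  t2 <- (seq_len(120) - 1) / 60
  core <- 10:110                               # away from the edges
  expect_lt(max(abs(out$gyro[core, 2] - sin(2 * pi * 5 * t2[core]))), 1e-2)
  # DC is preserved
  expect_equal(out$accel[, 1], rep(0.5, 120), tolerance = 1e-6)
  expect_error(resample_recording(rec, 256), "upsampling")
  expect_s3_class(resample_recording(rec, 256, allow_upsample = TRUE),
                  "imu_recording")
})

test_that("zero-phase Butterworth matches the analytic |H|^2 response", {
  rate <- 60
  t <- (0:599) / rate
  expect_equal(lowpass_zero_phase(rep(2.5, 600), rate, 10, 2),
               rep(2.5, 600), tolerance = 1e-7)
  y <- lowpass_zero_phase(sin(2 * pi * 25 * t), rate, 10, 2)
  amp <- max(abs(y[200:400]))
  # forward-backward bilinear Butterworth: |H|^2 with prewarped ratio
  r <- tan(pi * 25 / rate) / tan(pi * 10 / rate)
  expect_equal(amp, 1 / (1 + r^4), tolerance = 0.1)
  expect_lt(amp, 0.005)                        # 25 Hz essentially removed
  # zero phase: a symmetric pulse keeps its peak sample
  pulse <- exp(-0.5 * ((seq_len(301) - 151) / 12)^2)
  filtered <- lowpass_zero_phase(pulse, rate, 10, 2)
  expect_equal(which.max(filtered), 151)
  expect_error(lowpass_zero_phase(pulse, rate, 30, 2), "Nyquist")
})

test_that("initial contacts are the troughs after supra-threshold swings", {
  tr <- tiny_trial(duration = 26, noise = 0.01, seed = 31)
  cfg <- pipeline_config()
  rec <- filter_recording(resample_recording(normalize_recording(tr$recording),
                                             60), cfg)
  ev <- detect_initial_contacts(rec, cfg)
  n_planted <- length(tr$ic_times_s)
  expect_gte(n_planted, 20)
  hits <- vapply(tr$ic_times_s,
                 function(t) any(abs(ev$ic_times_s - t) <= 3 / 60), TRUE)
  expect_gte(mean(hits), 0.95)
  expect_true(all(diff(ev$ic_times_s) >= cfg$min_ic_interval_s))
  expect_true(all(ev$quality >= 0 & ev$quality <= 1))

  # a quiet signal yields no events, with a warning rather than an error
  expect_warning(ev0 <- detect_initial_contacts(flat_rec(rep(0, 600)), cfg),
                 "no mid-swing peak")
  expect_length(ev0$ic_times_s, 0)

  # unfiltered input is refused: the trough heuristic assumes filtering
  raw <- normalize_recording(tr$recording)
  expect_error(detect_initial_contacts(raw, cfg), "filter")
})

test_that("closely spaced candidate contacts resolve to the deeper trough", {
  rate <- 60
  t <- (0:(6 * rate - 1)) / rate
  g <- function(c, s, a) a * exp(-0.5 * ((t - c) / s)^2)
  # swing peak, deep trough at 2.0 s; second peak and shallow trough 0.3 s on
  gy <- g(1.8, 0.05, 0.5) - g(2.0, 0.04, 0.4) +
        g(2.15, 0.05, 0.5) - g(2.3, 0.04, 0.15)
  ev <- detect_initial_contacts(flat_rec(gy), pipeline_config())
  expect_length(ev$ic_times_s, 1)
  expect_lt(abs(ev$ic_times_s - 2.0), 3 / 60)
})

test_that("segmentation counts cycles, drops the first, discards over-length", {
  n <- 6 * 60
  rec <- flat_rec(rep(0.01, n))
  cfg <- pipeline_config()
  segs <- segment_strides(rec, gait_events(c(1, 2, 3, 4)), cfg)
  expect_length(segs, 2)                       # 3 raw cycles, first removed
  expect_equal(attr(segs, "n_raw_cycles"), 3L)
  expect_equal(vapply(segs, `[[`, 0L, "valid_length"), c(60L, 60L))

  expect_warning(s1 <- segment_strides(rec, gait_events(2.0), cfg), "fewer")
  expect_length(s1, 0)

  # 2 s cycle at 60 Hz = 120 samples > 108: discarded and counted
  segs2 <- segment_strides(rec, gait_events(c(0.5, 1.5, 3.5, 4.5)),
                           pipeline_config(drop_first_stride = FALSE))
  expect_length(segs2, 2)
  expect_equal(attr(segs2, "n_overlength"), 1L)
})

test_that("labels match by nearest timestamp, one-to-one, earlier wins", {
  seg <- function(ic, idx = 1L) stride_segment("S1", "T1", idx, ic,
                                               matrix(0.1, 6, 50), 50)
  labs <- data.frame(subject_id = "S1", trial_id = "T1", stride_index = 0:2,
                     stride_length_cm = c(110, 120, 130),
                     timestamp_s = c(9, 10, 11))
  out <- attach_labels(list(seg(10.02)), labs, max_offset_s = 0.25)
  expect_length(out, 1)
  expect_equal(out[[1]]$y_cm, 120)

  out2 <- attach_labels(list(seg(10.4)), labs, max_offset_s = 0.25)
  expect_length(out2, 0)
  expect_equal(attr(out2, "n_unmatched"), 1L)

  # two segments nearest the same label: the earlier one wins
  out3 <- attach_labels(list(seg(10.05, 1L), seg(10.10, 2L)), labs,
                        max_offset_s = 0.06)
  expect_length(out3, 1)
  expect_equal(out3[[1]]$ic_time_s, 10.05)

  bad <- rbind(labs, labs[1, ])
  expect_error(attach_labels(list(seg(10)), bad, max_offset_s = 0.25),
               "duplicate")
})

test_that("padding appends trailing zeros and refuses longer segments", {
  s <- stride_segment("S", "T", 0, 0, matrix(0.2, 6, 95), 95)
  p <- pad_segment(s, 108)
  expect_equal(ncol(p$x), 108)
  expect_true(all(p$x[, 96:108] == 0))
  expect_equal(p$valid_length, 95L)
  s108 <- stride_segment("S", "T", 0, 0, matrix(0.2, 6, 108), 108)
  expect_equal(pad_segment(s108, 108), s108)
  s109 <- stride_segment("S", "T", 0, 0, matrix(0.2, 6, 109), 109)
  expect_error(pad_segment(s109, 108), "exceeds")
})

test_that("subject-wise split partitions every stride exactly once", {
  segs <- c(lapply(1:5, random_segment, subject = "A"),
            lapply(6:9, random_segment, subject = "B"),
            lapply(10:12, random_segment, subject = "C"))
  ds <- labeled_stride_dataset(segs, 60, 108)
  sp <- split_by_subject(ds, c("A", "B"), "C")
  expect_equal(unname(sp$counts), c(9L, 0L, 3L))
  expect_equal(sum(sp$counts), length(segs))
  expect_error(split_by_subject(ds, c("A", "B"), c("B", "C")), "overlap")
  expect_error(split_by_subject(ds, c("A", "B"), "D"), "unknown")
  expect_error(split_by_subject(ds, "A", "B"), "not assigned")
  expect_error(split_by_subject(ds, c("A", "B", "C"), character(0)),
               "non-empty")
  sp2 <- split_by_subject(ds, c("A", "B"), "C")
  expect_equal(sp, sp2)
})

test_that("end-to-end: N planted strides give N-1 labelled segments", {
  tr <- tiny_trial(duration = 30, noise = 0.01, seed = 41)
  n <- nrow(tr$strides)
  for (true_events in c(TRUE, FALSE)) {
    ds <- preprocess_trials(list(tr), pipeline_config(),
                            use_true_events = true_events)
    expect_length(ds$segments, n - 1)
    expect_equal(attr(ds, "counters")$n_overlength, 0L)
    got <- vapply(ds$segments, `[[`, 0, "y_cm")
    expect_equal(got, tr$strides$stride_length_cm[-1], tolerance = 1e-12)
    expect_true(all(vapply(ds$segments,
                           function(s) max(abs(s$x)) <= 1, TRUE)))
  }
  # determinism of the whole pipeline
  d1 <- preprocess_trials(list(tr), pipeline_config())
  d2 <- preprocess_trials(list(tr), pipeline_config())
  expect_equal(d1, d2)
})

test_that("normalize and resample commute (both linear)", {
  tr <- tiny_trial(duration = 8, noise = 0.02, seed = 51)
  a <- resample_recording(normalize_recording(tr$recording), 60)
  b <- normalize_recording(resample_recording(tr$recording, 60))
  expect_equal(a$accel, b$accel, tolerance = 1e-9)
  expect_equal(a$gyro, b$gyro, tolerance = 1e-9)
})

test_that("cohort directory round trip reproduces the in-memory pipeline", {
  p <- gait_sim_params(n_subjects = 1, speeds_kmh = 4.0,
                       trial_duration_s = 12, seed = 61)
  d <- withr::local_tempdir()
  make_cohort(p, d, overwrite = TRUE)
  ds_disk <- preprocess_cohort(d, pipeline_config())
  ds_mem <- preprocess_trials(list(simulate_trial(p, "SUB01", 4.0)),
                              pipeline_config())
  expect_equal(length(ds_disk$segments), length(ds_mem$segments))
  expect_equal(vapply(ds_disk$segments, `[[`, 0, "y_cm"),
               vapply(ds_mem$segments, `[[`, 0, "y_cm"), tolerance = 1e-6)
})
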