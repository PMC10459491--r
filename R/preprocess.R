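# Pre-processing pipeline: sensor-range normalisation, downsampling to
# 60 Hz, zero-phase low-pass Butterworth filtering, gyroscope-based
# initial-contact detection, IC-to-IC stride segmentation with
# first-cycle removal, label attachment and trailing zero padding to a
# fixed 108-sample window (1.8 s at 60 Hz).

#' Pipeline configuration
#'
#' @param target_rate_hz working sample rate after downsampling (Hz).
#' @param filter_order,filter_cutoff_hz Butterworth low-pass design; the
#'   filter is applied forward-backward (zero phase), so the effective
#'   magnitude response is |H(f)|^2.
#' @param window_s fixed segment window (s); `pad_length` must equal
#'   `round(window_s * target_rate_hz)`.
#' @param pad_length fixed per-axis segment length in samples.
#' @param min_ic_interval_s minimum spacing between initial contacts (s).
#' @param swing_peak_threshold mid-swing peak threshold as a fraction of
#'   the gyroscope range (normalised units).
#' @param drop_first_stride drop the first measured gait cycle per trial
#'   (motion-initiation artefacts).
#' @param sagittal_channel which channel carries sagittal-plane angular
#'   velocity (`"gx"`, `"gy"` or `"gz"`).
#' @param max_label_offset_s label-matching tolerance (s).
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(target_rate_hz = 60, filter_order = 2,
                            filter_cutoff_hz = 10, window_s = 1.8,
                            pad_length = 108, min_ic_interval_s = 0.6,
                            swing_peak_threshold = 0.1,
                            drop_first_stride = TRUE,
                            sagittal_channel = "gy",
                            max_label_offset_s = 0.25) {
  assert_scalar_num(target_rate_hz, "target_rate_hz", positive = TRUE)
  assert_scalar_num(filter_cutoff_hz, "filter_cutoff_hz", positive = TRUE)
  if (pad_length != round(window_s * target_rate_hz))
    stop_gs("pad_length must equal round(window_s * target_rate_hz)")
  if (filter_cutoff_hz >= target_rate_hz / 2)
    stop_gs("filter_cutoff_hz must be below the Nyquist rate")
  if (swing_peak_threshold <= 0 || swing_peak_threshold >= 1)
    stop_gs("swing_peak_threshold must be in (0, 1)")
  sagittal_channel <- match.arg(sagittal_channel, c("gx", "gy", "gz"))
  structure(
    list(target_rate_hz = target_rate_hz, filter_order = as.integer(filter_order),
         filter_cutoff_hz = filter_cutoff_hz, window_s = window_s,
         pad_length = as.integer(pad_length),
         min_ic_interval_s = min_ic_interval_s,
         swing_peak_threshold = swing_peak_threshold,
         drop_first_stride = isTRUE(drop_first_stride),
         sagittal_channel = sagittal_channel,
         max_label_offset_s = max_label_offset_s),
    class = "pipeline_config")
}

#' Normalise a recording to its sensor ranges
#'
#' Divides accelerations by the accelerometer range (16 g) and angular
#' velocities by the gyroscope range (1000 deg/s), producing
#' dimensionless signals in [-1, 1]. The stored ranges are reset to 1 so
#' the operation is idempotent.
#'
#' @param rec an [imu_recording()].
#' @return normalised recording.
#' @export
normalize_recording <- function(rec) {
  stopifnot(inherits(rec, "imu_recording"))
  if (rec$accel_range_g <= 0 || rec$gyro_range_dps <= 0)
    stop_gs("sensor ranges must be positive")
  out <- imu_recording(rec$subject_id, rec$trial_id, rec$sample_rate_hz,
                       rec$accel / rec$accel_range_g,
                       rec$gyro / rec$gyro_range_dps,
                       accel_range_g = 1, gyro_range_dps = 1,
                       t0_s = rec$t0_s,
                       stages = unique(c(rec$stages, "normalize")))
  out
}

#' Resample a recording
#'
#' Downsampling applies an anti-aliasing zero-phase Butterworth low-pass
#' (order 4, cutoff 0.45 x target rate) before cubic-spline interpolation
#' onto the new uniform grid. Output length is
#' `round(T * target_rate_hz / sample_rate_hz)`.
#'
#' @param rec an [imu_recording()].
#' @param target_rate_hz new rate (Hz), must not exceed the current rate
#'   unless `allow_upsample = TRUE`.
#' @param allow_upsample permit upsampling.
#' @return resampled recording.
#' @export
resample_recording <- function(rec, target_rate_hz, allow_upsample = FALSE) {
  stopifnot(inherits(rec, "imu_recording"))
  assert_scalar_num(target_rate_hz, "target_rate_hz", positive = TRUE)
  src <- rec$sample_rate_hz
  if (target_rate_hz > src && !allow_upsample)
    stop_gs("upsampling requested (", src, " -> ", target_rate_hz,
            " Hz) without allow_upsample = TRUE")
  if (target_rate_hz == src) return(rec)
  n_in <- n_samples(rec)
  n_out <- round(n_in * target_rate_hz / src)
  t_in <- rec_times(rec)
  t_out <- rec$t0_s + (seq_len(n_out) - 1) / target_rate_hz
  ch <- rec_channels(rec)
  if (target_rate_hz < src) {
    cutoff <- 0.45 * target_rate_hz
    ch <- apply(ch, 2, lowpass_zero_phase, rate = src, cutoff_hz = cutoff,
                order = 4)
  }
  out <- vapply(seq_len(6), function(j)
    stats::spline(t_in, ch[, j], xout = t_out, method = "fmm")$y,
    numeric(n_out))
  # spline overshoot can marginally exceed the declared range; clamp
  amax <- rec$accel_range_g; gmax <- rec$gyro_range_dps
  imu_recording(rec$subject_id, rec$trial_id, target_rate_hz,
                pmax(pmin(out[, 1:3], amax), -amax),
                pmax(pmin(out[, 4:6], gmax), -gmax),
                accel_range_g = amax, gyro_range_dps = gmax,
                t0_s = rec$t0_s, stages = unique(c(rec$stages, "resample")))
}

#' Zero-phase Butterworth low-pass filter
#'
#' Second-order (by default) Butterworth low-pass applied forward and
#' backward so the net phase shift is zero and the effective magnitude
#' response is |H(f)|^2. Edges are padded by odd reflection (at least
#' 3 x filter order samples) to suppress start-up transients.
#'
#' @param x numeric vector.
#' @param rate sampling rate (Hz).
#' @param cutoff_hz cutoff frequency, must be below `rate/2`.
#' @param order filter order of one pass.
#' @return filtered vector, same length as `x`.
#' @export
lowpass_zero_phase <- function(x, rate, cutoff_hz, order = 2) {
  if (cutoff_hz >= rate / 2) stop_gs("cutoff_hz must be below the Nyquist rate")
  if (cutoff_hz <= 0) stop_gs("cutoff_hz must be positive")
  n <- length(x)
  bf <- signal::butter(order, cutoff_hz / (rate / 2), type = "low")
  np <- min(n - 1L, max(3L * order, round(2 * rate / cutoff_hz)))
  # centre the signal so the filter's zero initial conditions match the
  # signal level (unity DC gain then makes constants exact)
  mu <- mean(x)
  x <- x - mu
  xp <- c(2 * x[1] - x[(np + 1):2], x, 2 * x[n] - x[(n - 1):(n - np)])
  y <- signal::filter(bf, xp)
  y <- rev(as.numeric(signal::filter(bf, rev(as.numeric(y)))))
  y[(np + 1):(np + n)] + mu
}

#' Low-pass filter all six channels of a recording
#'
#' @param rec an [imu_recording()].
#' @param cfg a [pipeline_config()] (supplies cutoff and order).
#' @return filtered recording (stage tag `"filter"` added).
#' @export
filter_recording <- function(rec, cfg = pipeline_config()) {
  stopifnot(inherits(rec, "imu_recording"))
  ch <- apply(rec_channels(rec), 2, lowpass_zero_phase,
              rate = rec$sample_rate_hz, cutoff_hz = cfg$filter_cutoff_hz,
              order = cfg$filter_order)
  amax <- rec$accel_range_g; gmax <- rec$gyro_range_dps
  imu_recording(rec$subject_id, rec$trial_id, rec$sample_rate_hz,
                pmax(pmin(ch[, 1:3], amax), -amax),
                pmax(pmin(ch[, 4:6], gmax), -gmax),
                accel_range_g = amax, gyro_range_dps = gmax,
                t0_s = rec$t0_s, stages = unique(c(rec$stages, "filter")))
}

#' Gait events container
#'
#' @param ic_times_s strictly increasing initial-contact times (s).
#' @param ic_index sample indices of the events (optional).
#' @param quality per-event quality scores in [0, 1].
#' @param detection_channel channel identifier.
#' @return object of class `gait_events`.
#' @export
gait_events <- function(ic_times_s, ic_index = NULL,
                        quality = rep(1, length(ic_times_s)),
                        detection_channel = "gy") {
  if (length(ic_times_s) > 1 && any(diff(ic_times_s) <= 0))
    stop_gs("ic_times_s must be strictly increasing")
  structure(list(ic_times_s = as.numeric(ic_times_s), ic_index = ic_index,
                 quality = pmin(1, pmax(0, quality)),
                 detection_channel = detection_channel),
            class = "gait_events")
}

#' Detect initial contacts on the sagittal gyro channel
#'
#' Implements the gyroscope heuristic: a mid-swing positive peak above
#' `swing_peak_threshold` (fraction of the gyro range) marks an imminent
#' foot strike; the initial contact is the following local minimum of the
#' filtered sagittal angular velocity within `min_ic_interval_s`. Events
#' closer together than `min_ic_interval_s` are resolved in favour of the
#' deeper trough. The recording must already be low-pass filtered (the
#' stage tag is asserted: event detection on an unfiltered signal is not
#' the same algorithm).
#'
#' @param rec filtered, normalised recording at the working rate.
#' @param cfg a [pipeline_config()].
#' @return a [gait_events()] object; empty (with a warning) when no
#'   swing peak exceeds the threshold.
#' @export
detect_initial_contacts <- function(rec, cfg = pipeline_config()) {
  stopifnot(inherits(rec, "imu_recording"))
  if (!"filter" %in% rec$stages)
    stop_gs("recording must be low-pass filtered before IC detection ",
            "(stage tag 'filter' missing)")
  chan_idx <- c(gx = 4L, gy = 5L, gz = 6L)[[cfg$sagittal_channel]]
  s <- rec_channels(rec)[, chan_idx]
  thr <- cfg$swing_peak_threshold * rec$gyro_range_dps
  n <- length(s)
  fs <- rec$sample_rate_hz
  empty <- gait_events(numeric(0), integer(0), numeric(0), cfg$sagittal_channel)
  if (n < 3) { warn_gs("signal too short for event detection"); return(empty) }
  core <- 2:(n - 1)
  peaks <- core[s[core] > thr & s[core] >= s[core - 1] & s[core] > s[core + 1]]
  if (!length(peaks)) {
    warn_gs("no mid-swing peak exceeds the threshold; no events detected")
    return(empty)
  }
  win <- max(2L, round(cfg$min_ic_interval_s * fs))
  cand_idx <- integer(0); cand_val <- numeric(0)
  for (p in peaks) {
    hi <- min(n, p + win)
    if (hi - p < 2) next
    seg <- s[(p + 1):hi]
    rel <- which.min(seg)
    i <- p + rel
    # require a genuine local minimum (not the window edge still falling)
    if (rel == length(seg) && i < n && s[i + 1] < s[i]) next
    if (!length(cand_idx) || cand_idx[length(cand_idx)] != i) {
      cand_idx <- c(cand_idx, i); cand_val <- c(cand_val, s[i])
    }
  }
  if (!length(cand_idx)) {
    warn_gs("no trough found after any swing peak; no events detected")
    return(empty)
  }
  o <- order(cand_idx)
  cand_idx <- cand_idx[o]; cand_val <- cand_val[o]
  keep_idx <- integer(0); keep_val <- numeric(0)
  min_gap <- cfg$min_ic_interval_s * fs
  for (j in seq_along(cand_idx)) {
    if (length(keep_idx) &&
        cand_idx[j] - keep_idx[length(keep_idx)] < min_gap) {
      if (cand_val[j] < keep_val[length(keep_val)]) {   # deeper trough wins
        keep_idx[length(keep_idx)] <- cand_idx[j]
        keep_val[length(keep_val)] <- cand_val[j]
      }
    } else {
      keep_idx <- c(keep_idx, cand_idx[j]); keep_val <- c(keep_val, cand_val[j])
    }
  }
  times <- rec$t0_s + (keep_idx - 1) / fs
  quality <- pmin(1, pmax(0, -keep_val / thr))
  gait_events(times, keep_idx, quality, cfg$sagittal_channel)
}

#' Segment a recording into IC-to-IC gait cycles
#'
#' One segment per consecutive IC pair `[IC_k, IC_{k+1})`. The first
#' measured cycle of the trial is removed when
#' `cfg$drop_first_stride` (motion-initiation artefacts). Cycles longer
#' than `pad_length` samples cannot be represented in the fixed window
#' and are discarded (counted in attribute `n_overlength`).
#'
#' @param rec normalised recording at the working rate.
#' @param events a [gait_events()] object (detected or ground truth).
#' @param cfg a [pipeline_config()].
#' @return list of unpadded [stride_segment()]s; attributes
#'   `n_overlength` and `n_raw_cycles` hold counters.
#' @export
segment_strides <- function(rec, events, cfg = pipeline_config()) {
  stopifnot(inherits(rec, "imu_recording"), inherits(events, "gait_events"))
  fs <- rec$sample_rate_hz
  idx <- events$ic_index %||% (round((events$ic_times_s - rec$t0_s) * fs) + 1L)
  idx <- as.integer(pmin(pmax(idx, 1L), n_samples(rec)))
  if (length(idx) < 2) {
    warn_gs("fewer than two initial contacts: no segments")
    out <- list(); attr(out, "n_overlength") <- 0L
    attr(out, "n_raw_cycles") <- 0L
    return(out)
  }
  ch <- t(rec_channels(rec))    # 6 x T
  segs <- list(); n_over <- 0L
  n_raw <- length(idx) - 1L
  first <- if (cfg$drop_first_stride) 2L else 1L
  for (k in seq_len(n_raw)) {
    if (k < first) next
    a <- idx[k]; b <- idx[k + 1] - 1L
    len <- b - a + 1L
    if (len > cfg$pad_length) { n_over <- n_over + 1L; next }
    if (len < 1L) next
    segs[[length(segs) + 1L]] <- stride_segment(
      rec$subject_id, rec$trial_id, stride_index = k - 1L,
      ic_time_s = rec$t0_s + (a - 1) / fs,
      x = ch[, a:b, drop = FALSE], valid_length = len)
  }
  attr(segs, "n_overlength") <- n_over
  attr(segs, "n_raw_cycles") <- n_raw
  segs
}

#' Attach reference stride-length labels to segments
#'
#' Each segment is matched to the unused reference stride whose timestamp
#' is nearest the segment's IC time and within `max_offset_s`. Matching
#' is one-to-one; when two segments are nearest to the same label the
#' earlier segment wins and the later one is dropped. When `sync` events
#' are supplied, label timestamps are shifted into the recording clock by
#' aligning the first reference timestamp with the first sync event.
#'
#' @param segments list of [stride_segment()]s (one trial per call or
#'   mixed trials; matching is per trial).
#' @param labels a `stride_label_table` (see [read_stride_lengths()]).
#' @param sync optional `sync_events` for clock alignment.
#' @param max_offset_s matching tolerance (s).
#' @return list of labelled segments; attribute `n_unmatched` counts
#'   dropped segments.
#' @export
attach_labels <- function(segments, labels, sync = NULL, max_offset_s = 0.25) {
  if (anyDuplicated(labels[c("trial_id", "stride_index")]))
    stop_gs("duplicate (trial_id, stride_index) rows in label table")
  ts <- labels$timestamp_s
  if (!is.null(sync)) {
    stopifnot(inherits(sync, "sync_events"))
    if (length(sync$ic_times_s) && nrow(labels))
      ts <- ts + (sync$ic_times_s[1] - ts[1])
  }
  out <- list(); dropped <- 0L
  for (tid in unique(vapply(segments, `[[`, "", "trial_id"))) {
    seg_i <- which(vapply(segments, `[[`, "", "trial_id") == tid)
    lab_i <- which(labels$trial_id == tid)
    if (!length(lab_i)) { dropped <- dropped + length(seg_i); next }
    seg_i <- seg_i[order(vapply(segments[seg_i], `[[`, 0, "ic_time_s"))]
    used <- logical(length(lab_i))
    for (si in seg_i) {
      seg <- segments[[si]]
      d <- abs(ts[lab_i] - seg$ic_time_s)
      d[used] <- Inf
      j <- which.min(d)
      if (!is.finite(d[j]) || d[j] > max_offset_s) { dropped <- dropped + 1L; next }
      used[j] <- TRUE
      li <- lab_i[j]
      out[[length(out) + 1L]] <- stride_segment(
        seg$subject_id, seg$trial_id, seg$stride_index, seg$ic_time_s,
        seg$x, seg$valid_length, y_cm = labels$stride_length_cm[li])
    }
  }
  attr(out, "n_unmatched") <- dropped
  out
}

#' Zero-pad a segment to the fixed window length
#'
#' Trailing zeros are appended per axis (the IC-aligned onset stays at
#' column 0). Longer segments are a contract violation: the segmentation
#' stage must already have discarded them.
#'
#' @param segment a [stride_segment()].
#' @param pad_length target length in samples.
#' @return padded segment with unchanged `valid_length`.
#' @export
pad_segment <- function(segment, pad_length = 108) {
  stopifnot(inherits(segment, "stride_segment"))
  w <- ncol(segment$x)
  if (w > pad_length)
    stop_gs("segment of ", w, " samples exceeds pad_length ", pad_length)
  x <- cbind(segment$x, matrix(0, 6, pad_length - w))
  stride_segment(segment$subject_id, segment$trial_id, segment$stride_index,
                 segment$ic_time_s, x, valid_length = segment$valid_length,
                 y_cm = segment$y_cm)
}

#' Subject-wise dataset split
#'
#' Routes every segment to exactly one split according to its subject
#' identifier. The id sets must be disjoint, non-empty (train and test)
#' and together cover every subject present in the dataset.
#'
#' @param dataset a [labeled_stride_dataset()].
#' @param train_ids,test_ids,val_ids character vectors of subject ids.
#' @return object of class `dataset_split`: list with `train`,
#'   `validation` (or NULL), `test` datasets and a `counts` table.
#' @export
split_by_subject <- function(dataset, train_ids, test_ids, val_ids = NULL) {
  stopifnot(inherits(dataset, "labeled_stride_dataset"))
  if (!length(train_ids)) stop_gs("train_ids must be non-empty")
  if (!length(test_ids)) stop_gs("test_ids must be non-empty")
  all_ids <- c(train_ids, test_ids, val_ids)
  if (anyDuplicated(all_ids))
    stop_gs("subject id sets overlap: ",
            paste(unique(all_ids[duplicated(all_ids)]), collapse = ", "))
  present <- dataset_subjects(dataset)
  unknown <- setdiff(all_ids, present)
  if (length(unknown))
    stop_gs("unknown subject id(s): ", paste(unknown, collapse = ", "))
  uncovered <- setdiff(present, all_ids)
  if (length(uncovered))
    stop_gs("subjects not assigned to any split: ",
            paste(uncovered, collapse = ", "))
  pick <- function(ids) {
    segs <- Filter(function(s) s$subject_id %in% ids, dataset$segments)
    labeled_stride_dataset(segs, dataset$sample_rate_hz, dataset$pad_length)
  }
  train <- pick(train_ids); test <- pick(test_ids)
  val <- if (length(val_ids)) pick(val_ids) else NULL
  counts <- c(train = length(train$segments),
              validation = if (is.null(val)) 0L else length(val$segments),
              test = length(test$segments))
  structure(list(train = train, validation = val, test = test,
                 counts = counts), class = "dataset_split")
}

#' Run the full pre-processing pipeline on one trial
#'
#' Stage order: normalise -> resample -> filter -> IC detection ->
#' segmentation (first cycle removed) -> label attachment -> padding.
#'
#' @param rec raw [imu_recording()].
#' @param cfg a [pipeline_config()].
#' @param labels optional `stride_label_table` for this trial.
#' @param sync optional `sync_events`.
#' @param events optional precomputed [gait_events()] (bypasses
#'   detection, e.g. for ground-truth segmentation).
#' @return list with `segments` (padded, labelled when labels given),
#'   `events`, and `counters`.
#' @export
preprocess_trial <- function(rec, cfg = pipeline_config(), labels = NULL,
                             sync = NULL, events = NULL) {
  rec <- normalize_recording(rec)
  rec <- resample_recording(rec, cfg$target_rate_hz)
  rec <- filter_recording(rec, cfg)
  if (is.null(events)) events <- detect_initial_contacts(rec, cfg)
  segs <- segment_strides(rec, events, cfg)
  counters <- list(n_raw_cycles = attr(segs, "n_raw_cycles"),
                   n_overlength = attr(segs, "n_overlength"),
                   n_unmatched = 0L)
  if (!is.null(labels)) {
    segs <- attach_labels(segs, labels, sync, cfg$max_label_offset_s)
    counters$n_unmatched <- attr(segs, "n_unmatched")
  }
  segs <- lapply(segs, pad_segment, pad_length = cfg$pad_length)
  list(segments = segs, events = events, counters = counters)
}

#' Pre-process a list of simulated trials into a labelled dataset
#'
#' @param trials list of trials from [simulate_trial()]/[simulate_cohort()].
#' @param cfg a [pipeline_config()].
#' @param use_true_events segment at the planted (ground-truth) initial
#'   contacts instead of detected ones.
#' @return a [labeled_stride_dataset()]; attribute `counters` aggregates
#'   per-trial counters.
#' @export
preprocess_trials <- function(trials, cfg = pipeline_config(),
                              use_true_events = FALSE) {
  segs <- list()
  counters <- list(n_raw_cycles = 0L, n_overlength = 0L, n_unmatched = 0L)
  for (tr in trials) {
    labels <- tr$strides
    labels <- data.frame(subject_id = labels$subject_id,
                         trial_id = labels$trial_id,
                         stride_index = seq_len(nrow(labels)) - 1L,
                         stride_length_cm = labels$stride_length_cm,
                         timestamp_s = labels$ic_time_s,
                         stringsAsFactors = FALSE)
    ev <- if (use_true_events) gait_events(tr$ic_times_s) else NULL
    res <- preprocess_trial(tr$recording, cfg, labels = labels, events = ev)
    segs <- c(segs, res$segments)
    for (nm in names(counters))
      counters[[nm]] <- counters[[nm]] + (res$counters[[nm]] %||% 0L)
  }
  ds <- labeled_stride_dataset(segs, cfg$target_rate_hz, cfg$pad_length)
  attr(ds, "counters") <- counters
  ds
}

#' Pre-process a TRIPOD-layout cohort directory
#'
#' Reads every trial listed in the cohort manifest and runs
#' [preprocess_trial()] on it.
#'
#' @param dir cohort directory written by [make_cohort()].
#' @param cfg a [pipeline_config()].
#' @return a [labeled_stride_dataset()].
#' @export
preprocess_cohort <- function(dir, cfg = pipeline_config()) {
  manifest <- read_cohort_manifest(dir)
  segs <- list()
  for (tr in manifest$trials) {
    tdir <- file.path(dir, tr$dir)
    rec <- read_imu_csv(file.path(tdir, "RF.csv"),
                        sample_rate_hz = manifest$sample_rate_hz,
                        subject_id = tr$subject_id, trial_id = tr$trial_id,
                        accel_range_g = manifest$accel_range_g,
                        gyro_range_dps = manifest$gyro_range_dps)
    labels <- read_stride_lengths(file.path(tdir, "optogait.csv"),
                                  subject_id = tr$subject_id,
                                  trial_id = tr$trial_id)
    sync <- read_sync_info(file.path(tdir, "SyncInfo.csv"))
    res <- preprocess_trial(rec, cfg, labels = labels, sync = sync)
    segs <- c(segs, res$segments)
  }
  labeled_stride_dataset(segs, cfg$target_rate_hz, cfg$pad_length)
}
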