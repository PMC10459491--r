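# Core recording/segment containers and TRIPOD-style file I/O.
#
# File dialect: comma-separated, header row, UTF-8, '.' decimal. Column
# names are not fixed by the layout, hence the column_map indirection in
# read_imu_csv(). The labelled stride dataset travels as one JSON
# document per split (schema below).

LABELED_DATASET_SCHEMA <- "1.0"

#' Six-axis IMU recording
#'
#' Container for one trial of synchronous triaxial accelerometer (g) and
#' gyroscope (deg/s) data, together with the sample rate and the declared
#' sensor full-scale ranges. Processing stages applied to a recording are
#' tracked in the `stages` field so that order-sensitive steps (e.g.
#' initial-contact detection, which requires a filtered signal) can assert
#' their preconditions.
#'
#' @param subject_id,trial_id identifiers.
#' @param sample_rate_hz sampling rate in Hz (> 0).
#' @param accel T x 3 matrix of accelerations in g.
#' @param gyro T x 3 matrix of angular velocities in deg/s.
#' @param accel_range_g,gyro_range_dps declared sensor full-scale ranges.
#' @param t0_s time of the first sample (s).
#' @param stages character vector of processing-stage tags.
#' @return an object of class `imu_recording`.
#' @export
imu_recording <- function(subject_id, trial_id, sample_rate_hz, accel, gyro,
                          accel_range_g = 16, gyro_range_dps = 1000,
                          t0_s = 0, stages = character()) {
  accel <- as.matrix(accel); gyro <- as.matrix(gyro)
  assert_scalar_num(sample_rate_hz, "sample_rate_hz", positive = TRUE)
  assert_scalar_num(accel_range_g, "accel_range_g", positive = TRUE)
  assert_scalar_num(gyro_range_dps, "gyro_range_dps", positive = TRUE)
  if (ncol(accel) != 3L || ncol(gyro) != 3L)
    stop_gs("accel and gyro must each have 3 columns")
  if (nrow(accel) != nrow(gyro) || nrow(accel) < 1L)
    stop_gs("accel and gyro must have the same row count T >= 1")
  if (any(!is.finite(accel)) || any(!is.finite(gyro)))
    stop_gs("recording contains non-finite samples")
  if (max(abs(accel)) > accel_range_g + 1e-9)
    stop_gs("accelerometer samples exceed the declared range")
  if (max(abs(gyro)) > gyro_range_dps + 1e-9)
    stop_gs("gyroscope samples exceed the declared range")
  structure(
    list(subject_id = as.character(subject_id),
         trial_id = as.character(trial_id),
         sample_rate_hz = sample_rate_hz,
         accel = unname(accel), gyro = unname(gyro),
         accel_range_g = accel_range_g, gyro_range_dps = gyro_range_dps,
         t0_s = t0_s, stages = stages),
    class = "imu_recording")
}

#' @export
print.imu_recording <- function(x, ...) {
  cat(sprintf(
    "<imu_recording> %s/%s: %d samples @ %g Hz (%.1f s), ranges +-%g g / +-%g deg/s\n",
    x$subject_id, x$trial_id, nrow(x$accel), x$sample_rate_hz,
    nrow(x$accel) / x$sample_rate_hz, x$accel_range_g, x$gyro_range_dps))
  if (length(x$stages)) cat("  stages:", paste(x$stages, collapse = " -> "), "\n")
  invisible(x)
}

n_samples <- function(rec) nrow(rec$accel)

rec_times <- function(rec) rec$t0_s + (seq_len(n_samples(rec)) - 1) / rec$sample_rate_hz

# Six-channel matrix view (T x 6), channel order ax ay az gx gy gz.
rec_channels <- function(rec) cbind(rec$accel, rec$gyro)

#' One segmented gait cycle
#'
#' A stride segment holds the six-channel signal of one IC-to-IC gait
#' cycle as a 6 x pad_length matrix (channels ax ay az gx gy gz in rows,
#' time in columns, normalised units), the number of genuine samples
#' before zero padding, and optionally the reference stride length label.
#'
#' @param subject_id,trial_id,stride_index identifiers.
#' @param ic_time_s initial-contact time of the cycle start (s).
#' @param x 6 x L signal matrix (normalised units, |x| <= 1).
#' @param valid_length number of non-padding columns (defaults to ncol(x)).
#' @param y_cm reference stride length in cm, or `NA` if unlabelled.
#' @return an object of class `stride_segment`.
#' @export
stride_segment <- function(subject_id, trial_id, stride_index, ic_time_s,
                           x, valid_length = ncol(x), y_cm = NA_real_) {
  x <- as.matrix(x)
  if (nrow(x) != 6L) stop_gs("segment x must have 6 rows (channels)")
  if (valid_length > ncol(x)) stop_gs("valid_length exceeds segment width")
  if (max(abs(x)) > 1 + 1e-9)
    stop_gs("segment values must be normalised to |x| <= 1")
  if (valid_length < ncol(x) &&
      any(x[, (valid_length + 1):ncol(x)] != 0))
    stop_gs("padding columns beyond valid_length must be exactly zero")
  if (!is.na(y_cm) && y_cm <= 0) stop_gs("y_cm must be positive")
  structure(
    list(subject_id = as.character(subject_id),
         trial_id = as.character(trial_id),
         stride_index = as.integer(stride_index),
         ic_time_s = ic_time_s, x = unname(x),
         valid_length = as.integer(valid_length), y_cm = y_cm),
    class = "stride_segment")
}

#' Labelled stride dataset
#'
#' @param segments list of [stride_segment()] objects.
#' @param sample_rate_hz rate of the segment signals (Hz).
#' @param pad_length fixed per-axis segment length in samples.
#' @return an object of class `labeled_stride_dataset`.
#' @export
labeled_stride_dataset <- function(segments, sample_rate_hz, pad_length) {
  stopifnot(is.list(segments))
  for (s in segments) {
    if (!inherits(s, "stride_segment")) stop_gs("segments must be stride_segment objects")
    if (ncol(s$x) != pad_length)
      stop_gs("all segments must be padded to pad_length = ", pad_length)
  }
  structure(
    list(schema_version = LABELED_DATASET_SCHEMA,
         sample_rate_hz = sample_rate_hz,
         pad_length = as.integer(pad_length),
         segments = segments),
    class = "labeled_stride_dataset")
}

#' @export
print.labeled_stride_dataset <- function(x, ...) {
  subj <- unique(vapply(x$segments, `[[`, "", "subject_id"))
  cat(sprintf("<labeled_stride_dataset> %d segments, %d subjects, pad %d @ %g Hz\n",
              length(x$segments), length(subj), x$pad_length, x$sample_rate_hz))
  invisible(x)
}

dataset_subjects <- function(ds) unique(vapply(ds$segments, `[[`, "", "subject_id"))

dataset_labels <- function(ds) vapply(ds$segments, `[[`, 0, "y_cm")

#' Read a TRIPOD-style six-axis IMU CSV
#'
#' Values outside the declared sensor range are clipped to the range
#' (real IMUs saturate); the number of clipped cells is reported in a
#' warning and in the `clipped` attribute of the result.
#'
#' @param path CSV file path.
#' @param column_map named character vector mapping the six channel keys
#'   `ax, ay, az, gx, gy, gz` (and optionally `time`) to column names in
#'   the file.
#' @param sample_rate_hz sampling rate of the file (Hz).
#' @param subject_id,trial_id identifiers to attach.
#' @param accel_range_g,gyro_range_dps declared sensor ranges.
#' @return an [imu_recording()]; attribute `clipped` holds the clip count.
#' @export
read_imu_csv <- function(path, column_map = default_column_map(),
                         sample_rate_hz = 128,
                         subject_id = "UNKNOWN", trial_id = basename(dirname(path)),
                         accel_range_g = 16, gyro_range_dps = 1000) {
  if (!file.exists(path)) stop_gs("file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE, colClasses = "character")
  if (nrow(df) == 0L) stop_gs("empty IMU file: ", path)
  keys <- c("ax", "ay", "az", "gx", "gy", "gz")
  missing_keys <- setdiff(keys, names(column_map))
  if (length(missing_keys))
    stop_gs("column_map lacks channel keys: ", paste(missing_keys, collapse = ", "))
  missing_cols <- setdiff(unname(column_map[keys]), names(df))
  if (length(missing_cols))
    stop_gs("IMU file is missing required columns: ",
            paste(missing_cols, collapse = ", "))
  num <- function(key) {
    col <- df[[column_map[[key]]]]
    v <- suppressWarnings(as.numeric(col))
    if (anyNA(v)) {
      row <- which(is.na(v))[1]
      stop_gs("non-numeric value in column '", column_map[[key]],
              "' at data row ", row, ": '", col[row], "'")
    }
    v
  }
  accel <- cbind(num("ax"), num("ay"), num("az"))
  gyro <- cbind(num("gx"), num("gy"), num("gz"))
  clipped <- sum(abs(accel) > accel_range_g) + sum(abs(gyro) > gyro_range_dps)
  if (clipped > 0) {
    accel <- pmin(pmax(accel, -accel_range_g), accel_range_g)
    gyro <- pmin(pmax(gyro, -gyro_range_dps), gyro_range_dps)
    warn_gs(clipped, " sample(s) outside the declared sensor range were clipped")
  }
  t0 <- if ("time" %in% names(column_map) && column_map[["time"]] %in% names(df))
    suppressWarnings(as.numeric(df[[column_map[["time"]]]][1])) else 0
  if (is.na(t0)) t0 <- 0
  rec <- imu_recording(subject_id, trial_id, sample_rate_hz, accel, gyro,
                       accel_range_g, gyro_range_dps, t0_s = t0)
  attr(rec, "clipped") <- clipped
  rec
}

#' Default TRIPOD-dialect column map
#' @return named character vector usable as `column_map` in [read_imu_csv()].
#' @export
default_column_map <- function() {
  c(time = "time_s", ax = "ax_g", ay = "ay_g", az = "az_g",
    gx = "gx_dps", gy = "gy_dps", gz = "gz_dps")
}

#' Read initial-contact synchronisation timestamps
#'
#' @param path CSV with a column `ic_time_s` (first numeric column used as
#'   fallback). Duplicated timestamps are collapsed with a warning;
#'   decreasing timestamps are an error.
#' @return object of class `sync_events`: list with `ic_times_s`.
#' @export
read_sync_info <- function(path) {
  if (!file.exists(path)) stop_gs("file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE)
  col <- if ("ic_time_s" %in% names(df)) "ic_time_s" else names(df)[1]
  ts <- as.numeric(df[[col]])
  if (anyNA(ts)) stop_gs("non-numeric initial-contact timestamp in ", path)
  if (any(diff(ts) < 0)) stop_gs("initial-contact timestamps must be non-decreasing")
  ndup <- sum(diff(ts) == 0)
  if (ndup > 0) {
    warn_gs(ndup, " duplicate initial-contact timestamp(s) collapsed")
    ts <- unique(ts)
  }
  structure(list(ic_times_s = ts), class = "sync_events")
}

#' Read reference stride lengths (OptoGait-style CSV)
#'
#' @param path CSV with columns `stride_index`, `timestamp_s` (or
#'   `ic_time_s`) and `stride_length_cm` (or `stride_length_m` with
#'   `units = "m"`).
#' @param units `"cm"` (default) or `"m"`; metre values are multiplied by
#'   100. No auto-detection is performed.
#' @param subject_id,trial_id identifiers to attach.
#' @return data.frame of class `stride_label_table` with columns
#'   subject_id, trial_id, stride_index, stride_length_cm, timestamp_s.
#' @export
read_stride_lengths <- function(path, units = c("cm", "m"),
                                subject_id = "UNKNOWN",
                                trial_id = basename(dirname(path))) {
  units <- match.arg(units)
  if (!file.exists(path)) stop_gs("file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE)
  len_col <- intersect(c("stride_length_cm", "stride_length_m", "stride_length"),
                       names(df))[1]
  ts_col <- intersect(c("timestamp_s", "ic_time_s"), names(df))[1]
  if (is.na(len_col) || is.na(ts_col))
    stop_gs("stride-length file needs a timestamp and a stride_length column")
  len <- as.numeric(df[[len_col]]) * if (units == "m") 100 else 1
  ts <- as.numeric(df[[ts_col]])
  if (anyNA(len) || anyNA(ts)) stop_gs("non-numeric cell in ", path)
  if (any(len <= 0)) stop_gs("stride lengths must be positive (cm)")
  if (any(diff(ts) < 0)) stop_gs("label timestamps must be non-decreasing")
  idx <- if ("stride_index" %in% names(df)) as.integer(df$stride_index)
         else seq_len(nrow(df)) - 1L
  if (anyDuplicated(idx)) stop_gs("stride_index must be unique per trial")
  out <- data.frame(subject_id = subject_id, trial_id = trial_id,
                    stride_index = idx, stride_length_cm = len,
                    timestamp_s = ts, stringsAsFactors = FALSE)
  class(out) <- c("stride_label_table", "data.frame")
  out
}

#' Write / read the labelled stride dataset (JSON exchange format)
#'
#' One JSON document per split: `{schema_version, sample_rate_hz,
#' pad_length, segments: [{subject_id, trial_id, stride_index, ic_time_s,
#' valid_length, y_cm, x: 6 x pad_length}]}`. The round trip
#' `read(write(x))` is lossless to full float precision.
#'
#' @param dataset a [labeled_stride_dataset()].
#' @param path output/input JSON path.
#' @return `write_labeled_dataset` returns `path` invisibly;
#'   `read_labeled_dataset` returns the dataset.
#' @export
write_labeled_dataset <- function(dataset, path) {
  stopifnot(inherits(dataset, "labeled_stride_dataset"))
  doc <- list(
    schema_version = dataset$schema_version,
    sample_rate_hz = dataset$sample_rate_hz,
    pad_length = dataset$pad_length,
    segments = lapply(dataset$segments, function(s)
      list(subject_id = s$subject_id, trial_id = s$trial_id,
           stride_index = s$stride_index, ic_time_s = s$ic_time_s,
           valid_length = s$valid_length, y_cm = s$y_cm, x = s$x)))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       always_decimal = FALSE, na = "null")
  invisible(path)
}

#' @rdname write_labeled_dataset
#' @export
read_labeled_dataset <- function(path) {
  if (!file.exists(path)) stop_gs("file not found: ", path)
  doc <- tryCatch(jsonlite::read_json(path, simplifyVector = FALSE),
                  error = function(e) stop_gs("cannot parse dataset JSON: ",
                                              conditionMessage(e)))
  if (is.null(doc$schema_version) || !identical(doc$schema_version,
                                                LABELED_DATASET_SCHEMA))
    stop_gs("unsupported labelled-dataset schema version: ",
            doc$schema_version %||% "<missing>")
  segs <- lapply(doc$segments, function(s) {
    x <- do.call(rbind, lapply(s$x, function(r)
      vapply(r, function(v) if (is.null(v)) NA_real_ else as.numeric(v), 0)))
    stride_segment(s$subject_id, s$trial_id, s$stride_index, s$ic_time_s,
                   x, s$valid_length,
                   if (is.null(s$y_cm)) NA_real_ else as.numeric(s$y_cm))
  })
  labeled_stride_dataset(segs, doc$sample_rate_hz, doc$pad_length)
}
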