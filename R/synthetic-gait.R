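# Synthetic treadmill gait generator.
#
# Emulates multi-subject, three-speed treadmill trials recorded by a
# right-instep six-axis IMU (+-16 g, +-1000 deg/s, 128 Hz) with known
# initial-contact (IC) times and per-stride reference lengths. The signal
# model is deliberately minimal: it carries exactly the features the
# downstream stages rely on (a gyro IC trough for event detection, a
# swing-peak amplitude that encodes stride length for the regressor),
# not a biomechanically exact foot trajectory.
#
# Per stride, the sagittal gyro channel (gy) holds a small negative
# toe-off trough (~60% of the cycle), a positive mid-swing Gaussian pulse
# (~80%) and a sharp negative trough exactly at the next IC. The swing
# peak amplitude follows
#     A = k * (stride_length / leg_ref) * cadence,   k = 5,
# with leg_ref the cohort mean leg length (86.2 cm). Normalising by a
# fixed reference rather than the subject's own leg keeps the
# amplitude -> length mapping invertible from the signal alone
# (L = A * period * leg_ref / (60 k)), which is the generator's contract:
# a regressor must be able to recover the planted label for a subject it
# has never seen. Per-subject leg length (drawn from the anthropometric
# range 76-95 cm, mean 86.2, sd 4.3) enters through the subject's
# preferred stride length (1.5 x leg). The vertical accelerometer
# carries a 1 g gravity offset plus a damped 12 Hz impact transient of
# fixed amplitude at each IC.

SWING_GAIN <- 5          # deg/s per (stride/leg ratio * strides/min)
REF_LEG_CM <- 86.2       # cohort mean leg length, cm
IMPACT_BASE_G <- 1.8     # IC impact amplitude at the reference leg length
IC0_S <- 0.4             # time of the first planted IC

#' Simulation parameters for the synthetic gait cohort
#'
#' Defaults reproduce the acquisition conditions emulated by the package:
#' 15 subjects, three treadmill speeds around each subject's preferred
#' walking speed (PWS ~ N(3.9, 0.5^2) km/h truncated to [3.1, 4.9]),
#' two-minute trials at 128 Hz.
#'
#' @param n_subjects number of subjects.
#' @param speeds_kmh absolute treadmill speeds shared by all subjects, or
#'   `NULL` (default) for the per-subject grid {0.8, 1.0, 1.2} x PWS.
#' @param trial_duration_s trial duration (s).
#' @param sample_rate_hz IMU sampling rate (Hz).
#' @param stride_length_mean_cm subject mean stride length at PWS, or
#'   `NULL` to derive it from the subject's leg length (1.5 x leg).
#' @param stride_length_sd_cm within-trial stride-to-stride sd (cm).
#' @param cadence_spm fixed cadence in strides/min, or `NULL` to derive
#'   cadence from speed and stride length (cadence = speed / length).
#' @param noise_sd white sensor noise sd as a fraction of the full-scale
#'   range (must be < 0.2); also scales stride-timing jitter.
#' @param drift_per_min slow gyroscope bias drift (deg/s per minute).
#' @param seed master seed; all per-subject/per-trial substreams are
#'   derived from it by hashing.
#' @return an object of class `gait_sim_params`.
#' @export
gait_sim_params <- function(n_subjects = 15, speeds_kmh = NULL,
                            trial_duration_s = 120, sample_rate_hz = 128,
                            stride_length_mean_cm = NULL,
                            stride_length_sd_cm = 4,
                            cadence_spm = NULL,
                            noise_sd = 0.02, drift_per_min = 0.5,
                            seed = 1L) {
  assert_scalar_num(n_subjects, "n_subjects", positive = TRUE)
  assert_scalar_num(trial_duration_s, "trial_duration_s", positive = TRUE)
  assert_scalar_num(sample_rate_hz, "sample_rate_hz", positive = TRUE)
  assert_scalar_num(stride_length_sd_cm, "stride_length_sd_cm", nonneg = TRUE)
  assert_scalar_num(noise_sd, "noise_sd", nonneg = TRUE)
  assert_scalar_num(drift_per_min, "drift_per_min")
  if (noise_sd >= 0.2) stop_gs("noise_sd must be < 0.2 (fraction of range)")
  if (!is.null(speeds_kmh) && any(speeds_kmh <= 0))
    stop_gs("speeds_kmh must be positive")
  if (!is.null(stride_length_mean_cm)) {
    assert_scalar_num(stride_length_mean_cm, "stride_length_mean_cm",
                      positive = TRUE)
  }
  if (!is.null(cadence_spm))
    assert_scalar_num(cadence_spm, "cadence_spm", positive = TRUE)
  # impact transient at 12 Hz is the fastest planted component
  if (sample_rate_hz <= 2 * 12)
    stop_gs("sample_rate_hz must exceed twice the highest simulated frequency")
  structure(
    list(n_subjects = as.integer(n_subjects), speeds_kmh = speeds_kmh,
         trial_duration_s = trial_duration_s, sample_rate_hz = sample_rate_hz,
         stride_length_mean_cm = stride_length_mean_cm,
         stride_length_sd_cm = stride_length_sd_cm,
         cadence_spm = cadence_spm, noise_sd = noise_sd,
         drift_per_min = drift_per_min, seed = as.integer(seed)),
    class = "gait_sim_params")
}

# Per-subject anthropometrics, a deterministic function of (seed, subject).
subject_profile <- function(params, subject_id) {
  with_local_seed(hash_seed(params$seed, "subject", subject_id), {
    pws <- min(4.9, max(3.1, stats::rnorm(1, 3.9, 0.5)))
    leg <- min(95, max(76, stats::rnorm(1, REF_LEG_CM, 4.3)))
    list(pws_kmh = pws, leg_cm = leg)
  })
}

# Add a Gaussian bump evaluated only on a +-5 sd window (cheap).
add_bump <- function(sig, t, center, sd_s, amp) {
  dt <- t[2] - t[1]
  lo <- max(1L, floor((center - 5 * sd_s - t[1]) / dt) + 1L)
  hi <- min(length(t), ceiling((center + 5 * sd_s - t[1]) / dt) + 1L)
  if (lo > hi) return(sig)
  idx <- lo:hi
  sig[idx] <- sig[idx] + amp * exp(-0.5 * ((t[idx] - center) / sd_s)^2)
  sig
}

#' Simulate one treadmill trial
#'
#' Generates a six-axis recording of `trial_duration_s` seconds plus the
#' ground-truth stride table. Identical `(params, subject_id, speed_kmh)`
#' give byte-identical output.
#'
#' @param params a [gait_sim_params()] object.
#' @param subject_id subject identifier, e.g. `"SUB01"`.
#' @param speed_kmh treadmill speed (> 0) in km/h.
#' @return list with elements `recording` ([imu_recording()]),
#'   `strides` (data.frame: subject_id, trial_id, ic_time_s,
#'   stride_length_cm, swing_amp_dps, period_s, leg_length_cm) and
#'   `ic_times_s` (all planted IC times, including the one closing the
#'   final complete stride).
#' @export
simulate_trial <- function(params, subject_id, speed_kmh) {
  stopifnot(inherits(params, "gait_sim_params"))
  assert_scalar_num(speed_kmh, "speed_kmh", positive = TRUE)
  if (params$noise_sd >= 0.2) stop_gs("noise_sd must be < 0.2")
  prof <- subject_profile(params, subject_id)
  trial_id <- sprintf("%s_v%03d", subject_id, round(speed_kmh * 10))

  speed_cm_min <- speed_kmh * 1e5 / 60
  l_pws <- params$stride_length_mean_cm %||% (1.5 * prof$leg_cm)
  cad_pws <- (prof$pws_kmh * 1e5 / 60) / l_pws
  cad <- params$cadence_spm %||% (cad_pws * sqrt(speed_kmh / prof$pws_kmh))
  l_mean <- speed_cm_min / cad        # stride length consistent with speed
  period <- 60 / cad                  # s per stride
  dur <- params$trial_duration_s
  if (dur < IC0_S + period)
    stop_gs("trial_duration_s too short for one complete stride (needs >= ",
            round(IC0_S + period, 2), " s)")

  with_local_seed(hash_seed(params$seed, "trial", subject_id,
                            sprintf("%.4f", speed_kmh)), {
    # planted IC sequence; period jitter scales with noise_sd
    n_max <- ceiling((dur - IC0_S) / period) + 2L
    jitter <- if (params$noise_sd > 0)
      pmax(-2.5, pmin(2.5, stats::rnorm(n_max))) * params$noise_sd else
      numeric(n_max)
    periods <- period * (1 + jitter)
    ics <- IC0_S + c(0, cumsum(periods))
    ics <- ics[ics <= dur]
    n_str <- length(ics) - 1L           # complete IC-to-IC cycles
    if (n_str < 1L) stop_gs("trial too short: no complete stride")

    lens <- stats::rnorm(n_str, l_mean, params$stride_length_sd_cm)
    lens <- pmin(249, pmax(30.5, lens))
    p_k <- diff(ics)
    amps <- SWING_GAIN * (lens / REF_LEG_CM) * (60 / p_k)

    fs <- params$sample_rate_hz
    nt <- round(dur * fs)
    t <- (seq_len(nt) - 1) / fs

    gy <- numeric(nt)
    # lead-in: the subject is already walking, so a mid-swing pulse
    # precedes the first planted IC (the detector needs it)
    gy <- add_bump(gy, t, ics[1] - 0.20 * p_k[1], 0.05 * p_k[1], amps[1])
    # per-stride toe-off trough and mid-swing pulse
    for (k in seq_len(n_str)) {
      gy <- add_bump(gy, t, ics[k] + 0.60 * p_k[k], 0.07 * p_k[k], -0.25 * amps[k])
      gy <- add_bump(gy, t, ics[k] + 0.80 * p_k[k], 0.05 * p_k[k], amps[k])
    }
    # sharp trough exactly at each planted IC; depth tied to the adjacent
    # stride so it stays proportional to the local signal scale
    for (j in seq_along(ics)) {
      a <- amps[min(j, n_str)]
      p <- p_k[min(j, n_str)]
      gy <- add_bump(gy, t, ics[j], 0.035 * p, -0.5 * a)
    }
    gy <- gy + params$drift_per_min * t / 60

    # vertical accel: gravity + damped impact transient at each IC
    az <- rep(1, nt)
    b_imp <- IMPACT_BASE_G
    for (j in seq_along(ics)) {
      rel <- t - ics[j]
      idx <- which(rel >= 0 & rel < 0.4)
      az[idx] <- az[idx] + b_imp * exp(-rel[idx] / 0.08) * sin(2 * pi * 12 * rel[idx])
    }

    # remaining channels: low-amplitude stride-locked components plus
    # correlated (AR(1)) noise
    ar1 <- function(n, sd) {
      if (sd == 0) return(numeric(n))
      as.numeric(stats::filter(stats::rnorm(n, 0, sd * sqrt(1 - 0.9^2)),
                               0.9, method = "recursive"))
    }
    phase <- stats::runif(4, 0, 2 * pi)
    walk_ph <- 2 * pi * t / period
    ax <- 0.15 * sin(walk_ph + phase[1]) + ar1(nt, 0.05)
    ay <- 0.10 * sin(2 * walk_ph + phase[2]) + ar1(nt, 0.05)
    gx <- 25 * sin(walk_ph + phase[3]) + ar1(nt, 8)
    gz <- 20 * sin(walk_ph + phase[4]) + ar1(nt, 8)

    if (params$noise_sd > 0) {
      ax <- ax + stats::rnorm(nt, 0, params$noise_sd * 16)
      ay <- ay + stats::rnorm(nt, 0, params$noise_sd * 16)
      az <- az + stats::rnorm(nt, 0, params$noise_sd * 16)
      gx <- gx + stats::rnorm(nt, 0, params$noise_sd * 1000)
      gy <- gy + stats::rnorm(nt, 0, params$noise_sd * 1000)
      gz <- gz + stats::rnorm(nt, 0, params$noise_sd * 1000)
    }

    accel <- cbind(pmin(16, pmax(-16, ax)), pmin(16, pmax(-16, ay)),
                   pmin(16, pmax(-16, az)))
    gyro <- cbind(pmin(1000, pmax(-1000, gx)), pmin(1000, pmax(-1000, gy)),
                  pmin(1000, pmax(-1000, gz)))

    strides <- data.frame(
      subject_id = subject_id, trial_id = trial_id,
      ic_time_s = ics[seq_len(n_str)], stride_length_cm = lens,
      swing_amp_dps = amps, period_s = p_k, leg_length_cm = prof$leg_cm,
      stringsAsFactors = FALSE)

    list(recording = imu_recording(subject_id, trial_id, fs, accel, gyro,
                                   stages = "raw"),
         strides = strides, ic_times_s = ics, speed_kmh = speed_kmh,
         leg_length_cm = prof$leg_cm)
  })
}

# Per-subject speed grid.
subject_speeds <- function(params, subject_id) {
  if (!is.null(params$speeds_kmh)) return(params$speeds_kmh)
  prof <- subject_profile(params, subject_id)
  c(0.8, 1.0, 1.2) * prof$pws_kmh
}

subject_ids <- function(params) sprintf("SUB%02d", seq_len(params$n_subjects))

#' Simulate a whole cohort in memory
#'
#' @param params a [gait_sim_params()] object.
#' @return list of trials as returned by [simulate_trial()].
#' @export
simulate_cohort <- function(params) {
  out <- list()
  for (sid in subject_ids(params))
    for (v in subject_speeds(params, sid))
      out[[length(out) + 1L]] <- simulate_trial(params, sid, v)
  out
}

#' Write a TRIPOD-layout cohort to disk
#'
#' Creates `out_dir/<subject>/<trial>/` with `RF.csv` (time + six
#' channels), `SyncInfo.csv` (initial-contact timestamps) and
#' `optogait.csv` (reference stride lengths), plus a top-level
#' `manifest.json`. Output is byte-identical for identical params.
#'
#' @param params a [gait_sim_params()] object.
#' @param out_dir output directory.
#' @param overwrite allow writing into an existing non-empty directory.
#' @return the manifest (invisibly), as a list.
#' @export
make_cohort <- function(params, out_dir, overwrite = FALSE) {
  if (dir.exists(out_dir) && length(list.files(out_dir)) > 0 && !overwrite)
    stop_gs("out_dir exists and is not empty (use overwrite = TRUE): ", out_dir)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  trials <- list()
  for (sid in subject_ids(params)) {
    for (v in subject_speeds(params, sid)) {
      tr <- simulate_trial(params, sid, v)
      tdir <- file.path(out_dir, sid, tr$recording$trial_id)
      dir.create(tdir, recursive = TRUE, showWarnings = FALSE)
      write_trial_csvs(tr, tdir)
      trials[[length(trials) + 1L]] <- list(
        subject_id = sid, trial_id = tr$recording$trial_id,
        speed_kmh = round(v, 4), dir = file.path(sid, tr$recording$trial_id),
        n_strides = nrow(tr$strides))
    }
  }
  manifest <- list(schema_version = "1.0", seed = params$seed,
                   sample_rate_hz = params$sample_rate_hz,
                   accel_range_g = 16, gyro_range_dps = 1000,
                   subjects = subject_ids(params), trials = trials)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

write_trial_csvs <- function(trial, tdir) {
  rec <- trial$recording
  tt <- rec_times(rec)
  lines <- paste(fmt_num(tt), fmt_num(rec$accel[, 1]), fmt_num(rec$accel[, 2]),
                 fmt_num(rec$accel[, 3]), fmt_num(rec$gyro[, 1]),
                 fmt_num(rec$gyro[, 2]), fmt_num(rec$gyro[, 3]), sep = ",")
  writeLines(c("time_s,ax_g,ay_g,az_g,gx_dps,gy_dps,gz_dps", lines),
             file.path(tdir, "RF.csv"))
  writeLines(c("ic_time_s", fmt_num(trial$ic_times_s)),
             file.path(tdir, "SyncInfo.csv"))
  st <- trial$strides
  writeLines(c("stride_index,timestamp_s,stride_length_cm",
               paste(seq_len(nrow(st)) - 1L, fmt_num(st$ic_time_s),
                     fmt_num(st$stride_length_cm), sep = ",")),
             file.path(tdir, "optogait.csv"))
  invisible(tdir)
}

#' Read back a cohort manifest
#' @param dir cohort directory written by [make_cohort()].
#' @return manifest list.
#' @export
read_cohort_manifest <- function(dir) {
  path <- file.path(dir, "manifest.json")
  if (!file.exists(path)) stop_gs("no manifest.json in ", dir)
  jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
}
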