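# Agreement statistics between estimated and reference stride lengths:
# Bland-Altman bias and limits of agreement, minimal detectable change,
# MSE and R^2, plus a leave-one-subject-out cross-validation harness.
#
# Difference direction is estimate - reference throughout, so a positive
# mean error means overestimation. The limits-of-agreement multiplier is
# fixed at 1.96 (no t correction) and MDC = 1.96 * SD of differences.

#' Bland-Altman agreement report
#'
#' Computes differences `d = estimate - reference`, the mean error
#' (bias), the sample standard deviation of differences (n - 1), the
#' 95% limits of agreement `ME +- 1.96 * SD`, the minimal detectable
#' change `1.96 * SD`, plus MSE and R^2, and the per-pair
#' (mean, difference) table used for plotting.
#'
#' @param estimates,references numeric vectors of equal length >= 2 (cm).
#' @return object of class `agreement_report` with fields `n`, `me_cm`,
#'   `sd_cm`, `upper_loa_cm`, `lower_loa_cm`, `mdc_cm`, `mse_cm2`, `r2`,
#'   `pairs`.
#' @export
bland_altman <- function(estimates, references) {
  if (length(estimates) != length(references))
    stop_gs("estimates and references must have equal length")
  n <- length(estimates)
  if (n < 2) stop_gs("need at least 2 pairs (SD undefined otherwise)")
  if (any(!is.finite(estimates)) || any(!is.finite(references)))
    stop_gs("non-finite values in estimates or references")
  d <- estimates - references
  me <- mean(d)
  sd_d <- stats::sd(d)
  mr <- mse_r2(estimates, references)
  rep <- structure(list(
    n = n, me_cm = me, sd_cm = sd_d,
    upper_loa_cm = me + 1.96 * sd_d, lower_loa_cm = me - 1.96 * sd_d,
    mdc_cm = 1.96 * sd_d, mse_cm2 = mr$mse_cm2, r2 = mr$r2,
    pairs = data.frame(mean = (estimates + references) / 2, difference = d)),
    class = "agreement_report")
  validate_agreement(rep)
  rep
}

validate_agreement <- function(x) {
  stopifnot(abs(x$upper_loa_cm - (x$me_cm + 1.96 * x$sd_cm)) < 1e-9,
            abs(x$lower_loa_cm - (x$me_cm - 1.96 * x$sd_cm)) < 1e-9,
            abs(x$mdc_cm - 1.96 * x$sd_cm) < 1e-9,
            x$sd_cm >= 0,
            x$mse_cm2 >= x$me_cm^2 - 1e-9)
  invisible(x)
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf("<agreement_report> n = %d\n", x$n))
  cat(sprintf("  ME +- SD : %.2f +- %.2f cm\n", x$me_cm, x$sd_cm))
  cat(sprintf("  LoA      : [%.2f, %.2f] cm\n", x$lower_loa_cm, x$upper_loa_cm))
  cat(sprintf("  MDC      : %.2f cm\n", x$mdc_cm))
  cat(sprintf("  MSE      : %.2f cm^2   R^2: %s\n", x$mse_cm2,
              if (is.na(x$r2)) "undefined" else sprintf("%.3f", x$r2)))
  invisible(x)
}

#' Mean squared error and coefficient of determination
#'
#' `mse = mean((estimate - reference)^2)`;
#' `r2 = 1 - sum(d^2) / sum((reference - mean(reference))^2)`. With zero
#' reference variance R^2 is undefined and reported as `NA`.
#'
#' @param estimates,references numeric vectors (cm).
#' @return list with `mse_cm2` and `r2`.
#' @export
mse_r2 <- function(estimates, references) {
  if (length(estimates) != length(references) || length(estimates) < 2)
    stop_gs("need equal-length vectors with n >= 2")
  d <- estimates - references
  ss_ref <- sum((references - mean(references))^2)
  list(mse_cm2 = mean(d^2),
       r2 = if (ss_ref <= 0) NA_real_ else 1 - sum(d^2) / ss_ref)
}

#' Leave-one-subject-out cross-validation
#'
#' For each subject, trains on all other subjects' strides and predicts
#' the held-out subject's strides; reports a per-fold
#' [bland_altman()] report and a pooled report over all held-out
#' predictions. Per-fold seeds are derived from `seed`.
#'
#' @param dataset a labelled [labeled_stride_dataset()] (>= 2 subjects).
#' @param spec a [model_spec()].
#' @param cfg a [train_cfg()].
#' @param seed master seed for the per-fold substreams.
#' @param trainer function `(spec, train_set, cfg, seed) -> model`;
#'   defaults to [retrain_final()]. Injectable for mock-based tests.
#' @param predictor function `(model, segments) -> estimates`; defaults
#'   to [predict_cnn()].
#' @return object of class `cv_result`: list with `folds` (named list of
#'   per-fold reports), `pooled` ([bland_altman()] over all held-out
#'   pairs), `pooled_n`.
#' @export
loso_cv <- function(dataset, spec = model_spec(), cfg = train_cfg(),
                    seed = cfg$seed, trainer = NULL, predictor = predict_cnn) {
  stopifnot(inherits(dataset, "labeled_stride_dataset"))
  subs <- sort(dataset_subjects(dataset))
  if (length(subs) < 2) stop_gs("LOSO-CV needs at least 2 subjects")
  if (is.null(trainer))
    trainer <- function(spec, train_set, cfg, seed)
      retrain_final(spec, train_set, cfg, seed = seed)
  folds <- list(); est <- numeric(0); ref <- numeric(0)
  for (s in subs) {
    test_segs <- Filter(function(x) x$subject_id == s, dataset$segments)
    if (!length(test_segs)) {
      warn_gs("subject ", s, " has no segments; fold skipped")
      next
    }
    train_segs <- Filter(function(x) x$subject_id != s, dataset$segments)
    train_ds <- labeled_stride_dataset(train_segs, dataset$sample_rate_hz,
                                       dataset$pad_length)
    model <- trainer(spec, train_ds, cfg, hash_seed(seed, "fold", s))
    p <- predictor(model, test_segs)
    y <- vapply(test_segs, `[[`, 0, "y_cm")
    folds[[s]] <- bland_altman(p, y)
    est <- c(est, p); ref <- c(ref, y)
  }
  structure(list(folds = folds, pooled = bland_altman(est, ref),
                 pooled_n = length(est)), class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %d folds, pooled n = %d: ME %.2f +- %.2f cm\n",
              length(x$folds), x$pooled_n, x$pooled$me_cm, x$pooled$sd_cm))
  invisible(x)
}

#' Bland-Altman plot
#'
#' Scatter of per-pair (mean, difference) with the bias and the 95%
#' limits of agreement drawn as horizontal lines. Written as SVG or PNG
#' depending on the file extension.
#'
#' @param report an [bland_altman()] report.
#' @param path output file (`.svg` or `.png`).
#' @param main plot title.
#' @return `path`, invisibly.
#' @export
make_bland_altman_plot <- function(report, path, main = "Bland-Altman") {
  stopifnot(inherits(report, "agreement_report"))
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         svg = grDevices::svg(path, width = 7, height = 5),
         png = grDevices::png(path, width = 900, height = 640, res = 120),
         stop_gs("unsupported plot format: .", ext))
  on.exit(grDevices::dev.off())
  p <- report$pairs
  ylim <- range(c(p$difference, report$upper_loa_cm, report$lower_loa_cm))
  plot(p$mean, p$difference, pch = 16, cex = 0.5,
       col = grDevices::adjustcolor("steelblue4", 0.6),
       xlab = "mean of estimate and reference (cm)",
       ylab = "estimate - reference (cm)", main = main,
       ylim = ylim + c(-0.1, 0.1) * diff(ylim))
  graphics::abline(h = report$me_cm, col = "grey20", lwd = 2)
  graphics::abline(h = c(report$lower_loa_cm, report$upper_loa_cm),
                   col = "firebrick", lty = 2, lwd = 1.5)
  lab <- sprintf("ME %.2f; LoA [%.2f, %.2f]",
                 report$me_cm, report$lower_loa_cm, report$upper_loa_cm)
  graphics::mtext(lab, side = 3, line = 0.2, cex = 0.8)
  invisible(path)
}
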