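# Post-training quantization: calibration formulas, lattice rounding,
# the integer inference engine against an independent fake-quant oracle,
# model comparison and the C-array exporter.

test_that("calibration follows the affine min/max formulas", {
  # activations observed in [0, 2] -> scale 2/255, zero point -128
  qp <- gaitstride:::act_qparams(0, 2)
  expect_equal(qp$scale, 2 / 255)
  expect_equal(qp$zero_point, -128L)
  # symmetric range centres the zero point
  qp2 <- gaitstride:::act_qparams(-1, 1)
  expect_equal(qp2$scale, 2 / 255)
  expect_equal(qp2$zero_point, 0L)
  # the range is widened to include zero
  qp3 <- gaitstride:::act_qparams(0.5, 2)
  expect_equal(qp3$scale, 2 / 255)
  # an all-zero tensor floors the scale with a warning
  expect_warning(qp4 <- gaitstride:::act_qparams(0, 0), "floored")
  expect_gte(qp4$scale, 1e-8)
  # a constant positive tensor is handled by widening the range to zero
  expect_equal(gaitstride:::act_qparams(0.3, 0.3)$scale, 0.3 / 255)

  # per-channel weight scale = max|w| / 127
  W <- cbind(seq(-1, 1, length.out = 11), seq(-0.5, 0.25, length.out = 11))
  expect_equal(gaitstride:::weight_scales(W), c(1, 0.5) / 127)

  m <- tiny_net(1)
  qp5 <- calibrate_quantization(m, array(0.3, c(24, 1, 3)))
  expect_s3_class(qp5, "quant_params")
  expect_equal(qp5$n_representative, 1)
})

test_that("weight quantization is exact on lattice points and bounded", {
  m <- tiny_net(2)
  x <- array(runif(24 * 6 * 3, -0.5, 0.5), c(24, 6, 3))
  qm <- quantize_model(m, calibrate_quantization(m, x))
  for (i in 1:5) {
    l <- qm$layers[[i]]
    W <- m$weights[[paste0("W", i)]]
    deq <- sweep(l$qW, 2, l$w_scales, "*")
    err <- abs(deq - W)
    expect_lte(max(sweep(err, 2, l$w_scales, "/")), 0.5 + 1e-9)
    expect_lte(max(abs(l$qW)), 127)
    # the per-channel max weight maps to exactly +-127
    expect_true(all(apply(abs(l$qW), 2, max) == 127))
  }
  expect_equal(qm$clamp_count, 0L)

  # exact multiples of the scale quantize with zero error: with
  # max|w| = 1.27 the per-channel scale is exactly 0.01
  m2 <- tiny_net(3)
  u <- nrow(m2$weights$W5)
  m2$weights$W5 <- matrix(c(rep(0.01, u - 1), 1.27))
  qm2 <- quantize_model(m2, calibrate_quantization(m2, x))
  expect_equal(qm2$layers$output$w_scales, 0.01)
  expect_equal(drop(qm2$layers$output$qW), c(rep(1, u - 1), 127))

  # all-zero layer -> all-zero int8 tensor (degenerate but legal)
  m3 <- tiny_net(4)
  m3$weights$W4 <- m3$weights$W4 * 0
  expect_warning(qm3 <- quantize_model(m3, calibrate_quantization(m3, x)),
                 "saturated")
  expect_true(all(qm3$layers$dense$qW == 0))

  m3$weights$W1[1] <- NaN
  expect_error(quantize_model(m3, calibrate_quantization(m2, x)),
               "non-finite")
})

test_that("integer engine matches the dequantization oracle within 1 LSB", {
  agreement <- oracle_agreement(n_nets = 50, inputs_per_net = 2)
  expect_equal(agreement, 1)
})

test_that("integer inference is bit-deterministic and checks overflow", {
  m <- tiny_net(7)
  x <- array(runif(24 * 5 * 3, -0.6, 0.6), c(24, 5, 3))
  qm <- quantize_model(m, calibrate_quantization(m, x))
  one <- array(x[, 2, ], c(24, 1, 3))
  expect_identical(int8_predict(qm, one), int8_predict(qm, one))
  # all-zero input equals the oracle's bias-only path exactly
  z <- array(0, c(24, 1, 3))
  expect_equal(int8_predict(qm, z), int8_oracle(qm, z),
               tolerance = 1e-12)
  qm$layers$conv2$qb[] <- 3e9                  # beyond int32
  expect_error(int8_predict(qm, one), "overflow.*conv2")
})

test_that("float/int8 comparison reports deltas and relative MSE", {
  m <- tiny_net(8)
  x <- array(runif(24 * 8 * 3, -0.6, 0.6), c(24, 8, 3))
  qm <- quantize_model(m, calibrate_quantization(m, x))
  segs <- lapply(1:6, function(i) {
    xs <- matrix(runif(3 * 24, -0.6, 0.6), 3, 24)
    s <- list(subject_id = "S", trial_id = "T", stride_index = i,
              ic_time_s = i, x = xs, valid_length = 24L, y_cm = 100 + i)
    class(s) <- "stride_segment"
    s
  })
  cmp <- compare_models(m, qm, segs)
  expect_equal(nrow(cmp$pairs), 6)
  expect_true(is.finite(cmp$max_abs_delta))
  expect_true(all(c("mse_float32", "mse_int8", "mse_rel_diff") %in% names(cmp)))
  empty <- compare_models(m, qm, list())
  expect_equal(nrow(empty$pairs), 0)
  m2 <- tiny_net(9)
  if (!identical(unclass(m2$spec), unclass(m$spec)))
    expect_error(compare_models(m2, qm, segs), "differ")
})

test_that("C export reports memory and round-trips the arrays", {
  m <- build_model(model_spec(), train_cfg(seed = 10))
  x <- array(runif(108 * 4 * 6, -0.5, 0.5), c(108, 4, 6))
  qm <- quantize_model(m, calibrate_quantization(m, x))
  ex <- export_c_array(qm)
  mem <- ex$memory
  n_bias <- 32 + 16 + 32 + 128 + 1
  expect_equal(mem$weight_bytes, 64785 - n_bias)   # 1 byte per weight
  expect_equal(mem$bias_bytes, n_bias * 4)
  expect_gte(mem$activation_buffer_bytes, 108 * 6 + 108 * 32)
  # float32 footprint is 4x the int8 weight bytes
  memf <- memory_report(m)
  expect_equal(memf$weight_bytes, 4 * mem$weight_bytes)
  expect_equal(memf$bytes_per_element, 4L)

  parsed <- gaitstride:::parse_c_header(ex$header)
  expect_equal(parsed$conv1_weights, as.integer(qm$layers$conv1$qW))
  expect_equal(parsed$dense_bias, as.integer(qm$layers$dense$qb))
  expect_match(ex$header, "conv3_weight_scales")
  f <- withr::local_tempfile(fileext = ".h")
  export_c_array(qm, f)
  expect_identical(paste(readLines(f), collapse = "\n"), ex$header)
})

test_that("quantization error shrinks as the representative set grows", {
  m <- tiny_net(11)
  set.seed(77)
  pool <- array(runif(24 * 120 * 3, -0.7, 0.7), c(24, 120, 3))
  test_x <- array(runif(24 * 30 * 3, -0.7, 0.7), c(24, 30, 3))
  pf <- predict_cnn(m, test_x)
  dev <- vapply(c(1, 10, 100), function(n) {
    qm <- quantize_model(m, calibrate_quantization(
      m, pool[, seq_len(n), , drop = FALSE]))
    mean((int8_predict(qm, test_x) - pf)^2)
  }, 0)
  expect_lte(dev[3], dev[1] + 1e-12)
})
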