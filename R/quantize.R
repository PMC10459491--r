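# Post-training int8 quantization and a self-contained integer inference
# path.
#
# Scheme (the standard full-integer post-training path): asymmetric
# per-tensor activations (int8, scale s = (max - min)/255 with the range
# widened to include 0 and the zero point chosen so that real 0 maps to
# an integer exactly), symmetric per-output-channel weights (int8 in
# [-127, 127], zero point 0), and int32 biases at the combined scale
# s_input * s_weight. Requantization multiplies the int32 accumulator by
# a double-precision multiplier and rounds half to even, which is
# bit-exact across platforms at desk scale.

INT32_MAX <- 2147483647

act_qparams <- function(lo, hi) {
  lo <- min(lo, 0); hi <- max(hi, 0)
  scale <- (hi - lo) / 255
  if (scale < 1e-8) {
    warn_gs("constant activation tensor; scale floored at 1e-8")
    scale <- 1e-8
  }
  zp <- as.integer(max(-128, min(127, round(-128 - lo / scale))))
  list(scale = scale, zero_point = zp)
}

weight_scales <- function(W) pmax(apply(abs(W), 2, max) / 127, 1e-8)

# round-half-to-even quantization of a real tensor onto (scale, zp)
quantize_values <- function(x, scale, zp = 0L, lo = -128L, hi = 127L) {
  q <- round(x / scale) + zp
  clamped <- sum(q < lo | q > hi)
  list(q = pmin(pmax(q, lo), hi), clamped = clamped)
}

#' Calibrate quantization parameters on a representative dataset
#'
#' Runs the float model over the representative segments and records the
#' observed min/max of every activation tensor (input, each post-ReLU
#' convolution output, the dense hidden layer and the output). Max-pool
#' layers share their input's parameters since pooling cannot leave the
#' observed range.
#'
#' @param model a trained `trained_model`.
#' @param representative a [labeled_stride_dataset()] or list of
#'   segments (>= 1); typically the validation split of the final
#'   retraining.
#' @return object of class `quant_params`.
#' @export
calibrate_quantization <- function(model, representative) {
  stopifnot(inherits(model, "trained_model"))
  arr <- as_input_array(representative, model$spec$input_shape)
  if (dim(arr)[3] < 1) stop_gs("need at least one representative segment")
  ranges <- list(input = c(Inf, -Inf), act1 = c(Inf, -Inf),
                 act2 = c(Inf, -Inf), act3 = c(Inf, -Inf),
                 dense = c(Inf, -Inf), output = c(Inf, -Inf))
  upd <- function(r, x) c(min(r[1], min(x)), max(r[2], max(x)))
  n <- dim(arr)[2]
  for (b0 in seq.int(1L, n, 128L)) {
    xb <- arr[, b0:min(b0 + 127L, n), , drop = FALSE]
    fwd <- cnn_forward(model$weights, xb, keep = TRUE)
    ranges$input <- upd(ranges$input, xb)
    ranges$act1 <- upd(ranges$act1, fwd$c1$Y)
    ranges$act2 <- upd(ranges$act2, fwd$c2$Y)
    ranges$act3 <- upd(ranges$act3, fwd$c3$Y)
    ranges$dense <- upd(ranges$dense, fwd$H)
    ranges$output <- upd(ranges$output, fwd$pred)
  }
  acts <- lapply(ranges, function(r) act_qparams(r[1], r[2]))
  w <- model$weights
  structure(list(
    activations = acts,
    weight_scales = list(W1 = weight_scales(w$W1), W2 = weight_scales(w$W2),
                         W3 = weight_scales(w$W3), W4 = weight_scales(w$W4),
                         W5 = weight_scales(w$W5)),
    n_representative = n), class = "quant_params")
}

#' Quantize a trained float model to int8
#'
#' Weights are rounded to the nearest int8 lattice point (ties to even)
#' and clamped to [-127, 127]; biases are quantized as int32 at the
#' combined input x weight scale. The quantize -> dequantize round trip
#' has max elementwise error <= scale/2 (up to clamping, which is
#' counted).
#'
#' @param model a trained `trained_model`.
#' @param qparams output of [calibrate_quantization()].
#' @return object of class `quantized_model`.
#' @export
quantize_model <- function(model, qparams) {
  stopifnot(inherits(model, "trained_model"), inherits(qparams, "quant_params"))
  w <- model$weights
  if (any(!vapply(w, function(x) all(is.finite(x)), TRUE)))
    stop_gs("model has non-finite weights")
  a <- qparams$activations
  in_act <- list(a$input, a$act1, a$act2, a$act3, a$dense)
  out_act <- list(a$act1, a$act2, a$act3, a$dense, a$output)
  relu <- c(TRUE, TRUE, TRUE, TRUE, FALSE)
  layers <- list()
  clamped <- 0L
  for (i in 1:5) {
    Wn <- paste0("W", i); bn <- paste0("b", i)
    sw <- qparams$weight_scales[[Wn]]
    qw <- quantize_values(sweep(w[[Wn]], 2, sw, "/"), 1, 0L, -127L, 127L)
    clamped <- clamped + qw$clamped
    s_b <- in_act[[i]]$scale * sw
    qb <- round(w[[bn]] / s_b)
    if (any(abs(qb) > INT32_MAX)) {
      warn_gs("int32 bias saturated in layer ", i,
              " (degenerate weight scale)")
      qb <- pmin(pmax(qb, -INT32_MAX), INT32_MAX)
    }
    layers[[i]] <- list(
      qW = qw$q, qb = qb, w_scales = sw,
      in_scale = in_act[[i]]$scale, in_zp = in_act[[i]]$zero_point,
      out_scale = out_act[[i]]$scale, out_zp = out_act[[i]]$zero_point,
      relu = relu[i])
  }
  names(layers) <- c("conv1", "conv2", "conv3", "dense", "output")
  structure(list(spec = model$spec, layers = layers,
                 input = a$input, output = a$output,
                 clamp_count = clamped), class = "quantized_model")
}

#' @export
print.quantized_model <- function(x, ...) {
  nb <- sum(vapply(x$layers, function(l) length(l$qW), 0))
  cat(sprintf("<quantized_model> int8, %d weight bytes, output scale %.4g cm/LSB\n",
              nb, x$layers$output$out_scale))
  invisible(x)
}

# One integer conv/dense layer: x_q [L, N, C] int8 values (as doubles).
int8_layer <- function(xq, layer, name, conv = TRUE) {
  qW <- layer$qW
  if (conv) {
    d <- dim(xq); L <- d[1]; N <- d[2]; C <- d[3]
    k <- nrow(qW) %/% C; p <- (k - 1L) %/% 2L
    # real zero padding == (q - zp) of 0 in the centred representation
    Ap <- array(0, c(L + 2L * p, N, C))
    Ap[p + seq_len(L), , ] <- xq - layer$in_zp
    M <- Ap[im2col_index(L, C, N, k)]
    dim(M) <- c(L * N, k * C)
    acc <- M %*% qW
    acc <- acc + rep(layer$qb, each = L * N)
  } else {
    N <- ncol(xq)                      # xq is D x N here
    acc <- crossprod(xq - layer$in_zp, qW)   # N x U
    acc <- acc + rep(layer$qb, each = N)
  }
  if (max(abs(acc)) > INT32_MAX)
    stop_gs("int32 accumulator overflow in layer ", name)
  # requantize: double multiplier, round half to even, clamp
  mult <- layer$in_scale * layer$w_scales / layer$out_scale
  q <- round(sweep(acc, 2, mult, "*")) + layer$out_zp
  lo <- if (layer$relu) layer$out_zp else -128L
  q <- pmin(pmax(q, lo), 127)
  if (conv) dim(q) <- c(dim(xq)[1], dim(xq)[2], ncol(qW))
  q
}

int8_pool <- function(q) {
  Lo <- dim(q)[1] %/% 2L
  i1 <- seq.int(1L, 2L * Lo, 2L)
  pmax(q[i1, , , drop = FALSE], q[i1 + 1L, , , drop = FALSE])
}

#' Integer inference with the quantized model
#'
#' Bit-exact reference implementation of full-integer inference: int8
#' tensors, 32-bit integer accumulation (checked for overflow),
#' requantization by a double-precision multiplier with round half to
#' even, ReLU as `max(zero_point, q)`, max-pooling directly on the int8
#' lattice. The final output is dequantized to cm.
#'
#' @param qmodel a [quantize_model()] result.
#' @param x segments / dataset / array as in [predict_cnn()].
#' @return numeric vector of stride lengths (cm) on the int8 output grid.
#' @export
int8_predict <- function(qmodel, x) {
  stopifnot(inherits(qmodel, "quantized_model"))
  arr <- as_input_array(x, qmodel$spec$input_shape)
  n <- dim(arr)[2]
  if (n == 0) return(numeric(0))
  qin <- quantize_values(arr, qmodel$input$scale, qmodel$input$zero_point)$q
  q <- int8_layer(qin, qmodel$layers$conv1, "conv1")
  q <- int8_pool(q)
  q <- int8_layer(q, qmodel$layers$conv2, "conv2")
  q <- int8_pool(q)
  q <- int8_layer(q, qmodel$layers$conv3, "conv3")
  q <- int8_pool(q)
  d <- dim(q)                                  # [L, N, C]
  Xf <- aperm(q, c(1, 3, 2))
  dim(Xf) <- c(d[1] * d[3], d[2])              # D x N, flatten as float path
  q <- int8_layer(Xf, qmodel$layers$dense, "dense", conv = FALSE)  # N x U
  q <- int8_layer(t(q), qmodel$layers$output, "output", conv = FALSE) # N x 1
  drop((q - qmodel$layers$output$out_zp) * qmodel$layers$output$out_scale)
}

#' Compare float32 and int8 predictions
#'
#' @param fmodel the float `trained_model`.
#' @param qmodel the corresponding `quantized_model` (same spec).
#' @param segments test segments/dataset (may be labelled).
#' @return list with `pairs` (data.frame float32/int8/reference),
#'   `max_abs_delta`, and when labels are present `mse_float32`,
#'   `mse_int8`, `mse_ratio` and `mse_rel_diff`.
#' @export
compare_models <- function(fmodel, qmodel, segments) {
  stopifnot(inherits(fmodel, "trained_model"),
            inherits(qmodel, "quantized_model"))
  if (!identical(unclass(fmodel$spec), unclass(qmodel$spec)))
    stop_gs("float and quantized model specs differ")
  segs <- if (inherits(segments, "labeled_stride_dataset"))
    segments$segments else segments
  if (!length(segs))
    return(list(pairs = data.frame(float32 = numeric(0), int8 = numeric(0)),
                max_abs_delta = NA_real_))
  pf <- predict_cnn(fmodel, segs)
  pq <- int8_predict(qmodel, segs)
  y <- vapply(segs, `[[`, 0, "y_cm")
  out <- list(pairs = data.frame(float32 = pf, int8 = pq, reference = y),
              max_abs_delta = max(abs(pf - pq)))
  if (!anyNA(y)) {
    out$mse_float32 <- mean((pf - y)^2)
    out$mse_int8 <- mean((pq - y)^2)
    out$mse_ratio <- out$mse_int8 / out$mse_float32
    out$mse_rel_diff <- abs(out$mse_int8 - out$mse_float32) / out$mse_float32
  }
  out
}

# -- deployment artefact -------------------------------------------------

tensor_sizes <- function(spec) {
  s <- model_summary(spec)
  ly <- s$layers
  sizes <- ly$out_length * ly$out_channels
  names(sizes) <- ly$layer
  sizes
}

#' Memory accounting for a float or quantized model
#'
#' Flash is estimated as weights + biases + per-channel scale/zero-point
#' constants; RAM as the peak of a ping-pong two-buffer activation
#' schedule (the largest sum of any layer's input and output tensors).
#' These are transparent arithmetic estimates of the model data itself,
#' not toolchain measurements.
#'
#' @param model a `trained_model` (4-byte elements) or
#'   `quantized_model` (1-byte weights/activations, 4-byte biases).
#' @return object of class `memory_report`.
#' @export
memory_report <- function(model) {
  quant <- inherits(model, "quantized_model")
  spec <- model$spec
  smry <- model_summary(spec)
  n_bias <- sum(spec$conv_filters) + spec$dense_units + 1L
  n_weights <- smry$total_params - n_bias
  elem <- if (quant) 1L else 4L
  weight_bytes <- n_weights * elem
  bias_bytes <- n_bias * 4L
  n_scales <- if (quant)
    sum(spec$conv_filters) + spec$dense_units + 1L + 6L * 2L else 0L
  meta_bytes <- n_scales * 4L + if (quant) 6L * 4L else 0L
  sizes <- tensor_sizes(spec)
  act_seq <- sizes[c("input", "conv1", "pool1", "conv2", "pool2", "conv3",
                     "pool3", "dense", "output")]
  peak <- max(act_seq[-length(act_seq)] + act_seq[-1]) * elem
  structure(list(weight_bytes = weight_bytes, bias_bytes = bias_bytes,
                 metadata_bytes = meta_bytes,
                 activation_buffer_bytes = as.integer(peak),
                 total_flash_estimate = weight_bytes + bias_bytes + meta_bytes,
                 total_ram_estimate = as.integer(peak),
                 bytes_per_element = elem), class = "memory_report")
}

#' Export the quantized model as a C header
#'
#' Emits C99 `const int8_t` weight arrays, `const int32_t` bias arrays,
#' float scale arrays and zero points, preceded by a manifest comment,
#' plus a [memory_report()].
#'
#' @param qmodel a `quantized_model`.
#' @param path optional file to write.
#' @return list with `header` (character scalar) and `memory`
#'   ([memory_report()]). Written to `path` when given.
#' @export
export_c_array <- function(qmodel, path = NULL) {
  stopifnot(inherits(qmodel, "quantized_model"))
  mem <- memory_report(qmodel)
  fmt_arr <- function(name, type, v, fmt = "%d") {
    vals <- paste(sprintf(fmt, v), collapse = ", ")
    sprintf("const %s %s[%d] = { %s };", type, name, length(v), vals)
  }
  lines <- c(
    "/* gaitstride int8 stride-length model",
    sprintf(" * weight bytes: %d, bias bytes: %d, peak activation bytes: %d",
            mem$weight_bytes, mem$bias_bytes, mem$activation_buffer_bytes),
    sprintf(" * input: scale %.9g zero_point %d; output: scale %.9g zero_point %d",
            qmodel$input$scale, qmodel$input$zero_point,
            qmodel$output$scale, qmodel$output$zero_point),
    " */",
    "#include <stdint.h>", "")
  for (nm in names(qmodel$layers)) {
    l <- qmodel$layers[[nm]]
    lines <- c(lines,
      fmt_arr(paste0(nm, "_weights"), "int8_t", as.integer(l$qW)),
      fmt_arr(paste0(nm, "_bias"), "int32_t", as.integer(l$qb)),
      fmt_arr(paste0(nm, "_weight_scales"), "float", l$w_scales, "%.9g"),
      sprintf("const float %s_in_scale = %.9g; const int8_t %s_in_zp = %d;",
              nm, l$in_scale, nm, l$in_zp),
      sprintf("const float %s_out_scale = %.9g; const int8_t %s_out_zp = %d;",
              nm, l$out_scale, nm, l$out_zp),
      "")
  }
  header <- paste(lines, collapse = "\n")
  if (!is.null(path)) writeLines(header, path)
  list(header = header, memory = mem)
}

# Parse int arrays back out of an exported header (round-trip checking).
parse_c_header <- function(header) {
  out <- list()
  for (m in regmatches(header, gregexpr(
    "const int(8|32)_t ([A-Za-z0-9_]+)\\[[0-9]+\\] = \\{ ([^}]*) \\};",
    header))[[1]]) {
    name <- sub(".*_t ([A-Za-z0-9_]+)\\[.*", "\\1", m)
    vals <- sub(".*\\{ (.*) \\};", "\\1", m)
    out[[name]] <- as.integer(strsplit(vals, ", ")[[1]])
  }
  out
}
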