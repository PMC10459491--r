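# Shared fixtures: small simulated trials, tiny random networks, and the
# independent fake-quantization oracle used to cross-check the integer
# inference engine.

# Short trial with a handful of strides; cached per parameter set.
.trial_cache <- new.env(parent = emptyenv())
tiny_trial <- function(duration = 30, noise = 0.01, seed = 101,
                       subject = "SUB01", speed = 3.9) {
  key <- paste(duration, noise, seed, subject, speed)
  if (is.null(.trial_cache[[key]])) {
    p <- gait_sim_params(n_subjects = 1, trial_duration_s = duration,
                         noise_sd = noise, seed = seed)
    .trial_cache[[key]] <- simulate_trial(p, subject, speed)
  }
  .trial_cache[[key]]
}

labels_of <- function(trial) {
  st <- trial$strides
  data.frame(subject_id = st$subject_id, trial_id = st$trial_id,
             stride_index = seq_len(nrow(st)) - 1L,
             stride_length_cm = st$stride_length_cm,
             timestamp_s = st$ic_time_s, stringsAsFactors = FALSE)
}

# Random segment matrices (6 x pad, |x| <= 1, zero-padded after valid).
random_segment <- function(i, pad = 108, valid = sample(60:pad, 1),
                           y = runif(1, 90, 170), trial = "T1",
                           subject = "S1") {
  x <- matrix(0, 6, pad)
  x[, seq_len(valid)] <- matrix(runif(6 * valid, -0.9, 0.9), 6)
  stride_segment(subject, trial, i, i * 1.1, x, valid, y)
}

random_dataset <- function(n, pad = 108, subject = "S1") {
  labeled_stride_dataset(lapply(seq_len(n), random_segment, pad = pad,
                                subject = subject), 60, pad)
}

# Small random network with weights scaled so activations span a range.
tiny_net <- function(seed, L = 24, C = 3) {
  set.seed(seed)
  spec <- model_spec(sample(2:5, 3, replace = TRUE),
                     sample(c(3, 5), 3, replace = TRUE),
                     dense_units = sample(4:10, 1),
                     input_shape = c(L, C))
  m <- build_model(spec, train_cfg(seed = seed))
  m$weights <- lapply(m$weights, function(w) w * runif(1, 2, 5))
  m
}

# Independent oracle for the int8 engine: keep every tensor in float,
# but quantize it onto the layer's (scale, zero-point) grid after each
# stage; convolutions are evaluated as explicit nested-loop sums.
fake_quant <- function(x, s, zp) {
  q <- pmin(pmax(round(x / s) + zp, -128), 127)
  (q - zp) * s
}

int8_oracle <- function(qm, x) {
  stopifnot(length(dim(x)) == 3, dim(x)[2] == 1)
  cur <- array(fake_quant(x, qm$input$scale, qm$input$zero_point), dim(x))
  for (nm in c("conv1", "conv2", "conv3")) {
    l <- qm$layers[[nm]]
    L <- dim(cur)[1]; C <- dim(cur)[3]
    k <- nrow(l$qW) %/% C
    W <- sweep(l$qW, 2, l$w_scales, "*")
    b <- l$qb * l$in_scale * l$w_scales
    p <- (k - 1) %/% 2
    xp <- array(0, c(L + 2 * p, 1, C))
    xp[p + seq_len(L), 1, ] <- cur
    out <- array(0, c(L, 1, ncol(W)))
    for (f in seq_len(ncol(W))) for (li in seq_len(L)) {
      acc <- 0
      for (j in 0:(k - 1)) for (cc in seq_len(C))
        acc <- acc + xp[li + j, 1, cc] * W[j * C + cc, f]
      out[li, 1, f] <- acc + b[f]
    }
    out <- array(fake_quant(pmax(out, 0), l$out_scale, l$out_zp), dim(out))
    Lo <- L %/% 2
    cur <- pmax(out[seq(1, 2 * Lo, 2), , , drop = FALSE],
                out[seq(2, 2 * Lo, 2), , , drop = FALSE])
  }
  v <- as.vector(aperm(cur, c(1, 3, 2)))
  l <- qm$layers$dense
  h <- pmax(drop(v %*% sweep(l$qW, 2, l$w_scales, "*")) +
              l$qb * l$in_scale * l$w_scales, 0)
  h <- fake_quant(h, l$out_scale, l$out_zp)
  l <- qm$layers$output
  o <- drop(h %*% sweep(l$qW, 2, l$w_scales, "*")) +
    l$qb * l$in_scale * l$w_scales
  fake_quant(o, l$out_scale, l$out_zp)
}

# Engine-vs-oracle agreement over n random tiny networks; returns the
# fraction of cases within one output LSB.
oracle_agreement <- function(n_nets = 50, inputs_per_net = 2) {
  ok <- 0L; total <- 0L
  for (s in seq_len(n_nets)) {
    m <- tiny_net(1000 + s)
    L <- m$spec$input_shape[1]; C <- m$spec$input_shape[2]
    set.seed(2000 + s)
    rep_x <- array(runif(L * 4 * C, -0.6, 0.6), c(L, 4, C))
    qm <- quantize_model(m, calibrate_quantization(m, rep_x))
    for (i in seq_len(inputs_per_net)) {
      x <- array(runif(L * C, -0.6, 0.6), c(L, 1, C))
      engine <- int8_predict(qm, x)
      oracle <- int8_oracle(qm, x)
      total <- total + 1L
      if (abs(engine - oracle) <= qm$output$scale + 1e-12) ok <- ok + 1L
    }
  }
  ok / total
}
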