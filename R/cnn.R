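# 1D convolutional regression network, implemented from scratch.
#
# Architecture: [Conv1D(f1,k1)+ReLU -> MaxPool(2) -> Conv1D(f2,k2)+ReLU
# -> MaxPool(2) -> Conv1D(f3,k3)+ReLU -> MaxPool(2) -> flatten ->
# Dense(units)+ReLU -> Dense(1, linear)], trained with Adam on mean
# squared error (cm^2). Convolutions use 'same' padding and stride 1;
# pooling is size 2, stride 2, flooring odd lengths.
#
# Convolutions are evaluated as im2col gathers followed by BLAS matrix
# products; backpropagation mirrors this (col2im as per-offset block
# adds), which keeps the whole training loop in vectorised R.
#
# Tensor conventions:
#   activations  : array [L, N, C]   (time, batch, channels) -- batch in
#                  the middle so im2col/col2im are pure reshapes
#   conv weights : matrix [k*C_in, F], column block order = offset-major,
#                  channel-minor (row = offset*C_in + channel)
#   dense weights: matrix [D, U]; flatten order = time-major within
#                  each filter (column-major unravel of [L, C])

#' Network architecture specification
#'
#' @param conv_filters integer triple (f1, f2, f3) of Conv1D filters.
#' @param conv_kernels integer triple (k1, k2, k3) of odd kernel sizes.
#' @param dense_units hidden dense-layer width.
#' @param input_shape `(length, channels)` of one input segment.
#' @return object of class `model_spec`.
#' @export
model_spec <- function(conv_filters = c(32, 16, 32),
                       conv_kernels = c(5, 5, 15),
                       dense_units = 128, input_shape = c(108, 6)) {
  if (length(conv_filters) != 3 || any(conv_filters < 1))
    stop_gs("conv_filters must be three positive integers")
  if (length(conv_kernels) != 3 || any(conv_kernels < 1) ||
      any(conv_kernels %% 2 == 0))
    stop_gs("conv_kernels must be three positive odd integers")
  if (dense_units < 1) stop_gs("dense_units must be >= 1")
  structure(list(conv_filters = as.integer(conv_filters),
                 conv_kernels = as.integer(conv_kernels),
                 dense_units = as.integer(dense_units),
                 input_shape = as.integer(input_shape)),
            class = "model_spec")
}

#' Training configuration
#'
#' Optimiser defaults follow the reference setup: Adam with beta1 = 0.9,
#' beta2 = 0.999, epsilon = 1e-8; kernel initialisation truncated
#' normal(0, 0.1) (truncated at two standard deviations), bias constant
#' 0.1; mean-squared-error loss on stride length in cm.
#'
#' @param learning_rate Adam step size (0 is allowed and leaves weights
#'   unchanged, useful as an identity check).
#' @param batch_size minibatch size.
#' @param epochs training epochs.
#' @param beta1,beta2,epsilon Adam moment/stability constants.
#' @param init_sd kernel-init standard deviation.
#' @param bias_init constant bias initialisation.
#' @param seed seed controlling initialisation and batch shuffling.
#' @return object of class `train_cfg`.
#' @export
train_cfg <- function(learning_rate = 1e-4, batch_size = 64, epochs = 1500,
                      beta1 = 0.9, beta2 = 0.999, epsilon = 1e-8,
                      init_sd = 0.1, bias_init = 0.1, seed = 1L) {
  if (learning_rate < 0 || learning_rate >= 1)
    stop_gs("learning_rate must be in [0, 1)")
  if (batch_size < 1) stop_gs("batch_size must be >= 1")
  if (epochs < 0) stop_gs("epochs must be >= 0")
  structure(list(learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), beta1 = beta1, beta2 = beta2,
                 epsilon = epsilon, init_sd = init_sd, bias_init = bias_init,
                 seed = as.integer(seed)),
            class = "train_cfg")
}

#' Layer shapes and parameter count
#'
#' Walks the layer stack under the package's conventions ('same' conv
#' padding, pool size 2 stride 2 with floor) and reports per-layer output
#' shapes and trainable parameter counts. Errors when a kernel exceeds
#' the current sequence length or the sequence collapses to zero.
#'
#' @param spec a [model_spec()].
#' @return list with `layers` (data.frame: layer, out_length,
#'   out_channels, params) and `total_params`.
#' @export
model_summary <- function(spec) {
  stopifnot(inherits(spec, "model_spec"))
  L <- spec$input_shape[1]; C <- spec$input_shape[2]
  rows <- list()
  add <- function(name, L, C, p) rows[[length(rows) + 1L]] <<-
    data.frame(layer = name, out_length = L, out_channels = C, params = p)
  add("input", L, C, 0L)
  for (i in 1:3) {
    k <- spec$conv_kernels[i]; f <- spec$conv_filters[i]
    if (k > L) stop_gs("conv", i, ": kernel size ", k,
                       " exceeds sequence length ", L)
    add(paste0("conv", i), L, f, k * C * f + f)
    C <- f
    L <- L %/% 2L
    if (L < 1) stop_gs("pool", i, ": sequence length collapsed to 0")
    add(paste0("pool", i), L, C, 0L)
  }
  D <- L * C
  add("flatten", D, 1L, 0L)
  add("dense", spec$dense_units, 1L, D * spec$dense_units + spec$dense_units)
  add("output", 1L, 1L, spec$dense_units + 1L)
  layers <- do.call(rbind, rows)
  list(layers = layers, total_params = sum(layers$params),
       flatten_dim = D)
}

#' Build an initialised (untrained) model
#'
#' @param spec a [model_spec()].
#' @param cfg a [train_cfg()] (initialisers and seed).
#' @return object of class `trained_model` with freshly initialised
#'   float32-style weights and an empty training history.
#' @export
build_model <- function(spec, cfg = train_cfg()) {
  stopifnot(inherits(spec, "model_spec"), inherits(cfg, "train_cfg"))
  smry <- model_summary(spec)   # validates shapes
  with_local_seed(hash_seed(cfg$seed, "init"), {
    w <- list()
    C <- spec$input_shape[2]
    for (i in 1:3) {
      k <- spec$conv_kernels[i]; f <- spec$conv_filters[i]
      w[[paste0("W", i)]] <- matrix(rtruncnorm0(k * C * f, cfg$init_sd), k * C, f)
      w[[paste0("b", i)]] <- rep(cfg$bias_init, f)
      C <- f
    }
    D <- smry$flatten_dim; U <- spec$dense_units
    w$W4 <- matrix(rtruncnorm0(D * U, cfg$init_sd), D, U)
    w$b4 <- rep(cfg$bias_init, U)
    w$W5 <- matrix(rtruncnorm0(U, cfg$init_sd), U, 1)
    w$b5 <- cfg$bias_init
    structure(list(spec = spec, cfg = cfg, weights = w, history = NULL,
                   summary = smry),
              class = "trained_model")
  })
}

#' @export
print.trained_model <- function(x, ...) {
  cat(sprintf("<trained_model> %s filters, kernels %s, dense %d; %d parameters%s\n",
              paste(x$spec$conv_filters, collapse = "/"),
              paste(x$spec$conv_kernels, collapse = "/"),
              x$spec$dense_units, x$summary$total_params,
              if (is.null(x$history)) " (untrained)" else
                sprintf("; %d epochs trained", nrow(x$history))))
  invisible(x)
}

# ---- forward / backward primitives -------------------------------------

# im2col gather index for 'same' conv on an [Lp, N, C] padded array:
# rows (l fastest, then n), cols (offset j major, channel c minor)
im2col_index <- function(L, C, N, k) {
  p <- (k - 1L) %/% 2L
  Lp <- L + 2L * p
  l <- rep(seq_len(L), times = N)
  n <- rep(seq_len(N), each = L)
  base <- (n - 1L) * Lp + l              # length L*N
  idx <- matrix(0L, L * N, k * C)
  for (col in seq_len(k * C)) {
    jj <- (col - 1L) %/% C
    cc <- (col - 1L) %% C
    idx[, col] <- base + cc * (Lp * N) + jj
  }
  idx
}

conv_forward <- function(A, W, b, idx = NULL, relu = TRUE) {
  d <- dim(A); L <- d[1]; N <- d[2]; C <- d[3]
  F_ <- ncol(W); k <- nrow(W) %/% C
  p <- (k - 1L) %/% 2L
  Ap <- array(0, c(L + 2L * p, N, C))
  Ap[p + seq_len(L), , ] <- A
  if (is.null(idx)) idx <- im2col_index(L, C, N, k)
  M <- Ap[idx]
  dim(M) <- c(L * N, k * C)
  Z <- M %*% W
  Z <- Z + rep(b, each = L * N)
  mask <- NULL
  if (relu) { mask <- Z > 0; Z <- Z * mask }
  dim(Z) <- c(L, N, F_)
  list(Y = Z, M = M, mask = mask, dims = c(L = L, C = C, N = N, k = k, p = p))
}

conv_backward <- function(dY, fwd, W, idx_b = NULL, need_input_grad = TRUE) {
  L <- fwd$dims[["L"]]; C <- fwd$dims[["C"]]; N <- fwd$dims[["N"]]
  k <- fwd$dims[["k"]]; p <- fwd$dims[["p"]]
  F_ <- ncol(W)
  dZ <- dY
  dim(dZ) <- c(L * N, F_)
  if (!is.null(fwd$mask)) dZ <- dZ * fwd$mask
  dW <- crossprod(fwd$M, dZ)
  db <- colSums(dZ)
  if (!need_input_grad) return(list(dA = NULL, dW = dW, db = db))
  # input gradient = 'same' convolution of dZ with the kernel flipped in
  # the offset dimension and transposed in the channel dimensions:
  # Wt[(i*F + f), c] = W[(k-1-i)*C + c, f]
  ii <- rep(rep(0:(k - 1L), each = F_), times = C)
  ff <- rep(seq_len(F_), times = k * C)
  cc <- rep(seq_len(C), each = k * F_)
  Wt <- W[(ff - 1L) * (k * C) + (k - 1L - ii) * C + cc]
  dim(Wt) <- c(k * F_, C)
  dZp <- array(0, c(L + 2L * p, N, F_))
  dZp[p + seq_len(L), , ] <- dZ
  if (is.null(idx_b)) idx_b <- im2col_index(L, F_, N, k)
  Mz <- dZp[idx_b]
  dim(Mz) <- c(L * N, k * F_)
  dA <- Mz %*% Wt
  dim(dA) <- c(L, N, C)
  list(dA = dA, dW = dW, db = db)
}

pool_forward <- function(A) {
  d <- dim(A); L <- d[1]
  Lo <- L %/% 2L
  i1 <- seq.int(1L, 2L * Lo, 2L); i2 <- i1 + 1L
  a <- A[i1, , , drop = FALSE]; b <- A[i2, , , drop = FALSE]
  mask <- a >= b                 # ties -> earlier sample
  list(Y = a * mask + b * !mask, mask = mask, L_in = L)
}

pool_backward <- function(dY, fwd) {
  d <- dim(dY); Lo <- d[1]
  m1 <- dY * fwd$mask
  inter <- rbind(as.vector(m1), as.vector(dY - m1))  # row-interleave
  if (fwd$L_in == 2L * Lo) {
    dim(inter) <- c(fwd$L_in, d[2], d[3])
    return(inter)
  }
  dA <- array(0, c(fwd$L_in, d[2], d[3]))
  dim(inter) <- c(2L * Lo, d[2], d[3])
  dA[seq_len(2L * Lo), , ] <- inter
  dA
}

# Full forward pass. x: array [L, N, C]. Returns predictions and caches.
cnn_forward <- function(w, x, idx_cache = NULL, keep = FALSE) {
  N <- dim(x)[2]
  c1 <- conv_forward(x, w$W1, w$b1, idx_cache[[1]])
  p1 <- pool_forward(c1$Y)
  c2 <- conv_forward(p1$Y, w$W2, w$b2, idx_cache[[2]])
  p2 <- pool_forward(c2$Y)
  c3 <- conv_forward(p2$Y, w$W3, w$b3, idx_cache[[3]])
  p3 <- pool_forward(c3$Y)
  d <- dim(p3$Y)                               # [L, N, C]
  Xf <- aperm(p3$Y, c(1, 3, 2))
  dim(Xf) <- c(d[1] * d[3], N)
  Xf <- t(Xf)                                  # N x D, feature = (l, c)
  Z4 <- Xf %*% w$W4 + rep(w$b4, each = N)
  m4 <- Z4 > 0
  H <- Z4 * m4
  pred <- drop(H %*% w$W5) + w$b5
  if (!keep) return(list(pred = pred))
  list(pred = pred, c1 = c1, p1 = p1, c2 = c2, p2 = p2, c3 = c3, p3 = p3,
       Xf = Xf, m4 = m4, H = H)
}

cnn_backward <- function(w, fwd, dpred, idx_cache = NULL) {
  N <- length(dpred)
  dout <- matrix(dpred, N, 1)
  g <- list()
  g$W5 <- crossprod(fwd$H, dout)
  g$b5 <- sum(dout)
  dH <- (dout %*% t(w$W5)) * fwd$m4            # N x U
  g$W4 <- crossprod(fwd$Xf, dH)
  g$b4 <- colSums(dH)
  dXf <- t(dH %*% t(w$W4))                      # D x N
  d3 <- dim(fwd$p3$Y)                           # [L, N, C]
  dim(dXf) <- c(d3[1], d3[3], d3[2])
  dP3 <- aperm(dXf, c(1, 3, 2))
  dC3 <- pool_backward(dP3, fwd$p3)
  b3 <- conv_backward(dC3, fwd$c3, w$W3, idx_cache[[6]])
  g$W3 <- b3$dW; g$b3 <- b3$db
  dC2 <- pool_backward(b3$dA, fwd$p2)
  b2 <- conv_backward(dC2, fwd$c2, w$W2, idx_cache[[5]])
  g$W2 <- b2$dW; g$b2 <- b2$db
  dC1 <- pool_backward(b2$dA, fwd$p1)
  b1 <- conv_backward(dC1, fwd$c1, w$W1, need_input_grad = FALSE)
  g$W1 <- b1$dW; g$b1 <- b1$db
  g
}

# Convert dataset / segment list / matrix to an input array [L, C, N].
as_input_array <- function(x, input_shape = c(108L, 6L)) {
  if (is.array(x) && length(dim(x)) == 3) return(x)
  segs <- if (inherits(x, "labeled_stride_dataset")) x$segments
          else if (inherits(x, "stride_segment")) list(x)
          else x
  L <- input_shape[1]
  arr <- array(0, c(L, length(segs), input_shape[2]))
  for (i in seq_along(segs)) {
    xi <- segs[[i]]$x
    if (ncol(xi) != L)
      stop_gs("segment length ", ncol(xi), " does not match input_shape ", L)
    arr[, i, ] <- t(xi)
  }
  arr
}

#' Predict stride lengths (cm) with the float model
#'
#' A pure function of (weights, input): identical inputs give identical
#' outputs regardless of batch composition (up to BLAS reduction order,
#' < 1e-5 cm).
#'
#' @param model a `trained_model`.
#' @param x a [labeled_stride_dataset()], list of [stride_segment()]s,
#'   one segment, or an `[L, 6, N]` array.
#' @return numeric vector of predicted stride lengths in cm.
#' @export
predict_cnn <- function(model, x) {
  stopifnot(inherits(model, "trained_model"))
  arr <- as_input_array(x, model$spec$input_shape)
  cnn_forward(model$weights, arr)$pred
}

adam_init <- function(w) lapply(w, function(x) list(m = x * 0, v = x * 0))

adam_step <- function(w, g, st, cfg, t) {
  lr_t <- cfg$learning_rate * sqrt(1 - cfg$beta2^t) / (1 - cfg$beta1^t)
  for (nm in names(w)) {
    st[[nm]]$m <- cfg$beta1 * st[[nm]]$m + (1 - cfg$beta1) * g[[nm]]
    st[[nm]]$v <- cfg$beta2 * st[[nm]]$v + (1 - cfg$beta2) * g[[nm]]^2
    w[[nm]] <- w[[nm]] - lr_t * st[[nm]]$m / (sqrt(st[[nm]]$v) + cfg$epsilon)
  }
  list(w = w, st = st)
}

#' Train the network with Adam on mean squared error
#'
#' Minimises MSE (cm^2) on the training split for `cfg$epochs` epochs,
#' logging per-epoch training MSE (mean over minibatch losses) and, when
#' a validation set is given, full-pass validation MSE. Deterministic
#' given the seed up to floating-point reduction order.
#'
#' @param model a `trained_model` (typically from [build_model()]).
#' @param train a [labeled_stride_dataset()] with labels in cm.
#' @param cfg a [train_cfg()]; defaults to the model's own.
#' @param validation optional validation dataset.
#' @param verbose print progress every 50 epochs.
#' @return the trained model, `history` filled in
#'   (data.frame epoch/train_mse/val_mse).
#' @export
train_cnn <- function(model, train, cfg = model$cfg, validation = NULL,
                      verbose = FALSE) {
  stopifnot(inherits(model, "trained_model"))
  if (inherits(train, "dataset_split")) {
    validation <- validation %||% train$validation
    train <- train$train
  }
  if (!length(train$segments)) stop_gs("empty training split")
  y <- dataset_labels(train)
  if (anyNA(y)) stop_gs("training targets contain missing labels")
  X <- as_input_array(train, model$spec$input_shape)
  Xval <- if (!is.null(validation)) as_input_array(validation, model$spec$input_shape)
  yval <- if (!is.null(validation)) dataset_labels(validation)
  N <- dim(X)[2]
  w <- model$weights
  st <- adam_init(w)
  bs <- min(cfg$batch_size, N)
  # cache im2col gather indices per distinct batch size
  idx_for <- local({
    cache <- list()
    function(n, spec) {
      key <- as.character(n)
      if (is.null(cache[[key]])) {
        L <- spec$input_shape[1]; C <- spec$input_shape[2]
        f <- spec$conv_filters; k <- spec$conv_kernels
        cache[[key]] <<- list(
          im2col_index(L, C, n, k[1]),
          im2col_index(L %/% 2L, f[1], n, k[2]),
          im2col_index(L %/% 4L, f[2], n, k[3]),
          NULL,   # conv1 input gradient is never needed
          im2col_index(L %/% 2L, f[2], n, k[2]),
          im2col_index(L %/% 4L, f[3], n, k[3]))
      }
      cache[[key]]
    }
  })
  hist_tr <- numeric(cfg$epochs); hist_val <- rep(NA_real_, cfg$epochs)
  step <- 0L
  with_local_seed(hash_seed(cfg$seed, "shuffle"), {
    for (ep in seq_len(cfg$epochs)) {
      ord <- sample.int(N)
      losses <- numeric(0)
      for (b0 in seq.int(1L, N, bs)) {
        ids <- ord[b0:min(b0 + bs - 1L, N)]
        nb <- length(ids)
        xb <- X[, ids, , drop = FALSE]
        yb <- y[ids]
        idxc <- idx_for(nb, model$spec)
        fwd <- cnn_forward(w, xb, idxc, keep = TRUE)
        resid <- fwd$pred - yb
        loss <- mean(resid^2)
        if (!is.finite(loss))
          stop_gs("non-finite training loss at epoch ", ep,
                  " (step ", step + 1L, "); learning rate ",
                  cfg$learning_rate, ", batch ", nb)
        losses <- c(losses, loss)
        g <- cnn_backward(w, fwd, 2 * resid / nb, idxc)
        step <- step + 1L
        upd <- adam_step(w, g, st, cfg, step)
        w <- upd$w; st <- upd$st
      }
      hist_tr[ep] <- mean(losses)
      if (!is.null(validation)) {
        pv <- cnn_forward(w, Xval)$pred
        hist_val[ep] <- mean((pv - yval)^2)
      }
      if (verbose && ep %% 50 == 0)
        message(sprintf("epoch %d/%d  train MSE %.3f%s", ep, cfg$epochs,
                        hist_tr[ep],
                        if (is.null(validation)) "" else
                          sprintf("  val MSE %.3f", hist_val[ep])))
    }
  })
  model$weights <- w
  model$cfg <- cfg
  prev <- model$history
  hist <- data.frame(epoch = nrow(prev) %||% 0 + seq_len(cfg$epochs),
                     train_mse = hist_tr, val_mse = hist_val)
  # continued training (e.g. a fine-tuning phase) appends to the log
  model$history <- if (is.null(prev)) hist else rbind(prev, hist)
  model
}

#' Hyperparameter search grid
#'
#' @param batch_sizes,learning_rates,filters,kernels,dense_units candidate
#'   values.
#' @param per_layer_independent search filter/kernel values independently
#'   per convolution layer (TRUE) or tied across the three layers.
#' @return object of class `search_grid`.
#' @export
default_search_grid <- function(batch_sizes = c(32, 64, 128, 256),
                                learning_rates = c(1e-3, 1e-4, 1e-5),
                                filters = c(16, 32), kernels = c(5, 15),
                                dense_units = c(128, 256, 512, 1024),
                                per_layer_independent = TRUE) {
  if (!length(batch_sizes) || !length(learning_rates) || !length(filters) ||
      !length(kernels) || !length(dense_units))
    stop_gs("all grid value lists must be non-empty")
  structure(list(batch_sizes = batch_sizes, learning_rates = learning_rates,
                 filters = filters, kernels = kernels,
                 dense_units = dense_units,
                 per_layer_independent = isTRUE(per_layer_independent)),
            class = "search_grid")
}

enumerate_grid <- function(grid) {
  if (grid$per_layer_independent) {
    g <- expand.grid(f1 = grid$filters, k1 = grid$kernels,
                     f2 = grid$filters, k2 = grid$kernels,
                     f3 = grid$filters, k3 = grid$kernels,
                     dense = grid$dense_units, lr = grid$learning_rates,
                     batch = grid$batch_sizes)
  } else {
    g <- expand.grid(f = grid$filters, k = grid$kernels,
                     dense = grid$dense_units, lr = grid$learning_rates,
                     batch = grid$batch_sizes)
    g <- data.frame(f1 = g$f, k1 = g$k, f2 = g$f, k2 = g$k, f3 = g$f,
                    k3 = g$k, dense = g$dense, lr = g$lr, batch = g$batch)
  }
  g
}

#' Grid search over architecture and optimiser hyperparameters
#'
#' Evaluates every grid point on a subject-wise hold-out split and
#' selects the configuration with the lowest validation MSE. Ties are
#' broken by the smaller parameter count, then by enumeration order.
#'
#' @param grid a [default_search_grid()].
#' @param split a `dataset_split` with `train` and `validation`.
#' @param cfg_base a [train_cfg()] providing epochs/seed; learning rate
#'   and batch size are taken from the grid point.
#' @param trainer evaluation function
#'   `function(spec, cfg, train, validation) -> list(val_mse, train_mse)`;
#'   the default builds and trains the network. Injectable for cheap
#'   mock-based testing of the selection logic.
#' @param dry_run enumerate the grid without training.
#' @return list with `best_spec`, `best_cfg`, and `results` data.frame.
#' @export
grid_search <- function(grid, split = NULL, cfg_base = train_cfg(),
                        trainer = NULL, dry_run = FALSE) {
  stopifnot(inherits(grid, "search_grid"))
  g <- enumerate_grid(grid)
  if (!nrow(g)) stop_gs("empty grid")
  g$params <- vapply(seq_len(nrow(g)), function(i)
    model_summary(model_spec(c(g$f1[i], g$f2[i], g$f3[i]),
                             c(g$k1[i], g$k2[i], g$k3[i]),
                             g$dense[i]))$total_params, 0)
  if (dry_run) return(list(best_spec = NULL, best_cfg = NULL, results = g))
  if (is.null(split) || is.null(split$validation))
    stop_gs("grid_search needs a dataset_split with a validation set")
  if (is.null(trainer)) {
    trainer <- function(spec, cfg, train, validation) {
      m <- train_cnn(build_model(spec, cfg), train, cfg, validation)
      list(val_mse = utils::tail(m$history$val_mse, 1),
           train_mse = utils::tail(m$history$train_mse, 1))
    }
  }
  g$train_mse <- NA_real_; g$val_mse <- NA_real_
  for (i in seq_len(nrow(g))) {
    spec <- model_spec(c(g$f1[i], g$f2[i], g$f3[i]),
                       c(g$k1[i], g$k2[i], g$k3[i]), g$dense[i])
    cfg <- train_cfg(learning_rate = g$lr[i], batch_size = g$batch[i],
                     epochs = cfg_base$epochs, beta1 = cfg_base$beta1,
                     beta2 = cfg_base$beta2, epsilon = cfg_base$epsilon,
                     init_sd = cfg_base$init_sd, bias_init = cfg_base$bias_init,
                     seed = cfg_base$seed)
    r <- trainer(spec, cfg, split$train, split$validation)
    g$val_mse[i] <- r$val_mse
    g$train_mse[i] <- r$train_mse %||% NA_real_
  }
  o <- order(g$val_mse, g$params, seq_len(nrow(g)))
  best <- g[o[1], ]
  list(best_spec = model_spec(c(best$f1, best$f2, best$f3),
                              c(best$k1, best$k2, best$k3), best$dense),
       best_cfg = train_cfg(learning_rate = best$lr, batch_size = best$batch,
                            epochs = cfg_base$epochs, seed = cfg_base$seed),
       results = g)
}

#' Final retraining with a random stride-level 80/20 split
#'
#' Mirrors the final training phase: the chosen architecture is retrained
#' on a random (not subject-wise) 80/20 train/validation division of the
#' full training set, with no further hyperparameter changes. The
#' validation portion is kept on the returned model (field
#' `representative`) because it doubles as the representative dataset for
#' post-training quantization.
#'
#' @param spec the fixed [model_spec()].
#' @param train_set full training [labeled_stride_dataset()].
#' @param cfg a [train_cfg()], or a list of them: with a list, the phases
#'   are run back to back on the same split and the same weights (e.g. a
#'   coarse phase at a higher learning rate followed by a short
#'   fine-tuning phase at the reference rate), each with a fresh
#'   optimiser state; the history accumulates across phases.
#' @param val_fraction validation fraction (default 0.2).
#' @param seed split/initialisation seed (defaults to the first cfg's).
#' @return trained model with `representative` validation dataset.
#' @export
retrain_final <- function(spec, train_set, cfg = train_cfg(),
                          val_fraction = 0.2, seed = NULL) {
  stopifnot(inherits(train_set, "labeled_stride_dataset"))
  cfgs <- if (inherits(cfg, "train_cfg")) list(cfg) else cfg
  stopifnot(length(cfgs) >= 1, all(vapply(cfgs, inherits, TRUE, "train_cfg")))
  seed <- seed %||% cfgs[[1]]$seed
  N <- length(train_set$segments)
  if (N < 2) stop_gs("need at least 2 segments to retrain")
  n_val <- round(N * val_fraction)
  val_idx <- with_local_seed(hash_seed(seed, "retrain-split"),
                             sort(sample.int(N, n_val)))
  mk <- function(ii) labeled_stride_dataset(train_set$segments[ii],
                                            train_set$sample_rate_hz,
                                            train_set$pad_length)
  ds_val <- if (n_val > 0) mk(val_idx) else NULL
  ds_tr <- mk(setdiff(seq_len(N), val_idx))
  cfgs[[1]]$seed <- seed
  model <- build_model(spec, cfgs[[1]])
  for (i in seq_along(cfgs)) {
    ci <- cfgs[[i]]
    ci$seed <- hash_seed(seed, "phase", i)
    model <- train_cnn(model, ds_tr, ci, validation = ds_val)
  }
  model$representative <- ds_val
  model
}
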