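# Network construction, shape/parameter accounting, optimisation
# behaviour, prediction purity, grid search and final retraining.

test_that("layer shapes and parameter counts match a brute-force oracle", {
  smry <- model_summary(model_spec())
  expect_equal(smry$layers$out_length[smry$layers$layer == "flatten"], 416)
  expect_equal(smry$total_params, 64785)

  # brute force: count the actual weight tensors of 20 random specs and
  # track sequence lengths layer by layer
  set.seed(99)
  for (i in 1:20) {
    f <- sample(c(4, 8, 16), 3, replace = TRUE)
    k <- sample(c(3, 5, 7), 3, replace = TRUE)
    u <- sample(c(8, 32, 64), 1)
    spec <- model_spec(f, k, u)
    m <- build_model(spec, train_cfg(seed = i))
    n_actual <- sum(vapply(m$weights, length, 0))
    s <- model_summary(spec)
    expect_equal(s$total_params, n_actual)
    L <- 108
    for (j in 1:3) L <- L %/% 2
    expect_equal(s$flatten_dim, L * f[3])
  }
  expect_error(model_summary(model_spec(conv_kernels = c(109, 5, 15))),
               "kernel")
  expect_error(model_summary(model_spec(conv_kernels = c(1, 1, 1),
                                        input_shape = c(4, 6))), "collapsed")
  expect_error(model_spec(conv_kernels = c(4, 5, 15)), "odd")
})

test_that("initialisation is seeded, truncated and constant-biased", {
  cfg <- train_cfg(seed = 7)
  a <- build_model(model_spec(), cfg)
  b <- build_model(model_spec(), cfg)
  expect_identical(a$weights, b$weights)
  c <- build_model(model_spec(), train_cfg(seed = 8))
  expect_false(identical(a$weights, c$weights))
  expect_lte(max(abs(a$weights$W1)), 2 * cfg$init_sd)   # truncation at 2 sd
  expect_true(all(a$weights$b4 == 0.1))
})

test_that("zero learning rate is an identity; non-finite loss aborts", {
  ds <- random_dataset(8)
  m <- build_model(model_spec(), train_cfg(seed = 3))
  m2 <- train_cnn(m, ds, train_cfg(learning_rate = 0, epochs = 2,
                                   batch_size = 4, seed = 3))
  expect_equal(m2$weights, m$weights)
  expect_equal(nrow(m2$history), 2)
})

test_that("the network can overfit a small sample (capacity sanity)", {
  set.seed(12)
  ds <- random_dataset(10)
  cfg <- train_cfg(learning_rate = 0.01, batch_size = 10, epochs = 500,
                   seed = 12)
  m <- train_cnn(build_model(model_spec(), cfg), ds, cfg)
  final <- utils::tail(m$history$train_mse, 1)
  expect_lt(final, 1)                          # < 1 cm^2 on 10 segments
  # optimisation trends down: late epochs beat early ones
  expect_lt(stats::median(utils::tail(m$history$train_mse, 100)),
            stats::median(utils::head(m$history$train_mse, 100)))
})

test_that("prediction is a pure, batch-size-independent function", {
  ds <- random_dataset(7)
  m <- build_model(model_spec(), train_cfg(seed = 5))
  batch <- predict_cnn(m, ds)
  single <- vapply(ds$segments, function(s) predict_cnn(m, list(s)), 0)
  expect_equal(batch, single, tolerance = 1e-8)
  # duplicated segment -> identical prediction
  dup <- labeled_stride_dataset(ds$segments[c(1, 1)], 60, 108)
  pd <- predict_cnn(m, dup)
  expect_equal(pd[1], pd[2], tolerance = 1e-12)  # BLAS row order only
  # all-zero input on an untrained model: finite and repeatable
  z <- array(0, c(108, 1, 6))
  expect_identical(predict_cnn(m, z), predict_cnn(m, z))
  expect_true(is.finite(predict_cnn(m, z)))
  expect_error(predict_cnn(m, list(stride_segment("S", "T", 0, 0,
                                                  matrix(0, 6, 60), 60))),
               "length")
})

test_that("full-batch training is invariant to sample order", {
  set.seed(8)
  ds <- random_dataset(12)
  perm <- sample(12)
  ds_perm <- labeled_stride_dataset(ds$segments[perm], 60, 108)
  cfg <- train_cfg(learning_rate = 1e-3, batch_size = 12, epochs = 3, seed = 4)
  m1 <- train_cnn(build_model(model_spec(), cfg), ds, cfg)
  m2 <- train_cnn(build_model(model_spec(), cfg), ds_perm, cfg)
  expect_equal(m1$history$train_mse, m2$history$train_mse, tolerance = 1e-10)
})

test_that("grid search enumerates, selects the argmin and breaks ties", {
  g <- default_search_grid()
  dry <- grid_search(g, dry_run = TRUE)
  expect_equal(nrow(dry$results), 3072)        # 4 * 3 * (2*2)^3 * 4
  tied <- grid_search(default_search_grid(per_layer_independent = FALSE),
                      dry_run = TRUE)
  expect_equal(nrow(tied$results), 192)

  # mocked trainer: validation MSE is a known function of the spec
  mock <- function(spec, cfg, train, validation)
    list(val_mse = abs(spec$dense_units - 256) + cfg$learning_rate,
         train_mse = 0)
  small <- default_search_grid(batch_sizes = 32, learning_rates = c(1e-3, 1e-4),
                               filters = 4, kernels = 3,
                               dense_units = c(128, 256))
  ds <- random_dataset(6)
  split <- list(train = ds, validation = ds)
  res <- grid_search(small, split, train_cfg(epochs = 1), trainer = mock)
  expect_equal(res$best_spec$dense_units, 256L)
  expect_equal(res$best_cfg$learning_rate, 1e-4)

  # tie on val MSE -> fewer parameters wins
  mock_tie <- function(spec, cfg, train, validation)
    list(val_mse = 1, train_mse = 0)
  res2 <- grid_search(small, split, train_cfg(epochs = 1), trainer = mock_tie)
  expect_equal(res2$best_spec$dense_units, 128L)
  expect_error(default_search_grid(filters = numeric(0)), "non-empty")
})

test_that("final retraining uses a seeded stride-level 80/20 split", {
  set.seed(31)
  ds <- random_dataset(40)
  cfg <- train_cfg(learning_rate = 1e-3, batch_size = 16, epochs = 2, seed = 9)
  spec <- model_spec(c(4, 4, 4), c(3, 3, 3), 8)
  m <- retrain_final(spec, ds, cfg)
  expect_length(m$representative$segments, 8)  # 20% of 40
  expect_equal(nrow(m$history), 2)
  expect_false(anyNA(m$history$val_mse))
  m2 <- retrain_final(spec, ds, cfg)
  ids <- function(mm) vapply(mm$representative$segments, `[[`, 0L, "stride_index")
  expect_identical(ids(m), ids(m2))            # same seed, same membership

  # multi-phase schedule accumulates history on the same split
  m3 <- retrain_final(spec, ds, list(cfg, train_cfg(learning_rate = 1e-4,
                                                    batch_size = 16,
                                                    epochs = 3, seed = 9)))
  expect_equal(nrow(m3$history), 5)
  expect_identical(ids(m3), ids(m))
  expect_error(train_cnn(build_model(spec, cfg),
                         labeled_stride_dataset(list(), 60, 108), cfg),
               "empty")
})
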