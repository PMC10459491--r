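# End-to-end synthetic replication study: cohort generation,
# pre-processing, subject-wise split, final training, quantization and
# agreement evaluation. Used by the package's reproduction script and
# the acceptance test suite so that the experiment is defined in exactly
# one place.

#' Run the synthetic replication study
#'
#' Generates a treadmill cohort (15 subjects x 3 speeds by default),
#' runs the full pre-processing pipeline, splits train/test by subject
#' (12/3), trains the reference architecture with a two-phase Adam
#' schedule inside a 300-epoch budget (a coarse phase at the search
#' grid's 1e-3 learning rate, then a short fine-tuning phase at the
#' reference 1e-4 rate, which removes the residual calibration offset of
#' the coarse phase), quantizes the trained model to int8 using the
#' retraining validation split as the representative dataset, and
#' evaluates float32 and int8 agreement against the planted stride
#' lengths on the held-out subjects.
#'
#' @param seed master seed for cohort generation and training.
#' @param n_subjects cohort size (last `n_test` subjects form the test
#'   split).
#' @param n_test held-out subjects.
#' @param trial_duration_s trial length in seconds (45 s keeps the
#'   cohort near 1600 strides and the study inside a desktop-minutes
#'   compute envelope; the acquisition protocol emulated by the
#'   generator uses 120 s).
#' @param spec the network architecture.
#' @param epochs,learning_rates per-phase epoch counts and Adam learning
#'   rates (equal lengths).
#' @param batch_size minibatch size.
#' @param cfg_extra named list of additional [train_cfg()] overrides.
#' @return list with `dataset`, `split`, `model`, `qmodel`,
#'   `report_float` / `report_int8` ([bland_altman()] on the held-out
#'   subjects), `comparison` ([compare_models()]), and `params`.
#' @export
run_synthetic_study <- function(seed = 1, n_subjects = 15, n_test = 3,
                                trial_duration_s = 45,
                                spec = model_spec(),
                                epochs = c(250, 50),
                                learning_rates = c(1e-3, 1e-4),
                                batch_size = 64, cfg_extra = list()) {
  stopifnot(length(epochs) == length(learning_rates), n_test < n_subjects)
  params <- gait_sim_params(n_subjects = n_subjects,
                            trial_duration_s = trial_duration_s, seed = seed)
  trials <- simulate_cohort(params)
  dataset <- preprocess_trials(trials, pipeline_config())
  subs <- sort(dataset_subjects(dataset))
  n_train <- length(subs) - n_test
  split <- split_by_subject(dataset, subs[seq_len(n_train)],
                            subs[n_train + seq_len(n_test)])
  cfgs <- lapply(seq_along(epochs), function(i)
    do.call(train_cfg, c(list(learning_rate = learning_rates[i],
                              batch_size = batch_size, epochs = epochs[i],
                              seed = seed), cfg_extra)))
  model <- retrain_final(spec, split$train, cfgs, seed = hash_seed(seed, "study"))
  qparams <- calibrate_quantization(model, model$representative)
  qmodel <- quantize_model(model, qparams)
  y <- dataset_labels(split$test)
  pred_f <- predict_cnn(model, split$test)
  pred_q <- int8_predict(qmodel, split$test)
  list(params = params, dataset = dataset, split = split, model = model,
       qmodel = qmodel,
       report_float = bland_altman(pred_f, y),
       report_int8 = bland_altman(pred_q, y),
       comparison = compare_models(model, qmodel, split$test))
}
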