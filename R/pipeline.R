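#' Pipeline configuration
#'
#' One structure gathering every parameter block the end-to-end pipeline
#' needs: the extractor choice, the neuron/synapse/coupling blocks for the
#' spiking extractor, the window geometry for the RMS baseline, the MLP
#' hyperparameters and the synthetic-data spec. Every stage derives its
#' randomness from `seed`.
#'
#' @param extractor `"rms"`, `"spiking_isolated"` or `"spiking_inhibitory"`.
#' @param sample_rate recording rate (Hz), default 400.
#' @param seed master seed.
#' @param feature_period feature sampling period (ms), default 50.
#' @param dt neuron integration step (ms), default 0.5.
#' @param neuron,synapse,coupling,window parameter blocks (defaults are the
#'   published operating point of each module).
#' @param mlp list of classifier settings: `hidden`, `lr`, `max_epochs`,
#'   `patience`.
#' @param synthetic a [series_spec()]; defaults to the standard protocol
#'   (4 series at `sample_rate`, seeded from `seed`).
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(extractor = c("rms", "spiking_isolated",
                                          "spiking_inhibitory"),
                            sample_rate = 400, seed = 1,
                            feature_period = 50, dt = 0.5,
                            neuron = neuron_params(),
                            synapse = synapse_params(),
                            coupling = coupling_params(),
                            window = window_config(),
                            mlp = list(hidden = 9, lr = 0.01,
                                       max_epochs = 4000, patience = 50),
                            synthetic = NULL) {
  extractor <- match.arg(extractor)
  if (is.null(synthetic))
    synthetic <- series_spec(sample_rate = sample_rate, seed = seed)
  structure(list(extractor = extractor, sample_rate = sample_rate,
                 seed = seed, feature_period = feature_period, dt = dt,
                 neuron = neuron, synapse = synapse, coupling = coupling,
                 window = window, mlp = mlp, synthetic = synthetic),
            class = "pipeline_config")
}

#' Extract features according to a pipeline config
#'
#' Dispatches to the RMS baseline or the spiking sensory layer (isolated or
#' inhibitory), producing the shared `feature_matrix` dialect.
#'
#' @param recording an [emg_recording()].
#' @param config a [pipeline_config()].
#' @return A `feature_matrix`.
#' @export
extract_features <- function(recording, config) {
  stopifnot(inherits(config, "pipeline_config"))
  switch(config$extractor,
    rms = extract_rms_features(recording, config$window),
    spiking_isolated = extract_spiking_features(
      recording, config$feature_period, mode = "isolated", dt = config$dt,
      neuron = config$neuron, synapse = config$synapse,
      coupling = config$coupling),
    spiking_inhibitory = extract_spiking_features(
      recording, config$feature_period, mode = "inhibitory", dt = config$dt,
      neuron = config$neuron, synapse = config$synapse,
      coupling = config$coupling))
}

#' Run the full training pipeline
#'
#' Generates (or accepts) a train/test recording pair, extracts features
#' with the configured extractor, min-max normalizes them on the training
#' ranges, trains the sigmoid MLP with test-set early stopping, and
#' evaluates window-level accuracy on the held-out split.
#'
#' @param config a [pipeline_config()].
#' @param dataset optional list with labelled [emg_recording()]s `train`
#'   and `test`; when `NULL` the synthetic protocol in `config$synthetic`
#'   is generated.
#' @param model_file optional path; when given, the trained model (with its
#'   scaling and config fingerprint) is serialized there as JSON.
#' @return A list: `model` (with `scaling` attached), `history`, `report`
#'   (an `evaluation_report`, see [evaluate_classification()]), `features`
#'   (the scaled train/test matrices) and `config`.
#' @export
run_training_pipeline <- function(config, dataset = NULL,
                                  model_file = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.null(dataset)) dataset <- generate_dataset(config$synthetic)
  ftr <- extract_features(dataset$train, config)
  fte <- extract_features(dataset$test, config)
  if (nrow(ftr) == 0 || nrow(fte) == 0)
    stop("feature extraction produced no rows; recording too short?")
  scaling <- fit_feature_scaling(ftr)
  ftr_s <- apply_feature_scaling(ftr, scaling)
  fte_s <- apply_feature_scaling(fte, scaling)
  n_classes <- max(ftr$label, fte$label)
  n_in <- ncol(feature_values(ftr))
  model <- init_mlp(c(n_in, config$mlp$hidden, n_classes),
                    seed = config$seed)
  fit <- train_mlp(model, ftr_s, fte_s, lr = config$mlp$lr,
                   max_epochs = config$mlp$max_epochs,
                   patience = config$mlp$patience)
  model <- fit$model
  model$scaling <- scaling
  pred <- classify_mlp(model, feature_values(fte_s))
  report <- evaluate_classification(pred, fte_s$label, n_classes,
                                    extractor = config$extractor)
  if (!is.null(model_file))
    write_mlp(model, model_file,
              metadata = list(extractor = config$extractor,
                              seed = config$seed,
                              sample_rate = config$sample_rate,
                              stopped_epoch =
                                attr(fit$history, "stopped_epoch"),
                              best_epoch = attr(fit$history, "best_epoch")))
  list(model = model, history = fit$history, report = report,
       features = list(train = ftr_s, test = fte_s), config = config)
}

#' Stream a recording through a trained model
#'
#' Causal pass: features are extracted at the configured 50 ms instants,
#' scaled with the ranges stored in the model, and classified one instant
#' at a time, yielding one class decision per feature instant.
#'
#' @param model a trained `mlp_model` carrying its `scaling`.
#' @param recording an [emg_recording()].
#' @param config the [pipeline_config()] the model was trained under.
#' @return A data.frame `time_ms`, `class` (one row per feature instant).
#' @export
run_streaming_classification <- function(model, recording, config) {
  fm <- extract_features(recording, config)
  if (ncol(feature_values(fm)) != model$sizes[1])
    stop("extractor output width (", ncol(feature_values(fm)),
         ") does not match the model input size (", model$sizes[1], ")")
  if (!is.null(model$scaling))
    fm <- apply_feature_scaling(fm, model$scaling)
  data.frame(time_ms = fm$t_ms,
             class = classify_mlp(model, feature_values(fm)))
}

#' Evaluate a predicted class sequence
#'
#' Window-level accuracy (percent), per-class recall and the confusion
#' matrix.
#'
#' @param predictions integer predicted classes.
#' @param truth integer true classes, same length.
#' @param n_classes number of classes (default: max label seen).
#' @param extractor optional identity string stored in the report.
#' @return An object of class `evaluation_report`: `accuracy` (percent),
#'   `confusion` (truth rows x prediction columns), `per_class_recall`,
#'   `n`, `extractor`.
#' @export
evaluate_classification <- function(predictions, truth,
                                    n_classes = max(c(predictions, truth)),
                                    extractor = NULL) {
  if (length(predictions) != length(truth))
    stop("predictions and truth must have equal length")
  cls <- seq_len(n_classes)
  confusion <- table(factor(truth, levels = cls),
                     factor(predictions, levels = cls))
  acc <- 100 * sum(diag(confusion)) / length(truth)
  recall <- diag(confusion) / pmax(rowSums(confusion), 1)
  structure(list(accuracy = acc, confusion = unclass(confusion),
                 per_class_recall = as.numeric(recall),
                 n = length(truth), extractor = extractor),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report>%s accuracy %.2f%% on %d windows\n",
              if (is.null(x$extractor)) "" else paste0(" [", x$extractor, "]"),
              x$accuracy, x$n))
  invisible(x)
}

#' Paired comparison of the spiking and RMS extractors
#'
#' Runs two full training pipelines on the *same* train/test recordings --
#' the RMS baseline and the chosen spiking extractor -- and reports both
#' window-level accuracies together with their difference
#' `delta = spiking - rms` (percentage points), the paired design used to
#' compare the two feature families.
#'
#' @param config a [pipeline_config()]; its `extractor` field is ignored.
#' @param dataset optional dataset as in [run_training_pipeline()].
#' @param spiking_mode `"spiking_inhibitory"` (default) or
#'   `"spiking_isolated"`.
#' @return A list: `rms` and `spiking` pipeline results, `delta`
#'   (percentage points), and `accuracies` (named vector, percent).
#' @export
compare_extractors <- function(config, dataset = NULL,
                               spiking_mode = "spiking_inhibitory") {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.null(dataset)) dataset <- generate_dataset(config$synthetic)
  cfg_rms <- config; cfg_rms$extractor <- "rms"
  cfg_sp <- config; cfg_sp$extractor <- spiking_mode
  res_rms <- run_training_pipeline(cfg_rms, dataset)
  res_sp <- run_training_pipeline(cfg_sp, dataset)
  delta <- res_sp$report$accuracy - res_rms$report$accuracy
  list(rms = res_rms, spiking = res_sp, delta = delta,
       accuracies = c(rms = res_rms$report$accuracy,
                      spiking = res_sp$report$accuracy))
}
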