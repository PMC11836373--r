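# End-to-end orchestration: data -> wavelet preprocessing -> (optional)
# augmentation-policy search -> imbalance handling -> (optional) ACO
# hyperparameter tuning -> ViT training -> held-out evaluation.

#' Pipeline run configuration
#'
#' @param spec an [oct_spec()] describing the synthetic dataset, or `NULL`
#'   when `data_dir` points at an on-disk directory-per-class dataset.
#' @param data_dir optional dataset directory (overrides `spec`).
#' @param wavelet,dwt_levels,dwt_fraction wavelet preprocessing parameters
#'   (`dwt_levels = 0` disables preprocessing).
#' @param imbalance one of `"none"`, `"smote"`, `"weighted"`,
#'   `"smote+weighted"`.
#' @param weights_from `"resampled"` (recompute class weights after SMOTE;
#'   all-ones when fully balanced) or `"original"` (inverse frequencies of
#'   the pre-SMOTE counts).
#' @param model a [vit_config()].
#' @param epochs,batch_size,learning_rate training budget.
#' @param search_augmentation run ACO augmentation-policy search and apply
#'   the found policy to the training split.
#' @param tune_hyperparams run ACO hyperparameter tuning (with a cheap
#'   proxy budget) before the final fit.
#' @param hpo_lambda,aug_lambda regularization weights of the two searches.
#' @param val_fraction held-out fraction of the stratified split.
#' @param seed master seed of the run.
#' @param output_dir optional directory for artifacts (metrics CSV/YAML,
#'   traces, checkpoint).
#' @return a `run_config` list.
#' @export
run_config <- function(spec = oct_spec(), data_dir = NULL,
                       wavelet = "haar", dwt_levels = 2L, dwt_fraction = 0.5,
                       imbalance = c("none", "smote", "weighted",
                                     "smote+weighted"),
                       weights_from = c("resampled", "original"),
                       model = vit_config(), epochs = 10L, batch_size = 32L,
                       learning_rate = 1e-3, search_augmentation = FALSE,
                       tune_hyperparams = FALSE, hpo_lambda = 0.1,
                       aug_lambda = 0.01, val_fraction = 0.2, seed = 1L,
                       output_dir = NULL) {
  imbalance <- match.arg(imbalance)
  weights_from <- match.arg(weights_from)
  structure(as.list(environment()), class = "run_config")
}

#' Stratified train/validation split
#'
#' @param labels integer labels. @param val_fraction held-out fraction.
#' @param seed split seed.
#' @return list with integer index vectors `train` and `val`.
#' @export
stratified_split <- function(labels, val_fraction = 0.2, seed = 1L) {
  with_seed(seed, {
    tr <- va <- integer(0)
    for (c in sort(unique(labels))) {
      idx <- sample(which(labels == c))
      nv <- max(1L, round(val_fraction * length(idx)))
      va <- c(va, idx[seq_len(nv)])
      tr <- c(tr, idx[-seq_len(nv)])
    }
    list(train = sort(tr), val = sort(va))
  })
}

.subset_dataset <- function(dataset, idx) {
  oct_dataset(dataset$images[idx], dataset$labels[idx], dataset$class_names,
              dataset$synthetic[idx])
}

#' Run the full pipeline
#'
#' Stages, in order: load or generate the dataset; stratified split;
#' wavelet preprocessing; optional ACO augmentation-policy search (applied
#' to the training split); imbalance handling per `config$imbalance`;
#' optional ACO hyperparameter tuning; ViT training with (weighted)
#' cross-entropy via Adam; evaluation on the held-out split. The
#' minority class of the report is resolved from the ORIGINAL (pre-SMOTE)
#' class supports. Fully seeded; a stage failure aborts with the stage
#' name.
#'
#' @param config a [run_config()].
#' @return list with `model`, `report` (a [metrics_report()]), `history`,
#'   `split`, `config`, and (when run) `augmentation` / `tuning` search
#'   results.
#' @export
run_pipeline <- function(config = run_config()) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
  }
  dataset <- stage("data", {
    if (!is.null(config$data_dir)) read_dataset_dir(config$data_dir)
    else generate_dataset(config$spec)
  })
  split <- stratified_split(dataset$labels, config$val_fraction, config$seed)
  train <- .subset_dataset(dataset, split$train)
  val <- .subset_dataset(dataset, split$val)
  original_counts <- class_counts(train)

  if (config$dwt_levels > 0L) {
    train$images <- stage("preprocess", dwt_preprocess_batch(
      train$images, config$wavelet, config$dwt_levels, config$dwt_fraction))
    val$images <- stage("preprocess", dwt_preprocess_batch(
      val$images, config$wavelet, config$dwt_levels, config$dwt_fraction))
  }

  aug <- NULL
  if (isTRUE(config$search_augmentation)) {
    aug <- stage("augmentation-search", {
      probe <- vit_init(config$model)
      loss_fn <- function(img, y) .sample_loss(vit_forward(probe, img), y)
      search_augmentation_policy(default_augmentation_ops(), loss_fn, train,
                                 lambda = config$aug_lambda,
                                 n_eval = min(16L, length(train$labels)),
                                 seed = config$seed,
                                 aco_cfg = aco_config(n_ants = 8L,
                                                      max_iterations = 10L,
                                                      patience = 5L,
                                                      seed = config$seed))
    })
    if (length(aug$policy$steps) > 0L) {
      train$images <- lapply(seq_along(train$images), function(i)
        apply_policy(train$images[[i]], aug$policy,
                     seed = config$seed + i))
    }
  }

  use_smote <- config$imbalance %in% c("smote", "smote+weighted")
  use_weights <- config$imbalance %in% c("weighted", "smote+weighted")
  if (use_smote)
    train <- stage("smote", smote_resample(train, seed = config$seed))
  class_w <- NULL
  if (use_weights) {
    counts_for_w <- if (config$weights_from == "original") original_counts
    else class_counts(train)
    class_w <- class_weights(counts_for_w)
  }

  tuning <- NULL
  model_cfg <- config$model
  lr <- config$learning_rate
  batch <- config$batch_size
  if (isTRUE(config$tune_hyperparams)) {
    tuning <- stage("hyperparameter-tuning", {
      sub <- with_seed(config$seed,
                       sample(seq_along(train$labels),
                              min(60L, length(train$labels))))
      proxy <- .subset_dataset(train, sub)
      tune_hyperparams(hyperparam_space(), function(cfg) {
        mc <- model_cfg
        mc$dense_neurons <- as.integer(cfg$dense_neurons)
        m <- vit_init(mc)
        fit <- vit_train(m, proxy, epochs = 3L,
                         batch_size = as.integer(cfg$batch_size),
                         lr = cfg$learning_rate, class_w = class_w,
                         seed = config$seed)
        pr <- vit_predict(fit$model, val$images)
        list(loss = weighted_cross_entropy(pr, val$labels,
                                           rep(1, ncol(pr))))
      }, lambda = config$hpo_lambda,
      aco_cfg = aco_config(n_ants = 6L, max_iterations = 8L, patience = 4L,
                           seed = config$seed))
    })
    model_cfg$dense_neurons <- as.integer(tuning$config$dense_neurons)
    lr <- tuning$config$learning_rate
    batch <- as.integer(tuning$config$batch_size)
  }

  model <- vit_init(model_cfg)
  fit <- stage("train", vit_train(model, train, epochs = config$epochs,
                                  batch_size = batch, lr = lr,
                                  class_w = class_w, seed = config$seed))
  report <- stage("evaluate", {
    probs <- vit_predict(fit$model, val$images)
    pred <- max.col(probs, ties.method = "first")
    cm <- confusion_matrix(val$labels, pred, length(val$class_names))
    # minority class resolved from pre-SMOTE training supports
    metrics_report(cm, support = original_counts,
                   class_names = val$class_names)
  })

  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
    write_metrics_csv(report, file.path(config$output_dir, "metrics.csv"))
    yaml::write_yaml(list(
      accuracy = report$accuracy, precision_macro = report$macro_precision,
      recall_macro = report$macro_recall, f1_macro = report$macro_f1,
      minority_class_accuracy = report$minority_class_accuracy,
      imbalance = config$imbalance, seed = config$seed),
      file.path(config$output_dir, "metrics.yaml"))
    if (!is.null(fit$history) && nrow(fit$history))
      utils::write.csv(fit$history,
                       file.path(config$output_dir, "train_history.csv"),
                       row.names = FALSE)
    if (!is.null(tuning))
      write_trace_csv(tuning$trace, file.path(config$output_dir, "hpo_trace.csv"))
    if (!is.null(aug))
      write_trace_csv(aug$trace, file.path(config$output_dir, "aug_trace.csv"))
    saveRDS(fit$model, file.path(config$output_dir, "model.rds"))
  }

  list(model = fit$model, report = report, history = fit$history,
       split = split, config = config, augmentation = aug, tuning = tuning)
}
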