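#' Classifier configuration
#'
#' Hyperparameters of the dual-branch CNN-LSTM. The plantar-pressure branch
#' uses two convolutional blocks (each conv -> batch norm -> ReLU -> max
#' pool 2); the muscle-strain branch uses three convolutional layers
#' followed by a stride-4 pooling that aligns its temporal length with the
#' plantar branch before channel concatenation. The merged sequence feeds an
#' LSTM whose final hidden state passes through dropout and a softmax
#' output layer. Training uses Adam with step learning-rate decay, L2 weight
#' decay, and early stopping on an inner subject-wise validation split.
#'
#' @param plantar_filters Two conv output widths for the plantar branch.
#' @param strain_filters Three conv output widths for the strain branch.
#' @param kernel Odd convolution kernel size (samples).
#' @param lstm_hidden LSTM hidden units.
#' @param dropout Dropout rate in [0, 1) on the LSTM output.
#' @param weight_decay L2 penalty on weight matrices.
#' @param learning_rate Initial Adam learning rate.
#' @param lr_decay_factor,lr_decay_every Step decay: multiply by the factor
#'   every `lr_decay_every` epochs.
#' @param max_epochs Maximum training epochs.
#' @param early_stop_patience Epochs without validation improvement before
#'   stopping.
#' @param batch_size Mini-batch size.
#' @param n_augment Augmented copies per training window.
#' @return An object of class `model_config`.
#' @export
model_config <- function(plantar_filters = c(16, 32),
                         strain_filters = c(16, 32, 64),
                         kernel = 5,
                         lstm_hidden = 64,
                         dropout = 0.3,
                         weight_decay = 1e-4,
                         learning_rate = 1e-3,
                         lr_decay_factor = 0.5,
                         lr_decay_every = 20,
                         max_epochs = 100,
                         early_stop_patience = 10,
                         batch_size = 32,
                         n_augment = 1) {
  stopifnot(kernel %% 2 == 1, dropout >= 0, dropout < 1, lstm_hidden > 0,
            length(plantar_filters) == 2, length(strain_filters) == 3)
  structure(list(plantar_filters = plantar_filters,
                 strain_filters = strain_filters, kernel = kernel,
                 lstm_hidden = lstm_hidden, dropout = dropout,
                 weight_decay = weight_decay, learning_rate = learning_rate,
                 lr_decay_factor = lr_decay_factor,
                 lr_decay_every = lr_decay_every, max_epochs = max_epochs,
                 early_stop_patience = early_stop_patience,
                 batch_size = batch_size, n_augment = n_augment),
            class = "model_config")
}

#' Subject-wise grouped fold plan
#'
#' Assigns each subject to exactly one test fold, stratified by class:
#' within each class, subjects are sorted, shuffled with a seeded RNG, and
#' dealt round-robin (with a rotating per-class starting fold to balance
#' fold sizes). The result is invariant to the input ordering of subjects.
#'
#' @param subject_ids Character vector of subject IDs (duplicates allowed;
#'   unique subjects are used).
#' @param class_labels Class label per entry of `subject_ids` (same length),
#'   used for stratification; `NULL` for unstratified assignment.
#' @param n_folds Number of folds (default 5, i.e. about 80\%/20\%
#'   train/test subjects per fold).
#' @param seed Integer seed.
#' @return An object of class `fold_plan`: list with `assignment` (named
#'   integer vector subject -> fold), `folds` (per fold: `train` and `test`
#'   subject sets), `n_folds`.
#' @export
grouped_folds <- function(subject_ids, class_labels = NULL, n_folds = 5,
                          seed = 1) {
  df <- unique(data.frame(
    subject = as.character(subject_ids),
    class = if (is.null(class_labels)) "all"
            else as.character(class_labels),
    stringsAsFactors = FALSE))
  if (anyDuplicated(df$subject))
    stop("a subject appears with more than one class label", call. = FALSE)
  if (n_folds > nrow(df))
    stop("`n_folds` exceeds the number of subjects", call. = FALSE)
  assignment <- integer(0)
  offset <- 0L
  for (cl in sort(unique(df$class))) {
    subs <- sort(df$subject[df$class == cl])
    if (length(subs) < n_folds)
      warning(sprintf("class '%s' has fewer subjects (%d) than folds (%d); best-effort stratification",
                      cl, length(subs), n_folds))
    subs <- with_seed(derive_seed(seed, paste0("fold_", cl)),
                      sample(subs))
    fold <- ((seq_along(subs) - 1L + offset) %% n_folds) + 1L
    names(fold) <- subs
    assignment <- c(assignment, fold)
    offset <- (offset + length(subs)) %% n_folds
  }
  all_subs <- names(assignment)
  folds <- lapply(seq_len(n_folds), function(f)
    list(test = sort(all_subs[assignment == f]),
         train = sort(all_subs[assignment != f])))
  structure(list(assignment = assignment, folds = folds, n_folds = n_folds),
            class = "fold_plan")
}

#' @export
print.fold_plan <- function(x, ...) {
  sizes <- vapply(x$folds, function(f) length(f$test), numeric(1))
  cat(sprintf("<fold_plan> %d folds over %d subjects; test sizes: %s\n",
              x$n_folds, length(x$assignment),
              paste(sizes, collapse = ", ")))
  invisible(x)
}

modality_channels <- function(ws_x, modality) {
  switch(modality,
         plantar_only = ws_x[, , 1, drop = FALSE],
         strain_only = ws_x[, , 2:4, drop = FALSE],
         fused = ws_x,
         stop("unknown modality: ", modality, call. = FALSE))
}

check_no_leakage <- function(plan, windows) {
  for (f in plan$folds)
    if (length(intersect(f$train, f$test)) > 0)
      stop("subject leakage: train and test subject sets overlap",
           call. = FALSE)
  bad <- setdiff(unique(windows$subject_id), names(plan$assignment))
  if (length(bad) > 0)
    stop("windows carry subjects absent from the fold plan: ",
         paste(bad, collapse = ", "), call. = FALSE)
  invisible(TRUE)
}

#' Train the classifier across folds
#'
#' For each fold: selects the training subjects, holds out one subject per
#' class as an inner validation set for early stopping (keeping the test
#' fold untouched), augments the remaining training windows, and trains the
#' CNN-LSTM. Augmented windows inherit their source subject, so the
#' grouped-split constraint is preserved.
#'
#' @param windows A `window_set` over the cohort (fused channel layout,
#'   plantar + 3 strain channels).
#' @param plan A [grouped_folds()] plan covering the windows' subjects.
#' @param config A [model_config()].
#' @param modality `"fused"`, `"plantar_only"`, or `"strain_only"`.
#' @param seed Integer seed.
#' @return An object of class `fold_models`: list with `models` (one
#'   `cnn_lstm_model` per fold), `classes`, `plan`, `modality`, `config`.
#' @export
build_and_train <- function(windows, plan, config = model_config(),
                            modality = c("fused", "plantar_only",
                                         "strain_only"),
                            seed = 1) {
  modality <- match.arg(modality)
  stopifnot(inherits(windows, "window_set"), inherits(plan, "fold_plan"))
  check_no_leakage(plan, windows)
  classes <- sort(unique(windows$label))
  subj_class <- tapply(windows$label, windows$subject_id,
                       function(l) l[1])
  models <- vector("list", plan$n_folds)
  for (f in seq_len(plan$n_folds)) {
    train_subj <- plan$folds[[f]]$train
    # inner validation: one subject per class (only if the class keeps >= 2)
    val_subj <- character(0)
    for (cl in classes) {
      cls_subj <- sort(train_subj[subj_class[train_subj] == cl])
      if (length(cls_subj) >= 2) {
        pick <- with_seed(derive_seed(seed, paste0("val", f, cl)),
                          sample(cls_subj, 1))
        val_subj <- c(val_subj, pick)
      }
    }
    fit_subj <- setdiff(train_subj, val_subj)
    if (length(fit_subj) == 0)
      stop("empty training split in fold ", f, call. = FALSE)
    tr <- subset_windows(windows, windows$subject_id %in% fit_subj)
    if (dim(tr$x)[1] == 0)
      stop("no training windows in fold ", f, call. = FALSE)
    if (config$n_augment > 0)
      tr <- augment_window_set(tr, derive_seed(seed, paste0("aug", f)),
                               n_copies = config$n_augment)
    va <- subset_windows(windows, windows$subject_id %in% val_subj)
    x_tr <- modality_channels(tr$x, modality)
    y_tr <- match(tr$label, classes)
    x_va <- modality_channels(va$x, modality)
    y_va <- match(va$label, classes)
    models[[f]] <- train_network(x_tr, y_tr, x_va, y_va, config, modality,
                                 length(classes),
                                 derive_seed(seed, paste0("train", f,
                                                          modality)))
  }
  structure(list(models = models, classes = classes, plan = plan,
                 modality = modality, config = config),
            class = "fold_models")
}

#' Evaluate fold models on held-out subjects
#'
#' Predicts only windows of each fold's held-out subjects (original windows,
#' never augmented ones) and pools the confusion matrix across folds.
#' Subject leakage (a test subject found in the fold's training set) is a
#' hard failure.
#'
#' @param fold_models A [build_and_train()] result, or a list of
#'   fold-indexed stub predictors (each a `function(x_array)` returning
#'   class labels) together with `classes`/`plan`/`modality` fields.
#' @param windows The `window_set` used for evaluation.
#' @param plan Optional fold plan (defaults to the one stored with the
#'   models).
#' @param modality Optional modality override.
#' @return An object of class `eval_result`: `confusion` (true x predicted
#'   counts), `accuracy` (\%), `per_class` (precision/recall), `modality`,
#'   `per_fold_accuracy` (\%).
#' @export
evaluate_folds <- function(fold_models, windows, plan = NULL,
                           modality = NULL) {
  stopifnot(inherits(windows, "window_set"))
  plan <- plan %||% fold_models$plan
  modality <- modality %||% fold_models$modality
  classes <- fold_models$classes
  check_no_leakage(plan, windows)
  keep <- windows$lineage == "original"
  ws <- subset_windows(windows, keep)
  conf <- matrix(0L, length(classes), length(classes),
                 dimnames = list(true = classes, predicted = classes))
  per_fold <- numeric(plan$n_folds)
  for (f in seq_len(plan$n_folds)) {
    test_subj <- plan$folds[[f]]$test
    if (any(test_subj %in% plan$folds[[f]]$train))
      stop("subject leakage detected in fold ", f, call. = FALSE)
    sel <- ws$subject_id %in% test_subj
    if (!any(sel)) { per_fold[f] <- NA; next }
    te <- subset_windows(ws, sel)
    x_te <- modality_channels(te$x, modality)
    m <- fold_models$models[[f]]
    pred_idx <- if (is.function(m)) {
      pr <- m(x_te)
      if (is.character(pr)) match(pr, classes) else as.integer(pr)
    } else predict_windows(m, x_te)
    true_idx <- match(te$label, classes)
    for (i in seq_along(true_idx))
      conf[true_idx[i], pred_idx[i]] <- conf[true_idx[i], pred_idx[i]] + 1L
    per_fold[f] <- 100 * mean(pred_idx == true_idx)
  }
  total <- sum(conf)
  acc <- 100 * sum(diag(conf)) / total
  per_class <- data.frame(
    class = classes,
    precision = diag(conf) / pmax(colSums(conf), 1),
    recall = diag(conf) / pmax(rowSums(conf), 1))
  structure(list(confusion = conf, accuracy = acc, per_class = per_class,
                 modality = modality, per_fold_accuracy = per_fold,
                 n_windows = total), class = "eval_result")
}

#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf("<eval_result> modality %s: pooled accuracy %.2f%% over %d windows\n",
              x$modality, x$accuracy, x$n_windows))
  print(x$confusion)
  invisible(x)
}

#' Modality ablation
#'
#' Trains and evaluates the classifier three times on identical fold plans
#' and seeds: plantar channel only, strain channels only, and the fused
#' dual-modality input, and reports the three pooled accuracies with their
#' pairwise differences.
#'
#' @param windows A `window_set` (fused channel layout).
#' @param plan A [grouped_folds()] plan.
#' @param config A [model_config()].
#' @param seed Integer seed (shared across the three runs).
#' @return An object of class `ablation_result`: named list of three
#'   `eval_result`s plus `accuracy` (named vector, \%) and
#'   `pairwise_diff`.
#' @export
modality_ablation <- function(windows, plan, config = model_config(),
                              seed = 1) {
  mods <- c("plantar_only", "strain_only", "fused")
  evals <- list()
  for (m in mods) {
    fit <- build_and_train(windows, plan, config, modality = m, seed = seed)
    evals[[m]] <- evaluate_folds(fit, windows)
  }
  acc <- vapply(evals, function(e) e$accuracy, numeric(1))
  diffs <- c(fused_vs_plantar = unname(acc["fused"] - acc["plantar_only"]),
             fused_vs_strain = unname(acc["fused"] - acc["strain_only"]),
             strain_vs_plantar = unname(acc["strain_only"] -
                                          acc["plantar_only"]))
  structure(list(results = evals, accuracy = acc, pairwise_diff = diffs),
            class = "ablation_result")
}

#' @export
print.ablation_result <- function(x, ...) {
  cat("<ablation_result> pooled accuracies (%):\n")
  print(round(x$accuracy, 2))
  cat("pairwise differences (pp):\n")
  print(round(x$pairwise_diff, 2))
  invisible(x)
}
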