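test_that("grouped folds partition subjects with stratified balance", {
  ids <- sprintf("S%02d", 1:60)
  cls <- rep(c("healthy", "hemi_left", "hemi_right", "pd"), each = 15)
  plan <- grouped_folds(ids, cls, n_folds = 5, seed = 4)
  sizes <- vapply(plan$folds, function(f) length(f$test), numeric(1))
  expect_equal(sizes, rep(12, 5))
  for (f in plan$folds) {
    expect_length(intersect(f$train, f$test), 0)
    expect_setequal(c(f$train, f$test), ids)
  }
  # every subject in exactly one test fold
  all_test <- unlist(lapply(plan$folds, `[[`, "test"))
  expect_setequal(all_test, ids)
  expect_equal(length(all_test), 60)
})

test_that("fold assignment ignores input order but responds to the seed", {
  ids <- sprintf("S%02d", 1:20)
  cls <- rep(c("a", "b"), each = 10)
  p1 <- grouped_folds(ids, cls, n_folds = 4, seed = 9)
  sh <- sample(20)
  p2 <- grouped_folds(ids[sh], cls[sh], n_folds = 4, seed = 9)
  expect_identical(p1$assignment[sort(names(p1$assignment))],
                   p2$assignment[sort(names(p2$assignment))])
  p3 <- grouped_folds(ids, cls, n_folds = 4, seed = 10)
  expect_false(identical(p1$assignment[names(p3$assignment)],
                         p3$assignment))
  expect_warning(grouped_folds(c("A", "B"), c("x", "x"), n_folds = 2,
                               seed = 1), NA)
  expect_warning(grouped_folds(sprintf("S%d", 1:6),
                               c(rep("a", 5), "b"), n_folds = 3, seed = 1),
                 "fewer subjects")
  expect_error(grouped_folds(c("A", "B"), n_folds = 3), "exceeds")
})

test_that("evaluation with stub predictors matches analytic confusion matrices", {
  co <- two_class_cohort(n_per_class = 4, duration_s = 60)
  ws <- windows_from_cohort(co)
  plan <- grouped_folds(ws$subject_id, ws$label, n_folds = 2, seed = 1)
  classes <- sort(unique(ws$label))
  # perfect stub: fold-wise oracle built from the true labels by subject
  lab_of <- setNames(co$manifest$class_label, co$manifest$subject_id)
  make_stub <- function(test_subjects) {
    force(test_subjects)
    function(x) {
      # the evaluator feeds windows of these subjects in order
      n <- dim(x)[1]
      match(rep(lab_of[test_subjects],
                each = n / length(test_subjects)), classes)
    }
  }
  stubs <- lapply(plan$folds, function(f) make_stub(sort(f$test)))
  fm <- list(models = stubs, classes = classes, plan = plan,
             modality = "fused")
  ev <- evaluate_folds(fm, ws)
  expect_equal(ev$accuracy, 100)
  expect_equal(sum(ev$confusion) , sum(diag(ev$confusion)))
  # constant stub: accuracy equals the prevalence of the predicted class
  const <- lapply(plan$folds, function(f) function(x) rep(1L, dim(x)[1]))
  fm2 <- list(models = const, classes = classes, plan = plan,
              modality = "fused")
  ev2 <- evaluate_folds(fm2, ws)
  expect_equal(ev2$accuracy, 100 * mean(ws$label == classes[1]))
  # accuracy recomputed from the confusion matrix equals the reported one
  expect_equal(100 * sum(diag(ev2$confusion)) / sum(ev2$confusion),
               ev2$accuracy)
})

test_that("subject leakage is a hard failure", {
  co <- two_class_cohort(n_per_class = 3, duration_s = 60)
  ws <- windows_from_cohort(co)
  plan <- grouped_folds(ws$subject_id, ws$label, n_folds = 2, seed = 1)
  bad <- plan
  bad$folds[[1]]$train <- c(bad$folds[[1]]$train, bad$folds[[1]]$test[1])
  stub <- lapply(bad$folds, function(f) function(x) rep(1L, dim(x)[1]))
  fm <- list(models = stub, classes = sort(unique(ws$label)), plan = bad,
             modality = "fused")
  expect_error(evaluate_folds(fm, ws), "leakage")
})

test_that("zero leakage holds across many random cohorts", {
  set.seed(99)
  violations <- 0L
  for (i in 1:200) {
    n_sub <- sample(6:40, 1)
    n_cls <- sample(2:4, 1)
    ids <- sprintf("P%03d", seq_len(n_sub))
    cls <- sample(letters[1:n_cls], n_sub, replace = TRUE)
    k <- sample(2:min(5, n_sub), 1)
    plan <- suppressWarnings(grouped_folds(ids, cls, n_folds = k, seed = i))
    test_union <- unlist(lapply(plan$folds, `[[`, "test"))
    if (any(vapply(plan$folds, function(f)
      length(intersect(f$train, f$test)) > 0, logical(1))) ||
      !setequal(test_union, ids) || length(test_union) != n_sub)
      violations <- violations + 1L
  }
  expect_identical(violations, 0L)
})

test_that("a strain-only class signal leaves the plantar modality at chance", {
  arch <- function(lbl, trem)
    archetype_params(lbl, noise_sigma = 0.05,
                     tremor_hz = if (trem > 0) 3.5 else 0, tremor_amp = trem)
  co <- make_cohort(cohort_spec(
    class_counts = c(trem = 8, notrem = 8), duration_s = 90,
    master_seed = 7,
    archetypes = list(trem = arch("trem", 0.6), notrem = arch("notrem", 0))))
  ws <- windows_from_cohort(co)
  plan <- grouped_folds(ws$subject_id, ws$label, n_folds = 2, seed = 3)
  cfg <- tiny_model_config(max_epochs = 30)
  cfg$early_stop_patience <- 15
  ab <- modality_ablation(ws, plan, cfg, seed = 2)
  expect_gte(ab$accuracy[["strain_only"]], 90)
  expect_lte(abs(ab$accuracy[["strain_only"]] - ab$accuracy[["fused"]]), 10)
  expect_lte(ab$accuracy[["plantar_only"]], 70)   # chance is 50%
  # the three runs evaluated the same held-out windows
  expect_identical(ab$results$fused$n_windows,
                   ab$results$plantar_only$n_windows)
  expect_identical(rowSums(ab$results$fused$confusion),
                   rowSums(ab$results$strain_only$confusion))
})

test_that("training and evaluation are reproducible under a fixed seed", {
  co <- two_class_cohort(n_per_class = 4, duration_s = 60)
  ws <- windows_from_cohort(co)
  plan1 <- grouped_folds(ws$subject_id, ws$label, n_folds = 2, seed = 5)
  plan2 <- grouped_folds(ws$subject_id, ws$label, n_folds = 2, seed = 5)
  expect_identical(plan1$assignment, plan2$assignment)
  cfg <- tiny_model_config(max_epochs = 3)
  f1 <- build_and_train(ws, plan1, cfg, modality = "strain_only", seed = 8)
  f2 <- build_and_train(ws, plan2, cfg, modality = "strain_only", seed = 8)
  e1 <- evaluate_folds(f1, ws)
  e2 <- evaluate_folds(f2, ws)
  expect_lt(abs(e1$accuracy - e2$accuracy), 0.5)
  expect_identical(e1$confusion, e2$confusion)
})

test_that("augmented windows stay inside their subject's split", {
  co <- two_class_cohort(n_per_class = 3, duration_s = 60)
  ws <- windows_from_cohort(co)
  aug <- augment_window_set(ws, seed = 3, n_copies = 1)
  expect_true(all(aug$subject_id[aug$lineage != "original"] %in%
                    unique(ws$subject_id)))
  # evaluation ignores augmented windows
  plan <- grouped_folds(ws$subject_id, ws$label, n_folds = 3, seed = 2)
  stub <- lapply(plan$folds, function(f) function(x) rep(1L, dim(x)[1]))
  fm <- list(models = stub, classes = sort(unique(ws$label)), plan = plan,
             modality = "fused")
  ev_aug <- evaluate_folds(fm, aug)
  ev_orig <- evaluate_folds(fm, ws)
  expect_identical(ev_aug$confusion, ev_orig$confusion)
})
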