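#' Default pipeline configuration
#'
#' A compact, fully-specified configuration for [run_pipeline()]: cohort
#' composition and duration, preprocessing parameters, classifier
#' hyperparameters, cross-validation settings, and the energy scenario.
#' Stored as a plain list so it round-trips through YAML.
#'
#' @param master_seed Master seed for every stage.
#' @return A nested configuration list.
#' @export
default_pipeline_config <- function(master_seed = 1) {
  list(
    seed = master_seed,
    cohort = list(class_counts = list(healthy = 15, hemi_left = 15,
                                      hemi_right = 15, pd_td = 5, pd_ar = 5,
                                      pd_pigd = 5),
                  duration_s = 90),
    preprocess = list(cutoff_hz = 0.15, window_len = 300, overlap = 0.5),
    train = list(enabled = TRUE, max_epochs = 15, n_folds = 5,
                 ablation = FALSE, n_augment = 1),
    energy = list(enabled = TRUE))
}

read_pipeline_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config,
                                   call. = FALSE)
    config <- yaml::read_yaml(config)
  }
  base <- default_pipeline_config()
  # class_counts replaces wholesale: merging per class would silently keep
  # default classes the user left out
  merge_lists <- function(a, b) {
    for (nm in names(b))
      a[[nm]] <- if (is.list(a[[nm]]) && is.list(b[[nm]]) &&
                     nm != "class_counts")
        merge_lists(a[[nm]], b[[nm]]) else b[[nm]]
    a
  }
  merge_lists(base, config)
}

pipeline_stage <- function(name, log_path, expr) {
  line <- sprintf("[%s] stage %s: start", format(Sys.time(), "%H:%M:%S"),
                  name)
  cat(line, "\n", file = log_path, append = TRUE)
  out <- tryCatch(expr, error = function(e)
    stop(sprintf("[stage %s] %s", name, conditionMessage(e)),
         call. = FALSE))
  cat(sprintf("[%s] stage %s: done\n", format(Sys.time(), "%H:%M:%S"),
              name), file = log_path, append = TRUE)
  out
}

#' Run the full analysis pipeline
#'
#' Executes simulate -> preprocess -> window -> features -> grouped-CV
#' training (optionally the three-modality ablation) -> energy budget, and
#' writes every artifact (cohort manifest, feature table, evaluation
#' results, budget report, configuration, seeds, and a stage log) into a
#' run directory. Fully reproducible from the configuration and master
#' seed.
#'
#' @param config Configuration list or path to a YAML file; missing entries
#'   fall back to [default_pipeline_config()].
#' @param out_dir Run directory (created; default a fresh temporary
#'   directory).
#' @return The run directory path, invisibly; artifacts on disk.
#' @export
run_pipeline <- function(config = default_pipeline_config(),
                         out_dir = tempfile("gait_run_")) {
  cfg <- read_pipeline_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "log.txt")
  cat(sprintf("run started %s, master seed %d\n", Sys.time(), cfg$seed),
      file = log_path)
  jsonlite::write_json(cfg, file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)

  cohort <- pipeline_stage("simulate", log_path, {
    counts <- unlist(cfg$cohort$class_counts)
    make_cohort(cohort_spec(class_counts = counts,
                            duration_s = cfg$cohort$duration_s,
                            master_seed = cfg$seed))
  })
  utils::write.csv(cohort$manifest,
                   file.path(out_dir, "cohort_manifest.csv"),
                   row.names = FALSE)

  windows <- pipeline_stage("windowing", log_path, {
    ws <- windows_from_cohort(cohort,
                              window_len = cfg$preprocess$window_len,
                              overlap_fraction = cfg$preprocess$overlap,
                              cutoff_hz = cfg$preprocess$cutoff_hz)
    if (dim(ws$x)[1] == 0)
      stop("no windows produced; recordings shorter than the window length")
    ws
  })

  features <- pipeline_stage("features", log_path,
                             feature_table(cohort,
                                           cutoff_hz = cfg$preprocess$cutoff_hz))
  utils::write.csv(features, file.path(out_dir, "features.csv"),
                   row.names = FALSE)

  if (isTRUE(cfg$train$enabled)) {
    pipeline_stage("classifier", log_path, {
      plan <- grouped_folds(windows$subject_id, windows$label,
                            n_folds = cfg$train$n_folds,
                            seed = derive_seed(cfg$seed, "folds"))
      mc <- model_config(max_epochs = cfg$train$max_epochs,
                         n_augment = cfg$train$n_augment)
      if (isTRUE(cfg$train$ablation)) {
        ab <- modality_ablation(windows, plan, mc,
                                seed = derive_seed(cfg$seed, "train"))
        for (m in names(ab$results))
          write_eval_json(ab$results[[m]],
                          file.path(out_dir, sprintf("eval_%s.json", m)))
        jsonlite::write_json(as.list(ab$accuracy),
                             file.path(out_dir, "ablation_accuracy.json"),
                             auto_unbox = TRUE, digits = NA)
      } else {
        fit <- build_and_train(windows, plan, mc, modality = "fused",
                               seed = derive_seed(cfg$seed, "train"))
        ev <- evaluate_folds(fit, windows)
        write_eval_json(ev, file.path(out_dir, "eval_fused.json"))
      }
    })
  }

  if (isTRUE(cfg$energy$enabled)) {
    pipeline_stage("energy", log_path, {
      rep <- energy_report()
      jsonlite::write_json(unclass(rep), file.path(out_dir, "budget.json"),
                           auto_unbox = TRUE, digits = NA)
    })
  }

  jsonlite::write_json(
    list(seed = cfg$seed, n_subjects = nrow(cohort$manifest),
         n_windows = dim(windows$x)[1],
         r_version = as.character(getRversion())),
    file.path(out_dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

write_eval_json <- function(ev, path) {
  jsonlite::write_json(
    list(modality = ev$modality, accuracy = ev$accuracy,
         per_fold_accuracy = ev$per_fold_accuracy,
         confusion = as.data.frame.matrix(ev$confusion),
         per_class = ev$per_class),
    path, auto_unbox = TRUE, digits = NA)
  utils::write.csv(as.data.frame.matrix(ev$confusion),
                   sub("\\.json$", "_confusion.csv", path))
  invisible(path)
}

#' Paired pre/post rehabilitation comparison
#'
#' Per shared numeric metric: mean difference (post minus pre), 95\%
#' confidence interval, and two-tailed paired t-test p-value, on subjects
#' present in both tables. Unmatched subjects are listed and excluded with
#' a warning. A metric whose paired differences are all identical (e.g.
#' identical tables) gets a degenerate CI at the observed difference and an
#' `NA` p-value.
#'
#' @param pre_features,post_features Data frames with a subject column and
#'   numeric metric columns (e.g. from [feature_table()]).
#' @param paired_by Subject column name (default `"subject_id"`).
#' @param conf_level Confidence level (default 0.95).
#' @param holm Apply a Holm adjustment across metrics (default FALSE,
#'   matching per-metric reporting).
#' @return Data frame: metric, n, mean_pre, mean_post, mean_diff, ci_lower,
#'   ci_upper, p_value, significant (p < 0.05).
#' @export
rehab_compare <- function(pre_features, post_features,
                          paired_by = "subject_id", conf_level = 0.95,
                          holm = FALSE) {
  stopifnot(paired_by %in% names(pre_features),
            paired_by %in% names(post_features))
  common <- intersect(pre_features[[paired_by]], post_features[[paired_by]])
  dropped <- setdiff(union(pre_features[[paired_by]],
                           post_features[[paired_by]]), common)
  if (length(dropped) > 0)
    warning("unmatched subjects excluded: ", paste(dropped, collapse = ", "))
  if (length(common) < 2)
    stop("need at least 2 matched subjects", call. = FALSE)
  pre <- pre_features[match(common, pre_features[[paired_by]]), ]
  post <- post_features[match(common, post_features[[paired_by]]), ]
  metrics <- intersect(names(pre), names(post))
  metrics <- metrics[vapply(metrics, function(m)
    is.numeric(pre[[m]]) && is.numeric(post[[m]]), logical(1))]
  metrics <- setdiff(metrics, paired_by)
  rows <- lapply(metrics, function(m) {
    d <- post[[m]] - pre[[m]]
    ok <- is.finite(d)
    d <- d[ok]
    if (length(d) < 2) return(NULL)
    if (stats::sd(d) == 0) {
      md <- mean(d)
      data.frame(metric = m, n = length(d), mean_pre = mean(pre[[m]][ok]),
                 mean_post = mean(post[[m]][ok]), mean_diff = md,
                 ci_lower = md, ci_upper = md, p_value = NA_real_)
    } else {
      tt <- stats::t.test(d, conf.level = conf_level)
      data.frame(metric = m, n = length(d), mean_pre = mean(pre[[m]][ok]),
                 mean_post = mean(post[[m]][ok]), mean_diff = mean(d),
                 ci_lower = tt$conf.int[1], ci_upper = tt$conf.int[2],
                 p_value = tt$p.value)
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (holm) out$p_value <- stats::p.adjust(out$p_value, "holm")
  out$significant <- !is.na(out$p_value) & out$p_value < 0.05
  out
}
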