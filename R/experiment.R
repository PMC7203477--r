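#' Experiment configuration
#'
#' Bundles everything [run_experiment()] needs: the dataset source, which
#' pair-classification variations and which baselines to run, training and
#' sampling settings, dictionary/evaluation sizes, and an output directory.
#'
#' @param dataset An [epoch_dataset()] (already binned + scaled), a
#'   container path for [load_epochs()], or a [synthetic_config()] (raw
#'   data are generated, then binned by `bin_factor` and scaled by
#'   `scale_divisor`).
#' @param variations Subset of
#'   `c("single_single", "single_average", "average_average")`.
#' @param baselines Subset of `c("dnn", "svm", "smlr")`.
#' @param baseline_mode Subset of `c("single", "averaged")` — train/test
#'   baselines on raw trials, 20-trial within-class averages, or both.
#' @param train_cfg A [train_config()].
#' @param arch An [architecture_spec()] for the comparator (the baseline
#'   network reuses its hidden layers).
#' @param comparator `"ptc"` trains the network; `"chance"` substitutes an
#'   uninformative [stub_comparator()] (no training), a diagnostic mode
#'   that validates the evaluation protocol recovers chance.
#' @param n_dictionary Dictionary entries per class (default 100).
#' @param n_test_averages Test-side averages per class for
#'   average/average (default 80).
#' @param average_k Trials per average (default 20).
#' @param n_queries Optional cap on single-trial queries per fold.
#' @param folds Optional integer vector restricting which LOSO folds run.
#' @param bin_factor,scale_divisor Preprocessing applied when `dataset` is
#'   raw or synthetic.
#' @param seed Master seed; every stage derives its own seed from it.
#' @param out_dir Optional directory for results CSV, confusion CSVs and a
#'   JSON run manifest.
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(dataset,
                              variations = c("single_single", "single_average",
                                             "average_average"),
                              baselines = character(),
                              baseline_mode = "single",
                              train_cfg = train_config(),
                              arch = architecture_spec(),
                              comparator = c("ptc", "chance"),
                              n_dictionary = 100,
                              n_test_averages = 80,
                              average_k = 20,
                              n_queries = NULL,
                              folds = NULL,
                              bin_factor = 10,
                              scale_divisor = 20,
                              seed = 1L,
                              out_dir = NULL) {
  comparator <- match.arg(comparator)
  variations <- match.arg(variations, several.ok = TRUE,
                          choices = c("single_single", "single_average",
                                      "average_average"))
  if (length(baselines) > 0) {
    baselines <- match.arg(baselines, c("dnn", "svm", "smlr"),
                           several.ok = TRUE)
  }
  if (length(variations) + length(baselines) == 0) {
    stop_invalid("select at least one variation or baseline")
  }
  structure(list(dataset = dataset, variations = variations,
                 baselines = baselines, baseline_mode = baseline_mode,
                 train_cfg = train_cfg, arch = arch, comparator = comparator,
                 n_dictionary = n_dictionary,
                 n_test_averages = n_test_averages,
                 average_k = average_k, n_queries = n_queries,
                 folds = folds, bin_factor = bin_factor,
                 scale_divisor = scale_divisor,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "experiment_config")
}

resolve_dataset <- function(cfg) {
  ds <- cfg$dataset
  if (inherits(ds, "synthetic_config")) {
    ds <- generate_dataset(ds)
  } else if (is.character(ds)) {
    ds <- load_epochs(ds)
  }
  if (!ds$is_binned && cfg$bin_factor > 1) {
    ds <- bin_time_average(ds, cfg$bin_factor)
  }
  if (!is.null(cfg$scale_divisor) && cfg$scale_divisor != 1) {
    ds <- scale_amplitudes(ds, cfg$scale_divisor)
  }
  ds
}

#' Run the full experiment over LOSO folds
#'
#' For every selected analysis, fold and iteration: trains the model (or
#' substitutes the chance stub), evaluates same/different accuracy on the
#' held-out subject's evaluation pair set and multiclass accuracy through
#' the dictionary rule, and collects one results row.  Baselines contribute
#' multiclass accuracy only.  Rerunning with the same master seed
#' reproduces the table exactly.
#'
#' @param cfg An [experiment_config()].
#' @return A `ptc_results` tibble: one row per analysis x subject x
#'   iteration, with accuracies and confusion matrices as list-columns.
#' @export
run_experiment <- function(cfg) {
  ds <- resolve_dataset(cfg)
  folds <- make_loso_folds(ds, seed = derive_seed(cfg$seed, 1L))
  if (!is.null(cfg$folds)) folds <- folds[cfg$folds]
  rows <- list()

  for (variation in cfg$variations) {
    for (fold in folds) {
      rows_v <- run_variation_fold(cfg, ds, variation, fold)
      rows <- c(rows, rows_v)
    }
  }
  for (bl in cfg$baselines) {
    if (bl %in% c("svm", "smlr")) {
      for (mode in cfg$baseline_mode) {
        rows <- c(rows, list(baseline_linear(ds, bl, folds, mode = mode,
                                             average_k = cfg$average_k,
                                             seed = derive_seed(cfg$seed, 5L))))
      }
    } else {
      for (mode in cfg$baseline_mode) {
        rows <- c(rows, list(baseline_dnn(ds, folds, cfg, mode = mode)))
      }
    }
  }
  out <- bind_rows(rows)
  class(out) <- c("ptc_results", class(out))
  if (!is.null(cfg$out_dir)) write_results(cfg, out)
  out
}

run_variation_fold <- function(cfg, ds, variation, fold) {
  plan <- pair_sampling_plan(scheme = variation,
                             batch_size = cfg$train_cfg$batch_size,
                             average_k = cfg$average_k)
  test_pool <- filter_subjects(ds, fold$test_subject)
  known_pool <- filter_subjects(ds, c(fold$train_subjects, fold$val_subjects))
  results <- if (cfg$comparator == "chance") {
    list(structure(list(model = stub_comparator("uninformative"),
                        history = tibble(), best_epoch = NA_integer_,
                        test_subject = fold$test_subject,
                        fold = fold$fold, iteration = 1L,
                        seed = fold$seed),
                   class = "ptc_train_result"))
  } else {
    run_iterations(function(s) build_ptc_network(cfg$arch, seed = s),
                   ds, fold, plan, cfg$train_cfg)
  }
  lapply(results, function(res) {
    eval_seed <- derive_seed(fold$seed, 3L, res$iteration %||% 1L)
    ps <- build_test_pairs(test_pool, known_pool, scheme = variation,
                           n_per_class = cfg$n_dictionary,
                           n_test_averages = cfg$n_test_averages,
                           average_k = cfg$average_k,
                           n_queries = cfg$n_queries,
                           seed = eval_seed)
    sd_eval <- withr::with_seed(derive_seed(eval_seed, 1L),
                                evaluate_same_different(res$model, ps))
    dict <- build_dictionary(known_pool, n_per_class = cfg$n_dictionary,
                             entry_kind = if (variation == "single_single")
                               "single" else "average",
                             k = cfg$average_k, seed = derive_seed(eval_seed, 2L))
    mc_eval <- withr::with_seed(
      derive_seed(eval_seed, 4L),
      evaluate_multiclass(res$model, test_pool, dict, scheme = variation,
                          n_test_averages = cfg$n_test_averages,
                          average_k = cfg$average_k,
                          n_queries = cfg$n_queries,
                          seed = derive_seed(eval_seed, 3L)))
    tibble(analysis = variation, kind = "ptc",
           subject = fold$test_subject,
           iteration = res$iteration %||% 1L,
           sd_accuracy = sd_eval$accuracy,
           mc_accuracy = mc_eval$accuracy,
           sd_confusion = list(sd_eval$confusion),
           mc_confusion = list(mc_eval$confusion),
           best_epoch = res$best_epoch)
  })
}

#' Aggregate per-iteration results the canonical way
#'
#' Mean accuracies per subject (across iterations) first, then the mean
#' across subjects, per analysis.
#'
#' @param results A `ptc_results` tibble from [run_experiment()].
#' @return A tibble with one row per analysis: `sd_accuracy`,
#'   `mc_accuracy`, `n_subjects`.
#' @export
aggregate_results <- function(results) {
  results %>%
    group_by(.data$analysis, .data$kind, .data$subject) %>%
    summarise(sd_accuracy = mean(.data$sd_accuracy),
              mc_accuracy = mean(.data$mc_accuracy), .groups = "drop_last") %>%
    summarise(sd_accuracy = mean(.data$sd_accuracy),
              mc_accuracy = mean(.data$mc_accuracy),
              n_subjects = dplyr::n(), .groups = "drop")
}

#' Paired t-test between two subject-aligned accuracy vectors
#'
#' @param acc_a,acc_b Equal-length (>= 2) numeric vectors, one entry per
#'   subject, in the same subject order.
#' @return A tibble with `t`, `df`, `p`.
#' @export
paired_ttest <- function(acc_a, acc_b) {
  if (length(acc_a) != length(acc_b) || length(acc_a) < 2) {
    stop_invalid("need two subject-aligned vectors of equal length >= 2")
  }
  d <- acc_a - acc_b
  if (sd(d) < 1e-10 * (1 + abs(mean(d)))) {
    stop_degenerate("paired differences have zero variance; t is undefined")
  }
  ht <- t.test(acc_a, acc_b, paired = TRUE)
  tibble(t = unname(ht$statistic), df = unname(ht$parameter),
         p = ht$p.value)
}

# flatten (trial, channel, bin) to trials x features
flatten_trials <- function(ds) {
  d <- dim(ds$data)
  matrix(ds$data, d[1], d[2] * d[3])
}

# within-class k-averaged version of a pool (n_out averages per class)
averaged_pool <- function(ds, k, n_out_per_class) {
  d <- dim(ds$data)
  cls_idx <- split(seq_len(d[1]), ds$meta$class_label)
  out <- list(); cls <- character(); subj <- character()
  for (cl in names(cls_idx)) {
    for (r in seq_len(n_out_per_class)) {
      pick <- sample(cls_idx[[cl]], min(k, length(cls_idx[[cl]])))
      out[[length(out) + 1L]] <- colMeans(ds$data[pick, , , drop = FALSE],
                                          dims = 1)
      cls <- c(cls, cl)
      subj <- c(subj, ds$meta$subject_id[pick[1]])
    }
  }
  arr <- array(0, c(length(out), d[2], d[3]))
  for (i in seq_along(out)) arr[i, , ] <- out[[i]]
  epoch_dataset(arr, tibble(subject_id = subj,
                            trial_id = seq_along(out),
                            class_label = cls),
                sampling_rate = ds$sampling_rate, labels = ds$labels,
                is_binned = ds$is_binned, bin_width = ds$bin_width)
}

#' Linear SVM / sparse multinomial logistic regression baselines
#'
#' Trains per LOSO fold on all non-test subjects (no validation set) on the
#' flattened binned + scaled features.  The SVM is a linear-kernel
#' max-margin classifier with C chosen from
#' `c(1e-4, 1e-3, 1e-2, 0.1, 1, 10, 100)`; the sparse multinomial logistic
#' regression is L1-penalized with lambda chosen from
#' `c(1e-3, 1e-2, 0.1, 1, 10, 100, 1000)` (glmnet's penalty scale).
#' Hyperparameters are selected by subject-grouped 5-fold cross-validation
#' within the training pool.
#'
#' @param ds Binned + scaled [epoch_dataset()].
#' @param kind `"svm"` or `"smlr"`.
#' @param folds Fold plans from [make_loso_folds()].
#' @param mode `"single"` (raw trials) or `"averaged"` (20-trial
#'   within-class averages for both train and test pools).
#' @param average_k Trials per average in averaged mode.
#' @param grid Optional hyperparameter grid override.
#' @param seed Seed for averaging draws and inner-CV assignment.
#' @return A `ptc_results`-shaped tibble, one row per subject.
#' @export
baseline_linear <- function(ds, kind = c("svm", "smlr"), folds,
                            mode = c("single", "averaged"), average_k = 20,
                            grid = NULL, seed = NULL) {
  kind <- match.arg(kind)
  mode <- match.arg(mode)
  grid <- grid %||% if (kind == "svm") {
    c(1e-4, 1e-3, 1e-2, 0.1, 1, 10, 100)
  } else {
    c(1e-3, 1e-2, 0.1, 1, 10, 100, 1000)
  }
  rows <- lapply(folds, function(fold) {
    withr::with_seed(derive_seed(seed %||% 0L, fold$fold, 11L), {
      train_pool <- filter_subjects(
        ds, c(fold$train_subjects, fold$val_subjects))
      test_pool <- filter_subjects(ds, fold$test_subject)
      if (mode == "averaged") {
        n_tr <- max(3L, floor(min(table(train_pool$meta$class_label)) / 2))
        train_pool <- averaged_pool(train_pool, average_k, n_tr)
        n_te <- max(3L, min(table(test_pool$meta$class_label)))
        test_pool <- averaged_pool(test_pool, average_k, n_te)
      }
      if (length(unique(train_pool$meta$class_label)) < 2) {
        stop_capacity("training pool is degenerate (single class)")
      }
      x_tr <- flatten_trials(train_pool)
      y_tr <- factor(train_pool$meta$class_label, levels = ds$labels)
      x_te <- flatten_trials(test_pool)
      y_te <- factor(test_pool$meta$class_label, levels = ds$labels)
      best <- select_hyperparameter(x_tr, y_tr, train_pool$meta$subject_id,
                                    kind, grid)
      fit <- fit_linear(x_tr, y_tr, kind, best)
      pred <- predict_linear(fit, x_te, kind, best)
      tab <- table(y_te, factor(pred, levels = levels(y_te)))
      tibble(analysis = paste0(kind, "_", mode), kind = "baseline",
             subject = fold$test_subject, iteration = 1L,
             sd_accuracy = NA_real_,
             mc_accuracy = 100 * mean(pred == as.character(y_te)),
             sd_confusion = list(NULL),
             mc_confusion = list(unclass(as.matrix(
               sweep(tab, 1, pmax(rowSums(tab), 1), "/")))),
             best_epoch = NA_integer_,
             hyperparameter = best)
    })
  })
  out <- bind_rows(rows)
  class(out) <- c("ptc_results", class(out))
  out
}

select_hyperparameter <- function(x, y, subjects, kind, grid) {
  groups <- unique(subjects)
  n_folds <- min(5L, length(groups))
  if (n_folds < 2L) {
    assign_cv <- sample(rep_len(seq_len(2L), length(y)))
  } else {
    gfold <- sample(rep_len(seq_len(n_folds), length(groups)))
    assign_cv <- gfold[match(subjects, groups)]
  }
  acc <- numeric(length(grid))
  for (f in seq_len(max(assign_cv))) {
    tr <- assign_cv != f
    if (length(unique(y[tr])) < 2 || sum(!tr) == 0) next
    for (gi in seq_along(grid)) {
      fit <- fit_linear(x[tr, , drop = FALSE], droplevels(y[tr]), kind,
                        grid[gi])
      pred <- predict_linear(fit, x[!tr, , drop = FALSE], kind, grid[gi])
      acc[gi] <- acc[gi] + mean(pred == as.character(y[!tr]))
    }
  }
  grid[which.max(acc)]
}

fit_linear <- function(x, y, kind, hp) {
  if (kind == "svm") {
    e1071::svm(x, y, kernel = "linear", cost = hp, scale = FALSE)
  } else {
    glmnet::glmnet(x, y, family = "multinomial", alpha = 1,
                   lambda = hp, standardize = FALSE)
  }
}

predict_linear <- function(fit, x, kind, hp) {
  if (kind == "svm") {
    as.character(predict(fit, x))
  } else {
    as.character(predict(fit, x, s = hp, type = "class"))
  }
}

#' Deep-learning multiclass baseline over LOSO folds
#'
#' Trains the single-trial network (identical hidden layers to the
#' comparator) per fold and iteration on raw or averaged trials and scores
#' multiclass accuracy on the held-out subject.
#'
#' @param ds Binned + scaled [epoch_dataset()].
#' @param folds Fold plans.
#' @param cfg An [experiment_config()].
#' @param mode `"single"` or `"averaged"`.
#' @return A `ptc_results`-shaped tibble, one row per subject x iteration.
#' @export
baseline_dnn <- function(ds, folds, cfg, mode = c("single", "averaged")) {
  mode <- match.arg(mode)
  K <- length(ds$labels)
  rows <- list()
  for (fold in folds) {
    ds_use <- ds
    if (mode == "averaged") {
      ds_use <- withr::with_seed(derive_seed(cfg$seed, fold$fold, 21L), {
        pools <- lapply(unique(ds$meta$subject_id), function(s) {
          p <- filter_subjects(ds, s)
          averaged_pool(p, cfg$average_k,
                        max(3L, min(table(p$meta$class_label))))
        })
        merged <- pools[[1]]
        for (p in pools[-1]) {
          merged$data <- abind3(merged$data, p$data)
          p$meta$trial_id <- p$meta$trial_id + max(merged$meta$trial_id)
          merged$meta <- bind_rows(merged$meta, p$meta)
        }
        merged$meta$trial_id <- seq_len(nrow(merged$meta))
        merged
      })
    }
    results <- run_iterations(
      function(s) build_baseline_network(cfg$arch, n_classes = K, seed = s),
      ds_use, fold, plan = NULL, cfg = cfg$train_cfg)
    test_pool <- filter_subjects(ds_use, fold$test_subject)
    for (res in results) {
      probs <- forward_trials(res$model, test_pool$data)
      pred <- ds$labels[max.col(probs, ties.method = "first")]
      truth <- test_pool$meta$class_label
      tab <- table(factor(truth, ds$labels), factor(pred, ds$labels))
      rows[[length(rows) + 1L]] <- tibble(
        analysis = paste0("dnn_", mode), kind = "baseline",
        subject = fold$test_subject, iteration = res$iteration,
        sd_accuracy = NA_real_,
        mc_accuracy = 100 * mean(pred == truth),
        sd_confusion = list(NULL),
        mc_confusion = list(unclass(as.matrix(
          sweep(tab, 1, pmax(rowSums(tab), 1), "/")))),
        best_epoch = res$best_epoch)
    }
  }
  out <- bind_rows(rows)
  class(out) <- c("ptc_results", class(out))
  out
}

abind3 <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, c(da[1] + db[1], da[2], da[3]))
  out[seq_len(da[1]), , ] <- a
  out[da[1] + seq_len(db[1]), , ] <- b
  out
}

write_results <- function(cfg, results) {
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  flat <- results %>%
    select(-dplyr::any_of(c("sd_confusion", "mc_confusion")))
  readr::write_csv(flat, file.path(cfg$out_dir, "results.csv"))
  agg <- aggregate_results(results)
  readr::write_csv(agg, file.path(cfg$out_dir, "summary.csv"))
  for (i in seq_len(nrow(results))) {
    cm <- results$mc_confusion[[i]]
    if (is.null(cm)) next
    fn <- sprintf("confusion_%s_%s_it%d.csv", results$analysis[i],
                  results$subject[i], results$iteration[i])
    utils::write.csv(cm, file.path(cfg$out_dir, fn))
  }
  manifest <- list(seed = cfg$seed,
                   variations = cfg$variations,
                   baselines = cfg$baselines,
                   comparator = cfg$comparator,
                   n_dictionary = cfg$n_dictionary,
                   n_test_averages = cfg$n_test_averages,
                   average_k = cfg$average_k,
                   train = unclass(cfg$train_cfg),
                   arch = unclass(cfg$arch),
                   timestamp = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null", na = "null")
  invisible(cfg$out_dir)
}
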