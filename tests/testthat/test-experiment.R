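test_that("paired t-tests handle symmetric, equal and constant differences", {
  r <- paired_ttest(c(1, 2, 3), c(3, 2, 1))
  expect_equal(r$t, 0)
  expect_equal(r$p, 1)
  expect_error(paired_ttest(c(1, 2, 3), c(1, 2, 3)),
               class = "ptcnet_degenerate_error")
  expect_error(paired_ttest(c(0.6, 0.7, 0.8, 0.9), c(0.5, 0.6, 0.7, 0.8)),
               class = "ptcnet_degenerate_error")
  expect_error(paired_ttest(1:3, 1:4), class = "ptcnet_invalid_argument")
  # sanity on a real difference
  r2 <- paired_ttest(c(0.6, 0.72, 0.8, 0.95), c(0.5, 0.61, 0.7, 0.80))
  expect_gt(r2$t, 0)
  expect_lt(r2$p, 0.05)
})

test_that("linear baselines separate a separable toy at any grid point", {
  ds <- tiny_dataset(n_subjects = 4, n_per = 8, noise_sd = 0.1)
  folds <- make_loso_folds(ds, seed = 1)[1]
  for (kind in c("svm", "smlr")) {
    rows <- baseline_linear(ds, kind, folds, mode = "single", seed = 2)
    expect_equal(nrow(rows), 1L)
    expect_equal(rows$mc_accuracy, 100)
  }
})

test_that("heavy sparsity on pure noise collapses the classifier to chance", {
  ds <- tiny_dataset(n_subjects = 4, n_per = 15, noise_sd = 1, seed = 3)
  # erase class structure: labels permuted, signals pure noise
  withr::with_seed(4, {
    ds$data[] <- rnorm(length(ds$data))
    ds$meta$class_label <- sample(ds$meta$class_label)
  })
  folds <- make_loso_folds(ds, seed = 1)[1]
  rows <- baseline_linear(ds, "smlr", folds, mode = "single",
                          grid = 1000, seed = 5)
  expect_lt(abs(rows$mc_accuracy - 100 / 3), 22)
})

test_that("the single-trial network baseline trains and emits class probabilities", {
  ds <- tiny_dataset(n_subjects = 4, n_per = 10, noise_sd = 0.3)
  m <- build_baseline_network(tiny_spec(input_maps = 1, output_units = 3),
                              n_classes = 3, seed = 1)
  probs <- forward_trials(m, ds$data[1:7, , , drop = FALSE])
  expect_equal(dim(probs), c(7L, 3L))
  expect_equal(rowSums(probs), rep(1, 7), tolerance = 1e-6)

  folds <- make_loso_folds(ds, seed = 2)[1]
  cfg <- experiment_config(ds, variations = "single_single",
                           baselines = "dnn",
                           train_cfg = train_config(batch_size = 16,
                                                    max_epochs = 8,
                                                    patience_epochs = 10,
                                                    n_iterations = 1,
                                                    val_pairs = 24),
                           arch = tiny_spec(), seed = 3)
  rows <- baseline_dnn(ds, folds, cfg, mode = "single")
  expect_equal(nrow(rows), 1L)
  # separable toy: the trained baseline should beat chance comfortably
  expect_gt(rows$mc_accuracy, 50)
})

test_that("a chance-stub experiment recovers the chance row end to end", {
  ds <- tiny_dataset(n_subjects = 4, n_per = 12, noise_sd = 0.5)
  cfg <- experiment_config(ds,
                           variations = c("single_single", "average_average"),
                           comparator = "chance",
                           n_dictionary = 10, n_test_averages = 12,
                           average_k = 4, folds = 1:2,
                           bin_factor = 1, scale_divisor = 1,
                           seed = 7)
  res <- run_experiment(cfg)
  expect_s3_class(res, "ptc_results")
  expect_equal(nrow(res), 4L)  # 2 variations x 2 folds
  agg <- aggregate_results(res)
  # Table-2-shaped: one row per analysis with both accuracy columns
  expect_setequal(agg$analysis, c("single_single", "average_average"))
  expect_true(all(abs(agg$sd_accuracy - 50) < 15))
  expect_true(all(abs(agg$mc_accuracy - 100 / 3) < 20))
})

test_that("experiments are reproducible under the same master seed", {
  ds <- tiny_dataset(n_subjects = 4, n_per = 10, noise_sd = 0.5)
  cfg <- experiment_config(ds, variations = "single_single",
                           comparator = "chance", n_dictionary = 6,
                           folds = 1, bin_factor = 1, scale_divisor = 1,
                           seed = 11)
  r1 <- run_experiment(cfg)
  r2 <- run_experiment(cfg)
  expect_equal(r1$sd_accuracy, r2$sd_accuracy)
  expect_equal(r1$mc_accuracy, r2$mc_accuracy)
})

test_that("results aggregate iterations within subject before subjects", {
  rows <- tibble::tibble(
    analysis = "single_single", kind = "ptc",
    subject = c("S1", "S1", "S2"), iteration = c(1L, 2L, 1L),
    sd_accuracy = c(60, 70, 50), mc_accuracy = c(40, 50, 30))
  class(rows) <- c("ptc_results", class(rows))
  agg <- aggregate_results(rows)
  # S1 averages to 65/45 first, then averages with S2's 50/30
  expect_equal(agg$sd_accuracy, (65 + 50) / 2)
  expect_equal(agg$mc_accuracy, (45 + 30) / 2)
})

test_that("experiment outputs are persisted and re-aggregable", {
  ds <- tiny_dataset(n_subjects = 4, n_per = 10, noise_sd = 0.5)
  out_dir <- withr::local_tempdir()
  cfg <- experiment_config(ds, variations = "single_single",
                           comparator = "chance", n_dictionary = 5,
                           folds = 1:2, bin_factor = 1, scale_divisor = 1,
                           seed = 13, out_dir = out_dir)
  res <- run_experiment(cfg)
  expect_true(file.exists(file.path(out_dir, "results.csv")))
  expect_true(file.exists(file.path(out_dir, "summary.csv")))
  expect_true(file.exists(file.path(out_dir, "manifest.json")))
  # every reported mean is reproducible from the persisted per-fold records
  flat <- readr::read_csv(file.path(out_dir, "results.csv"),
                          show_col_types = FALSE)
  summ <- readr::read_csv(file.path(out_dir, "summary.csv"),
                          show_col_types = FALSE)
  redo <- flat %>%
    dplyr::group_by(analysis, subject) %>%
    dplyr::summarise(sd = mean(sd_accuracy), mc = mean(mc_accuracy),
                     .groups = "drop") %>%
    dplyr::summarise(sd = mean(sd), mc = mean(mc))
  expect_equal(redo$sd, summ$sd_accuracy)
  expect_equal(redo$mc, summ$mc_accuracy)
})

test_that("tidiers and autoplot methods return the expected shapes", {
  ds <- tiny_dataset(n_subjects = 4, n_per = 10, noise_sd = 0.3)
  fold <- make_loso_folds(ds, seed = 1)[[1]]
  cfg <- train_config(batch_size = 8, max_epochs = 2, patience_epochs = 3,
                      n_iterations = 1, val_pairs = 16)
  res <- train_model(build_ptc_network(tiny_spec(), seed = 1), ds, fold,
                     pair_sampling_plan("single_single", batch_size = 8),
                     cfg, seed = 2)
  td <- generics::tidy(res)
  expect_true(all(c("epoch", "metric", "value") %in% names(td)))
  gl <- generics::glance(res)
  expect_equal(nrow(gl), 1L)
  expect_s3_class(autoplot(res), "ggplot")

  test_pool <- filter_subjects(ds, fold$test_subject)
  known_pool <- filter_subjects(ds, c(fold$train_subjects, fold$val_subjects))
  ps <- build_test_pairs(test_pool, known_pool, "single_single",
                         n_per_class = 5, seed = 3)
  ev <- evaluate_same_different(oracle_stub(), ps)
  expect_s3_class(autoplot(ev), "ggplot")
  dict <- build_dictionary(known_pool, 5, "single", seed = 4)
  mc <- evaluate_multiclass(oracle_stub(), test_pool, dict, "single_single")
  expect_s3_class(autoplot(mc), "ggplot")
})
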