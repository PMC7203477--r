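test_that("ordered pair types count K same and K(K-1) different", {
  t3 <- enumerate_pair_types(3)
  expect_equal(nrow(t3), 9L)
  expect_equal(sum(t3$label == "same"), 3L)
  expect_equal(sum(t3$label == "different"), 6L)
  t1 <- enumerate_pair_types(1)
  expect_equal(table(factor(t1$label, c("same", "different"))),
               table(factor("same", c("same", "different"))))
  t2 <- enumerate_pair_types(2)
  expect_equal(sum(t2$label == "same"), 2L)
  expect_equal(sum(t2$label == "different"), 2L)
  expect_error(enumerate_pair_types(character()),
               class = "ptcnet_invalid_argument")
})

test_that("a pool of n single trials yields n(n-1) distinct ordered pairs", {
  ds <- tiny_dataset(n_subjects = 1, n_per = 20, classes = "a")
  keys <- paste0(ds$meta$subject_id, "#", ds$meta$trial_id)
  pairs <- tidyr::expand_grid(a = keys, b = keys)
  pairs <- pairs[pairs$a != pairs$b, ]
  expect_equal(nrow(dplyr::distinct(pairs)), 20 * 19)
  expect_equal(nrow(dplyr::distinct(pairs)), 380)
})

test_that("trial averages are unweighted means of k distinct trials", {
  ds <- tiny_dataset(n_subjects = 2, n_per = 6, noise_sd = 1)
  av <- withr::with_seed(1, make_trial_average(ds, "b", 4))
  expect_length(av$sources, 4L)
  expect_equal(length(unique(av$sources)), 4L)
  idx <- match(av$sources,
               paste0(ds$meta$subject_id, "#", ds$meta$trial_id))
  expect_equal(av$signal, colMeans(ds$data[idx, , , drop = FALSE], dims = 1))
  expect_true(all(ds$meta$class_label[idx] == "b"))

  # k = 1 returns the sampled trial itself
  one <- withr::with_seed(2, make_trial_average(ds, "a", 1))
  i1 <- match(one$sources, paste0(ds$meta$subject_id, "#", ds$meta$trial_id))
  expect_equal(one$signal, ds$data[i1, , ])

  # forced mean: two 1x1 trials of 0 and 2 average to 1
  small <- epoch_dataset(array(c(0, 2), c(2, 1, 1)),
                         tibble::tibble(subject_id = "S1", trial_id = 1:2,
                                        class_label = "a"), 250)
  expect_equal(as.numeric(make_trial_average(small, "a", 2)$signal), 1)

  # identical trials average to themselves
  const <- tiny_dataset(n_subjects = 1, n_per = 5, noise_sd = 0)
  avc <- withr::with_seed(3, make_trial_average(const, "c", 3))
  expect_equal(avc$signal, const$data[match(avc$sources[1],
    paste0(const$meta$subject_id, "#", const$meta$trial_id)), , ])

  # exclusion is honored and shortfalls raise capacity errors
  keys <- paste0(ds$meta$subject_id, "#", ds$meta$trial_id)
  excl <- keys[ds$meta$class_label == "b"][1:10]
  expect_error(make_trial_average(ds, "b", 4, exclude = excl),
               class = "ptcnet_capacity_error")
})

test_that("minibatch sampling hits the 2:1 weighted type distribution", {
  ds <- tiny_dataset(n_subjects = 3, n_per = 30, noise_sd = 1)
  plan <- pair_sampling_plan("single_single", batch_size = 144)
  n <- 12000
  mb <- sample_pair_minibatch(ds, plan, n = n, seed = 42)
  p_same <- mean(mb$meta$label == "same")
  se <- sqrt(0.25 / n)
  expect_lt(abs(p_same - 0.5), 3 * se)
  # each same type ~ 1/6, each different type ~ 1/12
  type <- paste(mb$meta$class_a, mb$meta$class_b)
  freq <- table(type) / n
  same_types <- paste(ds$labels, ds$labels)
  for (ty in names(freq)) {
    target <- if (ty %in% same_types) 1 / 6 else 1 / 12
    expect_lt(abs(freq[[ty]] - target),
              3 * sqrt(target * (1 - target) / n))
  }
})

test_that("sampled pairs honor label and disjointness invariants", {
  ds <- tiny_dataset(n_subjects = 3, n_per = 45, noise_sd = 1)
  for (scheme in c("single_single", "single_average", "average_average")) {
    plan <- pair_sampling_plan(scheme, batch_size = 50, average_k = 5)
    mb <- sample_pair_minibatch(ds, plan, n = 400, seed = 11)
    expect_equal(mb$meta$label,
                 ifelse(mb$meta$class_a == mb$meta$class_b,
                        "same", "different"))
    overlaps <- mapply(function(a, b) length(intersect(a, b)),
                       mb$meta$sources_a, mb$meta$sources_b)
    expect_true(all(overlaps == 0))  # covers self-pairing exclusion too
    k_a <- if (scheme == "average_average") 5L else 1L
    k_b <- if (scheme == "single_single") 1L else 5L
    expect_true(all(lengths(mb$meta$sources_a) == k_a))
    expect_true(all(lengths(mb$meta$sources_b) == k_b))
  }
})

test_that("pair sampling is reproducible under a fixed seed", {
  ds <- tiny_dataset(n_subjects = 3, n_per = 20, noise_sd = 1)
  plan <- pair_sampling_plan("average_average", average_k = 4)
  a <- sample_pair_minibatch(ds, plan, n = 60, seed = 5)
  b <- sample_pair_minibatch(ds, plan, n = 60, seed = 5)
  expect_identical(a$pairs, b$pairs)
  expect_identical(a$meta$label, b$meta$label)
})

test_that("the same-subject switch restricts single/single same pairs", {
  ds <- tiny_dataset(n_subjects = 4, n_per = 10, noise_sd = 1)
  plan <- pair_sampling_plan("single_single", allow_same_subject = FALSE)
  mb <- sample_pair_minibatch(ds, plan, n = 300, seed = 2)
  same_rows <- mb$meta$label == "same"
  subj_a <- sub("#.*$", "", vapply(mb$meta$sources_a, `[`, "", 1))
  subj_b <- sub("#.*$", "", vapply(mb$meta$sources_b, `[`, "", 1))
  expect_true(all(subj_a[same_rows] != subj_b[same_rows]))
})

test_that("capacity shortfalls raise informative errors", {
  ds <- tiny_dataset(n_subjects = 1, n_per = 3)
  plan <- pair_sampling_plan("average_average", average_k = 2)
  expect_error(sample_pair_minibatch(ds, plan, n = 4, seed = 1),
               class = "ptcnet_capacity_error")
})

test_that("test pair sets cross queries with the known-side set", {
  ds <- tiny_dataset(n_subjects = 4, n_per = 25, noise_sd = 1)
  test_pool <- filter_subjects(ds, "S01")
  known_pool <- filter_subjects(ds, c("S02", "S03", "S04"))

  # one test trial against 100 known signals over 3 classes = 300 comparisons
  one <- subset_trials(test_pool, 1)
  ps1 <- build_test_pairs(one, known_pool, "single_single",
                          n_per_class = 25, seed = 3)
  expect_equal(nrow(ps1$index), 75L)
  ps_full <- build_test_pairs(one, known_pool, "single_single",
                              n_per_class = 25, seed = 3)
  expect_equal(nrow(ps_full$index), 1L * 3L * 25L)

  # zero test trials -> empty evaluation set
  none <- subset_trials(test_pool, integer())
  ps0 <- build_test_pairs(none, known_pool, "single_single",
                          n_per_class = 5, seed = 3)
  expect_equal(nrow(ps0$index), 0L)

  # labels mark same-class pairings
  ps <- build_test_pairs(test_pool, known_pool, "single_average",
                         n_per_class = 5, average_k = 3, seed = 4)
  qcl <- ps$query_meta$class[ps$index$query]
  ecl <- ps$entry_meta$class[ps$index$entry]
  expect_equal(ps$index$label,
               ifelse(qcl == ecl, "same", "different"))

  # pools sharing subjects are rejected
  expect_error(build_test_pairs(test_pool, ds, "single_single"),
               class = "ptcnet_invalid_argument")
})

test_that("average/average test sets reuse trials across but not within averages", {
  ds <- tiny_dataset(n_subjects = 4, n_per = 22, noise_sd = 1)
  test_pool <- filter_subjects(ds, "S01")
  known_pool <- filter_subjects(ds, c("S02", "S03", "S04"))
  ps <- build_test_pairs(test_pool, known_pool, "average_average",
                         n_per_class = 4, n_test_averages = 30,
                         average_k = 20, seed = 5)
  # 30 averages of 20 from 22 trials/class forces reuse across averages
  expect_equal(nrow(ps$query_meta), 90L)
  within_ok <- vapply(ps$query_meta$sources,
                      function(s) length(unique(s)) == 20L, logical(1))
  expect_true(all(within_ok))
  all_src <- unlist(ps$query_meta$sources)
  expect_gt(length(all_src), length(unique(all_src)))  # reuse happened
  # every query-side source is the test subject's
  expect_true(all(startsWith(all_src, "S01#")))
})
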