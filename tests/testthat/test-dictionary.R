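test_that("dictionaries hold n_per_class entries per class with provenance", {
  ds <- tiny_dataset(n_subjects = 3, n_per = 12, noise_sd = 0.5)
  d <- build_dictionary(ds, n_per_class = 10, entry_kind = "single", seed = 1)
  expect_equal(dim(d$entries)[1], 30L)
  expect_equal(as.numeric(table(d$meta$class)), rep(10, 3))
  # singles are drawn without replacement and stored verbatim
  expect_equal(length(unique(unlist(d$meta$sources))), 30L)
  keys <- paste0(ds$meta$subject_id, "#", ds$meta$trial_id)
  i <- match(d$meta$sources[[7]], keys)
  expect_equal(d$entries[7, , ], ds$data[i, , ])

  # n_per_class = 1 single: the sampled trial itself
  d1 <- build_dictionary(ds, n_per_class = 1, entry_kind = "single", seed = 2)
  expect_equal(dim(d1$entries)[1], 3L)

  # averaged entries carry k distinct same-class sources
  da <- build_dictionary(ds, n_per_class = 6, entry_kind = "average", k = 5,
                         seed = 3)
  expect_true(all(lengths(da$meta$sources) == 5L))
  for (r in seq_len(nrow(da$meta))) {
    src_idx <- match(da$meta$sources[[r]], keys)
    expect_equal(length(unique(src_idx)), 5L)
    expect_true(all(ds$meta$class_label[src_idx] == da$meta$class[r]))
  }
  expect_error(build_dictionary(ds, n_per_class = 50, entry_kind = "single"),
               class = "ptcnet_capacity_error")
})

test_that("an oracle comparator makes the dictionary rule always correct", {
  ds <- tiny_dataset(n_subjects = 3, n_per = 8)
  dict <- build_dictionary(ds, n_per_class = 5, entry_kind = "single",
                           seed = 4)
  stub <- oracle_stub()
  for (k in 1:3) {
    query <- matrix(k, 2, 6)  # class-k-shaped signal
    dec <- classify_with_dictionary(stub, query, dict)
    expect_equal(dec$predicted_class, ds$labels[k])
    expect_equal(dec$scores$score[k], 1)
    expect_equal(sum(dec$scores$score), 1)
  }
})

test_that("classify_with_dictionary matches a brute-force double loop exactly", {
  ds <- tiny_dataset(n_subjects = 3, n_per = 10, noise_sd = 1)
  spec <- tiny_spec()
  m <- build_ptc_network(spec, seed = 5)
  dict <- build_dictionary(ds, n_per_class = 6, entry_kind = "single",
                           seed = 6)
  withr::with_seed(7, {
    for (q in 1:8) {
      query <- array(rnorm(2 * 6), c(2, 6))
      dec <- classify_with_dictionary(m, query, dict)
      # brute force: one forward_pair call per (class, entry)
      scores <- sapply(ds$labels, function(cl) {
        rows <- which(dict$meta$class == cl)
        mean(vapply(rows, function(r) {
          pair <- array(0, c(1, 2, 2, 6))
          pair[1, 1, , ] <- query
          pair[1, 2, , ] <- dict$entries[r, , ]
          forward_pair(m, pair)[1, "same"]
        }, numeric(1)))
      })
      expect_equal(dec$scores$score, unname(scores), tolerance = 1e-12)
      expect_equal(dec$predicted_class,
                   ds$labels[which.max(scores)])
    }
  })
})

test_that("argmax ties break deterministically toward the lowest class index", {
  ds <- tiny_dataset(n_subjects = 3, n_per = 4)
  dict <- build_dictionary(ds, n_per_class = 3, entry_kind = "single",
                           seed = 8)
  dec <- classify_with_dictionary(stub_comparator("fixed", p_same = 0.4),
                                  matrix(0, 2, 6), dict)
  expect_equal(dec$predicted_class, ds$labels[1])
})

test_that("same/different evaluation tabulates decisions and normalizes rows", {
  ds <- tiny_dataset(n_subjects = 4, n_per = 10)
  test_pool <- filter_subjects(ds, "S01")
  known_pool <- filter_subjects(ds, c("S02", "S03", "S04"))
  ps <- build_test_pairs(test_pool, known_pool, "single_single",
                         n_per_class = 5, seed = 9)
  # the oracle stub reads the class from the signal: perfect separation
  ev <- evaluate_same_different(oracle_stub(), ps)
  expect_equal(ev$accuracy, 100)
  expect_equal(unname(ev$confusion), matrix(c(100, 0, 0, 100), 2, 2))
  # rows always sum to 100
  u <- withr::with_seed(10,
    evaluate_same_different(stub_comparator("uninformative"), ps))
  expect_equal(unname(rowSums(u$confusion)), c(100, 100), tolerance = 0.01)
  # imbalanced sets (1 same : 2 different classes) use balanced accuracy
  expect_equal(u$accuracy, mean(diag(u$confusion)))
  empty <- ps; empty$index <- ps$index[0, ]
  expect_error(evaluate_same_different(oracle_stub(), empty),
               class = "ptcnet_invalid_argument")
})

test_that("multiclass evaluation recovers oracle accuracy and row proportions", {
  ds <- tiny_dataset(n_subjects = 4, n_per = 10)
  test_pool <- filter_subjects(ds, "S01")
  known_pool <- filter_subjects(ds, c("S02", "S03", "S04"))
  dict <- build_dictionary(known_pool, n_per_class = 5,
                           entry_kind = "single", seed = 11)
  ev <- evaluate_multiclass(oracle_stub(), test_pool, dict, "single_single")
  expect_equal(ev$accuracy, 100)
  expect_equal(unname(diag(ev$confusion)), rep(1, 3))
  expect_equal(unname(rowSums(ev$confusion)), rep(1, 3), tolerance = 1e-9)
  # uninformative comparator sits at chance over a reasonable query count
  ev0 <- withr::with_seed(12,
    evaluate_multiclass(stub_comparator("uninformative"), test_pool, dict,
                        "single_single"))
  expect_lt(abs(ev0$accuracy - 100 / 3), 25)  # 30 queries: loose sanity band
})

test_that("dictionary capacity and empty-class errors are raised", {
  ds <- tiny_dataset(n_subjects = 2, n_per = 3)
  dict <- build_dictionary(ds, n_per_class = 2, entry_kind = "single",
                           seed = 13)
  dict$meta$class[dict$meta$class == "a"] <- "b"  # class a now empty
  expect_error(
    classify_with_dictionary(stub_comparator("fixed"), matrix(0, 2, 6), dict),
    class = "ptcnet_configuration_error")
})

test_that("dictionaries and pair sets round-trip through their containers", {
  ds <- tiny_dataset(n_subjects = 4, n_per = 10, noise_sd = 0.5)
  test_pool <- filter_subjects(ds, "S01")
  known_pool <- filter_subjects(ds, c("S02", "S03", "S04"))

  dict <- build_dictionary(known_pool, n_per_class = 4,
                           entry_kind = "average", k = 3, seed = 21)
  p1 <- file.path(withr::local_tempdir(), "dict")
  save_dictionary(dict, p1)
  back <- load_dictionary(p1)
  expect_identical(back$entries, dict$entries)
  expect_equal(back$meta$class, dict$meta$class)
  expect_equal(back$meta$sources, dict$meta$sources)
  expect_equal(back$labels, dict$labels)

  ps <- build_test_pairs(test_pool, known_pool, "single_average",
                         n_per_class = 4, average_k = 3, seed = 22)
  p2 <- file.path(withr::local_tempdir(), "ps")
  save_pair_set(ps, p2)
  back2 <- load_pair_set(p2)
  expect_identical(back2$queries, ps$queries)
  expect_identical(back2$entries, ps$entries)
  expect_equal(back2$index$label, ps$index$label)
  expect_equal(back2$query_meta$sources, ps$query_meta$sources)
  # a reloaded set scores identically
  m <- build_ptc_network(tiny_spec(), seed = 23)
  expect_equal(evaluate_same_different(m, back2)$accuracy,
               evaluate_same_different(m, ps)$accuracy)
  expect_error(load_pair_set(p1), class = "ptcnet_format_error")
})
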