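test_that("default generator emulates the study geometry and trial counts", {
  cfg <- synthetic_config(n_subjects = 4, seed = 3)
  ds <- generate_dataset(cfg)
  expect_equal(dim(ds$data)[2:3], c(31, 370))
  expect_equal(ds$sampling_rate, 250)
  counts <- table(ds$meta$subject_id, ds$meta$class_label)
  expect_true(all(counts >= 60 & counts <= 70))
  # at the canonical 37 subjects the total lands in the thousands band the
  # per-subject range implies: 37 * 3 * [60, 70]
  full <- synthetic_config(seed = 3)
  n_expected <- full$n_subjects * 3 * 60:70
  expect_true(min(n_expected) == 6660 && max(n_expected) == 7770)
})

test_that("the generator is deterministic under a fixed seed", {
  cfg <- synthetic_config(n_subjects = 3, trials_per_class = c(5, 6), seed = 9)
  a <- generate_dataset(cfg)
  b <- generate_dataset(cfg)
  expect_identical(a$data, b$data)
  expect_identical(a$meta, b$meta)
  cfg2 <- cfg; cfg2$seed <- 10L
  c <- generate_dataset(cfg2)
  expect_false(identical(a$data, c$data))
})

test_that("without noise, jitter or lapses all trials of a class are identical", {
  cfg <- synthetic_config(n_subjects = 2, trials_per_class = c(4, 4),
                          noise_sd = 0, lapse_prob = 0, trial_jitter_sd = 0,
                          seed = 5)
  ds <- generate_dataset(cfg)
  idx <- which(ds$meta$subject_id == "S01" & ds$meta$class_label == "face")
  for (i in idx[-1]) {
    expect_equal(ds$data[i, , ], ds$data[idx[1], , ])
  }
  # and they equal the exposed ground-truth template
  expect_equal(ds$data[idx[1], , ], class_template(cfg, "face", 1))
})

test_that("templates expose the class/subject ground truth", {
  cfg <- synthetic_config(n_subjects = 2, seed = 4)
  zero <- cfg
  zero$components <- lapply(zero$components, function(cmp) {
    cmp$amplitude_per_class <- c(0, 0, 0); cmp
  })
  expect_equal(class_template(zero, 1, 1), matrix(0, 31, 370))
  # equal amplitudes for two classes give identical templates
  eq <- cfg
  eq$components <- lapply(eq$components, function(cmp) {
    cmp$amplitude_per_class[2] <- cmp$amplitude_per_class[1]; cmp
  })
  expect_equal(class_template(eq, 1, 2), class_template(eq, 2, 2))
  expect_error(class_template(cfg, 7, 1), class = "ptcnet_invalid_argument")
  expect_error(class_template(cfg, 1, 99), class = "ptcnet_invalid_argument")
})

test_that("high-SNR trials correlate best with their own class template", {
  cfg <- synthetic_config(n_subjects = 4, trials_per_class = c(90, 90),
                          noise_sd = 2, lapse_prob = 0, seed = 21)
  ds <- generate_dataset(cfg)
  n <- n_trials(ds)  # >= 1000 trials
  expect_gte(n, 1000)
  effs_cor <- matrix(0, n, 3)
  templates <- lapply(1:4, function(s) {
    lapply(1:3, function(k) as.vector(class_template(cfg, k, s)))
  })
  subj_of <- as.integer(sub("S", "", ds$meta$subject_id))
  for (i in seq_len(n)) {
    x <- as.vector(ds$data[i, , ])
    effs_cor[i, ] <- vapply(templates[[subj_of[i]]],
                            function(tp) cor(x, tp), numeric(1))
  }
  own <- effs_cor[cbind(seq_len(n), match(ds$meta$class_label, cfg$classes))]
  other <- (rowSums(effs_cor) - own) / 2
  expect_gt(mean(own), mean(other))
})

test_that("with lapse_prob = 1 trials carry no class signal", {
  cfg <- synthetic_config(n_subjects = 2, trials_per_class = c(40, 40),
                          lapse_prob = 1, seed = 6)
  ds <- generate_dataset(cfg)
  expect_true(all(ds$meta$lapse))
  cors <- vapply(seq_len(n_trials(ds)), function(i) {
    s <- as.integer(sub("S", "", ds$meta$subject_id[i]))
    k <- match(ds$meta$class_label[i], cfg$classes)
    cor(as.vector(ds$data[i, , ]), as.vector(class_template(cfg, k, s)))
  }, numeric(1))
  # mean within-class trial-template correlation is 0 within Monte-Carlo error
  se <- sd(cors) / sqrt(length(cors))
  expect_lt(abs(mean(cors)), 3 * se + 1e-3)
})

test_that("trial variance decomposes into signal plus stationary AR(1) noise", {
  # noise-only: variance should match sd^2 / (1 - phi^2)
  noise_cfg <- synthetic_config(n_subjects = 1, trials_per_class = c(30, 30),
                                n_channels = 4, noise_sd = 8,
                                noise_autocorr = 0.6, lapse_prob = 1, seed = 12)
  ds_n <- generate_dataset(noise_cfg)
  expect_gte(length(ds_n$data), 1e4)
  expect_equal(var(as.vector(ds_n$data)), 64 / (1 - 0.36), tolerance = 0.05)

  # signal + noise: total variance = signal variance + noise variance
  cfg <- synthetic_config(n_subjects = 1, trials_per_class = c(30, 30),
                          n_channels = 4, noise_sd = 8, noise_autocorr = 0.6,
                          lapse_prob = 0, trial_jitter_sd = 0, seed = 12)
  cfg$components <- lapply(default_components(4), function(cmp) cmp)
  ds_s <- generate_dataset(cfg)
  sig_cfg <- cfg; sig_cfg$noise_sd <- 1e-9
  ds_sig <- generate_dataset(sig_cfg)
  v_total <- var(as.vector(ds_s$data))
  v_sig <- var(as.vector(ds_sig$data))
  expect_equal(v_total, v_sig + 64 / (1 - 0.36), tolerance = 0.05)
})

test_that("factor-20 scaling brings amplitudes approximately into -1..1", {
  cfg <- synthetic_config(n_subjects = 4, seed = 8)
  ds <- scale_amplitudes(generate_dataset(cfg), 20)
  expect_gte(mean(abs(ds$data) <= 3), 0.95)
  # and the bulk genuinely sits in the unit band
  expect_gte(mean(abs(ds$data) <= 1), 0.8)
})

test_that("generator configs round-trip through YAML", {
  path <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(list(n_subjects = 3, trials_per_class = c(5, 6),
                        noise_sd = 4, seed = 2), path)
  cfg <- read_synthetic_config(path)
  expect_s3_class(cfg, "synthetic_config")
  expect_equal(cfg$n_subjects, 3L)
  expect_equal(cfg$noise_sd, 4)
  ds <- generate_dataset(cfg)
  expect_equal(length(unique(ds$meta$subject_id)), 3L)
})

test_that("degenerate generator configs are rejected", {
  expect_error(synthetic_config(n_subjects = 0),
               class = "ptcnet_invalid_argument")
  expect_error(synthetic_config(classes = character()),
               class = "ptcnet_invalid_argument")
  expect_error(synthetic_config(noise_autocorr = 1),
               class = "ptcnet_invalid_argument")
  expect_error(synthetic_config(lapse_prob = 1.5),
               class = "ptcnet_invalid_argument")
})
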