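# Shared fixtures: everything is generated in code at test time.

# tiny deterministic dataset: `n_per` trials per class per subject,
# class k trials have constant amplitude k (class recoverable from content)
tiny_dataset <- function(n_subjects = 3, n_per = 4, n_channels = 2,
                         n_timepoints = 6, classes = c("a", "b", "c"),
                         noise_sd = 0, seed = 1) {
  withr::with_seed(seed, {
    n <- n_subjects * n_per * length(classes)
    data <- array(0, c(n, n_channels, n_timepoints))
    subject_id <- character(n); trial_id <- integer(n); cl <- character(n)
    i <- 0L
    for (s in seq_len(n_subjects)) {
      tid <- 0L
      for (k in seq_along(classes)) {
        for (r in seq_len(n_per)) {
          i <- i + 1L; tid <- tid + 1L
          data[i, , ] <- k + rnorm(n_channels * n_timepoints, 0, noise_sd)
          subject_id[i] <- sprintf("S%02d", s)
          trial_id[i] <- tid
          cl[i] <- classes[k]
        }
      }
    }
    epoch_dataset(data, tibble::tibble(subject_id = subject_id,
                                       trial_id = trial_id,
                                       class_label = cl),
                  sampling_rate = 250, labels = classes)
  })
}

# a small architecture for cheap network tests; the spatial shape matches
# the (2 channels x 6 timepoints) trials of tiny_dataset()
tiny_spec <- function(input_maps = 2, output_units = 2, dropout = 0) {
  architecture_spec(input_maps = input_maps, spatial_shape = c(2, 6),
                    filters = c(3, 5), kernel = c(3, 3),
                    reduction_filters = 2, dense_widths = c(8, 4),
                    output_units = output_units, dropout = dropout)
}

# stub that recovers the class from the constant-amplitude signals used by
# tiny_dataset(): P(same) = 1 iff both sides round to the same class index
oracle_stub <- function() {
  stub_comparator("custom", fn = function(a, b) {
    n <- if (length(dim(a)) == 3) dim(a)[1] else 1L
    if (length(dim(a)) == 2) {
      as.numeric(round(mean(a)) == round(mean(b)))
    } else {
      sapply(seq_len(n), function(i) {
        as.numeric(round(mean(a[i, , ])) == round(mean(b[i, , ])))
      })
    }
  })
}

# closed-form trainable-parameter count, derived independently from the
# layer shapes (used as the oracle for the built models)
param_count_oracle <- function(spec) {
  kk <- prod(spec$kernel)
  total <- 2 * spec$input_maps            # input batch-norm
  c_prev <- spec$input_maps
  for (f in spec$filters) {
    total <- total + (c_prev * kk + 1) * f  # conv weights + bias
    c_cat <- c_prev + f
    total <- total + 2 * c_cat              # block batch-norm
    c_prev <- c_cat
  }
  total <- total + (c_prev * kk + 1) * spec$reduction_filters
  widths <- c(prod(spec$spatial_shape) * spec$reduction_filters,
              spec$dense_widths, spec$output_units)
  for (i in seq_len(length(widths) - 1)) {
    total <- total + widths[i] * widths[i + 1] + widths[i + 1]
  }
  total
}
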