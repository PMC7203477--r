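#' Declarative architecture of the pair comparator / baseline network
#'
#' The canonical network is four densely skip-connected convolutional
#' blocks.  Each block applies a zero-padded `kernel` convolution, a leaky
#' rectified linear activation, concatenates the result with the block's
#' input (which already carries every earlier block's output — DenseNet-style
#' concatenation), and batch-normalizes the concatenation.  A final
#' convolution reduces to `reduction_filters` maps, which are flattened into
#' the fully connected head.  With the defaults the post-concatenation
#' channel progression for a paired input is 14, 38, 74, 122, and the
#' flattened head sees `3 * 31 * 37` features.
#'
#' @param input_maps 2 for the paired comparator, 1 for the single-trial
#'   baseline.
#' @param spatial_shape `(channels, bins)` of one signal image; zero padding
#'   preserves it through every block.
#' @param filters Filters per block, strictly increasing (default
#'   `c(12, 24, 36, 48)` — equal steps from 12 to 48 over four blocks).
#' @param kernel Convolution kernel, odd sizes (default `c(3, 3)`).
#' @param reduction_filters Maps after the reduction convolution (default 3).
#' @param dense_widths Fully connected widths (default `c(64, 32)`).
#' @param output_units 2 (same/different) or the class count for the
#'   baseline; must be >= 2.
#' @param leaky_slope Negative-side slope of the leaky ReLU (default 0.3).
#' @param dropout Dropout proportion on the dense layers (default 0.10),
#'   applied after each hidden dense layer, never on the output.
#' @return An object of class `architecture_spec`.
#' @export
architecture_spec <- function(input_maps = 2,
                              spatial_shape = c(31, 37),
                              filters = c(12, 24, 36, 48),
                              kernel = c(3, 3),
                              reduction_filters = 3,
                              dense_widths = c(64, 32),
                              output_units = 2,
                              leaky_slope = 0.3,
                              dropout = 0.10) {
  if (!input_maps %in% c(1, 2)) {
    stop_config("input_maps must be 1 (baseline) or 2 (pair)")
  }
  if (length(filters) < 1 || any(diff(filters) <= 0)) {
    stop_config("filters must be a strictly increasing sequence")
  }
  if (any(kernel %% 2 != 1)) stop_config("kernel sizes must be odd")
  if (output_units < 2) stop_config("output_units must be >= 2")
  if (dropout < 0 || dropout >= 1) stop_config("dropout must be in [0, 1)")
  if (reduction_filters < 1) stop_config("reduction_filters must be >= 1")
  structure(list(input_maps = as.integer(input_maps),
                 spatial_shape = as.integer(spatial_shape),
                 filters = as.integer(filters),
                 kernel = as.integer(kernel),
                 reduction_filters = as.integer(reduction_filters),
                 dense_widths = as.integer(dense_widths),
                 output_units = as.integer(output_units),
                 leaky_slope = leaky_slope,
                 dropout = dropout),
            class = "architecture_spec")
}

#' Post-concatenation channel progression of a spec
#'
#' `c_0 = input_maps`, `c_i = c_{i-1} + filters_i`: each block's
#' batch-normalization sees the block's new maps plus everything before it.
#'
#' @param spec An [architecture_spec()].
#' @return Integer vector, one entry per block.
#' @export
channel_progression <- function(spec) {
  spec$input_maps + cumsum(spec$filters)
}

new_model <- function(spec, seed) {
  init <- with_seed_if(seed, init_params(spec))
  e <- new.env(parent = emptyenv())
  e$spec <- spec
  e$params <- init$params
  e$running <- init$running
  e$adam <- adam_init(init$params)
  e$seed <- seed
  # output-unit convention, persisted with the weights: unit 1 is P(same)
  # for the pair network, or class k for unit k in the baseline
  e$unit_convention <- if (spec$input_maps == 2) "unit1=same" else "unit_k=class_k"
  class(e) <- c(if (spec$input_maps == 2) "ptc_model" else "baseline_model",
                "nn_model")
  e
}

#' Build the paired-trial comparator network
#'
#' @param spec An [architecture_spec()] with `input_maps = 2` and
#'   `output_units = 2`.
#' @param seed Seed for weight initialization (Glorot uniform).
#' @return A model handle of class `ptc_model`.  Output unit 1 is P(same),
#'   unit 2 is P(different), a convention persisted with saved weights.
#' @export
build_ptc_network <- function(spec = architecture_spec(), seed = NULL) {
  if (spec$input_maps != 2 || spec$output_units != 2) {
    stop_config("the pair comparator needs input_maps = 2 and output_units = 2")
  }
  new_model(spec, seed)
}

#' Build the single-trial baseline network
#'
#' Identical hidden topology to the comparator built from the same spec;
#' only the input accepts one map and the output has one unit per class.
#'
#' @param spec An [architecture_spec()] (its `input_maps`/`output_units`
#'   are overridden).
#' @param n_classes Number of classes (output units).
#' @param seed Seed for weight initialization.
#' @return A model handle of class `baseline_model`.
#' @export
build_baseline_network <- function(spec = architecture_spec(), n_classes = 3,
                                   seed = NULL) {
  spec$input_maps <- 1L
  spec$output_units <- as.integer(n_classes)
  if (n_classes < 2) stop_config("n_classes must be >= 2")
  new_model(spec, seed)
}

#' Count trainable parameters of a built model
#'
#' Sums element counts over every trainable tensor (convolution and dense
#' weights and biases, batch-norm scale and shift; running statistics are
#' not trainable).
#'
#' @param model A model handle.
#' @return Integer parameter count.
#' @export
count_trainable_params <- function(model) {
  sum(vapply(model$params, length, integer(1)))
}

#' Per-layer summary of a built model
#'
#' @param model A model handle.
#' @return A tibble with one row per layer: `layer`, `output_channels`,
#'   `height`, `width`, `n_params`.
#' @export
model_summary <- function(model) {
  spec <- model$spec
  H <- spec$spatial_shape[1]; W <- spec$spatial_shape[2]
  kk <- prod(spec$kernel)
  rows <- list(tibble(layer = "input_batchnorm",
                      output_channels = spec$input_maps,
                      height = H, width = W,
                      n_params = 2L * spec$input_maps))
  c_prev <- spec$input_maps
  for (i in seq_along(spec$filters)) {
    f <- spec$filters[i]
    c_cat <- c_prev + f
    rows[[length(rows) + 1L]] <- tibble(
      layer = sprintf("block%d_conv", i), output_channels = f,
      height = H, width = W, n_params = (c_prev * kk + 1L) * f)
    rows[[length(rows) + 1L]] <- tibble(
      layer = sprintf("block%d_concat_batchnorm", i), output_channels = c_cat,
      height = H, width = W, n_params = 2L * c_cat)
    c_prev <- c_cat
  }
  rows[[length(rows) + 1L]] <- tibble(
    layer = "reduction_conv", output_channels = spec$reduction_filters,
    height = H, width = W,
    n_params = (c_prev * kk + 1L) * spec$reduction_filters)
  widths <- c(H * W * spec$reduction_filters, spec$dense_widths,
              spec$output_units)
  for (i in seq_len(length(widths) - 1L)) {
    nm <- if (i == length(widths) - 1L) "output_dense"
          else sprintf("dense%d", i)
    rows[[length(rows) + 1L]] <- tibble(
      layer = nm, output_channels = widths[i + 1L],
      height = 1L, width = 1L,
      n_params = widths[i] * widths[i + 1L] + widths[i + 1L])
  }
  bind_rows(rows)
}

# reshape a (B, maps, H, W) batch into the engine layout (H*W, maps, B)
to_engine <- function(x) {
  d <- dim(x)
  y <- aperm(x, c(3L, 4L, 2L, 1L))
  dim(y) <- c(d[3] * d[4], d[2], d[1])
  y
}

check_pair_shape <- function(x, spec) {
  d <- dim(x)
  if (length(d) != 4L || d[2] != spec$input_maps ||
      d[3] != spec$spatial_shape[1] || d[4] != spec$spatial_shape[2]) {
    stop_shape(sprintf(
      "expected input of shape (n, %d, %d, %d), got (%s)",
      spec$input_maps, spec$spatial_shape[1], spec$spatial_shape[2],
      paste(d, collapse = ", ")))
  }
}

#' Same/different probabilities for a batch of signal pairs
#'
#' @param model A `ptc_model` handle or a [stub_comparator()].
#' @param pairs Array of shape `(n_pairs, 2, channels, bins)`, or a
#'   `ptc_pair_batch` from [sample_pair_minibatch()].
#' @param chunk_size Pairs per forward chunk (memory control).
#' @return An `n x 2` matrix with columns `same`, `different`; rows sum
#'   to 1 and preserve input order.
#' @export
forward_pair <- function(model, pairs, chunk_size = 128L) {
  UseMethod("forward_pair")
}

#' @export
forward_pair.ptc_model <- function(model, pairs, chunk_size = 128L) {
  if (inherits(pairs, "ptc_pair_batch")) pairs <- pairs$pairs
  check_pair_shape(pairs, model$spec)
  n <- dim(pairs)[1]
  out <- matrix(0, n, 2, dimnames = list(NULL, c("same", "different")))
  for (s in seq(1L, n, by = chunk_size)) {
    rows <- s:min(s + chunk_size - 1L, n)
    x <- to_engine(pairs[rows, , , , drop = FALSE])
    out[rows, ] <- t(nn_forward(model, x, training = FALSE)$probs)
  }
  out
}

#' Class probabilities for a batch of single trials (baseline network)
#'
#' @param model A `baseline_model` handle.
#' @param trials Array `(n, channels, bins)`.
#' @param chunk_size Trials per forward chunk.
#' @return `n x n_classes` probability matrix, rows summing to 1.
#' @export
forward_trials <- function(model, trials, chunk_size = 128L) {
  d <- dim(trials)
  if (length(d) != 3L || d[2] != model$spec$spatial_shape[1] ||
      d[3] != model$spec$spatial_shape[2]) {
    stop_shape("trials must be (n, channels, bins) matching the spec")
  }
  dim(trials) <- c(d[1], 1L, d[2], d[3])
  n <- d[1]
  out <- matrix(0, n, model$spec$output_units)
  for (s in seq(1L, n, by = chunk_size)) {
    rows <- s:min(s + chunk_size - 1L, n)
    x <- to_engine(trials[rows, , , , drop = FALSE])
    out[rows, ] <- t(nn_forward(model, x, training = FALSE)$probs)
  }
  out
}

#' Save / load model weights
#'
#' Weights go to an RDS checkpoint next to a JSON manifest recording the
#' architecture, the output-unit convention and the initialization seed, so
#' a reloaded model can never silently flip its same/different units.
#'
#' @param model A model handle.
#' @param path Basename; writes `<path>.rds` and `<path>.json`.
#' @return `path`, invisibly.
#' @export
save_weights <- function(model, path) {
  saveRDS(list(params = model$params, running = model$running),
          paste0(path, ".rds"))
  jsonlite::write_json(
    list(spec = unclass(model$spec), unit_convention = model$unit_convention,
         seed = model$seed, n_params = count_trainable_params(model)),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA, null = "null", na = "null")
  invisible(path)
}

#' @rdname save_weights
#' @export
load_weights <- function(model, path) {
  ck <- readRDS(paste0(path, ".rds"))
  man <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  if (!identical(man$unit_convention, model$unit_convention)) {
    stop_format("checkpoint unit convention does not match the model")
  }
  model$params <- ck$params
  model$running <- ck$running
  invisible(model)
}

#' Stub comparators for protocol validation
#'
#' Drop-in replacements for a trained comparator that let the evaluation
#' protocols be exercised without a network: `"uninformative"` emits
#' symmetric random same/different probabilities independent of the input
#' (chance-recovery checks), `"fixed"` always emits `p_same`, and
#' `"custom"` delegates to `fn(a, b)` receiving the two sides as
#' `(n, channels, bins)` arrays and returning a P(same) vector.
#'
#' @param type One of `"uninformative"`, `"fixed"`, `"custom"`.
#' @param p_same Constant P(same) for `type = "fixed"`.
#' @param fn Function for `type = "custom"`.
#' @return An object of class `stub_comparator` usable wherever a
#'   `ptc_model` is accepted by the evaluation functions.
#' @export
stub_comparator <- function(type = c("uninformative", "fixed", "custom"),
                            p_same = 0.5, fn = NULL) {
  type <- match.arg(type)
  if (type == "custom" && !is.function(fn)) {
    stop_invalid("type = 'custom' needs a function `fn`")
  }
  structure(list(type = type, p_same = p_same, fn = fn),
            class = "stub_comparator")
}

#' @export
forward_pair.stub_comparator <- function(model, pairs, chunk_size = 128L) {
  if (inherits(pairs, "ptc_pair_batch")) pairs <- pairs$pairs
  n <- dim(pairs)[1]
  p <- switch(model$type,
              uninformative = runif(n),
              fixed = rep(model$p_same, n),
              custom = model$fn(pairs[, 1L, , , drop = TRUE],
                                pairs[, 2L, , , drop = TRUE]))
  if (length(p) == 1L) p <- rep(p, n)
  cbind(same = p, different = 1 - p)
}
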