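#' Training configuration
#'
#' Defaults follow the canonical protocol: Adam (step size 1e-3, beta1 0.9,
#' beta2 0.999), batch size 144, early stopping when validation loss fails
#' to improve for 30 epochs, weights restored to the best-validation-loss
#' epoch, 10 iterations per fold.  One "epoch" under dynamic pair
#' generation is `ceiling(n_training_trials / batch_size)` minibatches, so
#' epoch count scales with pool size.
#'
#' @param lr,beta1,beta2 Adam hyperparameters.
#' @param batch_size Pairs per minibatch (default 144).
#' @param patience_epochs Early-stopping patience (default 30).
#' @param max_epochs Hard epoch cap (default 500).
#' @param n_iterations Re-initialization/re-split iterations per fold
#'   (default 10).
#' @param val_pairs Size of the frozen validation pair set evaluated each
#'   epoch (default 288 = two batches).
#' @param resplit_per_iteration Re-randomize the 80/20 train/validation
#'   subject split on every iteration (default TRUE).
#' @return An object of class `train_config`.
#' @export
train_config <- function(lr = 1e-3, beta1 = 0.9, beta2 = 0.999,
                         batch_size = 144, patience_epochs = 30,
                         max_epochs = 500, n_iterations = 10,
                         val_pairs = 288, resplit_per_iteration = TRUE) {
  if (patience_epochs < 1) stop_invalid("patience_epochs must be >= 1")
  if (batch_size < 1) stop_invalid("batch_size must be >= 1")
  if (n_iterations < 1) stop_invalid("n_iterations must be >= 1")
  structure(list(lr = lr, beta1 = beta1, beta2 = beta2,
                 batch_size = as.integer(batch_size),
                 patience_epochs = as.integer(patience_epochs),
                 max_epochs = as.integer(max_epochs),
                 n_iterations = as.integer(n_iterations),
                 val_pairs = as.integer(val_pairs),
                 resplit_per_iteration = isTRUE(resplit_per_iteration)),
            class = "train_config")
}

#' Leave-one-subject-out fold plans
#'
#' One fold per subject: that subject is the test set; the remaining
#' subjects are split 80/20 (rounded to nearest, at least one validation
#' subject) into training and validation at the subject level, so no
#' subject's trials ever straddle pools.
#'
#' @param ds An [epoch_dataset()] (>= 3 subjects).
#' @param seed Seed controlling the 80/20 splits.
#' @return A list of fold plans: `test_subject`, `train_subjects`,
#'   `val_subjects`, `fold`, `seed`.
#' @export
make_loso_folds <- function(ds, seed = NULL) {
  subjects <- sort(unique(ds$meta$subject_id))
  S <- length(subjects)
  if (S < 3) {
    stop_capacity(sprintf(
      "leave-one-subject-out needs >= 3 subjects, got %d", S))
  }
  lapply(seq_len(S), function(i) {
    fold_seed <- derive_seed(seed %||% 0L, i, 1L)
    rest <- setdiff(subjects, subjects[i])
    split <- split_train_val(rest, fold_seed)
    list(test_subject = subjects[i],
         train_subjects = split$train, val_subjects = split$val,
         fold = i, seed = fold_seed)
  })
}

split_train_val <- function(rest, seed) {
  n_val <- max(1L, round(0.2 * length(rest)))
  withr::with_seed(seed, {
    val <- sort(sample(rest, n_val))
  })
  list(train = setdiff(rest, val), val = val)
}

#' Train a comparator (or baseline) on one fold
#'
#' Optimizes cross-entropy on dynamically sampled training pairs (or
#' labeled single trials for a baseline model), evaluates a frozen
#' validation pair set after each epoch, stops early on the patience rule,
#' and restores the weights of the epoch with the lowest validation loss.
#'
#' @param model A `ptc_model` or `baseline_model` handle (modified in
#'   place and returned inside the result).
#' @param ds The full [epoch_dataset()] (binned + scaled).
#' @param fold A fold plan from [make_loso_folds()].
#' @param plan A [pair_sampling_plan()] (ignored for baseline models).
#' @param cfg A [train_config()].
#' @param seed Seed for minibatch sampling, dropout and validation-set
#'   construction.
#' @return A `ptc_train_result`: per-epoch `history` tibble, `best_epoch`,
#'   the trained `model`, fold/iteration ids.
#' @export
train_model <- function(model, ds, fold, plan, cfg, seed = NULL) {
  train_pool <- filter_subjects(ds, fold$train_subjects)
  val_pool <- filter_subjects(ds, fold$val_subjects)
  baseline <- inherits(model, "baseline_model")
  seed <- seed %||% derive_seed(fold$seed %||% 0L, 7L)

  withr::with_seed(seed, {
    # frozen validation set: stable early-stopping signal
    if (baseline) {
      val_x <- val_pool$data
      val_y <- match(val_pool$meta$class_label, ds$labels)
      if (!is.null(cfg$val_pairs) && length(val_y) > cfg$val_pairs) {
        keep <- sort(sample(length(val_y), cfg$val_pairs))
        val_x <- val_x[keep, , , drop = FALSE]
        val_y <- val_y[keep]
      }
    } else {
      vb <- sample_pair_minibatch(val_pool, plan, n = cfg$val_pairs)
      val_x <- vb$pairs
      val_y <- ifelse(vb$meta$label == "same", 1L, 2L)
    }

    steps <- max(1L, ceiling(n_trials(train_pool) / cfg$batch_size))
    history <- vector("list", cfg$max_epochs)
    best_loss <- Inf
    best_epoch <- 0L
    best_params <- NULL
    best_running <- NULL
    for (ep in seq_len(cfg$max_epochs)) {
      tr_loss <- tr_acc <- 0
      for (st in seq_len(steps)) {
        if (baseline) {
          idx <- sample.int(n_trials(train_pool), cfg$batch_size,
                            replace = TRUE)
          xb <- train_pool$data[idx, , , drop = FALSE]
          dim(xb) <- c(length(idx), 1L, dim(ds$data)[2], dim(ds$data)[3])
          yb <- match(train_pool$meta$class_label[idx], ds$labels)
        } else {
          mb <- sample_pair_minibatch(train_pool, plan, n = cfg$batch_size)
          xb <- mb$pairs
          yb <- ifelse(mb$meta$label == "same", 1L, 2L)
        }
        fwd <- nn_forward(model, to_engine(xb), training = TRUE)
        bwd <- nn_backward(model, fwd$probs, fwd$cache, yb)
        if (!is.finite(bwd$loss)) {
          abort(sprintf("training diverged (non-finite loss) at epoch %d", ep),
                class = "ptcnet_divergence_error")
        }
        adam_step(model, bwd$grads, cfg$lr, cfg$beta1, cfg$beta2)
        tr_loss <- tr_loss + bwd$loss
        tr_acc <- tr_acc + bwd$acc
      }
      val <- eval_batch(model, val_x, val_y)
      history[[ep]] <- tibble(epoch = ep,
                              train_loss = tr_loss / steps,
                              train_acc = tr_acc / steps,
                              val_loss = val$loss, val_acc = val$acc)
      if (val$loss < best_loss) {
        best_loss <- val$loss
        best_epoch <- ep
        best_params <- model$params
        best_running <- model$running
      }
      if (ep - best_epoch >= cfg$patience_epochs) break
    }
    model$params <- best_params
    model$running <- best_running
    structure(list(history = bind_rows(history),
                   best_epoch = best_epoch,
                   model = model,
                   test_subject = fold$test_subject,
                   fold = fold$fold %||% NA_integer_,
                   iteration = NA_integer_,
                   seed = seed),
              class = "ptc_train_result")
  })
}

# evaluation-mode loss/accuracy on a fixed batch
eval_batch <- function(model, x, y, chunk_size = 128L) {
  n <- dim(x)[1]
  if (length(dim(x)) == 3L) dim(x) <- c(n, 1L, dim(x)[2], dim(x)[3])
  loss <- 0
  correct <- 0
  for (s in seq(1L, n, by = chunk_size)) {
    rows <- s:min(s + chunk_size - 1L, n)
    probs <- nn_forward(model, to_engine(x[rows, , , , drop = FALSE]),
                        training = FALSE)$probs
    picked <- probs[cbind(y[rows], seq_along(rows))]
    loss <- loss + sum(-log(pmax(picked, 1e-12)))
    correct <- correct + sum(apply(probs, 2, which.max) == y[rows])
  }
  list(loss = loss / n, acc = correct / n)
}

#' @export
print.ptc_train_result <- function(x, ...) {
  last <- x$history[nrow(x$history), ]
  cat(sprintf(
    "<ptc_train_result> subject %s: %d epochs, best epoch %d (val loss %.4f, val acc %.3f)\n",
    x$test_subject, nrow(x$history), x$best_epoch,
    x$history$val_loss[x$best_epoch], x$history$val_acc[x$best_epoch]))
  invisible(x)
}

#' Run repeated training iterations for one fold
#'
#' Each iteration re-initializes the network (distinct derived seeds) and,
#' by default, re-randomizes the fold's 80/20 train/validation subject
#' split; downstream metrics are averaged over iterations within subject
#' and then across subjects.
#'
#' @param build_fn Function `(seed) -> model handle`.
#' @param ds The full [epoch_dataset()].
#' @param fold A fold plan.
#' @param plan A [pair_sampling_plan()].
#' @param cfg A [train_config()].
#' @return List of `ptc_train_result`, one per iteration.
#' @export
run_iterations <- function(build_fn, ds, fold, plan, cfg) {
  lapply(seq_len(cfg$n_iterations), function(it) {
    it_seed <- derive_seed(fold$seed %||% 0L, 1000L, it)
    f <- fold
    if (cfg$resplit_per_iteration && it > 1L) {
      rest <- c(fold$train_subjects, fold$val_subjects)
      sp <- split_train_val(rest, it_seed)
      f$train_subjects <- sp$train
      f$val_subjects <- sp$val
    }
    model <- build_fn(it_seed)
    res <- tryCatch(
      train_model(model, ds, f, plan, cfg, seed = derive_seed(it_seed, 2L)),
      error = function(e) {
        abort(sprintf("iteration %d failed: %s", it, conditionMessage(e)),
              parent = e, class = "ptcnet_iteration_error")
      })
    res$iteration <- it
    res
  })
}

#' Audit a fold for test-subject leakage
#'
#' Scans the provenance of training/validation pair batches, dictionary
#' entries and evaluation pair sets for any source trial belonging to the
#' fold's test subject.  Returns the offending source keys (empty = clean).
#'
#' @param fold A fold plan.
#' @param ... Any mix of `ptc_pair_batch`, `ptc_dictionary` and
#'   `ptc_pair_set` objects.
#' @return Character vector of leaked `"subject#trial"` keys.
#' @export
audit_leakage <- function(fold, ...) {
  test_subj <- fold$test_subject
  leaked <- character()
  for (obj in list(...)) {
    srcs <- if (inherits(obj, "ptc_pair_batch")) {
      c(unlist(obj$meta$sources_a), unlist(obj$meta$sources_b))
    } else if (inherits(obj, "ptc_dictionary")) {
      unlist(obj$meta$sources)
    } else if (inherits(obj, "ptc_pair_set")) {
      unlist(obj$entry_meta$sources)  # known side only; queries are the test side
    } else {
      character()
    }
    leaked <- c(leaked, srcs[sub("#.*$", "", srcs) == test_subj])
  }
  unique(leaked)
}
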