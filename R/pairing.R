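#' Enumerate ordered class-pair types
#'
#' With K classes there are K^2 ordered (class_a, class_b) pair types: K
#' "same" and K(K-1) "different".  For the canonical 3-class problem that is
#' 3 same and 6 different pairings.
#'
#' @param K Number of classes (or a character vector of class labels).
#' @return A tibble with columns `class_a`, `class_b`, `label`
#'   ("same"/"different").
#' @export
enumerate_pair_types <- function(K) {
  labels <- if (is.character(K)) K else as.character(seq_len(K))
  if (length(labels) < 1) stop_invalid("K must be >= 1")
  tidyr::expand_grid(class_a = labels, class_b = labels) %>%
    mutate(label = ifelse(.data$class_a == .data$class_b,
                          "same", "different"))
}

#' Sampling plan for same/different pair minibatches
#'
#' Types are drawn from a weighted distribution over the K^2 ordered class
#' pairings; "same" pairings get weight 2 and "different" weight 1 so that
#' same and different examples are equally frequent despite there being
#' K(K-1) different pairings versus K same ones.
#'
#' @param scheme One of `"single_single"`, `"single_average"`,
#'   `"average_average"` — whether each slot of the pair holds a raw trial
#'   or a k-trial within-class average.  Slot a is the "unknown"/query side,
#'   slot b the "known"/dictionary side.
#' @param batch_size Examples per minibatch (default 144).
#' @param average_k Trials per average (default 20).
#' @param same_weight,diff_weight Sampling weights per same/different type.
#' @param allow_same_subject For `single_single` same pairs, whether the two
#'   trials may come from the same subject (default TRUE: drawn randomly
#'   from all subjects).  Self-pairing of a trial with itself is always
#'   excluded.
#' @return An object of class `pair_sampling_plan`.
#' @export
pair_sampling_plan <- function(scheme = c("single_single", "single_average",
                                          "average_average"),
                               batch_size = 144, average_k = 20,
                               same_weight = 2, diff_weight = 1,
                               allow_same_subject = TRUE) {
  scheme <- match.arg(scheme)
  if (batch_size < 1) stop_invalid("batch_size must be >= 1")
  if (same_weight <= 0 || diff_weight <= 0) {
    stop_invalid("type weights must be positive")
  }
  if (average_k < 1) stop_invalid("average_k must be >= 1")
  structure(list(scheme = scheme, batch_size = as.integer(batch_size),
                 average_k = as.integer(average_k),
                 same_weight = same_weight, diff_weight = diff_weight,
                 allow_same_subject = isTRUE(allow_same_subject)),
            class = "pair_sampling_plan")
}

# source keys are "subject_id#trial_id" strings
source_key <- function(meta, idx) {
  paste0(meta$subject_id[idx], "#", meta$trial_id[idx])
}

#' Average k randomly chosen trials of one class
#'
#' Draws `k` distinct trials of class `class_k` from the pool (excluding any
#' sources in `exclude`) without replacement and returns their unweighted
#' mean together with the source set, so disjointness can be audited
#' downstream.
#'
#' @param pool An [epoch_dataset()].
#' @param class_k Class label.
#' @param k Number of trials to average.
#' @param exclude Character vector of `"subject#trial"` source keys that
#'   must not enter the average.
#' @return A list with `signal` (channels x bins matrix) and `sources`
#'   (character vector of length `k`).
#' @export
make_trial_average <- function(pool, class_k, k, exclude = character()) {
  keys <- source_key(pool$meta, seq_len(n_trials(pool)))
  eligible <- which(pool$meta$class_label == class_k & !(keys %in% exclude))
  if (length(eligible) < k) {
    stop_capacity(sprintf(
      "class '%s' has %d eligible trials, %d short of the %d needed",
      class_k, length(eligible), k - length(eligible), k))
  }
  idx <- if (length(eligible) == 1L) eligible else sample(eligible, k)
  sig <- colMeans(pool$data[idx, , , drop = FALSE], dims = 1)
  list(signal = sig, sources = keys[idx])
}

scheme_kinds <- function(scheme) {
  switch(scheme,
         single_single = c("single", "single"),
         single_average = c("single", "average"),
         average_average = c("average", "average"))
}

#' Sample one balanced minibatch of pair examples
#'
#' Pair types are drawn from the plan's weighted type distribution; the
#' pair's two signals are then drawn dynamically from the pool (across all
#' its subjects) under the scheme's disjointness rules: the two sides of an
#' average/average pair share no source trials, the single trial of a
#' single/average pair never enters the average, and a single/single same
#' pair never pairs a trial with itself.
#'
#' @param pool Training-pool [epoch_dataset()].
#' @param plan A [pair_sampling_plan()].
#' @param n Number of examples (defaults to `plan$batch_size`).
#' @param seed Optional seed for reproducible draws.
#' @return A `ptc_pair_batch`: list with `pairs` (array
#'   `n x 2 x channels x bins`) and `meta` (tibble with `label`, `class_a`,
#'   `class_b`, `scheme` and list-columns `sources_a`, `sources_b`).
#' @export
sample_pair_minibatch <- function(pool, plan, n = plan$batch_size,
                                  seed = NULL) {
  with_seed_if(seed, {
    types <- enumerate_pair_types(pool$labels)
    w <- ifelse(types$label == "same", plan$same_weight, plan$diff_weight)
    kinds <- scheme_kinds(plan$scheme)
    d <- dim(pool$data)
    keys <- source_key(pool$meta, seq_len(d[1]))
    cls_idx <- split(seq_len(d[1]), pool$meta$class_label)
    k_a <- if (kinds[1] == "average") plan$average_k else 1L
    k_b <- if (kinds[2] == "average") plan$average_k else 1L
    for (cl in pool$labels) {
      avail <- length(cls_idx[[cl]] %||% integer())
      need <- k_a + k_b
      if (avail < need) {
        stop_capacity(sprintf(
          "class '%s' has %d trials, %d short of the %d needed for scheme %s",
          cl, avail, need - avail, need, plan$scheme))
      }
    }
    # draw k distinct trials of a class, avoiding `excl` (integer indices)
    draw <- function(cl, k, excl = integer()) {
      cand <- cls_idx[[cl]]
      if (length(excl) > 0) cand <- setdiff(cand, excl)
      if (length(cand) < k) {
        stop_capacity(sprintf("class '%s' has %d eligible trials, needs %d",
                              cl, length(cand), k))
      }
      if (length(cand) == 1L) cand else sample(cand, k)
    }
    side_signal <- function(idx) {
      if (length(idx) == 1L) pool$data[idx, , ]
      else colMeans(pool$data[idx, , , drop = FALSE], dims = 1)
    }
    pairs <- array(0, c(n, 2L, d[2], d[3]))
    src_a <- vector("list", n)
    src_b <- vector("list", n)
    t_idx <- sample.int(nrow(types), n, replace = TRUE, prob = w)
    for (i in seq_len(n)) {
      cl_a <- types$class_a[t_idx[i]]
      cl_b <- types$class_b[t_idx[i]]
      ia <- draw(cl_a, k_a)
      excl <- if (cl_a == cl_b) ia else integer()
      if (plan$scheme == "single_single" && cl_a == cl_b &&
          !plan$allow_same_subject) {
        excl <- which(pool$meta$subject_id == pool$meta$subject_id[ia])
      }
      ib <- draw(cl_b, k_b, excl = excl)
      pairs[i, 1L, , ] <- side_signal(ia)
      pairs[i, 2L, , ] <- side_signal(ib)
      src_a[[i]] <- keys[ia]
      src_b[[i]] <- keys[ib]
    }
    meta <- tibble(label = types$label[t_idx],
                   class_a = types$class_a[t_idx],
                   class_b = types$class_b[t_idx],
                   scheme = plan$scheme,
                   sources_a = src_a, sources_b = src_b)
    structure(list(pairs = pairs, meta = meta), class = "ptc_pair_batch")
  })
}

#' Build the evaluation pair set for one held-out subject
#'
#' For the single-sided schemes every query (a raw test-subject trial) is
#' paired against `n_per_class` known-side signals per class; for
#' average/average, `n_test_averages` test-side k-trial averages per class
#' are paired against the known-side set.  Known-side signals are raw trials
#' (single/single) or k-trial cross-subject averages (the averaging
#' schemes), drawn from the known pool only.  The set is stored compactly as
#' queries, entries, and an index table; batches are materialized lazily
#' during evaluation.
#'
#' @param test_pool Held-out subject's [epoch_dataset()].
#' @param known_pool Training+validation [epoch_dataset()]; must share no
#'   subjects with `test_pool`.
#' @param scheme Pairing scheme, as in [pair_sampling_plan()].
#' @param n_per_class Known-side signals per class (default 100).
#' @param n_test_averages Test-side averages per class for
#'   `average_average` (default 80).  Each average draws its k trials
#'   without replacement internally; reuse across averages is permitted.
#' @param average_k Trials per average (default 20).
#' @param n_queries Optional cap on the number of single-trial queries
#'   (subsampled evenly across classes); `NULL` keeps every test trial.
#' @param seed Optional seed.
#' @return A `ptc_pair_set`: queries array + metadata, entries array +
#'   metadata, and a pair index tibble with same/different labels.
#' @export
build_test_pairs <- function(test_pool, known_pool,
                             scheme = c("single_single", "single_average",
                                        "average_average"),
                             n_per_class = 100, n_test_averages = 80,
                             average_k = 20, n_queries = NULL, seed = NULL) {
  scheme <- match.arg(scheme)
  shared <- intersect(unique(test_pool$meta$subject_id),
                      unique(known_pool$meta$subject_id))
  if (length(shared) > 0) {
    stop_invalid(paste0("test and known pools share subject(s): ",
                        paste(shared, collapse = ", ")))
  }
  with_seed_if(seed, {
    kinds <- scheme_kinds(scheme)
    d <- dim(known_pool$data)[2:3]
    # known side: a dictionary-like entry set
    entries <- build_dictionary(known_pool, n_per_class = n_per_class,
                                entry_kind = if (kinds[2] == "single")
                                  "single" else "average",
                                k = average_k)
    # query side
    if (kinds[1] == "single") {
      qidx <- seq_len(n_trials(test_pool))
      if (!is.null(n_queries) && n_queries < length(qidx)) {
        per_cl <- split(qidx, test_pool$meta$class_label[qidx])
        take <- ceiling(n_queries / length(per_cl))
        qidx <- sort(unlist(lapply(per_cl, function(ix) {
          if (length(ix) <= take) ix else sample(ix, take)
        }), use.names = FALSE))
      }
      queries <- test_pool$data[qidx, , , drop = FALSE]
      qmeta <- tibble(class = test_pool$meta$class_label[qidx],
                      sources = as.list(source_key(test_pool$meta, qidx)))
    } else {
      qs <- list(); qcl <- character(); qsrc <- list()
      for (cl in known_pool$labels) {
        for (r in seq_len(n_test_averages)) {
          av <- make_trial_average(test_pool, cl, average_k)
          qs[[length(qs) + 1L]] <- av$signal
          qcl <- c(qcl, cl)
          qsrc[[length(qsrc) + 1L]] <- av$sources
        }
      }
      queries <- array(0, c(length(qs), d[1], d[2]))
      for (i in seq_along(qs)) queries[i, , ] <- qs[[i]]
      qmeta <- tibble(class = qcl, sources = qsrc)
    }
    n_q <- dim(queries)[1]
    n_e <- dim(entries$entries)[1]
    index <- tidyr::expand_grid(query = seq_len(n_q), entry = seq_len(n_e))
    index$label <- ifelse(qmeta$class[index$query] ==
                            entries$meta$class[index$entry],
                          "same", "different")
    structure(list(queries = queries, query_meta = qmeta,
                   entries = entries$entries, entry_meta = entries$meta,
                   index = index, scheme = scheme),
              class = "ptc_pair_set")
  })
}

#' @export
print.ptc_pair_set <- function(x, ...) {
  cat(sprintf("<ptc_pair_set> %s: %d queries x %d entries = %d pairs (%d same / %d different)\n",
              x$scheme, dim(x$queries)[1], dim(x$entries)[1], nrow(x$index),
              sum(x$index$label == "same"), sum(x$index$label == "different")))
  invisible(x)
}

# materialize a chunk of a pair set as an (n, 2, H, W) array
materialize_pairs <- function(ps, rows) {
  idx <- ps$index[rows, ]
  d <- dim(ps$queries)[2:3]
  out <- array(0, c(nrow(idx), 2L, d[1], d[2]))
  out[, 1L, , ] <- ps$queries[idx$query, , , drop = FALSE]
  out[, 2L, , ] <- ps$entries[idx$entry, , , drop = FALSE]
  out
}
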