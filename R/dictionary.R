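#' Build a dictionary of known-class entries
#'
#' The dictionary is the "known" side of the multiclass rule: per class,
#' `n_per_class` entries drawn uniformly at random from the known pool
#' (training + validation subjects), either raw single trials (sampled
#' without replacement) or k-trial within-class averages whose k sources
#' are distinct and drawn across subjects (independently per entry, so
#' trials may recur across entries).  Dictionary selection is deliberately
#' naive; optimizing it is out of scope.
#'
#' @param pool Known-pool [epoch_dataset()].
#' @param n_per_class Entries per class (default 100).
#' @param entry_kind `"single"` or `"average"`.
#' @param k Trials per averaged entry (default 20).
#' @param seed Optional seed.
#' @return A `ptc_dictionary`: `entries` array `(n, channels, bins)` and
#'   `meta` tibble (`class`, `kind`, list-column `sources`).
#' @export
build_dictionary <- function(pool, n_per_class = 100,
                             entry_kind = c("single", "average"), k = 20,
                             seed = NULL) {
  entry_kind <- match.arg(entry_kind)
  with_seed_if(seed, {
    d <- dim(pool$data)
    keys <- source_key(pool$meta, seq_len(d[1]))
    cls_idx <- split(seq_len(d[1]), pool$meta$class_label)
    n_tot <- n_per_class * length(pool$labels)
    entries <- array(0, c(n_tot, d[2], d[3]))
    cls <- character(n_tot)
    sources <- vector("list", n_tot)
    i <- 0L
    for (cl in pool$labels) {
      cand <- cls_idx[[cl]] %||% integer()
      need <- if (entry_kind == "single") n_per_class else k
      if (length(cand) < need) {
        stop_capacity(sprintf(
          "class '%s' has %d trials in the known pool, %d short of the %d needed",
          cl, length(cand), need - length(cand), need))
      }
      if (entry_kind == "single") {
        idx <- sample(cand, n_per_class)
        for (r in seq_len(n_per_class)) {
          i <- i + 1L
          entries[i, , ] <- pool$data[idx[r], , ]
          cls[i] <- cl
          sources[[i]] <- keys[idx[r]]
        }
      } else {
        for (r in seq_len(n_per_class)) {
          i <- i + 1L
          pick <- sample(cand, k)
          entries[i, , ] <- colMeans(pool$data[pick, , , drop = FALSE], dims = 1)
          cls[i] <- cl
          sources[[i]] <- keys[pick]
        }
      }
    }
    structure(list(entries = entries,
                   meta = tibble(class = cls, kind = entry_kind,
                                 sources = sources),
                   n_per_class = as.integer(n_per_class),
                   entry_kind = entry_kind, k = as.integer(k),
                   labels = pool$labels),
              class = "ptc_dictionary")
  })
}

#' @export
print.ptc_dictionary <- function(x, ...) {
  cat(sprintf("<ptc_dictionary> %d classes x %d %s entries\n",
              length(x$labels), x$n_per_class,
              if (x$entry_kind == "average") sprintf("%d-trial averaged", x$k)
              else "single-trial"))
  invisible(x)
}

# scores for a batch of queries against every dictionary entry:
# returns n_queries x K matrix of mean within-class P(same)
dictionary_scores <- function(model, queries, dict, chunk_size = 512L,
                              forward_chunk = 128L) {
  dq <- dim(queries)
  n_q <- dq[1]
  n_e <- dim(dict$entries)[1]
  if (n_e == 0 || any(table(factor(dict$meta$class, levels = dict$labels)) == 0)) {
    stop_config("every dictionary class needs at least one entry")
  }
  if (!all(dq[2:3] == dim(dict$entries)[2:3])) {
    stop_shape("query shape does not match dictionary entries")
  }
  K <- length(dict$labels)
  scores <- matrix(0, n_q, K, dimnames = list(NULL, dict$labels))
  cls_of_entry <- factor(dict$meta$class, levels = dict$labels)
  per_class_n <- as.numeric(table(cls_of_entry))
  # iterate over queries in blocks; each block crosses with all entries
  q_per_block <- max(1L, chunk_size %/% n_e)
  for (s in seq(1L, n_q, by = q_per_block)) {
    qr <- s:min(s + q_per_block - 1L, n_q)
    nb <- length(qr) * n_e
    pairs <- array(0, c(nb, 2L, dq[2], dq[3]))
    # query varies slowest so each query occupies a contiguous run
    pairs[, 1L, , ] <- queries[rep(qr, each = n_e), , , drop = FALSE]
    pairs[, 2L, , ] <- dict$entries[rep(seq_len(n_e), times = length(qr)), , ,
                                    drop = FALSE]
    p_same <- forward_pair(model, pairs, chunk_size = forward_chunk)[, "same"]
    for (j in seq_along(qr)) {
      block <- p_same[((j - 1L) * n_e + 1L):(j * n_e)]
      scores[qr[j], ] <- tapply(block, cls_of_entry, mean)
    }
  }
  scores
}

#' Classify one unknown signal with the dictionary rule
#'
#' The query is compared to every dictionary entry with the pair
#' comparator; each comparison's two output units are softmaxed and the
#' P(same) values are averaged within each class.  The predicted class is
#' the argmax of the class scores, ties broken deterministically by the
#' lowest class index.
#'
#' @param model A `ptc_model` or [stub_comparator()].
#' @param query A channels x bins matrix.
#' @param dict A [build_dictionary()] result.
#' @param keep_comparisons Keep the per-entry P(same) record.
#' @return A `dictionary_decision`: tibble of per-class scores, the
#'   predicted class, and optionally the per-comparison record.
#' @export
classify_with_dictionary <- function(model, query, dict,
                                     keep_comparisons = FALSE) {
  q <- array(query, c(1L, dim(query)))
  comparisons <- NULL
  if (keep_comparisons) {
    n_e <- dim(dict$entries)[1]
    pairs <- array(0, c(n_e, 2L, dim(query)[1], dim(query)[2]))
    pairs[, 1L, , ] <- q[rep(1L, n_e), , , drop = FALSE]
    pairs[, 2L, , ] <- dict$entries
    p_same <- forward_pair(model, pairs)[, "same"]
    comparisons <- tibble(entry = seq_len(n_e),
                          class = dict$meta$class, p_same = p_same)
    scores <- tapply(p_same, factor(dict$meta$class, levels = dict$labels),
                     mean)
    scores <- matrix(scores, 1L, dimnames = list(NULL, dict$labels))
  } else {
    scores <- dictionary_scores(model, q, dict)
  }
  pred <- dict$labels[which.max(scores[1L, ])]
  structure(list(scores = tibble(class = dict$labels,
                                 score = as.numeric(scores[1L, ])),
                 predicted_class = pred,
                 comparisons = comparisons),
            class = "dictionary_decision")
}

#' @export
print.dictionary_decision <- function(x, ...) {
  cat(sprintf("<dictionary_decision> predicted: %s\n", x$predicted_class))
  print(x$scores)
  invisible(x)
}

#' Same/different accuracy and confusion over an evaluation pair set
#'
#' Every pair gets an argmax same/different decision.  The confusion matrix
#' rows (actual same / actual different) are normalized to percent.  When
#' the set is imbalanced — as it is under the dictionary-style protocol,
#' where each query meets 1 same class and K-1 different ones — the summary
#' accuracy is the balanced mean of the two row accuracies; with a balanced
#' set it is the plain proportion correct.
#'
#' @param model A `ptc_model` or [stub_comparator()].
#' @param pair_set A [build_test_pairs()] result.
#' @param chunk_size Pairs per forward chunk.
#' @return A `ptc_sd_eval`: `accuracy` (percent), `confusion` (2 x 2
#'   percent, rows = actual), `n_pairs`, and the per-pair decisions tibble.
#' @export
evaluate_same_different <- function(model, pair_set, chunk_size = 512L,
                                    forward_chunk = 128L) {
  n <- nrow(pair_set$index)
  if (n == 0) stop_invalid("empty evaluation pair set")
  p_same <- numeric(n)
  for (s in seq(1L, n, by = chunk_size)) {
    rows <- s:min(s + chunk_size - 1L, n)
    p_same[rows] <- forward_pair(model, materialize_pairs(pair_set, rows),
                                 chunk_size = forward_chunk)[, "same"]
  }
  actual <- pair_set$index$label
  predicted <- ifelse(p_same >= 0.5, "same", "different")
  lev <- c("same", "different")
  tab <- table(factor(actual, lev), factor(predicted, lev))
  confusion <- sweep(tab, 1, pmax(rowSums(tab), 1), "/") * 100
  row_acc <- diag(confusion)
  counts <- rowSums(tab)
  accuracy <- if (length(unique(counts[counts > 0])) == 1L) {
    100 * mean(predicted == actual)
  } else {
    mean(row_acc[counts > 0])
  }
  structure(list(accuracy = accuracy,
                 confusion = unclass(as.matrix(confusion)),
                 n_pairs = n,
                 decisions = tibble(actual = actual, predicted = predicted,
                                    p_same = p_same)),
            class = "ptc_sd_eval")
}

#' @export
print.ptc_sd_eval <- function(x, ...) {
  cat(sprintf("<ptc_sd_eval> accuracy %.2f%% over %d pairs\n",
              x$accuracy, x$n_pairs))
  print(round(x$confusion, 2))
  invisible(x)
}

#' Multiclass accuracy via the dictionary rule
#'
#' Builds the scheme's queries from the held-out subject's pool (every raw
#' trial, optionally capped, for the single-sided schemes; `n_test_averages`
#' k-trial averages per class for average/average), scores each against the
#' dictionary, and tabulates a K x K confusion of row proportions.
#'
#' @param model A `ptc_model` or [stub_comparator()].
#' @param test_pool Held-out subject [epoch_dataset()].
#' @param dict A [build_dictionary()] result (known pool only).
#' @param scheme Pairing scheme.
#' @param n_test_averages Test-side averages per class for
#'   `average_average`.
#' @param average_k Trials per test-side average.
#' @param n_queries Optional cap on single-trial queries.
#' @param seed Optional seed for query construction.
#' @param chunk_size Pairs per forward chunk.
#' @return A `ptc_mc_eval`: `accuracy` (percent), `confusion` (K x K row
#'   proportions), and the per-query decisions tibble.
#' @export
evaluate_multiclass <- function(model, test_pool, dict,
                                scheme = c("single_single", "single_average",
                                           "average_average"),
                                n_test_averages = 80, average_k = 20,
                                n_queries = NULL, seed = NULL,
                                chunk_size = 512L) {
  scheme <- match.arg(scheme)
  with_seed_if(seed, {
    d <- dim(test_pool$data)
    if (scheme == "average_average") {
      qs <- vector("list", 0)
      qcl <- character()
      for (cl in dict$labels) {
        for (r in seq_len(n_test_averages)) {
          av <- make_trial_average(test_pool, cl, average_k)
          qs[[length(qs) + 1L]] <- av$signal
          qcl <- c(qcl, cl)
        }
      }
      queries <- array(0, c(length(qs), d[2], d[3]))
      for (i in seq_along(qs)) queries[i, , ] <- qs[[i]]
    } else {
      qidx <- seq_len(d[1])
      if (!is.null(n_queries) && n_queries < length(qidx)) {
        per_cl <- split(qidx, test_pool$meta$class_label)
        take <- ceiling(n_queries / length(per_cl))
        qidx <- sort(unlist(lapply(per_cl, function(ix) {
          if (length(ix) <= take) ix else sample(ix, take)
        }), use.names = FALSE))
      }
      queries <- test_pool$data[qidx, , , drop = FALSE]
      qcl <- test_pool$meta$class_label[qidx]
    }
    scores <- dictionary_scores(model, queries, dict, chunk_size = chunk_size)
    pred <- dict$labels[max.col(scores, ties.method = "first")]
    lev <- dict$labels
    tab <- table(factor(qcl, lev), factor(pred, lev))
    confusion <- sweep(tab, 1, pmax(rowSums(tab), 1), "/")
    structure(list(accuracy = 100 * mean(pred == qcl),
                   confusion = unclass(as.matrix(confusion)),
                   n_queries = length(qcl),
                   decisions = tibble(actual = qcl, predicted = pred)),
              class = "ptc_mc_eval")
  })
}

#' @export
print.ptc_mc_eval <- function(x, ...) {
  cat(sprintf("<ptc_mc_eval> accuracy %.2f%% over %d queries\n",
              x$accuracy, x$n_queries))
  print(round(x$confusion, 3))
  invisible(x)
}
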