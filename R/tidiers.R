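#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot ggplot aes geom_tile geom_text geom_line
#'   scale_fill_gradient labs theme_minimal facet_wrap
#' @export
ggplot2::autoplot

#' Tidy a training result into its per-epoch history
#'
#' @param x A `ptc_train_result`.
#' @param ... Unused.
#' @return A tibble with one row per epoch and metric:
#'   `epoch`, `metric`, `value`.
#' @export
tidy.ptc_train_result <- function(x, ...) {
  x$history %>%
    tidyr::pivot_longer(-"epoch", names_to = "metric", values_to = "value")
}

#' One-row summary of a training result
#'
#' @param x A `ptc_train_result`.
#' @param ... Unused.
#' @return A one-row tibble: test subject, epochs run, best epoch and its
#'   validation loss/accuracy.
#' @export
glance.ptc_train_result <- function(x, ...) {
  tibble(test_subject = x$test_subject,
         n_epochs = nrow(x$history),
         best_epoch = x$best_epoch,
         val_loss = x$history$val_loss[x$best_epoch],
         val_acc = x$history$val_acc[x$best_epoch])
}

#' @export
autoplot.ptc_train_result <- function(object, ...) {
  tidy(object) %>%
    mutate(set = ifelse(grepl("^train", .data$metric), "train", "validation"),
           quantity = ifelse(grepl("loss$", .data$metric), "loss", "accuracy")) %>%
    ggplot(aes(x = .data$epoch, y = .data$value, colour = .data$set)) +
    geom_line() +
    facet_wrap(~.data$quantity, scales = "free_y") +
    labs(x = "epoch", y = NULL, colour = NULL) +
    theme_minimal()
}

confusion_tibble <- function(cm) {
  as_tibble(as.table(cm), .name_repair = ~ c("actual", "predicted", "value"))
}

#' @export
autoplot.ptc_sd_eval <- function(object, ...) {
  confusion_tibble(object$confusion) %>%
    ggplot(aes(x = .data$predicted, y = .data$actual, fill = .data$value)) +
    geom_tile() +
    geom_text(aes(label = sprintf("%.1f", .data$value))) +
    scale_fill_gradient(low = "white", high = "steelblue", limits = c(0, 100)) +
    labs(title = sprintf("Same/different confusion (accuracy %.2f%%)",
                         object$accuracy),
         fill = "% of row") +
    theme_minimal()
}

#' @export
autoplot.ptc_mc_eval <- function(object, ...) {
  confusion_tibble(object$confusion) %>%
    ggplot(aes(x = .data$predicted, y = .data$actual, fill = .data$value)) +
    geom_tile() +
    geom_text(aes(label = sprintf("%.2f", .data$value))) +
    scale_fill_gradient(low = "white", high = "steelblue", limits = c(0, 1)) +
    labs(title = sprintf("Dictionary confusion (accuracy %.2f%%)",
                         object$accuracy),
         fill = "row prop.") +
    theme_minimal()
}

#' Tidy an experiment results table
#'
#' @param x A `ptc_results` tibble.
#' @param ... Unused.
#' @return The per-row accuracies without list-columns.
#' @export
tidy.ptc_results <- function(x, ...) {
  out <- x %>% select(-dplyr::any_of(c("sd_confusion", "mc_confusion")))
  class(out) <- setdiff(class(out), "ptc_results")
  out
}

#' Aggregated one-row-per-analysis summary of experiment results
#'
#' @param x A `ptc_results` tibble.
#' @param ... Unused.
#' @return The [aggregate_results()] table.
#' @export
glance.ptc_results <- function(x, ...) {
  aggregate_results(x)
}

#' @export
autoplot.ptc_results <- function(object, ...) {
  aggregate_results(object) %>%
    tidyr::pivot_longer(c("sd_accuracy", "mc_accuracy"),
                        names_to = "metric", values_to = "accuracy") %>%
    filter(is.finite(.data$accuracy)) %>%
    mutate(metric = ifelse(.data$metric == "sd_accuracy",
                           "same/different", "dictionary")) %>%
    ggplot(aes(x = .data$analysis, y = .data$accuracy, fill = .data$metric)) +
    ggplot2::geom_col(position = "dodge") +
    labs(x = NULL, y = "accuracy (%)", fill = NULL) +
    theme_minimal()
}
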