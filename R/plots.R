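#' Training-history curves for a fitted model
#'
#' Per-epoch training loss and, when a validation split was used, the five
#' validation metrics.
#'
#' @param object An `pepfusion_model`.
#' @param ... Unused.
#' @return A ggplot object (metric value vs epoch, one facet line per
#'   quantity).
#' @method autoplot pepfusion_model
#' @export
autoplot.pepfusion_model <- function(object, ...) {
  h <- object$history
  metrics <- intersect(c("loss", "precision", "coverage", "accuracy",
                         "absolute_true", "absolute_false"), names(h))
  long <- dplyr::bind_rows(lapply(metrics, function(m)
    tibble::tibble(epoch = h$epoch, metric = m, value = h[[m]])))
  long$metric <- factor(long$metric, levels = metrics)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$epoch, y = .data$value)) +
    ggplot2::geom_line(color = "steelblue") +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "epoch", y = NULL,
                  title = "Training loss and validation metrics") +
    ggplot2::theme_minimal()
}

#' Per-class prediction rates
#'
#' Bar chart comparing, per class, the fraction of peptides predicted
#' positive against the true prevalence — a quick view of which rare
#' classes the model over- or under-calls.
#'
#' @param predictions Tibble from [predict.pepfusion_model()].
#' @param truth Peptide tibble with a `labels` matrix (matched by `id`).
#' @return A ggplot object.
#' @export
plot_class_rates <- function(predictions, truth) {
  m <- match(predictions$id, truth$id)
  if (anyNA(m)) stop("prediction ids missing from `truth`", call. = FALSE)
  yt <- truth$labels[m, , drop = FALSE]
  yp <- predictions$.pred
  cls <- colnames(yt)
  long <- dplyr::bind_rows(
    tibble::tibble(class = cls, rate = colMeans(yt), what = "true"),
    tibble::tibble(class = cls, rate = colMeans(yp), what = "predicted"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$class, y = .data$rate,
                                     fill = .data$what)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "fraction of peptides", fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
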