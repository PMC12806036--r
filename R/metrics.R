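#' Multi-label evaluation metrics
#'
#' The five standard multi-label metrics over N samples and M classes, each
#' averaged over samples:
#' \describe{
#'   \item{precision}{`|y ∩ ŷ| / |ŷ|` — an empty prediction contributes 0
#'     (abstention is penalized).}
#'   \item{coverage}{`|y ∩ ŷ| / |y|`, the fraction of true labels
#'     recovered.}
#'   \item{accuracy}{`|y ∩ ŷ| / |y ∪ ŷ|`, the per-sample Jaccard index.}
#'   \item{absolute_true}{exact-match indicator — 1 only when the predicted
#'     label set is identical to the true set (subset accuracy).}
#'   \item{absolute_false}{`(|y ∪ ŷ| − |y ∩ ŷ|) / M`, the per-sample
#'     Hamming-style error rate.}
#' }
#' The chain `absolute_true <= accuracy <= min(precision, coverage)` always
#' holds.
#'
#' @param Y_true `N x M` binary matrix of true labels; every row must have
#'   at least one positive (coverage is undefined otherwise).
#' @param Y_pred `N x M` binary matrix of predicted labels.
#' @return A one-row tibble with the five metrics plus `n_samples` and
#'   `n_labels`.
#' @export
#' @examples
#' y <- matrix(c(1, 0, 0, 1), 2, 2)
#' multilabel_metrics(y, y)  # perfect prediction: (1, 1, 1, 1, 0)
multilabel_metrics <- function(Y_true, Y_pred) {
  if (!is.matrix(Y_true) || !is.matrix(Y_pred) ||
      !all(dim(Y_true) == dim(Y_pred)))
    stop("Y_true and Y_pred must be matrices of identical shape",
         call. = FALSE)
  if (!all(Y_true %in% c(0, 1)) || !all(Y_pred %in% c(0, 1)))
    stop("label matrices must be binary", call. = FALSE)
  ny <- rowSums(Y_true)
  if (any(ny == 0))
    stop("every true label set must be nonempty (coverage is undefined)",
         call. = FALSE)
  M <- ncol(Y_true)
  inter <- rowSums(Y_true * Y_pred)
  npred <- rowSums(Y_pred)
  uni <- ny + npred - inter
  prec_terms <- ifelse(npred == 0, 0, inter / pmax(npred, 1))
  tibble::tibble(
    precision = mean(prec_terms),
    coverage = mean(inter / ny),
    accuracy = mean(inter / uni),
    absolute_true = mean(inter == uni),
    absolute_false = mean((uni - inter) / M),
    n_samples = nrow(Y_true),
    n_labels = M)
}

#' Serialize a metrics report to JSON
#'
#' Fixed key names matching the five metric terms; numeric values keep full
#' precision. [metrics_from_json()] restores the one-row tibble exactly.
#'
#' @param report One-row tibble from [multilabel_metrics()].
#' @param path Optional path; when given, the JSON is also written there.
#' @return JSON string (invisibly when `path` is given).
#' @export
metrics_to_json <- function(report, path = NULL) {
  keys <- c("precision", "coverage", "accuracy", "absolute_true",
            "absolute_false", "n_samples", "n_labels")
  stopifnot(all(keys %in% names(report)), nrow(report) == 1L)
  txt <- jsonlite::toJSON(as.list(report[, keys]), auto_unbox = TRUE,
                          digits = NA)
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}

#' Restore a metrics report from JSON
#' @param json JSON string or path to a JSON file.
#' @return One-row tibble with the metric fields.
#' @export
metrics_from_json <- function(json) {
  x <- jsonlite::fromJSON(json)
  keys <- c("precision", "coverage", "accuracy", "absolute_true",
            "absolute_false", "n_samples", "n_labels")
  missing <- setdiff(keys, names(x))
  if (length(missing) > 0L)
    stop("missing metric field(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  tibble::as_tibble(x[keys])
}
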