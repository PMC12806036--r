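# Fusion head: concatenated branch features -> fully connected stack with
# ReLU + dropout -> linear layer to n_classes logits -> sigmoid.

fusion_init <- function(d_in, hidden, n_classes) {
  widths <- c(d_in, hidden)
  fcs <- lapply(seq_len(length(widths) - 1L), function(i)
    dense_init(widths[i], widths[i + 1L]))
  names(fcs) <- paste0("fc", seq_along(fcs))
  list(fcs = fcs, out = dense_init(widths[length(widths)], n_classes))
}

fusion_fwd <- function(X, p, dropout = 0.2, train = FALSE) {
  caches <- list(); h <- X
  for (i in seq_along(p$fcs)) {
    dn <- dense_fwd(h, p$fcs[[i]])
    ac <- relu_fwd(dn$out)
    dr <- dropout_fwd(ac$out, dropout, train)
    caches[[i]] <- list(dn = dn$cache, ac = ac$cache, dr = dr$cache)
    h <- dr$out
  }
  fin <- dense_fwd(h, p$out)
  probs <- 1 / (1 + exp(-fin$out))
  list(probs = probs, logits = fin$out,
       cache = list(fcs = caches, fin = fin$cache))
}

fusion_bwd <- function(dlogits, p, cache) {
  dfin <- dense_bwd(dlogits, p$out, cache$fin)
  grads <- list(fcs = vector("list", length(p$fcs)),
                out = list(W = dfin$dW, b = dfin$db))
  dh <- dfin$dX
  for (i in rev(seq_along(p$fcs))) {
    ci <- cache$fcs[[i]]
    dh <- dropout_bwd(dh, ci$dr)
    dh <- relu_bwd(dh, ci$ac)
    dn <- dense_bwd(dh, p$fcs[[i]], ci$dn)
    grads$fcs[[i]] <- list(W = dn$dW, b = dn$db)
    dh <- dn$dX
  }
  names(grads$fcs) <- paste0("fc", seq_along(p$fcs))
  list(dX = dh, grads = grads)
}

#' Fuse branch features into multi-label predictions
#'
#' Concatenates the supplied branch feature matrices (any non-empty subset
#' of the three branches — disabled branches are simply omitted, which
#' yields the single- and two-branch ablation architectures), applies the
#' fully connected fusion stack and sigmoid outputs, and thresholds each
#' class probability at `threshold` (ties go to the positive label).
#'
#' @param features Named list of `B x d` branch feature matrices (at least
#'   one).
#' @param params Fusion parameter list (from a trained model:
#'   `model$params$fusion`).
#' @param threshold Decision threshold in (0, 1), default 0.5.
#' @return List with `probabilities` (`B x n_classes`, entries in (0, 1))
#'   and `labels` (binary matrix, `labels = probabilities >= threshold`).
#' @export
fuse_forward <- function(features, params, threshold = 0.5) {
  if (!is.list(features) || length(features) == 0L)
    stop("at least one branch feature matrix is required", call. = FALSE)
  stopifnot(threshold > 0, threshold < 1)
  X <- do.call(cbind, features)
  fw <- fusion_fwd(X, params, train = FALSE)
  list(probabilities = fw$probs,
       labels = (fw$probs >= threshold) * 1L)
}

#' Class-weighted binary cross-entropy over label matrices
#'
#' Mean over samples and classes of binary cross-entropy with per-class
#' weights on the positive terms (the usual positive-class weighting for
#' imbalanced multi-label problems):
#' `-(w_c * y * log p + (1 - y) * log(1 - p))`. Probabilities are clamped
#' to `[1e-7, 1 - 1e-7]` before the logarithm. The default class weights
#' `N / (C * count_c)` (computed on the training split) amplify the
#' gradient of rare classes; unit weights reduce to plain BCE.
#'
#' @param probabilities `N x C` matrix of predicted probabilities.
#' @param true_labels `N x C` binary matrix.
#' @param class_weights Positive weight per class (default all 1).
#' @return Nonnegative scalar loss.
#' @export
multilabel_loss <- function(probabilities, true_labels, class_weights = NULL) {
  stopifnot(all(dim(probabilities) == dim(true_labels)))
  C <- ncol(probabilities)
  if (is.null(class_weights)) class_weights <- rep(1, C)
  stopifnot(length(class_weights) == C, all(class_weights > 0))
  p <- pmin(pmax(probabilities, 1e-7), 1 - 1e-7)
  W <- rep(class_weights, each = nrow(p))
  mean(-(W * true_labels * log(p) + (1 - true_labels) * log(1 - p)))
}

# Gradient of multilabel_loss wrt the logits (p = sigmoid(logits)):
# d/dz [-(w y log p + (1-y) log(1-p))] = (w y + (1-y)) p - w y.
multilabel_loss_grad <- function(probabilities, true_labels, class_weights) {
  n <- length(probabilities)
  W <- rep(class_weights, each = nrow(probabilities))
  wy <- W * true_labels
  ((wy + (1 - true_labels)) * probabilities - wy) / n
}

# Default imbalance-countering class weights on a training label matrix.
compute_class_weights <- function(labels) {
  counts <- pmax(colSums(labels), 1)
  nrow(labels) / (ncol(labels) * counts)
}
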