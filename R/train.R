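# End-to-end training of the fused multi-branch classifier.

make_encoder <- function(atomic_cfg) {
  switch(atomic_cfg$encoder,
         tiny = tiny_transformer_encoder(atomic_cfg$d_atom,
                                         atomic_cfg$n_layers,
                                         atomic_cfg$heads,
                                         pos_scale = atomic_cfg$pos_scale),
         bag = bag_of_tokens_encoder(atomic_cfg$d_atom),
         stop("unknown encoder: ", atomic_cfg$encoder, call. = FALSE))
}

init_model_params <- function(cfg, encoder, n_hg_nodes) {
  params <- list()
  d_in <- 0L
  if ("atomic" %in% cfg$branches) {
    params$atomic <- list(enc = encoder$init(seed = stats::runif(1) * 1e6),
                          head = atomic_head_init(encoder$d_atom,
                                                  cfg$atomic$d_head,
                                                  cfg$atomic$d_fuse))
    d_in <- d_in + cfg$atomic$d_fuse
  }
  if ("seq" %in% cfg$branches) {
    params$seq <- seq_branch_init(cfg$seq)
    d_in <- d_in + cfg$seq$d_fuse
  }
  if ("hyper" %in% cfg$branches) {
    params$hyper <- hypergat_params_init(n_hg_nodes, cfg$hg$d_hid,
                                         cfg$hg$d_fuse, cfg$hg$n_layers)
    d_in <- d_in + cfg$hg$d_fuse
  }
  params$fusion <- fusion_init(d_in, cfg$fusion$hidden, cfg$n_classes)
  params
}

#' Train the multi-granularity fusion classifier
#'
#' Trains all enabled branches and the fusion head end to end with
#' mini-batch gradient descent (Adam with decoupled weight decay and a
#' linear warmup/decay schedule). The k-mer hypergraph is built over the
#' training split (transductive training); held-out data attaches to the
#' frozen vocabulary at prediction time. A validation split is carved from
#' the training records and the five multi-label metrics on it are recorded
#' after every epoch.
#'
#' @param records Training peptide tibble (every record needs at least one
#'   positive label).
#' @param config Configuration list (see [default_config()],
#'   [tiny_config()]). `config$branches` selects any non-empty subset of
#'   `c("atomic", "seq", "hyper")`, giving the single- and multi-branch
#'   ablation architectures.
#' @param seed Integer seed governing initialization, shuffling and dropout.
#' @param encoder Optional encoder-contract object for the atomic branch;
#'   default built from `config$atomic$encoder`.
#' @param verbose Print per-epoch progress to stderr.
#' @return An object of class `pepfusion_model` with elements `params`, `config`,
#'   `train_hg` (frozen hypergraph), `class_weights`, `label_names` and
#'   `history` (per-epoch loss and validation metrics tibble).
#' @export
train_pepfusion <- function(records, config = tiny_config(), seed = 1L,
                       encoder = NULL, verbose = FALSE) {
  validate_peptide_tbl(records, require_positive = TRUE)
  cfg <- merge_config(default_config(config$n_classes), config)
  if (length(cfg$branches) == 0L)
    stop("at least one branch must be enabled", call. = FALSE)
  if (nrow(records) < 2L) stop("need at least 2 training records", call. = FALSE)
  if (ncol(records$labels) != cfg$n_classes)
    stop("label matrix has ", ncol(records$labels), " columns but config says ",
         cfg$n_classes, call. = FALSE)
  set.seed(as.integer(seed))
  tr <- cfg$training

  n <- nrow(records)
  n_val <- min(n - 1L, max(0L, round(tr$val_fraction * n)))
  val_idx <- if (n_val > 0L) sample.int(n, n_val) else integer(0)
  train_tbl <- if (n_val > 0L) records[-val_idx, , drop = FALSE] else records
  val_tbl <- records[val_idx, , drop = FALSE]
  N <- nrow(train_tbl)

  use_atomic <- "atomic" %in% cfg$branches
  use_seq <- "seq" %in% cfg$branches
  use_hyper <- "hyper" %in% cfg$branches

  res_ids <- if (use_seq) encode_residue_matrix(train_tbl$sequence, cfg$seq$n)
  str_ids <- if (use_seq) encode_structure_matrix(train_tbl$sequence, cfg$seq$n)
  atm_ids <- if (use_atomic) encode_smiles_batch(train_tbl$sequence,
                                                 cfg$atomic$L_atom)
  hg <- if (use_hyper) build_hypergraph(train_tbl, cfg$hg$k)

  enc <- if (use_atomic) {
    if (!is.null(encoder)) encoder else make_encoder(cfg$atomic)
  }
  params <- init_model_params(cfg, enc,
                              if (use_hyper) hg$n_nodes + 1L else 0L)
  class_weights <- if (tr$use_class_weights)
    compute_class_weights(train_tbl$labels) else rep(1, cfg$n_classes)

  val_ctx <- if (n_val > 0L) encode_context(cfg, hg, val_tbl)

  n_batches <- ceiling(N / tr$batch_size)
  total_steps <- tr$epochs * n_batches
  warmup <- max(1L, round(tr$warmup_frac * total_steps))
  opt <- adam_init(params)
  history <- vector("list", tr$epochs)

  for (epoch in seq_len(tr$epochs)) {
    perm <- sample.int(N)
    epoch_loss <- 0
    for (bi in seq_len(n_batches)) {
      idx <- perm[((bi - 1L) * tr$batch_size + 1L):min(bi * tr$batch_size, N)]
      feats <- list(); caches <- list()
      if (use_atomic) {
        af <- atomic_branch_fwd(atm_ids[idx, , drop = FALSE], enc,
                                params$atomic, cfg$atomic$dropout,
                                train = TRUE)
        feats$atomic <- af$out; caches$atomic <- af$cache
      }
      if (use_seq) {
        sf <- seq_branch_fwd(res_ids[idx, , drop = FALSE],
                             str_ids[idx, , drop = FALSE],
                             params$seq, cfg$seq, train = TRUE)
        feats$seq <- sf$out; caches$seq <- sf$cache
      }
      if (use_hyper) {
        hf <- hypergat_fwd(hg, params$hyper, cfg$hg$leaky_slope)
        feats$hyper <- hf$out[idx, , drop = FALSE]
        caches$hyper <- hf$cache
      }
      X <- do.call(cbind, feats)
      fw <- fusion_fwd(X, params$fusion, cfg$fusion$dropout, train = TRUE)
      y <- train_tbl$labels[idx, , drop = FALSE]
      loss <- multilabel_loss(fw$probs, y, class_weights)
      if (!is.finite(loss))
        stop("training diverged (non-finite loss) at epoch ", epoch,
             ", batch ", bi, "; reduce the learning rate", call. = FALSE)
      epoch_loss <- epoch_loss + loss * length(idx)

      dlogits <- multilabel_loss_grad(fw$probs, y, class_weights)
      fb <- fusion_bwd(dlogits, params$fusion, fw$cache)
      grads <- list(fusion = fb$grads)
      off <- 0L
      if (use_atomic) {
        sl <- off + seq_len(cfg$atomic$d_fuse); off <- off + cfg$atomic$d_fuse
        ab <- atomic_branch_bwd(fb$dX[, sl, drop = FALSE], enc,
                                params$atomic, caches$atomic)
        grads$atomic <- ab$grads
      }
      if (use_seq) {
        sl <- off + seq_len(cfg$seq$d_fuse); off <- off + cfg$seq$d_fuse
        sb <- seq_branch_bwd(fb$dX[, sl, drop = FALSE], params$seq,
                             cfg$seq, caches$seq)
        grads$seq <- sb$grads
      }
      if (use_hyper) {
        sl <- off + seq_len(cfg$hg$d_fuse)
        dfull <- matrix(0, hg$n_edges, cfg$hg$d_fuse)
        dfull[idx, ] <- fb$dX[, sl, drop = FALSE]
        grads$hyper <- hypergat_bwd(dfull, params$hyper, caches$hyper)
      }
      st <- adam_step(params, grads, opt, tr$lr, total_steps, warmup,
                      weight_decay = tr$weight_decay)
      params <- st$params; opt <- st$state
    }

    row <- tibble::tibble(epoch = epoch, loss = epoch_loss / N)
    if (n_val > 0L) {
      m <- eval_encoded(params, cfg, enc, val_ctx, val_tbl$labels)
      row <- dplyr::bind_cols(row, m[, c("precision", "coverage", "accuracy",
                                         "absolute_true", "absolute_false")])
    }
    history[[epoch]] <- row
    if (verbose)
      message(sprintf("epoch %d/%d  loss %.4f%s", epoch, tr$epochs,
                      row$loss,
                      if (n_val > 0L)
                        sprintf("  val abs.true %.3f", row$absolute_true)
                      else ""))
  }

  structure(list(params = params, config = cfg, encoder = enc,
                 train_hg = hg, class_weights = class_weights,
                 label_names = colnames(records$labels),
                 history = dplyr::bind_rows(history),
                 n_train = N, seed = as.integer(seed)),
            class = "pepfusion_model")
}

# Precompute the encoded representations a forward pass needs, so repeated
# evaluation (e.g. per-epoch validation) does not redo encoding work.
encode_context <- function(cfg, train_hg, tbl) {
  ctx <- list()
  if ("atomic" %in% cfg$branches)
    ctx$atm_ids <- encode_smiles_batch(tbl$sequence, cfg$atomic$L_atom)
  if ("seq" %in% cfg$branches) {
    ctx$res_ids <- encode_residue_matrix(tbl$sequence, cfg$seq$n)
    ctx$str_ids <- encode_structure_matrix(tbl$sequence, cfg$seq$n)
  }
  if ("hyper" %in% cfg$branches)
    ctx$ihg <- inference_hypergraph(train_hg, tbl, cfg$hg$unk_node)
  ctx
}

forward_encoded <- function(params, cfg, enc, ctx) {
  feats <- list()
  if ("atomic" %in% cfg$branches)
    feats$atomic <- atomic_branch_fwd(ctx$atm_ids, enc, params$atomic,
                                      train = FALSE)$out
  if ("seq" %in% cfg$branches)
    feats$seq <- seq_branch_fwd(ctx$res_ids, ctx$str_ids,
                                params$seq, cfg$seq, train = FALSE)$out
  if ("hyper" %in% cfg$branches)
    feats$hyper <- hypergat_fwd(ctx$ihg, params$hyper, cfg$hg$leaky_slope)$out
  fusion_fwd(do.call(cbind, feats), params$fusion, train = FALSE)$probs
}

# Forward pass on arbitrary records in eval mode; returns probability matrix.
forward_records <- function(params, cfg, enc, train_hg, tbl) {
  forward_encoded(params, cfg, enc, encode_context(cfg, train_hg, tbl))
}

eval_encoded <- function(params, cfg, enc, ctx, labels) {
  probs <- forward_encoded(params, cfg, enc, ctx)
  multilabel_metrics(labels, (probs >= cfg$fusion$threshold) * 1L)
}

#' Predict peptide function probabilities and labels
#'
#' Eval-mode, deterministic forward pass through the trained model. The
#' relational branch attaches new sequences to the frozen training k-mer
#' vocabulary ([inference_hypergraph()]). Records whose sequence is shorter
#' than the hypergraph k (or contains invalid residues) are reported in the
#' `"errors"` attribute of the result and skipped; all others proceed.
#'
#' @param object A trained `pepfusion_model`.
#' @param new_data Peptide tibble (a `labels` column is not required).
#' @param threshold Decision threshold; default from the model config (0.5).
#' @param ... Unused.
#' @return Tibble with `id`, `.prob` (probability matrix column) and
#'   `.pred` (binary label matrix column). Skipped records are listed in
#'   `attr(result, "errors")`.
#' @export
predict.pepfusion_model <- function(object, new_data,
                               threshold = NULL, ...) {
  cfg <- object$config
  if (is.null(threshold)) threshold <- cfg$fusion$threshold
  stopifnot(is.data.frame(new_data),
            all(c("id", "sequence") %in% names(new_data)))
  bad_res <- grepl(sprintf("[^%s]", paste(AA_ALPHABET, collapse = "")),
                   new_data$sequence) | !nzchar(new_data$sequence)
  bad_len <- if ("hyper" %in% cfg$branches)
    nchar(new_data$sequence) < cfg$hg$k else rep(FALSE, nrow(new_data))
  bad <- bad_res | bad_len
  errors <- tibble::tibble(
    id = new_data$id[bad],
    reason = ifelse(bad_res[bad], "invalid residues",
                    paste0("sequence shorter than k = ", cfg$hg$k)))
  ok <- new_data[!bad, , drop = FALSE]
  if (nrow(ok) == 0L) {
    out <- tibble::tibble(id = character(),
                          .prob = matrix(0, 0L, cfg$n_classes),
                          .pred = matrix(0L, 0L, cfg$n_classes))
    attr(out, "errors") <- errors
    return(out)
  }
  probs <- forward_records(object$params, cfg, object$encoder,
                           object$train_hg, ok)
  colnames(probs) <- object$label_names
  preds <- (probs >= threshold) * 1L
  out <- tibble::tibble(id = ok$id, .prob = probs, .pred = preds)
  if (nrow(errors) > 0L)
    warning(nrow(errors), " record(s) skipped; see attr(result, 'errors')",
            call. = FALSE)
  attr(out, "errors") <- errors
  out
}

#' @export
print.pepfusion_model <- function(x, ...) {
  cat("Multi-granularity peptide classifier\n")
  cat("  branches:", paste(x$config$branches, collapse = " + "), "\n")
  cat("  classes: ", x$config$n_classes,
      " | trained on ", x$n_train, " peptides\n", sep = "")
  if (nrow(x$history) > 0L) {
    last <- x$history[nrow(x$history), ]
    cat(sprintf("  final training loss %.4f", last$loss))
    if ("absolute_true" %in% names(last))
      cat(sprintf(" | validation absolute true %.3f", last$absolute_true))
    cat("\n")
  }
  invisible(x)
}

#' Save a trained model to disk
#' @param model An `pepfusion_model`.
#' @param path Destination file.
#' @return `path`, invisibly.
#' @export
save_pepfusion <- function(model, path) {
  stopifnot(inherits(model, "pepfusion_model"))
  saveRDS(model, path)
  invisible(path)
}

#' Load a model saved with [save_pepfusion()]
#' @param path File path.
#' @return The `pepfusion_model`.
#' @export
load_pepfusion <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "pepfusion_model"))
    stop("file does not contain a pepfusion_model", call. = FALSE)
  model
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Per-class summary of a trained model
#'
#' One row per label class: its name and the loss weight it received
#' (inversely proportional to training prevalence).
#'
#' @param x An `pepfusion_model`.
#' @param ... Unused.
#' @return Tibble with columns `class`, `class_weight`.
#' @method tidy pepfusion_model
#' @export
tidy.pepfusion_model <- function(x, ...) {
  tibble::tibble(class = x$label_names,
                 class_weight = unname(x$class_weights))
}

#' One-row summary of a trained model
#'
#' @param x An `pepfusion_model`.
#' @param ... Unused.
#' @return One-row tibble: branches, classes, training size, epochs, final
#'   loss and final validation metrics (when a validation split was used).
#' @method glance pepfusion_model
#' @export
glance.pepfusion_model <- function(x, ...) {
  last <- x$history[nrow(x$history), ]
  out <- tibble::tibble(branches = paste(x$config$branches, collapse = "+"),
                        n_classes = x$config$n_classes,
                        n_train = x$n_train,
                        epochs = nrow(x$history),
                        final_loss = last$loss)
  if ("absolute_true" %in% names(last))
    out <- dplyr::bind_cols(out, last[, c("precision", "coverage", "accuracy",
                                          "absolute_true", "absolute_false")])
  out
}
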