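#' Default model configuration
#'
#' Nested configuration for the three branches, fusion head and training
#' loop. Defaults follow the published settings where the method states
#' them: residue window `n = 50`, embedding width `d = 192`, TextCNN filter
#' widths 2-5, k-mer size 5, decision threshold 0.5, batch size 128,
#' learning rate 5e-6 and 30 epochs. The learning-rate default is a
#' fine-tuning rate (appropriate when a pretrained atomic encoder is
#' plugged in); [tiny_config()] raises it for random-init training.
#'
#' @param n_classes Number of label classes (default 21).
#' @return Named nested list with entries `branches`, `atomic`, `seq`,
#'   `hg`, `fusion`, `training`.
#' @export
default_config <- function(n_classes = 21L) {
  list(
    n_classes = as.integer(n_classes),
    branches = c("atomic", "seq", "hyper"),
    atomic = list(enabled = TRUE, encoder = "tiny", L_atom = 256L,
                  d_atom = 64L, n_layers = 2L, heads = 4L,
                  d_head = 64L, d_fuse = 128L, dropout = 0.2,
                  pos_scale = 0.3),
    seq = list(n = 50L, d = 192L, heads = 8L,
               filter_sizes = c(2L, 3L, 4L, 5L), filters_per_size = 64L,
               d_merge = 128L, d_fuse = 128L, dropout = 0.2,
               pos_scale = 0.3),
    hg = list(k = 5L, n_layers = 2L, d_hid = 64L, d_fuse = 128L,
              leaky_slope = 0.2, unk_node = TRUE),
    fusion = list(hidden = 128L, dropout = 0.2, threshold = 0.5),
    training = list(batch_size = 128L, lr = 5e-6, epochs = 30L,
                    warmup_frac = 0.1, weight_decay = 0.01,
                    val_fraction = 0.1, use_class_weights = TRUE)
  )
}

#' Tiny configuration for CPU-scale experiments
#'
#' A deliberately small instantiation of the architecture (narrow widths,
#' one-layer atomic encoder, short SMILES window, 32-dimensional branch
#' features) with a random-init-appropriate learning rate of 1e-3. This is
#' the configuration used by the package's own tests and reproduction
#' script; it trains in minutes on one CPU core while exercising every
#' architectural element of the full model.
#'
#' @param n_classes Number of label classes (default 8, matching the
#'   reduced synthetic benchmark).
#' @param epochs Training epochs (default 30).
#' @return Configuration list as in [default_config()].
#' @export
tiny_config <- function(n_classes = 8L, epochs = 30L) {
  cfg <- default_config(n_classes)
  cfg$atomic <- utils::modifyList(cfg$atomic, list(
    L_atom = 48L, d_atom = 24L, n_layers = 1L, heads = 2L,
    d_head = 32L, d_fuse = 32L))
  cfg$seq <- utils::modifyList(cfg$seq, list(
    d = 32L, heads = 2L, filters_per_size = 8L, d_merge = 48L, d_fuse = 32L))
  cfg$hg <- utils::modifyList(cfg$hg, list(d_hid = 16L, d_fuse = 32L))
  cfg$fusion$hidden <- 64L
  cfg$training <- utils::modifyList(cfg$training, list(
    lr = 1e-3, epochs = as.integer(epochs)))
  cfg
}

# Validate a config tree against the default schema: unknown keys are
# rejected, known keys override defaults.
merge_config <- function(base, override) {
  if (is.null(override)) return(base)
  for (nm in names(override)) {
    if (!nm %in% names(base))
      stop("unknown configuration key: ", nm, call. = FALSE)
    if (is.list(base[[nm]]) && is.list(override[[nm]]))
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    else base[[nm]] <- override[[nm]]
  }
  base
}
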