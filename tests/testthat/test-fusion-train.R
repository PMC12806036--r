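tiny_train_cfg <- function(branches = c("atomic", "seq", "hyper"),
                           epochs = 2L, n_classes = 4L) {
  cfg <- tiny_config(n_classes, epochs = epochs)
  cfg$branches <- branches
  cfg$atomic <- utils::modifyList(cfg$atomic, list(
    L_atom = 32L, d_atom = 8L, n_layers = 1L, heads = 2L,
    d_head = 8L, d_fuse = 8L))
  cfg$seq <- utils::modifyList(cfg$seq, list(
    d = 16L, heads = 2L, filters_per_size = 4L, d_merge = 12L, d_fuse = 8L))
  cfg$hg <- utils::modifyList(cfg$hg, list(d_hid = 8L, d_fuse = 8L))
  cfg$fusion$hidden <- 12L
  cfg$training$batch_size <- 32L
  cfg
}

test_that("fusion head emits (0,1) probabilities with >= threshold labels", {
  ns <- asNamespace("pepfusion")
  set.seed(12)
  params <- ns$fusion_init(6L, 8L, 5L)
  feats <- list(a = matrix(rnorm(12), 4, 3), b = matrix(rnorm(12), 4, 3))
  out <- fuse_forward(feats, params)
  expect_equal(dim(out$probabilities), c(4L, 5L))
  expect_true(all(out$probabilities > 0 & out$probabilities < 1))
  expect_equal(out$labels, (out$probabilities >= 0.5) * 1L)

  # a probability exactly at the threshold is called positive
  p_half <- ns$fusion_init(1L, 1L, 1L)
  p_half$fcs$fc1$W[] <- 0; p_half$fcs$fc1$b[] <- 0
  p_half$out$W[] <- 0; p_half$out$b[] <- 0     # logit 0 -> prob exactly 0.5
  out_half <- fuse_forward(list(x = matrix(1, 1, 1)), p_half)
  expect_equal(out_half$probabilities[1, 1], 0.5)
  expect_equal(out_half$labels[1, 1], 1L)

  expect_error(fuse_forward(list(), params), "at least one")
})

test_that("all seven branch-combination architectures train and evaluate", {
  recs <- generate_peptides(120, n_classes = 4, noise_rate = 0, seed = 21)
  combos <- list("1" = "atomic", "2" = "seq", "3" = "hyper",
                 "12" = c("atomic", "seq"), "13" = c("atomic", "hyper"),
                 "23" = c("seq", "hyper"),
                 "123" = c("atomic", "seq", "hyper"))
  for (nm in names(combos)) {
    cfg <- tiny_train_cfg(branches = combos[[nm]], epochs = 1L)
    m <- train_pepfusion(recs, cfg, seed = 3)
    pr <- predict(m, recs[1:10, ])
    expect_equal(dim(pr$.prob), c(10L, 4L))
    rep <- multilabel_metrics(recs$labels[1:10, ], pr$.pred)
    expect_true(all(is.finite(unlist(rep))), label = paste("combo", nm))
  }
  expect_error(train_pepfusion(recs, utils::modifyList(tiny_train_cfg(),
                                                  list(branches = character(0))),
                          seed = 1),
               "at least one branch")
})

test_that("training reduces the loss on noise-free synthetic data", {
  recs <- generate_peptides(150, n_classes = 4, noise_rate = 0, seed = 5)
  drops <- sapply(1:3, function(seed) {
    cfg <- tiny_train_cfg(branches = "seq", epochs = 6L)
    m <- train_pepfusion(recs, cfg, seed = seed)
    h <- m$history
    h$loss[1] - h$loss[nrow(h)]
  })
  # stochastic sanity: loss goes down for every seed
  expect_true(all(drops > 0))
})

test_that("models serialize and reload with identical predictions", {
  recs <- generate_peptides(60, n_classes = 4, seed = 8)
  m <- train_pepfusion(recs, tiny_train_cfg(epochs = 1L), seed = 2)
  pr1 <- predict(m, recs[1:12, ])
  path <- withr::local_tempfile(fileext = ".rds")
  save_pepfusion(m, path)
  m2 <- load_pepfusion(path)
  pr2 <- predict(m2, recs[1:12, ])
  expect_identical(pr1$.prob, pr2$.prob)

  saveRDS(list(), path)
  expect_error(load_pepfusion(path), "pepfusion_model")
})

test_that("prediction is deterministic, complete and chunk-independent", {
  recs <- generate_peptides(50, n_classes = 4, seed = 14)
  m <- train_pepfusion(recs, tiny_train_cfg(epochs = 1L), seed = 4)
  pr1 <- predict(m, recs)
  pr2 <- predict(m, recs)
  expect_identical(pr1$.prob, pr2$.prob)
  expect_equal(nrow(pr1), nrow(recs))

  # short and invalid sequences become error entries, others proceed
  mixed <- tibble::tibble(
    id = c("ok1", "short", "ok2"),
    sequence = c(recs$sequence[1], "ACD", recs$sequence[2]),
    labels = recs$labels[1:3, ])
  expect_warning(prm <- predict(m, mixed), "skipped")
  expect_equal(prm$id, c("ok1", "ok2"))
  errs <- attr(prm, "errors")
  expect_equal(errs$id, "short")
  expect_match(errs$reason, "shorter than k")
})

test_that("tidy, glance and autoplot summarize a fitted model", {
  recs <- generate_peptides(60, n_classes = 4, seed = 9)
  m <- train_pepfusion(recs, tiny_train_cfg(epochs = 2L), seed = 6)
  td <- tidy(m)
  expect_equal(nrow(td), 4L)
  expect_true(all(td$class_weight > 0))
  gl <- glance(m)
  expect_equal(gl$epochs, 2L)
  expect_equal(gl$n_classes, 4L)
  expect_s3_class(autoplot(m), "ggplot")
  pl <- plot_class_rates(predict(m, recs), recs)
  expect_s3_class(pl, "ggplot")
})
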