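test_that("kmers walks the sequence with stride one", {
  expect_equal(kmers("PAMNH", 3), c("PAM", "AMN", "MNH"))
  k2 <- kmers("PAMNH", 2)
  expect_equal(k2, c("PA", "AM", "MN", "NH"))
  expect_true(all(c("AM", "MN") %in% k2))
  expect_equal(kmers("PAMNH", 5), "PAMNH")
  expect_equal(kmers("PAMNH", 1), c("P", "A", "M", "N", "H"))
  expect_error(kmers("PAMNH", 6), "exceeds")
  expect_error(kmers("PAMNH", 0), ">= 1")
})

fig_tbl <- function() {
  tibble::tibble(id = c("s1", "s2", "s3"),
                 sequence = c("SKIVGAFD", "VGALLDKA", "FDGSLKA"),
                 labels = matrix(1L, 3, 2))
}

test_that("hypergraph construction matches the three-sequence worked example", {
  hg <- build_hypergraph(fig_tbl(), k = 2)
  H <- pepfusion:::incidence_matrix(hg)
  expect_equal(hg$n_edges, 3L)
  # shared 2-mers connect the sequences exactly as expected
  expect_equal(unname(H[, "VG"]), c(1L, 1L, 0L))
  expect_equal(unname(H[, "FD"]), c(1L, 0L, 1L))
  expect_equal(unname(H[, "KA"]), c(0L, 1L, 1L))
  # incidence row sums = unique k-mer counts per sequence
  for (j in 1:3)
    expect_equal(sum(H[j, ]),
                 length(unique(kmers(fig_tbl()$sequence[j], 2))))
  # column sums = document frequency
  expect_equal(unname(colSums(H)), hg$df)
  expect_equal(hg$idf, log(3 / hg$df))
})

test_that("tf-idf incidence weights encode frequency x diversity", {
  tbl <- tibble::tibble(id = c("a", "b"),
                        sequence = c("AAAA", "AACA"),
                        labels = matrix(1L, 2, 1))
  hg <- build_hypergraph(tbl, k = 2)
  # "AA" occurs 3x in sequence a, df = 2 -> idf = 0 -> weight 0
  aa <- which(hg$node_vocab == "AA")
  w_aa <- hg$weight[hg$node == aa & hg$edge == 1]
  expect_equal(hg$tf[hg$node == aa & hg$edge == 1], 3L)
  expect_equal(w_aa, 0)
  # "CA" only in b: tf 1, idf ln(2)
  ca <- which(hg$node_vocab == "CA")
  expect_equal(hg$weight[hg$node == ca], log(2))

  # single sequence: all idf = ln(1) = 0
  hg1 <- build_hypergraph(tbl[1, ], k = 2)
  expect_true(all(hg1$idf == 0))
  expect_equal(hg1$n_edges, 1L)

  # identical sequences share identical incidence rows
  tbl2 <- tibble::tibble(id = c("x", "y"), sequence = c("SKIVG", "SKIVG"),
                         labels = matrix(1L, 2, 1))
  H2 <- pepfusion:::incidence_matrix(build_hypergraph(tbl2, k = 2))
  expect_equal(unname(H2[1, ]), unname(H2[2, ]))

  expect_error(build_hypergraph(tbl, k = 5), "shorter than k")
})

test_that("edge and node updates match the brute-force evaluator", {
  set.seed(101)
  for (r in 1:20) {
    su <- random_hypergraph_setup(n_nodes = sample(4:8, 1),
                                  n_edges = sample(2:4, 1), d = 4)
    hv <- matrix(rnorm(su$hg$n_nodes * 4), su$hg$n_nodes, 4)
    he <- matrix(rnorm(su$hg$n_edges * 4), su$hg$n_edges, 4)
    Wv <- matrix(rnorm(16), 4, 4); We <- matrix(rnorm(16), 4, 4)
    W <- matrix(0, su$hg$n_edges, su$hg$n_nodes)
    W[cbind(su$hg$edge, su$hg$node)] <- su$hg$weight

    eu <- edge_update(hv, he, su$hg, Wv, We)
    oe <- oracle_edge_update(hv, he, su$H, W, t(Wv), t(We))
    expect_lt(max(abs(eu$features - oe$features)), 1e-6)

    nu <- node_update(hv, he, su$hg, Wv, We)
    on <- oracle_node_update(he, hv, su$H, t(Wv), t(We))
    expect_lt(max(abs(nu$features - on$features)), 1e-6)
  }
})

test_that("full relational forward matches the brute-force stack", {
  set.seed(202)
  for (r in 1:10) {
    su <- random_hypergraph_setup(n_nodes = sample(5:8, 1),
                                  n_edges = sample(2:4, 1), d = 4)
    mine <- hypergat_forward(su$hg, su$params)
    ref <- oracle_hypergat_forward(su$hg, su$params)
    expect_lt(max(abs(mine - ref)), 1e-6)
  }
})

test_that("attention neighborhoods are probability distributions", {
  set.seed(303)
  for (r in 1:100) {
    su <- random_hypergraph_setup(n_nodes = sample(4:10, 1),
                                  n_edges = sample(2:5, 1), d = 4)
    hv <- matrix(rnorm(su$hg$n_nodes * 4), su$hg$n_nodes, 4)
    he <- matrix(rnorm(su$hg$n_edges * 4), su$hg$n_edges, 4)
    Wv <- matrix(rnorm(16), 4, 4); We <- matrix(rnorm(16), 4, 4)
    beta <- edge_update(hv, he, su$hg, Wv, We)$attention
    alpha <- node_update(hv, he, su$hg, Wv, We)$attention
    bsums <- tapply(beta, su$hg$edge, sum)
    asums <- tapply(alpha, su$hg$node, sum)
    expect_true(all(abs(bsums - 1) < 1e-6))
    expect_true(all(abs(asums - 1) < 1e-6))
    # single-member neighborhoods get weight exactly 1
    esize <- table(su$hg$edge)
    if (any(esize == 1)) {
      e1 <- as.integer(names(esize)[esize == 1][1])
      expect_equal(unname(beta[su$hg$edge == e1]), 1)
    }
  }
})

test_that("node and edge relabeling leaves per-sequence features unchanged", {
  set.seed(404)
  su <- random_hypergraph_setup(n_nodes = 7, n_edges = 3, d = 4)
  base <- hypergat_forward(su$hg, su$params)
  perm <- sample(su$hg$n_nodes)
  hg2 <- su$hg
  hg2$node <- match(su$hg$node, perm)      # node v becomes position of v in perm
  hg2$node_vocab <- su$hg$node_vocab[perm]
  hg2$df <- su$hg$df[perm]; hg2$idf <- su$hg$idf[perm]
  p2 <- su$params
  p2$emb <- su$params$emb[perm, , drop = FALSE]
  out2 <- hypergat_forward(hg2, p2)
  expect_lt(max(abs(base - out2)), 1e-6)
})

test_that("inference hypergraphs freeze vocabulary, df and idf", {
  train <- fig_tbl()
  hg <- build_hypergraph(train, k = 2)
  new_known <- tibble::tibble(id = "q1", sequence = "SKIV",
                              labels = matrix(0L, 1, 2))
  ih <- inference_hypergraph(hg, new_known)
  used <- unique(ih$node)
  expect_true(all(used <= length(hg$node_vocab)))   # no UNK needed
  expect_equal(ih$idf[seq_along(hg$idf)], hg$idf)

  # one novel k-mer maps to the UNK node
  new_unk <- tibble::tibble(id = "q2", sequence = "SKIW",
                            labels = matrix(0L, 1, 2))
  ih2 <- inference_hypergraph(hg, new_unk)
  expect_true(ih2$unk_node %in% ih2$node)
  expect_equal(ih2$idf[ih2$unk_node], 0)

  # fully novel sequence with UNK disabled errors
  alien <- tibble::tibble(id = "q3", sequence = "WWWWW",
                          labels = matrix(0L, 1, 2))
  expect_error(inference_hypergraph(hg, alien, unk_node = FALSE),
               "shares no k-mer")

  # empty batch gives an empty edge set
  ih0 <- inference_hypergraph(hg, train[0, ])
  expect_equal(ih0$n_edges, 0L)
})
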