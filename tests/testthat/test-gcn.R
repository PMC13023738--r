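# small helper: per-view graphs over a separable two-cluster cohort
cluster_graphs <- function(n_per = 50, separation = 6, dim = 8, seed = 1,
                           k = 5) {
  tc <- generate_two_cluster(n_per, separation, dim, seed)
  X <- scale(tc$views$combined)
  list(graphs = list(combined = build_graph(X, graph_config(k))),
       labels = tc$labels, X = X)
}

test_that("the graph convolution layer matches hand arithmetic", {
  X <- rbind(c(1, 2), c(3, 0.5), c(0, 1))
  expect_equal(gcn_layer(diag(3), X, diag(2), c(0, 0)), X)
  expect_equal(gcn_layer(diag(3), matrix(0, 3, 2), diag(2), c(0, 0)),
               matrix(0, 3, 2))
  # 3-node path graph with hand-set parameters and slope 0.25
  A3 <- matrix(0, 3, 3); A3[1, 2] <- A3[2, 1] <- A3[2, 3] <- A3[3, 2] <- 1
  Ah <- normalize_adjacency(A3)
  W <- matrix(c(1, -1, 0.5, 2), 2, 2)
  b <- c(0.1, -0.2)
  pre <- Ah %*% (X %*% W) + matrix(b, 3, 2, byrow = TRUE)
  expect_equal(gcn_layer(Ah, X, W, b, 0.25),
               ifelse(pre > 0, pre, 0.25 * pre))
  expect_error(gcn_layer(diag(3), X, diag(3), c(0, 0, 0)), "shape")
})

test_that("self-expression is plain feature mixing", {
  H <- matrix(c(1, 2, 3, 4), 2, 2)
  expect_equal(self_expression(H, diag(2)), H)
  expect_equal(self_expression(H, matrix(0, 2, 2)), matrix(0, 2, 2))
  C <- matrix(c(1, 0.5, -1, 2), 2, 2)
  expect_equal(self_expression(H, C), H %*% C)
  expect_error(self_expression(H, diag(3)), "shape")
})

test_that("self-attention is a row-stochastic softmax mixture", {
  set.seed(2)
  H <- matrix(rnorm(12), 4, 3)
  Vw <- matrix(rnorm(9), 3, 3)
  # zero query: uniform attention, every output row is the mean of H Vw
  out <- self_attention(H, matrix(0, 3, 3), diag(3), Vw)
  expect_equal(out$attention, matrix(0.25, 4, 4))
  mean_row <- colMeans(H %*% Vw)
  for (i in 1:4) expect_equal(out$H[i, ], mean_row, tolerance = 1e-12)
  # one node: weight exactly 1
  out1 <- self_attention(H[1, , drop = FALSE], diag(3), diag(3), Vw)
  expect_equal(out1$attention[1, 1], 1)
  # 3-node hand example
  Qw <- diag(3); Kw <- diag(3)
  H3 <- H[1:3, ]
  Sc <- (H3 %*% Qw) %*% t(H3 %*% Kw) / sqrt(3)
  Aexp <- t(apply(Sc, 1, function(r) exp(r - max(r)) / sum(exp(r - max(r)))))
  out3 <- self_attention(H3, Qw, Kw, Vw)
  expect_equal(out3$attention, Aexp, tolerance = 1e-12)
  expect_equal(rowSums(out3$attention), rep(1, 3), tolerance = 1e-6)
})

test_that("training separates the separable fixture and records its loss", {
  cg <- cluster_graphs(n_per = 50, seed = 1)
  cfg <- model_config(epochs = 200L, seed = 0L)
  m <- gcnsase_train(cg$graphs, cg$labels, cfg)
  expect_length(m$loss_trace, 200)
  expect_lt(m$loss_trace[10], m$loss_trace[1])
  probs <- gcnsase_forward(m, cg$graphs)$probs
  expect_gte(auc(probs[, "class1"], cg$labels), 0.99)
})

test_that("zero learning rates leave parameters at initialisation", {
  cg <- cluster_graphs(n_per = 10, seed = 2)
  cfg0 <- model_config(epochs = 5L, lr_encoder = 0, lr_classifier = 0,
                       weight_decay = 0, seed = 3L)
  m <- gcnsase_train(cg$graphs, cg$labels, cfg0)
  set.seed(child_seed(3L, 40L))
  ref <- smccanet:::init_view_params(ncol(cg$X), cfg0$hidden_dim)
  expect_equal(m$params$combined$W, ref$W, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(m$params$combined$Wc, ref$Wc, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("class weighting raises minority training recall", {
  # 10:90 imbalance; paired seeded runs with and without weighting
  set.seed(7)
  n <- 100
  X <- matrix(rnorm(n * 6), n, 6)
  labels <- c(rep(1L, 10), rep(0L, 90))
  X[labels == 1L, 1:2] <- X[labels == 1L, 1:2] + 1.2
  g <- list(v = build_graph(scale(X), graph_config(8)))
  recall <- sapply(c(TRUE, FALSE), function(cw) {
    m <- gcnsase_train(g, labels, model_config(
      epochs = 80L, seed = 0L, class_weighting = cw, dropout = 0))
    pred <- gcnsase_forward(m, g)$probs[, "class1"] > 0.5
    sum(pred & labels == 1L) / sum(labels == 1L)
  })
  expect_gt(recall[1], recall[2])
})

test_that("the forward pass is permutation-equivariant and deterministic", {
  cg <- cluster_graphs(n_per = 15, seed = 4)
  m <- gcnsase_train(cg$graphs, cg$labels, model_config(epochs = 20L,
                                                        seed = 1L))
  p1 <- gcnsase_forward(m, cg$graphs)$probs
  p2 <- gcnsase_forward(m, cg$graphs)$probs
  expect_identical(p1, p2)  # dropout off at inference: bitwise agreement
  perm <- sample(nrow(p1))
  g <- cg$graphs$combined
  gp <- g
  gp$adjacency <- g$adjacency[perm, perm]
  gp$node_features <- g$node_features[perm, , drop = FALSE]
  gp$train_mask <- g$train_mask[perm]
  pp <- gcnsase_forward(m, list(combined = gp))$probs
  expect_equal(pp, p1[perm, ], tolerance = 1e-5)
})

test_that("ablation toggles reduce to the plain GCN path", {
  cg <- cluster_graphs(n_per = 10, seed = 6)
  cfg <- model_config(epochs = 1L, seed = 2L, use_attention = FALSE,
                      use_self_expression = FALSE, dropout = 0)
  m <- gcnsase_train(cg$graphs, cg$labels, cfg)
  par <- m$params$combined
  H <- gcn_layer(cg$graphs$combined$adjacency,
                 cg$graphs$combined$node_features, par$W, par$b,
                 cfg$leaky_slope)
  logits <- H %*% par$Wc + matrix(par$bc, nrow(H), 2, byrow = TRUE)
  expect_equal(unname(gcnsase_forward(m, cg$graphs)$per_view_logits$combined),
               unname(logits), tolerance = 1e-10)
})

test_that("prediction on attached nodes honours the probability contract", {
  tc <- generate_two_cluster(40, separation = 6, dim = 6, seed = 9)
  X <- scale(tc$views$combined)
  tr <- c(1:30, 41:70); te <- setdiff(1:80, tr)
  g <- build_graph(X[tr, ], graph_config(5))
  m <- gcnsase_train(list(v = g), tc$labels[tr],
                     model_config(epochs = 100L, seed = 0L))
  ext <- attach_nodes(g, X[te, , drop = FALSE])
  probs <- predict_proba(m, list(v = ext))
  expect_equal(rowSums(probs), rep(1, length(te)), tolerance = 1e-6)
  expect_gte(auc(probs[, "class1"], tc$labels[te]), 0.95)
  # a duplicated confident training subject keeps its predicted class
  tr_probs <- gcnsase_forward(m, list(v = g))$probs
  conf <- which.max(abs(tr_probs[, "class1"] - 0.5))
  extd <- attach_nodes(g, X[tr[conf], , drop = FALSE])
  pd <- predict_proba(m, list(v = extd))
  expect_equal(pd[1, "class1"] > 0.5, tr_probs[conf, "class1"] > 0.5)
  # untrained model refuses to predict
  fake <- m; fake$trained <- FALSE
  expect_error(predict_proba(fake, list(v = ext)), "not trained")
})

test_that("single-class training labels are rejected", {
  cg <- cluster_graphs(n_per = 5, seed = 3)
  expect_error(gcnsase_train(cg$graphs, rep(0L, 10), model_config()),
               "single class")
})
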