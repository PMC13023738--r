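#' Classifier configuration
#'
#' Hyperparameters of the per-view graph-convolutional encoder with
#' feature-wise self-expression and scaled dot-product self-attention.
#' Defaults take one value from each conventional search space: hidden
#' dimension from \{64, 128, 256, 512\}, Adam learning rates from
#' \{1e-5, 1e-4, 5e-4, 1e-3\}, dropout from \{0, 0.3, 0.5, 0.7\}, weight
#' decay from \{0, 1e-5, 1e-4, 1e-3\}, leaky-rectifier slope 0.25, 200
#' epochs, seeds from \{0, ..., 9\}.
#'
#' @param hidden_dim encoder width
#' @param lr_encoder,lr_classifier Adam learning rates for the encoder and
#'   the linear classifier head
#' @param dropout dropout probability applied after the attention block,
#'   training only
#' @param leaky_slope negative-side slope of the leaky rectifier (0 recovers
#'   a plain rectifier)
#' @param epochs training epochs
#' @param weight_decay l2 coefficient added to all weight-matrix gradients
#' @param seed seed fixing parameter init and dropout masks
#' @param use_attention,use_self_expression ablation toggles
#' @param class_weighting inverse-frequency class weights in the loss
#' @param fusion `"prob_mean"` (mean of per-view softmax probabilities) or
#'   `"logit_mean"`
#' @return an object of class `model_config`
#' @export
model_config <- function(hidden_dim = 64L, lr_encoder = 1e-3,
                         lr_classifier = 1e-3, dropout = 0.3,
                         leaky_slope = 0.25, epochs = 200L,
                         weight_decay = 1e-4, seed = 0L,
                         use_attention = TRUE, use_self_expression = TRUE,
                         class_weighting = TRUE,
                         fusion = c("prob_mean", "logit_mean")) {
  if (epochs < 1) stop_config("epochs must be >= 1")
  if (dropout < 0 || dropout >= 1) stop_config("dropout must lie in [0, 1)")
  if (leaky_slope < 0) stop_config("leaky_slope must be >= 0")
  structure(list(
    hidden_dim = as.integer(hidden_dim), lr_encoder = lr_encoder,
    lr_classifier = lr_classifier, dropout = dropout,
    leaky_slope = leaky_slope, epochs = as.integer(epochs),
    weight_decay = weight_decay, seed = as.integer(seed),
    use_attention = isTRUE(use_attention),
    use_self_expression = isTRUE(use_self_expression),
    class_weighting = isTRUE(class_weighting),
    fusion = match.arg(fusion)
  ), class = "model_config")
}

leaky_relu <- function(x, slope) ifelse(x > 0, x, slope * x)

row_softmax <- function(x) {
  x <- x - apply(x, 1, max)
  e <- exp(x)
  e / rowSums(e)
}

#' Graph convolution layer
#'
#' `H = activation(A_hat %*% (X %*% W) + b)` with a leaky rectifier
#' (slope 0 gives the plain rectifier).
#'
#' @param adjacency normalised adjacency
#' @param X node features
#' @param W,b weight matrix and bias vector
#' @param slope leaky-rectifier negative slope
#' @return hidden representation matrix
#' @export
gcn_layer <- function(adjacency, X, W, b, slope = 0.25) {
  if (ncol(X) != nrow(W)) stop_config("shape mismatch in gcn_layer")
  leaky_relu(adjacency %*% (X %*% W) + matrix(b, nrow(X), length(b),
                                              byrow = TRUE), slope)
}

#' Feature-wise self-expression
#'
#' `H' = H %*% C`: latent feature dimensions are re-expressed as linear
#' combinations of each other through the learned coefficient matrix `C`;
#' the node dimension is untouched.
#'
#' @param H hidden matrix (nodes x hidden)
#' @param C hidden x hidden coefficient matrix
#' @return reconstructed hidden matrix
#' @export
self_expression <- function(H, C) {
  if (ncol(H) != nrow(C)) stop_config("shape mismatch in self_expression")
  H %*% C
}

#' Scaled dot-product self-attention over nodes
#'
#' `A = softmax((H Q_w)(H K_w)' / sqrt(d_k))` row-wise;
#' `H'' = A %*% (H V_w)`.  Single head, `d_k` = projection width.
#'
#' @param H hidden matrix
#' @param Q_w,K_w,V_w projection matrices
#' @return list with `H` (attended output) and `attention` (row-stochastic
#'   weight matrix)
#' @export
self_attention <- function(H, Q_w, K_w, V_w) {
  if (ncol(H) != nrow(Q_w)) stop_config("shape mismatch in self_attention")
  dk <- ncol(Q_w)
  Q <- H %*% Q_w; Km <- H %*% K_w; V <- H %*% V_w
  A <- row_softmax(tcrossprod(Q, Km) / sqrt(dk))
  list(H = A %*% V, attention = A)
}

glorot <- function(n_in, n_out) {
  lim <- sqrt(6 / (n_in + n_out))
  matrix(runif(n_in * n_out, -lim, lim), n_in, n_out)
}

init_view_params <- function(p, h) {
  list(
    W = glorot(p, h), b = numeric(h),
    C = diag(h) + matrix(rnorm(h * h, sd = 0.01), h, h),
    Qw = glorot(h, h), Kw = glorot(h, h), Vw = glorot(h, h),
    Wc = glorot(h, 2), bc = numeric(2)
  )
}

# forward pass through one view; keeps intermediates for backprop
view_forward <- function(adj, X, par, cfg, training = FALSE,
                         drop_mask = NULL) {
  AX <- adj %*% X
  Z <- AX %*% par$W + matrix(par$b, nrow(X), length(par$b), byrow = TRUE)
  H1 <- leaky_relu(Z, cfg$leaky_slope)
  H2 <- if (cfg$use_self_expression) H1 %*% par$C else H1
  if (cfg$use_attention) {
    att <- self_attention(H2, par$Qw, par$Kw, par$Vw)
    H3 <- att$H
  } else {
    att <- NULL
    H3 <- H2
  }
  if (training && cfg$dropout > 0) {
    if (is.null(drop_mask))
      drop_mask <- matrix(runif(length(H3)) >= cfg$dropout, nrow(H3))
    H4 <- H3 * drop_mask / (1 - cfg$dropout)
  } else {
    drop_mask <- NULL
    H4 <- H3
  }
  logits <- H4 %*% par$Wc + matrix(par$bc, nrow(X), 2, byrow = TRUE)
  list(AX = AX, Z = Z, H1 = H1, H2 = H2, H3 = H3, H4 = H4, att = att,
       drop_mask = drop_mask, logits = logits)
}

view_backward <- function(fw, par, cfg, dlogits) {
  g <- list()
  g$Wc <- crossprod(fw$H4, dlogits)
  g$bc <- colSums(dlogits)
  dH4 <- dlogits %*% t(par$Wc)
  dH3 <- if (!is.null(fw$drop_mask))
    dH4 * fw$drop_mask / (1 - cfg$dropout) else dH4
  if (cfg$use_attention) {
    A <- fw$att$attention
    H2 <- fw$H2
    dk <- ncol(par$Qw)
    Q <- H2 %*% par$Qw; Km <- H2 %*% par$Kw; V <- H2 %*% par$Vw
    dA <- tcrossprod(dH3, V)           # dH3 %*% t(V)
    dV <- crossprod(A, dH3)
    dS <- A * (dA - rowSums(dA * A))
    dQ <- dS %*% Km / sqrt(dk)
    dK <- crossprod(dS, Q) / sqrt(dk)
    g$Qw <- crossprod(H2, dQ)
    g$Kw <- crossprod(H2, dK)
    g$Vw <- crossprod(H2, dV)
    dH2 <- dQ %*% t(par$Qw) + dK %*% t(par$Kw) + dV %*% t(par$Vw)
  } else {
    g$Qw <- g$Kw <- g$Vw <- matrix(0, nrow(par$Qw), ncol(par$Qw))
    dH2 <- dH3
  }
  if (cfg$use_self_expression) {
    g$C <- crossprod(fw$H1, dH2)
    dH1 <- dH2 %*% t(par$C)
  } else {
    g$C <- matrix(0, nrow(par$C), ncol(par$C))
    dH1 <- dH2
  }
  dZ <- dH1 * ifelse(fw$Z > 0, 1, cfg$leaky_slope)
  g$W <- crossprod(fw$AX, dZ)
  g$b <- colSums(dZ)
  g
}

adam_init <- function(par) lapply(par, function(p)
  list(m = p * 0, v = p * 0))

adam_step <- function(par, grad, state, lr, t, wd,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
                      decay_names = c("W", "C", "Qw", "Kw", "Vw", "Wc")) {
  for (nm in names(par)) {
    g <- grad[[nm]]
    if (wd > 0 && nm %in% decay_names) g <- g + wd * par[[nm]]
    state[[nm]]$m <- beta1 * state[[nm]]$m + (1 - beta1) * g
    state[[nm]]$v <- beta2 * state[[nm]]$v + (1 - beta2) * g^2
    mhat <- state[[nm]]$m / (1 - beta1^t)
    vhat <- state[[nm]]$v / (1 - beta2^t)
    par[[nm]] <- par[[nm]] - lr[[nm]] * mhat / (sqrt(vhat) + eps)
  }
  list(par = par, state = state)
}

check_graphs <- function(graphs) {
  if (inherits(graphs, "population_graph")) graphs <- list(view1 = graphs)
  n <- unique(vapply(graphs, function(g) nrow(g$adjacency), integer(1)))
  if (length(n) != 1)
    stop_config("all view graphs must share the same node set")
  graphs
}

#' Train the multi-view graph classifier
#'
#' One graph-convolution encoder, feature-wise self-expression, single-head
#' scaled dot-product self-attention, dropout and a linear classifier per
#' view; all views are optimised jointly for `epochs` steps, each with its
#' own Adam state (encoder and classifier head at their own learning rates).
#' The loss is the sum over views of class-weighted cross-entropy on the
#' training nodes.
#'
#' @param graphs named list of per-view `population_graph`s over the same
#'   subjects (training nodes only, or use `train_mask`)
#' @param labels binary labels, one per node
#' @param config a [model_config()]
#' @param train_mask logical mask of nodes contributing to the loss
#'   (default: the graphs' own train mask)
#' @return an object of class `gcnsase_model` with parameters, config and
#'   the per-epoch loss trace
#' @export
gcnsase_train <- function(graphs, labels, config = model_config(),
                          train_mask = NULL) {
  graphs <- check_graphs(graphs)
  n <- nrow(graphs[[1]]$adjacency)
  labels <- as.integer(labels)
  if (length(labels) != n) stop_config("labels must align with graph nodes")
  if (is.null(train_mask)) train_mask <- graphs[[1]]$train_mask
  y <- labels[train_mask]
  if (length(unique(y)) < 2)
    stop_config("training labels contain a single class")

  set.seed(child_seed(config$seed, 40L))
  h <- config$hidden_dim
  params <- lapply(graphs, function(g)
    init_view_params(ncol(g$node_features), h))
  states <- lapply(params, adam_init)
  lr <- list(W = config$lr_encoder, b = config$lr_encoder,
             C = config$lr_encoder, Qw = config$lr_encoder,
             Kw = config$lr_encoder, Vw = config$lr_encoder,
             Wc = config$lr_classifier, bc = config$lr_classifier)

  cw <- if (config$class_weighting) {
    tab <- table(factor(y, levels = c(0, 1)))
    length(y) / (2 * as.numeric(tab))
  } else c(1, 1)
  wt_node <- numeric(n)
  wt_node[train_mask] <- cw[labels[train_mask] + 1L]
  wsum <- sum(wt_node)
  onehot <- cbind(1 - labels, labels)

  loss_trace <- numeric(config$epochs)
  for (epoch in seq_len(config$epochs)) {
    total_loss <- 0
    for (v in names(graphs)) {
      g <- graphs[[v]]
      fw <- view_forward(g$adjacency, g$node_features, params[[v]], config,
                         training = TRUE)
      probs <- row_softmax(fw$logits)
      li <- -log(pmax(probs[cbind(seq_len(n), labels + 1L)], 1e-12))
      total_loss <- total_loss + sum(wt_node * li) / wsum
      dlogits <- (probs - onehot) * wt_node / wsum
      grad <- view_backward(fw, params[[v]], config, dlogits)
      upd <- adam_step(params[[v]], grad, states[[v]], lr, epoch,
                       config$weight_decay)
      params[[v]] <- upd$par
      states[[v]] <- upd$state
    }
    loss_trace[epoch] <- total_loss
  }

  structure(list(
    params = params, config = config, loss_trace = loss_trace,
    view_names = names(graphs), trained = TRUE
  ), class = "gcnsase_model")
}

#' @export
print.gcnsase_model <- function(x, ...) {
  cat(sprintf(
    "gcnsase_model: %d view(s), hidden %d, %d epochs, final loss %.4f\n",
    length(x$view_names), x$config$hidden_dim, x$config$epochs,
    utils::tail(x$loss_trace, 1)))
  invisible(x)
}

#' Forward pass of the trained classifier
#'
#' @param model a `gcnsase_model`
#' @param graphs named per-view `population_graph`s (attached nodes allowed)
#' @param training if `TRUE`, dropout is active (used internally)
#' @return list with `per_view_logits` and fused `probs` (rows sum to 1)
#' @export
gcnsase_forward <- function(model, graphs, training = FALSE) {
  graphs <- check_graphs(graphs)
  if (!setequal(names(graphs), model$view_names))
    stop_config("missing view: model expects %s",
                paste(model$view_names, collapse = ", "))
  logits <- list()
  probs <- NULL
  for (v in model$view_names) {
    g <- graphs[[v]]
    fw <- view_forward(g$adjacency, g$node_features, model$params[[v]],
                       model$config, training = training)
    logits[[v]] <- fw$logits
    pv <- if (model$config$fusion == "prob_mean") row_softmax(fw$logits)
          else fw$logits
    probs <- if (is.null(probs)) pv else probs + pv
  }
  probs <- probs / length(logits)
  if (model$config$fusion == "logit_mean") probs <- row_softmax(probs)
  colnames(probs) <- c("class0", "class1")
  list(per_view_logits = logits, probs = probs)
}

#' Fused class probabilities for query nodes
#'
#' @param model a trained `gcnsase_model`
#' @param graphs per-view graphs extended with [attach_nodes()]
#' @param query_mask logical mask of nodes to report (default: the attached,
#'   non-training nodes)
#' @return probability matrix, rows summing to 1
#' @export
predict_proba <- function(model, graphs, query_mask = NULL) {
  if (!isTRUE(model$trained)) stop_config("model is not trained")
  graphs <- check_graphs(graphs)
  if (is.null(query_mask)) query_mask <- !graphs[[1]]$train_mask
  out <- gcnsase_forward(model, graphs, training = FALSE)
  out$probs[query_mask, , drop = FALSE]
}
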