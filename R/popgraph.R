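#' Population-graph configuration
#'
#' @param k_neighbors number of nearest neighbours retained per node (must be
#'   >= 1 and smaller than the node count at build time); the usual search
#'   space is \{5, 10, 15, 20\}
#' @param tau optional similarity threshold sparsifier used instead of kNN
#'   when supplied (no default value)
#' @return an object of class `graph_config`
#' @export
graph_config <- function(k_neighbors = 10L, tau = NULL) {
  if (k_neighbors < 1) stop_config("k_neighbors must be >= 1")
  structure(list(k_neighbors = as.integer(k_neighbors),
                 similarity = "cosine", tau = tau),
            class = "graph_config")
}

#' Cosine similarity matrix between subject rows
#'
#' `S[i, j] = x_i . x_j / (||x_i|| ||x_j||)`; all-zero rows get similarity 0
#' to every other node (with a warning) and 1 on the diagonal.
#'
#' @param X subjects x features numeric matrix
#' @return symmetric similarity matrix with unit diagonal
#' @export
cosine_similarity_matrix <- function(X) {
  check_matrix(X, "X")
  nrm <- sqrt(rowSums(X^2))
  zero <- nrm < .Machine$double.eps
  if (any(zero)) {
    warning("all-zero rows: similarity set to 0 for those nodes")
    nrm[zero] <- 1
  }
  S <- tcrossprod(X / nrm)
  if (any(zero)) { S[zero, ] <- 0; S[, zero] <- 0 }
  S <- (S + t(S)) / 2
  diag(S) <- 1
  S
}

#' k-nearest-neighbour sparsification of a similarity matrix
#'
#' Keeps each row's `k` largest off-diagonal similarities (ties broken toward
#' the lower column index), symmetrises by elementwise maximum (union kNN),
#' and clips retained negative similarities to 0.  When `tau` is supplied it
#' replaces the kNN rule: off-diagonal entries `>= tau` are kept.
#'
#' @param S symmetric similarity matrix
#' @param k neighbours per node (`k < n`)
#' @param tau optional similarity threshold used instead of kNN
#' @return sparse symmetric nonnegative adjacency with zero diagonal
#' @export
knn_sparsify <- function(S, k, tau = NULL) {
  n <- nrow(S)
  if (!is.null(tau)) {
    A <- S
    diag(A) <- 0
    A[A < tau] <- 0
    return(pmax(pmax(A, t(A)), 0))
  }
  if (k >= n) stop_config("k must be smaller than the number of nodes")
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    s <- S[i, ]
    s[i] <- -Inf
    keep <- order(-s, seq_len(n))[seq_len(k)]
    A[i, keep] <- S[i, keep]
  }
  A <- pmax(A, t(A))  # union symmetrisation
  pmax(A, 0)
}

#' Symmetric normalisation with self-loops
#'
#' `A_hat = D^{-1/2} (A + I) D^{-1/2}` with `D` the degree diagonal of
#' `A + I`.  The self-loop guarantees positive degree, so isolated nodes are
#' well-defined.
#'
#' @param A symmetric nonnegative adjacency (zero diagonal expected)
#' @return normalised adjacency
#' @export
normalize_adjacency <- function(A) {
  if (any(A < 0)) stop_config("adjacency must be nonnegative")
  n <- nrow(A)
  Ai <- A + diag(n)
  dinv <- 1 / sqrt(rowSums(Ai))
  Ai * tcrossprod(dinv)
}

#' Build a population graph from node features
#'
#' Composition of cosine similarity, kNN sparsification and symmetric
#' normalisation.  Labels are never consulted (the API takes none), so graph
#' construction is leakage-free by design; build it on training rows only.
#'
#' @param X subjects x selected-features matrix (training rows)
#' @param config a [graph_config()]
#' @param node_ids optional subject identifiers
#' @return an object of class `population_graph` with fields `adjacency`
#'   (normalised), `raw_adjacency`, `node_features`, `node_ids`,
#'   `train_mask`, `config`
#' @export
build_graph <- function(X, config = graph_config(), node_ids = NULL) {
  check_matrix(X, "X")
  S <- cosine_similarity_matrix(X)
  A <- knn_sparsify(S, config$k_neighbors, config$tau)
  if (is.null(node_ids)) node_ids <- rownames(X)
  if (is.null(node_ids)) node_ids <- sprintf("n%04d", seq_len(nrow(X)))
  structure(list(
    adjacency = normalize_adjacency(A), raw_adjacency = A,
    node_features = X, node_ids = node_ids,
    train_mask = rep(TRUE, nrow(X)), config = config
  ), class = "population_graph")
}

#' @export
print.population_graph <- function(x, ...) {
  cat(sprintf("population_graph: %d nodes (%d training), k = %d, %d edges\n",
              nrow(x$adjacency), sum(x$train_mask), x$config$k_neighbors,
              sum(x$raw_adjacency > 0) / 2))
  invisible(x)
}

#' Attach held-out nodes to a fitted population graph
#'
#' Each new node is connected to its `k` most cosine-similar training nodes;
#' new-to-new edges are never created, and the extended adjacency is
#' renormalised.  The extended `train_mask` marks attached nodes `FALSE`.
#'
#' @param graph a `population_graph` built on training rows
#' @param X_new held-out rows with the same feature columns
#' @param k neighbours per attached node (default: the graph's k)
#' @return the extended `population_graph`
#' @export
attach_nodes <- function(graph, X_new, k = graph$config$k_neighbors) {
  if (ncol(X_new) != ncol(graph$node_features))
    stop_config("feature mismatch between new nodes and graph")
  n_new <- nrow(X_new)
  if (n_new == 0) return(graph)
  X_tr <- graph$node_features
  n_tr <- nrow(X_tr)
  k <- min(k, n_tr)

  nrm_tr <- sqrt(rowSums(X_tr^2)); nrm_tr[nrm_tr < .Machine$double.eps] <- 1
  nrm_nw <- sqrt(rowSums(X_new^2)); nrm_nw[nrm_nw < .Machine$double.eps] <- 1
  S <- (X_new / nrm_nw) %*% t(X_tr / nrm_tr)  # n_new x n_tr

  A <- matrix(0, n_tr + n_new, n_tr + n_new)
  A[seq_len(n_tr), seq_len(n_tr)] <- graph$raw_adjacency
  for (i in seq_len(n_new)) {
    keep <- order(-S[i, ], seq_len(n_tr))[seq_len(k)]
    w <- pmax(S[i, keep], 0)
    A[n_tr + i, keep] <- w
    A[keep, n_tr + i] <- w
  }
  new_ids <- rownames(X_new)
  if (is.null(new_ids)) new_ids <- sprintf("q%04d", seq_len(n_new))
  structure(list(
    adjacency = normalize_adjacency(A), raw_adjacency = A,
    node_features = rbind(X_tr, X_new),
    node_ids = c(graph$node_ids, new_ids),
    train_mask = c(graph$train_mask, rep(FALSE, n_new)),
    config = graph$config
  ), class = "population_graph")
}
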