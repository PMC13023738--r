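#' Penalty configuration for the sparse multi-view CCA solvers
#'
#' Each view k carries the composite penalty
#' `lambda_k * (beta_k * FGL(w_k) + (1 - beta_k) * ||w_k||_1)`, where FGL is
#' the fused-group lasso: the sum of Euclidean norms of `w` over feature
#' groups (default grouping: overlapping adjacent index pairs).  For the
#' uncertainty-weighted solver only the first view mixes in the fused-group
#' term; the remaining views carry a plain lasso.
#'
#' @param lambdas per-view regularisation strengths (recycled to the number
#'   of views); all >= 0
#' @param beta mix between fused-group (beta) and plain lasso (1 - beta),
#'   in \[0, 1\]
#' @param groups optional list (one entry per view) of integer-vector feature
#'   groups for the FGL term; `NULL` means adjacent pairs
#' @return an object of class `penalty_config`
#' @export
penalty_config <- function(lambdas = 0.1, beta = 0.5, groups = NULL) {
  if (any(lambdas < 0)) stop_config("lambdas must be >= 0")
  if (beta < 0 || beta > 1) stop_config("beta must lie in [0, 1]")
  structure(list(lambdas = lambdas, beta = beta, groups = groups),
            class = "penalty_config")
}

#' Solver options for the alternating SMCCA optimizers
#'
#' @param max_iter outer iteration cap
#' @param tol convergence tolerance on the max absolute weight change
#' @param eps smoothing floor for the un-squared loss / variance estimates
#' @param cd_sweeps coordinate-descent sweeps per inner solve
#' @param cd_tol coordinate-descent convergence tolerance
#' @param mm_steps majorization rounds for the fused-group term per update
#' @param monotone if `TRUE`, a per-view update is accepted only when it does
#'   not increase the objective (guards the descent property through the
#'   scale renormalisation)
#' @return a list of options
#' @export
solver_options <- function(max_iter = 100L, tol = 1e-5, eps = 1e-6,
                           cd_sweeps = 30L, cd_tol = 1e-8, mm_steps = 3L,
                           monotone = TRUE) {
  list(max_iter = as.integer(max_iter), tol = tol, eps = eps,
       cd_sweeps = as.integer(cd_sweeps), cd_tol = cd_tol,
       mm_steps = as.integer(mm_steps), monotone = isTRUE(monotone))
}

#' Soft-thresholding operator
#'
#' `sign(x) * max(|x| - t, 0)`, the proximal operator of the l1 penalty.
#'
#' @param x numeric value(s)
#' @param t threshold (>= 0)
#' @return thresholded value(s)
#' @export
soft_threshold <- function(x, t) {
  if (any(t < 0)) stop_config("threshold must be >= 0")
  sign(x) * pmax(abs(x) - t, 0)
}

default_groups <- function(p) {
  if (p < 2) return(list(1L))
  lapply(seq_len(p - 1L), function(j) c(j, j + 1L))
}

#' Fused-group lasso penalty value
#'
#' Sum over groups g of `||w[g]||_2`.  The default grouping is overlapping
#' adjacent index pairs \{j, j+1\}.
#'
#' @param w numeric weight vector
#' @param groups list of integer vectors; `NULL` for adjacent pairs
#' @return the penalty value
#' @export
fused_group_penalty <- function(w, groups = NULL) {
  if (is.null(groups)) groups <- default_groups(length(w))
  idx <- unlist(groups)
  if (any(idx < 1) || any(idx > length(w)))
    stop_config("group index out of range")
  sum(vapply(groups, function(g) sqrt(sum(w[g]^2)), numeric(1)))
}

# quadratic majorization diagonal of the FGL term at w0:
# D_l = sum over groups containing l of 1 / (2 max(||w0[g]||, eps))
fgl_majorization_diag <- function(w0, groups, eps) {
  D <- numeric(length(w0))
  for (g in groups) {
    nrm <- max(sqrt(sum(w0[g]^2)), eps)
    D[g] <- D[g] + 1 / (2 * nrm)
  }
  D
}

get_views <- function(dataset) {
  if (inherits(dataset, "multimodal_dataset")) return(dataset$views)
  if (is.list(dataset) && all(vapply(dataset, is.matrix, logical(1)))) {
    if (is.null(names(dataset)))
      names(dataset) <- sprintf("view%d", seq_along(dataset))
    return(dataset)
  }
  stop_config("dataset must be a multimodal_dataset or a list of matrices")
}

smcca_penalty_value <- function(weights, lambdas, betas, groups) {
  tot <- 0
  for (k in seq_along(weights)) {
    w <- weights[[k]]
    fg <- if (betas[k] > 0) fused_group_penalty(w, groups[[k]]) else 0
    tot <- tot + lambdas[k] * (betas[k] * fg + (1 - betas[k]) * sum(abs(w)))
  }
  tot
}

smcca_objective <- function(Xs, weights, lambdas, betas, groups, method,
                            sigma = NULL) {
  K <- length(Xs)
  V <- lapply(seq_len(K), function(k) drop(Xs[[k]] %*% weights[[k]]))
  loss <- 0
  for (i in seq_len(K - 1)) for (j in seq(i + 1, K)) {
    d <- sqrt(sum((V[[i]] - V[[j]])^2))
    if (method == "rAdaSMCCA") {
      loss <- loss + d
    } else {
      s <- sigma[i, j]
      loss <- loss + d^2 / (2 * s^2) + log(s)
    }
  }
  loss + smcca_penalty_value(weights, lambdas, betas, groups)
}

fit_smcca_core <- function(dataset, penalty, opts, method) {
  views <- get_views(dataset)
  K <- length(views)
  if (K < 2) stop_config("need >= 2 views")
  for (v in names(views)) check_matrix(views[[v]], v)
  if (any(vapply(views, function(x) all(abs(x) < .Machine$double.eps),
                 logical(1))))
    stop_config("degenerate: a view is entirely zero")

  std <- lapply(views, standardize_columns)
  Xs <- lapply(std, `[[`, "x")
  ps <- vapply(Xs, ncol, integer(1))
  n <- nrow(Xs[[1]])

  lambdas <- rep_len(penalty$lambdas, K)
  betas <- rep(penalty$beta, K)
  if (method == "unAdaSMCCA" && K > 1) betas[-1] <- 0
  groups <- penalty$groups
  if (is.null(groups)) groups <- lapply(ps, default_groups)

  Gs <- lapply(Xs, crossprod)
  weights <- lapply(ps, function(p) rep(1 / sqrt(p), p))
  for (k in seq_len(K)) {
    s <- sqrt(sum((Xs[[k]] %*% weights[[k]])^2))
    weights[[k]] <- weights[[k]] / s
  }

  eps <- opts$eps
  sigma <- matrix(NA_real_, K, K)
  trace <- numeric(0)
  converged <- FALSE

  variates <- function(ws) lapply(seq_len(K), function(k)
    drop(Xs[[k]] %*% ws[[k]]))

  for (iter in seq_len(opts$max_iter)) {
    w_prev <- weights
    V <- variates(weights)
    delta <- matrix(0, K, K)
    for (i in seq_len(K - 1)) for (j in seq(i + 1, K)) {
      d <- sqrt(sum((V[[i]] - V[[j]])^2))
      if (method == "rAdaSMCCA") {
        delta[i, j] <- delta[j, i] <- 1 / (2 * max(d, eps))
      } else {
        s <- max(d, eps)  # closed-form stationary point of d^2/(2s^2) + log s
        sigma[i, j] <- sigma[j, i] <- s
        delta[i, j] <- delta[j, i] <- 1 / (2 * s^2)
      }
    }
    obj_cur <- smcca_objective(Xs, weights, lambdas, betas, groups, method,
                               sigma)

    for (k in seq_len(K)) {
      others <- setdiff(seq_len(K), k)
      S <- sum(delta[k, others])
      target <- Reduce(`+`, lapply(others, function(j) delta[k, j] * V[[j]]))
      cvec <- drop(crossprod(Xs[[k]], target))
      l1 <- lambdas[k] * (1 - betas[k])
      w_cand <- weights[[k]]
      for (m in seq_len(opts$mm_steps)) {
        ridge <- if (betas[k] > 0)
          lambdas[k] * betas[k] *
            fgl_majorization_diag(w_cand, groups[[k]], eps)
        else numeric(ps[k])
        w_cand <- .cd_quad_lasso(Gs[[k]], cvec, S, ridge, l1, w_cand,
                                 opts$cd_sweeps, opts$cd_tol)
        if (betas[k] == 0) break
      }
      s <- sqrt(sum((Xs[[k]] %*% w_cand)^2))
      if (s > 1e-10) w_cand <- w_cand / s else w_cand <- numeric(ps[k])

      if (opts$monotone) {
        trial <- weights; trial[[k]] <- w_cand
        obj_new <- smcca_objective(Xs, trial, lambdas, betas, groups, method,
                                   sigma)
        if (obj_new <= obj_cur + 1e-10) {
          weights <- trial
          obj_cur <- obj_new
          V[[k]] <- drop(Xs[[k]] %*% w_cand)
        }
      } else {
        weights[[k]] <- w_cand
        V[[k]] <- drop(Xs[[k]] %*% w_cand)
      }
    }

    trace <- c(trace, obj_cur)
    dw <- max(vapply(seq_len(K), function(k)
      max(abs(weights[[k]] - w_prev[[k]])), numeric(1)))
    if (dw < opts$tol) { converged <- TRUE; break }
  }

  names(weights) <- names(views)
  for (k in seq_len(K)) names(weights[[k]]) <- colnames(views[[k]])
  degenerate <- all(vapply(weights, function(w) all(w == 0), logical(1)))
  structure(list(
    weights = weights, penalty = penalty, objective_trace = trace,
    sigma = if (method == "unAdaSMCCA") sigma else NULL,
    converged = converged, degenerate = degenerate, method = method,
    centers = lapply(std, `[[`, "center"),
    scales = lapply(std, `[[`, "scale"),
    view_names = names(views), n = n
  ), class = "canonical_model")
}

#' Fit the robust adaptive sparse multi-view CCA
#'
#' Minimises the sum over view pairs of the un-squared distance
#' `||X_i w_i - X_j w_j||_2` plus composite fused-group/lasso penalties,
#' subject to the scale convention `||X_k w_k||_2 = 1`.  The un-squared loss
#' damps gradient dominance by strongly-correlated pairs; it is optimised by
#' iteratively reweighted least squares (half-quadratic smoothing with floor
#' `eps`), each view subproblem solved by proximal coordinate descent with a
#' quadratic majorization of the fused-group term, followed by
#' renormalisation.  Updates that would increase the objective are rejected,
#' so the recorded trace is non-increasing.
#'
#' @param dataset a `multimodal_dataset` or list of subject-aligned matrices
#'   (columns are standardised internally; the transform is stored on the
#'   model and replayed on new data)
#' @param penalty a [penalty_config()]
#' @param opts a [solver_options()]
#' @return an object of class `canonical_model`
#' @export
fit_radasmcca <- function(dataset, penalty = penalty_config(),
                          opts = solver_options()) {
  fit_smcca_core(dataset, penalty, opts, "rAdaSMCCA")
}

#' Fit the uncertainty-weighted adaptive sparse multi-view CCA
#'
#' Minimises `sum_{i<j} d_ij^2 / (2 sigma_ij^2) + log sigma_ij` plus
#' penalties, alternating the closed-form variance update
#' `sigma_ij = max(d_ij, eps)` (the stationary point of
#' `d^2/(2 s^2) + log s`) with penalized weighted least-squares view updates.
#' Per the model definition, only the first view mixes the fused-group term;
#' the remaining views carry a plain lasso (the bare norm in the original
#' formulation is interpreted as l1, consistent with the sparsity intent;
#' switch by setting `penalty$beta` and per-view `groups`).
#'
#' @inheritParams fit_radasmcca
#' @return an object of class `canonical_model` with `$sigma` holding the
#'   pairwise uncertainty estimates
#' @export
fit_unadasmcca <- function(dataset, penalty = penalty_config(),
                           opts = solver_options()) {
  fit_smcca_core(dataset, penalty, opts, "unAdaSMCCA")
}

#' @export
print.canonical_model <- function(x, ...) {
  nz <- vapply(x$weights, function(w) sum(w != 0), integer(1))
  cat(sprintf("canonical_model (%s): %d views, converged=%s\n", x$method,
              length(x$weights), x$converged))
  cat("  nonzero weights:", paste(sprintf("%s=%d", names(nz), nz),
                                  collapse = ", "), "\n")
  invisible(x)
}

# project raw view matrices through a fitted model's standardisation + weights
canonical_variates <- function(model, views) {
  lapply(seq_along(model$view_names), function(k) {
    v <- model$view_names[k]
    x <- views[[v]]
    xs <- standardize_columns(x, model$centers[[k]], model$scales[[k]])$x
    drop(xs %*% model$weights[[k]])
  })
}

#' Pairwise canonical correlation score
#'
#' Absolute Pearson correlation between each pair of canonical variates
#' `X_i w_i`, `X_j w_j`, and their mean.  A zero-variance variate scores 0
#' for its pairs, with a warning.
#'
#' @param dataset data whose views conform with the model (standardised with
#'   the model's stored training transform)
#' @param model a `canonical_model`
#' @return an object of class `association_score` with fields `pairwise`
#'   (named vector) and `mean_ccc`
#' @export
pairwise_ccc <- function(dataset, model) {
  views <- get_views(dataset)
  V <- canonical_variates(model, views)
  K <- length(V)
  out <- c(); nm <- c()
  for (i in seq_len(K - 1)) for (j in seq(i + 1, K)) {
    if (sd(V[[i]]) < 1e-12 || sd(V[[j]]) < 1e-12) {
      warning("zero-variance canonical variate; pair scored 0")
      r <- 0
    } else r <- abs(cor(V[[i]], V[[j]]))
    out <- c(out, r)
    nm <- c(nm, paste0(model$view_names[i], ":", model$view_names[j]))
  }
  names(out) <- nm
  structure(list(pairwise = out, mean_ccc = mean(out)),
            class = "association_score")
}

#' Nested model selection by validation canonical correlation
#'
#' Splits the provided (training-only) data into `folds` internal folds; for
#' each candidate method and lambda configuration, fits on the remaining
#' folds and scores the mean absolute canonical correlation on the held-out
#' fold.  The configuration with the highest mean validation score is
#' refitted on all provided rows.
#'
#' @param dataset a training partition (`multimodal_dataset` or view list)
#' @param methods subset of `c("rAdaSMCCA", "unAdaSMCCA")`
#' @param grid numeric vector of candidate lambda values; with
#'   `expand = "shared"` each value is used for all views (tractable
#'   default), with `"factorial"` the full per-view cross product is searched
#' @param folds number of internal folds
#' @param beta fused-group/lasso mix passed to [penalty_config()]
#' @param seed integer seed for the fold shuffle
#' @param opts [solver_options()] used for the internal fits
#' @param expand `"shared"` or `"factorial"`
#' @return list with `method`, `penalty`, `model` (refit on all rows), and
#'   `table` of per-configuration validation scores
#' @export
select_model <- function(dataset,
                         methods = c("rAdaSMCCA", "unAdaSMCCA"),
                         grid = c(0.01, 0.1, 1, 10), folds = 5L,
                         beta = 0.5, seed = 1L,
                         opts = solver_options(max_iter = 30L),
                         expand = c("shared", "factorial")) {
  expand <- match.arg(expand)
  if (length(grid) == 0) stop_config("empty lambda grid")
  views <- get_views(dataset)
  n <- nrow(views[[1]])
  K <- length(views)
  set.seed(child_seed(seed, 20L))
  fold_id <- sample(rep_len(seq_len(folds), n))

  configs <- if (expand == "shared") {
    lapply(grid, function(l) rep(l, K))
  } else {
    grids <- rep(list(grid), K)
    lapply(seq_len(nrow(do.call(expand.grid, grids))), function(i)
      as.numeric(do.call(expand.grid, grids)[i, ]))
  }

  fitters <- list(rAdaSMCCA = fit_radasmcca, unAdaSMCCA = fit_unadasmcca)
  rows <- list()
  best <- list(score = -Inf)
  for (m in methods) {
    for (lam in configs) {
      pen <- penalty_config(lambdas = lam, beta = beta)
      scores <- vapply(seq_len(folds), function(f) {
        tr <- which(fold_id != f); va <- which(fold_id == f)
        fit <- fitters[[m]](lapply(views, function(v)
          v[tr, , drop = FALSE]), pen, opts)
        if (fit$degenerate) return(0)
        pairwise_ccc(lapply(views, function(v) v[va, , drop = FALSE]),
                     fit)$mean_ccc
      }, numeric(1))
      sc <- mean(scores)
      rows[[length(rows) + 1]] <- data.frame(
        method = m, lambdas = paste(lam, collapse = "/"), mean_ccc = sc)
      if (sc > best$score)
        best <- list(score = sc, method = m, penalty = pen)
    }
  }
  model <- fitters[[best$method]](views, best$penalty, solver_options())
  list(method = best$method, penalty = best$penalty, model = model,
       table = do.call(rbind, rows))
}

#' Rank features by absolute canonical weight
#'
#' Per view, features are ordered by descending `|w|` (stable on ties,
#' preserving original feature order) and the top `ceiling(r * dim)` are
#' retained.  The near-equivalent alternative of ranking by each feature's
#' absolute correlation with its view's canonical variate is available via
#' `by = "correlation"` (requires `dataset`); the two orders coincide only
#' approximately, and the weight rule is the default because it is what the
#' penalty directly controls.
#'
#' @param model a `canonical_model`
#' @param ratio retained feature ratio r in (0, 1\]
#' @param by `"weight"` (default) or `"correlation"`
#' @param dataset data used to compute feature-variate correlations when
#'   `by = "correlation"`
#' @return an object of class `feature_ranking`: per-view data.frames of
#'   `(feature, weight, abs_weight)` in rank order, plus `retained` index
#'   vectors (into the original column order) and the ratio
#' @export
rank_features <- function(model, ratio = 0.1, by = c("weight", "correlation"),
                          dataset = NULL) {
  by <- match.arg(by)
  if (ratio <= 0 || ratio > 1) stop_config("ratio must lie in (0, 1]")
  if (by == "correlation") {
    if (is.null(dataset))
      stop_config("dataset is required for correlation-based ranking")
    views <- get_views(dataset)
    variates <- canonical_variates(model, views)
  }
  per_view <- list()
  retained <- list()
  for (k in seq_along(model$weights)) {
    w <- model$weights[[k]]
    key <- if (by == "weight") abs(w) else {
      v <- variates[[k]]
      if (sd(v) < 1e-12) abs(w)  # degenerate variate: fall back to weights
      else abs(suppressWarnings(cor(views[[model$view_names[k]]], v)))
    }
    key[!is.finite(key)] <- 0
    ord <- order(-key, seq_along(w))
    nm <- names(w)
    if (is.null(nm)) nm <- sprintf("f%04d", seq_along(w))
    per_view[[model$view_names[k]]] <- data.frame(
      feature = nm[ord], weight = w[ord], abs_weight = abs(w[ord]),
      index = ord, stringsAsFactors = FALSE, row.names = NULL)
    n_keep <- ceiling(ratio * length(w))
    retained[[model$view_names[k]]] <- ord[seq_len(n_keep)]
  }
  structure(list(per_view = per_view, retained = retained, ratio = ratio),
            class = "feature_ranking")
}

#' @export
print.feature_ranking <- function(x, ...) {
  cat("feature_ranking (ratio =", x$ratio, ")\n")
  for (v in names(x$retained))
    cat(sprintf("  %-6s retains %d features\n", v, length(x$retained[[v]])))
  invisible(x)
}
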