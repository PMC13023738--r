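test_that("soft threshold matches its closed form", {
  expect_equal(soft_threshold(3.0, 1.0), 2.0)
  expect_equal(soft_threshold(-0.5, 1.0), 0.0)
  expect_equal(soft_threshold(-2.0, 0.5), -1.5)
  expect_error(soft_threshold(1, -1), ">= 0")
})

test_that("fused-group penalty enumerates group norms", {
  expect_equal(fused_group_penalty(c(0, 0, 0)), 0)
  expect_equal(fused_group_penalty(c(3, 4), groups = list(1:2)), 5)
  expect_equal(fused_group_penalty(c(1, 1, 1)), 2 * sqrt(2))
  expect_error(fused_group_penalty(c(1, 2), groups = list(c(1, 5))),
               "out of range")
})

test_that("both solvers fit correlated views and keep a monotone trace", {
  ds <- toy_dataset(seed = 3)
  for (fitter in list(fit_radasmcca, fit_unadasmcca)) {
    m <- fitter(ds, penalty_config(lambdas = 0.1, beta = 0.5))
    expect_true(all(diff(m$objective_trace) <= 1e-8))
    expect_gte(pairwise_ccc(ds, m)$mean_ccc, 0.9)
    # scale constraint on standardised views
    for (k in 1:3) {
      xs <- scale(ds$views[[k]])
      expect_equal(sqrt(sum((xs %*% m$weights[[k]])^2)), 1,
                   tolerance = 1e-6)
    }
  }
})

test_that("an overwhelming penalty produces the degenerate zero model", {
  ds <- toy_dataset(seed = 5)
  m <- fit_radasmcca(ds, penalty_config(lambdas = 1e6, beta = 0.5))
  expect_true(m$degenerate)
  expect_true(all(unlist(m$weights) == 0))
  w <- capture_warnings(cc <- pairwise_ccc(ds, m))  # one warning per pair
  expect_true(all(grepl("zero-variance", w)))
  expect_equal(cc$mean_ccc, 0)
})

test_that("noiseless rank-1 two-view data reaches near-perfect correlation", {
  set.seed(2)
  n <- 60
  z <- rnorm(n)
  X1 <- cbind(z, matrix(rnorm(n * 4, sd = 0.01), n))
  X2 <- cbind(z, matrix(rnorm(n * 3, sd = 0.01), n))
  colnames(X1) <- paste0("a", 1:5); colnames(X2) <- paste0("b", 1:4)
  m <- fit_radasmcca(list(v1 = X1, v2 = X2),
                     penalty_config(lambdas = 1e-4, beta = 0.5))
  expect_gte(pairwise_ccc(list(v1 = X1, v2 = X2), m)$mean_ccc, 0.99)
})

test_that("variance update equals the stationary point of its objective", {
  # sigma minimising d^2/(2 s^2) + log s is s = d: verify numerically
  for (d in c(0.5, 1.3, 2.7)) {
    opt <- optimize(function(s) d^2 / (2 * s^2) + log(s),
                    interval = c(1e-4, 50))
    expect_equal(opt$minimum, d, tolerance = 1e-4)
  }
  # and the solver records exactly that value for the iterate in hand:
  # after one outer iteration sigma equals the distance of the initial
  # (uniform, normalised) variates
  ds <- toy_dataset(seed = 9)
  opts <- solver_options(max_iter = 1L)
  m <- fit_unadasmcca(ds, penalty_config(lambdas = 0.1, beta = 0.5), opts)
  Xs <- lapply(ds$views, scale)
  w0 <- lapply(Xs, function(x) {
    w <- rep(1 / sqrt(ncol(x)), ncol(x))
    w / sqrt(sum((x %*% w)^2))
  })
  d12 <- sqrt(sum((Xs[[1]] %*% w0[[1]] - Xs[[2]] %*% w0[[2]])^2))
  expect_equal(m$sigma[1, 2], max(d12, 1e-6), tolerance = 1e-10)
  expect_true(all(m$sigma[upper.tri(m$sigma)] > 0))
})

test_that("identical views (zero pairwise distance) stay finite", {
  set.seed(4)
  X <- matrix(rnorm(40 * 6), 40, 6, dimnames = list(NULL, paste0("f", 1:6)))
  for (fitter in list(fit_radasmcca, fit_unadasmcca)) {
    m <- fitter(list(v1 = X, v2 = X), penalty_config(lambdas = 0.01))
    expect_true(all(is.finite(unlist(m$weights))))
  }
})

test_that("IRLS fixed point matches a generic numerical minimiser", {
  # 2-view, 3-feature toy: compare converged objective values
  set.seed(6)
  n <- 25
  z <- rnorm(n)
  X1 <- scale(cbind(z + rnorm(n, sd = 0.3), rnorm(n), rnorm(n)))
  X2 <- scale(cbind(z + rnorm(n, sd = 0.3), rnorm(n), rnorm(n)))
  colnames(X1) <- paste0("a", 1:3); colnames(X2) <- paste0("b", 1:3)
  lambda <- 0.05; beta <- 0.5
  m <- fit_radasmcca(list(v1 = X1, v2 = X2),
                     penalty_config(lambdas = lambda, beta = beta),
                     solver_options(max_iter = 300L, tol = 1e-9))
  solver_obj <- tail(m$objective_trace, 1)
  oracle_obj <- robust_objective_oracle(
    scale(X1), scale(X2), lambda, beta,
    extra_starts = list(unlist(m$weights)))
  # the oracle also polishes from the solver solution, so oracle <= solver;
  # agreement within 1e-4 certifies the IRLS fixed point
  expect_lte(abs(solver_obj - oracle_obj), 1e-4)
})

test_that("feature permutation permutes weights identically (lasso case)", {
  ds <- toy_dataset(seed = 12)
  pen <- penalty_config(lambdas = 0.2, beta = 0)  # singleton/no-group case
  tight <- solver_options(max_iter = 500L, tol = 1e-10, cd_sweeps = 200L,
                          cd_tol = 1e-13)
  m1 <- fit_radasmcca(ds, pen, tight)
  set.seed(1); perm <- lapply(ds$views, function(v) sample(ncol(v)))
  views_p <- lapply(seq_along(ds$views), function(k)
    ds$views[[k]][, perm[[k]], drop = FALSE])
  names(views_p) <- names(ds$views)
  m2 <- fit_radasmcca(views_p, pen, tight)
  for (k in 1:3)
    expect_equal(unname(m2$weights[[k]]), unname(m1$weights[[k]][perm[[k]]]),
                 tolerance = 1e-6)
})

test_that("sparsity is monotone in lambda over the standard grid", {
  ds <- toy_dataset(n = 80, seed = 15)
  nnz <- sapply(c(0.01, 0.1, 1, 10), function(l) {
    m <- fit_radasmcca(ds, penalty_config(lambdas = l, beta = 0.5))
    sum(unlist(m$weights) != 0)
  })
  expect_true(all(diff(nnz) <= 0))
})

test_that("pairwise CCC has the stated symmetries and null level", {
  set.seed(8)
  X <- matrix(rnorm(50 * 6), 50, 6, dimnames = list(NULL, paste0("f", 1:6)))
  views <- list(v1 = X, v2 = X, v3 = X)
  m <- fit_radasmcca(views, penalty_config(lambdas = 0.01))
  cc <- pairwise_ccc(views, m)
  expect_equal(unname(cc$pairwise), rep(cc$pairwise[[1]], 3))
  expect_equal(cc$mean_ccc, 1, tolerance = 1e-8)
  # scoring a fitted model on fresh independent noise stays near zero
  ds <- toy_dataset(n = 60, seed = 20)
  m2 <- fit_radasmcca(ds, penalty_config(lambdas = 0.1))
  set.seed(99)
  noise <- lapply(ds$views, function(v) {
    m <- matrix(rnorm(400 * ncol(v)), 400, ncol(v))
    colnames(m) <- colnames(v)
    m
  })
  expect_lte(pairwise_ccc(noise, m2)$mean_ccc, 0.2)
})

test_that("model selection picks the signal-bearing penalty", {
  ds <- toy_dataset(n = 80, seed = 30)
  sel <- select_model(ds, methods = "rAdaSMCCA", grid = c(0.1, 1e6),
                      folds = 3, seed = 1)
  expect_equal(sel$penalty$lambdas, rep(0.1, 3))
  # a single grid point is returned as-is; selection is deterministic
  sel1 <- select_model(ds, methods = "rAdaSMCCA", grid = 0.1, folds = 3,
                       seed = 2)
  expect_equal(sel1$penalty$lambdas, rep(0.1, 3))
  sel2 <- select_model(ds, methods = "rAdaSMCCA", grid = 0.1, folds = 3,
                       seed = 2)
  expect_identical(sel1$table, sel2$table)
  expect_error(select_model(ds, grid = numeric(0)), "empty")
})

test_that("feature ranking orders by |weight| with the ceiling rule", {
  m <- structure(list(weights = list(v1 = c(f1 = 0.1, f2 = -0.9, f3 = 0.5)),
                      view_names = "v1"), class = "canonical_model")
  rk <- rank_features(m, ratio = 1)
  expect_equal(rk$per_view$v1$index, c(2L, 3L, 1L))
  m140 <- structure(list(weights = list(v1 = rnorm(140)),
                         view_names = "v1"), class = "canonical_model")
  expect_length(rank_features(m140, 0.10)$retained$v1, 14)
  # stable ties: equal |weights| keep original order
  mt <- structure(list(weights = list(v1 = c(0.5, -0.5, 0.5)),
                       view_names = "v1"), class = "canonical_model")
  expect_equal(rank_features(mt, 1)$per_view$v1$index, 1:3)
  expect_error(rank_features(m, 0), "ratio")
})

test_that("correlation-based ranking approximates the weight-based order", {
  ds <- toy_dataset(n = 80, seed = 33)
  m <- fit_radasmcca(ds, penalty_config(lambdas = 0.1))
  rw <- rank_features(m, 0.5)
  rc <- rank_features(m, 0.5, by = "correlation", dataset = ds)
  # both rankings put the planted support (features 1-4) on top
  for (v in names(rw$retained)) {
    expect_true(all(1:4 %in% rw$retained[[v]]))
    expect_true(all(1:4 %in% rc$retained[[v]]))
  }
  expect_error(rank_features(m, 0.5, by = "correlation"), "dataset")
})
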