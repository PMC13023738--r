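#' Stratified development/test split
#'
#' Allocates `round(n * test_fraction)` subjects to the test set using
#' per-class largest-remainder rounding, so class proportions are preserved
#' as closely as integer counts allow (a 323-subject 26/297 cohort at 20%
#' yields exactly 65 test / 258 development subjects).
#'
#' @param labels binary vector
#' @param test_fraction fraction held out
#' @param seed integer seed
#' @return list with `dev_indices`, `test_indices`
#' @export
stratified_split <- function(labels, test_fraction = 0.2, seed = 1L) {
  labels <- as.integer(labels)
  n <- length(labels)
  classes <- sort(unique(labels))
  if (length(classes) < 2) stop_config("both classes must be present")
  n_test <- round(n * test_fraction)
  per_class <- vapply(classes, function(c) sum(labels == c), numeric(1))
  exact <- per_class * test_fraction
  base <- floor(exact)
  rem <- n_test - sum(base)
  if (rem > 0) {
    extra <- order(-(exact - base))[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  if (any(base < 1) || any(base >= per_class))
    stop_config("a class is too small for stratified allocation")
  set.seed(child_seed(seed, 30L))
  test_idx <- integer(0)
  for (ci in seq_along(classes)) {
    members <- which(labels == classes[ci])
    test_idx <- c(test_idx, sample(members, base[ci]))
  }
  test_idx <- sort(test_idx)
  list(dev_indices = setdiff(seq_len(n), test_idx), test_indices = test_idx)
}

#' Repeated stratified K-fold assignments
#'
#' Each repeat reshuffles with its own child seed; within a repeat, each
#' class is dealt into folds as evenly as possible, so per-fold class counts
#' differ by at most one from proportional allocation.  Defaults give
#' 10 x 5 = 50 (repeat, fold) validation sets.
#'
#' @param dev_labels binary labels of the development partition
#' @param repeats,folds protocol dimensions
#' @param seed integer seed
#' @return list of `repeats` integer vectors of fold ids (1..folds)
#' @export
make_folds <- function(dev_labels, repeats = 10L, folds = 5L, seed = 1L) {
  dev_labels <- as.integer(dev_labels)
  n <- length(dev_labels)
  classes <- sort(unique(dev_labels))
  if (min(table(dev_labels)) < folds)
    stop_config("folds exceed the minority class count")
  lapply(seq_len(repeats), function(r) {
    set.seed(child_seed(seed, 100L + r))
    fold_id <- integer(n)
    for (c in classes) {
      members <- sample(which(dev_labels == c))
      fold_id[members] <- rep_len(seq_len(folds), length(members))
    }
    fold_id
  })
}

#' Area under the ROC curve (Mann-Whitney formulation)
#'
#' Fraction of (positive, negative) pairs whose scores are correctly
#' ordered, ties counted one half; computed via midranks.
#'
#' @param scores numeric predicted scores
#' @param labels binary labels
#' @return AUC in \[0, 1\]
#' @export
auc <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0 || n0 == 0) stop_config("AUC undefined for a single class")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Percentile bootstrap confidence interval for a mean
#'
#' Resamples the supplied values (e.g. fold-level AUCs) with replacement and
#' returns the percentile interval of the resampled mean.
#'
#' @param values numeric vector (>= 2 values)
#' @param n_boot number of resamples
#' @param level confidence level
#' @param seed integer seed
#' @return named vector `c(lower, upper)`
#' @export
bootstrap_ci <- function(values, n_boot = 1000L, level = 0.95, seed = 1L) {
  if (length(values) < 2) stop_config("need >= 2 values")
  set.seed(child_seed(seed, 50L))
  means <- vapply(seq_len(n_boot), function(i)
    mean(sample(values, replace = TRUE)), numeric(1))
  alpha <- (1 - level) / 2
  ci <- unname(quantile(means, c(alpha, 1 - alpha), type = 7))
  c(lower = ci[1], upper = ci[2])
}

#' Paired Wilcoxon signed-rank test
#'
#' Zero differences are discarded (classic treatment); ranks of the absolute
#' differences use midranks for ties.  The two-sided p-value is exact (full
#' enumeration of sign assignments) for n <= 15 after zero removal, and a
#' normal approximation with tie correction and continuity correction
#' otherwise.
#'
#' @param a,b paired numeric vectors
#' @return list with `statistic` (V, the positive-rank sum), `p_value`, `n`
#'   (pairs used)
#' @export
wilcoxon_signed_rank <- function(a, b) {
  if (length(a) != length(b)) stop_config("a and b must have equal lengths")
  d <- a - b
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) return(list(statistic = 0, p_value = 1, n = 0L))
  r <- rank(abs(d), ties.method = "average")
  V <- sum(r[d > 0])
  if (n <= 15) {
    # exact: enumerate all 2^n sign assignments of the observed ranks
    sums <- 0
    for (i in seq_len(n)) {
      sums <- as.vector(outer(sums, c(0, r[i]), `+`))
    }
    mu <- n * (n + 1) / 4
    p <- mean(abs(sums - mu) >= abs(V - mu) - 1e-9)
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    if (sig2 <= 0) return(list(statistic = V, p_value = 1, n = n))
    z <- V - mu
    z <- (z - sign(z) * 0.5) / sqrt(sig2)
    p <- 2 * pnorm(-abs(z))
  }
  list(statistic = V, p_value = min(p, 1), n = as.integer(n))
}

#' Mann-Whitney rank-sum test (two independent groups)
#'
#' Midranks for ties; exact enumeration of group assignments for combined
#' n <= 20 (no ties), normal approximation with tie and continuity
#' correction otherwise.
#'
#' @param x,y numeric samples
#' @return list with `statistic` (U for `x`), `p_value`
#' @export
mann_whitney <- function(x, y) {
  if (length(x) == 0 || length(y) == 0) stop_config("empty group")
  nx <- length(x); ny <- length(y)
  r <- rank(c(x, y), ties.method = "average")
  U <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  has_ties <- anyDuplicated(c(x, y)) > 0
  if (nx + ny <= 20 && !has_ties) {
    combos <- utils::combn(nx + ny, nx)
    stats <- apply(combos, 2, function(idx)
      sum(r[idx]) - nx * (nx + 1) / 2)
    mu <- nx * ny / 2
    p <- mean(abs(stats - mu) >= abs(U - mu) - 1e-9)
  } else {
    mu <- nx * ny / 2
    ties <- table(r)
    sig2 <- nx * ny / 12 *
      ((nx + ny + 1) - sum(ties^3 - ties) / ((nx + ny) * (nx + ny - 1)))
    if (sig2 <= 0) return(list(statistic = U, p_value = 1))
    z <- U - mu
    z <- (z - sign(z) * 0.5) / sqrt(sig2)
    p <- 2 * pnorm(-abs(z))
  }
  list(statistic = U, p_value = min(p, 1))
}

#' Pipeline configuration for the cross-validated two-stage run
#'
#' @param deg a [deg_config()]; set `NULL` to skip the gene-view filter
#' @param method Stage I solver, `"rAdaSMCCA"` or `"unAdaSMCCA"`
#' @param penalty a [penalty_config()] used when `nested_selection` is off
#' @param nested_selection if `TRUE`, run [select_model()] inside every fold
#'   (slow); default reuses `penalty`
#' @param grid lambda grid for nested selection
#' @param ratio retained feature ratio
#' @param graph a [graph_config()]
#' @param model a [model_config()]
#' @param use_stage1_features ablation toggle: `FALSE` feeds raw
#'   (unselected) features to Stage II
#' @param min_genes lower bound on genes forwarded to Stage I when the
#'   differential-expression gate passes fewer (the top genes by p fill in)
#' @return a list of class `pipeline_config`
#' @export
pipeline_config <- function(deg = deg_config(), method = "rAdaSMCCA",
                            penalty = penalty_config(lambdas = 0.1),
                            nested_selection = FALSE,
                            grid = c(0.01, 0.1, 1, 10),
                            ratio = 0.1, graph = graph_config(),
                            model = model_config(),
                            use_stage1_features = TRUE,
                            min_genes = 10L) {
  structure(list(deg = deg, method = method, penalty = penalty,
                 nested_selection = nested_selection, grid = grid,
                 ratio = ratio, graph = graph, model = model,
                 use_stage1_features = use_stage1_features,
                 min_genes = as.integer(min_genes)),
            class = "pipeline_config")
}

# fit the full two-stage pipeline on training rows, score validation rows.
# Returns scores (P(class 1)) for the validation rows.
fit_score_pipeline <- function(dataset, train_idx, val_idx, config) {
  train <- subset_subjects(dataset, train_idx)
  val_views <- lapply(dataset$views, function(v) v[val_idx, , drop = FALSE])

  views_tr <- train$views
  views_va <- val_views

  gene_view <- if ("gene" %in% names(views_tr)) "gene" else NULL
  if (!is.null(config$deg) && !is.null(gene_view)) {
    stats <- moderate_variances(
      fit_gene_models(views_tr[[gene_view]], train$labels))
    keep <- select_degs(stats, config$deg)
    if (length(keep) < config$min_genes) {
      keep <- order(stats$p_value)[seq_len(config$min_genes)]
    }
    keep <- sort(keep)
    views_tr[[gene_view]] <- views_tr[[gene_view]][, keep, drop = FALSE]
    views_va[[gene_view]] <- views_va[[gene_view]][, keep, drop = FALSE]
  }

  if (config$use_stage1_features) {
    if (isTRUE(config$nested_selection)) {
      sel <- select_model(views_tr, grid = config$grid,
                          beta = config$penalty$beta,
                          seed = config$model$seed)
      cm <- sel$model
    } else {
      fitter <- if (config$method == "unAdaSMCCA") fit_unadasmcca
                else fit_radasmcca
      cm <- fitter(views_tr, config$penalty)
    }
    ranking <- rank_features(cm, config$ratio)
    sel_tr <- lapply(names(views_tr), function(v)
      views_tr[[v]][, ranking$retained[[v]], drop = FALSE])
    sel_va <- lapply(names(views_va), function(v)
      views_va[[v]][, ranking$retained[[v]], drop = FALSE])
    names(sel_tr) <- names(views_tr); names(sel_va) <- names(views_va)
  } else {
    sel_tr <- views_tr; sel_va <- views_va
  }

  # per-view: standardise on training rows, build graph, then attach
  graphs_tr <- list(); graphs_full <- list()
  for (v in names(sel_tr)) {
    std <- standardize_columns(sel_tr[[v]])
    g <- build_graph(std$x, config$graph)
    xva <- standardize_columns(sel_va[[v]], std$center, std$scale)$x
    graphs_tr[[v]] <- g
    graphs_full[[v]] <- attach_nodes(g, xva)
  }
  model <- gcnsase_train(graphs_tr, train$labels, config$model)
  probs <- predict_proba(model, graphs_full)
  probs[, "class1"]
}

#' Repeated stratified cross-validation of the two-stage pipeline
#'
#' Per (repeat, fold): the differential-expression filter, Stage I fit and
#' feature ranking, per-view feature subsetting, graph construction and
#' classifier training all see only the training partition; the held-out
#' fold is attached to the trained graphs and scored by AUC.  A leakage
#' guard snapshots the validation rows before each fold and verifies they
#' are untouched afterwards.  Optional comparator scorers (functions
#' `f(X_train, y_train, X_val) -> scores`) are evaluated on identical folds
#' for paired testing.
#'
#' @param dataset the development partition (`multimodal_dataset`)
#' @param config a [pipeline_config()]
#' @param comparators named list of comparator scorer functions
#' @param repeats,folds protocol dimensions
#' @param seed integer seed for fold shuffles
#' @return an object of class `cv_result`: per-iteration AUCs (per model),
#'   mean, sd, bootstrap CI, per-iteration predictions, fold hash
#' @export
run_rscv <- function(dataset, config = pipeline_config(),
                     comparators = NULL, repeats = 10L, folds = 5L,
                     seed = 1L) {
  fold_plans <- make_folds(dataset$labels, repeats, folds, seed)
  models <- c("pipeline", names(comparators))
  aucs <- matrix(NA_real_, repeats * folds, length(models),
                 dimnames = list(NULL, models))
  preds <- vector("list", repeats * folds)
  it <- 0L
  for (r in seq_len(repeats)) {
    fold_id <- fold_plans[[r]]
    for (f in seq_len(folds)) {
      it <- it + 1L
      val_idx <- which(fold_id == f)
      train_idx <- which(fold_id != f)
      guard <- lapply(dataset$views, function(v) v[val_idx, , drop = FALSE])

      scores <- fit_score_pipeline(dataset, train_idx, val_idx, config)
      aucs[it, "pipeline"] <- auc(scores, dataset$labels[val_idx])
      preds[[it]] <- list(repeat_ = r, fold = f, indices = val_idx,
                          scores = scores)

      if (!is.null(comparators)) {
        Xtr <- do.call(cbind, lapply(dataset$views, function(v)
          v[train_idx, , drop = FALSE]))
        Xva <- do.call(cbind, lapply(dataset$views, function(v)
          v[val_idx, , drop = FALSE]))
        for (cm in names(comparators)) {
          sc <- comparators[[cm]](Xtr, dataset$labels[train_idx], Xva)
          aucs[it, cm] <- auc(sc, dataset$labels[val_idx])
        }
      }

      after <- lapply(dataset$views, function(v) v[val_idx, , drop = FALSE])
      if (!identical(guard, after))
        stop("leakage guard tripped: validation rows were modified")
    }
  }
  summary <- data.frame(
    model = models,
    mean_auc = colMeans(aucs), sd_auc = apply(aucs, 2, sd),
    row.names = NULL)
  cis <- t(vapply(models, function(m)
    bootstrap_ci(aucs[, m], seed = seed), numeric(2)))
  summary$ci_lower <- cis[, 1]; summary$ci_upper <- cis[, 2]
  structure(list(
    aucs = aucs, summary = summary, predictions = preds,
    repeats = repeats, folds = folds, seed = seed,
    fold_hash = sum(vapply(fold_plans, function(x)
      sum(x * seq_along(x)), numeric(1)))
  ), class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("cv_result: %d x %d = %d iterations\n", x$repeats, x$folds,
              nrow(x$aucs)))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Ablation runner over identical folds
#'
#' Runs [run_rscv()] once per case with the same fold seed, so all cases are
#' evaluated on identical partitions and can be compared pairwise.  The
#' conventional cases: 0 = full model; 1 = without Stage I feature
#' extraction (raw features); 2 = without self-attention; 3/4 = alternative
#' hidden widths.
#'
#' @param dataset the development partition
#' @param cases named list of [pipeline_config()]s (see [ablation_cases()])
#' @param repeats,folds,seed as in [run_rscv()]
#' @return list of `cv_result`s plus a summary table; fold hashes are
#'   verified equal across cases
#' @export
run_ablation <- function(dataset, cases, repeats = 10L, folds = 5L,
                         seed = 1L) {
  if (length(cases) < 1) stop_config("need at least one case")
  results <- lapply(cases, function(cfg)
    run_rscv(dataset, cfg, repeats = repeats, folds = folds, seed = seed))
  hashes <- vapply(results, `[[`, numeric(1), "fold_hash")
  stopifnot(length(unique(hashes)) == 1)
  summary <- data.frame(
    case = names(cases),
    mean_auc = vapply(results, function(r)
      r$summary$mean_auc[1], numeric(1)),
    sd_auc = vapply(results, function(r) r$summary$sd_auc[1], numeric(1)),
    row.names = NULL)
  list(results = results, summary = summary)
}

#' Standard ablation case configurations
#'
#' @param base a [pipeline_config()] to derive cases from
#' @param cases integer subset of 0:4
#' @return named list of configs
#' @export
ablation_cases <- function(base = pipeline_config(), cases = 0:2) {
  make <- function(i) {
    cfg <- base
    if (i == 1) cfg$use_stage1_features <- FALSE
    if (i == 2) cfg$model$use_attention <- FALSE
    if (i == 3) cfg$model$hidden_dim <- 512L
    if (i == 4) cfg$model$hidden_dim <- 1024L
    cfg
  }
  out <- lapply(cases, make)
  names(out) <- paste0("case", cases)
  out
}

#' Single confirmatory evaluation on the held-out test partition
#'
#' Trains the full pipeline on the development rows and scores the test rows
#' exactly once per workspace: a second call with the same workspace object
#' errors, enforcing the single-use contract of a confirmatory holdout.
#'
#' @param dataset the full `multimodal_dataset`
#' @param split a [stratified_split()] of its labels
#' @param config a [pipeline_config()]
#' @param workspace an environment logging holdout access (created by
#'   [holdout_workspace()])
#' @return list with `auc`, `scores`, `labels`
#' @export
final_holdout_eval <- function(dataset, split, config = pipeline_config(),
                               workspace = holdout_workspace()) {
  if (length(workspace$access_log) > 0)
    stop("protocol violation: the held-out test set was already evaluated")
  scores <- fit_score_pipeline(dataset, split$dev_indices,
                               split$test_indices, config)
  workspace$access_log <- c(workspace$access_log,
                            format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  list(auc = auc(scores, dataset$labels[split$test_indices]),
       scores = scores, labels = dataset$labels[split$test_indices])
}

#' Create a holdout-access workspace
#' @return an environment with an empty `access_log`
#' @export
holdout_workspace <- function() {
  e <- new.env()
  e$access_log <- character(0)
  e
}
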