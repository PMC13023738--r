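#' Integrate top-ranked features across views
#'
#' Concatenates each view's top `per_view_count` features (by the Stage I
#' ranking) into one subject x feature matrix, z-scored per feature; the
#' default 30 per view yields 90 integrated features for three views.
#'
#' @param dataset a `multimodal_dataset`
#' @param ranking a [rank_features()] result covering the dataset's views
#' @param per_view_count features taken from each view
#' @return z-scored numeric matrix
#' @export
integrate_top_features <- function(dataset, ranking, per_view_count = 30L) {
  views <- dataset$views
  blocks <- lapply(names(views), function(v) {
    rk <- ranking$per_view[[v]]
    if (is.null(rk)) stop_config("ranking lacks view '%s'", v)
    if (nrow(rk) < per_view_count)
      stop_config("view '%s' has fewer than %d ranked features", v,
                  per_view_count)
    views[[v]][, rk$index[seq_len(per_view_count)], drop = FALSE]
  })
  X <- do.call(cbind, blocks)
  standardize_columns(X)$x
}

#' Best-of-restarts k-means clustering
#'
#' Seeded, deterministic given the seed; the best of `restarts` starts by
#' within-cluster sum of squares is returned.
#'
#' @param X numeric matrix
#' @param k cluster count (2 <= k < n)
#' @param restarts random restarts
#' @param seed integer seed
#' @return integer cluster labels in 1..k
#' @export
kmeans_cluster <- function(X, k, restarts = 50L, seed = 1L) {
  if (k < 2 || k >= nrow(X)) stop_config("k must satisfy 2 <= k < n")
  set.seed(child_seed(seed, 60L))
  km <- kmeans(X, centers = k, nstart = restarts, iter.max = 100L)
  km$cluster
}

#' Internal cluster validity indices
#'
#' Calinski-Harabasz: between-cluster dispersion over within-cluster
#' dispersion, scaled by degrees of freedom.  Davies-Bouldin: mean over
#' clusters of the worst pairwise `(s_i + s_j) / d_ij` ratio, with `s_i` the
#' mean distance to the centroid.  Silhouette: mean over points of
#' `(b - a) / max(a, b)`; singleton clusters contribute 0 by convention.
#'
#' @param X numeric matrix
#' @param labels cluster assignment
#' @return named vector `c(ch, db, silhouette)`
#' @export
validity_indices <- function(X, labels) {
  labels <- as.integer(factor(labels))
  k <- max(labels)
  n <- nrow(X)
  if (k < 2) stop_config("validity indices undefined for k = 1")

  centroids <- t(vapply(seq_len(k), function(c)
    colMeans(X[labels == c, , drop = FALSE]), numeric(ncol(X))))
  overall <- colMeans(X)
  sizes <- tabulate(labels, k)

  ssb <- sum(sizes * rowSums((centroids -
    matrix(overall, k, ncol(X), byrow = TRUE))^2))
  ssw <- sum(vapply(seq_len(k), function(c)
    sum(sweep(X[labels == c, , drop = FALSE], 2, centroids[c, ], "-")^2),
    numeric(1)))
  ch <- (ssb / (k - 1)) / (ssw / (n - k))

  s_i <- vapply(seq_len(k), function(c) {
    m <- X[labels == c, , drop = FALSE]
    mean(sqrt(rowSums(sweep(m, 2, centroids[c, ], "-")^2)))
  }, numeric(1))
  db_terms <- vapply(seq_len(k), function(i) {
    max(vapply(setdiff(seq_len(k), i), function(j) {
      dij <- sqrt(sum((centroids[i, ] - centroids[j, ])^2))
      (s_i[i] + s_i[j]) / dij
    }, numeric(1)))
  }, numeric(1))
  db <- mean(db_terms)

  D <- as.matrix(dist(X))
  sil <- vapply(seq_len(n), function(i) {
    own <- labels[i]
    if (sizes[own] == 1) return(0)
    a <- sum(D[i, labels == own]) / (sizes[own] - 1)
    b <- min(vapply(setdiff(seq_len(k), own), function(c)
      mean(D[i, labels == c]), numeric(1)))
    (b - a) / max(a, b)
  }, numeric(1))

  c(ch = ch, db = db, silhouette = mean(sil))
}

#' Select the cluster count by internal indices
#'
#' For each candidate k, clusters with [kmeans_cluster()] and computes the
#' three validity indices; the winner is the majority vote of (max CH,
#' min DB, max silhouette), smaller k breaking ties.
#'
#' @param X numeric matrix
#' @param k_range candidate cluster counts
#' @param restarts,seed passed to [kmeans_cluster()]
#' @return list with `best_k`, `table` (one row per candidate), `labels`
#'   (assignment at `best_k`)
#' @export
select_k <- function(X, k_range = 2:4, restarts = 50L, seed = 1L) {
  if (length(k_range) == 0) stop_config("k_range must be nonempty")
  rows <- lapply(k_range, function(k) {
    lab <- kmeans_cluster(X, k, restarts, seed)
    c(k = k, validity_indices(X, lab))
  })
  tab <- as.data.frame(do.call(rbind, rows))
  votes <- c(tab$k[which.max(tab$ch)], tab$k[which.min(tab$db)],
             tab$k[which.max(tab$silhouette)])
  counts <- table(votes)
  winners <- as.integer(names(counts)[counts == max(counts)])
  best_k <- min(winners)
  list(best_k = best_k,
       table = tab,
       labels = kmeans_cluster(X, best_k, restarts, seed))
}

#' Consensus clustering by subsampled co-association
#'
#' Monti-style scheme: `n_resamples` random subsamples of
#' `subsample_fraction` of the subjects are clustered by k-means; the
#' co-association matrix records, for each subject pair, the fraction of
#' co-sampled runs in which they landed in the same cluster (diagonal set to
#' 1).  Final consensus labels cut an average-linkage hierarchical tree of
#' `1 - M` into k groups.
#'
#' @param X numeric matrix
#' @param k cluster count
#' @param n_resamples subsampling runs
#' @param subsample_fraction fraction of subjects per run
#' @param restarts,seed clustering controls
#' @return list with `labels`, `coassociation`
#' @export
consensus_cluster <- function(X, k, n_resamples = 100L,
                              subsample_fraction = 0.8, restarts = 10L,
                              seed = 1L) {
  n <- nrow(X)
  together <- matrix(0, n, n)
  sampled <- matrix(0, n, n)
  m <- max(2L, round(subsample_fraction * n))
  for (b in seq_len(n_resamples)) {
    set.seed(child_seed(seed, 200L + b))
    idx <- sample.int(n, m)
    lab <- kmeans_cluster(X[idx, , drop = FALSE], k, restarts,
                          seed = child_seed(seed, 400L + b))
    co <- outer(lab, lab, `==`) * 1
    together[idx, idx] <- together[idx, idx] + co
    sampled[idx, idx] <- sampled[idx, idx] + 1
  }
  M <- ifelse(sampled > 0, together / pmax(sampled, 1), 0)
  diag(M) <- 1
  hc <- hclust(stats::as.dist(1 - M), method = "average")
  list(labels = cutree(hc, k = k), coassociation = M)
}

#' Clinical contrast between two subtypes
#'
#' Two-sided Mann-Whitney rank-sum p-value for a covariate across exactly
#' two clusters (exact for combined n <= 20 without ties).
#'
#' @param labels cluster assignment with exactly 2 distinct values
#' @param covariate numeric covariate per subject
#' @return two-sided p-value
#' @export
compare_clinical <- function(labels, covariate) {
  g <- sort(unique(labels))
  if (length(g) != 2) stop_config("default contrast needs exactly 2 clusters")
  x <- covariate[labels == g[1]]
  y <- covariate[labels == g[2]]
  mann_whitney(x, y)$p_value
}

#' Cluster-by-conversion contingency table
#'
#' @param labels cluster assignment
#' @param conversion_flags binary per-subject conversion indicator
#' @return list with `counts` (cluster x \{non-converter, converter\}) and
#'   per-cluster `rates`
#' @export
conversion_crosstab <- function(labels, conversion_flags) {
  if (length(labels) != length(conversion_flags))
    stop_config("length mismatch")
  if (!all(conversion_flags %in% c(0, 1)))
    stop_config("conversion flags must be binary")
  counts <- table(cluster = labels,
                  conversion = factor(conversion_flags, levels = c(0, 1),
                                      labels = c("non_converter",
                                                 "converter")))
  rates <- counts[, "converter"] / rowSums(counts)
  list(counts = counts, rates = rates)
}

#' Two-component principal-component projection
#'
#' Mean-centred projection onto the top principal axes, with a deterministic
#' sign convention (the largest-magnitude loading of each axis is positive).
#'
#' @param X numeric matrix
#' @param n_components number of components
#' @return n x n_components coordinate matrix (attribute `sdev` holds the
#'   component standard deviations)
#' @export
pca_project <- function(X, n_components = 2L) {
  if (n_components > min(dim(X)))
    stop_config("n_components exceeds matrix rank bound")
  pc <- prcomp(X, center = TRUE, scale. = FALSE)
  rot <- pc$rotation[, seq_len(n_components), drop = FALSE]
  for (j in seq_len(ncol(rot))) {
    top <- which.max(abs(rot[, j]))
    if (rot[top, j] < 0) rot[, j] <- -rot[, j]
  }
  coords <- scale(X, center = TRUE, scale = FALSE) %*% rot
  attr(coords, "sdev") <- pc$sdev[seq_len(n_components)]
  coords
}

#' Full subtype analysis of a cohort
#'
#' Integrates top features, selects k by internal indices, runs consensus
#' clustering, contrasts clinical covariates across the two-cluster
#' solution, and cross-tabulates conversion.
#'
#' @param dataset a `multimodal_dataset` (typically the non-positive
#'   subjects)
#' @param ranking a Stage I [rank_features()] result
#' @param per_view_count features per view to integrate
#' @param k_range candidate cluster counts
#' @param n_resamples consensus resamples
#' @param seed integer seed
#' @return an object of class `subtype_result`
#' @export
subtype_analysis <- function(dataset, ranking, per_view_count = 30L,
                             k_range = 2:4, n_resamples = 100L, seed = 1L) {
  X <- integrate_top_features(dataset, ranking, per_view_count)
  ks <- select_k(X, k_range, seed = seed)
  cons <- consensus_cluster(X, ks$best_k, n_resamples = n_resamples,
                            seed = seed)
  clinical_tests <- NULL
  if (ks$best_k == 2) {
    clinical_tests <- c(
      age = compare_clinical(ks$labels, dataset$clinical$age),
      cognitive_score = compare_clinical(ks$labels,
                                         dataset$clinical$cognitive_score))
  }
  structure(list(
    labels = ks$labels, k = ks$best_k, indices = ks$table,
    consensus = cons, clinical_tests = clinical_tests,
    conversion_table = conversion_crosstab(
      ks$labels, dataset$clinical$conversion_flag),
    pca_coords = pca_project(X, 2L)
  ), class = "subtype_result")
}

#' @export
print.subtype_result <- function(x, ...) {
  cat("subtype_result: k =", x$k, "\n")
  print(x$indices, row.names = FALSE)
  if (!is.null(x$clinical_tests)) {
    cat("clinical contrasts (p):\n")
    print(x$clinical_tests)
  }
  invisible(x)
}
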