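#' Configuration for the synthetic multimodal generator
#'
#' Describes a cohort in which three subject-aligned views (structural-imaging
#' ROI volumes, PET ROI uptake ratios, and a gene-expression panel) share
#' low-rank latent factors through sparse per-view loadings, with a rare
#' positive diagnosis class that shifts the signal features and correlates
#' with clinical covariates.  Defaults mirror a 323-subject cohort with 26
#' positives, view dimensions 140/90/500, and a 10-feature signal support per
#' view.
#'
#' @param n_subjects number of subjects
#' @param dims integer vector of three per-view feature counts
#' @param n_latent number of shared latent factors
#' @param support_size number of signal (nonzero-loading) features per view
#' @param signal_strength magnitude of each nonzero loading
#' @param noise_sd residual Gaussian standard deviation
#' @param class_fraction positive-class prevalence in (0, 1)
#' @param class_effect additive mean shift on signal features for positives
#' @param conversion_fraction fraction of negatives flagged as converters
#'   (those nearest the positive-class latent centroid)
#' @param seed master integer seed; component draws use [child_seed()]
#' @return an object of class `sim_config`
#' @export
sim_config <- function(n_subjects = 323L,
                       dims = c(140L, 90L, 500L),
                       n_latent = 1L,
                       support_size = 10L,
                       signal_strength = 1,
                       noise_sd = 0.5,
                       class_fraction = 26 / 323,
                       class_effect = 1,
                       conversion_fraction = 0.12,
                       seed = 1L) {
  if (length(dims) != 3L || any(dims < 1))
    stop_config("dims must be three positive feature counts")
  if (n_subjects < 4 || n_latent < 1 || support_size < 1)
    stop_config("all counts must be positive (n_subjects >= 4)")
  if (support_size > min(dims))
    stop_config("support_size must not exceed any view dimension")
  if (class_fraction <= 0 || class_fraction >= 1)
    stop_config("class_fraction must lie in (0, 1)")
  if (noise_sd < 0) stop_config("noise_sd must be >= 0")
  structure(list(
    n_subjects = as.integer(n_subjects), dims = as.integer(dims),
    n_latent = as.integer(n_latent), support_size = as.integer(support_size),
    signal_strength = signal_strength, noise_sd = noise_sd,
    class_fraction = class_fraction, class_effect = class_effect,
    conversion_fraction = conversion_fraction, seed = as.integer(seed)
  ), class = "sim_config")
}

view_names_default <- c("smri", "pet", "gene")

new_multimodal_dataset <- function(views, labels, subject_ids, clinical,
                                   truth = NULL) {
  n <- length(subject_ids)
  if (anyDuplicated(subject_ids)) stop_config("subject_ids must be unique")
  for (v in names(views)) {
    if (nrow(views[[v]]) != n)
      stop_config("view '%s' does not share the common subject count", v)
    if (is.null(colnames(views[[v]])))
      stop_config("view '%s' lacks feature names", v)
  }
  if (length(labels) != n || !all(labels %in% c(0L, 1L)))
    stop_config("labels must be binary and aligned with subjects")
  if (nrow(clinical) != n)
    stop_config("clinical rows must align with subjects")
  structure(list(
    views = views, labels = as.integer(labels), subject_ids = subject_ids,
    feature_names = lapply(views, colnames), clinical = clinical,
    truth = truth
  ), class = "multimodal_dataset")
}

#' @export
print.multimodal_dataset <- function(x, ...) {
  cat("multimodal_dataset:", length(x$subject_ids), "subjects,",
      length(x$views), "view(s)\n")
  for (v in names(x$views))
    cat(sprintf("  %-6s %d features\n", v, ncol(x$views[[v]])))
  cat("  positives:", sum(x$labels), "/", length(x$labels), "\n")
  invisible(x)
}

# loading vector for one view/factor: equal magnitudes on a leading
# contiguous support, alternating signs (factor > 1 flips the phase).
make_loading <- function(p, support_size, strength, factor_index) {
  u <- numeric(p)
  signs <- rep_len(c(1, -1), support_size)
  if (factor_index %% 2 == 0) signs <- -signs
  u[seq_len(support_size)] <- strength * signs
  u
}

#' Generate a synthetic multimodal dataset
#'
#' Subjects draw standard-normal latent factors `z`; view k is built as
#' `z %*% t(U_k)` plus Gaussian noise, where each loading column of `U_k` is
#' zero outside a contiguous support of `support_size` features.  A fixed
#' number `round(n * class_fraction)` of subjects is labelled positive and
#' receives an additive `class_effect` shift on the signal features of every
#' view.  Age and cognitive score are drawn with class-dependent means
#' (age ~ N(72, 6) + 3 for positives; cognitive_score ~ N(28, 1.5) - 2.5 for
#' positives), and a conversion flag marks the `conversion_fraction` of
#' negatives nearest the positive-class centroid in latent space.
#'
#' @param config a [sim_config()]
#' @return a `multimodal_dataset`; `$truth` records supports, loadings and
#'   latent factors
#' @export
generate_multimodal <- function(config) {
  if (!inherits(config, "sim_config")) config <- do.call(sim_config, config)
  n <- config$n_subjects
  L <- config$n_latent

  set.seed(child_seed(config$seed, 0L))
  z <- matrix(rnorm(n * L), n, L)

  set.seed(child_seed(config$seed, 2L))
  n_pos <- max(1L, round(n * config$class_fraction))
  labels <- integer(n)
  labels[sample.int(n, n_pos)] <- 1L

  views <- list()
  supports <- list()
  loadings <- list()
  for (k in seq_len(3L)) {
    p <- config$dims[k]
    U <- vapply(seq_len(L), function(l)
      make_loading(p, config$support_size, config$signal_strength, l),
      numeric(p))
    X <- z %*% t(U)
    set.seed(child_seed(config$seed, 10L + k))
    if (config$noise_sd > 0)
      X <- X + matrix(rnorm(n * p, sd = config$noise_sd), n, p)
    sup <- seq_len(config$support_size)
    X[labels == 1L, sup] <- X[labels == 1L, sup] + config$class_effect
    colnames(X) <- sprintf("%s_f%03d", view_names_default[k], seq_len(p))
    views[[view_names_default[k]]] <- X
    supports[[view_names_default[k]]] <- sup
    loadings[[view_names_default[k]]] <- U
  }

  set.seed(child_seed(config$seed, 3L))
  age <- rnorm(n, 72, 6) + 3 * labels
  cognitive_score <- rnorm(n, 28, 1.5) - 2.5 * labels

  # converters: negatives closest to the positive-class latent centroid
  conversion_flag <- integer(n)
  neg <- which(labels == 0L)
  if (length(neg) > 0 && any(labels == 1L)) {
    centroid <- colMeans(z[labels == 1L, , drop = FALSE])
    d <- sqrt(rowSums((z[neg, , drop = FALSE] -
                         matrix(centroid, length(neg), L, byrow = TRUE))^2))
    n_conv <- round(config$conversion_fraction * length(neg))
    conversion_flag[neg[order(d)[seq_len(n_conv)]]] <- 1L
  }

  subject_ids <- sprintf("S%04d", seq_len(n))
  clinical <- data.frame(
    subject_id = subject_ids, age = age,
    cognitive_score = cognitive_score, conversion_flag = conversion_flag,
    stringsAsFactors = FALSE
  )
  new_multimodal_dataset(
    views, labels, subject_ids, clinical,
    truth = list(supports = supports, loadings = loadings, latent = z)
  )
}

#' Generate a two-cluster single-view fixture
#'
#' Two isotropic unit-variance Gaussian clusters whose centroids sit
#' `separation` apart along the first axis; the labels record the true
#' cluster.  Used to exercise subtyping, graph attachment and clustering
#' oracles.
#'
#' @param n_per_cluster points per cluster (>= 2)
#' @param separation Euclidean distance between cluster centroids
#' @param dim feature dimension (>= 1)
#' @param seed integer seed
#' @return a `multimodal_dataset` with a single view named `"combined"`
#' @export
generate_two_cluster <- function(n_per_cluster, separation = 10, dim = 10L,
                                 seed = 1L) {
  if (n_per_cluster < 2) stop_config("n_per_cluster must be >= 2")
  if (dim < 1) stop_config("dim must be >= 1")
  n <- 2L * n_per_cluster
  set.seed(child_seed(seed, 0L))
  X <- matrix(rnorm(n * dim), n, dim)
  X[seq_len(n_per_cluster), 1] <- X[seq_len(n_per_cluster), 1] + separation
  colnames(X) <- sprintf("combined_f%03d", seq_len(dim))
  labels <- rep(c(1L, 0L), each = n_per_cluster)
  subject_ids <- sprintf("S%04d", seq_len(n))
  clinical <- data.frame(
    subject_id = subject_ids, age = rep(72, n),
    cognitive_score = rep(28, n), conversion_flag = integer(n),
    stringsAsFactors = FALSE
  )
  new_multimodal_dataset(list(combined = X), labels, subject_ids, clinical,
                         truth = list(cluster = labels))
}

#' Subset a multimodal dataset by subject rows
#'
#' @param dataset a `multimodal_dataset`
#' @param idx integer row indices
#' @return the subset `multimodal_dataset`
#' @export
subset_subjects <- function(dataset, idx) {
  new_multimodal_dataset(
    lapply(dataset$views, function(v) v[idx, , drop = FALSE]),
    dataset$labels[idx], dataset$subject_ids[idx],
    dataset$clinical[idx, , drop = FALSE],
    truth = dataset$truth
  )
}

#' Write a multimodal dataset as delimited text
#'
#' Each view becomes `<name>.tsv` (subjects in rows, first column
#' `subject_id`, header of feature names); the phenotype table becomes
#' `pheno.tsv` with columns subject_id, label, age, cognitive_score,
#' conversion_flag.
#'
#' @param dataset a `multimodal_dataset`
#' @param dir output directory (created if missing)
#' @return invisibly, the written file paths
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (v in names(dataset$views)) {
    df <- data.frame(subject_id = dataset$subject_ids,
                     dataset$views[[v]], check.names = FALSE)
    p <- file.path(dir, paste0(v, ".tsv"))
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, p)
  }
  pheno <- data.frame(
    subject_id = dataset$subject_ids, label = dataset$labels,
    age = dataset$clinical$age,
    cognitive_score = dataset$clinical$cognitive_score,
    conversion_flag = dataset$clinical$conversion_flag
  )
  p <- file.path(dir, "pheno.tsv")
  utils::write.table(pheno, p, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(paths, p))
}

#' Read a multimodal dataset written by [write_dataset()]
#'
#' @param view_paths named character vector of view TSV paths
#' @param pheno_path phenotype TSV path
#' @return a `multimodal_dataset`
#' @export
read_dataset <- function(view_paths, pheno_path) {
  pheno <- utils::read.delim(pheno_path, stringsAsFactors = FALSE)
  views <- lapply(view_paths, function(p) {
    df <- utils::read.delim(p, check.names = FALSE, stringsAsFactors = FALSE)
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- df[[1]]
    storage.mode(m) <- "double"
    m[match(pheno$subject_id, rownames(m)), , drop = FALSE]
  })
  if (is.null(names(views)))
    names(views) <- sub("\\.tsv$", "", basename(view_paths))
  clinical <- pheno[, c("subject_id", "age", "cognitive_score",
                        "conversion_flag")]
  new_multimodal_dataset(views, pheno$label, pheno$subject_id, clinical)
}
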