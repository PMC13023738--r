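#' Differential-expression gate configuration
#'
#' Genes pass when `p < p_threshold` and `|logFC| > lfc_threshold` (both
#' strict, matching the conventional "p < 0.05 and |logFC| > 0.5" gate).
#'
#' @param p_threshold raw-p significance level in (0, 1)
#' @param lfc_threshold absolute log-fold-change bound (>= 0)
#' @return an object of class `deg_config`
#' @export
deg_config <- function(p_threshold = 0.05, lfc_threshold = 0.5) {
  if (p_threshold <= 0 || p_threshold >= 1)
    stop_config("p_threshold must lie in (0, 1)")
  if (lfc_threshold < 0) stop_config("lfc_threshold must be >= 0")
  structure(list(p_threshold = p_threshold, lfc_threshold = lfc_threshold),
            class = "deg_config")
}

#' Fit per-gene two-group linear models
#'
#' For each gene (column of `expr`) computes the group-mean difference on the
#' provided (assumed log) scale, `logFC = mean(group 1) - mean(group 0)`, and
#' the pooled residual variance of the two-group model with `n - 2` residual
#' degrees of freedom.  Expression is assumed already log-scale, as
#' post-normalisation microarray data are.
#'
#' @param expr subjects x genes numeric matrix
#' @param labels binary vector, one per subject; both classes need >= 2
#'   subjects
#' @return an object of class `gene_stats` (data.frame of per-gene stats plus
#'   attributes `residual_df`, `n`)
#' @export
fit_gene_models <- function(expr, labels) {
  check_matrix(expr, "expr")
  labels <- as.integer(labels)
  if (length(labels) != nrow(expr))
    stop_config("labels must align with expr rows")
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 < 2 || n0 < 2)
    stop_config("insufficient data: each class needs >= 2 subjects")
  n <- n1 + n0
  m1 <- colMeans(expr[labels == 1L, , drop = FALSE])
  m0 <- colMeans(expr[labels == 0L, , drop = FALSE])
  ss1 <- colSums(sweep(expr[labels == 1L, , drop = FALSE], 2, m1, "-")^2)
  ss0 <- colSums(sweep(expr[labels == 0L, , drop = FALSE], 2, m0, "-")^2)
  df <- n - 2L
  s2 <- (ss1 + ss0) / df
  genes <- colnames(expr)
  if (is.null(genes)) genes <- sprintf("g%04d", seq_along(m1))
  out <- data.frame(
    gene = genes, logFC = m1 - m0, residual_variance = s2,
    residual_df = df, degenerate = s2 < .Machine$double.eps,
    stringsAsFactors = FALSE, row.names = NULL
  )
  structure(out, class = c("gene_stats", "data.frame"),
            n = n, stdev_unscaled = sqrt(1 / n1 + 1 / n0))
}

# solve trigamma(x) = y by Newton iteration on the monotone decreasing map
trigamma_inverse <- function(y) {
  if (y <= 0) return(Inf)
  if (y > 1e7) return(1 / sqrt(y))
  if (y < 1e-6) return(1 / y)
  x <- 0.5 + 1 / y
  for (i in seq_len(50L)) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, deriv = 2L)
    x <- x + dif
    if (abs(dif / x) < 1e-10) break
  }
  x
}

#' Empirical-Bayes moderation of per-gene variances
#'
#' Shrinks per-gene residual variances toward a common prior estimated by
#' moment matching on the log variances: with `e_g = log(s2_g)` adjusted by
#' digamma/trigamma terms of the residual degrees of freedom, the prior df
#' solves `trigamma(d0/2) = var(e) - trigamma(df/2)` and the prior variance is
#' recovered from the mean of `e`.  The moderated variance is
#' `(d0 * s2_0 + df * s2_g) / (d0 + df)`; moderated t statistics use
#' `df + d0` degrees of freedom (capped at the pooled residual df).
#'
#' @param stats a `gene_stats` from [fit_gene_models()]
#' @return `stats` augmented with `prior_df`, `prior_variance`,
#'   `moderated_variance`, `moderated_t`, `p_value`
#' @export
moderate_variances <- function(stats) {
  if (!inherits(stats, "gene_stats")) stop_config("stats must be gene_stats")
  df <- stats$residual_df[1]
  if (nrow(stats) < 10) stop_config("need >= 10 genes for moderation")
  ok <- stats$residual_variance > 0
  if (!any(ok)) stop_config("degenerate: all residual variances are zero")

  e <- log(stats$residual_variance[ok]) - digamma(df / 2) + log(df / 2)
  emean <- mean(e)
  evar <- var(e) - trigamma(df / 2)
  if (is.finite(evar) && evar > 0) {
    prior_df <- 2 * trigamma_inverse(evar)
    prior_var <- exp(emean + digamma(prior_df / 2) - log(prior_df / 2))
  } else {
    # no excess dispersion in the log variances: infinite prior df, common
    # variance estimated by the plain mean
    prior_df <- Inf
    prior_var <- mean(stats$residual_variance[ok])
  }

  if (is.finite(prior_df)) {
    s2_post <- (prior_df * prior_var + df * stats$residual_variance) /
      (prior_df + df)
  } else {
    s2_post <- rep(prior_var, nrow(stats))
  }
  # total df capped at the pooled residual df across genes
  df_total <- min(df + prior_df, df * nrow(stats))
  tstat <- stats$logFC / (sqrt(s2_post) * attr(stats, "stdev_unscaled"))
  pval <- 2 * pt(-abs(tstat), df = df_total)

  stats$prior_df <- prior_df
  stats$prior_variance <- prior_var
  stats$moderated_variance <- s2_post
  stats$moderated_t <- tstat
  stats$p_value <- pval
  attr(stats, "moderated") <- TRUE
  stats
}

#' Select differentially expressed genes
#'
#' Applies the strict double gate `p_value < p_threshold` and
#' `|logFC| > lfc_threshold`; survivors are ordered by ascending p.
#'
#' @param stats a moderated `gene_stats`
#' @param config a [deg_config()]
#' @return integer vector of gene column indices (possibly empty), ordered by
#'   ascending p-value, with the gene names as names
#' @export
select_degs <- function(stats, config = deg_config()) {
  if (!isTRUE(attr(stats, "moderated")))
    stop_config("moderation must be applied before selection")
  pass <- which(stats$p_value < config$p_threshold &
                  abs(stats$logFC) > config$lfc_threshold)
  pass <- pass[order(stats$p_value[pass])]
  names(pass) <- stats$gene[pass]
  pass
}

# convenience: fit + moderate + select on a training partition only
deg_screen <- function(expr, labels, config = deg_config()) {
  select_degs(moderate_variances(fit_gene_models(expr, labels)), config)
}
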