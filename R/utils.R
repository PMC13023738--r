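#' @useDynLib smccanet, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats cor dist hclust cutree kmeans prcomp pt pnorm rnorm runif
#'   sd var quantile
NULL

stop_config <- function(...) stop(sprintf(...), call. = FALSE)

#' Derive a child seed from a master seed
#'
#' All randomness in the package flows from a single integer seed; independent
#' random components (latent factors, noise, labels, clinical covariates, fold
#' shuffles, parameter init) use fixed offsets from it so that changing one
#' component's draw never perturbs another's.  Results stay inside the 32-bit
#' integer range expected by [set.seed()].
#'
#' @param seed master integer seed
#' @param offset fixed non-negative integer offset identifying the component
#' @return an integer seed
#' @export
child_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 1000 + offset) %% 2147483647L)
}

check_matrix <- function(x, name = "x") {
  if (!is.matrix(x) || !is.numeric(x))
    stop_config("%s must be a numeric matrix", name)
  if (any(!is.finite(x)))
    stop_config("%s contains non-finite values", name)
  invisible(x)
}

# z-score columns; constant columns are centred and left at zero spread.
# Returns the transform so the same scaling can be replayed on new rows
# (train-only statistics, applied unchanged to validation/test partitions).
standardize_columns <- function(x, center = NULL, scale = NULL) {
  if (is.null(center)) center <- colMeans(x)
  if (is.null(scale)) {
    scale <- apply(x, 2, sd)
    scale[scale < .Machine$double.eps] <- 1
  }
  list(
    x = sweep(sweep(x, 2, center, "-"), 2, scale, "/"),
    center = center, scale = scale
  )
}
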