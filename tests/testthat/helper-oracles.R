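# Independent oracles used across the suite.  Deliberately naive: brute-force
# enumeration / textbook formulas, no shared code with the implementation.

# AUC by explicit pair counting (ties count one half)
brute_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  tot / (length(pos) * length(neg))
}

# adjusted Rand index
ari <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- sum(tab)
  expected <- sum_a * sum_b / comb2(n)
  (sum_ij - expected) / ((sum_a + sum_b) / 2 - expected)
}

# textbook cluster validity indices, naive loops
brute_indices <- function(X, labels) {
  labels <- as.integer(factor(labels))
  k <- max(labels); n <- nrow(X)
  cent <- lapply(1:k, function(c) colMeans(X[labels == c, , drop = FALSE]))
  gmean <- colMeans(X)
  ssb <- 0; ssw <- 0
  for (c in 1:k) {
    nc <- sum(labels == c)
    ssb <- ssb + nc * sum((cent[[c]] - gmean)^2)
    for (i in which(labels == c)) ssw <- ssw + sum((X[i, ] - cent[[c]])^2)
  }
  ch <- (ssb / (k - 1)) / (ssw / (n - k))
  s <- sapply(1:k, function(c) {
    mean(sapply(which(labels == c), function(i)
      sqrt(sum((X[i, ] - cent[[c]])^2))))
  })
  db_terms <- sapply(1:k, function(i) {
    max(sapply(setdiff(1:k, i), function(j)
      (s[i] + s[j]) / sqrt(sum((cent[[i]] - cent[[j]])^2))))
  })
  sil <- sapply(1:n, function(i) {
    own <- labels[i]
    nown <- sum(labels == own)
    if (nown == 1) return(0)
    a <- mean(sapply(setdiff(which(labels == own), i), function(j)
      sqrt(sum((X[i, ] - X[j, ])^2))))
    b <- min(sapply(setdiff(1:k, own), function(c)
      mean(sapply(which(labels == c), function(j)
        sqrt(sum((X[i, ] - X[j, ])^2))))))
    (b - a) / max(a, b)
  })
  c(ch = ch, db = mean(db_terms), silhouette = mean(sil))
}

# small correlated multimodal fixture for solver tests
toy_dataset <- function(n = 60, dims = c(12L, 10L, 15L), support = 4L,
                        noise = 0.3, seed = 1L, class_effect = 0) {
  generate_multimodal(sim_config(
    n_subjects = n, dims = dims, support_size = support,
    signal_strength = 1, noise_sd = noise, class_fraction = 0.25,
    class_effect = class_effect, seed = seed))
}

# direct minimisation oracle for the robust two-view objective: weights are
# normalised inside the objective, so optim explores the constrained surface
robust_objective_oracle <- function(X1, X2, lambda, beta,
                                    extra_starts = list()) {
  obj <- function(par) {
    w1 <- par[1:ncol(X1)]; w2 <- par[-(1:ncol(X1))]
    s1 <- sqrt(sum((X1 %*% w1)^2)); s2 <- sqrt(sum((X2 %*% w2)^2))
    if (s1 < 1e-8 || s2 < 1e-8) return(1e6)
    w1 <- w1 / s1; w2 <- w2 / s2
    pen <- function(w) {
      fgl <- sum(sapply(seq_len(length(w) - 1), function(j)
        sqrt(w[j]^2 + w[j + 1]^2)))
      lambda * (beta * fgl + (1 - beta) * sum(abs(w)))
    }
    sqrt(sum((X1 %*% w1 - X2 %*% w2)^2)) + pen(w1) + pen(w2)
  }
  starts <- extra_starts
  for (s in 1:12) {
    set.seed(s)
    starts <- c(starts, list(rnorm(ncol(X1) + ncol(X2))))
  }
  best <- Inf
  for (par0 in starts) {
    fit <- optim(par0, obj, method = "Nelder-Mead",
                 control = list(maxit = 5000, reltol = 1e-12))
    fit <- optim(fit$par, obj, method = "Nelder-Mead",
                 control = list(maxit = 5000, reltol = 1e-12))
    best <- min(best, fit$value)
  }
  best
}
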