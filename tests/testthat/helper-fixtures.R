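# Shared fixtures and independent brute-force oracles used across tests.

# Direct NB pseudo-bulk fixture: one column per sample, gene means drawn
# heavy-tailed, per-group dispersion phi. Fast stand-in for full single-cell
# simulation in unit tests.
rnb_pseudobulk <- function(G = 2000, n_per_group = 3, phi = c(0.04, 0.04),
                           mean_lib = 5e5, seed = 1) {
  set.seed(seed)
  n_groups <- length(phi)
  p <- rlnorm(G, -1, 2); p <- p / sum(p)
  mu <- p * mean_lib
  counts <- matrix(0L, G, n_groups * n_per_group)
  grp <- character(0)
  for (g in seq_len(n_groups)) {
    for (s in seq_len(n_per_group)) {
      j <- (g - 1) * n_per_group + s
      counts[, j] <- rnbinom(G, mu = mu, size = 1 / max(phi[g], 1e-8))
    }
    grp <- c(grp, rep(paste0("g", g), n_per_group))
  }
  rownames(counts) <- sprintf("gene%d", seq_len(G))
  colnames(counts) <- paste0(grp, "_s", sequence(rep(n_per_group, n_groups)))
  pseudobulk(counts, sample_group = grp)
}

# Straight-line reimplementation of the trimmed weighted mean of M-values
# (log-ratio trim 0.30, intensity trim 0.05, precision weights, reference by
# upper-quartile CPM closest to the mean), geometric mean 1.
tmm_oracle <- function(counts, lib = colSums(counts)) {
  f75 <- apply(counts, 2, function(u) quantile(u, 0.75)) / lib
  ref <- which.min(abs(f75 - mean(f75)))
  one_factor <- function(obs, libo) {
    refc <- counts[, ref]; libr <- lib[ref]
    fin <- obs > 0 & refc > 0
    logR <- log2((obs[fin] / libo) / (refc[fin] / libr))
    absE <- (log2(obs[fin] / libo) + log2(refc[fin] / libr)) / 2
    v <- (libo - obs[fin]) / (libo * obs[fin]) +
      (libr - refc[fin]) / (libr * refc[fin])
    if (max(abs(logR)) < 1e-6) return(1)
    n <- length(logR)
    loL <- floor(n * 0.3) + 1; hiL <- n + 1 - loL
    loS <- floor(n * 0.05) + 1; hiS <- n + 1 - loS
    keep <- (rank(logR) >= loL & rank(logR) <= hiL) &
      (rank(absE) >= loS & rank(absE) <= hiS)
    2^(sum(logR[keep] / v[keep]) / sum(1 / v[keep]))
  }
  f <- vapply(seq_len(ncol(counts)),
              function(j) one_factor(counts[, j], lib[j]), 0)
  f / exp(mean(log(f)))
}

# Per-gene weighted least squares by explicit normal equations.
wls_oracle <- function(E, X, W = NULL) {
  G <- nrow(E); p <- ncol(X); n <- ncol(E)
  if (is.null(W)) W <- matrix(1, G, n)
  coef <- matrix(0, G, p); sigma2 <- numeric(G)
  se_mat <- array(0, c(G, p, p))
  for (g in seq_len(G)) {
    Wg <- diag(W[g, ], n)
    A <- solve(t(X) %*% Wg %*% X)
    b <- A %*% t(X) %*% Wg %*% E[g, ]
    coef[g, ] <- b
    r <- E[g, ] - X %*% b
    sigma2[g] <- sum(W[g, ] * r^2) / (n - p)
    se_mat[g, , ] <- A
  }
  list(coef = coef, sigma2 = sigma2, cov = se_mat)
}

# Benjamini-Hochberg by the step-up definition.
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(n); out[o] <- adj
  out
}
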