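# Independent brute-force oracles. Each is written from the definition, using
# none of the package's code paths, so agreement is a genuine cross-check.

# midranks by explicit counting: r_i = #{x_j < x_i} + (#{x_j == x_i} + 1) / 2
oracle_midrank <- function(x) {
  vapply(seq_along(x), function(i) {
    sum(x < x[i]) + (sum(x == x[i]) + 1) / 2
  }, numeric(1))
}

oracle_pearson <- function(a, b) {
  n <- length(a)
  num <- sum(a * b) - n * mean(a) * mean(b)
  den <- sqrt((sum(a^2) - n * mean(a)^2) * (sum(b^2) - n * mean(b)^2))
  num / den
}

# Spearman: count-based midranks, then Pearson by the sum formula, p by t
oracle_spearman <- function(x, y) {
  ra <- oracle_midrank(x); rb <- oracle_midrank(y)
  rho <- oracle_pearson(ra, rb)
  n <- length(x)
  p <- if (abs(rho) >= 1 - 1e-12) 0 else {
    tt <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * pt(-abs(tt), n - 2)
  }
  list(rho = rho, p = p)
}

# partial Spearman: rank by counting, regress out [1, Z] via normal equations,
# correlate residuals
oracle_partial_spearman <- function(x, y, Z) {
  Z <- as.matrix(Z)
  ra <- oracle_midrank(x); rb <- oracle_midrank(y)
  Zr <- apply(Z, 2, oracle_midrank)
  X <- cbind(1, Zr)
  beta_a <- solve(t(X) %*% X, t(X) %*% ra)
  beta_b <- solve(t(X) %*% X, t(X) %*% rb)
  res_a <- ra - X %*% beta_a
  res_b <- rb - X %*% beta_b
  rho <- oracle_pearson(as.numeric(res_a), as.numeric(res_b))
  n <- length(x); k <- ncol(Z)
  p <- if (abs(rho) >= 1 - 1e-12) 0 else {
    tt <- rho * sqrt((n - 2 - k) / (1 - rho^2))
    2 * pt(-abs(tt), n - 2 - k)
  }
  list(rho = rho, p = p)
}

# BH step-up by explicit loop: q_(i) = min_{j >= i} p_(j) * m / j, clipped at 1
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q_sorted <- numeric(m)
  terms <- (m / seq_len(m)) * ps
  for (i in seq_len(m)) {
    q_sorted[i] <- min(1, min(terms[i:m]))
  }
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

# exact overlap p by enumerating every feasible overlap count and summing
# hypergeometric point masses per the alternative's rule
oracle_overlap_p <- function(k, na, nb, nu, alternative) {
  lo <- max(0, na + nb - nu)
  hi <- min(na, nb)
  kk <- lo:hi
  mass <- dhyper(kk, na, nu - na, nb)
  if (alternative == "greater") {
    sum(mass[kk >= k])
  } else {
    obs <- dhyper(k, na, nu - na, nb)
    min(1, sum(mass[mass <= obs * (1 + 1e-7)]))
  }
}

# complete linkage recomputed from scratch at every step from the base
# pairwise distance matrix; returns merge heights and member partitions
oracle_complete_linkage <- function(x) {
  D0 <- as.matrix(dist(x))
  clusters <- as.list(seq_len(nrow(x)))
  heights <- numeric(0)
  partitions <- list()
  while (length(clusters) > 1L) {
    best <- c(NA, NA); best_d <- Inf
    for (i in seq_len(length(clusters) - 1L)) {
      for (j in seq.int(i + 1L, length(clusters))) {
        d <- max(D0[clusters[[i]], clusters[[j]]])
        if (d < best_d) { best_d <- d; best <- c(i, j) }
      }
    }
    heights <- c(heights, best_d)
    merged <- sort(c(clusters[[best[1]]], clusters[[best[2]]]))
    partitions[[length(partitions) + 1L]] <- merged
    clusters[[best[1]]] <- merged
    clusters[[best[2]]] <- NULL
  }
  list(heights = heights, partitions = partitions)
}

# small helpers used across test files
random_gene_universe <- function(n) sprintf("G%03d", seq_len(n))

make_drug_sig <- function(id, up, down, universe, cell_line = "MCF7",
                          dose = 10, time = 24) {
  drug_signature(id, up = up, down = down, universe = universe,
                 cell_line = cell_line, dose = dose, time = time)
}

# disjoint random up/down sets drawn in one pass
random_drug_sig <- function(id, universe, n_up = 10, n_dn = n_up, ...) {
  pick <- sample(universe, n_up + n_dn)
  make_drug_sig(id, pick[seq_len(n_up)], pick[n_up + seq_len(n_dn)], universe, ...)
}
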