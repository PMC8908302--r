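# Independent oracles used by the test suite. Each deliberately takes a
# different algorithmic route from the package implementation it checks.

# Euclidean-NMF reference by hierarchical alternating least squares (HALS):
# same objective as the package's multiplicative updates, different
# optimizer.
hals_nmf <- function(Y, K, seed = 1L, max_iter = 500L, tol = 1e-7) {
  set.seed(seed)
  I <- nrow(Y); J <- ncol(Y)
  W <- matrix(runif(I * K), I, K) * sqrt(mean(Y) / K)
  H <- matrix(runif(K * J), K, J) * sqrt(mean(Y) / K)
  obj <- function() sum((Y - W %*% H)^2)
  prev <- obj()
  for (it in seq_len(max_iter)) {
    A <- Y %*% t(H); B <- H %*% t(H)
    for (k in seq_len(K)) {
      if (B[k, k] > 0) {
        W[, k] <- pmax(0, W[, k] + (A[, k] - W %*% B[, k]) / B[k, k])
      }
    }
    Cm <- t(W) %*% Y; D <- t(W) %*% W
    for (k in seq_len(K)) {
      if (D[k, k] > 0) {
        H[k, ] <- pmax(0, H[k, ] + (Cm[k, ] - D[k, ] %*% H) / D[k, k])
      }
    }
    cur <- obj()
    if (prev - cur < tol * prev) break
    prev <- cur
  }
  list(W = W, H = H, objective = obj())
}

hals_best <- function(Y, K, n_starts, max_iter = 500L) {
  min(vapply(seq_len(n_starts), function(s) {
    hals_nmf(Y, K, seed = 1000L + s, max_iter = max_iter)$objective
  }, numeric(1L)))
}

# Brute-force average-linkage (UPGMA) agglomeration plus explicit cophenetic
# distance extraction by recording merge heights per pair.
oracle_cophenetic <- function(consensus) {
  d <- 1 - consensus
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  coph <- matrix(0, n, n)
  active <- rep(TRUE, length(clusters))
  cluster_dist <- function(ci, cj) {
    mean(d[clusters[[ci]], clusters[[cj]], drop = FALSE])
  }
  while (sum(active) > 1L) {
    act <- which(active)
    best <- c(NA, NA); bd <- Inf
    for (a in seq_along(act)) {
      for (b in seq_len(a - 1L)) {
        dd <- cluster_dist(act[a], act[b])
        if (dd < bd) { bd <- dd; best <- c(act[a], act[b]) }
      }
    }
    for (x in clusters[[best[1L]]]) {
      for (y in clusters[[best[2L]]]) {
        coph[x, y] <- coph[y, x] <- bd
      }
    }
    clusters[[best[1L]]] <- c(clusters[[best[1L]]], clusters[[best[2L]]])
    active[best[2L]] <- FALSE
  }
  ut <- upper.tri(d)
  if (sd(d[ut]) == 0 || sd(coph[ut]) == 0) return(NA_real_)
  cor(d[ut], coph[ut])
}

# Day-by-day longest-run scan over a carry calendar.
oracle_longest_run <- function(days) {
  days <- sort(unique(days))
  if (length(days) == 0L) return(0L)
  all_days <- seq(min(days), max(days), by = "day")
  present <- all_days %in% days
  best <- run <- 0L
  for (p in present) {
    run <- if (p) run + 1L else 0L
    best <- max(best, run)
  }
  best
}

# Record-by-record tally of per-participant detection totals.
oracle_participant_tally <- function(log, ids) {
  tot <- setNames(numeric(length(ids)), ids)
  for (r in seq_len(nrow(log))) {
    tot[log$observer_id[r]] <- tot[log$observer_id[r]] + 1
    tot[log$observed_id[r]] <- tot[log$observed_id[r]] + 1
  }
  tot
}

# Pearson r and two-tailed p by the textbook formulas.
oracle_pearson <- function(x, y) {
  n <- length(x)
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  tt <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * pt(-abs(tt), n - 2))
}

# A random symmetric "consensus-like" matrix: entries in [0, 1], unit
# diagonal.
random_consensus <- function(n, seed) {
  set.seed(seed)
  C <- matrix(runif(n * n), n, n)
  C <- (C + t(C)) / 2
  diag(C) <- 1
  C
}
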