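# Non-negative matrix factorization of the contact matrix, Y ~ H U.
#
# H (I x K) holds per-epoch activity of each latent subnetwork; U (K x J)
# holds per-dyad tie weights. The objective is the squared Frobenius norm
# ||Y - HU||_F^2, minimized by Lee-Seung multiplicative updates, which are
# guaranteed non-increasing in the objective. Rank selection combines the
# residual sum of squares with consensus clustering of dyads across random
# restarts, scored by the cophenetic correlation coefficient.

as_dense_Y <- function(Y) {
  if (inherits(Y, "contact_matrix")) Y <- Y$Y
  Y <- as.matrix(Y)
  if (any(Y < 0)) stop("Y must be nonnegative", call. = FALSE)
  Y
}

#' Euclidean-loss NMF by multiplicative updates
#'
#' Fits `Y ~ H U` with `H >= 0`, `U >= 0` minimizing
#' `||Y - HU||_F^2` via the multiplicative update rules
#' `H <- H * (Y U') / (H U U' + eps)` and `U <- U * (H' Y) / (H' H U + eps)`.
#' Entries of `H` and `U` are initialized i.i.d. uniform, scaled so the
#' reconstruction matches `mean(Y)`. The objective is recorded each
#' iteration; iteration stops when its relative decrease falls below `tol`
#' or after `max_iter` iterations.
#'
#' The returned model is put in canonical form: each row of `U` is scaled to
#' unit maximum (compensated in the matching column of `H`) and factors are
#' ordered by decreasing total activity `sum(H[, k])`. This removes the
#' diagonal scale/permutation indeterminacy and makes runs comparable.
#'
#' @param Y A `contact_matrix` or nonnegative numeric matrix with at least
#'   one positive entry.
#' @param K Rank, `1 <= K <= min(dim(Y))`.
#' @param seed RNG seed; the fit is deterministic given `seed`.
#' @param max_iter Maximum multiplicative-update iterations.
#' @param tol Relative objective-decrease convergence tolerance.
#' @param eps Small denominator guard; never produces negative entries.
#' @return A `factor_model` list: `H`, `U`, `K`, `objective` (final
#'   `||Y - HU||_F^2`), `objective_trace`, `n_iter`, `seed`, `converged`.
#' @export
nmf_frobenius <- function(Y, K, seed = 1L, max_iter = 2000L, tol = 1e-5,
                          eps = 1e-9) {
  Y <- as_dense_Y(Y)
  I <- nrow(Y); J <- ncol(Y)
  if (K < 1L) stop("K must be >= 1", call. = FALSE)
  if (K > min(I, J)) stop("K exceeds min(dim(Y))", call. = FALSE)
  ymean <- mean(Y)
  if (ymean == 0) stop("Y is all zero; nothing to factorize", call. = FALSE)

  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(seed)
  scale0 <- sqrt(ymean / K)
  H <- matrix(stats::runif(I * K), I, K) * scale0
  U <- matrix(stats::runif(K * J), K, J) * scale0

  obj <- function(H, U) {
    R <- Y - H %*% U
    sum(R * R)
  }
  trace <- numeric(max_iter + 1L)
  trace[1L] <- obj(H, U)
  converged <- FALSE
  it <- 0L
  for (it in seq_len(max_iter)) {
    H <- H * (Y %*% t(U)) / (H %*% (U %*% t(U)) + eps)
    U <- U * (t(H) %*% Y) / (crossprod(H) %*% U + eps)
    trace[it + 1L] <- obj(H, U)
    if (trace[it] - trace[it + 1L] < tol * trace[it]) {
      converged <- TRUE
      break
    }
  }
  trace <- trace[seq_len(it + 1L)]
  cn <- canonicalize_hu(H, U)
  structure(list(H = cn$H, U = cn$U, K = as.integer(K),
                 objective = trace[length(trace)],
                 objective_trace = trace, n_iter = it,
                 seed = as.integer(seed), converged = converged),
            class = "factor_model")
}

# Scale each row of U to unit maximum (compensating in H's columns) and sort
# factors by decreasing total activity. All-zero rows are left unscaled.
canonicalize_hu <- function(H, U) {
  rmax <- apply(U, 1L, max)
  s <- ifelse(rmax > 0, rmax, 1)
  U <- U / s
  H <- H * rep(s, each = nrow(H))
  ord <- order(colSums(H), decreasing = TRUE)
  list(H = H[, ord, drop = FALSE], U = U[ord, , drop = FALSE])
}

#' @export
print.factor_model <- function(x, ...) {
  cat(sprintf(
    "factor_model: K = %d, objective = %.6g, %d iteration(s)%s, seed %d\n",
    x$K, x$objective, x$n_iter,
    if (x$converged) " (converged)" else "", x$seed))
  invisible(x)
}

#' Residual sum of squares of a factor model
#'
#' @param Y The matrix (or `contact_matrix`) the model was fitted to.
#' @param model A `factor_model`, or a list with elements `H` and `U`.
#' @return `sum((Y - H U)^2)`.
#' @export
rss <- function(Y, model) {
  Y <- as_dense_Y(Y)
  H <- model$H; U <- model$U
  if (nrow(H) != nrow(Y) || ncol(U) != ncol(Y) || ncol(H) != nrow(U)) {
    stop("shape mismatch between Y and model", call. = FALSE)
  }
  R <- Y - H %*% U
  sum(R * R)
}

#' Best-of-n multistart NMF fit
#'
#' Runs [nmf_frobenius()] with seeds `base_seed + 0:(n_starts-1)` and keeps
#' the lowest-objective model. Per-run objectives are attached as attribute
#' `start_objectives`.
#'
#' @inheritParams nmf_frobenius
#' @param n_starts Number of seeded restarts, >= 1.
#' @param base_seed First seed.
#' @return The best `factor_model`.
#' @export
multistart_fit <- function(Y, K, n_starts = 10L, base_seed = 1L,
                           max_iter = 2000L, tol = 1e-5) {
  stopifnot(n_starts >= 1L)
  Y <- as_dense_Y(Y)
  objs <- numeric(n_starts)
  best <- NULL
  for (s in seq_len(n_starts)) {
    m <- nmf_frobenius(Y, K, seed = base_seed + s - 1L,
                       max_iter = max_iter, tol = tol)
    objs[s] <- m$objective
    if (is.null(best) || m$objective < best$objective) best <- m
  }
  attr(best, "start_objectives") <- objs
  best
}

# Dominant-factor assignment of each dyad column: argmax_k U[k, j], ties to
# the lowest k; all-zero columns get NA (a null label that never matches).
dominant_factor <- function(U) {
  lab <- apply(U, 2L, which.max)
  lab[apply(U, 2L, max) <= 0] <- NA_integer_
  lab
}

#' Consensus matrix over repeated NMF runs
#'
#' For each of `n_runs` seeded fits at rank `K`, every dyad column is
#' assigned to its dominant factor (`argmax_k u[k, j]`, ties to the lowest
#' `k`; all-zero columns get a null label that matches nothing). Entry
#' `[j, j']` is the fraction of runs in which dyads `j` and `j'` share an
#' assignment; the matrix is symmetric with unit diagonal and is invariant
#' to run order.
#'
#' @inheritParams nmf_frobenius
#' @param n_runs Number of seeded runs, >= 2.
#' @param base_seed First seed.
#' @return A J x J numeric matrix with entries in `[0, 1]`.
#' @export
consensus_matrix <- function(Y, K, n_runs = 30L, base_seed = 1L,
                             max_iter = 2000L, tol = 1e-5) {
  stopifnot(n_runs >= 2L)
  Y <- as_dense_Y(Y)
  J <- ncol(Y)
  agree <- matrix(0, J, J)
  for (r in seq_len(n_runs)) {
    m <- nmf_frobenius(Y, K, seed = base_seed + r - 1L,
                       max_iter = max_iter, tol = tol)
    lab <- dominant_factor(m$U)
    same <- outer(lab, lab, `==`)
    same[is.na(same)] <- FALSE
    agree <- agree + same
  }
  C <- agree / n_runs
  diag(C) <- 1
  C
}

#' Cophenetic correlation coefficient of a consensus matrix
#'
#' Treats `1 - consensus` as a dissimilarity, builds an average-linkage
#' dendrogram, and returns the Pearson correlation between the original
#' dissimilarities and the dendrogram's cophenetic distances. Values near 1
#' indicate that the consensus is close to ultrametric, i.e. the clustering
#' over restarts is stable.
#'
#' @param consensus Symmetric matrix with entries in `[0, 1]`.
#' @return Correlation in `[-1, 1]`, or `NA_real_` when the dissimilarities
#'   are constant (zero variance).
#' @export
cophenetic_coefficient <- function(consensus) {
  if (!isSymmetric(unname(consensus), tol = 1e-8)) {
    stop("consensus matrix must be symmetric", call. = FALSE)
  }
  d <- stats::as.dist(1 - consensus)
  dv <- as.vector(d)
  if (length(dv) < 1L || stats::sd(dv) == 0) return(NA_real_)
  hc <- stats::hclust(d, method = "average")
  cd <- as.vector(stats::cophenetic(hc))
  if (stats::sd(cd) == 0) return(NA_real_)
  stats::cor(dv, cd)
}

#' Rank selection table: RSS and cophenetic coefficient per candidate K
#'
#' For each rank in `K_range`, computes the best-of-`n_starts` residual sum
#' of squares and the cophenetic correlation coefficient of the
#' `n_runs`-run consensus matrix. The full table is always returned so the
#' analyst can weigh interpretability; when `auto = TRUE`, `chosen_K` is the
#' largest candidate (scanning upward, stopping at the first drop) whose
#' cophenetic coefficient is at least `coph_threshold`.
#'
#' @inheritParams consensus_matrix
#' @param K_range Integer vector of candidate ranks.
#' @param n_starts Restarts for the RSS fit.
#' @param auto Apply the automatic choice rule.
#' @param coph_threshold Cophenetic threshold for the auto rule.
#' @return A `rank_selection` list: `table` (data.frame `K`, `rss`,
#'   `cophenetic`), `consensus` (list of consensus matrices, by rank),
#'   `chosen_K` (integer or `NA`).
#' @export
select_rank <- function(Y, K_range, n_runs = 30L, n_starts = 10L,
                        base_seed = 1L, max_iter = 2000L, tol = 1e-5,
                        auto = FALSE, coph_threshold = 0.95) {
  if (length(K_range) < 1L) stop("K_range is empty", call. = FALSE)
  Y <- as_dense_Y(Y)
  K_range <- sort(unique(as.integer(K_range)))
  rss_k <- coph_k <- numeric(length(K_range))
  cons <- vector("list", length(K_range))
  for (idx in seq_along(K_range)) {
    K <- K_range[idx]
    best <- multistart_fit(Y, K, n_starts = n_starts,
                           base_seed = base_seed + 1000L * idx,
                           max_iter = max_iter, tol = tol)
    rss_k[idx] <- best$objective
    cons[[idx]] <- consensus_matrix(Y, K, n_runs = n_runs,
                                    base_seed = base_seed + 1000L * idx,
                                    max_iter = max_iter, tol = tol)
    coph_k[idx] <- cophenetic_coefficient(cons[[idx]])
  }
  if (any(diff(rss_k) > 0)) {
    warning("rss_by_K is not non-increasing; consider more restarts")
  }
  chosen <- NA_integer_
  if (auto) {
    # largest K meeting the threshold before the first drop below it
    ok <- !is.na(coph_k) & coph_k >= coph_threshold
    upto <- if (all(ok)) length(ok) else which(!ok)[1L] - 1L
    if (upto >= 1L) chosen <- K_range[upto]
  }
  structure(list(
    table = data.frame(K = K_range, rss = rss_k, cophenetic = coph_k),
    consensus = stats::setNames(cons, paste0("K", K_range)),
    chosen_K = chosen
  ), class = "rank_selection")
}

#' @export
print.rank_selection <- function(x, ...) {
  print(x$table, row.names = FALSE)
  if (!is.na(x$chosen_K)) cat("chosen K:", x$chosen_K, "\n")
  invisible(x)
}

#' Persist a factor model
#'
#' Writes `H` and `U` as Matrix Market files plus a JSON metadata sidecar.
#'
#' @param model A `factor_model`.
#' @param stem Path stem; writes `<stem>_H.mtx`, `<stem>_U.mtx`,
#'   `<stem>.json`.
#' @export
write_factor_model <- function(model, stem) {
  Matrix::writeMM(methods::as(Matrix::Matrix(model$H, sparse = TRUE),
                              "CsparseMatrix"), paste0(stem, "_H.mtx"))
  Matrix::writeMM(methods::as(Matrix::Matrix(model$U, sparse = TRUE),
                              "CsparseMatrix"), paste0(stem, "_U.mtx"))
  meta <- list(K = model$K, seed = model$seed, objective = model$objective,
               n_iter = model$n_iter, converged = model$converged,
               normalization = "U rows unit-max, factors by activity")
  jsonlite::write_json(meta, paste0(stem, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(stem)
}

#' Read a factor model written by [write_factor_model()]
#'
#' @param stem Path stem used when writing.
#' @return A `factor_model` (without objective trace).
#' @export
read_factor_model <- function(stem) {
  H <- as.matrix(Matrix::readMM(paste0(stem, "_H.mtx")))
  U <- as.matrix(Matrix::readMM(paste0(stem, "_U.mtx")))
  meta <- jsonlite::read_json(paste0(stem, ".json"), simplifyVector = TRUE)
  structure(list(H = H, U = U, K = as.integer(meta$K),
                 objective = meta$objective, objective_trace = NULL,
                 n_iter = meta$n_iter, seed = as.integer(meta$seed),
                 converged = meta$converged),
            class = "factor_model")
}
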