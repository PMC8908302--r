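# Reconstruction of each latent factor as a weighted undirected participant
# graph, with eigenvector centralities and per-factor activity series.

#' Reconstruct a factor's subnetwork graph
#'
#' Row `k` of the coefficient matrix `U` assigns a tie weight to every dyad;
#' the factor's subnetwork is the undirected graph whose edge (a, b) carries
#' weight `u[k, j]` whenever that weight exceeds `threshold`. Isolated nodes
#' are retained: the node set is always the full participant set.
#'
#' @param model A `factor_model`.
#' @param k Factor index, `1 <= k <= model$K`.
#' @param dyads The `dyad_index` whose columns match `U`.
#' @param threshold Prune edges with weight `<= threshold`; default 0 keeps
#'   every strictly positive tie.
#' @return A `subnetwork_graph` list: `factor_index`, `nodes`, `edges`
#'   (data.frame `a`, `b`, `weight`), `weight_threshold`.
#' @export
factor_to_graph <- function(model, k, dyads, threshold = 0) {
  if (k < 1L || k > model$K) stop("invalid factor index", call. = FALSE)
  if (threshold < 0) stop("threshold must be nonnegative", call. = FALSE)
  w <- model$U[k, ]
  keep <- w > threshold
  structure(list(
    factor_index = as.integer(k),
    nodes = dyads$participants,
    edges = data.frame(a = dyads$pairs[keep, 1L],
                       b = dyads$pairs[keep, 2L],
                       weight = w[keep]),
    weight_threshold = threshold
  ), class = "subnetwork_graph")
}

#' @export
print.subnetwork_graph <- function(x, ...) {
  cat(sprintf("subnetwork_graph: factor %d, %d nodes, %d edges (w > %g)\n",
              x$factor_index, length(x$nodes), nrow(x$edges),
              x$weight_threshold))
  invisible(x)
}

#' Weighted adjacency matrix of a subnetwork graph
#'
#' @param graph A `subnetwork_graph`.
#' @return Dense symmetric numeric matrix with participant ids as dimnames.
#' @export
graph_adjacency <- function(graph) {
  n <- length(graph$nodes)
  A <- matrix(0, n, n, dimnames = list(graph$nodes, graph$nodes))
  if (nrow(graph$edges) > 0L) {
    ia <- match(graph$edges$a, graph$nodes)
    ib <- match(graph$edges$b, graph$nodes)
    A[cbind(ia, ib)] <- graph$edges$weight
    A[cbind(ib, ia)] <- graph$edges$weight
  }
  A
}

#' Eigenvector centrality of a weighted graph
#'
#' Computes the principal (Perron) eigenvector of the weighted adjacency
#' matrix by shifted power iteration started from the uniform vector, and
#' normalizes it to unit maximum. The diagonal shift (a multiple of the mean
#' weighted degree) leaves eigenvectors unchanged while guaranteeing
#' convergence on bipartite graphs, where plain power iteration oscillates.
#' Nodes outside the component attaining the principal eigenvalue receive
#' (near-)zero scores.
#'
#' @param graph A `subnetwork_graph`, or a symmetric nonnegative adjacency
#'   matrix.
#' @param tol Convergence tolerance on the iterate's max-norm change.
#' @param max_iter Maximum power iterations.
#' @return Named numeric vector of centralities in `[0, 1]` with maximum 1.
#' @export
eigenvector_centrality <- function(graph, tol = 1e-13, max_iter = 100000L) {
  A <- if (inherits(graph, "subnetwork_graph")) graph_adjacency(graph)
       else as.matrix(graph)
  if (any(A < 0)) stop("adjacency must be nonnegative", call. = FALSE)
  if (all(A == 0)) {
    stop("graph has no positive edge weight; centrality undefined",
         call. = FALSE)
  }
  n <- nrow(A)
  shift <- mean(rowSums(A))
  x <- rep(1 / n, n)
  for (it in seq_len(max_iter)) {
    x_new <- A %*% x + shift * x
    x_new <- x_new / max(x_new)
    if (max(abs(x_new - x)) < tol) {
      x <- x_new
      break
    }
    x <- x_new
  }
  out <- as.vector(x)
  out[out < 0] <- 0
  names(out) <- rownames(A)
  out / max(out)
}

#' Log-transform centrality scores
#'
#' Natural log of the max-normalized centralities, with zeros floored first
#' so every participant keeps a finite score. The maximally central
#' participant maps to exactly 0.
#'
#' @param raw Centralities in `[0, 1]`.
#' @param floor Substitution value for scores below it; default `1e-6`.
#' @return `log(pmax(raw, floor))`.
#' @export
log_centrality <- function(raw, floor = 1e-6) {
  if (floor <= 0) stop("floor must be positive", call. = FALSE)
  log(pmax(raw, floor))
}

#' Per-participant centrality table across all factors
#'
#' Builds each factor's subnetwork graph and tabulates raw (max-normalized)
#' and log eigenvector centralities. Factors whose graph has no positive
#' edge yield `NA` columns with a warning.
#'
#' @inheritParams factor_to_graph
#' @param floor Log floor, see [log_centrality()].
#' @return data.frame with `participant_id` and, per factor `k`, columns
#'   `raw_k` and `log_k`.
#' @export
centrality_table <- function(model, dyads, threshold = 0, floor = 1e-6) {
  out <- data.frame(participant_id = dyads$participants)
  for (k in seq_len(model$K)) {
    g <- factor_to_graph(model, k, dyads, threshold)
    raw <- tryCatch(eigenvector_centrality(g), error = function(e) {
      warning("factor ", k, ": ", conditionMessage(e))
      rep(NA_real_, length(dyads$participants))
    })
    out[[paste0("raw_", k)]] <- unname(raw)
    out[[paste0("log_", k)]] <- log_centrality(unname(raw), floor)
  }
  out
}

#' Activity time series of one factor
#'
#' Column `k` of the basis matrix `H` labeled with epoch start times; the
#' top-`top_m` epochs (ties broken by time) are attached for comparison with
#' external event calendars.
#'
#' @param model A `factor_model`.
#' @param k Factor index.
#' @param grid The `epoch_grid` matching `H`'s rows.
#' @param top_m Number of peak epochs to report.
#' @return data.frame `epoch`, `start`, `activity`, with attribute
#'   `top_epochs` (data.frame of the `top_m` highest-activity epochs).
#' @export
activity_series <- function(model, k, grid, top_m = 10L) {
  if (k < 1L || k > model$K) stop("invalid factor index", call. = FALSE)
  if (nrow(model$H) != grid$I) stop("grid does not match H", call. = FALSE)
  ser <- data.frame(epoch = seq_len(grid$I),
                    start = epoch_start_times(grid),
                    activity = model$H[, k])
  ord <- order(-ser$activity, ser$epoch)
  attr(ser, "top_epochs") <- ser[ord[seq_len(min(top_m, nrow(ser)))], ]
  ser
}

#' Write a subnetwork graph as a weighted edge list
#'
#' @param graph A `subnetwork_graph`.
#' @param path Output path (delimited text `a,b,weight`).
#' @export
write_edge_list <- function(graph, path) {
  utils::write.csv(graph$edges, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
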