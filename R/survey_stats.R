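# Scoring of self-report scales: PCA-based item retention, internal
# consistency (Cronbach's alpha, McDonald's omega), composite scores, and
# the descriptive / correlation tables relating scale composites to
# per-factor log centralities.

#' Read a survey response table
#'
#' @param path Delimited text, one row per participant, first column
#'   `participant_id`, remaining columns item responses (integers; empty
#'   cells are missing).
#' @param delim Field delimiter.
#' @return data.frame with character `participant_id` and numeric item
#'   columns.
#' @export
read_survey <- function(path, delim = ",") {
  s <- utils::read.table(path, header = TRUE, sep = delim,
                         stringsAsFactors = FALSE)
  if (!"participant_id" %in% names(s)) {
    stop("survey table needs a participant_id column", call. = FALSE)
  }
  s$participant_id <- as.character(s$participant_id)
  for (nm in setdiff(names(s), "participant_id")) {
    s[[nm]] <- as.numeric(s[[nm]])
  }
  s
}

#' Load the packaged survey codebook
#'
#' Maps item short codes to their scale, response range, published
#' first-component loading and retention status. The shipped configuration
#' reflects the study instrument: a 9-item pro-community attitude set (7
#' retained), a 5-item openness set (4 retained), and single-item happiness
#' and subjective-health measures on 0-10 scales.
#'
#' @return data.frame with columns `item`, `scale`, `min`, `max`,
#'   `loading_full`, `retained`, `label`.
#' @export
load_codebook <- function() {
  path <- system.file("extdata", "survey_codebook.csv", package = "proxnet",
                      mustWork = TRUE)
  cb <- utils::read.csv(path, stringsAsFactors = FALSE)
  cb$retained <- as.logical(cb$retained)
  cb
}

#' Items of a scale from a codebook
#'
#' @param codebook As from [load_codebook()].
#' @param scale Scale name.
#' @param retained_only Keep only retained items.
#' @return Character vector of item codes.
#' @export
scale_items <- function(codebook, scale, retained_only = TRUE) {
  rows <- codebook[codebook$scale == scale, ]
  if (retained_only) rows <- rows[rows$retained, ]
  rows$item
}

complete_items <- function(items, min_rows = 3L) {
  X <- as.matrix(items)
  X <- X[stats::complete.cases(X), , drop = FALSE]
  if (nrow(X) < min_rows) {
    stop("need >= ", min_rows, " complete respondents", call. = FALSE)
  }
  X
}

#' First-principal-component loadings of an item set
#'
#' Loadings of each item on the first principal component of the item
#' correlation matrix (complete cases), signed so the loading sum is
#' positive.
#'
#' @param items Numeric matrix or data.frame of responses (rows =
#'   respondents, columns = items), >= 2 items and >= 3 complete rows.
#' @return Named numeric vector of loadings.
#' @export
pca_first_loadings <- function(items) {
  X <- complete_items(items)
  if (ncol(X) < 2L) stop("need >= 2 items", call. = FALSE)
  sds <- apply(X, 2L, stats::sd)
  if (any(sds == 0)) {
    stop("zero-variance item(s): ",
         paste(colnames(X)[sds == 0], collapse = ", "), call. = FALSE)
  }
  R <- stats::cor(X)
  e <- eigen(R, symmetric = TRUE)
  l <- e$vectors[, 1L] * sqrt(e$values[1L])
  if (sum(l) < 0) l <- -l
  stats::setNames(l, colnames(X))
}

#' Retain items by loading threshold and manual exclusions
#'
#' @param loadings Named loadings as from [pca_first_loadings()].
#' @param threshold Minimum loading to retain, default 0.45.
#' @param manual_exclusions Item names excluded regardless of loading
#'   (theory-driven exclusions the threshold cannot express).
#' @return Character vector of retained item names; error if empty.
#' @export
retain_items <- function(loadings, threshold = 0.45,
                         manual_exclusions = character()) {
  if (threshold < 0 || threshold > 1) {
    stop("threshold must be in [0, 1]", call. = FALSE)
  }
  keep <- names(loadings)[loadings >= threshold &
                            !names(loadings) %in% manual_exclusions]
  if (length(keep) == 0L) stop("no items retained", call. = FALSE)
  keep
}

#' Cronbach's alpha
#'
#' `alpha = k/(k-1) * (1 - sum(item variances) / var(row sums))` over
#' complete cases.
#'
#' @param items Response matrix/data.frame, >= 2 items, >= 3 complete rows.
#' @return Alpha coefficient.
#' @export
cronbach_alpha <- function(items) {
  X <- complete_items(items)
  k <- ncol(X)
  if (k < 2L) stop("need >= 2 items", call. = FALSE)
  iv <- sum(apply(X, 2L, stats::var))
  tv <- stats::var(rowSums(X))
  if (tv == 0) stop("total score has zero variance", call. = FALSE)
  k / (k - 1) * (1 - iv / tv)
}

# Single-factor fit of a correlation matrix by minimum residual (minres):
# minimize sum_{i<j} (R_ij - l_i l_j)^2, initialized at the first-PC
# loadings. One code path for any k >= 2 (maximum-likelihood fitting is not
# identified at k = 2).
one_factor_loadings <- function(R) {
  k <- ncol(R)
  e <- eigen(R, symmetric = TRUE)
  l0 <- e$vectors[, 1L] * sqrt(e$values[1L])
  if (sum(l0) < 0) l0 <- -l0
  off <- upper.tri(R)
  fn <- function(l) sum((R[off] - tcrossprod(l)[off])^2)
  gr <- function(l) {
    Res <- tcrossprod(l) - R
    diag(Res) <- 0
    2 * Res %*% l
  }
  fit <- stats::optim(l0, fn, gr, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-12))
  l <- fit$par
  if (sum(l) < 0) l <- -l
  stats::setNames(l, colnames(R))
}

#' McDonald's omega (one-factor)
#'
#' `omega = (sum lambda)^2 / ((sum lambda)^2 + sum theta)` where `lambda`
#' are standardized loadings from a single-factor minimum-residual fit of
#' the item correlation matrix and `theta = 1 - lambda^2` the uniquenesses.
#' Being computed on the correlation matrix, omega is invariant to per-item
#' positive linear rescaling.
#'
#' @param items Response matrix/data.frame, >= 2 items, >= 3 complete rows.
#' @return Omega coefficient.
#' @export
mcdonald_omega <- function(items) {
  X <- complete_items(items)
  if (ncol(X) < 2L) stop("need >= 2 items", call. = FALSE)
  sds <- apply(X, 2L, stats::sd)
  if (any(sds == 0)) {
    stop("zero-variance item(s): ",
         paste(colnames(X)[sds == 0], collapse = ", "), call. = FALSE)
  }
  R <- stats::cor(X)
  l <- one_factor_loadings(R)
  if (any(l >= 1)) {
    stop("Heywood case: standardized loading >= 1 for item(s) ",
         paste(names(l)[l >= 1], collapse = ", "),
         "; one-factor model unsuitable", call. = FALSE)
  }
  theta <- 1 - l^2
  sum(l)^2 / (sum(l)^2 + sum(theta))
}

#' Composite scale score
#'
#' Mean of answered retained items per participant; missing when fewer than
#' half (ceiling) of the retained items were answered.
#'
#' @param items Response matrix/data.frame including at least the retained
#'   columns.
#' @param retained Character vector of retained item names.
#' @param min_answered Minimum answered-item count; default
#'   `ceiling(length(retained) / 2)`.
#' @return Numeric vector, one score (or `NA`) per row.
#' @export
composite_score <- function(items, retained,
                            min_answered = ceiling(length(retained) / 2)) {
  if (length(retained) == 0L) stop("retained set is empty", call. = FALSE)
  X <- as.matrix(items[, retained, drop = FALSE])
  n_ans <- rowSums(!is.na(X))
  score <- rowMeans(X, na.rm = TRUE)
  score[n_ans < min_answered] <- NA_real_
  score
}

#' Descriptive statistics table
#'
#' @param variables data.frame of numeric variables (missing allowed).
#' @return data.frame `variable`, `N`, `mean`, `median`, `sd` (n-1
#'   denominator; `NA` for a single observation), `min`, `max`.
#' @export
describe <- function(variables) {
  rows <- lapply(names(variables), function(nm) {
    v <- variables[[nm]]
    v <- v[!is.na(v)]
    if (length(v) == 0L) stop("variable ", nm, " has no values", call. = FALSE)
    data.frame(variable = nm, N = length(v), mean = mean(v),
               median = stats::median(v),
               sd = if (length(v) > 1L) stats::sd(v) else NA_real_,
               min = min(v), max = max(v))
  })
  do.call(rbind, rows)
}

#' Pairwise Pearson correlation table with significance flags
#'
#' Pearson r with two-tailed p-values from the t distribution on n-2
#' degrees of freedom, under pairwise deletion of missing values.
#' Significance flags: dagger for p < 0.10, `*` for p < 0.05, `**` for
#' p < 0.01. Pairs with fewer than 3 complete observations or zero variance
#' are reported missing.
#'
#' @param table data.frame of numeric variables.
#' @return A `correlation_table` list of matrices `r`, `p`, `n`, `flag`.
#' @export
correlate <- function(table) {
  nms <- names(table)
  m <- length(nms)
  r <- p <- matrix(NA_real_, m, m, dimnames = list(nms, nms))
  n <- matrix(0L, m, m, dimnames = list(nms, nms))
  for (a in seq_len(m)) {
    for (b in seq_len(a)) {
      x <- table[[a]]; y <- table[[b]]
      ok <- !is.na(x) & !is.na(y)
      n[a, b] <- n[b, a] <- sum(ok)
      if (sum(ok) < 3L) next
      if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) next
      rv <- stats::cor(x[ok], y[ok])
      r[a, b] <- r[b, a] <- rv
      if (a == b) {
        p[a, b] <- NA_real_
      } else {
        df <- sum(ok) - 2L
        tt <- rv * sqrt(df / max(1 - rv^2, .Machine$double.eps))
        p[a, b] <- p[b, a] <- 2 * stats::pt(-abs(tt), df)
      }
    }
  }
  structure(list(r = r, p = p, n = n, flag = sig_flags(p)),
            class = "correlation_table")
}

#' Significance flags for a p-value matrix or vector
#'
#' @param p Numeric p-values.
#' @return Character: `"**"` (p < .01), `"*"` (p < .05), `"†"`
#'   (p < .10), else `""` (`NA` p gives `""`).
#' @export
sig_flags <- function(p) {
  f <- ifelse(is.na(p), "",
              ifelse(p < 0.01, "**",
                     ifelse(p < 0.05, "*",
                            ifelse(p < 0.10, "†", ""))))
  if (is.matrix(p)) dimnames(f) <- dimnames(p)
  f
}

#' @export
print.correlation_table <- function(x, digits = 2, ...) {
  fmt <- matrix(paste0(formatC(x$r, digits = digits, format = "f"), x$flag),
                nrow(x$r), dimnames = dimnames(x$r))
  fmt[is.na(x$r)] <- "."
  diag(fmt) <- "-"
  print(fmt, quote = FALSE)
  invisible(x)
}

#' Write a correlation table as delimited text
#'
#' Long format: one row per variable pair with r, p, n and the flag column.
#'
#' @param ct A `correlation_table`.
#' @param path Output path.
#' @export
write_correlation_table <- function(ct, path) {
  nms <- rownames(ct$r)
  idx <- which(lower.tri(ct$r), arr.ind = TRUE)
  df <- data.frame(var1 = nms[idx[, 2L]], var2 = nms[idx[, 1L]],
                   r = ct$r[idx], p = ct$p[idx], n = ct$n[idx],
                   flag = ct$flag[idx])
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
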