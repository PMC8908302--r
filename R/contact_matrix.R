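# The epoch-by-dyad social contact matrix Y.
#
# Rows index fixed-length time bins ("epochs", default 30 minutes) covering
# the study window; columns index unordered participant pairs ("dyads").
# y[i, j] counts device detections between dyad j's two members during epoch
# i. Y is held sparse (Matrix::dgCMatrix); the contract is positional access
# plus dense export.

#' Build an epoch grid
#'
#' Divides the inclusive day range `[start, end]` into half-open epochs of
#' `epoch_minutes` aligned to midnight of `start`; a detection at an epoch
#' boundary belongs to the later epoch. Wall-clock time throughout (no DST
#' adjustment).
#'
#' @param start,end First and last study dates (inclusive).
#' @param epoch_minutes Epoch length in minutes; must divide 1440.
#' @param timezone Timezone label for epoch timestamps.
#' @return An `epoch_grid` list with fields `start_date`, `end_date`,
#'   `epoch_minutes`, `epochs_per_day`, `n_days`, `I` (total epoch count)
#'   and `timezone`.
#' @examples
#' g <- build_epoch_grid("2017-12-01", "2018-06-30", 30)
#' g$I  # 10176 epochs over 212 days
#' @export
build_epoch_grid <- function(start, end, epoch_minutes = 30L,
                             timezone = "UTC") {
  start <- as.Date(start); end <- as.Date(end)
  if (is.na(start) || is.na(end) || start > end) {
    stop("invalid epoch grid dates", call. = FALSE)
  }
  epoch_minutes <- as.integer(epoch_minutes)
  if (epoch_minutes < 1L || 1440L %% epoch_minutes != 0L) {
    stop("epoch_minutes must be a positive divisor of 1440", call. = FALSE)
  }
  epd <- 1440L %/% epoch_minutes
  n_days <- as.integer(end - start) + 1L
  structure(list(
    start_date = start, end_date = end,
    epoch_minutes = epoch_minutes, epochs_per_day = epd,
    n_days = n_days, I = n_days * epd, timezone = timezone
  ), class = "epoch_grid")
}

#' Map timestamps to epoch indices
#'
#' @param grid An `epoch_grid`.
#' @param timestamps POSIXct vector.
#' @return 1-based integer epoch indices; `NA` for timestamps outside the
#'   grid.
#' @export
epoch_index <- function(grid, timestamps) {
  origin <- as.POSIXct(paste(grid$start_date, "00:00:00"),
                       tz = grid$timezone)
  mins <- as.numeric(difftime(timestamps, origin, units = "mins"))
  idx <- floor(mins / grid$epoch_minutes) + 1
  idx[idx < 1 | idx > grid$I] <- NA
  as.integer(idx)
}

#' Epoch start times of a grid
#'
#' @param grid An `epoch_grid`.
#' @return POSIXct vector of length `grid$I`.
#' @export
epoch_start_times <- function(grid) {
  origin <- as.POSIXct(paste(grid$start_date, "00:00:00"),
                       tz = grid$timezone)
  origin + (seq_len(grid$I) - 1) * grid$epoch_minutes * 60
}

#' Build a dyad index
#'
#' Orders the N participants lexicographically and lays out the J = N(N-1)/2
#' unordered pairs in row-major upper-triangle order: (1,2), (1,3), ...,
#' (1,N), (2,3), ... Each pair is stored smaller id first.
#'
#' @param participant_ids Unique participant ids, N >= 2.
#' @return A `dyad_index` list with `participants` (sorted ids), `pairs`
#'   (J x 2 character matrix) and `J`.
#' @export
build_dyad_index <- function(participant_ids) {
  ids <- as.character(participant_ids)
  if (anyDuplicated(ids)) stop("duplicate participant ids", call. = FALSE)
  if (length(ids) < 2L) stop("need at least 2 participants", call. = FALSE)
  ids <- sort(ids)
  n <- length(ids)
  i <- rep.int(seq_len(n - 1L), (n - 1L):1L)
  j <- unlist(lapply(seq_len(n - 1L), function(a) (a + 1L):n))
  structure(list(
    participants = ids,
    pairs = cbind(a = ids[i], b = ids[j]),
    J = (n * (n - 1L)) %/% 2L
  ), class = "dyad_index")
}

#' Column index of a dyad
#'
#' @param dyads A `dyad_index`.
#' @param a,b Participant ids (vectors of equal length, order-free).
#' @return Integer column indices; `NA` where an id is unknown.
#' @export
dyad_column <- function(dyads, a, b) {
  n <- length(dyads$participants)
  pa <- match(as.character(a), dyads$participants)
  pb <- match(as.character(b), dyads$participants)
  lo <- pmin(pa, pb); hi <- pmax(pa, pb)
  out <- ((lo - 1L) * (2L * n - lo)) %/% 2L + (hi - lo)
  out[is.na(pa) | is.na(pb) | lo == hi] <- NA
  as.integer(out)
}

#' Build the social contact matrix Y
#'
#' Scores social contact for every dyad and epoch as the number of device
#' detections between the pair falling in that epoch. `direction_rule =
#' "sum"` adds the A-observes-B and B-observes-A counts; `"max"` takes the
#' larger of the two per-epoch directional counts. An optional `cap`
#' truncates each cell (the physical ceiling is one detection per direction
#' per scan interval).
#'
#' @param log A participant-id `detection_log`, already windowed to the grid.
#' @param grid An `epoch_grid`.
#' @param dyads A `dyad_index`; every id in `log` must be present.
#' @param direction_rule `"sum"` (default) or `"max"`.
#' @param cap Optional positive integer cell cap; `NULL` disables.
#' @return A `contact_matrix` list with sparse integer matrix `Y` (I x J),
#'   `grid` and `dyads`.
#' @export
build_contact_matrix <- function(log, grid, dyads,
                                 direction_rule = c("sum", "max"),
                                 cap = NULL) {
  direction_rule <- match.arg(direction_rule)
  i <- epoch_index(grid, log$timestamp)
  if (anyNA(i)) stop("detection record outside the epoch grid", call. = FALSE)
  j <- dyad_column(dyads, log$observer_id, log$observed_id)
  if (anyNA(j)) stop("detection record with unknown participant", call. = FALSE)
  if (direction_rule == "sum" || length(i) == 0L) {
    Y <- Matrix::sparseMatrix(i = i, j = j, x = rep(1, length(i)),
                              dims = c(grid$I, dyads$J))
  } else {
    dir_ab <- log$observer_id < log$observed_id
    key <- paste(i, j, dir_ab)
    tab <- tapply(rep(1, length(i)), key, sum)
    parts <- strsplit(names(tab), " ", fixed = TRUE)
    ki <- as.integer(vapply(parts, `[[`, "", 1L))
    kj <- as.integer(vapply(parts, `[[`, "", 2L))
    cell <- paste(ki, kj)
    mx <- tapply(as.numeric(tab), cell, max)
    cp <- strsplit(names(mx), " ", fixed = TRUE)
    Y <- Matrix::sparseMatrix(
      i = as.integer(vapply(cp, `[[`, "", 1L)),
      j = as.integer(vapply(cp, `[[`, "", 2L)),
      x = as.numeric(mx), dims = c(grid$I, dyads$J)
    )
  }
  if (!is.null(cap)) {
    if (cap < 0) stop("cap must be nonnegative", call. = FALSE)
    Y@x <- pmin(Y@x, cap)
  }
  new_contact_matrix(Y, grid, dyads)
}

new_contact_matrix <- function(Y, grid, dyads) {
  stopifnot(nrow(Y) == grid$I, ncol(Y) == dyads$J)
  structure(list(Y = methods::as(Y, "CsparseMatrix"), grid = grid,
                 dyads = dyads),
            class = "contact_matrix")
}

#' @export
as.matrix.contact_matrix <- function(x, ...) as.matrix(x$Y)

#' @export
dim.contact_matrix <- function(x) dim(x$Y)

#' @export
print.contact_matrix <- function(x, ...) {
  cat(sprintf(
    "contact_matrix: %d epochs x %d dyads (%d participants), %d nonzero cells\n",
    nrow(x$Y), ncol(x$Y), length(x$dyads$participants),
    length(x$Y@x)))
  invisible(x)
}

#' Summarize a contact matrix
#'
#' Reports, per participant, total detections across all their dyads divided
#' by the number of study days (detections/day), plus the overall nonzero
#' cell fraction and the dyad column sums.
#'
#' @param cm A `contact_matrix`.
#' @return List with `per_participant` (data.frame: participant_id,
#'   detections, per_day), `mean_detections_per_day` (average over
#'   participants), `nonzero_fraction`, `column_sums`.
#' @export
matrix_summary <- function(cm) {
  csums <- Matrix::colSums(cm$Y)
  ids <- cm$dyads$participants
  tot <- stats::setNames(numeric(length(ids)), ids)
  for (r in seq_len(nrow(cm$dyads$pairs))) {
    tot[cm$dyads$pairs[r, 1L]] <- tot[cm$dyads$pairs[r, 1L]] + csums[r]
    tot[cm$dyads$pairs[r, 2L]] <- tot[cm$dyads$pairs[r, 2L]] + csums[r]
  }
  per_day <- tot / cm$grid$n_days
  list(
    per_participant = data.frame(participant_id = ids,
                                 detections = unname(tot),
                                 per_day = unname(per_day)),
    mean_detections_per_day = mean(per_day),
    nonzero_fraction = length(cm$Y@x) / prod(dim(cm$Y)),
    column_sums = csums
  )
}

#' Write a contact matrix to disk
#'
#' Stores `Y` in Matrix Market format plus two delimited sidecars: epoch
#' start times and dyad labels.
#'
#' @param cm A `contact_matrix`.
#' @param stem Output path stem; writes `<stem>.mtx`, `<stem>_epochs.csv`,
#'   `<stem>_dyads.csv`.
#' @export
write_contact_matrix <- function(cm, stem) {
  Matrix::writeMM(cm$Y, paste0(stem, ".mtx"))
  utils::write.csv(
    data.frame(epoch = seq_len(cm$grid$I),
               start = format(epoch_start_times(cm$grid),
                              "%Y-%m-%d %H:%M:%S")),
    paste0(stem, "_epochs.csv"), row.names = FALSE, quote = FALSE)
  utils::write.csv(
    data.frame(dyad = seq_len(cm$dyads$J),
               a = cm$dyads$pairs[, 1L], b = cm$dyads$pairs[, 2L]),
    paste0(stem, "_dyads.csv"), row.names = FALSE, quote = FALSE)
  invisible(stem)
}

#' Read a contact matrix written by [write_contact_matrix()]
#'
#' @param stem Path stem used when writing.
#' @param grid The `epoch_grid` of the stored matrix.
#' @return A `contact_matrix`.
#' @export
read_contact_matrix <- function(stem, grid) {
  Y <- methods::as(Matrix::readMM(paste0(stem, ".mtx")), "CsparseMatrix")
  dy <- utils::read.csv(paste0(stem, "_dyads.csv"),
                        colClasses = "character")
  dyads <- build_dyad_index(sort(unique(c(dy$a, dy$b))))
  new_contact_matrix(Y, grid, dyads)
}
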