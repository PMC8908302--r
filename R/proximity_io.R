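# Reading, validating and windowing raw proximity detection logs.
#
# A detection log is a delimited text file with a header
# `timestamp,observer_id,observed_id`: one row per device-sees-device event.
# In-memory, a log is a data.frame with columns `timestamp` (POSIXct, one
# fixed study timezone), `observer_id` and `observed_id` (character), carrying
# class "detection_log".

new_detection_log <- function(timestamp, observer_id, observed_id) {
  df <- data.frame(
    timestamp = timestamp,
    observer_id = as.character(observer_id),
    observed_id = as.character(observed_id),
    stringsAsFactors = FALSE
  )
  class(df) <- c("detection_log", "data.frame")
  df
}

#' Read a proximity detection log
#'
#' Parses a delimited text file of device detection events. Each row records
#' that one participant's device observed another device at a given time.
#' Rows whose timestamp cannot be parsed, that are incomplete, or that are
#' self-detections (observer equals observed) are skipped and counted; the
#' skip count is reported via [message()] and attached as attribute
#' `n_skipped`.
#'
#' @param path Path to a delimited text file with header columns
#'   `timestamp,observer_id,observed_id`. Timestamps are ISO-8601
#'   (`YYYY-MM-DD HH:MM[:SS]` or with a `T` separator).
#' @param timezone Timezone label applied to all timestamps. The whole study
#'   uses one fixed wall-clock timezone; epoch boundaries never shift for DST.
#' @param delim Field delimiter, default comma.
#' @param quiet Suppress the skip-count message.
#' @return A `detection_log` data.frame with columns `timestamp`,
#'   `observer_id`, `observed_id`, in file order, with attribute `n_skipped`.
#' @export
read_detections <- function(path, timezone = "UTC", delim = ",", quiet = FALSE) {
  if (!file.exists(path)) {
    stop("detection log not readable: ", path, call. = FALSE)
  }
  raw <- utils::read.table(path, header = TRUE, sep = delim,
                           colClasses = "character", fill = TRUE,
                           stringsAsFactors = FALSE)
  if (nrow(raw) == 0L) {
    out <- new_detection_log(as.POSIXct(character(), tz = timezone),
                             character(), character())
    attr(out, "n_skipped") <- 0L
    return(out)
  }
  if (ncol(raw) < 3L) {
    stop("detection log needs >= 3 columns (timestamp, observer, observed)",
         call. = FALSE)
  }
  ts <- parse_timestamps(raw[[1L]], timezone)
  obs <- trimws(raw[[2L]])
  seen <- trimws(raw[[3L]])
  bad <- is.na(ts) | obs == "" | seen == "" | is.na(obs) | is.na(seen) |
    obs == seen
  n_skipped <- sum(bad)
  if (n_skipped > 0L && !quiet) {
    message("read_detections: skipped ", n_skipped, " malformed row(s)")
  }
  out <- new_detection_log(ts[!bad], obs[!bad], seen[!bad])
  attr(out, "n_skipped") <- as.integer(n_skipped)
  out
}

parse_timestamps <- function(x, timezone) {
  x <- gsub("T", " ", trimws(x), fixed = TRUE)
  # strptime (unlike as.POSIXct + tryFormats) yields per-element NA on
  # failure instead of raising
  ts <- strptime(x, "%Y-%m-%d %H:%M:%S", tz = timezone)
  retry <- is.na(ts)
  if (any(retry)) {
    ts[retry] <- strptime(x[retry], "%Y-%m-%d %H:%M", tz = timezone)
  }
  as.POSIXct(ts)
}

#' Write a detection log
#'
#' Inverse of [read_detections()]: writes the standard three-column delimited
#' format so that a written log reads back to an identical record sequence.
#'
#' @param log A `detection_log` data.frame.
#' @param path Output file path.
#' @param delim Field delimiter.
#' @export
write_detections <- function(log, path, delim = ",") {
  df <- data.frame(
    timestamp = format(log$timestamp, "%Y-%m-%d %H:%M:%S"),
    observer_id = log$observer_id,
    observed_id = log$observed_id
  )
  utils::write.table(df, path, sep = delim, row.names = FALSE,
                     col.names = TRUE, quote = FALSE)
  invisible(path)
}

#' Restrict a detection log to a study window
#'
#' Keeps records whose calendar date lies within `[start, end]`, both ends
#' inclusive; record order is preserved. Idempotent.
#'
#' @param log A `detection_log` data.frame.
#' @param start,end Dates (or strings coercible via [as.Date()]) bounding the
#'   study window.
#' @return The filtered `detection_log`.
#' @export
window_records <- function(log, start, end) {
  start <- as.Date(start); end <- as.Date(end)
  if (is.na(start) || is.na(end)) stop("invalid window dates", call. = FALSE)
  if (start > end) stop("window start is after end", call. = FALSE)
  d <- as.Date(log$timestamp, tz = tz_of(log$timestamp))
  keep <- d >= start & d <= end
  out <- log[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("detection_log", "data.frame")
  out
}

tz_of <- function(x) {
  tz <- attr(x, "tzone")
  if (is.null(tz) || identical(tz, "")) "UTC" else tz[1L]
}

#' Read a participant/device roster
#'
#' @param path Delimited text with header `participant_id,device_id`.
#' @param delim Field delimiter.
#' @return A data.frame with character columns `participant_id` and
#'   `device_id`. The device-to-participant map must be injective.
#' @export
read_roster <- function(path, delim = ",") {
  r <- utils::read.table(path, header = TRUE, sep = delim,
                         colClasses = "character", stringsAsFactors = FALSE)
  if (!all(c("participant_id", "device_id") %in% names(r))) {
    stop("roster needs columns participant_id, device_id", call. = FALSE)
  }
  if (anyDuplicated(r$device_id)) {
    stop("roster device_id -> participant_id map must be injective",
         call. = FALSE)
  }
  r[, c("participant_id", "device_id")]
}

#' Read a carry record
#'
#' One row per (participant, calendar day) on which the participant's device
#' uploaded any data.
#'
#' @param path Delimited text with header `participant_id,date`.
#' @param delim Field delimiter.
#' @return data.frame with columns `participant_id` (character) and `date`
#'   (Date).
#' @export
read_carry_record <- function(path, delim = ",") {
  r <- utils::read.table(path, header = TRUE, sep = delim,
                         colClasses = "character", stringsAsFactors = FALSE)
  if (!all(c("participant_id", "date") %in% names(r))) {
    stop("carry record needs columns participant_id, date", call. = FALSE)
  }
  data.frame(participant_id = r$participant_id, date = as.Date(r$date))
}

#' Apply the device-carrying inclusion rule
#'
#' Participants are retained when they carried the device "continuously" for
#' long enough: by default, when their longest run of consecutive calendar
#' carry-days reaches `min_days` (default 61, i.e. more than two months).
#' With `rule = "total"` the cumulative number of distinct carry-days is used
#' instead.
#'
#' @param carry A carry-record data.frame as from [read_carry_record()].
#' @param min_days Minimum qualifying day count, default 61.
#' @param rule `"consecutive"` (longest run of consecutive days) or
#'   `"total"` (count of distinct days).
#' @return Sorted character vector of included participant ids.
#' @export
apply_inclusion_rule <- function(carry, min_days = 61L,
                                 rule = c("consecutive", "total")) {
  rule <- match.arg(rule)
  if (min_days < 1L) stop("min_days must be >= 1", call. = FALSE)
  days_by <- split(carry$date, carry$participant_id)
  ok <- vapply(days_by, function(d) {
    d <- sort(unique(d))
    if (rule == "total") return(length(d) >= min_days)
    longest_run(d) >= min_days
  }, logical(1L))
  sort(names(days_by)[ok])
}

longest_run <- function(days) {
  if (length(days) == 0L) return(0L)
  gaps <- c(TRUE, diff(as.integer(days)) != 1L)
  run_id <- cumsum(gaps)
  max(tabulate(run_id))
}

#' Map device ids in a detection log to participant ids
#'
#' Devices also hear non-study Bluetooth hardware; records whose observer or
#' observed device is not in the roster are dropped and counted.
#'
#' @param log A `detection_log` whose id columns hold device ids.
#' @param roster Roster data.frame from [read_roster()].
#' @param quiet Suppress the drop-count message.
#' @return A `detection_log` whose id columns hold participant ids, with
#'   attribute `n_dropped`.
#' @export
map_to_participants <- function(log, roster, quiet = FALSE) {
  map <- stats::setNames(roster$participant_id, roster$device_id)
  obs <- unname(map[log$observer_id])
  seen <- unname(map[log$observed_id])
  keep <- !is.na(obs) & !is.na(seen)
  n_dropped <- sum(!keep)
  if (n_dropped > 0L && !quiet) {
    message("map_to_participants: dropped ", n_dropped,
            " record(s) with non-roster devices")
  }
  out <- new_detection_log(log$timestamp[keep], obs[keep], seen[keep])
  attr(out, "n_dropped") <- as.integer(n_dropped)
  out
}
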