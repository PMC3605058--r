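#' @useDynLib avkit, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats approx ave coef lm median optim optimize p.adjust pf pt
#'   quantile rbinom rlnorm rnorm rpois runif sd var dpois setNames fft
#' @importFrom utils read.csv write.csv read.delim write.table head tail
NULL

#' Vigilance-state vocabulary
#'
#' The fixed set of vigilance-state labels used throughout the package:
#' wakefulness, rapid-eye-movement sleep and the non-REM stages (light sleep
#' s1 and s2, slow-wave sleep s3/s4 combined).
#'
#' @return Character vector of admissible state labels.
#' @export
vigilance_states <- function() c("WAKE", "REM", "S1", "S2", "S3S4")

#' Construct a hypnogram
#'
#' A hypnogram is an ordered list of non-overlapping intervals of constant
#' vigilance state. It defines the segments within which events are
#' rate-matched and avalanches are extracted; avalanches never span a
#' segment boundary.
#'
#' @param start,end Numeric vectors of interval start/end times in seconds.
#' @param state Character vector of state labels, see [vigilance_states()].
#' @return A `hypnogram` object (a data frame with columns `start`, `end`,
#'   `state`).
#' @examples
#' hypnogram(c(0, 300), c(300, 600), c("WAKE", "S2"))
#' @export
hypnogram <- function(start, end, state) {
  stopifnot(length(start) == length(end), length(start) == length(state))
  state <- as.character(state)
  bad <- setdiff(unique(state), vigilance_states())
  if (length(bad) > 0) {
    stop("unknown vigilance state label(s): ", paste(bad, collapse = ", "))
  }
  if (any(end <= start)) stop("hypnogram intervals must have end > start")
  o <- order(start)
  start <- start[o]; end <- end[o]; state <- state[o]
  if (length(start) > 1 && any(start[-1] < end[-length(end)])) {
    stop("hypnogram intervals must not overlap")
  }
  h <- data.frame(start = as.numeric(start), end = as.numeric(end),
                  state = state, stringsAsFactors = FALSE)
  class(h) <- c("hypnogram", "data.frame")
  h
}

#' Read / write a hypnogram as CSV
#'
#' The on-disk format is a CSV with header `start_s,end_s,state`.
#'
#' @param path File path.
#' @param h A [hypnogram()].
#' @return `read_hypnogram` returns a `hypnogram`; `write_hypnogram` returns
#'   `path` invisibly.
#' @export
read_hypnogram <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  hypnogram(d$start_s, d$end_s, d$state)
}

#' @rdname read_hypnogram
#' @export
write_hypnogram <- function(h, path) {
  stopifnot(inherits(h, "hypnogram"))
  write.csv(data.frame(start_s = h$start, end_s = h$end, state = h$state),
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Construct an event raster
#'
#' A per-channel timestamped binary event raster, the substrate of all
#' avalanche statistics. Events are (channel, time) pairs; segment labels
#' (a [hypnogram()]) partition the recording into intervals of constant
#' vigilance state.
#'
#' @param n_channels Number of channels (recording sites).
#' @param channel Integer vector of 1-based channel indices, one per event.
#' @param time Numeric vector of event times in seconds.
#' @param duration Total recording duration in seconds.
#' @param rate_r Nominal per-channel event rate in Hz (may be `NA` for
#'   rasters not produced by rate matching).
#' @param segment_labels Optional [hypnogram()] of constant-state segments.
#'   When `NULL`, the whole recording is treated as one `WAKE` segment.
#' @param channel_group Optional character vector of length `n_channels`
#'   assigning each channel to a group (e.g. a neocortical vs.
#'   amygdala/hippocampus analog).
#' @return An `event_raster` object.
#' @export
event_raster <- function(n_channels, channel, time, duration,
                         rate_r = NA_real_, segment_labels = NULL,
                         channel_group = NULL) {
  stopifnot(length(channel) == length(time))
  n_channels <- as.integer(n_channels)
  if (n_channels < 1) stop("n_channels must be >= 1")
  channel <- as.integer(channel)
  time <- as.numeric(time)
  if (length(time) > 0) {
    if (any(channel < 1L | channel > n_channels)) {
      stop("channel indices must lie in [1, n_channels]")
    }
    if (any(time < 0 | time >= duration)) {
      stop("event times must lie in [0, duration)")
    }
  }
  if (is.null(segment_labels)) {
    segment_labels <- if (duration > 0) {
      hypnogram(0, duration, "WAKE")
    } else {
      h <- data.frame(start = numeric(0), end = numeric(0),
                      state = character(0))
      class(h) <- c("hypnogram", "data.frame")
      h
    }
  }
  if (!is.null(channel_group)) {
    stopifnot(length(channel_group) == n_channels)
    channel_group <- as.character(channel_group)
  }
  o <- order(time, channel)
  r <- list(n_channels = n_channels,
            events = data.frame(channel = channel[o], time = time[o]),
            duration = as.numeric(duration),
            rate_r = as.numeric(rate_r),
            segment_labels = segment_labels,
            channel_group = channel_group)
  class(r) <- "event_raster"
  r
}

#' @export
print.event_raster <- function(x, ...) {
  cat(sprintf("event_raster: %d channels, %d events, %.1f s", x$n_channels,
              nrow(x$events), x$duration))
  if (!is.na(x$rate_r)) cat(sprintf(", nominal rate %.3g Hz", x$rate_r))
  cat(sprintf(", %d segment(s)\n", nrow(x$segment_labels)))
  invisible(x)
}

#' Number of events in a raster
#' @param raster An [event_raster()].
#' @return Integer event count.
#' @export
n_events <- function(raster) {
  stopifnot(inherits(raster, "event_raster"))
  nrow(raster$events)
}

#' Read / write an event raster as CSV plus JSON sidecar
#'
#' Events are stored as a CSV with header `channel,time_s`; raster metadata
#' (channel count, duration, nominal rate, channel groups and segment
#' labels) go to a JSON sidecar `<path>.json`.
#'
#' @param raster An [event_raster()].
#' @param path CSV file path; the sidecar is written next to it.
#' @return `read_event_raster` returns an `event_raster`;
#'   `write_event_raster` returns `path` invisibly.
#' @export
write_event_raster <- function(raster, path) {
  stopifnot(inherits(raster, "event_raster"))
  write.csv(data.frame(channel = raster$events$channel,
                       time_s = raster$events$time),
            path, row.names = FALSE, quote = FALSE)
  meta <- list(n_channels = raster$n_channels,
               duration = raster$duration,
               rate_r = raster$rate_r,
               channel_group = raster$channel_group,
               segment_labels = list(start = raster$segment_labels$start,
                                     end = raster$segment_labels$end,
                                     state = raster$segment_labels$state))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_event_raster
#' @export
read_event_raster <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  seg <- NULL
  if (!is.null(meta$segment_labels) &&
      length(meta$segment_labels$start) > 0) {
    seg <- hypnogram(meta$segment_labels$start, meta$segment_labels$end,
                     meta$segment_labels$state)
  }
  event_raster(meta$n_channels, d$channel, d$time_s, meta$duration,
               rate_r = if (is.null(meta$rate_r)) NA_real_ else meta$rate_r,
               segment_labels = seg,
               channel_group = meta$channel_group)
}
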