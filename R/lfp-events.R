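# From analog multichannel signals to rate-matched binary event rasters.

#' Zero-phase Butterworth low-pass filter
#'
#' Filters a signal with a Butterworth low-pass design applied
#' forward-backward (zero phase), so deflection-lobe times are not shifted.
#' Note that the forward-backward pass squares the magnitude response: a
#' sine at `k` times the cutoff is attenuated by `(1 + k^(2*order))^(-1)`
#' rather than the single-pass `(1 + k^(2*order))^(-1/2)`.
#'
#' @param x Numeric signal vector.
#' @param fs Sampling rate in Hz.
#' @param cutoff Cutoff frequency in Hz (default 40).
#' @param order Filter order (default 4).
#' @return Filtered signal, same length as `x`.
#' @export
lowpass_filter <- function(x, fs, cutoff = 40, order = 4) {
  if (!is.finite(cutoff) || cutoff <= 0 || cutoff >= fs / 2) {
    stop("cutoff must lie in (0, fs/2)")
  }
  bf <- signal::butter(order, cutoff / (fs / 2), type = "low")
  n <- length(x)
  if (n < 2) return(as.numeric(x))
  # odd-reflection padding suppresses the start/end transients of the
  # forward-backward pass
  np <- min(n - 1, 30 * order)
  head_pad <- 2 * x[1] - x[(np + 1):2]
  tail_pad <- 2 * x[n] - x[(n - 1):(n - np)]
  y <- signal::filtfilt(bf, c(head_pad, x, tail_pad))
  as.numeric(y[(np + 1):(np + n)])
}

#' Detect positive deflection lobes
#'
#' After per-segment mean subtraction, a deflection lobe is a maximal run
#' of positive samples between two zero crossings. The lobe area is the
#' time integral of the signal over the lobe (trapezoidal, with the zero
#' crossings located by linear interpolation), which is proportional to the
#' total displaced charge when the signal is an LFP voltage. The lobe time
#' stamp is the time of its peak sample.
#'
#' @param x Numeric signal vector (one channel, one segment).
#' @param fs Sampling rate in Hz.
#' @param t0 Time of the first sample in seconds (default 0).
#' @param center Subtract the segment mean before detecting zero crossings
#'   (default `TRUE`; the zero reference is required for crossing
#'   detection).
#' @return Data frame with columns `start`, `end`, `area`, `peak_time`
#'   (seconds / signal x seconds), one row per lobe, ordered in time. An
#'   all-negative signal yields zero rows.
#' @export
deflection_lobes <- function(x, fs, t0 = 0, center = TRUE) {
  x <- as.numeric(x)
  if (center && length(x) > 0) x <- x - mean(x)
  n <- length(x)
  empty <- data.frame(start = numeric(0), end = numeric(0),
                      area = numeric(0), peak_time = numeric(0))
  if (n == 0) return(empty)
  pos <- x > 0
  if (!any(pos)) return(empty)
  d <- diff(c(FALSE, pos, FALSE))
  i_start <- which(d == 1L)         # first positive sample of each run
  i_end <- which(d == -1L) - 1L     # last positive sample
  dt <- 1 / fs
  tt <- t0 + (seq_len(n) - 1) * dt
  out <- lapply(seq_along(i_start), function(k) {
    i1 <- i_start[k]; i2 <- i_end[k]
    seg <- x[i1:i2]
    # interior trapezoids between consecutive positive samples
    area <- if (i2 > i1) sum((seg[-1] + seg[-length(seg)]) / 2) * dt else 0
    # leading edge: linear zero crossing between i1-1 and i1
    if (i1 > 1) {
      frac <- x[i1] / (x[i1] - x[i1 - 1])   # distance back to the crossing
      start <- tt[i1] - frac * dt
      area <- area + x[i1] * frac * dt / 2
    } else {
      start <- tt[1]
    }
    # trailing edge
    if (i2 < n) {
      frac <- x[i2] / (x[i2] - x[i2 + 1])
      end <- tt[i2] + frac * dt
      area <- area + x[i2] * frac * dt / 2
    } else {
      end <- tt[n]
    }
    ipk <- i1 + which.max(seg) - 1L
    c(start = start, end = end, area = area, peak_time = tt[ipk])
  })
  as.data.frame(do.call(rbind, out))
}

#' Deflection lobes of a whole multichannel recording
#'
#' Applies the low-pass filter and lobe detection per channel and per
#' constant-state segment of the hypnogram (the mean is subtracted per
#' segment, so the zero reference adapts to slow level shifts between
#' states).
#'
#' @param signals Channels x samples numeric matrix, or a
#'   `synthetic_night`.
#' @param fs Sampling rate in Hz (taken from the night if one is given).
#' @param hyp A [hypnogram()]; defaults to the night's hypnogram or one
#'   whole-recording segment.
#' @param cutoff,order Low-pass settings passed to [lowpass_filter()];
#'   `cutoff = NULL` skips filtering.
#' @return Data frame of lobes with columns `channel`, `start`, `end`,
#'   `area`, `peak_time`.
#' @export
night_lobes <- function(signals, fs = NULL, hyp = NULL, cutoff = 40,
                        order = 4) {
  if (inherits(signals, "synthetic_night")) {
    if (is.null(fs)) fs <- signals$fs
    if (is.null(hyp)) hyp <- signals$hypnogram
    signals <- signals$signals
  }
  stopifnot(is.matrix(signals), !is.null(fs))
  if (is.null(hyp)) hyp <- hypnogram(0, ncol(signals) / fs, "WAKE")
  res <- vector("list", nrow(signals) * nrow(hyp))
  k <- 0L
  for (ch in seq_len(nrow(signals))) {
    x <- signals[ch, ]
    if (!is.null(cutoff)) x <- lowpass_filter(x, fs, cutoff, order)
    for (i in seq_len(nrow(hyp))) {
      i0 <- floor(hyp$start[i] * fs) + 1L
      i1 <- min(ceiling(hyp$end[i] * fs), length(x))
      if (i1 <= i0) next
      lb <- deflection_lobes(x[i0:i1], fs, t0 = (i0 - 1L) / fs)
      if (nrow(lb) == 0) next
      k <- k + 1L
      lb$channel <- ch
      res[[k]] <- lb
    }
  }
  if (k == 0L) {
    return(data.frame(channel = integer(0), start = numeric(0),
                      end = numeric(0), area = numeric(0),
                      peak_time = numeric(0)))
  }
  out <- do.call(rbind, res[seq_len(k)])
  out[, c("channel", "start", "end", "area", "peak_time")]
}

# round-half-up, deterministic across platforms (unlike round()'s
# round-half-even)
round_half_up <- function(x) floor(x + 0.5)

#' Rate-matched binary events from deflection lobes
#'
#' Converts lobes to binary events by an area threshold chosen separately
#' for every channel and every constant-state segment, such that each
#' channel contributes exactly `k = round(rate * segment duration)` events
#' per segment (the `k` largest-area lobes; ties broken by earlier peak
#' time). Fixing the rate instead of the threshold gives every site in
#' every state the same chance to contribute to avalanches and makes the
#' events invariant to any positive rescaling of a channel's signal.
#'
#' @param lobes Data frame as returned by [night_lobes()] (columns
#'   `channel`, `area`, `peak_time`). Lobes outside all hypnogram
#'   intervals are dropped.
#' @param hyp A [hypnogram()] of constant-state segments.
#' @param rate Target per-channel event rate in Hz.
#' @param n_channels Total number of channels (defaults to
#'   `max(lobes$channel)`).
#' @param channel_group Optional per-channel group labels.
#' @return An [event_raster()] whose event times are lobe peak times. If a
#'   channel has fewer than `k` lobes in a segment, all its lobes are used
#'   and a warning reports the shortfall.
#' @export
rate_matched_events <- function(lobes, hyp, rate, n_channels = NULL,
                                channel_group = NULL) {
  stopifnot(inherits(hyp, "hypnogram"))
  if (!is.finite(rate) || rate <= 0) stop("rate must be > 0")
  if (is.null(n_channels)) {
    n_channels <- if (nrow(lobes) > 0) max(lobes$channel) else 1L
  }
  dur <- if (nrow(hyp) > 0) max(hyp$end) else 0
  if (nrow(hyp) == 0 || nrow(lobes) == 0) {
    return(event_raster(n_channels, integer(0), numeric(0), dur,
                        rate_r = rate, segment_labels = hyp,
                        channel_group = channel_group))
  }
  chan <- integer(0); tm <- numeric(0)
  shortfall <- 0L
  for (i in seq_len(nrow(hyp))) {
    k <- round_half_up(rate * (hyp$end[i] - hyp$start[i]))
    if (k < 1) next
    inseg <- lobes$peak_time >= hyp$start[i] & lobes$peak_time < hyp$end[i]
    for (ch in seq_len(n_channels)) {
      lb <- lobes[inseg & lobes$channel == ch, ]
      if (nrow(lb) == 0) { shortfall <- shortfall + k; next }
      o <- order(-lb$area, lb$peak_time)
      take <- head(o, k)
      if (length(take) < k) shortfall <- shortfall + (k - length(take))
      chan <- c(chan, rep(ch, length(take)))
      tm <- c(tm, lb$peak_time[take])
    }
  }
  if (shortfall > 0L) {
    warning(sprintf("rate matching short by %d event(s): not enough lobes",
                    shortfall))
  }
  event_raster(n_channels, chan, tm, max(dur, if (length(tm)) max(tm) * (1 + 1e-12) else 0),
               rate_r = rate, segment_labels = hyp,
               channel_group = channel_group)
}
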