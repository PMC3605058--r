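# Synthetic event rasters and whole-night recordings with known ground truth.

#' Independent Poisson event raster
#'
#' Generates `n_units` mutually independent homogeneous Poisson processes,
#' each with per-unit event rate `rate`. This is the uncorrelated reference
#' process: its avalanche size distribution at bin size one mean
#' inter-event interval is close to exponential, with no excess of large
#' avalanches.
#'
#' @param n_units Number of units (channels), >= 1.
#' @param rate Per-unit event rate in Hz, > 0.
#' @param duration Recording duration in seconds, >= 0.
#' @param seed Optional integer seed; all randomness of the call flows from
#'   it.
#' @return An [event_raster()].
#' @examples
#' r <- gen_independent_poisson(44, 0.25, 1000, seed = 1)
#' @export
gen_independent_poisson <- function(n_units, rate, duration, seed = NULL) {
  check_gen_args(n_units, rate, duration)
  if (!is.null(seed)) set.seed(seed)
  if (duration == 0) {
    return(event_raster(n_units, integer(0), numeric(0), 0, rate_r = rate))
  }
  counts <- rpois(n_units, rate * duration)
  channel <- rep(seq_len(n_units), counts)
  time <- runif(sum(counts), 0, duration)
  event_raster(n_units, channel, time, duration, rate_r = rate)
}

#' Clustered event raster (two stimulus-driven subsets)
#'
#' Two subsets of units (sizes `n1` and `n2`) each share a common Poisson
#' stimulus train at rate `rate`; every unit of a subset fires once per
#' stimulus, with Gaussian timing jitter of standard deviation `jitter_sd`.
#' Units are therefore strongly correlated within a subset and independent
#' across subsets, producing an avalanche size distribution with
#' characteristic bumps at the subset sizes.
#'
#' @param n1,n2 Subset sizes, both >= 1.
#' @param rate Stimulus rate in Hz (equals the per-unit event rate).
#' @param duration Recording duration in seconds.
#' @param jitter_sd Standard deviation of the per-unit Gaussian timing
#'   jitter in seconds (default 25 ms).
#' @param seed Optional integer seed.
#' @return An [event_raster()]; units `1..n1` form the first subset.
#' @export
gen_clustered <- function(n1, n2, rate, duration, jitter_sd = 0.025,
                          seed = NULL) {
  if (n1 < 1 || n2 < 1) stop("subset sizes n1 and n2 must be >= 1")
  check_gen_args(n1 + n2, rate, duration)
  if (jitter_sd < 0) stop("jitter_sd must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  n_units <- n1 + n2
  if (duration == 0) {
    return(event_raster(n_units, integer(0), numeric(0), 0, rate_r = rate))
  }
  chan <- integer(0); tm <- numeric(0)
  offs <- c(0L, n1)
  sizes <- c(n1, n2)
  for (k in 1:2) {
    stim <- runif(rpois(1, rate * duration), 0, duration)
    for (u in seq_len(sizes[k])) {
      t_u <- stim + rnorm(length(stim), 0, jitter_sd)
      t_u <- t_u[t_u >= 0 & t_u < duration]
      chan <- c(chan, rep(offs[k] + u, length(t_u)))
      tm <- c(tm, t_u)
    }
  }
  event_raster(n_units, chan, tm, duration, rate_r = rate)
}

#' Correlated event raster (chained event sharing)
#'
#' Unit 1 is a homogeneous Poisson process at `rate`. Each subsequent unit
#' keeps every event of the previous unit with probability `share` and adds
#' fresh Poisson events at rate `(1 - share) * rate`, so the expected
#' per-unit rate stays exactly `rate` while neighbouring units share a
#' fraction `share` of their event times. With `share` close to 1 all units
#' are nearly identical and large avalanches dominate; with `share = 0` the
#' units are mutually independent.
#'
#' @inheritParams gen_independent_poisson
#' @param share Fraction of event times carried over from the previous unit,
#'   in \[0, 1\] (default 0.99).
#' @return An [event_raster()].
#' @export
gen_correlated <- function(n_units, rate, duration, share = 0.99,
                           seed = NULL) {
  check_gen_args(n_units, rate, duration)
  if (share < 0 || share > 1) stop("share must lie in [0, 1]")
  if (!is.null(seed)) set.seed(seed)
  if (duration == 0) {
    return(event_raster(n_units, integer(0), numeric(0), 0, rate_r = rate))
  }
  chan <- vector("list", n_units); tms <- vector("list", n_units)
  prev <- runif(rpois(1, rate * duration), 0, duration)
  tms[[1]] <- prev; chan[[1]] <- rep(1L, length(prev))
  if (n_units > 1) {
    for (u in 2:n_units) {
      keep <- prev[runif(length(prev)) < share]
      fresh <- runif(rpois(1, (1 - share) * rate * duration), 0, duration)
      prev <- c(keep, fresh)
      tms[[u]] <- prev; chan[[u]] <- rep(u, length(prev))
    }
  }
  event_raster(n_units, unlist(chan), unlist(tms), duration, rate_r = rate)
}

check_gen_args <- function(n_units, rate, duration) {
  if (n_units < 1) stop("n_units must be >= 1")
  if (!is.finite(rate) || rate <= 0) stop("rate must be > 0")
  if (!is.finite(duration) || duration < 0) stop("duration must be >= 0")
  invisible(TRUE)
}

#' Pink (1/f) noise with a low-frequency knee
#'
#' FFT-filtered Gaussian noise whose power spectrum falls off as 1/f above
#' a knee frequency and is flat below it, standardized to unit variance.
#' The knee bounds the power of very slow drifts, which would otherwise
#' produce arbitrarily long, large-area deflection lobes unrelated to the
#' inserted events. Used as the background of parametric synthetic nights.
#'
#' @param n Number of samples.
#' @param fs Sampling rate in Hz.
#' @param f_knee Knee frequency in Hz (default 1).
#' @return Numeric vector of length `n`.
#' @keywords internal
pink_noise <- function(n, fs = 1, f_knee = 0) {
  if (n < 2) return(rnorm(n))
  x <- rnorm(n)
  xf <- fft(x)
  f <- c(1, seq_len(n - 1))
  f <- pmin(f, n - f + 1) * fs / n   # two-sided frequency in Hz
  xf <- xf / sqrt(pmax(f, f_knee))
  y <- Re(fft(xf, inverse = TRUE)) / n
  (y - mean(y)) / sd(y)
}

#' Generate a synthetic night
#'
#' Produces a full multichannel "night": analog signals plus a hypnogram,
#' with per-state ground truth recorded. Two generating modes:
#'
#' * `"parametric"`: per-channel pink-noise background plus transient
#'   half-sine deflection lobes inserted at event times whose cross-channel
#'   correlation is controlled per state (parameter `correlation`, the
#'   probability that a channel fires on a shared master event). Only the
#'   lobe areas and their cross-channel timing matter downstream, so the
#'   background makes no attempt at realistic spectral content.
#' * `"socm"`: each state's segment is the virtual-LFP output of the
#'   sandpile model run at that state's propagation efficacy `dE`
#'   (see [virtual_lfp()]); one model sweep maps to one sample at `fs`.
#'
#' @param state_schedule A [hypnogram()]; segments of >= 150 s are
#'   recommended so that downstream rate matching has enough lobes.
#' @param per_state_params Named list, one entry per state occurring in the
#'   schedule. For `"parametric"`: `correlation` (0-1), optional
#'   `event_rate` (Hz, default 1), `lobe_amp` (default 8), `lobe_dur` (s,
#'   default 0.1), `jitter_sd` (s, default 0.025). For `"socm"`: `dE`.
#' @param n_channels Number of channels (default 44; `"socm"` mode forces
#'   the electrode count of the virtual array, 64).
#' @param fs Sampling rate in Hz (default 400).
#' @param mode `"parametric"` or `"socm"`.
#' @param seed Optional integer seed.
#' @param socm_args Named list of overrides passed to [virtual_lfp()] in
#'   `"socm"` mode; defaults use a 25-side lattice with a 4x4x4 electrode
#'   array at spacing 5 to keep whole-night simulation tractable.
#' @return A `synthetic_night` object: list with `signals`
#'   (channels x samples matrix), `fs`, `hypnogram`, `ground_truth`,
#'   `mode`.
#' @export
gen_synthetic_night <- function(state_schedule, per_state_params,
                                n_channels = 44, fs = 400,
                                mode = c("parametric", "socm"), seed = NULL,
                                socm_args = list()) {
  mode <- match.arg(mode)
  stopifnot(inherits(state_schedule, "hypnogram"))
  if (!is.finite(fs) || fs <= 0) stop("fs must be > 0")
  states <- unique(state_schedule$state)
  missing_par <- setdiff(states, names(per_state_params))
  if (length(missing_par) > 0) {
    stop("no parameters for scheduled state(s): ",
         paste(missing_par, collapse = ", "))
  }
  if (!is.null(seed)) set.seed(seed)
  if (mode == "socm") n_channels <- 64L
  total <- max(state_schedule$end)
  n_samples <- ceiling(total * fs)
  sig <- matrix(0, nrow = n_channels, ncol = n_samples)

  for (i in seq_len(nrow(state_schedule))) {
    st <- state_schedule$state[i]
    i0 <- floor(state_schedule$start[i] * fs) + 1L
    i1 <- min(ceiling(state_schedule$end[i] * fs), n_samples)
    nseg <- i1 - i0 + 1L
    p <- per_state_params[[st]]
    if (mode == "parametric") {
      sig[, i0:i1] <- parametric_segment(n_channels, nseg, fs, p)
    } else {
      args <- c(list(dE = p$dE, n_ticks = nseg), socm_args)
      if (is.null(args$L)) args$L <- 25L
      if (is.null(args$spacing)) args$spacing <- 5L
      v <- do.call(virtual_lfp, args)
      sig[, i0:i1] <- v$signals[, seq_len(nseg), drop = FALSE]
    }
  }
  night <- list(signals = sig, fs = fs, hypnogram = state_schedule,
                ground_truth = per_state_params[states], mode = mode)
  class(night) <- "synthetic_night"
  night
}

# One constant-state parametric segment: pink noise + correlated half-sine
# deflection lobes. `correlation` is the probability that a channel takes
# part in a shared (master) event; each channel additionally gets
# independent events so its total event rate is `event_rate` exactly in
# expectation.
parametric_segment <- function(n_channels, nseg, fs, p) {
  corr <- p$correlation
  if (is.null(corr) || corr < 0 || corr > 1) {
    stop("parametric mode needs a correlation parameter in [0, 1]")
  }
  ev_rate <- if (is.null(p$event_rate)) 1 else p$event_rate
  amp <- if (is.null(p$lobe_amp)) 8 else p$lobe_amp
  lobe_dur <- if (is.null(p$lobe_dur)) 0.1 else p$lobe_dur
  jit <- if (is.null(p$jitter_sd)) 0.025 else p$jitter_sd
  dur_s <- nseg / fs
  x <- matrix(0, n_channels, nseg)
  for (ch in seq_len(n_channels)) {
    x[ch, ] <- pink_noise(nseg, fs = fs, f_knee = 1)
  }
  # master events shared across channels; each carries a shared amplitude
  # factor (a global wave of enhanced activity), so that the downstream
  # rank-based rate matching selects the same shared events on every
  # participating channel
  master <- runif(rpois(1, ev_rate * dur_s), 0, dur_s)
  master_amp <- rlnorm(length(master), 0, 0.6)
  lobe_n <- max(3L, round(lobe_dur * fs))
  lobe <- sin(pi * seq(0, 1, length.out = lobe_n))
  for (ch in seq_len(n_channels)) {
    sel <- runif(length(master)) < corr
    take <- master[sel]
    own <- runif(rpois(1, (1 - corr) * ev_rate * dur_s), 0, dur_s)
    tt <- c(take + rnorm(length(take), 0, jit), own)
    aa <- amp * c(master_amp[sel], rlnorm(length(own), 0, 0.6)) *
      rlnorm(length(tt), 0, 0.2)
    keep <- tt >= 0 & tt < dur_s
    tt <- tt[keep]; aa <- aa[keep]
    for (k in seq_along(tt)) {
      j0 <- floor(tt[k] * fs) + 1L
      j1 <- min(j0 + lobe_n - 1L, nseg)
      x[ch, j0:j1] <- x[ch, j0:j1] + aa[k] * lobe[seq_len(j1 - j0 + 1L)]
    }
  }
  x
}

#' @export
print.synthetic_night <- function(x, ...) {
  cat(sprintf("synthetic_night (%s): %d channels x %d samples @ %g Hz, %d segment(s)\n",
              x$mode, nrow(x$signals), ncol(x$signals), x$fs,
              nrow(x$hypnogram)))
  invisible(x)
}

#' Write / read synthetic-night signals as CSV
#'
#' Signals are stored as a plain CSV matrix (samples in rows, one column
#' per channel) with the sampling rate and hypnogram in a JSON sidecar.
#'
#' @param night A `synthetic_night`.
#' @param path CSV path.
#' @return `read_synthetic_night` returns a `synthetic_night` (without
#'   ground truth, which is not serialized); `write_synthetic_night`
#'   returns `path` invisibly.
#' @export
write_synthetic_night <- function(night, path) {
  stopifnot(inherits(night, "synthetic_night"))
  m <- t(night$signals)
  colnames(m) <- paste0("ch", seq_len(ncol(m)))
  write.csv(m, path, row.names = FALSE, quote = FALSE)
  meta <- list(fs = night$fs,
               hypnogram = list(start = night$hypnogram$start,
                                end = night$hypnogram$end,
                                state = night$hypnogram$state))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_synthetic_night
#' @export
read_synthetic_night <- function(path) {
  m <- as.matrix(read.csv(path))
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  night <- list(signals = t(m), fs = meta$fs,
                hypnogram = hypnogram(meta$hypnogram$start,
                                      meta$hypnogram$end,
                                      meta$hypnogram$state),
                ground_truth = NULL, mode = "unknown")
  class(night) <- "synthetic_night"
  night
}
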