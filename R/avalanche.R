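# Binning, avalanche extraction, and avalanche measures.

#' Mean inter-event interval
#'
#' The natural time unit for avalanche binning: with per-channel event rate
#' `rate_r` and `n_channels` recording sites all producing events at that
#' rate, events arrive at `rate_r * n_channels` per second on the merged
#' time axis, so the mean inter-event interval is
#' `1 / (rate_r * n_channels)` seconds. Bin sizes are expressed as
#' multiples of this quantity.
#'
#' @param rate_r Per-channel event rate in Hz, > 0.
#' @param n_channels Number of recording sites, >= 1.
#' @return Mean inter-event interval in seconds.
#' @examples
#' mean_iei(1, 50)    # 0.020 s
#' mean_iei(0.1, 50)  # 0.200 s
#' @export
mean_iei <- function(rate_r, n_channels) {
  if (!is.finite(rate_r) || rate_r <= 0) stop("rate_r must be > 0")
  if (!is.finite(n_channels) || n_channels < 1) {
    stop("n_channels must be >= 1")
  }
  1 / (rate_r * n_channels)
}

#' Bin an event raster
#'
#' Tiles every constant-state segment of the raster with contiguous
#' half-open bins `[t, t + w)` of width `w = bs_factor * <IEI>`, anchored
#' at the segment start (plus `offset`). Every event falls in exactly one
#' bin; events in the trailing partial bin of a segment are dropped from
#' the tiling (the bins must tile the segment exactly).
#'
#' @param raster An [event_raster()] with a known `rate_r`.
#' @param bs_factor Bin size as a multiple of the mean inter-event
#'   interval.
#' @param offset Bin anchoring offset in seconds (default 0); used e.g. to
#'   align bins to random starting points.
#' @param resolution Minimum admissible bin width in seconds (e.g. the
#'   sampling interval, 2.5 ms at 400 Hz). A bin width below it is
#'   rejected, since sub-resolution bins are not meaningful. Default 0
#'   (no check).
#' @param min_segment Minimum segment duration in seconds; shorter
#'   segments are skipped (default 0; the vigilance-state analysis uses
#'   150 s).
#' @return A `binned_raster`: list with `counts` (list of per-segment
#'   integer vectors), `segments` (data frame `start`, `end`, `state`),
#'   `bin_width`, `bs_factor`, `mean_iei`, `rate_r`, `n_channels`, and
#'   `event_bins` (per-event segment/bin assignment, `NA` for dropped
#'   events).
#' @export
bin_events <- function(raster, bs_factor, offset = 0, resolution = 0,
                       min_segment = 0) {
  stopifnot(inherits(raster, "event_raster"))
  if (is.na(raster$rate_r)) stop("raster has no nominal rate_r")
  miei <- mean_iei(raster$rate_r, raster$n_channels)
  w <- bs_factor * miei
  if (w <= 0) stop("bin width must be > 0")
  if (resolution > 0 && w < resolution) {
    stop(sprintf("bin width %.4g s is below the time resolution %.4g s",
                 w, resolution))
  }
  segs <- raster$segment_labels
  keep <- (segs$end - segs$start) >= min_segment
  segs <- segs[keep, , drop = FALSE]
  counts <- vector("list", nrow(segs))
  ev_seg <- rep(NA_integer_, nrow(raster$events))
  ev_bin <- rep(NA_integer_, nrow(raster$events))
  tm <- raster$events$time
  for (i in seq_len(nrow(segs))) {
    a <- segs$start[i] + offset
    n_bins <- floor((segs$end[i] - a) / w)
    if (n_bins < 1) { counts[[i]] <- integer(0); next }
    sel <- which(tm >= a & tm < a + n_bins * w)
    b <- pmin(floor((tm[sel] - a) / w) + 1L, n_bins)
    counts[[i]] <- tabulate(b, nbins = n_bins)
    ev_seg[sel] <- i
    ev_bin[sel] <- b
  }
  out <- list(counts = counts,
              segments = as.data.frame(segs),
              bin_width = w, bs_factor = bs_factor, mean_iei = miei,
              rate_r = raster$rate_r, n_channels = raster$n_channels,
              event_bins = data.frame(segment = ev_seg, bin = ev_bin))
  class(out) <- "binned_raster"
  out
}

#' Extract avalanches from binned counts
#'
#' An avalanche is a maximal run of consecutive non-empty bins; subsequent
#' avalanches are separated by empty bins. Its size `s` is the total number
#' of events in the run and its duration `d` the number of bins. Runs
#' still open at a segment end are discarded (their true extent is
#' unknown), so avalanches never span segment boundaries.
#'
#' @param binned A `binned_raster` from [bin_events()], or a plain
#'   non-negative integer vector / list of vectors of bin counts.
#' @param state,night Optional labels stored on the result.
#' @return An `avalanche_set`: list with `avalanches` (data frame
#'   `segment`, `start_bin`, `duration`, `size`), `profiles` (list of
#'   per-bin event counts, one vector per avalanche), and the binning
#'   context (`bs_factor`, `rate_r`, `mean_iei`, `n_channels`).
#' @export
extract_avalanches <- function(binned, state = NA_character_,
                               night = NA_character_) {
  ctx <- list(bs_factor = NA_real_, rate_r = NA_real_, mean_iei = NA_real_,
              n_channels = NA_integer_)
  if (inherits(binned, "binned_raster")) {
    ctx <- binned[c("bs_factor", "rate_r", "mean_iei", "n_channels")]
    counts <- binned$counts
  } else if (is.list(binned)) {
    counts <- binned
  } else {
    counts <- list(binned)
  }
  seg_id <- integer(0); start_bin <- integer(0)
  durs <- integer(0); sizes <- numeric(0)
  profiles <- list()
  for (i in seq_along(counts)) {
    cc <- counts[[i]]
    if (length(cc) == 0) next
    if (any(cc < 0)) stop("bin counts must be non-negative")
    nz <- cc > 0
    d <- diff(c(FALSE, nz, FALSE))
    st <- which(d == 1L); en <- which(d == -1L) - 1L
    # discard a run still open at the segment end
    open_end <- length(st) > 0 && en[length(en)] == length(cc) && nz[length(cc)]
    if (open_end) { st <- st[-length(st)]; en <- en[-length(en)] }
    for (k in seq_along(st)) {
      prof <- cc[st[k]:en[k]]
      seg_id <- c(seg_id, i); start_bin <- c(start_bin, st[k])
      durs <- c(durs, length(prof)); sizes <- c(sizes, sum(prof))
      profiles[[length(profiles) + 1L]] <- prof
    }
  }
  out <- list(avalanches = data.frame(segment = seg_id,
                                      start_bin = start_bin,
                                      duration = durs, size = sizes),
              profiles = profiles,
              bs_factor = ctx$bs_factor, rate_r = ctx$rate_r,
              mean_iei = ctx$mean_iei, n_channels = ctx$n_channels,
              state = state, night = night)
  class(out) <- "avalanche_set"
  out
}

#' @export
print.avalanche_set <- function(x, ...) {
  cat(sprintf("avalanche_set: %d avalanches", nrow(x$avalanches)))
  if (!is.na(x$bs_factor)) cat(sprintf(" (bs = %g <IEI>)", x$bs_factor))
  if (nrow(x$avalanches) > 0) {
    cat(sprintf(", mean size %.3g, mean duration %.3g bins",
                mean(x$avalanches$size), mean(x$avalanches$duration)))
  }
  cat("\n")
  invisible(x)
}

#' Bin a raster and extract its avalanches in one call
#'
#' @inheritParams bin_events
#' @inheritParams extract_avalanches
#' @param ... Passed to [bin_events()].
#' @return An `avalanche_set`.
#' @export
avalanches <- function(raster, bs_factor, state = NA_character_,
                       night = NA_character_, ...) {
  extract_avalanches(bin_events(raster, bs_factor, ...),
                     state = state, night = night)
}

#' Branching parameter from binned counts
#'
#' For every time bin with a non-zero count `n(t)` that is followed by
#' another bin of the same segment, the single-transition branching ratio
#' is `n(t+1) / n(t)`; the branching parameter `sigma` is the average over
#' all such transitions. `sigma = 1` marks a critical branching process;
#' `sigma < 1` a diminishing one. By the literal definition, transitions
#' into an empty bin (avalanche ends) are included; set
#' `within_avalanche = TRUE` to restrict to transitions whose successor
#' bin is also non-empty.
#'
#' @param binned A `binned_raster`, vector, or list of count vectors.
#' @param within_avalanche Restrict to within-avalanche transitions
#'   (default `FALSE`).
#' @return The branching parameter, or `NA` if no valid transition exists.
#' @examples
#' branching_sigma(c(2, 4, 0, 3, 3))  # mean of 2, 0, 1 -> 1
#' @export
branching_sigma <- function(binned, within_avalanche = FALSE) {
  counts <- if (inherits(binned, "binned_raster")) binned$counts
            else if (is.list(binned)) binned else list(binned)
  num <- 0; nn <- 0L
  for (cc in counts) {
    if (length(cc) < 2) next
    pre <- cc[-length(cc)]; post <- cc[-1]
    ok <- pre > 0
    if (within_avalanche) ok <- ok & post > 0
    num <- num + sum(post[ok] / pre[ok])
    nn <- nn + sum(ok)
  }
  if (nn == 0L) return(NA_real_)
  num / nn
}

#' Avalanche size / duration frequency distributions
#'
#' @param avs An `avalanche_set`.
#' @param log_bin Apply logarithmic binning (for display smoothing only);
#'   default `FALSE` returns raw per-integer frequencies.
#' @param bins_per_decade Number of logarithmic bins per decade when
#'   `log_bin = TRUE`.
#' @return Data frame with columns `s` (or `d`), `count` and `p`
#'   (probability). `sum(count)` equals the number of avalanches and, for
#'   sizes, `sum(s * count)` equals the total number of events in
#'   avalanches.
#' @export
size_distribution <- function(avs, log_bin = FALSE, bins_per_decade = 10) {
  stopifnot(inherits(avs, "avalanche_set"))
  freq_table(avs$avalanches$size, "s", log_bin, bins_per_decade)
}

#' @rdname size_distribution
#' @export
duration_distribution <- function(avs, log_bin = FALSE,
                                  bins_per_decade = 10) {
  stopifnot(inherits(avs, "avalanche_set"))
  freq_table(avs$avalanches$duration, "d", log_bin, bins_per_decade)
}

freq_table <- function(x, name, log_bin, bins_per_decade) {
  if (length(x) == 0) {
    out <- data.frame(v = numeric(0), count = integer(0), p = numeric(0))
    names(out)[1] <- name
    return(out)
  }
  if (!log_bin) {
    tb <- table(x)
    out <- data.frame(v = as.numeric(names(tb)),
                      count = as.integer(tb))
  } else {
    edges <- 10^seq(0, ceiling(log10(max(x))) + 1e-9,
                    by = 1 / bins_per_decade)
    edges <- unique(c(edges[edges <= max(x)], max(x) + 1))
    idx <- findInterval(x, edges, rightmost.closed = FALSE)
    tb <- table(idx)
    centers <- sqrt(edges[-length(edges)] * edges[-1])
    out <- data.frame(v = centers[as.integer(names(tb))],
                      count = as.integer(tb))
  }
  out$p <- out$count / sum(out$count)
  names(out)[1] <- name
  out
}

#' Inter-event and inter-avalanche interval distributions
#'
#' Inter-event intervals (IEI) are the successive differences of all event
#' times merged across channels (within each constant-state segment).
#' Every IEI larger than the bin width `bs_factor * <IEI>` necessarily
#' separates two avalanches and therefore contributes to the
#' inter-avalanche-interval (IAI) sample.
#'
#' @param raster An [event_raster()].
#' @param bs_factor Bin size in units of the mean inter-event interval.
#' @return List with numeric vectors `iei` and `iai` and the `bin_width`
#'   used for the IAI threshold. Fewer than two events yield empty
#'   vectors.
#' @export
iei_iai_distributions <- function(raster, bs_factor) {
  stopifnot(inherits(raster, "event_raster"))
  w <- bs_factor * mean_iei(raster$rate_r, raster$n_channels)
  segs <- raster$segment_labels
  tm <- raster$events$time
  ieis <- numeric(0)
  for (i in seq_len(nrow(segs))) {
    ts <- sort(tm[tm >= segs$start[i] & tm < segs$end[i]])
    if (length(ts) >= 2) ieis <- c(ieis, diff(ts))
  }
  list(iei = ieis, iai = ieis[ieis > w], bin_width = w)
}

#' Avalanche measures for one raster over a parameter grid
#'
#' Computes, for each bin-size factor, the mean avalanche size, mean
#' duration, branching parameter and avalanche count of a raster. Grid
#' cells whose bin width falls below `resolution` are skipped (reported
#' as `NA` rows), mirroring the practical lower limit set by the sampling
#' interval.
#'
#' @param raster An [event_raster()].
#' @param bs_factors Numeric vector of bin sizes in units of the mean
#'   inter-event interval. The canonical grid is
#'   `c(1/32, 1/16, 1/8, 1/4, 1/2, 1, 2, 4)`.
#' @param night,state Labels attached to the output rows (state defaults
#'   to per-segment states when the raster has a hypnogram with several
#'   states; in that case measures are computed per state by restricting
#'   to that state's segments).
#' @param resolution Minimum admissible bin width in seconds.
#' @param min_segment Minimum segment duration in seconds.
#' @return Data frame with one row per (state x bs_factor):
#'   columns `night`, `state`, `bs_factor`, `rate_r`, `mean_size`,
#'   `mean_duration`, `sigma`, `n_avalanches`.
#' @export
avalanche_measures <- function(raster, bs_factors = bs_grid(),
                               night = NA_character_, state = NULL,
                               resolution = 0, min_segment = 0) {
  stopifnot(inherits(raster, "event_raster"))
  states <- if (is.null(state)) unique(raster$segment_labels$state) else state
  rows <- list()
  for (st in states) {
    segs <- raster$segment_labels[raster$segment_labels$state == st, ,
                                  drop = FALSE]
    sub <- raster
    sub$segment_labels <- segs
    for (bs in bs_factors) {
      w <- bs * mean_iei(raster$rate_r, raster$n_channels)
      if (resolution > 0 && w < resolution) {
        rows[[length(rows) + 1L]] <- data.frame(
          night = night, state = st, bs_factor = bs,
          rate_r = raster$rate_r, mean_size = NA_real_,
          mean_duration = NA_real_, sigma = NA_real_,
          n_avalanches = NA_integer_)
        next
      }
      bn <- bin_events(sub, bs, min_segment = min_segment)
      avs <- extract_avalanches(bn, state = st, night = night)
      a <- avs$avalanches
      rows[[length(rows) + 1L]] <- data.frame(
        night = night, state = st, bs_factor = bs,
        rate_r = raster$rate_r,
        mean_size = if (nrow(a)) mean(a$size) else NA_real_,
        mean_duration = if (nrow(a)) mean(a$duration) else NA_real_,
        sigma = branching_sigma(bn),
        n_avalanches = nrow(a))
    }
  }
  do.call(rbind, rows)
}

#' Canonical bin-size grid
#' @return `c(1/32, 1/16, 1/8, 1/4, 1/2, 1, 2, 4)`.
#' @export
bs_grid <- function() c(1 / 32, 1 / 16, 1 / 8, 1 / 4, 1 / 2, 1, 2, 4)

#' Canonical event-rate grid (Hz)
#' @return `c(0.1, 0.25, 0.5, 1)`.
#' @export
rate_grid <- function() c(0.1, 0.25, 0.5, 1)

#' Normalize avalanche measures across vigilance states
#'
#' For every (night, bs_factor, rate_r) group, divides each state's mean
#' size by the normalization factor Xi, the unweighted mean of the
#' per-state mean sizes of that night. The normalized mean size of state
#' `v` is `mean_size(v) / Xi`, so the mean over states of the normalized
#' measure is exactly 1; the normalization removes between-night
#' differences in channel count and overall level. Mean duration and the
#' branching parameter are normalized analogously.
#'
#' @param tbl A measure table from [avalanche_measures()] (rows for >= 1
#'   nights and states).
#' @return The table with added columns `size_rel`, `dur_rel`,
#'   `sigma_rel`. Groups with a single state get all relative measures
#'   exactly 1.
#' @export
normalized_measures <- function(tbl) {
  need <- c("night", "state", "bs_factor", "rate_r", "mean_size",
            "mean_duration", "sigma")
  stopifnot(all(need %in% names(tbl)))
  key <- interaction(tbl$night, tbl$bs_factor, tbl$rate_r, drop = TRUE)
  rel <- function(x, k) {
    g <- ave(x, k, FUN = function(v) mean(v))
    out <- x / g
    out[is.na(x)] <- NA_real_
    out
  }
  tbl$size_rel <- rel(tbl$mean_size, key)
  tbl$dur_rel <- rel(tbl$mean_duration, key)
  tbl$sigma_rel <- rel(tbl$sigma, key)
  tbl
}

#' Write / read distribution tables and measure tables
#'
#' Frequency distributions go to TSV (`s<TAB>count`); measure tables to
#' CSV with their column names.
#'
#' @param dist A data frame from [size_distribution()].
#' @param tbl A measure table.
#' @param path File path.
#' @return The path, invisibly (writers); a data frame (readers).
#' @export
write_distribution <- function(dist, path) {
  write.table(dist[, 1:2], path, sep = "\t", row.names = FALSE,
              quote = FALSE)
  invisible(path)
}

#' @rdname write_distribution
#' @export
read_distribution <- function(path) {
  d <- read.delim(path)
  d$p <- d$count / sum(d$count)
  d
}

#' @rdname write_distribution
#' @export
write_measure_table <- function(tbl, path) {
  write.csv(tbl, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_distribution
#' @export
read_measure_table <- function(path) read.csv(path, stringsAsFactors = FALSE)
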