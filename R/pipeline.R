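# End-to-end convenience: from an analog night to a measure table.

#' Avalanche measure table for a whole night
#'
#' Runs the full analysis chain on a multichannel night: low-pass filter,
#' deflection-lobe detection, rate-matched event extraction per
#' constant-state segment, then avalanche measures over the
#' (bin size, rate) grid.
#'
#' @param night A `synthetic_night`, or a channels x samples matrix (then
#'   `fs` and `hyp` are required).
#' @param rates Per-channel event rates in Hz (default the canonical grid
#'   `c(0.1, 0.25, 0.5, 1)`).
#' @param bs_factors Bin sizes in mean inter-event intervals (default the
#'   canonical grid `1/32 .. 4`).
#' @param night_label Label for the `night` column.
#' @param fs,hyp Sampling rate and [hypnogram()] when `night` is a plain
#'   matrix.
#' @param min_segment Minimum usable segment duration in seconds (default
#'   150).
#' @param cutoff,order Low-pass settings (default 40 Hz, order 4).
#' @return Measure table: one row per (state, bs_factor, rate), see
#'   [avalanche_measures()]. Cells whose bin width falls below the
#'   sampling interval are `NA`.
#' @export
night_measures <- function(night, rates = rate_grid(),
                           bs_factors = bs_grid(),
                           night_label = "night1", fs = NULL, hyp = NULL,
                           min_segment = 150, cutoff = 40, order = 4) {
  if (inherits(night, "synthetic_night")) {
    fs <- night$fs
    hyp <- night$hypnogram
  } else if (is.null(fs) || is.null(hyp)) {
    stop("fs and hyp are required for a plain signal matrix")
  }
  keep <- (hyp$end - hyp$start) >= min_segment
  hyp_use <- hyp[keep, , drop = FALSE]
  class(hyp_use) <- class(hyp)
  if (nrow(hyp_use) == 0) stop("no segment reaches min_segment")
  lobes <- night_lobes(night, fs = fs, hyp = hyp_use, cutoff = cutoff,
                       order = order)
  rows <- list()
  for (r in rates) {
    raster <- suppressWarnings(
      rate_matched_events(lobes, hyp_use, r,
                          n_channels = if (inherits(night, "synthetic_night"))
                            nrow(night$signals) else nrow(night)))
    rows[[length(rows) + 1L]] <-
      avalanche_measures(raster, bs_factors, night = night_label,
                         resolution = 1 / fs)
  }
  do.call(rbind, rows)
}
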