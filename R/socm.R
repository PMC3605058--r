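# R-level interface to the Bak-Tang-Wiesenfeld sandpile: lattice state,
# drive/relax primitives, batch runs with subsampling, and virtual-LFP
# electrode sampling.

#' Create a sandpile lattice state
#'
#' A cubic lattice of side `L` whose sites carry non-negative energies.
#' A site topples when its energy reaches the threshold 6 (the cubic
#' coordination number): it loses 6 and sends `dE` to each of its six
#' nearest neighbours; energy crossing the open boundary is lost. `dE` is
#' the propagation efficacy, the model's stand-in for effective synaptic
#' strength: `dE = 1` is critical, `dE < 1` subcritical, `dE > 1`
#' supercritical.
#'
#' @param L Lattice side length (default 25, i.e. 15625 sites).
#' @param dE Propagation efficacy (default 1).
#' @param energies Optional numeric vector of length `L^3` (default all
#'   zero). Order: x fastest, then y, then z.
#' @param seed Optional seed for subsequent driving.
#' @return A `soc_state` object.
#' @export
soc_lattice <- function(L = 25, dE = 1, energies = NULL, seed = NULL) {
  L <- as.integer(L)
  if (L < 2) stop("L must be >= 2")
  if (is.null(energies)) energies <- numeric(L^3)
  if (length(energies) != L^3) stop("energies must have length L^3")
  if (any(energies < 0)) stop("energies must be non-negative")
  if (!is.null(seed)) set.seed(seed)
  st <- list(L = L, dE = dE, threshold = 6, energies = as.numeric(energies))
  class(st) <- "soc_state"
  st
}

#' @export
print.soc_state <- function(x, ...) {
  cat(sprintf("soc_state: L = %d (%d sites), dE = %g, mean energy %.3f\n",
              x$L, x$L^3, x$dE, mean(x$energies)))
  invisible(x)
}

#' Drive the sandpile with one energy grain
#'
#' Adds one energy unit to a uniformly random site. May only be called on
#' a quiescent lattice (all energies below threshold).
#'
#' @param state A `soc_state`.
#' @return The updated state, with the driven site index in
#'   `attr(, "driven_site")`.
#' @export
soc_drive <- function(state) {
  stopifnot(inherits(state, "soc_state"))
  if (any(state$energies >= state$threshold)) {
    stop("soc_drive called mid-avalanche: lattice is not quiescent")
  }
  site <- sample.int(state$L^3, 1)
  state$energies[site] <- state$energies[site] + 1
  attr(state, "driven_site") <- site
  state
}

#' Relax the sandpile to quiescence
#'
#' Runs synchronous toppling sweeps (all super-threshold sites topple
#' simultaneously) until every site is below threshold, logging the
#' avalanche. At most the driven site should be super-threshold on entry.
#'
#' @param state A `soc_state`.
#' @param max_sweeps Cap on the number of sweeps; a run hitting it (only
#'   possible for `dE > 1` runaway activity) is truncated and flagged.
#' @param sub_idx Optional 1-based site indices to log subsampled
#'   topplings for (see [sub_cube_indices()]).
#' @return List with `state` (quiescent) and `log`: `size` (total
#'   topplings), `duration` (sweeps), `boundary_edges` (toppling edges
#'   that crossed the open boundary), `sweep_topplings`, `sub_counts`,
#'   `truncated`.
#' @export
soc_relax <- function(state, max_sweeps = 1e6, sub_idx = integer(0)) {
  stopifnot(inherits(state, "soc_state"))
  r <- socm_relax_cpp(state$energies, state$L, state$dE, max_sweeps,
                      as.integer(sub_idx) - 1L)
  state$energies <- r$energies
  attr(state, "driven_site") <- NULL
  list(state = state,
       log = r[c("size", "duration", "boundary_edges", "sweep_topplings",
                 "sub_counts", "truncated")])
}

#' Linear indices of a centered regular sampling cube
#'
#' The subsampling geometry: a centered regular cube of `side^3` sites
#' with `spacing` lattice units between neighbouring sampled sites
#' (default 4 x 4 x 4 = 64 sites at spacing 2).
#'
#' @param L Lattice side length.
#' @param side Sites per cube edge (default 4).
#' @param spacing Lattice spacing between sampled sites (default 2).
#' @return Integer vector of 1-based linear site indices (x fastest).
#' @export
sub_cube_indices <- function(L, side = 4, spacing = 2) {
  extent <- spacing * (side - 1)
  if (extent >= L) stop("sampling cube does not fit the lattice")
  start <- floor((L - extent + 1) / 2)
  if (start < 1) stop("sampling cube does not fit the lattice")
  pos <- start + spacing * (0:(side - 1))
  g <- expand.grid(x = pos, y = pos, z = pos)
  as.integer((g$x - 1) + L * (g$y - 1) + L^2 * (g$z - 1) + 1)
}

#' Run the sandpile model
#'
#' Burn-in (driving without recording, by default until the mean lattice
#' energy is stationary or `burn_in` grains, whichever first), then
#' records `n_avalanches` avalanches. Optionally logs the topplings on a
#' subsampled cube of sites, on a concatenated sweep ("tick") time axis
#' where consecutive avalanches are separated by one empty tick.
#'
#' @param L Lattice side (default 25).
#' @param dE Propagation efficacy (default 1).
#' @param n_avalanches Number of avalanches (size >= 1) to record.
#' @param burn_in Maximum burn-in drive-relax cycles (default 1e5).
#' @param seed Optional seed.
#' @param subsample Log subsampled topplings (default `TRUE`).
#' @param side,spacing Subsampling cube geometry (default 4 and 2).
#' @param max_sweeps Per-avalanche sweep cap (default 1e6).
#' @param stationarity_stop End burn-in early once the running mean
#'   energy drifts < 0.1% between consecutive 2000-drive windows three
#'   times in a row (default `TRUE`).
#' @return A `socm_run`: list with `sizes`, `durations`, `truncated`,
#'   `sub_tick` / `sub_count` (subsampled events: 0-based tick and
#'   toppling count), `total_ticks`, `energy_trace`, `mean_energy` and
#'   the run parameters.
#' @export
run_socm <- function(L = 25, dE = 1, n_avalanches = 1e4, burn_in = 1e5,
                     seed = NULL, subsample = TRUE, side = 4, spacing = 2,
                     max_sweeps = 1e6, stationarity_stop = TRUE) {
  if (!is.null(seed)) set.seed(seed)
  if (n_avalanches < 0) stop("n_avalanches must be >= 0")
  sub_idx <- if (subsample) sub_cube_indices(L, side, spacing) else integer(0)
  if (n_avalanches == 0) {
    out <- list(sizes = numeric(0), durations = numeric(0),
                truncated = integer(0), sub_tick = numeric(0),
                sub_count = integer(0), total_ticks = 0,
                energy_trace = numeric(0), mean_energy = NA_real_)
  } else {
    out <- socm_run_cpp(L, dE, as.integer(n_avalanches),
                        as.integer(burn_in), max_sweeps,
                        as.integer(sub_idx) - 1L, 3.0, stationarity_stop)
  }
  out$L <- L; out$dE <- dE; out$sub_idx <- sub_idx
  out$n_sub_sites <- length(sub_idx)
  class(out) <- "socm_run"
  out
}

#' @export
print.socm_run <- function(x, ...) {
  cat(sprintf("socm_run: L = %d, dE = %g, %d avalanches", x$L, x$dE,
              length(x$sizes)))
  if (length(x$sizes) > 0) {
    cat(sprintf(", mean size %.1f, mean duration %.1f sweeps",
                mean(x$sizes), mean(x$durations)))
  }
  if (sum(x$truncated) > 0) {
    cat(sprintf(" [%d truncated]", sum(x$truncated)))
  }
  cat("\n")
  invisible(x)
}

#' Subsampled avalanche sizes per full-model avalanche
#'
#' Under subsampling, the size of a model avalanche is the number of
#' topplings on the sampled sites during that avalanche; avalanches that
#' touch no sampled site have size 0 and are excluded by default, since
#' they are invisible to the observer.
#'
#' @param run A `socm_run` with subsampling enabled.
#' @param drop_zero Drop invisible avalanches (default `TRUE`).
#' @return Numeric vector of subsampled sizes.
#' @export
subsample_sizes <- function(run, drop_zero = TRUE) {
  stopifnot(inherits(run, "socm_run"))
  if (run$n_sub_sites == 0) stop("run has no subsampling log")
  n <- length(run$sizes)
  starts <- c(0, cumsum(run$durations + 1))[seq_len(n)]
  idx <- findInterval(run$sub_tick, starts)
  s <- numeric(n)
  if (length(idx) > 0) {
    agg <- tapply(run$sub_count, idx, sum)
    s[as.integer(names(agg))] <- agg
  }
  if (drop_zero) s <- s[s > 0]
  s
}

#' Empirical mean inter-event interval of the subsampled series
#'
#' Computed from the merged subsampled event times on the tick axis
#' (events in the same sweep contribute zero intervals), as the observed
#' analog of `1/(r N)` for the model.
#'
#' @param run A `socm_run` with subsampling enabled.
#' @return Mean inter-event interval in ticks.
#' @export
subsample_mean_iei <- function(run) {
  stopifnot(inherits(run, "socm_run"))
  times <- rep(run$sub_tick, run$sub_count)
  if (length(times) < 2) return(NA_real_)
  mean(diff(times))
}

#' Bin the subsampled event series and extract avalanches
#'
#' The observer-level analysis of the model: the subsampled toppling
#' series is binned at `bs_factor` times its empirical mean inter-event
#' interval, with bins aligned to a random starting point to avoid
#' alignment bias, and avalanches are extracted as maximal runs of
#' non-empty bins -- exactly as for experimental event rasters.
#'
#' @param run A `socm_run` with subsampling enabled.
#' @param bs_factor Bin size in units of the empirical mean inter-event
#'   interval (default 1).
#' @param offset Bin alignment offset in ticks; `"random"` (default)
#'   draws it uniformly from one bin width.
#' @return An `avalanche_set` (sizes in events on sampled sites,
#'   durations in bins); `mean_iei` is in ticks. The binned count vector
#'   is attached as `$counts` for branching-parameter estimation with
#'   [branching_sigma()].
#' @export
subsampled_avalanches <- function(run, bs_factor = 1, offset = "random") {
  stopifnot(inherits(run, "socm_run"))
  if (run$n_sub_sites == 0) stop("run has no subsampling log")
  miei <- subsample_mean_iei(run)
  if (!is.finite(miei) || miei <= 0) stop("too few subsampled events")
  w <- bs_factor * miei
  a <- if (identical(offset, "random")) runif(1, 0, w) else as.numeric(offset)
  times <- rep(run$sub_tick, run$sub_count)
  times <- times[times >= a]
  n_bins <- max(1, ceiling((run$total_ticks - a) / w))
  b <- pmin(floor((times - a) / w) + 1L, n_bins)
  counts <- tabulate(b, nbins = n_bins)
  avs <- extract_avalanches(list(counts))
  avs$bs_factor <- bs_factor
  avs$mean_iei <- miei
  avs$n_channels <- run$n_sub_sites
  avs$counts <- counts
  avs
}

#' Virtual-LFP sampling of the sandpile
#'
#' Runs the driven model and records, at every sweep, an analog signal on
#' a cubic array of virtual electrodes. Each electrode reads the sum of
#' topplings over all sites, weighted by a Gaussian kernel
#' `exp(-||x - tip||^2 / (2 * kernel_var))` centered on its tip. The
#' resulting multichannel signal is processed downstream exactly like
#' recorded LFP (deflection lobes, rate-matched events, avalanches). The
#' study-scale geometry is a 50-side lattice sampled by 4 x 4 x 4
#' electrodes at spacing 15 with kernel variance 5.
#'
#' @param L Lattice side (default 50).
#' @param dE Propagation efficacy (default 1).
#' @param n_ticks Number of sweeps (samples) to emit.
#' @param n_side Electrodes per array edge (default 4).
#' @param spacing Lattice spacing between electrode tips (default 15).
#' @param kernel_var Gaussian kernel variance in lattice units squared
#'   (default 5).
#' @param burn_in Burn-in drive-relax cycles (default 2e4).
#' @param seed Optional seed.
#' @param max_sweeps Per-avalanche sweep cap.
#' @param init_energies Optional initial energy vector of length `L^3`
#'   (default: uniform random below threshold). Any initially
#'   supra-threshold sites relax as a first avalanche; useful for
#'   deterministic kernel checks.
#' @return List with `signals` (electrodes x ticks matrix), `tips`
#'   (1-based electrode coordinates), `n_avalanches`.
#' @export
virtual_lfp <- function(L = 50, dE = 1, n_ticks, n_side = 4, spacing = 15,
                        kernel_var = 5, burn_in = 2e4, seed = NULL,
                        max_sweeps = 1e6, init_energies = NULL) {
  if (!is.null(seed)) set.seed(seed)
  extent <- spacing * (n_side - 1)
  if (extent >= L) stop("electrode array does not fit the lattice")
  start <- floor((L - extent + 1) / 2)
  if (start < 1) stop("electrode array does not fit the lattice")
  pos <- start + spacing * (0:(n_side - 1))
  g <- expand.grid(x = pos, y = pos, z = pos)
  tips <- as.matrix(g) - 1  # 0-based for the C++ side
  if (is.null(init_energies)) init_energies <- numeric(0)
  r <- socm_lfp_cpp(L, dE, n_ticks, as.integer(burn_in), max_sweeps,
                    tips, kernel_var, 3.0, init_energies)
  list(signals = r$signals, tips = as.matrix(g),
       n_avalanches = r$n_avalanches, L = L, dE = dE,
       kernel_var = kernel_var)
}
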