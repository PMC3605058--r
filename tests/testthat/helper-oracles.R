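# Independent oracles used across the test files. These deliberately use
# naive loop-based logic, distinct from the package's vectorized code
# paths.

# Brute-force avalanche extraction straight from raw event times: count
# events per half-open bin of width w tiling [0, n_bins * w), then walk
# the bins sequentially collecting maximal non-empty runs. Runs touching
# the final bin are dropped, mirroring the package contract.
brute_force_avalanches <- function(times, w, t_end) {
  n_bins <- floor(t_end / w)
  counts <- integer(n_bins)
  for (t in times) {
    b <- floor(t / w) + 1
    if (b >= 1 && b <= n_bins) counts[b] <- counts[b] + 1L
  }
  sizes <- integer(0); durs <- integer(0)
  cur_s <- 0L; cur_d <- 0L
  for (b in seq_len(n_bins)) {
    if (counts[b] > 0) {
      cur_s <- cur_s + counts[b]; cur_d <- cur_d + 1L
      if (b == n_bins) { cur_s <- 0L; cur_d <- 0L }  # open at segment end
    } else if (cur_d > 0) {
      sizes <- c(sizes, cur_s); durs <- c(durs, cur_d)
      cur_s <- 0L; cur_d <- 0L
    }
  }
  list(sizes = sizes, durations = durs)
}

# Exhaustive grid-search MLE for the discrete power law on a small
# support: direct likelihood evaluation over a fine tau grid.
grid_search_tau <- function(x, smin, smax, taus = seq(1.01, 4, by = 1e-4)) {
  s <- smin:smax
  ll <- vapply(taus, function(tau) {
    z <- sum(s^(-tau))
    -tau * sum(log(x)) - length(x) * log(z)
  }, 0)
  taus[which.max(ll)]
}

# Exhaustive paired permutation test (all sign flips) for a single
# difference vector; two-sided on the t statistic.
exhaustive_sign_flip_p <- function(d) {
  n <- length(d)
  tstat <- function(x) mean(x) / (sd(x) / sqrt(n))
  obs <- abs(tstat(d))
  flips <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
  vals <- apply(flips, 1, function(f) abs(tstat(f * d)))
  mean(vals >= obs - 1e-12)
}

# Measure table filled with iid noise: the null for cluster-test
# calibration.
null_measure_table <- function(n_nights, states, bs_vals, r_vals) {
  g <- expand.grid(night = paste0("n", seq_len(n_nights)), state = states,
                   bs_factor = bs_vals, rate_r = r_vals,
                   stringsAsFactors = FALSE)
  g$value <- rnorm(nrow(g))
  g
}
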