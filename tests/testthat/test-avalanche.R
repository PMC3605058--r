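# Binning, avalanche extraction and avalanche measures.

test_that("mean inter-event interval follows 1/(r N)", {
  expect_identical(mean_iei(1, 50), 0.020)
  expect_identical(mean_iei(0.1, 50), 0.200)
  expect_equal(mean_iei(0.25, 44), 1 / 11)
  expect_error(mean_iei(0, 50), "rate_r")
  expect_error(mean_iei(1, 0), "n_channels")
})

test_that("binning tiles segments and conserves events", {
  r <- event_raster(2, c(1, 2, 1), c(0.01, 0.02, 1.5), 2,
                    rate_r = 0.5)  # <IEI> = 1 s
  bn <- bin_events(r, 1)
  expect_equal(bn$counts[[1]], c(2L, 1L))

  # empty raster -> all-zero counts
  r0 <- event_raster(2, integer(0), numeric(0), 2, rate_r = 0.5)
  expect_equal(bin_events(r0, 1)$counts[[1]], c(0L, 0L))

  # conservation: total counts = in-tiling events
  set.seed(1)
  rr <- gen_independent_poisson(5, 0.5, 500, seed = 1)
  bn2 <- bin_events(rr, 1 / 2)
  expect_equal(sum(unlist(bn2$counts)), sum(!is.na(bn2$event_bins$bin)))

  # bin width below the resolution is rejected: r = 1 Hz, N = 50 gives
  # <IEI> = 20 ms, so bs = 1/32 means 0.625 ms bins < the 2.5 ms sampling
  rhi <- gen_independent_poisson(50, 1, 10, seed = 3)
  expect_error(bin_events(rhi, 1 / 32, resolution = 0.0025),
               "resolution")
})

test_that("avalanche extraction matches the definition on hand cases", {
  a <- extract_avalanches(c(0, 3, 1, 0, 2, 0))
  expect_equal(a$avalanches$size, c(4, 2))
  expect_equal(a$avalanches$duration, c(2, 1))
  expect_equal(a$profiles, list(c(3, 1), 2))

  expect_equal(nrow(extract_avalanches(c(0, 0, 0))$avalanches), 0)

  # a run open at the segment end is discarded; a single full bin vector
  # counts when terminated
  one <- extract_avalanches(c(5, 0))
  expect_equal(one$avalanches$size, 5)
  expect_equal(nrow(extract_avalanches(c(0, 5))$avalanches), 0)
  expect_error(extract_avalanches(c(1, -1)), "non-negative")
})

test_that("avalanche extraction agrees with the brute-force oracle", {
  for (i in 1:20) {
    set.seed(i)
    n <- sample(5:200, 1)
    t_end <- runif(1, 5, 50)
    times <- runif(n, 0, t_end)
    w <- runif(1, 0.05, 2)
    oracle <- brute_force_avalanches(times, w, t_end)
    r <- event_raster(1, rep(1, n), times, t_end, rate_r = 1)
    bs <- w / mean_iei(1, 1)
    avs <- avalanches(r, bs)
    expect_equal(avs$avalanches$size, as.numeric(oracle$sizes))
    expect_equal(avs$avalanches$duration, as.integer(oracle$durations))
  }
})

test_that("every event belongs to exactly one avalanche (conservation)", {
  for (i in 1:5) {
    r <- gen_correlated(10, 0.5, 400, share = 0.7, seed = 100 + i)
    bn <- bin_events(r, 1)
    avs <- extract_avalanches(bn)
    # all but the events of a possibly-open trailing run are in avalanches
    counts <- bn$counts[[1]]
    nz <- which(counts > 0)
    open_tail <- if (length(counts) > 0 && counts[length(counts)] > 0) {
      last_zero <- max(c(0, which(counts == 0)))
      sum(counts[(last_zero + 1):length(counts)])
    } else 0
    expect_equal(sum(avs$avalanches$size), sum(counts) - open_tail)
  }
})

test_that("branching parameter follows its transition-average definition", {
  expect_equal(branching_sigma(c(2, 4, 0, 3, 3)), 1.0)
  expect_equal(branching_sigma(c(5, 5, 5, 5)), 1.0)
  expect_equal(branching_sigma(c(1, 0, 1, 0)), 0)
  expect_true(is.na(branching_sigma(c(0, 0, 1))))
  # within-avalanche variant drops transitions into empty bins
  expect_equal(branching_sigma(c(2, 4, 0, 3, 3), within_avalanche = TRUE),
               mean(c(2, 1)))
})

test_that("size distributions conserve counts and events", {
  avs <- extract_avalanches(c(0, 3, 1, 0, 2, 0, 1, 1, 0))
  fs <- size_distribution(avs)
  expect_equal(sum(fs$count), nrow(avs$avalanches))
  expect_equal(sum(fs$s * fs$count), sum(avs$avalanches$size))
  expect_equal(fs$count[fs$s == 2], 2L)
  fd <- duration_distribution(avs)
  expect_equal(sum(fd$count), nrow(avs$avalanches))
  # all sizes 1
  a1 <- extract_avalanches(c(1, 0, 1, 0, 1, 0))
  f1 <- size_distribution(a1)
  expect_equal(f1$count, 3L)
  expect_equal(f1$s, 1)
  # empty set -> empty table
  expect_equal(nrow(size_distribution(extract_avalanches(c(0, 0)))), 0)
  # log binning preserves total count
  set.seed(2)
  ab <- extract_avalanches(list(rpois(2000, 1)))
  expect_equal(sum(size_distribution(ab, log_bin = TRUE)$count),
               nrow(ab$avalanches))
})

test_that("IEI/IAI pooling and thresholding follow the definitions", {
  r <- event_raster(2, c(1, 2, 1), c(0, 1, 3), 4, rate_r = 0.5)
  # merged times {0,1,3}: IEIs {1,2}; bin width 1.5<IEI> = 1.5*1 = wait
  # <IEI> = 1/(0.5*2) = 1 s; bs 1.5 -> width 1.5 s -> IAI = {2}
  d <- iei_iai_distributions(r, 1.5)
  expect_equal(sort(d$iei), c(1, 2))
  expect_equal(d$iai, 2)
  # too few events
  r1 <- event_raster(1, 1, 0.5, 2, rate_r = 1)
  expect_equal(length(iei_iai_distributions(r1, 1)$iei), 0)
  # every gap between binned avalanches implies an inter-event interval
  # exceeding the bin width, so the IAI count bounds the gap count
  rr <- gen_independent_poisson(4, 0.5, 300, seed = 9)
  dd <- iei_iai_distributions(rr, 1)
  avs <- avalanches(rr, 1)
  expect_gte(length(dd$iai), nrow(avs$avalanches) - 1)
  expect_true(all(dd$iai > dd$bin_width))
})

test_that("larger bins flatten the fitted size-distribution slope", {
  night <- gen_synthetic_night(hypnogram(0, 300, "WAKE"),
                               list(WAKE = list(dE = 1)), mode = "socm",
                               seed = 14)
  lobes <- night_lobes(night)
  raster <- rate_matched_events(lobes, night$hypnogram, 0.5, 64)
  tau_of <- function(bs) {
    s <- avalanches(raster, bs)$avalanches$size
    fit_family(s, "power_law", smax = max(s))$params["tau"]
  }
  expect_gt(tau_of(1 / 4), tau_of(2))
})

test_that("normalized measures average to exactly 1 over states", {
  tbl <- data.frame(night = "n1", state = c("WAKE", "REM"),
                    bs_factor = 1, rate_r = 0.25,
                    mean_size = c(2, 4), mean_duration = c(1.5, 2.5),
                    sigma = c(0.8, 1.0), n_avalanches = c(10L, 10L))
  nm <- normalized_measures(tbl)
  expect_equal(nm$size_rel, c(2 / 3, 4 / 3))
  expect_identical(mean(nm$size_rel), 1)
  expect_identical(mean(nm$dur_rel), 1)
  expect_identical(mean(nm$sigma_rel), 1)
  # identical states -> all 1; single state -> degenerate 1
  tbl2 <- tbl; tbl2$mean_size <- c(3, 3)
  expect_equal(normalized_measures(tbl2)$size_rel, c(1, 1))
  expect_equal(normalized_measures(tbl[1, ])$size_rel, 1)
})

test_that("sigma at fixed bs is approximately rate-invariant", {
  night <- gen_synthetic_night(hypnogram(0, 300, "WAKE"),
                               list(WAKE = list(correlation = 0.4)),
                               n_channels = 20, seed = 15)
  lobes <- night_lobes(night)
  sig <- vapply(c(0.25, 0.5, 1), function(r) {
    raster <- rate_matched_events(lobes, night$hypnogram, r, 20)
    branching_sigma(bin_events(raster, 1))
  }, 0)
  expect_lt(max(sig) - min(sig), 0.25)
})

test_that("distribution and measure tables round-trip to disk", {
  avs <- extract_avalanches(c(0, 3, 1, 0, 2, 0))
  p <- file.path(tempdir(), "fs.tsv")
  write_distribution(size_distribution(avs), p)
  expect_equal(read_distribution(p)$count, c(1L, 1L))
  tbl <- data.frame(night = "n1", state = "WAKE", bs_factor = 1,
                    rate_r = 0.25, mean_size = 2.5, mean_duration = 1.5,
                    sigma = 0.9, n_avalanches = 12L)
  pm <- file.path(tempdir(), "m.csv")
  write_measure_table(tbl, pm)
  expect_equal(read_measure_table(pm)$mean_size, 2.5)
})
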