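# Cluster-based randomization tests and participation profiles.

test_that("identical state measures yield no clusters", {
  set.seed(1)
  g <- expand.grid(night = paste0("n", 1:6), state = c("WAKE", "REM"),
                   bs_factor = c(0.5, 1), rate_r = c(0.25, 0.5),
                   stringsAsFactors = FALSE)
  base <- rnorm(nrow(g) / 2)
  g$value <- rep(base, 2)  # states exactly equal within night/cell
  res <- cluster_randomization(g, "value", c("WAKE", "REM"), n_perm = 200,
                               seed = 2)
  expect_equal(nrow(res$clusters), 0)
  expect_equal(res$p_min, 1)
})

test_that("a grid-wide injected offset produces one significant cluster", {
  set.seed(3)
  g <- null_measure_table(10, c("WAKE", "REM"), c(0.25, 0.5, 1, 2),
                          c(0.1, 0.25, 0.5, 1))
  g$value[g$state == "REM"] <- g$value[g$state == "REM"] - 2
  res <- cluster_randomization(g, "value", c("WAKE", "REM"),
                               n_perm = 500, seed = 4)
  expect_gte(nrow(res$clusters), 1)
  main <- res$clusters[which.max(abs(res$clusters$mass)), ]
  expect_lt(main$p, 0.05)
  # the dominant cluster spans (nearly) the full grid
  expect_gte(sum(res$cells$cluster == main$cluster), 14)
})

test_that("single-cell pairwise test equals the exhaustive permutation oracle", {
  set.seed(5)
  for (i in 1:3) {
    d <- rnorm(8, mean = runif(1, 0, 1.2))
    g <- data.frame(night = rep(paste0("n", 1:8), 2),
                    state = rep(c("WAKE", "REM"), each = 8),
                    bs_factor = 1, rate_r = 0.25,
                    value = c(d, numeric(8)))
    res <- cluster_randomization(g, "value", c("WAKE", "REM"),
                                 exact = TRUE, seed = 6)
    oracle <- exhaustive_sign_flip_p(d)
    if (nrow(res$clusters) == 1) {
      expect_equal(res$clusters$p, oracle, tolerance = 1e-12)
    } else {
      # no supra-threshold cell: the observed |t| cannot be extreme
      expect_gt(oracle, 0.05)
    }
  }
})

test_that("omnibus F detects graded state differences and respects blocks", {
  set.seed(7)
  g <- null_measure_table(8, c("WAKE", "REM", "S3S4"), c(0.5, 1),
                          c(0.25, 0.5))
  shift <- c(WAKE = 0, REM = -1, S3S4 = 1)
  g$value <- g$value + shift[g$state]
  res <- cluster_randomization(g, "value", "omnibus", n_perm = 300,
                               seed = 8)
  expect_lt(res$p_min, 0.05)
  expect_identical(res$metric, "F_omnibus")
})

test_that("masked (NA) cells never join clusters", {
  set.seed(9)
  g <- null_measure_table(6, c("WAKE", "REM"), c(0.5, 1, 2), c(0.25, 0.5))
  g$value[g$state == "REM"] <- g$value[g$state == "REM"] - 3
  g$value[g$bs_factor == 1 & g$rate_r == 0.25] <- NA
  res <- cluster_randomization(g, "value", c("WAKE", "REM"), n_perm = 200,
                               seed = 10)
  cells <- res$cells
  expect_true(all(cells$cluster[is.na(cells$p_uncorrected)] == 0))
})

test_that("cluster test preconditions", {
  g <- null_measure_table(1, c("WAKE", "REM"), 1, 0.25)
  expect_error(cluster_randomization(g, "value", c("WAKE", "REM")),
               ">= 2 nights")
  g2 <- null_measure_table(4, c("WAKE", "REM"), 1, 0.25)
  expect_warning(cluster_randomization(g2, "value", c("WAKE", "REM"),
                                       n_perm = 50, seed = 1),
                 "coarse")
})

test_that("cluster-corrected type-I error stays at or below nominal", {
  set.seed(11)
  n_rep <- 400
  rejections <- 0L
  for (i in seq_len(n_rep)) {
    g <- null_measure_table(8, c("WAKE", "REM", "S3S4"), c(0.5, 1),
                            c(0.25, 0.5))
    res <- cluster_randomization(g, "value", "omnibus", n_perm = 200)
    if (res$p_min < 0.05) rejections <- rejections + 1L
  }
  rate <- rejections / n_rep
  # 0.05 plus ~3 binomial standard errors
  expect_lte(rate, 0.05 + 3 * sqrt(0.05 * 0.95 / n_rep))
})

test_that("Holm step-down follows the sequential Bonferroni rule", {
  res <- sequential_bonferroni(c(0.001, 0.04, 0.04))
  expect_equal(res$reject, c(TRUE, FALSE, FALSE))
  expect_equal(sequential_bonferroni(rep(1, 5))$reject, rep(FALSE, 5))
  expect_true(sequential_bonferroni(0.04)$reject)
  expect_length(sequential_bonferroni(numeric(0))$reject, 0)
  expect_error(sequential_bonferroni(c(0.5, 1.2)), "0, 1")
})

test_that("participation profiles are normalized per contact", {
  r <- gen_correlated(10, 0.5, 600, share = 0.6, seed = 12)
  P <- participation_profiles(r, 1)
  for (ch in 1:10) {
    if (!is.na(P[ch, 1])) expect_equal(sum(P[ch, ]), 1)
  }
})

test_that("participation test is calibrated under homogeneous contacts", {
  set.seed(13)
  ps <- vapply(1:30, function(i) {
    r <- gen_clustered(6, 6, 0.5, 400, jitter_sd = 0.02, seed = 100 + i)
    # label shuffle of a homogeneous raster: groups are exchangeable
    participation_compare(r, 1, groups = sample(rep(c("NC", "AH"), 6)),
                          n_perm = 120)$p_min
  }, 0)
  expect_lte(mean(ps < 0.05), 0.05 + 3 * sqrt(0.05 * 0.95 / 30))
})

test_that("a group firing only in isolation shows a small-s cluster", {
  set.seed(14)
  # group A: shared events (large avalanches); group B: lone events
  shared <- runif(150, 0, 600)
  chanA <- rep(1:5, each = 150)
  tA <- rep(shared, 5) + rnorm(750, 0, 0.004)
  nB <- 150
  chanB <- rep(6:10, each = nB)
  tB <- runif(5 * nB, 0, 600)
  keep <- tA >= 0 & tA < 600
  r <- event_raster(10, c(chanA[keep], chanB), c(tA[keep], tB), 600,
                    rate_r = 0.25,
                    channel_group = rep(c("NC", "AH"), each = 5))
  res <- participation_compare(r, 1, n_perm = 300, seed = 15)
  expect_lt(res$p_min, 0.05)
  expect_error(participation_compare(r, 1, groups = rep(c("NC", "AH"),
                                                        c(9, 1))),
               ">= 2 contacts")
})

test_that("dE-graded synthetic nights yield significant omnibus clusters", {
  # artifact-level analog of the vigilance-state comparison: three states
  # generated at dE = 0.994 / 0.997 / 1.0, several nights, omnibus F on
  # the normalized measures over a (bs, r) grid
  hyp <- hypnogram(c(0, 160, 320), c(160, 320, 480),
                   c("REM", "WAKE", "S3S4"))
  pp <- list(REM = list(dE = 0.994), WAKE = list(dE = 0.997),
             S3S4 = list(dE = 1.0))
  tbs <- lapply(1:6, function(i) {
    night <- gen_synthetic_night(hyp, pp, mode = "socm", seed = 500 + i)
    night_measures(night, rates = c(0.25, 0.5), bs_factors = c(0.5, 1),
                   night_label = paste0("n", i), min_segment = 150)
  })
  tbl <- normalized_measures(do.call(rbind, tbs))
  for (m in c("size_rel", "dur_rel", "sigma_rel")) {
    res <- cluster_randomization(tbl, m, "omnibus", n_perm = 500,
                                 seed = 16)
    expect_lt(res$p_min, 0.05)
  }
  # and the state means order with dE
  agg <- tapply(tbl$size_rel, tbl$state, mean)
  expect_true(agg[["REM"]] < agg[["WAKE"]] &&
                agg[["WAKE"]] < agg[["S3S4"]])
})
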