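# Cluster-based randomization tests of avalanche measures across
# vigilance states over the (bin size, rate) grid, plus per-contact
# avalanche-participation analysis.

# label 4-connected clusters of supra-threshold cells on a grid;
# same-sign cells cluster together (sign = matrix of -1/0/+1)
label_clusters <- function(supra, sign) {
  nr <- nrow(supra); nc <- ncol(supra)
  lab <- matrix(0L, nr, nc)
  cur <- 0L
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    if (!supra[i, j] || lab[i, j] != 0L) next
    cur <- cur + 1L
    queue <- list(c(i, j))
    lab[i, j] <- cur
    while (length(queue) > 0) {
      q <- queue[[1]]; queue <- queue[-1]
      for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
        a <- q[1] + d[1]; b <- q[2] + d[2]
        if (a >= 1 && a <= nr && b >= 1 && b <= nc && supra[a, b] &&
            lab[a, b] == 0L && sign[a, b] == sign[q[1], q[2]]) {
          lab[a, b] <- cur
          queue <- c(queue, list(c(a, b)))
        }
      }
    }
  }
  lab
}

# paired t statistics for a nights x cells difference matrix (NA columns
# allowed); returns t and two-sided p
paired_t_cells <- function(D) {
  n <- nrow(D)
  m <- colMeans(D)
  ss <- colSums(D^2)
  s2 <- (ss - n * m^2) / (n - 1)
  s2[s2 < 0] <- 0
  tt <- m / sqrt(s2 / n)
  tt[!is.finite(tt)] <- 0
  p <- 2 * pt(-abs(tt), df = n - 1)
  list(t = tt, p = p)
}

# repeated-measures F (states as within factor, nights as blocks) per
# cell; A is nights x states x cells
rm_f_cells <- function(A) {
  n <- dim(A)[1]; k <- dim(A)[2]; nc <- dim(A)[3]
  grand <- apply(A, 3, mean)
  sm <- apply(A, c(2, 3), mean)                    # k x cells
  nm <- apply(A, c(1, 3), mean)                    # n x cells
  ss_state <- n * colSums((sm - matrix(grand, k, nc, byrow = TRUE))^2)
  ss_night <- k * colSums((nm - matrix(grand, n, nc, byrow = TRUE))^2)
  ss_tot <- apply(A, 3, function(m) sum((m - mean(m))^2))
  ss_err <- pmax(ss_tot - ss_state - ss_night, 0)
  df1 <- k - 1; df2 <- (k - 1) * (n - 1)
  f <- (ss_state / df1) / (ss_err / df2)
  f[!is.finite(f)] <- 0
  p <- pf(f, df1, df2, lower.tail = FALSE)
  list(f = f, p = p, df1 = df1, df2 = df2)
}

# clusters + masses for one map of statistics laid out on the grid
grid_clusters <- function(stat, p, ok, nb, nr, cell_alpha, signed) {
  sm <- matrix(stat, nb, nr); pm <- matrix(p, nb, nr)
  okm <- matrix(ok, nb, nr)
  supra <- okm & pm < cell_alpha
  sgn <- if (signed) sign(sm) else matrix(1, nb, nr)
  sgn[!supra] <- 0
  lab <- label_clusters(supra, sgn)
  ids <- setdiff(unique(as.integer(lab)), 0L)
  mass <- vapply(ids, function(id) sum(sm[lab == id]), 0)
  list(lab = lab, ids = ids, mass = mass)
}

#' Cluster-based randomization test of avalanche measures across states
#'
#' Tests whether an avalanche measure differs between vigilance states
#' across nights, jointly over the whole (bin size, rate) parameter grid,
#' with a cluster-based correction for the multiple comparisons. Per grid
#' cell the statistic is a paired t (two states) or a repeated-measures F
#' with nights as blocks (omnibus over all states); cells with
#' uncorrected p below `cell_alpha` are joined into clusters by
#' 4-connectivity on the ordered grid (same-sign cells only, for t), and
#' each cluster's mass (summed statistic) is referred to a permutation
#' null obtained by re-labelling states within each night. Cells
#' undefined for any night (e.g. bin width below the sampling resolution)
#' are masked from clustering.
#'
#' @param measures Measure table (see [avalanche_measures()] /
#'   [normalized_measures()]) with columns `night`, `state`, `bs_factor`,
#'   `rate_r` and the measure named by `value`.
#' @param value Name of the measure column to test (e.g. `"size_rel"`).
#' @param comparison Character vector of two states for a pairwise test,
#'   or `"omnibus"` (default) for the repeated-measures F over all
#'   states.
#' @param n_perm Number of random permutations (default 1000; < 100
#'   triggers a warning).
#' @param seed Optional seed.
#' @param cell_alpha Cluster-forming threshold on the per-cell
#'   uncorrected p (default 0.05, two-sided).
#' @param exact For pairwise tests with few nights, enumerate all `2^n`
#'   within-night label swaps instead of sampling (default `FALSE`).
#' @return A `cluster_test` object: list with `metric` (`"T_pairwise"` or
#'   `"F_omnibus"`), `cells` (data frame `bs_factor`, `rate_r`, `stat`,
#'   `p_uncorrected`, `cluster`), `clusters` (data frame `cluster`,
#'   `mass`, `p`), `n_perm`, `p_min` (smallest cluster p, 1 when no
#'   cluster formed).
#' @export
cluster_randomization <- function(measures, value,
                                  comparison = "omnibus", n_perm = 1000,
                                  seed = NULL, cell_alpha = 0.05,
                                  exact = FALSE) {
  stopifnot(value %in% names(measures))
  if (!is.null(seed)) set.seed(seed)
  if (n_perm < 100) warning("n_perm < 100: cluster p-values are coarse")
  nights <- sort(unique(measures$night))
  if (length(nights) < 2) stop("need >= 2 nights")
  pairwise <- !identical(comparison, "omnibus")
  states <- if (pairwise) comparison else sort(unique(measures$state))
  if (pairwise && length(states) != 2) {
    stop("pairwise comparison needs exactly 2 states")
  }
  bs_vals <- sort(unique(measures$bs_factor))
  r_vals <- sort(unique(measures$rate_r))
  nb <- length(bs_vals); nr <- length(r_vals)
  ncell <- nb * nr
  # array nights x states x cells, cells in (bs, r) order with bs fastest
  A <- array(NA_real_, c(length(nights), length(states), ncell))
  for (row in seq_len(nrow(measures))) {
    i <- match(measures$night[row], nights)
    s <- match(measures$state[row], states)
    if (is.na(s)) next
    c1 <- match(measures$bs_factor[row], bs_vals)
    c2 <- match(measures$rate_r[row], r_vals)
    A[i, s, (c2 - 1) * nb + c1] <- measures[[value]][row]
  }
  ok <- apply(A, 3, function(m) all(is.finite(m)))
  if (!any(ok)) stop("no grid cell has complete data")
  A[, , !ok] <- 0  # masked; never enters clusters
  n <- length(nights)

  if (pairwise) {
    D <- A[, 1, , drop = TRUE] - A[, 2, , drop = TRUE]
    D <- matrix(D, nrow = n)
    obs <- paired_t_cells(D)
    cl <- grid_clusters(obs$t, obs$p, ok, nb, nr, cell_alpha, TRUE)
    flip_sets <- if (exact) {
      if (n > 20) stop("exact enumeration limited to 20 nights")
      m <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
      lapply(seq_len(nrow(m)), function(i) m[i, ])
    } else {
      lapply(seq_len(n_perm), function(i) sample(c(-1, 1), n, TRUE))
    }
    null_max <- vapply(flip_sets, function(fl) {
      pr <- paired_t_cells(D * fl)
      pc <- grid_clusters(pr$t, pr$p, ok, nb, nr, cell_alpha, TRUE)
      if (length(pc$mass) == 0) 0 else max(abs(pc$mass))
    }, 0)
    metric <- "T_pairwise"
  } else {
    obs <- rm_f_cells(A)
    obs$t <- obs$f
    cl <- grid_clusters(obs$f, obs$p, ok, nb, nr, cell_alpha, FALSE)
    k <- length(states)
    null_max <- vapply(seq_len(n_perm), function(b) {
      Ap <- A
      for (i in seq_len(n)) Ap[i, , ] <- A[i, sample.int(k), ]
      pr <- rm_f_cells(Ap)
      pc <- grid_clusters(pr$f, pr$p, ok, nb, nr, cell_alpha, FALSE)
      if (length(pc$mass) == 0) 0 else max(abs(pc$mass))
    }, 0)
    metric <- "F_omnibus"
  }
  denom <- length(null_max) + !exact  # exact: plain fraction over all flips
  p_cl <- vapply(cl$mass, function(m) {
    (sum(null_max >= abs(m)) + !exact) / denom
  }, 0)
  cells <- data.frame(
    bs_factor = rep(bs_vals, nr), rate_r = rep(r_vals, each = nb),
    stat = obs$t, p_uncorrected = ifelse(ok, obs$p, NA_real_),
    cluster = as.integer(cl$lab))
  clusters <- data.frame(cluster = cl$ids, mass = cl$mass, p = p_cl)
  res <- list(metric = metric, cells = cells, clusters = clusters,
              n_perm = length(null_max),
              p_min = if (nrow(clusters)) min(clusters$p) else 1)
  class(res) <- "cluster_test"
  res
}

#' @export
print.cluster_test <- function(x, ...) {
  cat(sprintf("cluster_test (%s): %d cluster(s), %d permutations\n",
              x$metric, nrow(x$clusters), x$n_perm))
  if (nrow(x$clusters) > 0) print(x$clusters)
  invisible(x)
}

#' Holm step-down (sequential Bonferroni) correction
#'
#' Orders the p-values, compares the smallest against `alpha/m`, the next
#' against `alpha/(m-1)`, and so on, stopping at the first failure. This
#' controls the family-wise error rate at `alpha` over the whole family
#' of comparisons.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @param alpha Family-wise level (default 0.05).
#' @return List with `reject` (logical, in input order) and `adjusted`
#'   (Holm-adjusted p-values). Empty input gives empty output.
#' @examples
#' sequential_bonferroni(c(0.001, 0.04, 0.04))$reject  # TRUE FALSE FALSE
#' @export
sequential_bonferroni <- function(p, alpha = 0.05) {
  if (length(p) == 0) {
    return(list(reject = logical(0), adjusted = numeric(0)))
  }
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  adj <- p.adjust(p, method = "holm")
  list(reject = !is.na(adj) & adj <= alpha, adjusted = adj)
}

#' Per-contact avalanche participation profiles
#'
#' For every contact (channel) `c`, the probability `p_c(s)` that one of
#' its events takes part in an avalanche of size `s`, for
#' `s = 1..n_channels` (avalanches larger than the channel count, which
#' are rare for experimental-style rasters, are counted in the top bin).
#' Each contact's profile sums to 1.
#'
#' @param raster An [event_raster()].
#' @param bs_factor Bin size in units of the mean inter-event interval.
#' @param ... Passed to [bin_events()].
#' @return Matrix `n_channels x n_channels` of probabilities (rows:
#'   contacts; columns: sizes `1..N`); rows of contacts with no counted
#'   events are `NA`.
#' @export
participation_profiles <- function(raster, bs_factor, ...) {
  stopifnot(inherits(raster, "event_raster"))
  bn <- bin_events(raster, bs_factor, ...)
  avs <- extract_avalanches(bn)
  a <- avs$avalanches
  N <- raster$n_channels
  P <- matrix(NA_real_, N, N)
  if (nrow(a) == 0) return(P)
  # per-segment lookup bin -> avalanche size
  sizes_of_event <- rep(NA_real_, nrow(bn$event_bins))
  for (seg in unique(a$segment)) {
    nbin <- length(bn$counts[[seg]])
    lut <- rep(NA_real_, nbin)
    rows <- which(a$segment == seg)
    for (rr in rows) {
      lut[a$start_bin[rr]:(a$start_bin[rr] + a$duration[rr] - 1L)] <-
        a$size[rr]
    }
    ev <- which(!is.na(bn$event_bins$segment) & bn$event_bins$segment == seg)
    sizes_of_event[ev] <- lut[bn$event_bins$bin[ev]]
  }
  s_capped <- pmin(sizes_of_event, N)
  for (ch in seq_len(N)) {
    sel <- raster$events$channel == ch & !is.na(s_capped)
    if (!any(sel)) next
    P[ch, ] <- tabulate(s_capped[sel], nbins = N) / sum(sel)
  }
  P
}

#' Compare participation profiles between contact groups
#'
#' Tests whether two groups of contacts (e.g. neocortical versus
#' amygdala/hippocampus) contribute differently to avalanches of each
#' size: per size `s` a two-sample t statistic compares `p_c(s)` between
#' the groups; contiguous supra-threshold sizes form 1-D clusters whose
#' mass is referred to a null obtained by shuffling the group labels over
#' contacts.
#'
#' @param raster An [event_raster()].
#' @param bs_factor Bin size in units of the mean inter-event interval.
#' @param groups Character vector of group labels, one per channel
#'   (default `raster$channel_group`). Exactly two distinct labels; each
#'   group needs >= 2 contacts.
#' @param n_perm Number of label permutations (default 1000).
#' @param seed Optional seed.
#' @param cell_alpha Cluster-forming threshold (default 0.05).
#' @param ... Passed to [participation_profiles()].
#' @return A `cluster_test` object over the size axis (in `cells`,
#'   `bs_factor` carries the size `s`).
#' @export
participation_compare <- function(raster, bs_factor,
                                  groups = raster$channel_group,
                                  n_perm = 1000, seed = NULL,
                                  cell_alpha = 0.05, ...) {
  if (is.null(groups)) stop("no channel groups given")
  stopifnot(length(groups) == raster$n_channels)
  if (!is.null(seed)) set.seed(seed)
  gl <- sort(unique(groups))
  if (length(gl) != 2) stop("exactly two contact groups required")
  if (min(table(groups)) < 2) stop("each group needs >= 2 contacts")
  P <- participation_profiles(raster, bs_factor, ...)
  keep <- !is.na(P[, 1])
  P <- P[keep, , drop = FALSE]
  g <- groups[keep]
  if (min(table(g)) < 2) stop("each group needs >= 2 contacts with events")
  ns <- ncol(P)
  tstat <- function(gg) {
    a <- P[gg == gl[1], , drop = FALSE]
    b <- P[gg == gl[2], , drop = FALSE]
    na <- nrow(a); nb_ <- nrow(b)
    sp <- ((na - 1) * apply(a, 2, var) + (nb_ - 1) * apply(b, 2, var)) /
      (na + nb_ - 2)
    tt <- (colMeans(a) - colMeans(b)) / sqrt(sp * (1 / na + 1 / nb_))
    tt[!is.finite(tt)] <- 0
    list(t = tt, p = 2 * pt(-abs(tt), df = na + nb_ - 2))
  }
  obs <- tstat(g)
  cl <- grid_clusters(obs$t, obs$p, rep(TRUE, ns), ns, 1L, cell_alpha, TRUE)
  null_max <- vapply(seq_len(n_perm), function(b) {
    pr <- tstat(sample(g))
    pc <- grid_clusters(pr$t, pr$p, rep(TRUE, ns), ns, 1L, cell_alpha, TRUE)
    if (length(pc$mass) == 0) 0 else max(abs(pc$mass))
  }, 0)
  p_cl <- vapply(cl$mass, function(m) {
    (1 + sum(null_max >= abs(m))) / (n_perm + 1)
  }, 0)
  res <- list(metric = "T_pairwise",
              cells = data.frame(s = seq_len(ns), stat = obs$t,
                                 p_uncorrected = obs$p,
                                 cluster = as.integer(cl$lab)),
              clusters = data.frame(cluster = cl$ids, mass = cl$mass,
                                    p = p_cl),
              n_perm = n_perm,
              p_min = if (length(p_cl)) min(p_cl) else 1)
  class(res) <- "cluster_test"
  res
}
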