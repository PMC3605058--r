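# Avalanche shape functions S(t,d), scaling collapse, and the scaling
# exponent b. Near criticality the per-bin activity profile of an
# avalanche of duration d is expected to obey S(t,d) = F(t/d) * d^b for a
# universal shape F; collapsing the empirical profiles onto a common curve
# and checking that the fitted scale factor chi(d) follows a power law in
# d is a scaling test that complements the size distribution.

#' Mean avalanche profiles per duration
#'
#' `S(t, d)` is the mean number of events in bin `t` (`t = 1..d`) over all
#' avalanches of duration `d`. Durations below `d_min` are skipped, since
#' very short avalanches have too few time points to define a shape
#' function, as are durations represented by fewer than `min_count`
#' avalanches.
#'
#' @param avs An `avalanche_set`.
#' @param d_min Minimum duration in bins (default 8).
#' @param min_count Minimum number of avalanches per retained duration
#'   (default 10).
#' @return Named list of numeric vectors, one per retained duration `d`
#'   (names are the durations); each vector has length `d` and sums to the
#'   mean size of duration-`d` avalanches. Empty list if no duration
#'   qualifies.
#' @export
mean_profiles <- function(avs, d_min = 8, min_count = 10) {
  stopifnot(inherits(avs, "avalanche_set"))
  durs <- avs$avalanches$duration
  keep_d <- sort(unique(durs[durs >= d_min]))
  out <- list()
  for (d in keep_d) {
    idx <- which(durs == d)
    if (length(idx) < min_count) next
    m <- do.call(rbind, avs$profiles[idx])
    out[[as.character(d)]] <- colMeans(m)
  }
  out
}

#' Scaling collapse of avalanche profiles
#'
#' Maps every profile `S(t, d)` onto the common rescaled time axis
#' `t/d` in (0, 1] (linear interpolation onto an `n_grid`-point grid) and
#' finds per-duration amplitude factors `chi(d)` that minimize the mean
#' absolute difference between the rescaled curves
#' `S(t/d, d) / chi(d)`. The smallest duration serves as the reference
#' (`chi = 1`); the remaining factors are found by coordinate descent,
#' each coordinate by golden-section search on `log(chi)`. The objective
#' is the mean absolute inter-curve distance over all pairs (set
#' `objective = "reference"` to measure distances to the reference curve
#' only).
#'
#' @param profiles Named list from [mean_profiles()] (>= 3 durations).
#' @param n_grid Number of points of the common `t/d` grid (default 50).
#' @param objective `"pairwise"` (default) or `"reference"`.
#' @param max_iter,tol Coordinate-descent stopping controls.
#' @return A `collapse_result`: list with `durations`, `chi`,
#'   `collapse_cost` (the minimized mean absolute inter-curve distance),
#'   `curves` (matrix of rescaled curves, durations in rows) and `grid`.
#' @export
shape_collapse <- function(profiles, n_grid = 50,
                           objective = c("pairwise", "reference"),
                           max_iter = 100, tol = 1e-10) {
  objective <- match.arg(objective)
  if (length(profiles) < 3) stop("need >= 3 distinct durations to collapse")
  durs <- as.numeric(names(profiles))
  o <- order(durs)
  durs <- durs[o]; profiles <- profiles[o]
  u <- seq_len(n_grid) / n_grid
  # anchor each profile at S = 0 for t/d -> 0 (the bin preceding an
  # avalanche is empty by definition), so that coarse and fine profiles
  # interpolate consistently near the start
  Y <- t(vapply(profiles, function(p) {
    d <- length(p)
    approx(x = 0:d / d, y = c(0, p), xout = u, rule = 2)$y
  }, numeric(n_grid)))
  k <- nrow(Y)
  # initialize from curve-amplitude ratios (already optimal for exact
  # scaling); coordinate descent on the non-smooth L1 objective then only
  # has to polish, which avoids poor local minima of an all-ones start
  chi <- unname(rowMeans(Y) / mean(Y[1, ]))
  chi[!is.finite(chi) | chi <= 0] <- 1
  chi <- chi / chi[1]

  cost_fun <- function(chi) {
    Z <- sweep(Y, 1, chi, "/")
    if (objective == "pairwise") {
      tot <- 0; np <- 0L
      for (i in 1:(k - 1)) for (j in (i + 1):k) {
        tot <- tot + mean(abs(Z[i, ] - Z[j, ])); np <- np + 1L
      }
      tot / np
    } else {
      mean(vapply(2:k, function(i) mean(abs(Z[i, ] - Z[1, ])), 0))
    }
  }

  prev <- cost_fun(chi)
  for (it in seq_len(max_iter)) {
    for (i in 2:k) {
      f <- function(lc) {
        ch <- chi; ch[i] <- exp(lc)
        cost_fun(ch)
      }
      opt <- optimize(f, lower = log(chi[i]) - 2, upper = log(chi[i]) + 2,
                      tol = 1e-9)
      chi[i] <- exp(opt$minimum)
    }
    cur <- cost_fun(chi)
    if (prev - cur < tol) break
    prev <- cur
  }
  res <- list(durations = durs, chi = chi, collapse_cost = prev,
              curves = sweep(Y, 1, chi, "/"), grid = u)
  class(res) <- "collapse_result"
  res
}

#' @export
print.collapse_result <- function(x, ...) {
  cat(sprintf("collapse_result: %d durations (d = %g..%g), cost %.4g\n",
              length(x$durations), min(x$durations), max(x$durations),
              x$collapse_cost))
  invisible(x)
}

#' Scaling exponent b from the collapse factors
#'
#' Least-squares slope of `log chi(d)` versus `log d` over a fit range.
#' If `chi(d) ~ d^b`, the system is close to criticality with critical
#' exponent `b`. Points outside the fit range are still predicted from
#' the fitted line; a breakdown flag is raised when any point falls below
#' the scaling line by more than `drop_tol` in natural log (the signature
#' of subsampling: the estimated scale factor drops for large `d`).
#'
#' @param collapse A `collapse_result`, or a numeric vector of `chi`
#'   values with durations in `d`.
#' @param d Durations (ignored when `collapse` is a `collapse_result`).
#' @param fit_range Length-2 numeric range of durations used for the fit
#'   (default: all).
#' @param drop_tol Log-residual tolerance before flagging breakdown
#'   (default 0.2, i.e. a drop by more than ~22% below the line).
#' @return List with `b`, `intercept`, `diagnostics` (data frame `d`,
#'   `chi`, `fitted`, `resid`, `in_range`), `breakdown` (logical), `rmse`
#'   (within the fit range).
#' @export
scaling_exponent <- function(collapse, d = NULL, fit_range = NULL,
                             drop_tol = 0.2) {
  if (inherits(collapse, "collapse_result")) {
    chi <- collapse$chi; d <- collapse$durations
  } else {
    chi <- as.numeric(collapse)
    if (is.null(d)) stop("durations d required")
  }
  if (length(chi) < 3) stop("need >= 3 chi values")
  if (any(chi <= 0)) stop("chi must be positive")
  if (is.null(fit_range)) fit_range <- range(d)
  inr <- d >= fit_range[1] & d <= fit_range[2]
  if (sum(inr) < 2) stop("fit range must contain >= 2 durations")
  fit <- lm(log(chi[inr]) ~ log(d[inr]))
  b <- unname(coef(fit)[2]); a <- unname(coef(fit)[1])
  pred <- a + b * log(d)
  resid <- log(chi) - pred
  rmse <- sqrt(mean(resid[inr]^2))
  list(b = b, intercept = a,
       diagnostics = data.frame(d = d, chi = chi, fitted = exp(pred),
                                resid = resid, in_range = inr),
       breakdown = any(resid < -max(drop_tol, 3 * rmse)),
       rmse = rmse)
}

#' Bootstrap percentile intervals for the collapse factors
#'
#' Resamples avalanches (within each duration) with replacement, recomputes
#' the mean profiles and the collapse, and reports per-duration percentile
#' intervals for `chi(d)` (default the 25th and 75th percentiles).
#'
#' @param avs An `avalanche_set`.
#' @param n_boot Number of bootstrap replicates (default 50).
#' @param probs Percentiles to report (default `c(0.25, 0.75)`).
#' @param seed Optional seed.
#' @param ... Passed to [mean_profiles()] and [shape_collapse()].
#' @return Data frame with `d`, `chi`, and one column per percentile.
#' @export
collapse_bootstrap <- function(avs, n_boot = 50, probs = c(0.25, 0.75),
                               seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  dots <- list(...)
  mp_args <- dots[names(dots) %in% c("d_min", "min_count")]
  sc_args <- dots[names(dots) %in% c("n_grid", "objective")]
  base_prof <- do.call(mean_profiles, c(list(avs), mp_args))
  base <- do.call(shape_collapse, c(list(base_prof), sc_args))
  durs <- base$durations
  boot <- matrix(NA_real_, n_boot, length(durs))
  idx_by_d <- lapply(durs, function(d) which(avs$avalanches$duration == d))
  for (b in seq_len(n_boot)) {
    prof <- list()
    for (j in seq_along(durs)) {
      idx <- idx_by_d[[j]]
      take <- sample(idx, length(idx), replace = TRUE)
      prof[[as.character(durs[j])]] <-
        colMeans(do.call(rbind, avs$profiles[take]))
    }
    cb <- tryCatch(do.call(shape_collapse, c(list(prof), sc_args)),
                   error = function(e) NULL)
    if (!is.null(cb)) boot[b, ] <- cb$chi
  }
  qs <- apply(boot, 2, quantile, probs = probs, na.rm = TRUE)
  out <- data.frame(d = durs, chi = base$chi)
  for (i in seq_along(probs)) {
    out[[sprintf("q%02d", round(100 * probs[i]))]] <- qs[i, ]
  }
  out
}
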