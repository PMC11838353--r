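#' Robust two-pass standardization of an IBD rate track
#'
#' Real scans contain loci under strong selection (e.g. *LCT* in European
#' ancestry samples) whose extreme rates would inflate the null mean and
#' standard deviation. Standardization therefore proceeds in two passes.
#' First an initial outlier threshold is computed as the genome-wide median
#' rate plus four standard deviations (plain sample SD, denominator M-1, over
#' all rates). Second, a revised mean and SD are computed over the rates at
#' or below that threshold, and every position — outliers included — is
#' standardized with the revised moments.
#'
#' @param track A `rate_track` from [compute_ibd_rates()].
#' @return A `z_track`: list with `grid`, `z` (standardized values), `rate`,
#'   `outlier` (logical, rate above the initial threshold), and `moments`
#'   (list `initial_threshold`, `mu_hat`, `sigma_hat`, `n_excluded`).
#' @export
robust_standardize <- function(track) {
  stopifnot(inherits(track, "rate_track"))
  r <- track$rate
  if (length(r) < 2) stop("degenerate-track error: fewer than 2 grid points")
  initial_threshold <- stats::median(r) + 4 * stats::sd(r)
  keep <- r <= initial_threshold
  mu_hat <- mean(r[keep])
  sigma_hat <- stats::sd(r[keep])
  if (!is.finite(sigma_hat) || sigma_hat == 0)
    stop("degenerate-track error: zero variance among non-outlier rates")
  structure(list(grid = track$grid,
                 z = (r - mu_hat) / sigma_hat,
                 rate = r,
                 outlier = !keep,
                 moments = list(initial_threshold = initial_threshold,
                                mu_hat = mu_hat, sigma_hat = sigma_hat,
                                n_excluded = sum(!keep))),
            class = "z_track")
}

#' @export
print.z_track <- function(x, ...) {
  cat("z_track: M =", x$grid$M, "positions,",
      x$moments$n_excluded, "outlier(s) excluded from moments\n",
      " mu_hat =", format(x$moments$mu_hat, digits = 4),
      ", sigma_hat =", format(x$moments$sigma_hat, digits = 4),
      ", max z =", format(max(x$z), digits = 4), "\n")
  invisible(x)
}

#' @export
as.data.frame.z_track <- function(x, ...) {
  cbind(x$grid$points, rate = x$rate, z = x$z, outlier = x$outlier)
}

#' Autocovariance of the standardized track at multiples of the grid spacing
#'
#' Estimates the autocovariance of the standardized rates at genetic lags
#' k * delta for k = 1, 2, ... up to `max_lag_cm`. Pairs are formed within
#' chromosomes only and pooled across chromosomes; pairs in which either
#' member is an outlier (above the initial threshold) are excluded. Each
#' estimate is the mean of (z_m - zbar)(z_{m+k} - zbar) over the retained
#' pairs, with zbar the mean of the included (non-outlier) z values and the
#' pair count as denominator.
#'
#' @param ztrack A `z_track`.
#' @param max_lag_cm Maximum genetic lag in cM (default 4.0).
#' @param center If `TRUE` (default), center by the included-points mean;
#'   if `FALSE`, assume mean zero (the two agree after [robust_standardize()],
#'   whose revised moments make the included mean exactly zero).
#' @return List with `lags` (in Morgans) and `covariances`.
#' @export
autocovariance_curve <- function(ztrack, max_lag_cm = 4, center = TRUE) {
  stopifnot(inherits(ztrack, "z_track"))
  d <- ztrack$grid$delta_cm
  K <- floor(max_lag_cm / d + 1e-9)
  if (K < 1) stop("estimation error: max_lag_cm below the grid spacing")
  zbar <- if (center) mean(ztrack$z[!ztrack$outlier]) else 0
  zc <- ztrack$z - zbar
  chrom <- ztrack$grid$points$chrom
  zs <- split(zc, chrom)
  oks <- split(!ztrack$outlier, chrom)
  sums <- numeric(K)
  counts <- numeric(K)
  for (i in seq_along(zs)) {
    z <- zs[[i]]
    ok <- oks[[i]]
    n <- length(z)
    for (k in seq_len(min(K, n - 1L))) {
      use <- ok[1:(n - k)] & ok[(k + 1):n]
      sums[k] <- sums[k] + sum(z[1:(n - k)][use] * z[(k + 1):n][use])
      counts[k] <- counts[k] + sum(use)
    }
  }
  if (counts[1] == 0) stop("estimation error: no valid pairs at lag 1")
  valid <- counts > 0
  list(lags = (seq_len(K) * d / 100)[valid],
       covariances = (sums / counts)[valid])
}

#' Fit the exponential autocorrelation decay parameter
#'
#' Under the Ornstein-Uhlenbeck model the autocovariance at genetic lag x
#' (Morgans) is exp(-theta * x). The decay parameter is estimated by ordinary
#' least squares of log(covariance) on lag through the origin:
#' theta_hat = -sum(x * log c) / sum(x^2). Non-positive covariance estimates
#' carry no log-scale information and are dropped before fitting.
#'
#' @param lags Genetic lags in Morgans (strictly increasing).
#' @param covariances Autocovariance estimates at those lags.
#' @return A `theta_fit`: list with `theta_hat` (per Morgan), `lags`,
#'   `covariances` (the positive pairs used), `n_lags_used`.
#' @examples
#' fit_theta(lags = c(0.01, 0.02, 0.03),
#'           covariances = exp(-60 * c(0.01, 0.02, 0.03)))$theta_hat  # 60
#' @export
fit_theta <- function(lags, covariances) {
  stopifnot(length(lags) == length(covariances))
  pos <- covariances > 0
  if (sum(pos) < 3)
    stop("estimation error: fewer than 3 positive autocovariance estimates")
  x <- lags[pos]
  y <- log(covariances[pos])
  theta_hat <- -sum(x * y) / sum(x^2)
  if (!is.finite(theta_hat) || theta_hat <= 0)
    stop("estimation error: non-positive decay estimate; ",
         "the track shows no exponential correlation decay")
  structure(list(theta_hat = theta_hat, lags = x,
                 covariances = covariances[pos], n_lags_used = sum(pos)),
            class = "theta_fit")
}

#' @export
print.theta_fit <- function(x, ...) {
  cat("theta_fit: theta_hat =", format(x$theta_hat, digits = 5),
      "per Morgan (", x$n_lags_used, "lags )\n")
  invisible(x)
}

#' Estimate the decay parameter directly from a standardized track
#'
#' Convenience wrapper: [autocovariance_curve()] followed by [fit_theta()].
#'
#' @inheritParams autocovariance_curve
#' @return A `theta_fit`.
#' @export
estimate_theta <- function(ztrack, max_lag_cm = 4, center = TRUE) {
  ac <- autocovariance_curve(ztrack, max_lag_cm = max_lag_cm, center = center)
  fit_theta(ac$lags, ac$covariances)
}
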