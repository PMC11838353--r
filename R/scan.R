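#' Per-position hypothesis test
#'
#' Rejects the null of no excess IBD sharing at position m iff the
#' standardized rate strictly exceeds the multiple-testing quantile
#' (equality fails to reject).
#'
#' @param ztrack A `z_track`.
#' @param z_star Multiple-testing quantile (e.g. from [analytical_quantile()]).
#' @return Logical vector of rejections, one per grid point.
#' @export
test_positions <- function(ztrack, z_star) {
  stopifnot(inherits(ztrack, "z_track"), is.numeric(z_star), length(z_star) == 1)
  ztrack$z > z_star
}

#' Call significant regions
#'
#' Groups maximal runs of consecutive rejected positions within a chromosome
#' into candidate regions. A region's span is the genetic distance between
#' its first and last rejected grid points, (run length - 1) * Delta; only
#' regions spanning at least `min_span_cm` are reported. The peak is the
#' position with the highest IBD rate in the run, and its p value is the
#' upper normal tail at the peak's standardized value, flagged as underflow
#' when it is below the smallest positive double.
#'
#' @param ztrack A `z_track`.
#' @param calls Logical rejections from [test_positions()].
#' @param min_span_cm Minimum reported region span in cM (default 0.50).
#' @return Data.frame with one row per region: `chrom`, `start_cm`, `end_cm`,
#'   `span_cm`, `start_bp`, `end_bp`, `peak_cm`, `peak_bp`, `peak_rate`,
#'   `peak_z`, `p_value`, `underflow`.
#' @export
call_regions <- function(ztrack, calls, min_span_cm = 0.5) {
  stopifnot(inherits(ztrack, "z_track"), length(calls) == ztrack$grid$M)
  pts <- ztrack$grid$points
  d <- ztrack$grid$delta_cm
  out <- list()
  for (chrom in unique(pts$chrom)) {
    sel <- pts$chrom == chrom
    cc <- calls[sel]
    if (!any(cc)) next
    r <- rle(cc)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (i in which(r$values)) {
      span <- (r$lengths[i] - 1L) * d
      if (span < min_span_cm) next
      idx <- which(sel)[starts[i]:ends[i]]
      peak <- idx[which.max(ztrack$rate[idx])]
      p <- stats::pnorm(ztrack$z[peak], lower.tail = FALSE)
      out[[length(out) + 1L]] <- data.frame(
        chrom = chrom,
        start_cm = pts$cm[idx[1]], end_cm = pts$cm[idx[length(idx)]],
        span_cm = span,
        start_bp = pts$bp[idx[1]], end_bp = pts$bp[idx[length(idx)]],
        peak_cm = pts$cm[peak], peak_bp = pts$bp[peak],
        peak_rate = ztrack$rate[peak], peak_z = ztrack$z[peak],
        p_value = p, underflow = p == 0)
    }
  }
  if (!length(out))
    return(data.frame(chrom = character(), start_cm = numeric(),
                      end_cm = numeric(), span_cm = numeric(),
                      start_bp = numeric(), end_bp = numeric(),
                      peak_cm = numeric(), peak_bp = numeric(),
                      peak_rate = numeric(), peak_z = numeric(),
                      p_value = numeric(), underflow = logical()))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(-res$peak_rate), , drop = FALSE]
}

#' Format a region report in the publication layout
#'
#' Renders [call_regions()] output with positions in Mb and an explicit
#' `"underflow"` marker for p values too small for double precision.
#'
#' @param regions Data.frame from [call_regions()].
#' @param dataset Optional dataset label for the first column.
#' @return Data.frame with columns `dataset`, `chrom`, `max_rate`,
#'   `region_size_cm`, `position_mb`, `span_mb`, `p_value` (character).
#' @export
format_regions <- function(regions, dataset = "") {
  data.frame(
    dataset = dataset,
    chrom = regions$chrom,
    max_rate = regions$peak_rate,
    region_size_cm = regions$span_cm,
    position_mb = round(regions$peak_bp / 1e6, 2),
    span_mb = sprintf("%.2f-%.2f", regions$start_bp / 1e6, regions$end_bp / 1e6),
    p_value = ifelse(regions$underflow, "underflow",
                     sprintf("%.3g", regions$p_value)))
}

#' Max-min scan statistic
#'
#' Diagnostic robust to isolated single-point exceedances: replace each
#' standardized value by the minimum over a window of `window` consecutive
#' statistics centered on it (within-chromosome neighbors only at chromosome
#' ends), then take the genome-wide maximum. `window = 1` is the plain
#' maximum; `window = 3` suppresses spikes not flanked by elevated neighbors.
#'
#' @param ztrack A `z_track`.
#' @param window Odd positive window size (1 and 3 are the standard choices).
#' @return The max-min statistic (scalar).
#' @export
max_min_statistic <- function(ztrack, window = 1) {
  stopifnot(inherits(ztrack, "z_track"))
  if (window < 1 || window %% 2 == 0)
    stop("domain error: window must be odd and >= 1")
  half <- (window - 1L) / 2L
  best <- -Inf
  for (z in split(ztrack$z, ztrack$grid$points$chrom)) {
    n <- length(z)
    mins <- z
    if (half > 0) {
      for (s in seq_len(half)) {
        lead <- c(z[-seq_len(s)], rep(Inf, s))
        lag <- c(rep(Inf, s), z[seq_len(n - s)])
        mins <- pmin(mins, lead, lag)
      }
    }
    best <- max(best, mins)
  }
  best
}

#' Count non-overlapping windows containing a significant result
#'
#' Partitions each chromosome into consecutive windows of `window_cm`,
#' anchored at the chromosome's first grid point, and counts the windows
#' containing at least one rejection. On a correlated rate process a single
#' family-wise error typically produces several adjacent rejections; this
#' diagnostic shows whether they aggregate into one window or scatter.
#'
#' @param calls Logical rejections from [test_positions()].
#' @param grid The `scan_grid` the calls were computed on.
#' @param window_cm Window size in cM (>= grid spacing).
#' @return Integer count of windows with at least one rejection.
#' @export
count_significant_windows <- function(calls, grid, window_cm) {
  stopifnot(inherits(grid, "scan_grid"), length(calls) == grid$M,
            window_cm >= grid$delta_cm)
  total <- 0L
  pts <- grid$points
  for (chrom in unique(pts$chrom)) {
    sel <- pts$chrom == chrom
    cm <- pts$cm[sel]
    cc <- calls[sel]
    if (!any(cc)) next
    win <- floor((cm[cc] - cm[1]) / window_cm + 1e-9)
    total <- total + length(unique(win))
  }
  total
}

#' Plot a genome scan with its thresholds
#'
#' Draws IBD rates against cumulative genetic position, alternating shading
#' by chromosome, with horizontal lines for the genome-wide median, the
#' heuristic median-plus-four-SD threshold, and any calibrated thresholds
#' supplied (analytical, simulation), mapped back to the rate scale via the
#' revised moments.
#'
#' @param ztrack A `z_track`.
#' @param thresholds Named list of `threshold_result` objects (optional).
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly, `NULL`.
#' @export
plot_scan <- function(ztrack, thresholds = list(), ...) {
  stopifnot(inherits(ztrack, "z_track"))
  pts <- ztrack$grid$points
  chroms <- unique(pts$chrom)
  offs <- c(0, cumsum(vapply(chroms, function(ch) {
    cm <- pts$cm[pts$chrom == ch]
    diff(range(cm)) + 5
  }, numeric(1))))
  x <- numeric(nrow(pts))
  for (i in seq_along(chroms)) {
    sel <- pts$chrom == chroms[i]
    x[sel] <- pts$cm[sel] - min(pts$cm[sel]) + offs[i]
  }
  graphics::plot(x, ztrack$rate, type = "l", xlab = "genetic position (cM)",
                 ylab = "IBD rate", col = "grey30", ...)
  med <- stats::median(ztrack$rate)
  graphics::abline(h = med, col = "blue", lty = 2)
  graphics::abline(h = med + 4 * stats::sd(ztrack$rate), col = "orange", lty = 2)
  cols <- c(analytical = "forestgreen", simulation = "red", bonferroni = "purple")
  for (nm in names(thresholds)) {
    th <- thresholds[[nm]]
    rate_thr <- ztrack$moments$mu_hat + th$z_star * ztrack$moments$sigma_hat
    graphics::abline(h = rate_thr,
                     col = if (nm %in% names(cols)) cols[[nm]] else "black")
  }
  invisible(NULL)
}
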