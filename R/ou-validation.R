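#' Simulate an Ornstein-Uhlenbeck null genome
#'
#' Draws one standardized-rate track under the null model: an independent
#' discretely observed Ornstein-Uhlenbeck chain per chromosome, each started
#' at N(0, 1), with transitions as in [simulate_ou_chain()]. The synthetic
#' grid assumes 1 cM per Mb for the bp column.
#'
#' @param theta Decay parameter per Morgan.
#' @param chrom_lengths_cm Chromosome genetic lengths in cM.
#' @param delta_cm Grid spacing in cM.
#' @param stationary Passed to [simulate_ou_chain()].
#' @return A `z_track` (with `rate` set to the z values and no outliers).
#'   Uses the current RNG state.
#' @export
simulate_ou_genome <- function(theta, chrom_lengths_cm, delta_cm,
                               stationary = FALSE) {
  stopifnot(all(chrom_lengths_cm > 0), delta_cm > 0, theta > 0)
  chroms <- as.character(seq_along(chrom_lengths_cm))
  pts <- vector("list", length(chroms))
  zs <- vector("list", length(chroms))
  for (i in seq_along(chroms)) {
    n <- as.integer(floor(chrom_lengths_cm[i] / delta_cm)) + 1L
    cm <- (seq_len(n) - 1L) * delta_cm
    pts[[i]] <- data.frame(chrom = chroms[i], cm = cm, bp = cm * 1e6)
    zs[[i]] <- simulate_ou_chain(n, theta, delta_cm / 100,
                                 stationary = stationary)
  }
  points <- do.call(rbind, pts)
  z <- unlist(zs, use.names = FALSE)
  grid <- structure(list(points = points, delta_cm = delta_cm, trim_cm = 0,
                         M = nrow(points),
                         L_morgans = sum(chrom_lengths_cm) / 100,
                         C = length(chroms)),
                    class = "scan_grid")
  structure(list(grid = grid, z = z, rate = z,
                 outlier = rep(FALSE, length(z)),
                 moments = list(initial_threshold = Inf, mu_hat = 0,
                                sigma_hat = 1, n_excluded = 0L)),
            class = "z_track")
}

#' Empirical family-wise error rate on Ornstein-Uhlenbeck nulls
#'
#' Validation harness for threshold calibration: simulates `n_replicates`
#' null genomes from the Ornstein-Uhlenbeck model, runs each through the
#' scan's own two-pass standardization (the test always standardizes by
#' moments estimated from the scanned genome itself, never by the generative
#' truth), and reports, per threshold method, the fraction of genomes with at
#' least one position exceeding the method's quantile. With
#' `reestimate_theta = FALSE` (default) thresholds are computed once from the
#' true theta; with `TRUE`, theta is re-estimated from each simulated genome
#' and analytical/simulation thresholds are recomputed per replicate.
#'
#' @param n_replicates Number of simulated genomes (>= 100).
#' @param theta True decay parameter per Morgan.
#' @param chrom_lengths_cm Chromosome lengths in cM.
#' @param delta_cm Grid spacing in cM.
#' @param alpha_fw Family-wise significance level.
#' @param methods Subset of `c("analytical", "simulation", "bonferroni")`.
#' @param J Simulation count for the simulation-based threshold.
#' @param seed Optional integer seed for the whole experiment.
#' @param reestimate_theta Re-estimate theta from each simulated genome.
#' @return An `fwer_report`: list with `fwer` (named fractions), `n_reject`,
#'   `se` (binomial standard errors), `thresholds` (the `threshold_result`s
#'   for the fixed-theta mode), `n_replicates`, `theta`, `alpha_fw`, `seed`.
#' @export
run_fwer_experiment <- function(n_replicates, theta, chrom_lengths_cm,
                                delta_cm, alpha_fw = 0.05,
                                methods = c("analytical", "simulation",
                                            "bonferroni"),
                                J = 2000, seed = NULL,
                                reestimate_theta = FALSE) {
  methods <- match.arg(methods, several.ok = TRUE)
  if (n_replicates < 100)
    stop("configuration error: need at least 100 replicates")
  if (alpha_fw <= 0 || alpha_fw >= 0.5)
    stop("configuration error: alpha_fw must be in (0, 0.5)")
  if (!is.null(seed)) set.seed(seed)
  L <- sum(chrom_lengths_cm) / 100
  C <- length(chrom_lengths_cm)
  delta_m <- delta_cm / 100
  M <- sum(floor(chrom_lengths_cm / delta_cm)) + C

  thresholds <- list()
  if (!reestimate_theta) {
    for (m in methods) {
      thresholds[[m]] <- switch(m,
        analytical = analytical_quantile(alpha_fw, theta, L, C, delta_m),
        simulation = simulation_quantile(alpha_fw, theta, L, delta_m, J = J),
        bonferroni = bonferroni_quantile(alpha_fw, M))
    }
  }

  n_reject <- stats::setNames(integer(length(methods)), methods)
  for (r in seq_len(n_replicates)) {
    raw <- simulate_ou_genome(theta, chrom_lengths_cm, delta_cm)
    track <- structure(list(grid = raw$grid, rate = raw$z, count = raw$z,
                            min_cm = NA_real_, f_n = NA_real_,
                            n_skipped = 0L),
                       class = "rate_track")
    genome <- robust_standardize(track)
    th_hat <- if (reestimate_theta)
      estimate_theta(genome)$theta_hat else theta
    for (m in methods) {
      z_star <- if (reestimate_theta) {
        switch(m,
          analytical = analytical_quantile(alpha_fw, th_hat, L, C, delta_m)$z_star,
          simulation = simulation_quantile(alpha_fw, th_hat, L, delta_m,
                                           J = J)$z_star,
          bonferroni = bonferroni_quantile(alpha_fw, M)$z_star)
      } else thresholds[[m]]$z_star
      if (any(genome$z > z_star)) n_reject[m] <- n_reject[m] + 1L
    }
  }
  fwer <- n_reject / n_replicates
  structure(list(fwer = fwer, n_reject = n_reject,
                 se = sqrt(fwer * (1 - fwer) / n_replicates),
                 thresholds = thresholds, n_replicates = n_replicates,
                 theta = theta, alpha_fw = alpha_fw,
                 seed = if (is.null(seed)) NA_integer_ else as.integer(seed)),
            class = "fwer_report")
}

#' @export
print.fwer_report <- function(x, ...) {
  cat("fwer_report:", x$n_replicates, "OU null genomes, theta =", x$theta,
      ", family-wise level", x$alpha_fw, "\n")
  for (m in names(x$fwer))
    cat(sprintf("  %-11s FWER = %.3f (SE %.3f)\n", m, x$fwer[m], x$se[m]))
  invisible(x)
}

#' Write a synthetic IBD segment file
#'
#' End-to-end test fixture: draws segments with midpoints uniform along the
#' genome (chromosomes weighted by genetic length), genetic lengths from a
#' shifted exponential with mean `length_scale_cm` (shifted by the detection
#' threshold `min_cm`, so every written segment is detectable), and haplotype
#' pairs uniform without replacement (for diploids, pairs within one
#' individual are redrawn). The number of segments is chosen so the expected
#' IBD rate at an interior position is `mean_rate`. This generator exercises
#' the scan plumbing; it does not emulate coalescent segment clustering.
#'
#' @param path Output path for the 8-column tab-separated segment file.
#' @param n_samples Number of individuals.
#' @param ploidy `"diploid"` or `"haploid"`.
#' @param chrom_lengths_cm Chromosome genetic lengths in cM.
#' @param map Optional `genetic_map`; default assumes 1 cM per Mb.
#' @param mean_rate Target mean IBD rate at interior positions.
#' @param length_scale_cm Mean segment genetic length in cM (> `min_cm`).
#' @param min_cm Detection threshold in cM.
#' @param seed Optional integer seed.
#' @return Invisibly, the `genetic_map` used (handy when it was synthesized).
#' @export
synthetic_segment_file <- function(path, n_samples,
                                   ploidy = c("diploid", "haploid"),
                                   chrom_lengths_cm, map = NULL,
                                   mean_rate, length_scale_cm, min_cm = 2,
                                   seed = NULL) {
  ploidy <- match.arg(ploidy)
  if (length_scale_cm <= min_cm)
    stop("configuration error: length_scale_cm must exceed the detection threshold")
  if (mean_rate < 0 || mean_rate > 1)
    stop("configuration error: mean_rate must be in [0, 1]")
  if (!is.null(seed)) set.seed(seed)
  chroms <- as.character(seq_along(chrom_lengths_cm))
  if (is.null(map)) {
    map <- genetic_map(do.call(rbind, lapply(seq_along(chroms), function(i)
      data.frame(chrom = chroms[i], bp = c(0, chrom_lengths_cm[i] * 1e6),
                 cm = c(0, chrom_lengths_cm[i])))))
  }
  f_n <- pair_count(n_samples, ploidy)
  G <- sum(chrom_lengths_cm)
  S <- round(mean_rate * f_n * G / length_scale_cm)
  n_hap <- if (ploidy == "diploid") 2L * n_samples else n_samples
  rows <- vector("list", S)
  if (S > 0) {
    ci <- sample.int(length(chroms), S, replace = TRUE,
                     prob = chrom_lengths_cm / G)
    mid <- stats::runif(S) * chrom_lengths_cm[ci]
    len <- min_cm + stats::rexp(S, rate = 1 / (length_scale_cm - min_cm))
    s_cm <- pmax(0, mid - len / 2)
    e_cm <- pmin(chrom_lengths_cm[ci], mid + len / 2)
    for (i in seq_len(S)) {
      repeat {
        hp <- sample.int(n_hap, 2L)
        if (ploidy == "haploid" ||
            ((hp[1] - 1L) %/% 2L) != ((hp[2] - 1L) %/% 2L)) break
      }
      id <- (hp - 1L) %/% (if (ploidy == "diploid") 2L else 1L) + 1L
      hapix <- if (ploidy == "diploid") (hp - 1L) %% 2L + 1L else c(1L, 1L)
      chrom <- chroms[ci[i]]
      rows[[i]] <- data.frame(
        sample1 = paste0("s", id[1]), hap1 = hapix[1],
        sample2 = paste0("s", id[2]), hap2 = hapix[2],
        chrom = chrom,
        start_bp = round(interpolate_map(map, chrom, s_cm[i], from = "cm")),
        end_bp = round(interpolate_map(map, chrom, e_cm[i], from = "cm")),
        length_cm = e_cm[i] - s_cm[i])
    }
  }
  df <- if (S > 0) do.call(rbind, rows) else
    data.frame(sample1 = character(), hap1 = integer(), sample2 = character(),
               hap2 = integer(), chrom = character(), start_bp = numeric(),
               end_bp = numeric(), length_cm = numeric())
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(map)
}
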