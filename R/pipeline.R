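#' Run the full IBD-rate selection scan
#'
#' Convenience pipeline from a detected-segment file and a recombination map
#' to a region report: builds the testing grid, computes IBD rates, robustly
#' standardizes them, estimates the autocorrelation decay parameter, derives
#' the genome-wide significance threshold by the requested method, and calls
#' contiguous significant regions.
#'
#' @param segments_path Path to an 8-column `.seg` file.
#' @param map_path Path to a recombination map.
#' @param n_samples Number of individuals.
#' @param ploidy `"diploid"` or `"haploid"`.
#' @param min_cm IBD segment detection threshold in cM (2.0 or 3.0 typical).
#' @param step_cm Test spacing in cM.
#' @param trim_cm Grid trim per chromosome end; defaults to `min_cm`.
#' @param alpha_fw Family-wise significance level.
#' @param method Threshold method: `"analytical"`, `"simulation"`, or
#'   `"bonferroni"`.
#' @param min_region_cm Minimum reported region span in cM.
#' @param map_dialect Passed to [read_genetic_map()].
#' @param J Simulation count (simulation method only).
#' @param seed Optional seed (simulation method only).
#' @return An `ibd_scan` result: list with `ztrack`, `theta` (a `theta_fit`),
#'   `threshold` (a `threshold_result`), `heuristic`, `calls`, `regions`.
#' @export
ibd_scan <- function(segments_path, map_path, n_samples,
                     ploidy = c("diploid", "haploid"),
                     min_cm = 2, step_cm = 0.02, trim_cm = NULL,
                     alpha_fw = 0.05,
                     method = c("analytical", "simulation", "bonferroni"),
                     min_region_cm = 0.5, map_dialect = "plink",
                     J = 2000, seed = NULL) {
  ploidy <- match.arg(ploidy)
  method <- match.arg(method)
  if (is.null(trim_cm)) trim_cm <- min_cm
  map <- read_genetic_map(map_path, dialect = map_dialect)
  grid <- build_grid(map, delta_cm = step_cm, trim_cm = trim_cm)
  segs <- read_ibd_segments(segments_path, min_cm = min_cm)
  track <- compute_ibd_rates(segs, grid, map, n = n_samples, ploidy = ploidy,
                             min_cm = min_cm)
  ztrack <- robust_standardize(track)
  theta <- estimate_theta(ztrack)
  if (theta$theta_hat <= 20 && method == "analytical")
    message("theta_hat = ", round(theta$theta_hat, 2),
            " <= 20: the simulation-based threshold is recommended ",
            "over the analytical approximation at low decay rates")
  threshold <- switch(method,
    analytical = analytical_quantile(alpha_fw, theta$theta_hat,
                                     grid$L_morgans, grid$C, step_cm / 100),
    simulation = simulation_quantile(alpha_fw, theta$theta_hat,
                                     grid$L_morgans, step_cm / 100,
                                     J = J, seed = seed),
    bonferroni = bonferroni_quantile(alpha_fw, grid$M))
  calls <- test_positions(ztrack, threshold$z_star)
  regions <- call_regions(ztrack, calls, min_span_cm = min_region_cm)
  structure(list(ztrack = ztrack, theta = theta, threshold = threshold,
                 heuristic = heuristic_threshold(track),
                 calls = calls, regions = regions),
            class = "ibd_scan")
}

#' @export
print.ibd_scan <- function(x, ...) {
  cat("ibd_scan:", x$ztrack$grid$M, "tests,",
      sum(x$calls), "rejection(s),", nrow(x$regions), "region(s)\n")
  print(x$theta)
  print(x$threshold)
  if (nrow(x$regions)) {
    cat("regions:\n")
    print(format_regions(x$regions), row.names = FALSE)
  }
  invisible(x)
}

#' Serialize a threshold or theta fit to JSON
#'
#' @param x A `threshold_result`, `theta_fit`, or `fwer_report`.
#' @param path Output path.
#' @return Invisibly, the JSON string written.
#' @export
write_result_json <- function(x, path) {
  obj <- unclass(x)
  obj$thresholds <- NULL  # nested threshold objects flatten poorly; drop
  txt <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, null = "null",
                          na = "null")
  writeLines(txt, path)
  invisible(txt)
}
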