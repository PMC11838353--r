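#' Read detected IBD segments
#'
#' Parses the 8-column tab-separated segment dialect written by hap-ibd and
#' ibd-ends: sample1, haplotype1 (1|2), sample2, haplotype2, chromosome,
#' start bp, end bp, genetic length in cM. Gzip-compressed files are read
#' transparently. Segments shorter than the detection threshold `min_cm` are
#' dropped; within-individual pairs (both haplotypes of the same sample) are
#' retained but flagged in the `self_pair` column so that rate computation can
#' exclude them consistently with the diploid pair count.
#'
#' @param path Path to a `.seg` (optionally `.gz`) file.
#' @param min_cm Minimum segment genetic length in cM (inclusive).
#' @return A data.frame with columns `sample1`, `hap1`, `sample2`, `hap2`,
#'   `chrom`, `start_bp`, `end_bp`, `length_cm`, `self_pair`.
#' @export
read_ibd_segments <- function(path, min_cm = 0) {
  if (!file.exists(path)) stop("segment file not found: ", path)
  raw <- tryCatch(
    utils::read.table(path, header = FALSE, sep = "\t",
                      stringsAsFactors = FALSE,
                      col.names = c("sample1", "hap1", "sample2", "hap2",
                                    "chrom", "start_bp", "end_bp", "length_cm"),
                      colClasses = c("character", "integer", "character",
                                     "integer", "character", "numeric",
                                     "numeric", "numeric")),
    error = function(e) {
      if (length(readLines(path, n = 1L)) == 0L) return(NULL)
      stop("parse error in segment file ", path, ": ", conditionMessage(e))
    })
  if (is.null(raw) || nrow(raw) == 0L) {
    raw <- data.frame(sample1 = character(), hap1 = integer(),
                      sample2 = character(), hap2 = integer(),
                      chrom = character(), start_bp = numeric(),
                      end_bp = numeric(), length_cm = numeric())
  }
  bad <- which(!(raw$start_bp < raw$end_bp) | !(raw$length_cm > 0))
  if (length(bad))
    stop("parse error: non-positive segment span at line ", bad[1])
  raw$self_pair <- raw$sample1 == raw$sample2
  raw[raw$length_cm >= min_cm, , drop = FALSE]
}

#' Number of haplotype pairs tested
#'
#' The denominator f(n) of the IBD rate: the number of eligible haplotype
#' pairs among n individuals. For diploids f(n) = 2n(2n-1)/2 - 2n, which
#' excludes within-individual pairs; for haploids f(n) = n^2.
#'
#' @param n Number of individuals (>= 2).
#' @param ploidy `"diploid"` or `"haploid"`.
#' @return Integer-valued pair count.
#' @examples
#' pair_count(10, "diploid")  # 170
#' pair_count(4, "haploid")   # 16
#' @export
pair_count <- function(n, ploidy = c("diploid", "haploid")) {
  ploidy <- match.arg(ploidy)
  if (!is.numeric(n) || n < 2) stop("domain error: need n >= 2 individuals")
  if (ploidy == "diploid") 2 * n * (2 * n - 1) / 2 - 2 * n else n^2
}

#' Compute the IBD rate track on a scan grid
#'
#' For every focal position m on the grid, the IBD rate is the number of
#' retained segments whose genetic span covers the position (closed interval:
#' a segment covers p iff start_cM <= p <= end_cM), divided by the haplotype
#' pair count f(n). Segment bp endpoints are converted to cM by linear
#' interpolation on the map; endpoints beyond the mapped range are clamped to
#' the map ends. Coverage is accumulated with a difference array, one pass
#' over the segments.
#'
#' For diploid data, within-individual (homozygosity-by-descent) pairs are
#' excluded from the numerator, mirroring their exclusion from f(n).
#'
#' @param segments Data.frame from [read_ibd_segments()].
#' @param grid A `scan_grid` from [build_grid()].
#' @param map The `genetic_map` used to build the grid.
#' @param n Number of individuals.
#' @param ploidy `"diploid"` or `"haploid"`.
#' @param min_cm Segment length threshold in cM; segments below it are ignored.
#' @return A `rate_track`: list with `grid`, `rate` (one value per grid
#'   point), `count` (raw coverage counts), `min_cm`, `f_n`, `n_skipped`
#'   (segments on chromosomes absent from the grid).
#' @export
compute_ibd_rates <- function(segments, grid, map, n,
                              ploidy = c("diploid", "haploid"), min_cm = 0) {
  ploidy <- match.arg(ploidy)
  stopifnot(inherits(grid, "scan_grid"), inherits(map, "genetic_map"))
  f_n <- pair_count(n, ploidy)
  keep <- segments$length_cm >= min_cm
  if (ploidy == "diploid" && nrow(segments))
    keep <- keep & !segments$self_pair
  segments <- segments[keep, , drop = FALSE]

  chroms <- unique(grid$points$chrom)
  known <- segments$chrom %in% chroms
  n_skipped <- sum(!known)
  if (n_skipped > 0) {
    warning(n_skipped, " segment(s) on chromosomes absent from the grid were skipped")
    segments <- segments[known, , drop = FALSE]
  }

  count <- numeric(grid$M)
  offset <- 0L
  for (chrom in chroms) {
    gcm <- grid$points$cm[grid$points$chrom == chrom]
    npts <- length(gcm)
    seg <- segments[segments$chrom == chrom, , drop = FALSE]
    if (nrow(seg)) {
      tab <- map[[chrom]]
      s_cm <- interpolate_map(map, chrom,
                              pmin(pmax(seg$start_bp, tab$bp[1]), tab$bp[nrow(tab)]),
                              from = "bp")
      e_cm <- interpolate_map(map, chrom,
                              pmin(pmax(seg$end_bp, tab$bp[1]), tab$bp[nrow(tab)]),
                              from = "bp")
      g0 <- gcm[1]
      d <- grid$delta_cm
      lo <- pmax(1L, as.integer(ceiling((s_cm - g0) / d - 1e-9)) + 1L)
      hi <- pmin(npts, as.integer(floor((e_cm - g0) / d + 1e-9)) + 1L)
      ok <- lo <= hi
      if (any(ok)) {
        diffarr <- numeric(npts + 1L)
        tl <- tabulate(lo[ok], nbins = npts)
        th <- tabulate(hi[ok] + 1L, nbins = npts + 1L)
        diffarr[seq_len(npts)] <- tl
        diffarr <- diffarr - th
        count[offset + seq_len(npts)] <- cumsum(diffarr[seq_len(npts)])
      }
    }
    offset <- offset + npts
  }
  rate <- count / f_n
  if (any(rate == 0))
    message("zero IBD rates present at ", sum(rate == 0), " focal position(s); ",
            "with small samples, review the scan plots to assess whether rates ",
            "are truncated to zero")
  structure(list(grid = grid, rate = rate, count = count,
                 min_cm = min_cm, f_n = f_n, n_skipped = n_skipped),
            class = "rate_track")
}

#' @export
print.rate_track <- function(x, ...) {
  cat("rate_track: M =", x$grid$M, "positions, f(n) =", x$f_n,
      ", min segment", x$min_cm, "cM\n",
      " mean rate", format(mean(x$rate), digits = 4),
      ", max rate", format(max(x$rate), digits = 4), "\n")
  invisible(x)
}

#' @export
as.data.frame.rate_track <- function(x, ...) {
  cbind(x$grid$points, rate = x$rate)
}

#' Write a rate or standardized track as TSV
#'
#' @param x A `rate_track` or `z_track`.
#' @param path Output file path.
#' @return Invisibly, the data.frame written (columns `chrom`, `cm`, `bp`,
#'   `rate`, plus `z` and `outlier` for a `z_track`).
#' @export
write_track <- function(x, path) {
  df <- as.data.frame(x)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}
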