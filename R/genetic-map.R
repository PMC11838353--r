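#' Read a recombination map
#'
#' Reads a genetic (recombination) map into a `genetic_map` object: one
#' monotone bp/cM lookup table per chromosome, used for linear interpolation
#' between physical and genetic coordinates.
#'
#' Two dialects are supported. `"plink"` is the PLINK `.map` layout with four
#' whitespace-separated columns (chromosome, marker id, cM position, bp
#' position); `"tsv"` is a three-column (chromosome, bp, cM) table. Files may
#' be gzip-compressed; compression is detected from the connection, not the
#' file name.
#'
#' @param path Path to the map file.
#' @param dialect `"plink"` (chrom, id, cM, bp) or `"tsv"` (chrom, bp, cM).
#' @return A `genetic_map`: a named list with one `data.frame(bp, cm)` per
#'   chromosome, rows ordered by bp. Duplicate bp entries are collapsed to
#'   their first record.
#' @examples
#' f <- tempfile(fileext = ".map")
#' writeLines(c("1 rs1 0.0 1", "1 rs2 1.0 1000000"), f)
#' gm <- read_genetic_map(f, dialect = "plink")
#' interpolate_map(gm, "1", 500000, from = "bp")
#' @seealso [interpolate_map()], [build_grid()]
#' @export
read_genetic_map <- function(path, dialect = c("plink", "tsv")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("map file not found: ", path)
  raw <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE)
  if (dialect == "plink") {
    if (ncol(raw) < 4L)
      stop("map-format error: PLINK dialect needs 4 columns (chrom, id, cM, bp)")
    df <- data.frame(chrom = as.character(raw[[1]]),
                     bp = as.numeric(raw[[4]]), cm = as.numeric(raw[[3]]))
  } else {
    if (ncol(raw) < 3L)
      stop("map-format error: tsv dialect needs 3 columns (chrom, bp, cM)")
    df <- data.frame(chrom = as.character(raw[[1]]),
                     bp = as.numeric(raw[[2]]), cm = as.numeric(raw[[3]]))
  }
  if (anyNA(df$bp) || anyNA(df$cm))
    stop("map-format error: non-numeric bp or cM values")
  genetic_map(df)
}

#' Construct a genetic map from a data frame
#'
#' @param df A `data.frame` with columns `chrom`, `bp`, `cm`.
#' @return A `genetic_map` object.
#' @export
genetic_map <- function(df) {
  stopifnot(all(c("chrom", "bp", "cm") %in% names(df)))
  tabs <- lapply(split(df[c("bp", "cm")], df$chrom), function(tab) {
    tab <- tab[!duplicated(tab$bp), , drop = FALSE]
    if (nrow(tab) < 2L)
      stop("map-format error: fewer than 2 distinct records on a chromosome")
    if (is.unsorted(tab$bp, strictly = TRUE))
      stop("map-format error: bp positions not strictly increasing within a chromosome")
    if (is.unsorted(tab$cm))
      stop("map-format error: cM positions decrease within a chromosome")
    rownames(tab) <- NULL
    tab
  })
  structure(tabs, class = "genetic_map")
}

#' @export
print.genetic_map <- function(x, ...) {
  spans <- vapply(x, function(tab) tab$cm[nrow(tab)] - tab$cm[1], numeric(1))
  cat("genetic_map:", length(x), "chromosome(s),",
      format(sum(spans), digits = 6), "cM total\n")
  invisible(x)
}

#' Interpolate between physical and genetic coordinates
#'
#' Piecewise-linear interpolation along a chromosome's map, exact at the map
#' knots. The cM-to-bp direction inverts the same piecewise-linear function;
#' where the map is flat (zero recombination over a bp stretch) the inverse is
#' resolved deterministically to the leftmost bp of the stretch.
#'
#' @param map A `genetic_map`.
#' @param chrom Chromosome identifier.
#' @param pos Numeric vector of query positions (bp or cM, per `from`).
#' @param from `"bp"` to convert bp to cM, `"cm"` for the inverse.
#' @return Numeric vector of interpolated positions.
#' @export
interpolate_map <- function(map, chrom, pos, from = c("bp", "cm")) {
  from <- match.arg(from)
  chrom <- as.character(chrom)
  tab <- map[[chrom]]
  if (is.null(tab)) stop("chromosome not in map: ", chrom)
  if (from == "bp") {
    if (any(pos < tab$bp[1] | pos > tab$bp[nrow(tab)]))
      stop("out-of-range error: bp query outside mapped range on chromosome ", chrom)
    stats::approx(tab$bp, tab$cm, xout = pos, ties = "ordered")$y
  } else {
    if (any(pos < tab$cm[1] | pos > tab$cm[nrow(tab)]))
      stop("out-of-range error: cM query outside mapped range on chromosome ", chrom)
    # ties = min: flat cM stretches invert to the left knot
    stats::approx(tab$cm, tab$bp, xout = pos, ties = min)$y
  }
}

#' Build the uniform centiMorgan testing grid
#'
#' Lays out focal test positions at a constant genetic spacing `delta_cm`
#' along every chromosome of the map, after trimming `trim_cm` from each
#' chromosome end. Trimming keeps focal positions away from map ends where
#' segments at the detection threshold cannot be fully observed; the default
#' convention is to trim by the segment detection threshold (2.0 cM for a
#' 2.0 cM scan).
#'
#' @param map A `genetic_map`.
#' @param delta_cm Grid spacing in cM (> 0).
#' @param trim_cm Genetic distance trimmed from each chromosome end (>= 0).
#' @return A `scan_grid`: list with `points` (data.frame `chrom`, `cm`, `bp`),
#'   `delta_cm`, `trim_cm`, `M` (total focal positions), `L_morgans` (total
#'   untrimmed genetic length in Morgans), and `C` (chromosome count).
#' @examples
#' gm <- genetic_map(data.frame(chrom = "1", bp = c(0, 100e6), cm = c(0, 100)))
#' g <- build_grid(gm, delta_cm = 0.02, trim_cm = 2)
#' g$M  # floor(96/0.02) + 1 = 4801
#' @export
build_grid <- function(map, delta_cm, trim_cm = 0) {
  stopifnot(inherits(map, "genetic_map"), delta_cm > 0, trim_cm >= 0)
  pts <- lapply(names(map), function(chrom) {
    tab <- map[[chrom]]
    lo <- tab$cm[1]
    hi <- tab$cm[nrow(tab)]
    if (hi - lo <= 2 * trim_cm)
      stop("degenerate-chromosome error: chromosome ", chrom,
           " span ", hi - lo, " cM <= 2*trim_cm")
    start <- lo + trim_cm
    end <- hi - trim_cm
    n <- floor((end - start) / delta_cm + 1e-9) + 1L
    cm <- start + (seq_len(n) - 1L) * delta_cm
    data.frame(chrom = chrom, cm = cm,
               bp = interpolate_map(map, chrom, cm, from = "cm"))
  })
  points <- do.call(rbind, pts)
  rownames(points) <- NULL
  lengths_cm <- vapply(map, function(tab) tab$cm[nrow(tab)] - tab$cm[1], numeric(1))
  structure(list(points = points, delta_cm = delta_cm, trim_cm = trim_cm,
                 M = nrow(points), L_morgans = sum(lengths_cm) / 100,
                 C = length(map)),
            class = "scan_grid")
}

#' @export
print.scan_grid <- function(x, ...) {
  cat("scan_grid: M =", x$M, "focal positions on", x$C, "chromosome(s)\n",
      " spacing", x$delta_cm, "cM, trim", x$trim_cm, "cM per end,",
      "L =", format(x$L_morgans, digits = 6), "Morgans\n")
  invisible(x)
}
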