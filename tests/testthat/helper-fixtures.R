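# Fixtures built in code: linear maps (1 cM per Mb), hand-made tracks.

linear_map <- function(n_chrom = 1, len_cm = 100) {
  genetic_map(do.call(rbind, lapply(seq_len(n_chrom), function(i)
    data.frame(chrom = as.character(i), bp = c(0, len_cm * 1e6),
               cm = c(0, len_cm)))))
}

# Random strictly increasing map on one chromosome.
random_map <- function(n_knots = 10, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  bp <- sort(sample.int(1e8, n_knots))
  cm <- cumsum(c(0, runif(n_knots - 1, 0.1, 5)))
  genetic_map(data.frame(chrom = "1", bp = bp, cm = cm))
}

# Assemble a z_track directly from per-chromosome z vectors.
make_ztrack <- function(z_by_chrom, delta_cm = 0.02, rate = NULL) {
  pts <- do.call(rbind, lapply(seq_along(z_by_chrom), function(i) {
    n <- length(z_by_chrom[[i]])
    cm <- (seq_len(n) - 1) * delta_cm
    data.frame(chrom = as.character(i), cm = cm, bp = cm * 1e6)
  }))
  z <- unlist(z_by_chrom, use.names = FALSE)
  grid <- structure(list(points = pts, delta_cm = delta_cm, trim_cm = 0,
                         M = nrow(pts),
                         L_morgans = sum(vapply(z_by_chrom, function(v)
                           (length(v) - 1) * delta_cm, numeric(1))) / 100,
                         C = length(z_by_chrom)),
                    class = "scan_grid")
  structure(list(grid = grid, z = z,
                 rate = if (is.null(rate)) z else rate,
                 outlier = rep(FALSE, length(z)),
                 moments = list(initial_threshold = Inf, mu_hat = 0,
                                sigma_hat = 1, n_excluded = 0L)),
            class = "z_track")
}

# Write a segment file from a data.frame of columns matching the seg dialect.
write_seg_file <- function(df, path = tempfile(fileext = ".seg")) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  path
}

seg_row <- function(chrom = "1", start_bp, end_bp, length_cm,
                    s1 = "a", h1 = 1, s2 = "b", h2 = 1) {
  data.frame(sample1 = s1, hap1 = h1, sample2 = s2, hap2 = h2,
             chrom = chrom, start_bp = start_bp, end_bp = end_bp,
             length_cm = length_cm)
}

# Brute-force IBD coverage oracle: count, per grid point, segments whose
# genetic span covers it (closed interval).
brute_force_rates <- function(seg_cm, grid_cm, f_n) {
  counts <- vapply(grid_cm, function(p)
    sum(seg_cm$start <= p & p <= seg_cm$end), numeric(1))
  counts / f_n
}
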