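test_that("pair counts follow the diploid and haploid formulas", {
  expect_equal(pair_count(10, "diploid"), 170)
  expect_equal(pair_count(4, "haploid"), 16)
  expect_equal(pair_count(2500, "diploid"), 12492500)
  expect_error(pair_count(1, "diploid"), "domain")
})

test_that("segment reading filters by length and flags self pairs", {
  df <- rbind(seg_row("1", 1e6, 2.9e6, 1.9),
              seg_row("1", 1e6, 3.0e6, 2.0),
              seg_row("1", 1e6, 4.5e6, 3.5, s1 = "c", s2 = "c", h2 = 2))
  path <- write_seg_file(df)
  expect_equal(nrow(read_ibd_segments(path, min_cm = 2.0)), 2L)
  expect_equal(nrow(read_ibd_segments(path, min_cm = 3.0)), 1L)
  segs <- read_ibd_segments(path, min_cm = 0)
  expect_equal(segs$self_pair, c(FALSE, FALSE, TRUE))

  empty <- write_seg_file(df[0, ])
  expect_equal(nrow(read_ibd_segments(empty, min_cm = 2)), 0L)

  bad <- write_seg_file(seg_row("1", 5e6, 4e6, 1.0))
  expect_error(read_ibd_segments(bad), "parse error")
})

test_that("rates follow the closed-interval overlap definition", {
  gm <- linear_map(1, 100)
  g <- build_grid(gm, delta_cm = 1, trim_cm = 0)
  # three distinct-pair segments covering 50 cM
  df <- rbind(seg_row("1", 45e6, 55e6, 10, s1 = "a", s2 = "b"),
              seg_row("1", 48e6, 52e6, 4, s1 = "a", s2 = "c"),
              seg_row("1", 50e6, 60e6, 10, s1 = "b", s2 = "c"))
  segs <- read_ibd_segments(write_seg_file(df), min_cm = 2)
  tr <- compute_ibd_rates(segs, g, gm, n = 10, ploidy = "diploid", min_cm = 2)
  expect_equal(tr$rate[g$points$cm == 50], 3 / 170)
  # closed endpoints: a [10, 12] cM segment covers the 10 and 12 cM points
  seg2 <- read_ibd_segments(
    write_seg_file(seg_row("1", 10e6, 12e6, 2)), min_cm = 2)
  tr2 <- compute_ibd_rates(seg2, g, gm, n = 10, ploidy = "diploid", min_cm = 2)
  expect_equal(which(tr2$count == 1), which(g$points$cm %in% c(10, 11, 12)))
})

test_that("difference-array rates equal the brute-force overlap oracle", {
  set.seed(11)
  gm <- linear_map(2, 60)
  g <- build_grid(gm, delta_cm = 0.25, trim_cm = 0)
  n_seg <- 100
  chrom <- sample(c("1", "2"), n_seg, replace = TRUE)
  start <- runif(n_seg, 0, 55)
  len <- runif(n_seg, 0.5, 8)
  df <- seg_row(chrom, start * 1e6, pmin(60, start + len) * 1e6,
                pmin(60, start + len) - start,
                s1 = paste0("s", sample(50, n_seg, TRUE)),
                s2 = paste0("t", sample(50, n_seg, TRUE)))
  segs <- read_ibd_segments(write_seg_file(df), min_cm = 2)
  f_n <- pair_count(100, "diploid")
  tr <- compute_ibd_rates(segs, g, gm, n = 100, ploidy = "diploid", min_cm = 2)
  for (ch in c("1", "2")) {
    seg_cm <- data.frame(start = segs$start_bp[segs$chrom == ch] / 1e6,
                         end = segs$end_bp[segs$chrom == ch] / 1e6)
    oracle <- brute_force_rates(seg_cm, g$points$cm[g$points$chrom == ch], f_n)
    expect_equal(tr$rate[g$points$chrom == ch], oracle)
  }
  # conservation: total coverage equals summed per-segment point counts
  per_seg <- mapply(function(ch, s, e) {
    gc <- g$points$cm[g$points$chrom == ch]
    sum(s / 1e6 <= gc & gc <= e / 1e6)
  }, segs$chrom, segs$start_bp, segs$end_bp)
  expect_equal(sum(tr$count), sum(per_seg))
})

test_that("rates are order-invariant and monotone in the length threshold", {
  set.seed(3)
  gm <- linear_map(1, 50)
  g <- build_grid(gm, delta_cm = 0.1, trim_cm = 0)
  start <- runif(60, 0, 45)
  df <- seg_row("1", start * 1e6, (start + runif(60, 1, 6)) * 1e6,
                runif(60, 1, 6),
                s1 = paste0("s", sample(20, 60, TRUE)),
                s2 = paste0("t", sample(20, 60, TRUE)))
  p1 <- write_seg_file(df)
  p2 <- write_seg_file(df[sample(nrow(df)), ])
  s1 <- read_ibd_segments(p1, min_cm = 0)
  s2 <- read_ibd_segments(p2, min_cm = 0)
  t_lo <- compute_ibd_rates(s1, g, gm, 20, "diploid", min_cm = 2)
  t_shuf <- compute_ibd_rates(s2, g, gm, 20, "diploid", min_cm = 2)
  t_hi <- compute_ibd_rates(s1, g, gm, 20, "diploid", min_cm = 3)
  expect_equal(t_lo$rate, t_shuf$rate)
  expect_true(all(t_hi$rate <= t_lo$rate))
})

test_that("segments on unknown chromosomes are skipped with a warning", {
  gm <- linear_map(1, 50)
  g <- build_grid(gm, delta_cm = 1, trim_cm = 0)
  df <- rbind(seg_row("1", 10e6, 15e6, 5), seg_row("9", 10e6, 15e6, 5))
  segs <- read_ibd_segments(write_seg_file(df), min_cm = 2)
  expect_warning(
    tr <- compute_ibd_rates(segs, g, gm, 10, "diploid", min_cm = 2),
    "skipped")
  expect_equal(tr$n_skipped, 1L)
  expect_equal(max(tr$count), 1)
})

test_that("within-individual pairs are excluded from diploid numerators", {
  gm <- linear_map(1, 50)
  g <- build_grid(gm, delta_cm = 1, trim_cm = 0)
  df <- rbind(seg_row("1", 10e6, 15e6, 5, s1 = "a", s2 = "b"),
              seg_row("1", 10e6, 15e6, 5, s1 = "a", h1 = 1, s2 = "a", h2 = 2))
  segs <- read_ibd_segments(write_seg_file(df), min_cm = 2)
  tr_d <- compute_ibd_rates(segs, g, gm, 10, "diploid", min_cm = 2)
  expect_equal(max(tr_d$count), 1)
  tr_h <- compute_ibd_rates(segs, g, gm, 10, "haploid", min_cm = 2)
  expect_equal(max(tr_h$count), 2)
})
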