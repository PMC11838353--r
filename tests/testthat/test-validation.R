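test_that("simulated OU genomes are stationary with independent chromosomes", {
  set.seed(31)
  # marginal at a fixed position over replicates
  vals <- replicate(300, simulate_ou_genome(50, c(50, 50), 0.1)$z[100])
  expect_equal(mean(vals), 0, tolerance = 0.12)
  expect_equal(var(vals), 1, tolerance = 0.18)
  # cross-chromosome correlation at matched offsets ~ 0
  set.seed(32)
  pairs <- t(replicate(400, {
    g <- simulate_ou_genome(50, c(20, 20), 0.1)
    ch <- g$grid$points$chrom
    c(g$z[ch == "1"][50], g$z[ch == "2"][50])
  }))
  expect_lt(abs(cor(pairs[, 1], pairs[, 2])), 0.12)
})

test_that("the empirical autocovariance decays as exp(-theta * lag)", {
  set.seed(33)
  theta <- 40
  # pool 16 chains of 500 cM: the lag-k product estimator on a single strongly
  # correlated chain has Monte Carlo SE ~ 0.02 at this pooled size
  chains <- replicate(16, simulate_ou_chain(25001, theta, 2e-4),
                      simplify = FALSE)
  for (lag_cm in c(0.5, 1, 2, 4)) {
    k <- round(lag_cm / 0.02)
    emp <- mean(vapply(chains, function(z) {
      n <- length(z)
      mean(z[1:(n - k)] * z[(k + 1):n])
    }, numeric(1)))
    expect_lt(abs(emp - exp(-theta * lag_cm / 100)), 0.06)
  }
})

test_that("FWER experiments are reproducible and preserve threshold ordering", {
  a <- run_fwer_experiment(100, theta = 50, chrom_lengths_cm = rep(50, 4),
                           delta_cm = 0.1, alpha_fw = 0.05, J = 500,
                           seed = 77)
  b <- run_fwer_experiment(100, theta = 50, chrom_lengths_cm = rep(50, 4),
                           delta_cm = 0.1, alpha_fw = 0.05, J = 500,
                           seed = 77)
  expect_identical(a$fwer, b$fwer)
  expect_equal(unname(a$fwer), unname(a$n_reject) / a$n_replicates)
  # bonferroni is the most stringent, simulation the least (up to MC noise)
  expect_lte(a$fwer[["bonferroni"]], a$fwer[["analytical"]])
  expect_lte(a$fwer[["analytical"]], a$fwer[["simulation"]] + 0.03)
  expect_error(run_fwer_experiment(50, 50, rep(50, 4), 0.1),
               "configuration error")
})

test_that("synthetic segment files drive the full pipeline end to end", {
  seg <- tempfile(fileext = ".seg")
  map_file <- tempfile(fileext = ".map")
  map <- synthetic_segment_file(seg, n_samples = 100, ploidy = "diploid",
                                chrom_lengths_cm = rep(100, 4),
                                mean_rate = 0.002, length_scale_cm = 5,
                                min_cm = 2, seed = 55)
  # write the matching linear map in PLINK dialect
  rows <- unlist(lapply(names(map), function(ch)
    sprintf("%s k%s_%d %.4f %d", ch, ch, seq_len(nrow(map[[ch]])),
            map[[ch]]$cm, map[[ch]]$bp)))
  writeLines(rows, map_file)

  grid <- build_grid(map, delta_cm = 0.05, trim_cm = 2)
  segs <- read_ibd_segments(seg, min_cm = 2)
  tr <- compute_ibd_rates(segs, grid, map, 100, "diploid", min_cm = 2)
  expect_lt(abs(mean(tr$rate) / 0.002 - 1), 0.2)

  res <- ibd_scan(seg, map_file, n_samples = 100, ploidy = "diploid",
                  min_cm = 2, step_cm = 0.05, alpha_fw = 0.05,
                  method = "analytical")
  expect_s3_class(res$theta, "theta_fit")
  expect_s3_class(res$threshold, "threshold_result")

  # an injected spike of co-located segments creates exactly one region
  extra <- seg_row("1", rep(49.5e6, 50), rep(52.5e6, 50), 3,
                   s1 = paste0("x", 1:50), s2 = paste0("y", 1:50))
  seg2 <- tempfile(fileext = ".seg")
  writeLines(c(readLines(seg), apply(extra, 1, paste, collapse = "\t")), seg2)
  res2 <- ibd_scan(seg2, map_file, n_samples = 100, ploidy = "diploid",
                   min_cm = 2, step_cm = 0.05, method = "analytical")
  expect_equal(nrow(res2$regions), 1L)
  expect_equal(res2$regions$chrom, "1")
  expect_gt(res2$regions$peak_cm, 49.5)
  expect_lt(res2$regions$peak_cm, 52.5)
})

test_that("a zero-segment fixture fails standardization loudly", {
  seg <- tempfile(fileext = ".seg")
  map <- synthetic_segment_file(seg, n_samples = 10, ploidy = "diploid",
                                chrom_lengths_cm = 100, mean_rate = 0,
                                length_scale_cm = 5, min_cm = 2, seed = 1)
  grid <- build_grid(map, delta_cm = 0.1, trim_cm = 2)
  segs <- read_ibd_segments(seg, min_cm = 2)
  tr <- suppressMessages(
    compute_ibd_rates(segs, grid, map, 10, "diploid", min_cm = 2))
  expect_error(robust_standardize(tr), "degenerate-track")
})

test_that("null pipelines rarely call regions at the family-wise level", {
  set.seed(88)
  hits <- replicate(10, {
    g <- simulate_ou_genome(50, rep(100, 4), 0.05)
    th <- analytical_quantile(0.05, 50, 4, 4, 5e-4)
    nrow(call_regions(g, test_positions(g, th$z_star), min_span_cm = 0.5))
  })
  expect_gte(mean(hits == 0), 0.9)
})
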