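# ibdscan

Genome-wide significance thresholds for selection scans based on excess
identity-by-descent (IBD) segment sharing.

Scans for recent positive selection often flag loci where the IBD rate — the
fraction of haplotype pairs sharing a detectable IBD segment overlapping a
position — is a few standard deviations above the genome-wide average. That
heuristic has no multiple-testing correction: with tests every 0.02 cM a
human-scale scan runs tens of thousands of correlated tests. `ibdscan`
calibrates the scan by modeling the standardized IBD rates
$\tilde Z_m = (\bar Y_m - \hat\mu)/\hat\sigma$ along the genome as an
Ornstein–Uhlenbeck (OU) process with autocorrelation $e^{-\theta d}$ at
genetic distance $d$ Morgans, and solving

$$P\Big(\max_m \tilde Z_m \ge z\Big) \approx 1 - \exp\Big\{-\big[C(1-\Phi(z))
+ \theta L\, z\, \phi(z)\, \nu(z\sqrt{2\theta\Delta})\big]\Big\} = \alpha$$

for the quantile $z_{\alpha^*}$ controlling the family-wise error rate
(FWER) at level $\alpha$, given the genome length $L$ (Morgans), chromosome
count $C$, test spacing $\Delta$, and the decay parameter $\theta$ estimated
from the data by a log-linear fit to the rate autocovariances. A Monte Carlo
threshold (simulating the fitted OU process) and the Bonferroni correction
are provided alongside, plus region calling for contiguous significant
stretches and a simulation harness that verifies FWER control on OU null
genomes. It is aimed at population-genetics analysts who already have
detected IBD segments (hap-ibd / ibd-ends style `.seg` files) and a
recombination map.

## Worked example

Generate a synthetic cohort of 200 diploids on ten 100 cM chromosomes with a
background IBD rate of 5×10⁻⁴, inject a locus with excess sharing on
chromosome 3 near 50 cM, and run the full scan:

```r
library(ibdscan)
map <- synthetic_segment_file("example.seg", n_samples = 200,
                              ploidy = "diploid",
                              chrom_lengths_cm = rep(100, 10),
                              mean_rate = 5e-4, length_scale_cm = 4,
                              min_cm = 2, seed = 7)
rows <- unlist(lapply(names(map), function(ch)
  sprintf("%s m%s_%d %.4f %d", ch, ch, seq_len(nrow(map[[ch]])),
          map[[ch]]$cm, map[[ch]]$bp)))
writeLines(rows, "example.map")
extra <- data.frame(s1 = paste0("x", 1:60), h1 = 1, s2 = paste0("y", 1:60),
                    h2 = 1, chrom = "3", start = 48.2e6, end = 51.8e6,
                    len = 3.6)
write.table(extra, "example.seg", sep = "\t", quote = FALSE,
            row.names = FALSE, col.names = FALSE, append = TRUE)

res <- ibd_scan("example.seg", "example.map", n_samples = 200,
                ploidy = "diploid", min_cm = 2, step_cm = 0.02,
                alpha_fw = 0.05, method = "analytical")
res
#> ibd_scan: 48010 tests, 181 rejection(s), 1 region(s)
#> theta_fit: theta_hat = 35.794 per Morgan ( 200 lags )
#> threshold_result [ analytical ]: z* = 4.2592 , genome-wide significance level = 1.026e-05 (family-wise 0.05 )
#> regions:
#>  dataset chrom   max_rate region_size_cm position_mb     span_mb  p_value
#>              3 0.00127204            3.6        51.2 48.20-51.80 9.21e-22
```

Reading the output: 48,010 focal positions were tested (ten chromosomes,
0.02 cM spacing, 2.0 cM trimmed from each end). The autocovariance fit
estimated $\hat\theta \approx 35.8$ per Morgan; at family-wise level 0.05
the analytical threshold is $z^* = 4.26$ standard deviations above the
revised mean, a per-test genome-wide significance level of
$1.0\times10^{-5}$. The 181 rejected positions form exactly one contiguous
region ≥ 0.50 cM — the injected locus on chromosome 3 spanning
48.2–51.8 Mb, with peak rate 1.27×10⁻³ and p = 9.2×10⁻²² at the peak. The
background never rejects.

Threshold-only usage needs no data at all:

```r
analytical_quantile(0.05, theta = 45, L_morgans = 35.45, C = 22,
                    delta_morgans = 0.0002)
#> threshold_result [ analytical ]: z* = 4.5993 , genome-wide significance level = 2.12e-06 (family-wise 0.05 )
```

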