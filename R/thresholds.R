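#' Discretization correction for discretely sampled process maxima
#'
#' The boundary-crossing rate of a continuously observed Ornstein-Uhlenbeck
#' process overstates the exceedance probability of its maximum over a
#' discrete grid. Siegmund's correction factor nu(y), evaluated here by the
#' standard rational approximation
#' \deqn{\nu(y) = \frac{(2/y)(\Phi(y/2) - 1/2)}{(y/2)\Phi(y/2) + \phi(y/2)},}
#' scales the crossing rate down according to the effective step
#' y = z * sqrt(2 * theta * Delta). It satisfies nu(0) = 1 (the continuous
#' limit) and decreases strictly in y; for small y it is close to
#' exp(-0.583 y).
#'
#' @param y Non-negative numeric vector.
#' @return nu(y), in (0, 1].
#' @export
nu <- function(y) {
  if (any(y < 0)) stop("domain error: nu() requires y >= 0")
  out <- numeric(length(y))
  zero <- y == 0
  out[zero] <- 1
  yy <- y[!zero]
  out[!zero] <- ((2 / yy) * (stats::pnorm(yy / 2) - 0.5)) /
    ((yy / 2) * stats::pnorm(yy / 2) + stats::dnorm(yy / 2))
  out
}

fwer_approx <- function(z, theta, L_morgans, C, delta_morgans) {
  1 - exp(-(C * (1 - stats::pnorm(z)) +
              theta * L_morgans * z * stats::dnorm(z) *
                nu(z * sqrt(2 * theta * delta_morgans))))
}

threshold_result <- function(method, alpha_fw, z_star, theta = NA_real_,
                             L_morgans = NA_real_, C = NA_integer_,
                             delta_morgans = NA_real_, M = NA_integer_,
                             J = NA_integer_, seed = NA_integer_) {
  structure(list(method = method, alpha_fw = alpha_fw, z_star = z_star,
                 alpha_star = stats::pnorm(z_star, lower.tail = FALSE),
                 theta = theta, L_morgans = L_morgans, C = C,
                 delta_morgans = delta_morgans, M = M, J = J, seed = seed),
            class = "threshold_result")
}

#' @export
print.threshold_result <- function(x, ...) {
  cat("threshold_result [", x$method, "]: z* =", format(x$z_star, digits = 5),
      ", genome-wide significance level =", format(x$alpha_star, digits = 4),
      "(family-wise", x$alpha_fw, ")\n")
  invisible(x)
}

#' Analytical genome-wide significance threshold
#'
#' Solves for the multiple-testing quantile z* at which the probability that
#' the maximum standardized IBD rate over the genome exceeds z equals the
#' family-wise level alpha, under the Ornstein-Uhlenbeck approximation
#' \deqn{P(\max_m \tilde Z_m \ge z) \approx 1 - \exp\{-[C(1-\Phi(z)) +
#'   \theta L z \phi(z) \nu(z\sqrt{2\theta\Delta})]\},}
#' with theta the autocorrelation decay per Morgan, L the genome length in
#' Morgans, C the chromosome count and Delta the test spacing in Morgans.
#' The root is found by bracketed bisection on z in (1, 10) and polished to a
#' residual below 1e-12.
#'
#' @param alpha_fw Family-wise significance level in (0, 0.5).
#' @param theta Decay parameter per Morgan (> 0).
#' @param L_morgans Total genome genetic length in Morgans.
#' @param C Number of chromosomes.
#' @param delta_morgans Test spacing in Morgans (cM spacing / 100).
#' @return A `threshold_result` with `z_star` and the per-test genome-wide
#'   significance level `alpha_star` = 1 - Phi(z_star).
#' @examples
#' analytical_quantile(0.05, theta = 58.84, L_morgans = 10, C = 10,
#'                     delta_morgans = 0.0002)$z_star  # ~4.36
#' @export
analytical_quantile <- function(alpha_fw, theta, L_morgans, C, delta_morgans) {
  stopifnot(alpha_fw > 0, alpha_fw < 0.5, theta > 0, L_morgans > 0,
            C >= 1, delta_morgans > 0)
  f <- function(z) fwer_approx(z, theta, L_morgans, C, delta_morgans) - alpha_fw
  lo <- 1; hi <- 10
  if (f(lo) < 0 || f(hi) > 0)
    stop("configuration error: no root in z bracket [1, 10] for alpha_fw = ",
         alpha_fw, ", theta = ", theta, ", L = ", L_morgans, ", C = ", C,
         ", delta = ", delta_morgans)
  z <- stats::uniroot(f, c(lo, hi), tol = 1e-14)$root
  # polish by bisection until the FWER residual is below 1e-12
  flo <- f(lo); fhi <- f(hi)
  a <- lo; b <- hi
  while (abs(f(z)) > 1e-12 && (b - a) > .Machine$double.eps * 8) {
    if (sign(f(z)) == sign(flo)) { a <- z } else { b <- z }
    z <- (a + b) / 2
  }
  threshold_result("analytical", alpha_fw, z,
                   theta = theta, L_morgans = L_morgans, C = C,
                   delta_morgans = delta_morgans,
                   M = as.integer(floor(L_morgans / delta_morgans)))
}

#' Simulate a discretely observed Ornstein-Uhlenbeck chain
#'
#' Draws the first-order autoregressive chain matching the standardized IBD
#' rate process under the null: z_1 ~ N(0, 1) and, for m >= 2,
#' z_m | z_{m-1} ~ N(z_{m-1} exp(-theta Delta), 2 - 2 exp(-theta Delta)).
#' The recursion is evaluated at C speed with `stats::filter()`. The
#' `stationary` flag replaces the conditional variance with the exactly
#' stationary form 1 - exp(-2 theta Delta); the two differ at order
#' (theta Delta)^2 and the default follows the scan's published recursion.
#'
#' @param M Number of grid steps (>= 1).
#' @param theta Decay parameter per Morgan.
#' @param delta_morgans Grid spacing in Morgans.
#' @param stationary Use the exactly stationary innovation variance.
#' @return Numeric vector of length M. Uses (and advances) the current RNG
#'   state; call `set.seed()` beforehand for reproducibility.
#' @export
simulate_ou_chain <- function(M, theta, delta_morgans, stationary = FALSE) {
  stopifnot(M >= 1, theta > 0, delta_morgans > 0)
  rho <- exp(-theta * delta_morgans)
  z1 <- stats::rnorm(1)
  if (M == 1) return(z1)
  s <- if (stationary) sqrt(1 - rho^2) else sqrt(2 - 2 * rho)
  innov <- c(z1, stats::rnorm(M - 1, sd = s))
  as.numeric(stats::filter(innov, rho, method = "recursive"))
}

#' Simulation-based genome-wide significance threshold
#'
#' Monte Carlo alternative to [analytical_quantile()]: simulates J
#' Ornstein-Uhlenbeck chains, each a single chromosome of the total genome
#' length (M = floor(L / Delta) steps), records each chain's maximum, and
#' returns the empirical (1 - alpha) quantile of the J maxima as the order
#' statistic of rank ceiling((1 - alpha) * J).
#'
#' @inheritParams analytical_quantile
#' @param J Number of simulated genomes (>= 100; alpha_fw * J >= 5).
#' @param seed Optional integer seed; if `NULL` the current RNG state is used.
#' @param stationary Passed to [simulate_ou_chain()].
#' @return A `threshold_result` recording `J` and `seed`.
#' @export
simulation_quantile <- function(alpha_fw, theta, L_morgans, delta_morgans,
                                J = 2000, seed = NULL, stationary = FALSE) {
  stopifnot(alpha_fw > 0, alpha_fw < 1, theta > 0, L_morgans > 0,
            delta_morgans > 0)
  if (J < 100 || alpha_fw * J < 5)
    stop("configuration error: need J >= 100 and alpha_fw * J >= 5 ",
         "to estimate the (1 - alpha_fw) quantile")
  if (!is.null(seed)) set.seed(seed)
  M <- as.integer(floor(L_morgans / delta_morgans))
  maxima <- vapply(seq_len(J), function(j)
    max(simulate_ou_chain(M, theta, delta_morgans, stationary = stationary)),
    numeric(1))
  z_star <- sort(maxima)[ceiling((1 - alpha_fw) * J)]
  threshold_result("simulation", alpha_fw, z_star,
                   theta = theta, L_morgans = L_morgans,
                   delta_morgans = delta_morgans, M = M, J = as.integer(J),
                   seed = if (is.null(seed)) NA_integer_ else as.integer(seed))
}

#' Bonferroni genome-wide significance threshold
#'
#' @param alpha_fw Family-wise significance level.
#' @param M Number of tests (>= 1).
#' @return A `threshold_result` with `alpha_star` = alpha_fw / M and
#'   `z_star` = Phi^{-1}(1 - alpha_star).
#' @examples
#' bonferroni_quantile(0.05, 48010)$alpha_star  # ~1.04e-6
#' @export
bonferroni_quantile <- function(alpha_fw, M) {
  stopifnot(alpha_fw > 0, alpha_fw < 1, M >= 1)
  alpha_star <- alpha_fw / M
  res <- threshold_result("bonferroni", alpha_fw,
                          stats::qnorm(1 - alpha_star), M = as.integer(M))
  res$alpha_star <- alpha_star
  res
}

#' Heuristic median-plus-four-SD threshold
#'
#' The pre-existing rule of thumb that the calibrated thresholds replace:
#' flag rates above the genome-wide median plus four standard deviations.
#' Its implied per-test significance level is fixed at
#' 1 - Phi(4) = 3.17e-5 and does not adapt to genome size, spacing, or the
#' correlation of the rate process.
#'
#' @param track A `rate_track`, or `NULL` for the level alone.
#' @return List with `rate_threshold` (or `NA` without a track), `z_star` = 4,
#'   and `alpha_star` = 1 - Phi(4).
#' @export
heuristic_threshold <- function(track = NULL) {
  thr <- if (is.null(track)) NA_real_ else
    stats::median(track$rate) + 4 * stats::sd(track$rate)
  list(rate_threshold = thr, z_star = 4,
       alpha_star = stats::pnorm(4, lower.tail = FALSE))
}
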