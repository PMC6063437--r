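#' Luria-Delbruck fluctuation analysis
#'
#' Mutant counts across parallel cultures follow the Luria-Delbruck
#' distribution: mutations arise at random during exponential growth and
#' each founds a clone whose final size depends on when it arose, producing
#' the characteristic heavy ("jackpot") tail. The distribution is computed
#' by the Ma-Sandri-Sarkar recursion and `m`, the expected number of
#' mutations per culture, is estimated by the Lea-Coulson method of the
#' median (the primary estimator), by maximum likelihood, or by the p0
#' (zero-class) method. The per-cell mutation rate is `m / Nt` with `Nt`
#' the final number of cells per culture.
#'
#' @name fluctuation_module
NULL

#' Luria-Delbruck probability mass function (Ma-Sandri-Sarkar recursion)
#'
#' `p_0 = exp(-m)`; `p_r = (m/r) * sum_{i=0}^{r-1} p_i / (r - i + 1)`.
#' The distribution has a power-law tail (~ m/r^2), so partial sums
#' approach 1 slowly.
#'
#' @param m Expected mutations per culture (>= 0).
#' @param r_max Largest count to tabulate.
#' @return Numeric vector of probabilities for counts `0:r_max`.
#' @examples
#' ld_pmf(1, 5)
#' @export
ld_pmf <- function(m, r_max) {
  if (!is.numeric(m) || length(m) != 1L || !is.finite(m) || m < 0) {
    stop("`m` must be a single finite number >= 0", call. = FALSE)
  }
  r_max <- as.integer(r_max)
  if (r_max < 0L) stop("`r_max` must be >= 0", call. = FALSE)
  p <- numeric(r_max + 1L)
  p[1L] <- exp(-m)
  if (m == 0 || r_max == 0L) return(p)
  for (r in seq_len(r_max)) {
    # sum over i = 0..r-1 of p_i / (r - i + 1)
    p[r + 1L] <- (m / r) * sum(p[seq_len(r)] / ((r + 1L):2L))
  }
  p
}

#' Method-of-the-median estimate of m (Lea-Coulson)
#'
#' Solves `median/m - ln(m) = 1.24` for `m` by bisection. The left side is
#' strictly decreasing in `m`, so the root is unique for any positive
#' median. The median of an even number of cultures is the mean of the two
#' central order statistics.
#'
#' @param counts Non-negative mutant counts per culture, or a single
#'   pre-computed median via `median_count`.
#' @param median_count Optional; supply the median directly instead of
#'   `counts`.
#' @return The estimate of `m` (expected mutations per culture).
#' @examples
#' estimate_m_median(median_count = 1.24)  # exactly 1
#' @export
estimate_m_median <- function(counts = NULL, median_count = NULL) {
  r_med <- if (is.null(median_count)) {
    stopifnot(!is.null(counts))
    median(counts)
  } else median_count
  if (!is.finite(r_med) || r_med <= 0) {
    stop("median count is 0; the method of the median is inapplicable ",
         "(use estimate_m_p0)", call. = FALSE)
  }
  f <- function(m) r_med / m - log(m) - 1.24
  lo <- 1e-8
  hi <- max(r_med, 1) * 100
  if (f(lo) < 0 || f(hi) > 0) stop("root not bracketed", call. = FALSE)
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) lo <- mid else hi <- mid
    if (hi - lo < 1e-12 * hi) break
  }
  (lo + hi) / 2
}

#' Maximum-likelihood estimate of m under the Luria-Delbruck distribution
#'
#' Maximizes the Ma-Sandri-Sarkar log-likelihood by bounded 1-D
#' optimization. Counts above `r_cap` (jackpot cultures) are pooled into
#' the tail term `1 - sum_{r <= r_cap} p_r`, the standard treatment that
#' keeps the recursion affordable without discarding information. With a
#' plating fraction below 1 the tabulated pmf is thinned binomially before
#' the likelihood is formed.
#'
#' @param counts Non-negative mutant counts per culture.
#' @param r_cap Cap above which counts contribute through the pooled tail.
#' @param plating_fraction Fraction of each culture plated, in (0, 1].
#' @return The MLE of `m`.
#' @export
estimate_m_mle <- function(counts, r_cap = 500L, plating_fraction = 1) {
  counts <- as.integer(counts)
  if (any(counts < 0L)) stop("counts must be non-negative", call. = FALSE)
  if (all(counts == 0L)) {
    stop("all counts are zero; use estimate_m_p0", call. = FALSE)
  }
  r_cap <- as.integer(r_cap)
  capped <- pmin(counts, r_cap + 1L)  # r_cap + 1 encodes "in the tail"
  tab <- tabulate(capped + 1L, nbins = r_cap + 2L)  # counts of 0..r_cap, tail
  n_tail <- tab[r_cap + 2L]
  obs <- which(tab[seq_len(r_cap + 1L)] > 0L)  # 1-based indices: count r = obs-1

  negll <- function(m) {
    p <- ld_pmf(m, r_cap)
    if (plating_fraction < 1) p <- .thin_pmf(p, plating_fraction)
    p <- pmax(p, 1e-300)
    ll <- sum(tab[obs] * log(p[obs]))
    if (n_tail > 0L) ll <- ll + n_tail * log(max(1 - sum(p), 1e-300))
    -ll
  }
  upper <- max(estimate_m_median(median_count = max(median(counts), 0.5)) * 20, 10)
  optimize(negll, interval = c(1e-6, upper), tol = 1e-8)$minimum
}

# Binomial thinning of a pmf tabulated on 0..r_max: observed k ~ Binom(r, pf)
.thin_pmf <- function(p, plating_fraction) {
  r_max <- length(p) - 1L
  q <- numeric(length(p))
  for (r in 0:r_max) {
    k <- 0:r
    q[k + 1L] <- q[k + 1L] + p[r + 1L] * stats::dbinom(k, r, plating_fraction)
  }
  q
}

#' p0 (zero-class) estimate of m
#'
#' `m = -ln(fraction of cultures with zero mutants)`, from the Poisson
#' number of mutations per culture.
#'
#' @param counts Non-negative mutant counts per culture.
#' @return The p0 estimate of `m`.
#' @examples
#' estimate_m_p0(c(0, 0, 0, 1, 5))
#' @export
estimate_m_p0 <- function(counts) {
  if (length(counts) == 0L) stop("no counts", call. = FALSE)
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  p0 <- mean(counts == 0)
  if (p0 == 0) {
    stop("no zero-count cultures; the p0 method is inapplicable", call. = FALSE)
  }
  -log(p0)
}

#' Construct a fluctuation experiment
#'
#' @param mutant_counts Dilution-corrected selective-plate colony counts,
#'   one per culture (>= 5 cultures).
#' @param Nt Final cells per culture (from the permissive-plate titer).
#' @param plating_fraction Fraction of each culture plated selectively.
#' @return An object of class `fluctuation_experiment`.
#' @export
fluctuation_experiment <- function(mutant_counts, Nt, plating_fraction = 1) {
  if (length(mutant_counts) < 5L) {
    stop("need at least 5 parallel cultures", call. = FALSE)
  }
  if (any(mutant_counts < 0)) stop("counts must be non-negative", call. = FALSE)
  if (!is.finite(Nt) || Nt <= 0) stop("`Nt` must be positive", call. = FALSE)
  if (Nt < max(mutant_counts)) {
    stop("`Nt` must be at least the largest mutant count", call. = FALSE)
  }
  if (plating_fraction <= 0 || plating_fraction > 1) {
    stop("`plating_fraction` must be in (0, 1]", call. = FALSE)
  }
  structure(
    list(mutant_counts = as.numeric(mutant_counts),
         n_cultures = length(mutant_counts),
         Nt = Nt, plating_fraction = plating_fraction),
    class = "fluctuation_experiment"
  )
}

#' Per-cell mutation rate with a 95% confidence interval
#'
#' Estimates `m` by the requested estimator and reports `rate = m / Nt`.
#' The CI uses the dispersion of the log estimator,
#' `sigma_ln(m) = 1.225 * m^-0.315 / sqrt(C)` with `C` parallel cultures,
#' giving `CI = m * exp(+/- 1.96 * sigma)` (then divided by `Nt`). This
#' standard approximation is documented and swappable; it is accurate for
#' the median estimator over the practically relevant range of `m`.
#' A plating fraction below 1 is handled exactly (binomial thinning) inside
#' the MLE and left uncorrected — with a warning — for the median and p0
#' methods.
#'
#' @param experiment A [fluctuation_experiment()].
#' @param estimator `"median"` (default), `"mle"` or `"p0"`.
#' @return An object of class `mutation_rate_estimate`: list with `m`,
#'   `rate`, `ci_low`, `ci_high` (on the rate scale), `m_ci_low`,
#'   `m_ci_high`, `estimator`, `n_cultures`.
#' @export
mutation_rate <- function(experiment, estimator = c("median", "mle", "p0")) {
  stopifnot(inherits(experiment, "fluctuation_experiment"))
  estimator <- match.arg(estimator)
  counts <- experiment$mutant_counts
  if (experiment$plating_fraction < 1 && estimator != "mle") {
    warning("plating_fraction < 1 is not corrected by the ", estimator,
            " estimator; treat the rate as approximate", call. = FALSE)
  }
  m <- switch(estimator,
    median = estimate_m_median(counts),
    mle = estimate_m_mle(counts, plating_fraction = experiment$plating_fraction),
    p0 = estimate_m_p0(counts)
  )
  C <- experiment$n_cultures
  sigma <- if (m > 0) 1.225 * m^(-0.315) / sqrt(C) else NA_real_
  m_ci <- if (m > 0) m * exp(c(-1, 1) * qnorm(0.975) * sigma) else c(0, 0)
  structure(
    list(m = m, rate = m / experiment$Nt,
         ci_low = m_ci[1] / experiment$Nt, ci_high = m_ci[2] / experiment$Nt,
         m_ci_low = m_ci[1], m_ci_high = m_ci[2],
         estimator = estimator, n_cultures = C),
    class = "mutation_rate_estimate"
  )
}

#' @export
print.mutation_rate_estimate <- function(x, ...) {
  cat(sprintf(
    "<mutation_rate_estimate> m = %.4g, rate = %.4g per cell (95%% CI %.4g-%.4g), %s, C = %d\n",
    x$m, x$rate, x$ci_low, x$ci_high, x$estimator, x$n_cultures))
  invisible(x)
}

#' Median mutation frequency with an order-statistic 95% CI
#'
#' Per-culture frequency = (mutant count x selective-plate dilution) /
#' (viable count x permissive-plate dilution). The median is reported with
#' the distribution-free CI given by the binomial(n, 1/2) rank interval:
#' the (l, n+1-l) order statistics with `l` the 2.5% binomial quantile
#' (for n = 24 this is the 7th and 18th ranked frequency). Cultures with a
#' zero viable count are excluded with a warning.
#'
#' @param mutant_counts,viable_counts Paired per-culture plate counts.
#' @param mutant_dilution,viable_dilution Dilution factors applied to each
#'   plate (count x dilution = per-culture number); scalars or per-culture
#'   vectors.
#' @return An object of class `frequency_estimate`: list with
#'   `median_frequency`, `ci_low`, `ci_high`, `n_cultures`, `frequencies`.
#' @export
mutation_frequency <- function(mutant_counts, viable_counts,
                               mutant_dilution = 1, viable_dilution = 1) {
  n <- length(mutant_counts)
  if (length(viable_counts) != n) {
    stop("mutant and viable counts must be paired per culture", call. = FALSE)
  }
  mutant_dilution <- rep_len(mutant_dilution, n)
  viable_dilution <- rep_len(viable_dilution, n)
  keep <- viable_counts > 0
  if (any(!keep)) {
    warning(sum(!keep), " culture(s) with zero viable count excluded",
            call. = FALSE)
  }
  freq <- (mutant_counts[keep] * mutant_dilution[keep]) /
    (viable_counts[keep] * viable_dilution[keep])
  n <- length(freq)
  if (n == 0L) stop("no cultures with viable counts", call. = FALSE)
  sorted <- sort(freq)
  l <- qbinom(0.025, n, 0.5)
  if (l < 1L) l <- 1L
  u <- n + 1L - l
  structure(
    list(median_frequency = median(freq),
         ci_low = sorted[l], ci_high = sorted[u],
         n_cultures = n, frequencies = freq),
    class = "frequency_estimate"
  )
}

#' @export
print.frequency_estimate <- function(x, ...) {
  cat(sprintf(
    "<frequency_estimate> median %.4g (95%% CI %.4g-%.4g), n = %d cultures\n",
    x$median_frequency, x$ci_low, x$ci_high, x$n_cultures))
  invisible(x)
}

#' Percent survival relative to a vehicle control
#'
#' @param treated_cfu CFU count of the drug-treated culture.
#' @param control_cfu CFU count of the vehicle (e.g. DMSO) control.
#' @return Survival in percent.
#' @examples
#' percent_survival(50, 200)  # 25
#' @export
percent_survival <- function(treated_cfu, control_cfu) {
  if (any(control_cfu <= 0)) stop("control CFU must be positive", call. = FALSE)
  if (any(treated_cfu < 0)) stop("treated CFU must be non-negative", call. = FALSE)
  100 * treated_cfu / control_cfu
}
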