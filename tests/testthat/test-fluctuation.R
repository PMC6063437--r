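test_that("the Ma-Sandri-Sarkar recursion reproduces known values", {
  expect_equal(ld_pmf(2, 0), exp(-2))
  expect_equal(ld_pmf(1, 1)[2], exp(-1) / 2, tolerance = 1e-12)  # 0.1839
  expect_equal(ld_pmf(0, 5), c(1, 0, 0, 0, 0, 0))
  expect_error(ld_pmf(-1, 10), ">= 0")
})

test_that("the recursion agrees with FFT inversion of the Lea-Coulson pgf", {
  for (m in c(0.5, 2, 5)) {
    expect_lt(max(abs(ld_pmf(m, 100) - oracle_ld_pmf(m, 100))), 1e-6)
  }
})

test_that("pmf partial sums are non-decreasing, bounded by 1, with ~m/r tail", {
  for (m in c(0.5, 2, 5)) {
    p <- ld_pmf(m, 500)
    expect_true(all(p >= 0))
    cum <- cumsum(p)
    expect_true(all(diff(cum) >= 0))
    expect_lte(cum[length(cum)], 1)
    # the power-law tail: remaining mass at r_max is close to m/(r_max + 1)
    expect_equal(1 - cum[length(cum)], m / 501, tolerance = 0.15)
    # and the partial sum keeps growing toward 1 with a larger cap
    expect_gt(sum(ld_pmf(m, 2000)), cum[length(cum)])
  }
})

test_that("the method of the median solves the Lea-Coulson equation", {
  expect_equal(estimate_m_median(median_count = 1.24), 1, tolerance = 1e-9)
  expect_equal(estimate_m_median(median_count = 5), 2.375203, tolerance = 1e-6)
  expect_equal(estimate_m_median(median_count = 30), 8.788715, tolerance = 1e-6)
  # against the independent uniroot oracle over a grid
  for (med in c(0.5, 1, 3, 12, 80)) {
    expect_equal(estimate_m_median(median_count = med), oracle_m_median(med),
                 tolerance = 1e-8)
  }
  # monotone in the median count
  ms <- vapply(c(0.5, 1, 2, 5, 10, 30), function(r)
    estimate_m_median(median_count = r), numeric(1))
  expect_true(all(diff(ms) > 0))
  expect_error(estimate_m_median(c(0, 0, 0, 1)), "estimate_m_p0")
})

test_that("the MLE recovers m from large samples and sits at a likelihood maximum", {
  counts <- sample_ld_counts(2, 10000, seed = 42)
  m_hat <- estimate_m_mle(counts)
  expect_gt(m_hat, 1.9)
  expect_lt(m_hat, 2.1)
  # local-maximum property of the reported optimum
  ll <- function(m, counts, r_cap = 500L) {
    p <- pmax(ld_pmf(m, r_cap), 1e-300)
    tail_p <- max(1 - sum(p), 1e-300)
    sum(ifelse(counts > r_cap, log(tail_p), log(p[pmin(counts, r_cap) + 1])))
  }
  expect_gte(ll(m_hat, counts), ll(m_hat - 0.01, counts))
  expect_gte(ll(m_hat, counts), ll(m_hat + 0.01, counts))
  expect_error(estimate_m_mle(c(0, 0, 0)), "estimate_m_p0")
})

test_that("the MLE corrects for partial plating by binomial thinning", {
  set.seed(42)
  full <- sample_ld_counts(2, 3000)
  thinned <- rbinom(length(full), full, 0.5)
  m_hat <- estimate_m_mle(thinned, plating_fraction = 0.5)
  expect_lt(abs(m_hat - 2) / 2, 0.15)
  # ignoring the thinning underestimates m
  expect_lt(estimate_m_mle(thinned), m_hat)
})

test_that("the p0 method inverts the Poisson zero class", {
  expect_equal(estimate_m_p0(c(rep(0, 3679), rep(1, 6321))), 1, tolerance = 1e-3)
  expect_equal(estimate_m_p0(rep(0, 10)), 0)
  expect_equal(estimate_m_p0(c(rep(0, 60), rep(3, 40))), 0.5108, tolerance = 1e-4)
  expect_error(estimate_m_p0(c(1, 2, 3, 4, 5)), "p0")
})

test_that("mutation_rate divides m by Nt and brackets it with the dispersion CI", {
  # counts engineered to have median 5 -> m = 2.375203
  counts <- c(0, 1, 2, 4, 5, 5, 6, 9, 14, 30, 2, 7)
  expect_equal(median(counts), 5)
  expt <- fluctuation_experiment(counts, Nt = 1e8)
  est <- mutation_rate(expt, "median")
  expect_equal(est$rate, 2.375203e-8, tolerance = 1e-6)
  expect_equal(est$m / expt$Nt, est$rate)
  expect_true(est$ci_low < est$rate && est$rate < est$ci_high)
  # the CI follows m * exp(+/- 1.96 * 1.225 m^-0.315 / sqrt(C))
  sigma <- 1.225 * est$m^(-0.315) / sqrt(length(counts))
  expect_equal(est$m_ci_high / est$m, exp(qnorm(0.975) * sigma), tolerance = 1e-9)
  expect_error(fluctuation_experiment(counts, Nt = -1), "positive")
  expect_error(fluctuation_experiment(c(1, 2), Nt = 1e8), "at least 5")
  expect_error(fluctuation_experiment(counts, Nt = 10), "largest mutant count")
})

test_that("the median estimator leaves partial plating uncorrected with a warning", {
  expt <- fluctuation_experiment(c(1, 3, 5, 7, 9, 11), Nt = 1e7,
                                 plating_fraction = 0.5)
  expect_warning(est <- mutation_rate(expt, "median"), "plating_fraction")
  expect_gt(est$m, 0)
})

test_that("dispersion-formula CI for m has near-nominal coverage at C = 24", {
  set.seed(42)
  m_true <- 2
  hits <- 0; n_ok <- 0
  for (i in 1:500) {
    counts <- sample_ld_counts(m_true, 24, r_max = 500)
    if (median(counts) == 0) next
    est <- mutation_rate(fluctuation_experiment(counts, 1e8), "median")
    n_ok <- n_ok + 1
    if (est$m_ci_low <= m_true && m_true <= est$m_ci_high) hits <- hits + 1
  }
  coverage <- hits / n_ok
  expect_gte(coverage, 0.88)
  expect_lte(coverage, 0.99)
})

test_that("median frequency uses the binomial(n, 1/2) rank interval", {
  # 5 identical cultures: degenerate CI at the common frequency
  est <- mutation_frequency(rep(10, 5), rep(1e7, 5))
  expect_equal(est$median_frequency, 1e-6)
  expect_equal(est$ci_low, 1e-6)
  expect_equal(est$ci_high, 1e-6)
  # simple median
  est <- mutation_frequency(1:5, rep(1e7, 5))
  expect_equal(est$median_frequency, 3e-7)
  # n = 24: the CI is the (7th, 18th) order statistics
  set.seed(3)
  mutants <- sample(5:100, 24)
  est <- mutation_frequency(mutants, rep(1e6, 24))
  sorted <- sort(mutants / 1e6)
  expect_equal(est$ci_low, sorted[7])
  expect_equal(est$ci_high, sorted[18])
  # dilution factors scale each plate count
  est <- mutation_frequency(rep(2, 5), rep(100, 5),
                            mutant_dilution = 10, viable_dilution = 1e4)
  expect_equal(est$median_frequency, 20 / 1e6)
  # zero-viable cultures are excluded with a warning
  expect_warning(est <- mutation_frequency(c(1, 2, 3), c(1e6, 0, 1e6)),
                 "excluded")
  expect_equal(est$n_cultures, 2)
})

test_that("percent survival is the treated/control CFU ratio", {
  expect_equal(percent_survival(200, 200), 100)
  expect_equal(percent_survival(50, 200), 25)
  expect_equal(percent_survival(0, 200), 0)
  expect_error(percent_survival(10, 0), "positive")
})
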