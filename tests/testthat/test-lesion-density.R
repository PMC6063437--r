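test_that("relative amplification follows E^-(dCt_t - dCt_u) with clamping", {
  expect_equal(relative_amplification(5.415, 5.0), 0.750, tolerance = 1e-3)
  expect_equal(relative_amplification(5, 5), 1)
  expect_equal(relative_amplification(6, 5), 0.5)
  # treated amplifying better than untreated is clamped to 1 with a warning
  expect_warning(f <- relative_amplification(4.8, 5.0), "clamped")
  expect_equal(f, 1)
  expect_error(relative_amplification(5, 5, efficiency = 1), "efficiency")
})

test_that("the Poisson zero-class inversion gives uracils per 10 kb", {
  expect_equal(lesion_density(0.75, 3000), 0.9589, tolerance = 1e-4)
  expect_equal(lesion_density(1, 3000), 0)
  expect_equal(lesion_density(exp(-0.8), 4000), 2, tolerance = 1e-12)
  expect_error(lesion_density(0, 3000), "total signal loss")
  expect_error(lesion_density(-0.1, 3000), "total signal loss")
})

test_that("density is decreasing in the fraction and additive over lesion classes", {
  fr <- seq(0.05, 1, by = 0.05)
  d <- vapply(fr, lesion_density, numeric(1), amplicon_length = 3000)
  expect_true(all(diff(d) < 0))
  set.seed(5)
  f1 <- runif(20, 0.2, 1)
  f2 <- runif(20, 0.2, 1)
  for (i in seq_along(f1)) {
    expect_equal(lesion_density(f1[i] * f2[i], 4000),
                 lesion_density(f1[i], 4000) + lesion_density(f2[i], 4000),
                 tolerance = 1e-12)
  }
})

test_that("a noise-free plate round-trips to the exact density with zero CI width", {
  true_density <- 1.5
  L <- 3000L
  dct_delay <- -log2(exp(-true_density * L / 1e4))
  plate <- manual_plate(dct_treated = 5 + dct_delay, dct_untreated = 5, L = L)
  est <- density_with_ci(plate, "long", "norm", n_boot = 200, seed = 1)
  expect_equal(est$density, true_density, tolerance = 1e-9)
  expect_equal(est$ci_high - est$ci_low, 0, tolerance = 1e-9)
})

test_that("a noisy N = 6 plate recovers the density and is seed-deterministic", {
  cfg <- sim_config(seed = 42, density_true = 1.0, ct_noise_sd = 0.1)
  plate <- simulate_qpcr_plate(cfg)
  est1 <- density_with_ci(plate, "amp3000", "amp100_norm", seed = 7)
  est2 <- density_with_ci(plate, "amp3000", "amp100_norm", seed = 7)
  expect_lt(abs(est1$density - 1.0), 0.2)
  expect_identical(est1$ci_low, est2$ci_low)
  expect_identical(est1$ci_high, est2$ci_high)
  expect_true(est1$ci_low <= est1$density && est1$density <= est1$ci_high)
})

test_that("bootstrap and delta-method intervals roughly agree on a noisy plate", {
  cfg <- sim_config(seed = 14, density_true = 1.0, ct_noise_sd = 0.15)
  plate <- simulate_qpcr_plate(cfg)
  bs <- density_with_ci(plate, "amp3000", "amp100_norm", seed = 3)
  dm <- density_with_ci(plate, "amp3000", "amp100_norm", method = "delta")
  expect_equal(bs$density, dm$density)
  # same order of magnitude of uncertainty
  w_bs <- bs$ci_high - bs$ci_low
  w_dm <- dm$ci_high - dm$ci_low
  expect_gt(w_bs / w_dm, 0.5)
  expect_lt(w_bs / w_dm, 2)
})

test_that("density estimation demands replicates and known targets", {
  plate <- manual_plate(5.4, 5.0, reps = 1L)
  expect_error(density_with_ci(plate, "long", "norm"), "at least 2 replicate")
  plate3 <- manual_plate(5.4, 5.0)
  expect_error(density_with_ci(plate3, "nope", "norm"), "no treated wells")
})

test_that("3 kb and 4 kb amplicons over the same lesion field agree statistically", {
  set.seed(42)
  d3 <- d4 <- numeric(8)
  for (i in 1:8) {
    plate <- simulate_qpcr_plate(sim_config(seed = NULL, density_true = 1.2,
                                            ct_noise_sd = 0.15))
    point <- function(target) {
      tt <- plate$ct[plate$target == target & plate$treated]
      ut <- plate$ct[plate$target == target & !plate$treated]
      tn <- plate$ct[plate$target == "amp100_norm" & plate$treated]
      un <- plate$ct[plate$target == "amp100_norm" & !plate$treated]
      L <- plate$amplicon_length[plate$target == target][1]
      f <- suppressWarnings(
        relative_amplification(mean(tt) - mean(tn), mean(ut) - mean(un)))
      lesion_density(max(f, 1e-12), L)
    }
    d3[i] <- point("amp3000")
    d4[i] <- point("amp4000")
  }
  res <- compare_densities(d3, d4)
  expect_gt(res$p, 0.01)
})

test_that("group comparison matches the textbook pooled-variance t-test", {
  expect_equal(compare_densities(c(1, 2, 3), c(1, 2, 3)), list(t = 0, p = 1))
  res <- compare_densities(c(0.9, 1.0, 1.1), c(1.9, 2.0, 2.1))
  orc <- oracle_pooled_t(c(0.9, 1.0, 1.1), c(1.9, 2.0, 2.1))
  expect_equal(res$t, -12.25, tolerance = 1e-3)
  expect_equal(res$t, orc$t, tolerance = 1e-10)
  expect_equal(res$p, orc$p, tolerance = 1e-10)
  expect_lt(res$p, 0.001)
  # degenerate zero-variance case falls back to the documented convention
  expect_equal(compare_densities(c(1, 1), c(1, 1)), list(t = 0, p = 1))
  # random cases agree with the closed form
  set.seed(9)
  for (i in 1:10) {
    a <- rnorm(5); b <- rnorm(7, 0.5)
    res <- compare_densities(a, b)
    orc <- oracle_pooled_t(a, b)
    expect_equal(res$t, orc$t, tolerance = 1e-10)
    expect_equal(res$p, orc$p, tolerance = 1e-10)
  }
  expect_error(compare_densities(1, c(1, 2)), "at least 2")
})
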