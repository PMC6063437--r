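# Independent oracles used to cross-check the package implementations.
# These deliberately take different computational routes from the code
# under test.

# Lea-Coulson median equation solved with stats::uniroot (the package uses
# its own bisection)
oracle_m_median <- function(median_count) {
  stats::uniroot(function(m) median_count / m - log(m) - 1.24,
                 lower = 1e-8, upper = max(median_count, 1) * 100,
                 tol = 1e-12)$root
}

# Luria-Delbruck pmf by FFT inversion of the closed-form Lea-Coulson
# probability generating function G(z) = exp(m (1-z) ln(1-z) / z)
# (the package uses the Ma-Sandri-Sarkar recursion)
oracle_ld_pmf <- function(m, r_max, N = 16384) {
  k <- 0:(N - 1)
  z <- exp(2i * pi * k / N)
  g <- exp(m * (1 - z) * log(1 - z) / z)
  g[1] <- 1 + 0i
  (Re(stats::fft(g)) / N)[1:(r_max + 1)]
}

# Wilson score interval by the closed form
oracle_wilson <- function(x, n, conf = 0.95) {
  z <- qnorm(1 - (1 - conf) / 2)
  p <- x / n
  centre <- (p + z^2 / (2 * n)) / (1 + z^2 / n)
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / (1 + z^2 / n)
  c(centre - half, centre + half)
}

# Pooled-variance two-sample t statistic and two-sided p by the textbook
# closed form
oracle_pooled_t <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
  t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  list(t = t, p = 2 * pt(-abs(t), df = na + nb - 2))
}

# A Ct plate built by hand (no generator): four well groups with exact Cts
manual_plate <- function(dct_treated, dct_untreated, L = 3000L,
                         reps = 3L, norm_ct = 18, sample_id = "manual") {
  tibble::tibble(
    sample_id = sample_id,
    target = rep(c("long", "long", "norm", "norm"), each = reps),
    amplicon_length = rep(c(L, L, 100L, 100L), each = reps),
    treated = rep(c(TRUE, FALSE, TRUE, FALSE), each = reps),
    ct = rep(c(norm_ct + dct_treated, norm_ct + dct_untreated,
               norm_ct, norm_ct), each = reps)
  )
}
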