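#' Uracil lesion density from long-amplicon qPCR
#'
#' UDG excises uracil leaving an abasic site; Endonuclease VIII converts it
#' to a strand break that blocks the polymerase. A long amplicon (3-4 kb)
#' therefore amplifies only from templates carrying zero lesions within it,
#' while the ~100 bp normalizer amplicon is effectively lesion-free and
#' corrects for template loading. With lesions placed as a Poisson process
#' of density d per 10 kb, the intact-template fraction for an amplicon of
#' length L bp is exp(-d L / 10000) — so the observed treated/untreated
#' relative amplification At/Au inverts to
#' `d = -ln(At/Au) * 10000 / L`.
#'
#' @name lesion_density_module
NULL

#' Treated/untreated relative amplification from delta-Cts
#'
#' Both delta-Cts must be taken against the matched ~100 bp normalizer.
#' One extra cycle of delay in the treated sample halves its relative
#' amplification (at E = 2). Fractions marginally above 1 (treated
#' amplifying better than untreated, i.e. pure noise at zero lesion
#' density) are clamped to 1 with a warning rather than propagated into a
#' negative density, since the Poisson model's support is [0, 1].
#'
#' @param treated_dct Delta-Ct of the treated long amplicon vs its normalizer.
#' @param untreated_dct Delta-Ct of the untreated long amplicon vs its normalizer.
#' @param efficiency Per-cycle amplification factor in (1, 2].
#' @return Relative amplification fraction in (0, 1].
#' @examples
#' relative_amplification(5.415, 5.0)   # ~0.75
#' relative_amplification(6, 5)         # 0.5
#' @export
relative_amplification <- function(treated_dct, untreated_dct, efficiency = 2) {
  .check_efficiency(efficiency)
  frac <- relative_quantity(delta_ct(treated_dct, untreated_dct), efficiency)
  if (frac > 1) {
    warning(sprintf(
      "relative amplification %.4f > 1 (treated amplified better); clamped to 1",
      frac), call. = FALSE)
    frac <- 1
  }
  frac
}

#' Uracil density per 10 kb from a relative amplification
#'
#' The Poisson zero-class inversion: `density = -ln(fraction) * 10000 /
#' amplicon_length`. A fraction of 1 (no amplification loss) gives density
#' 0; a fraction of 0 would mean total signal loss, where the density is
#' unbounded and an error is raised.
#'
#' @param fraction Treated/untreated relative amplification in (0, 1].
#' @param amplicon_length Long-amplicon length in bp.
#' @return Lesions (uracils) per 10 kb of DNA.
#' @examples
#' lesion_density(0.75, 3000)  # ~0.96, i.e. about 1 uracil per 10 kb
#' @export
lesion_density <- function(fraction, amplicon_length) {
  if (!is.numeric(fraction) || !is.finite(fraction)) {
    stop("`fraction` must be a finite number", call. = FALSE)
  }
  if (fraction <= 0) stop("total signal loss; density undefined", call. = FALSE)
  if (fraction > 1) stop("`fraction` must be <= 1; clamp upstream", call. = FALSE)
  if (amplicon_length <= 0) stop("`amplicon_length` must be positive", call. = FALSE)
  -log(fraction) * 10000 / amplicon_length
}

.pull_wells <- function(ct, target_name, treated_flag) {
  cts <- ct$ct[ct$target == target_name & ct$treated == treated_flag]
  if (length(cts) == 0L) {
    stop(sprintf("no %s wells for target '%s'",
                 if (treated_flag) "treated" else "untreated", target_name),
         call. = FALSE)
  }
  cts
}

#' Lesion-density point estimate with a bootstrap 95% CI
#'
#' The point estimate uses the mean Ct of each of the four well groups
#' (treated/untreated x long-amplicon/normalizer). The CI comes from a
#' nonparametric bootstrap that resamples wells within each group
#' independently and recomputes the density; with N = 6 replicates the
#' delta-Ct noise is non-normal after exponentiation, so the percentile
#' bootstrap is the primary interval (the delta method is available via
#' `method = "delta"` for cross-checking).
#'
#' @param ct A Ct table (tibble/data.frame with columns `sample_id`,
#'   `target`, `amplicon_length`, `treated`, `ct`) holding the wells of one
#'   sample: treated and untreated wells for both the long amplicon and the
#'   normalizer.
#' @param target Long-amplicon target name in `ct$target`.
#' @param normalizer Normalizer (~100 bp) target name.
#' @param efficiency Per-cycle amplification factor in (1, 2].
#' @param n_boot Number of bootstrap resamples.
#' @param seed Integer seed making the CI reproducible.
#' @param method `"bootstrap"` (default) or `"delta"` (first-order delta
#'   method on the delta-delta-Ct variance).
#' @return An object of class `lesion_density_estimate`: a list with
#'   `density` (per 10 kb), `ci_low`, `ci_high`, `fraction`,
#'   `amplicon_length`, `n_replicates`, `method`.
#' @export
density_with_ci <- function(ct, target, normalizer, efficiency = 2,
                            n_boot = 2000, seed = NULL,
                            method = c("bootstrap", "delta")) {
  method <- match.arg(method)
  .check_efficiency(efficiency)
  wells <- list(
    tt = .pull_wells(ct, target, TRUE),
    tn = .pull_wells(ct, normalizer, TRUE),
    ut = .pull_wells(ct, target, FALSE),
    un = .pull_wells(ct, normalizer, FALSE)
  )
  if (any(lengths(wells) < 2L)) {
    stop("at least 2 replicate wells are required in every group", call. = FALSE)
  }
  amplicon_length <- unique(ct$amplicon_length[ct$target == target])
  if (length(amplicon_length) != 1L) {
    stop("target '", target, "' maps to more than one amplicon_length", call. = FALSE)
  }

  dct_t <- delta_ct(mean(wells$tt), mean(wells$tn))
  dct_u <- delta_ct(mean(wells$ut), mean(wells$un))
  frac <- suppressWarnings(relative_amplification(dct_t, dct_u, efficiency))
  density <- lesion_density(frac, amplicon_length)

  if (method == "bootstrap") {
    if (!is.null(seed)) {
      old <- .Random.seed_save()
      on.exit(.Random.seed_restore(old), add = TRUE)
      set.seed(seed)
    }
    boot_means <- lapply(wells, function(w) {
      idx <- matrix(sample.int(length(w), length(w) * n_boot, replace = TRUE),
                    nrow = length(w))
      colMeans(matrix(w[idx], nrow = length(w)))
    })
    ddct <- (boot_means$tt - boot_means$tn) - (boot_means$ut - boot_means$un)
    frac_b <- pmin(efficiency^(-ddct), 1)
    ok <- is.finite(frac_b) & frac_b > 0
    if (mean(!ok) > 0.5) {
      stop("bootstrap density undefined in > 50% of resamples", call. = FALSE)
    }
    dens_b <- -log(frac_b[ok]) * 10000 / amplicon_length
    ci <- unname(quantile(dens_b, c(0.025, 0.975), type = 7))
  } else {
    # delta method: var(ddCt) from the four independent well-group means,
    # density = ln(E) * ddct * 1e4 / L is linear in ddct (pre-clamp)
    v <- sum(vapply(wells, function(w) var(w) / length(w), numeric(1)))
    se_density <- log(efficiency) * sqrt(v) * 10000 / amplicon_length
    ci <- density + c(-1, 1) * qnorm(0.975) * se_density
    ci[1] <- max(ci[1], 0)
  }
  ci[1] <- min(ci[1], density)
  ci[2] <- max(ci[2], density)

  structure(
    list(density = density, ci_low = ci[1], ci_high = ci[2],
         fraction = frac, amplicon_length = amplicon_length,
         n_replicates = min(lengths(wells)), method = method),
    class = "lesion_density_estimate"
  )
}

#' @export
print.lesion_density_estimate <- function(x, ...) {
  cat(sprintf(
    "<lesion_density_estimate> %.3f uracils/10 kb (95%% CI %.3f-%.3f), %d bp amplicon, n = %d, %s CI\n",
    x$density, x$ci_low, x$ci_high, x$amplicon_length, x$n_replicates, x$method))
  invisible(x)
}

#' Compare two groups of replicate densities by unpaired t-test
#'
#' Two-sided unpaired Student t-test with pooled (equal) variance. When
#' both groups are constant with equal means the test is degenerate and
#' `t = 0, p = 1` is returned by convention.
#'
#' @param group_a,group_b Numeric vectors of replicate density estimates
#'   (each of length >= 2).
#' @return A list with `t` and `p`.
#' @examples
#' compare_densities(c(0.9, 1.0, 1.1), c(1.9, 2.0, 2.1))
#' @export
compare_densities <- function(group_a, group_b) {
  if (length(group_a) < 2L || length(group_b) < 2L) {
    stop("each group needs at least 2 replicates", call. = FALSE)
  }
  if (var(group_a) == 0 && var(group_b) == 0) {
    if (mean(group_a) == mean(group_b)) return(list(t = 0, p = 1))
    return(list(t = sign(mean(group_a) - mean(group_b)) * Inf, p = 0))
  }
  tt <- t.test(group_a, group_b, var.equal = TRUE)
  list(t = unname(tt$statistic), p = tt$p.value)
}

# Save/restore .Random.seed so seeded helpers do not disturb the caller's RNG
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}
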