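#' Mutation-spectrum partitioning
#'
#' Sequencing the reporter allele in independent revertants yields a
#' spectrum: how many of the sequenced mutants carry each base-substitution
#' class (strand-collapsed labels read on the top strand, so "A>C" means
#' A:T -> C:G). The overall rate (or frequency) is partitioned into
#' class-specific rates by multiplying with the class proportion; class
#' CIs are the overall CI scaled by the same proportion (a documented
#' choice — a multinomial bootstrap that also propagates spectrum sampling
#' error is available via [class_rate_bootstrap_ci()]). Two conditions are
#' called significantly different when their 95% CIs do not overlap; this
#' is a conservative criterion.
#'
#' @name spectra_module
NULL

#' Construct a mutation spectrum
#'
#' @param condition Condition label (strain/treatment).
#' @param class_counts Named integer vector of counts per mutation class,
#'   e.g. `c("A>C" = 30, "T>G" = 37, "G>C" = 5)`.
#' @param total_sequenced Total revertants sequenced (>= sum of counts;
#'   classes not listed make up the difference).
#' @return An object of class `mutation_spectrum`.
#' @export
mutation_spectrum <- function(condition, class_counts, total_sequenced) {
  if (is.null(names(class_counts)) || any(names(class_counts) == "")) {
    stop("`class_counts` must be a named vector", call. = FALSE)
  }
  if (any(class_counts < 0)) stop("counts must be non-negative", call. = FALSE)
  total_sequenced <- as.integer(total_sequenced)
  if (is.na(total_sequenced) || total_sequenced <= 0L) {
    stop("`total_sequenced` must be a positive integer", call. = FALSE)
  }
  if (sum(class_counts) > total_sequenced) {
    stop("class counts sum to more than `total_sequenced`", call. = FALSE)
  }
  structure(
    list(condition = condition,
         class_counts = setNames(as.integer(class_counts), names(class_counts)),
         total_sequenced = total_sequenced),
    class = "mutation_spectrum"
  )
}

#' @export
print.mutation_spectrum <- function(x, ...) {
  cat(sprintf("<mutation_spectrum> %s: %s of %d sequenced\n", x$condition,
              paste(sprintf("%s=%d", names(x$class_counts), x$class_counts),
                    collapse = ", "),
              x$total_sequenced))
  invisible(x)
}

.spectrum_count <- function(spectrum, classes) {
  known <- names(spectrum$class_counts)
  unknown <- setdiff(classes, known)
  if (length(unknown) > 0L) {
    stop("unknown mutation class(es) ", paste(unknown, collapse = ", "),
         "; known classes: ", paste(known, collapse = ", "), call. = FALSE)
  }
  sum(spectrum$class_counts[classes])
}

#' Proportion of sequenced revertants in a class (or class set)
#'
#' Point estimate `count / total_sequenced` with a Wilson score 95%
#' interval (computed by `prop.test` without continuity correction).
#'
#' @param spectrum A [mutation_spectrum()].
#' @param classes Character vector of class labels to pool.
#' @return List with `proportion`, `ci_low`, `ci_high`, `count`, `total`.
#' @examples
#' sp <- mutation_spectrum("apn1", c("A>C" = 30, "T>G" = 37, "G>C" = 5), 72)
#' class_proportion(sp, c("A>C", "T>G"))
#' @export
class_proportion <- function(spectrum, classes) {
  stopifnot(inherits(spectrum, "mutation_spectrum"))
  count <- .spectrum_count(spectrum, classes)
  total <- spectrum$total_sequenced
  ci <- if (count == 0L) {
    c(0, prop.test(0, total, correct = FALSE)$conf.int[2])
  } else {
    prop.test(count, total, correct = FALSE)$conf.int[1:2]
  }
  list(proportion = count / total, ci_low = unname(ci[1]),
       ci_high = unname(ci[2]), count = count, total = total)
}

#' Class-specific rate from an overall rate and a spectrum
#'
#' `rate_class = overall rate x count/total`; the CI is the overall CI
#' scaled by the same proportion. A class never observed in the spectrum
#' gets rate 0 with a rule-of-three upper bound
#' `overall ci_high x 3/total`.
#'
#' @param overall A [mutation_rate_estimate][mutation_rate] or
#'   [frequency_estimate][mutation_frequency] (or any list with `rate` or
#'   `median_frequency` plus `ci_low`, `ci_high`).
#' @param spectrum A [mutation_spectrum()].
#' @param classes Character vector of class labels to pool.
#' @return An object of class `class_rate_estimate`: list with `classes`,
#'   `rate`, `ci_low`, `ci_high`, `proportion`.
#' @export
class_rate <- function(overall, spectrum, classes) {
  stopifnot(inherits(spectrum, "mutation_spectrum"))
  point <- if (!is.null(overall$rate)) overall$rate else overall$median_frequency
  if (is.null(point) || point < 0) {
    stop("`overall` must carry a non-negative rate or median_frequency",
         call. = FALSE)
  }
  count <- .spectrum_count(spectrum, classes)
  total <- spectrum$total_sequenced
  prop <- count / total
  if (count == 0L) {
    est <- list(rate = 0, ci_low = 0, ci_high = overall$ci_high * 3 / total)
  } else {
    est <- list(rate = point * prop,
                ci_low = overall$ci_low * prop,
                ci_high = overall$ci_high * prop)
  }
  structure(c(list(classes = classes), est, list(proportion = prop)),
            class = "class_rate_estimate")
}

#' @export
print.class_rate_estimate <- function(x, ...) {
  cat(sprintf("<class_rate_estimate> %s: %.4g (95%% CI %.4g-%.4g)\n",
              paste(x$classes, collapse = "+"), x$rate, x$ci_low, x$ci_high))
  invisible(x)
}

#' Bootstrap class-rate CI propagating spectrum sampling error
#'
#' Resamples the spectrum binomially (class count out of total) and, when
#' culture counts are supplied, the cultures with replacement (re-running
#' the median estimator), multiplying the two resampled components. This
#' is the alternative to the default scaled-CI rule for users who want the
#' multinomial sampling error of the sequenced sample reflected in the
#' class CI.
#'
#' @param overall A [mutation_rate_estimate][mutation_rate].
#' @param spectrum A [mutation_spectrum()].
#' @param classes Class labels to pool.
#' @param counts Optional per-culture mutant counts to resample; when
#'   omitted only the spectrum is resampled and the overall rate is held
#'   fixed.
#' @param Nt Final cells per culture (required with `counts`).
#' @param n_boot Number of resamples.
#' @param seed Integer seed.
#' @return A `class_rate_estimate` with percentile-bootstrap bounds.
#' @export
class_rate_bootstrap_ci <- function(overall, spectrum, classes,
                                    counts = NULL, Nt = NULL,
                                    n_boot = 2000, seed = NULL) {
  stopifnot(inherits(spectrum, "mutation_spectrum"))
  if (!is.null(seed)) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(seed)
  }
  count <- .spectrum_count(spectrum, classes)
  total <- spectrum$total_sequenced
  prop_b <- rbinom(n_boot, total, count / total) / total
  rate_b <- if (is.null(counts)) {
    rep(overall$rate, n_boot)
  } else {
    stopifnot(!is.null(Nt))
    vapply(seq_len(n_boot), function(i) {
      res <- sample(counts, replace = TRUE)
      med <- median(res)
      if (med <= 0) NA_real_ else estimate_m_median(median_count = med) / Nt
    }, numeric(1))
  }
  boot <- rate_b * prop_b
  boot <- boot[is.finite(boot)]
  ci <- unname(quantile(boot, c(0.025, 0.975)))
  structure(
    list(classes = classes, rate = overall$rate * count / total,
         ci_low = ci[1], ci_high = ci[2], proportion = count / total),
    class = "class_rate_estimate"
  )
}

#' Fold change between two (class) rate estimates
#'
#' @param high,low `class_rate_estimate`s, rate estimates, or bare numbers;
#'   the returned fold is `high / low`.
#' @return The fold change.
#' @examples
#' fold_change(15e-9, 2e-9)  # 7.5
#' @export
fold_change <- function(high, low) {
  pull_rate <- function(x) {
    if (is.numeric(x)) return(x)
    if (!is.null(x$rate)) return(x$rate)
    if (!is.null(x$median_frequency)) return(x$median_frequency)
    stop("cannot extract a rate from object of class ", class(x)[1],
         call. = FALSE)
  }
  h <- pull_rate(high)
  l <- pull_rate(low)
  if (l <= 0) stop("undefined fold; report absolute rates", call. = FALSE)
  h / l
}

#' Are two estimates significantly different by CI non-overlap?
#'
#' `TRUE` iff the 95% intervals are disjoint (touching bounds count as
#' overlapping). Non-overlap of 95% CIs is a conservative significance
#' criterion: it implies p < 0.05 but the converse does not hold.
#'
#' @param a,b Estimates carrying `ci_low` and `ci_high`.
#' @return Logical.
#' @export
ci_overlap_significant <- function(a, b) {
  for (x in list(a, b)) {
    if (is.null(x$ci_low) || is.null(x$ci_high) || x$ci_low > x$ci_high) {
      stop("both arguments need well-formed `ci_low` <= `ci_high`", call. = FALSE)
    }
  }
  a$ci_low > b$ci_high || b$ci_low > a$ci_high
}
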