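#' Seeded generators emulating the three data-producing assays
#'
#' The generators mirror the study designs the analysis functions expect:
#' 12-24 parallel cultures for fluctuation assays, N = 6 qPCR replicate
#' wells per condition with a ~100 bp normalizer plus 3 kb / 4 kb long
#' amplicons, and multinomial revertant spectra. Lesions are Poisson-placed
#' so the intact-template fraction is the Poisson zero-class
#' `exp(-density * L / 1e4)` — the same model [lesion_density()] inverts,
#' which makes noise-free round-trips exact. Ct noise is Gaussian on the
#' cycle scale (sd 0.15 by default, a typical technical variance for
#' SYBR-green qPCR). All generators are deterministic given a seed.
#'
#' @name synthetic_data_module
NULL

#' Simulation configuration
#'
#' Bundles the generator parameters with their study-design defaults:
#' 24 parallel cultures, N = 6 qPCR replicates, amplicons of 100/3000/4000
#' bp, Ct noise sd 0.15 cycles, perfect doubling efficiency.
#'
#' @param seed Integer seed.
#' @param n_cultures Parallel cultures per fluctuation assay.
#' @param m_true Expected mutations per culture.
#' @param Nt Final cells per culture.
#' @param density_true Lesions per 10 kb for the qPCR plate.
#' @param amplicon_lengths Amplicon lengths in bp; the shortest is the
#'   normalizer.
#' @param n_qpcr_reps Replicate wells per condition.
#' @param ct_noise_sd Gaussian Ct noise, cycles.
#' @param efficiency Per-cycle amplification factor in (1, 2].
#' @param spectrum_probs Named class probabilities summing to 1.
#' @param n_sequenced Revertants sequenced per spectrum.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_cultures = 24L, m_true = 2, Nt = 2e7,
                       density_true = 1, amplicon_lengths = c(100L, 3000L, 4000L),
                       n_qpcr_reps = 6L, ct_noise_sd = 0.15, efficiency = 2,
                       spectrum_probs = c("A>C" = 0.42, "T>G" = 0.51, "G>C" = 0.07),
                       n_sequenced = 72L) {
  stopifnot(n_cultures >= 1L, n_qpcr_reps >= 1L, Nt > 0, m_true >= 0,
            density_true >= 0, ct_noise_sd >= 0, all(amplicon_lengths >= 50))
  .check_efficiency(efficiency)
  if (abs(sum(spectrum_probs) - 1) > 1e-8) {
    stop("`spectrum_probs` must sum to 1", call. = FALSE)
  }
  structure(as.list(environment()), class = "sim_config")
}

#' Sample Luria-Delbruck mutant counts
#'
#' Inverse-CDF sampling from the Ma-Sandri-Sarkar pmf. The table is
#' extended until the cumulative mass reaches `1 - 1e-9` or `r_max`,
#' whichever comes first; the ~m/r power-law tail makes the former
#' unreachable for realistic m, so draws falling beyond the table are
#' assigned `r_max` (a capped jackpot). This leaves the zero class and the
#' median untouched for any m of practical size.
#'
#' @param m Expected mutations per culture.
#' @param n_cultures Number of cultures to draw.
#' @param seed Integer seed (optional; uses the current RNG stream if NULL).
#' @param r_max Hard cap on the tabulated pmf.
#' @return Integer vector of mutant counts.
#' @examples
#' sample_ld_counts(2, 24, seed = 1)
#' @export
sample_ld_counts <- function(m, n_cultures, seed = NULL, r_max = 5000L) {
  if (m < 0) stop("`m` must be >= 0", call. = FALSE)
  if (!is.null(seed)) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(seed)
  }
  if (m == 0) return(integer(n_cultures))
  p <- ld_pmf(m, r_max)
  cum <- cumsum(p)
  u <- runif(n_cultures)
  counts <- findInterval(u, cum) # 0 when u < cum[1] (= p0), up to r_max + 1
  as.integer(pmin(counts, r_max))
}

#' Mechanistic per-generation culture-growth simulator
#'
#' An independent mechanism against which the pmf-based machinery can be
#' cross-checked: the culture doubles from `N0` to `Nt`; in each generation
#' the number of new mutants is Poisson with mean `rate x cells dividing`,
#' and every mutant lineage doubles deterministically thereafter (the
#' classic Luria-Delbruck assumption of equal mutant fitness and no
#' phenotypic lag). The expected total number of mutations is
#' `rate x (Nt - N0)`.
#'
#' @param N0 Initial cells (>= 1).
#' @param Nt Final cells (> N0; rounded to the nearest power-of-two
#'   multiple of N0 internally).
#' @param rate_per_division Mutation probability per cell division.
#' @param seed Integer seed (optional).
#' @return Final mutant count (one culture).
#' @export
simulate_culture_growth <- function(N0, Nt, rate_per_division, seed = NULL) {
  stopifnot(N0 >= 1, Nt > N0, rate_per_division >= 0)
  if (rate_per_division * Nt > 1e7) {
    stop("expected mutant number exceeds 1e7; degenerate regime", call. = FALSE)
  }
  if (!is.null(seed)) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(seed)
  }
  generations <- round(log2(Nt / N0))
  if (generations < 1) stop("`Nt` must allow at least one doubling", call. = FALSE)
  mutants <- 0
  for (g in seq_len(generations)) {
    dividing <- N0 * 2^(g - 1)
    new_mutants <- rpois(1L, rate_per_division * dividing)
    # lineages founded in generation g double for the remaining generations
    mutants <- mutants + new_mutants * 2^(generations - g)
  }
  mutants
}

#' Simulate a long-amplicon qPCR plate
#'
#' For each amplicon of length L, treated wells carry the lesion signal:
#' the intact-template fraction `f = exp(-density_true * L / 1e4)` delays
#' the treated Ct by `-log_E(f)` cycles; untreated wells omit the term, and
#' the shortest (~100 bp) amplicon acts as a lesion-free normalizer on both
#' sides. Gaussian noise of `ct_noise_sd` cycles is added per well. Base
#' Cts grow mildly with amplicon length (a loading/efficiency offset that
#' the normalization removes).
#'
#' @param config A [sim_config()]; `density_true`, `amplicon_lengths`,
#'   `n_qpcr_reps`, `ct_noise_sd`, `efficiency` and `seed` are used.
#' @param sample_id Sample label written to the table.
#' @return A tibble Ct table with columns `sample_id`, `target`,
#'   `amplicon_length`, `treated`, `ct` (one row per well).
#' @examples
#' plate <- simulate_qpcr_plate(sim_config(seed = 7, density_true = 1.5))
#' @export
simulate_qpcr_plate <- function(config = sim_config(), sample_id = "sim") {
  stopifnot(inherits(config, "sim_config"))
  if (config$density_true < 0) stop("`density_true` must be >= 0", call. = FALSE)
  if (!is.null(config$seed)) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(config$seed)
  }
  lengths_bp <- sort(as.integer(config$amplicon_lengths))
  normalizer <- lengths_bp[1]
  rows <- lapply(lengths_bp, function(L) {
    base_ct <- 18 + 2 * log10(L / 100 + 1)  # longer amplicons cross later
    lesion_delay <- if (L == normalizer) 0 else {
      f <- exp(-config$density_true * L / 1e4)
      -log(f) / log(config$efficiency)
    }
    target <- if (L == normalizer) sprintf("amp%d_norm", L) else sprintf("amp%d", L)
    make <- function(treated) {
      tibble::tibble(
        sample_id = sample_id,
        target = target,
        amplicon_length = L,
        treated = treated,
        ct = base_ct + (if (treated) lesion_delay else 0) +
          rnorm(config$n_qpcr_reps, 0, config$ct_noise_sd)
      )
    }
    dplyr::bind_rows(make(TRUE), make(FALSE))
  })
  dplyr::bind_rows(rows)
}

#' Sample a mutation spectrum
#'
#' Multinomial draw of `n_sequenced` revertants over the configured class
#' probabilities.
#'
#' @param n_sequenced Number of revertants sequenced (> 0).
#' @param spectrum_probs Named class probabilities summing to 1.
#' @param seed Integer seed (optional).
#' @param condition Condition label for the returned spectrum.
#' @return A [mutation_spectrum()].
#' @export
sample_spectrum <- function(n_sequenced, spectrum_probs, seed = NULL,
                            condition = "sim") {
  if (abs(sum(spectrum_probs) - 1) > 1e-8) {
    stop("`spectrum_probs` must sum to 1", call. = FALSE)
  }
  if (!is.null(seed)) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(seed)
  }
  counts <- drop(rmultinom(1L, n_sequenced, spectrum_probs))
  names(counts) <- names(spectrum_probs)
  mutation_spectrum(condition, counts, n_sequenced)
}
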