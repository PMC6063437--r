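---
title: "Quantifying uracil in DNA: lesion densities from long-amplicon qPCR and mutation rates from fluctuation assays"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying uracil in DNA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(uralens)
```

## The two measurements

Uracil enters genomic DNA when polymerases incorporate dUTP in place of
dTTP; its steady-state level reflects the cellular [dUTP]/[dTTP] balance
and, at individual loci, how much repair-associated DNA synthesis the
locus experiences. `uralens` implements the two complementary ways this is
quantified in a yeast reporter system:

1. **Direct physical counting** of uracils at a locus by long-amplicon
   qPCR after in-vitro UDG/Endonuclease VIII digestion.
2. **Genetic counting** of uracil-derived mutations through fluctuation
   assays at a reversion reporter, with sequencing of revertants to split
   the rate into base-substitution classes.

## Lesion density from amplification loss

UDG excises uracil, leaving an abasic site; EndoVIII cleaves the backbone
there. A cleaved template cannot support amplification across the break,
so a long amplicon (3–4 kb here) amplifies only from the sub-population of
molecules with *zero* lesions inside it. A ~100 bp amplicon at the same
locus is small enough that hitting a lesion is negligible; its Ct
normalizes for template loading. If lesions fall as a Poisson process with
density $d$ per 10 kb, the zero-lesion fraction of an $L$-bp amplicon is
$e^{-dL/10^4}$, and equating it with the observed treated/untreated
relative amplification $A_t/A_u$ gives

$$ d \;=\; -\ln\!\left(\frac{A_t}{A_u}\right)\times\frac{10^4}{L}. $$

The fraction itself comes from Ct arithmetic: with per-cycle efficiency
$E$ (default 2, i.e. perfect doubling — no standard curves are fitted),
$A_t/A_u = E^{-(\Delta Ct_t - \Delta Ct_u)}$, each $\Delta Ct$ taken
against the matched short amplicon. Replicates are averaged on the Ct
scale before differencing (the usual $\Delta\Delta$Ct convention; the
alternative — averaging linear quantities — changes results only at
second order in the noise).

```{r worked}
frac <- relative_amplification(treated_dct = 5.415, untreated_dct = 5.0)
frac
lesion_density(frac, amplicon_length = 3000)
```

A ~75% relative amplification of a 3 kb amplicon therefore corresponds to
roughly one uracil per 10 kb.

Two numerical edges are handled explicitly. A fraction marginally above 1
(treated wells amplifying *better*, which pure noise produces at low
density) is clamped to 1 with a warning instead of returning a negative
density — the Poisson model's support ends at zero lesions. A fraction of
0 (total signal loss) leaves the density unbounded and raises an error
rather than returning infinity.

### Uncertainty

`density_with_ci()` resamples wells within each of the four groups
(treated/untreated × long/normalizer) independently and recomputes the
density; the percentile interval over 2000 resamples is the default 95%
CI. With only N = 6 replicate wells per group the exponentiation makes the
density error visibly non-normal, which is why the bootstrap is primary
and the first-order delta method (`method = "delta"`) is kept as a
cross-check. Group comparisons use the unpaired equal-variance Student
t-test, matching the convention of the experimental design this package
accompanies (the replicates are treated as exchangeable; whether they are
biological or technical is immaterial to the arithmetic, though it does
affect interpretation).

## Mutation rates from fluctuation assays

In a fluctuation assay, parallel cultures grow from a small inoculum to
$N_t$ cells and are plated selectively; mutant counts across cultures
follow the Luria–Delbrück distribution, whose heavy "jackpot" tail
reflects mutations arising early in growth. The package computes the
distribution with the Ma–Sandri–Sarkar recursion

$$ p_0 = e^{-m}, \qquad
   p_r = \frac{m}{r}\sum_{i=0}^{r-1}\frac{p_i}{r-i+1}, $$

where $m$ is the expected number of mutations per culture. The tail decays
as $m/r^2$, so the mass beyond a cap $r$ is about $m/(r{+}1)$; partial
sums converge to 1 slowly, and both the sampler and the MLE account for
the truncated tail explicitly (the sampler assigns beyond-table draws to
the cap, the MLE pools them into $1-\sum_{r\le r_{\text{cap}}} p_r$).

The primary estimator is the **Lea–Coulson method of the median**: solve

$$ \frac{\tilde r}{m} - \ln m = 1.24 $$

for $m$, with $\tilde r$ the sample median mutant count. The left side is
strictly decreasing in $m$, so bisection on $[10^{-8}, 100\max(\tilde
r,1)]$ to relative width $10^{-12}$ is deterministic and unique. Two
cross-checking estimators are provided: the MLE under the full
distribution, and the p0 method $m = -\ln(\text{zero fraction})$. The
median method requires $\tilde r > 0$; when more than half the cultures
carry no mutants (which is guaranteed on average once $m < \ln 2$) it
refuses and points to the p0 method rather than extrapolating.

The per-cell rate is $m/N_t$. Its 95% CI uses the dispersion of $\ln m$,
$\sigma_{\ln m} = 1.225\,m^{-0.315}/\sqrt{C}$ for $C$ cultures, so
$\text{CI} = m\,e^{\pm 1.96\sigma_{\ln m}}$. This classical approximation
is the package's documented choice; it is deliberately isolated in one
place so a different CI strategy can be substituted, and its empirical
coverage at the design size used throughout ($C = 24$, $m = 2$) is
verified by simulation in the test suite (it lands near 0.94). Partial
plating is corrected exactly — by binomial thinning of the pmf — only in
the MLE; the median method warns and proceeds uncorrected.

Median mutation *frequencies* (mutants per viable cell after a drug
exposure, where rates are not identifiable) carry the distribution-free
order-statistic CI: the $(l,\,n{+}1{-}l)$ ranked frequencies with $l$ the
2.5% quantile of Binomial$(n, 1/2)$ — for $n = 24$ cultures, the 7th and
18th.

## Mutation spectra

Sequencing $n$ independent revertants multinomially samples the spectrum
of mutation classes. `class_proportion()` reports Wilson 95% intervals
(via `prop.test` without continuity correction). `class_rate()` partitions
an overall rate by the class proportion; its CI is the overall CI scaled
by the same proportion. That choice propagates only the rate uncertainty —
the published procedure this mirrors is external to the package — so a
multinomial bootstrap (`class_rate_bootstrap_ci()`) that additionally
resamples the spectrum and the cultures is provided; neither mode is
asserted to be "the" canonical one. A class absent from the spectrum gets
rate 0 with a rule-of-three upper bound. Significance between conditions
is reported as non-overlap of 95% CIs, which is conservative (non-overlap
implies $p<0.05$; overlap does not imply its negation).

## What the generators emulate — and what they do not

`simulate_qpcr_plate()` places lesions as a Poisson process, so the
intact-template fraction is exactly the zero-class the estimator inverts;
noise-free round-trips are therefore exact by construction, and recovery
tests at zero noise validate the arithmetic, not the model. Ct noise is
Gaussian on the cycle scale, sd 0.15 cycles by default — a typical
technical variance for SYBR-green qPCR. Defaults mirror the study design
the package accompanies: N = 6 replicate wells, amplicons of 100/3000/4000
bp, 24 parallel cultures, and a default $m$ of 2 with $N_t = 2\times10^7$
cells (a saturated 1 mL yeast culture). The base-Ct offset grows mildly
with amplicon length; normalization removes it, and no attempt is made to
model amplicon-specific efficiencies, primer effects, plate-position
effects, or inhibitor carry-over. Passing recovery tests therefore shows
the estimators invert the stated model at realistic noise, not that real
plates are free of those artefacts.

`sample_ld_counts()` draws from the Ma–Sandri–Sarkar pmf by inverse CDF.
`simulate_culture_growth()` is an independent *mechanism*: per-generation
Poisson mutation with deterministic doubling of mutant lineages
(equal fitness, no phenotypic lag — the classic assumptions; stochastic
birth–death of lineages is out of scope). Agreement of its zero class
with the pmf is one of the cross-checks in the test suite, validating the
recursion against a derivation-free mechanism.

Two statistical facts about the study-scale designs are worth stating
plainly, because the tests encode them. First, at $m = 0.5$ the
Luria–Delbrück zero class is $e^{-0.5} \approx 0.61 > 1/2$, so the sample
median is 0 and the method of the median is undefined there regardless of
sample size; comparisons across estimators at low $m$ must route through
p0 or the MLE. Second, with Ct noise of 0.15 cycles on N = 6 wells the
density measurement on a 3 kb amplicon has an error sd of
$\ln 2 \times 0.15\sqrt{4/6}\times 10/3 \approx 0.28$ per 10 kb: a single
plate at density 1.0 is reproducible to roughly ±30%, while the *median*
over 200 plates recovers the true density to well within 10%. The
recovery tests assert the latter (bias), and the per-plate scatter is what
the bootstrap CI — whose empirical coverage the suite verifies at
0.88–0.99 — is for.

## Problem sizes in the test suite

The property tests run the generators at the design sizes above: 1,000
cultures for estimator-concordance checks, 10,000 runs for the
mechanism-vs-pmf zero-class comparison, 500 plates for bootstrap-CI
coverage, and 200 replicates for parameter-recovery medians. These sizes
put the binomial error of each empirical proportion well inside the
asserted bands while keeping the full suite under a minute of
computation.

## Reproducibility

Every stochastic function takes an explicit seed and restores the
caller's RNG state; reports written by `run_report()` carry the seed,
package version and input hashes, and contain no timestamp, so the same
configuration and seed produce byte-identical output.
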