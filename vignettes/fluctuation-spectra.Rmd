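---
title: "Mutation rates and spectra from fluctuation assays"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mutation rates and spectra from fluctuation assays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flucspec)
```

## The estimation problem

A fluctuation assay grows many parallel cultures from small inocula, plates
each on selective medium, and counts resistant colonies. Because a mutation
arising early in a culture's growth founds a large resistant clone, the
per-culture mutant counts follow the heavy-tailed Luria–Delbrück
distribution, and the mutation rate per cell division $\mu$ cannot be read
off as a simple average. `flucspec` implements the median-based estimator

$$\mu = \frac{f}{\ln(N\mu)},$$

where $f$ is the median mutant frequency across cultures and $N$ is the
per-culture population size. The equation is implicit in $\mu$; `drakefit()`
solves it by bisection (relative tolerance $10^{-10}$) on the bracket
$(e/N,\, f]$, where $\mu \ln(N\mu)$ is strictly increasing so the root is
unique.

Before estimation, each selective count is corrected by subtracting
verification-positive colonies — apparent mutants that still express the
reporter (for a silenced *URA3* reporter: FOA-resistant colonies that grow
without uracil) — and scaled by the selective dilution. $N$ is taken as the
median across cultures of the permissive-plate census (dilution times
count); the mean is available by option, but the median matches the spirit
of a median-based estimator and resists plating outliers.

## Confidence intervals

No standard interval exists for this estimator, so the package uses a
distribution-free construction: a binomial order-statistic interval for the
median mutant frequency (the largest symmetric pair of order statistics
whose exact coverage reaches the level), transformed through the monotone
Drake relation at the same $N$. With fewer than six cultures no pair of
order statistics reaches 95%; the widest interval is then reported and
flagged. This is the package's own design choice, documented as such — it
is *not* a published method, and printed intervals from other software will
not match it.

Two degenerate situations use the lower branch of the implicit equation
(where $N\mu < e$ but the relation is still monotone for $N\mu > 1/e$):
the all-zero-counts case, reported as the upper bound obtained from one
hypothetical mutant ($f_{\min} = 1/N$), and confidence bounds whose
frequency falls below $e/N$.

## The synthetic assay generator

`simulate_cultures()` draws colony counts with the statistical structure
the estimator assumes, so the whole pipeline is testable without data:

* **Growth** is deterministic synchronous doubling over
  $G = \lfloor \log_2(N_{final}/N_0) \rfloor$ generations. Mutations per
  generation are Poisson in the number of divisions, and each mutant
  lineage doubles thereafter — the standard discrete-generation
  Luria–Delbrück formulation.
* **Defaults are one realistic assay, chosen once**: each culture is
  inoculated with a single colony ($N_0 = 1{,}562{,}500$ cells — protocols
  of this kind start cultures from single colonies of $10^6$–$10^7$
  cells), and six doublings bring it to exactly $N = 10^8$; $\mu = 5
  \times 10^{-8}$ per division; 18 cultures; the whole culture plated
  selectively and a $10^6$-fold dilution plated permissively (about 100
  countable colonies, ordinary counting statistics).
* **Silenced false positives**: a fraction of apparent resistant colonies
  in such reporter assays are epigenetically silenced, not mutant. The
  generator draws an independent apparent-mutant count, adds a binomial
  fraction (default 0.3) of it to the selective count, and records it as
  verification-positive, mimicking the verify-and-exclude workflow.
* **What it does not emulate**: stochastic growth and cell death,
  phenotypic lag, mutant fitness costs, back mutation, plating efficiency
  below the stated dilutions, and culture-to-culture variation in final
  size beyond plating noise. Passing recovery tests therefore certify the
  arithmetic and the sampling model, not robustness to these real-data
  effects.

`simulate_spectrum()` is a multinomial draw over the five spectrum
categories (default proportions follow a substitution-dominated wild-type
spectrum, 7:40:1:1:1), and `generate_reference()` builds a synthetic ORF
with embedded homopolymer runs for exercising the classifiers; its run
index is produced by re-scanning the assembled sequence, so it is
consistent by construction.

## Known limitation: small-$m$ bias of the median estimator

The median formula omits the additive constant of the Lea–Coulson median
relation, so when the expected number of mutations per culture
$m = N\mu$ is small (the default conditions give $m = 5$), the estimator
converges to a value noticeably *above* the true rate — the convergence
test in the suite measures the estimand at roughly a fifth to a quarter
above $\mu$ under the default conditions. Two practical consequences,
both measured by the suite rather than assumed:

* the recovered rate from large simulated assays sits high by about that
  factor, and
* the order-statistic interval, which is calibrated for the estimator's
  own estimand, covers the *true* rate in fewer than nominal replicates
  (the suite measures coverage of truth near 80% for a nominal 95%
  interval at 18 cultures), while its construction is verified separately
  by the collapse, ordering and convergence properties.

Correcting this would require a different estimator (Lea–Coulson $p_0$ or
maximum likelihood), which is outside this package's scope. Fold changes
between genotypes measured at similar $m$ are much less affected, since
the bias largely cancels in ratios.

## Spectrum classification and run context

Mutation calls (isolate, 1-based position, ref allele, alt allele — one
allele empty for indels) are classified into five categories: base
substitution, 1-bp deletion, 1-bp insertion, complex, other. Two or more
events in one isolate within a 10-bp window (chained; the window is
configurable) form one *complex* mutation — clustered changes arising as a
single event — and are tallied once per cluster in spectra. Any remaining
event of length ≥ 2 (multi-bp indels, duplications) is *other*.

Run context: 1-bp indels are left-normalised to the start of the run of
the deleted/inserted base, and the run length is that of the maximal run
containing the normalised site; this makes run membership well defined
and placement invariant (verified exhaustively for runs up to length 8).
Substitutions take the run of the reference base at their site.
`fraction_in_runs()` then gives, e.g., the fraction of 1-bp deletions in
runs of $N \ge 3$ — the quantity used to diagnose mismatch-repair loss,
where slippage intermediates in long runs go uncorrected.

## Rate partitioning, repair efficiency, synergy

`partition_rates()` splits a genotype's total rate across categories in
proportion to spectrum counts. A category with zero observed mutations is
reported as the upper bound from a pseudo-count of one and flagged; bounds
are excluded from the conservation identity (non-bound rates sum exactly
to the total before rounding). Reporting uses two significant figures for
rates and ratios and whole percent for efficiencies, with full precision
kept in the objects.

Repair efficiency is $100 - 100\,\mu_{proficient}/\mu_{deficient}$ — the
percentage of errors of a type that the repair pathway corrects, computed
per category from matching partitions. The synergy index divides the
relative double-mutant rate by the sum of the relative single-mutant
rates; values above 1 indicate overlapping pathways acting on the same
replication errors.

## Comparing spectra

Two procedures are provided:

* `chisq_independence()`: Pearson chi-square without continuity
  correction on the category-by-genotype table, zero-margin rows dropped
  first, asymptotic p-value even when expected counts are small (a
  warning is issued). This convention — not an exact test — is how
  published spectrum tables of this kind are computed, and
  `pairwise_compare()` reproduces such a table: all pairs plus the
  overall test, with Bonferroni adjustment $\min(1, m p)$ applied to the
  4-decimal reported p-values and $m$ equal to the number of reported
  comparisons (7 for four genotypes).
* `mc_homogeneity()`: the observed Pearson statistic referred to its
  exact conditional null — tables drawn with both margins fixed
  (multivariate hypergeometric, Patefield's algorithm), equivalent to
  permuting the genotype label of every individual mutation. The p-value
  uses the add-one estimator $(1 + \#\{sim \ge obs\})/(1 + n_{iter})$,
  so it is never exactly zero and has resolution $1/n_{iter}$ (default
  $10^5$); the empirical 95th percentile of the simulated statistics is
  reported as the critical 5% value.

## Numerical choices and problem sizes

Bisection tolerance $10^{-10}$ relative; ties at an observed statistic of
zero are counted as exceedances (so identical columns give $p = 1$
exactly); the even-culture median is the mean of the two central order
statistics; dilutions are census multipliers ≥ 1 with binomial-thinning
plating (a Poisson approximation takes over only for jackpot censuses
beyond integer range). The suite's simulation scales, chosen as desk-scale
study sizes: recovery at 1000 cultures; interval calibration over 1000
replicates of the 18-culture design; Monte-Carlo validity at
$n_{iter} = 10^5$ on two size-200 draws from a uniform multinomial, where
every expected count is large and the conditional and asymptotic nulls
agree.
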