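---
title: "Windowed diversity, ROD sweep scans and structure inference with rodscan"
author: "rodscan maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Windowed diversity, ROD sweep scans and structure inference with rodscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rodscan)
```

## The problem rodscan addresses

Marine fish cohorts sampled along a coastline are often genetically almost
homogeneous: larvae disperse on currents, gene flow is high, and pairwise
differentiation between sampling sites can be indistinguishable from zero.
Against that near-uniform background, localized selection — for example
fishing pressure acting on growth, maturation or behaviour — leaves a
different signature: short genomic intervals where one population has *lost*
diversity relative to an unfished baseline, and where windowed
differentiation against that baseline spikes.

rodscan implements this scan as a reusable pipeline. One population is
flagged as the **reference** (a marine-protected-area cohort with effectively
zero fishing pressure); every other population is screened against it with
two windowed statistics:

* nucleotide diversity $\pi$, and its **reduction of diversity**
  $\mathrm{ROD} = \lvert 1 - \pi_{\mathrm{pop}} / \pi_{\mathrm{ref}} \rvert$;
* the Weir–Cockerham fixation index $F_{ST}$ between the population and the
  reference.

Windows in the top 5% of *both* statistics are called outliers, merged into
candidate sweep regions, and annotated with overlapping genes. Around the
scan sit the standard supporting analyses: variant filtering, sliding-window
$\pi$ / $F_{ST}$ / Tajima's $D$ tracks, an identity-by-state neighbor-joining
tree, and an admixture-model fit with cross-validation over the number of
ancestral populations $K$.

Every stage is verifiable at desk scale because the package ships its own
cohort simulator with known ground truth.

## Statistical definitions

**Per-site diversity.** At a site with $n$ observed allele copies and
alt-allele frequency $\hat p$, the unbiased heterozygosity is
$2 \hat p (1-\hat p)\, n/(n-1)$ — equivalently, the fraction of differing
pairs among the $n$ copies. Window $\pi$ sums per-site values and divides by
the *window span*, so monomorphic and unsequenced positions dilute the
estimate exactly as in VCFtools' `--window-pi`. Genome-wide $\pi$ divides the
same sum by total genome length.

**$F_{ST}$.** The Weir & Cockerham (1984) estimator, per site decomposed into
among-population ($a$) and within-population ($b$, $c$) variance components,
aggregated as the ratio of sums $\sum a / \sum (a+b+c)$ across a window or
the genome. Ratio-of-sums aggregation is what VCFtools reports and has lower
bias than averaging per-site ratios. Finite-sample estimates are **not
clamped**: panmictic cohorts legitimately produce small negative values, and
the package preserves them. Hudson's estimator is available as a labelled
alternative (`hudson_fst()`) for cross-checks.

**Tajima's $D$.** The classical normalized difference between the
mean-pairwise-difference estimate and Watterson's $S/a_1$, with the canonical
$a_1, a_2, b_1, b_2, c_1, c_2, e_1, e_2$ constants computed from the copy
number $n$. Windows with no segregating sites are undefined (`NA`). With
missing genotypes, per-site $\hat\pi$ uses each site's own copy count and the
window's constants use the rounded mean copy count over segregating sites —
exact when data are complete.

**ROD.** The printed definition takes an absolute value, which makes the
statistic two-sided: a population with diversity *above* the reference also
scores. That is the default, exactly as printed; `one_sided = TRUE` in
`call_outlier_windows()` ranks the signed value $1 - \pi_{pop}/\pi_{ref}$
instead, since sweeps specifically reduce diversity.

**Outlier calling.** The 95th percentile of windowed $F_{ST}$ and of ROD are
computed genome-wide per scanned population (undefined windows excluded);
the called set is the **intersection** of the two single-statistic outlier
sets. Reading "top 5% of both" as an intersection is the standard joint
screen; the union is available behind `mode = "union"`. Ties at a threshold
are included ($\ge$), so degenerate constant tracks return every window,
with a warning.

## Tunable parameters

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| window size | 100,000 | bp | standard resequencing window; ~100s of SNPs per window at $\pi \approx 3\times10^{-3}$ |
| window step | 10,000 | bp | 10× overlap smooths tracks without hiding narrow sweeps |
| MAF filter | > 0.01 | frequency | removes singletons/monomorphic calls from a 60-sample joint callset |
| depth filter | > 3 | reads | below ~3 reads a diploid genotype is unreliable |
| missing-rate filter | < 0.2 | fraction | sites typed in <80% of genotypes carry unstable frequency estimates |
| outlier fraction | 0.05 | — | the conventional empirical-outlier cut for selection scans |
| `min_sites` (ROD ranking) | 10 | sites/window | a ratio of two noisy small $\pi$ values is unstable; low-coverage windows are excluded from ranking rather than fed into percentiles |
| `max_gap` (region merge) | 0 | bp | only overlapping/adjacent outlier windows merge; no merge rule is standard, so the least aggressive one is the default |
| CV folds | 5 | — | ADMIXTURE's default masking granularity |
| EM convergence | rel. $\Delta\log L < 10^{-8}$, max 2000 iter | — | tight enough that restarts agree to ~6 digits |
| $P$ bound $\epsilon$ | $10^{-6}$ | frequency | keeps the binomial log-likelihood finite |

All three filter inequalities are **strict**, matching the convention
"MAF > 0.01, depth > 3, missing rate < 0.2". The depth criterion is applied
to the per-site *mean* of genotype depths by default (site-level filtering in
the VCFtools style); `depth_mode = "genotype"` masks individual low-depth
genotypes instead, after which the missingness filter takes over. Both
readings are supported because site-level versus genotype-level depth
filtering is a genuine ambiguity in common pipelines; the mean is the
default.

Window coordinates are half-open `[start, start + window)` in 1-based space,
with starts at 1, 10,001, 20,001, …; trailing partial windows are retained
and flagged. BED exports convert to 0-based half-open; VCF and TSV outputs
stay 1-based.

## The cohort simulator

`simulate_cohort()` draws cohorts under the Balding–Nichols $F$-model:

1. each variable site receives an ancestral frequency
   $p \sim \mathrm{Uniform}(0.05, 0.95)$;
2. each population's frequency is a
   $\mathrm{Beta}\!\left(\frac{p(1-F)}{F}, \frac{(1-p)(1-F)}{F}\right)$ draw
   (or $p$ itself when $F=0$), so the expected differentiation between
   populations is controlled in closed form by $F$;
3. diploid genotypes are $\mathrm{Binomial}(2, f_{pop})$ draws;
4. per-genotype depth is negative-binomial (overdispersed coverage is the
   realistic stress case for the depth filter) and genotypes go missing
   independently at a configurable rate.

The number of variable sites is chosen so that expected genome-wide per-site
$\pi$ matches `target_pi` (default $3.1 \times 10^{-3}$, the scale observed
in coastal marine fish): since a site with ancestral frequency $p$
contributes $2pq(1-F)$ in expectation, the site count is
`target_pi * genome_length / E[2pq(1-F)]` with the expectation available in
closed form for the uniform spectrum.

**Sweep footprints** are implanted by frequency-pushing: inside a declared
interval, each affected population's site frequency is replaced, with
probability equal to the configured `reduction`, by a Bernoulli($f$) fixation
draw. This is the limiting case of a Beta concentrated on $\{0, 1\}$ and
scales expected heterozygosity by exactly $(1 - \mathrm{reduction})$, which
makes the footprint testable in closed form. Only the footprint matters for
the scan — the statistics detect diversity loss and differentiation, not
selection dynamics.

**Admixed cohorts** (for structure-inference testing) draw $K$ source
frequency vectors by the same Balding–Nichols mechanism, per-individual
ancestry $Q \sim \mathrm{Dirichlet}(\alpha)$, and genotypes
$\mathrm{Binomial}(2, \sum_k q_{ik} p_{kl})$, with the true $Q$ stored in the
truth record.

### What the simulator does *not* emulate

* **Linkage disequilibrium.** Sites are independent. None of the implemented
  statistics requires LD, but haplotype-based scans (iHS, XP-EHH) could not
  be validated against this generator.
* **The neutral site-frequency spectrum.** The uniform ancestral spectrum
  keeps most sites polymorphic (so the MAF filter has work to do) but is
  *not* the $1/x$ neutral spectrum. A direct consequence: windowed Tajima's
  $D$ on simulated cohorts is strongly *positive* — there is an excess of
  intermediate-frequency variants by construction — so the simulator cannot
  be used to check the neutral centering of $D$. The test suite instead
  verifies centering on windows whose segregating sites are drawn directly
  from the neutral sample SFS (derived-allele count $i$ with probability
  $\propto 1/i$), and verifies the statistic's value against a longhand
  implementation of the constants.
* **Sequencing error and genotype-likelihood uncertainty.** Genotypes are
  drawn exactly; depth affects only the filter.
* **Demography.** The generator targets the *summary statistics* a scan
  consumes ($\pi$ scale, near-zero $F_{ST}$), not any particular population
  history.

Passing recovery tests therefore demonstrate that the pipeline detects the
statistical footprint it defines, under idealized sampling — not that it
would have identical power on real data with LD, calling error and complex
demography.

## Structure inference choices

The tree input is an **identity-by-state** distance,
$d(i,j) = \mathrm{mean}\, \lvert g_i - g_j \rvert / 2$ over co-genotyped
sites. Classic NJ workflows leave the distance unspecified; IBS is the
simplest genotype-native choice and is documented as this package's
decision, not as a reconstruction of any particular workflow. Neighbor
joining follows Saitou–Nei exactly, with deterministic lowest-index
tie-breaking and PHYLIP-style clamping of negative branch lengths to zero
(the pre-clamp value is reported in a message). NJ is exact on additive
matrices, which the test suite exploits: random trees on 4–8 taxa are
reconstructed to machine precision and cross-checked against `ape::nj`.

The admixture model is fitted by plain EM rather than block-relaxation or
quasi-Newton acceleration: the likelihood and its fixed points are
identical, the update is a dozen lines of verifiable linear algebra, and
speed is irrelevant at desk scale. $K = 1$ collapses to pooled allele
frequencies in closed form, which pins the likelihood computation in tests.
Cross-validation masks random folds of observed genotype *entries*
(ADMIXTURE-style), refits, and scores masked dosages by RMSE against the
prediction $2\,\hat Q \hat P$; `scan_K()` repeats each $K$ with distinct
seeds and keeps the per-$K$ minimum, mirroring the repeat-and-take-best
protocol. The number of folds is a package decision (5); the protocol it
mirrors does not state one.

Mixture labels are non-identifiable, so all truth comparisons in the test
suite align $\hat Q$ to the truth by the best column permutation
(`align_Q()`). A practical note from the package's own verification runs:
with only tens of individuals, the *joint* maximum-likelihood $\hat Q$ is
noticeably noisier than $\hat Q$ computed at the true source frequencies,
because $\hat P$ absorbs sampling noise; recovery error is therefore
measured across replicate cohorts rather than on a single draw.

## Numerical and degenerate-input conventions

* Sites where either population has fewer than two genotyped individuals are
  skipped for $F_{ST}$; sites with fewer than two observed copies are
  skipped for $\pi$. Windows with zero usable sites report $\pi = 0$
  (diversity genuinely unobserved) but `NA` for ratio statistics
  ($F_{ST}$, ROD, $D$).
* $F_{ST}$ sites with a zero denominator ($a+b+c = 0$, i.e. monomorphic
  across both populations) contribute nothing to window sums.
* ROD is undefined where the reference window's $\pi$ is 0, or below the
  `min_sites` coverage floor; undefined windows never enter percentile
  ranking.
* Filtering an already-filtered matrix removes nothing (idempotence is
  asserted in the suite); per-criterion failure counts count *all* failures,
  so they can exceed the number of removed variants.
* EM asserts a non-decreasing log-likelihood at every iteration and warns if
  numerical clamping ever violates it (it does not, at the shipped
  tolerances).
* The 5% cut is computed genome-wide per scanned population, not per
  chromosome — a chromosome-level cut would misbehave on chromosomes
  consisting mostly of one sweep.

## Problem sizes used in the verification suite

The suite is sized for a desk-scale machine: oracle fixtures use ≤ 30 sites;
calibration and recovery checks use cohorts of 1.5–4 Mb with 10–40 diploids
(15,000–35,000 sites at the default diversity), 50 seeded replicates for
sweep recovery, 20 per $F$ value for $F_{ST}$ recovery, and 10 for the CV
scan. These sizes were chosen so each property is measured with comfortable
Monte-Carlo margin while the whole suite completes in a few minutes.

## Known limitations

* Per-site independence means no LD-aware pruning is provided (or needed)
  before the NJ/admixture stages; on real data, pruning should happen
  upstream.
* The depth filter interprets "depth" at the site level by default; callers
  whose DP conventions differ (e.g. summed rather than per-genotype DP)
  should pass pre-computed matrices accordingly.
* The admixture EM is not accelerated; cohorts beyond ~10⁵ sites × hundreds
  of samples will be slow, and thinning (as `run_pipeline()` does for the CV
  scan) is recommended.
* Merged sweep regions report peak statistics only; no significance is
  attached to region calls beyond the empirical-percentile definition.
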