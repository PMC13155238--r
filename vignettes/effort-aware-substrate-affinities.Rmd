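---
title: "Effort-aware substrate affinities: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Effort-aware substrate affinities: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(myxindic)
```

This vignette is the package's account of its statistical machinery: the
models and their assumptions, the tunable parameters and their defaults,
what the synthetic-data generators do and do not emulate, and the numerical
and design choices made where more than one construction was defensible.

## The analysis frame

The unit of analysis is the occurrence *record* of a slime mould sporocarp
observation, annotated with country, taxonomy, a verbatim microhabitat
descriptor, and optionally coordinates, elevation bounds and a measured pH.
Records are presence-only: an unobserved species-by-substrate combination is
a non-report, never an absence. All analyses therefore condition on
observation and weight by recording effort rather than imputing zeros.

Harmonisation maps verbatim descriptors onto ten substrate classes through
an ordered keyword-pattern vocabulary. The mapping is deliberately
conservative: a descriptor matching the patterns of more than one class
(e.g. "moss on rotten log") stays unassigned, and the indeterminate class
MSC is assigned only on explicit wording. The default English rule set ships
with the package and is replaceable via YAML; harmonisation is idempotent
and case/diacritic-insensitive.

Aggregation produces one row per observed (country, substrate, species)
cell with count $y \ge 1$. Each row carries the cell total $T_{cs}$, the
leave-one-out exposure $E = T_{cs} - y$ (records of *other* species in the
cell) and the offset $\log(E + c)$. The constant $c = 1$ keeps the offset
finite at $E = 0$ and is configurable. Rows with $E < 5$ and substrates
with fewer than 100 records are flagged, not dropped; the rarity threshold
is the pre-declared rule for excluding substrates from rankings.

## Diversity standardisation

Good's coverage in the simple form $1 - f_1/n$ serves descriptive stratum
tables. Rarefaction uses the exact hypergeometric expectations: richness by
$S - \sum_i \binom{n - x_i}{m} / \binom{n}{m}$, and orders 1 and 2 through
the expected abundance-frequency counts $E[f_k(m)]$, exponentiating the
expected entropy and inverting the expected concentration. These are the
standard interpolation constructions; tests verify them against exhaustive
enumeration of all subsamples for $n \le 12$ and against an independent
richness-rarefaction implementation.

Coverage-based standardisation finds the smallest $m$ whose estimated
coverage (exact interpolated form for $m < n$; the Good–Turing
$f_1/f_2$-adjusted form at $m = n$, with the usual $f_2 = 0$ fallback)
reaches the target $C^*$ (default 0.90, sensitivity at 0.85). One point
worth stating explicitly: equality of Hill numbers across orders for an
equal-abundance assemblage holds only at the observed scale ($m = n$).
Random subsamples of an even community are uneven, so interpolated
$^0\!D > {}^1\!D > {}^2\!D$ strictly at $m < n$; this is correct behaviour,
not a defect.

Bootstrap intervals resample $n$ records from the empirical proportions
(200 replicates by default) and are reported as estimate $\pm 1.96$
bootstrap SDs. Percentile bounds were rejected: the multinomial bootstrap
systematically loses rare species, so the percentile interval for rarefied
richness sits below the point estimate. The symmetric form — also the
behaviour of the standard coverage-standardisation software — keeps the
estimate inside its interval. An unseen-species-adjusted resampling variant
(`boot_variant = "chao"`) is available.

## The zero-truncated NB effort model

The multi-species model is

$$y_{csi} \sim \mathrm{ZTNB}(\mu_{csi}, k), \qquad
\log \mu_{csi} = \beta_0 + \beta_{s} + b_i + u_c + \log(E_{csi} + 1),$$

with NB2 dispersion (variance $\mu + \mu^2/k$ before truncation), species
intercepts $b_i$, country intercepts $u_c$, and dead wood (LIG) as the
reference substrate. Truncation reflects the structural absence of zeros.
Estimation is Laplace-approximated maximum likelihood via `glmmTMB`
(`truncated_nbinom2`); a singular random-effect variance is reported as a
boundary flag rather than an error. The package also provides a
fixed-effects ZTNB regression (`ztnb_glm()`, direct ML with analytic
gradients); when the random-effect variances are zero the two agree, which
the tests assert, and the fast path drives cross-validation folds and large
simulation studies.

Fixed effects are *conditional per-unit-effort* contrasts — relative
recording intensity given that a species was recorded in a cell — not
abundance multipliers. Pairwise substrate comparisons are estimated
marginal means at offset 0 with single-step max-|z| ("Tukey") adjustment
via `emmeans`; a test cross-checks the adjusted p-values against a
Monte-Carlo maximum-|z| null computed from the fitted contrast correlation.
Rank uncertainty comes from a parametric bootstrap (simulate from the fit,
refit, rank unit-effort means; 200 replicates by default, 2,000 for
production runs). The information-weighted variant shrinks each replicate's
log-means toward the replicate grand mean with retention factor
$w_s = n_s / \sum_s n_s$ before ranking, so weakly informed substrates lean
on the pooled mean. The correlated random-slopes specification
`(1 + substrate | taxon)` is available (`taxon_slopes = TRUE`) and is the
baseline of the sensitivity suite; intercepts-only is the package default
because the slopes model is frequently singular on sparse archives.

### A note on the self-referential offset

In the full archive generator the substrate effect scales *every* species
in a cell equally, and the exposure is the within-cell leave-one-out total
of the same counts — so a proportional substrate elevation cancels from the
per-unit-effort contrast, and end-to-end archive-level rate ratios hover
near 1 regardless of the configured rates. This is a genuine property of
the self-referential offset design, not a bug. Parameter-recovery studies
therefore use `simulate_count_frame()`, which draws counts from the model
with *exogenous* per-cell exposures; under that design the configured
$\beta$ is exactly the estimand, and the tests verify unbiased recovery
with calibrated Wald intervals.

## Indicator analysis

Sites are observed (country, group) combinations — country × substrate for
substrate indicators, country × pH band for screening — each carrying its
total record count as an effort weight. For taxon $t$ and group $g$, with
$m_g$ the effort-weighted mean presence over the sites of $g$:

* specificity $A = m_{g}/\sum_{g'} m_{g'}$ (group-equalised);
* fidelity $B = m_{g}$ (weighted occupancy);
* statistic $\mathrm{IndVal\,E} = \sqrt{A B}$.

The group-equalised, fully weighted construction is the default; the
classic unweighted components and a weights-in-A-only variant are selectable
(`weighted`, `weighted_B`). Taxa occupying fewer than three sites are
dropped as inherently unstable.

Inference respects the country block structure throughout: permutation
tests shuffle group labels only within countries (add-one p-values,
$p = (1 + \#\{\text{perm} \ge \text{obs}\})/(1 + n_{\text{perm}})$, floor
$1/(1+n_{\text{perm}})$), Benjamini–Hochberg adjustment runs across the
taxon list, bootstrap intervals resample sites within groups, and K-fold
validation partitions countries (K = 5 for substrates, K = 3 for pH bands),
choosing each taxon's best group on training sites (ties: larger training
fidelity, then lexicographic group code) and recomputing A and B on held-out
sites. A taxon absent from either partition of a fold contributes nothing;
never-estimable taxa are reported as unavailable. Presence-based A×B scores
for higher taxa use plain presence counts
($A = $ focal presences / total presences, $B = $ focal presences / focal
sites) and carry no inferential testing. pH outputs are labelled screening:
the measured-pH subset is sparse and unbalanced by construction, and the
outputs rank candidates for co-measurement rather than support confirmatory
inference.

## Elevational profiles

Midpoint elevations are binned into ~60 equal-width bins; the exposure of a
country × bin cell is its total record count. Per species,

$$y_{cb} \sim \mathrm{Poisson}(\mu_{cb}), \qquad
\log \mu_{cb} = f(\mathrm{elev}_b) + \log E_{cb},$$

with $f$ a natural cubic spline (default df = 4, internal knots at
quantiles of the occupied bin midpoints), fitted by iteratively reweighted
least squares with a weak ridge penalty ($10^{-8}$) on the coefficients for
stability in sparse bins. Countries pool through the shared offset; no
country term enters $f$. The modal elevation is the argmax of
$\exp(f)$ on a 512-point grid restricted to the species' observed elevation
range (first grid point on exact ties); modes within one grid step of the
domain edge are flagged boundary cases. Multiplying all exposures by a
constant shifts only the intercept, so the mode is exactly invariant — a
property tested to machine precision. Uncertainty comes from a parametric
bootstrap (redraw cell counts from fitted means, refit, re-take the
argmax). Modes are descriptive summaries of relative recording intensity,
not ecological optima.

## Validation suite

*Randomized-quantile residuals*: each observation's residual is its
randomized rank among $S$ simulated responses (default 250) — Uniform(0,1)
under the true model — summarised by a Kolmogorov–Smirnov uniformity check
and a two-sided simulation-based dispersion test (observed vs simulated
response variance).

*Leave-one-country-out cross-validation*: per fold the model is refitted
without one country; held-out cells are predicted with the country effect
at its population mean (0) and taxon conditional modes where the taxon was
seen in training. Predictions are the **conditional (zero-truncated) means**
$\mu/(1 - p_0)$: held-out rows exist only where a count was recorded, and
regressing positive counts on the log of the *untruncated* mean attenuates
the calibration slope to ~0.6 even under the true model (the truncation
floor flattens the low end). With conditional means the slope is ~1 under
the true model, which is what a calibration diagnostic should report.
The pooled slope comes from a Poisson GLM of held-out $y$ on
$\log \hat\mu$ with Eicker–Huber–White (HC0) standard errors (verified
against a brute-force sandwich computation); RMSE, Poisson deviance
$2\sum[y \log(y/\hat\mu) - (y - \hat\mu)]$ and a decile calibration table
with per-decile counts accompany it. Per-fold slopes are reported alongside
the pooled slope (the primary).

*Sensitivity variants*: V1 baseline with taxon random slopes; V2 no slopes;
V3 excludes substrates under 100 records; V4 down-weights rows of rare
substrates by $\min(1, n_s/100)$ — the weighting rule is a documented
package choice. Δlog(rate ratio) vs V1 is reported with Wald-combined
intervals by default; parametric-bootstrap intervals are available
(`B > 0`) but refit two random-slope models per replicate and are not the
default.

*pH-mode concordance*: per-species modal pH on 0.01- and 0.1-unit grids via
the same Poisson-spline machinery (log offset = total measured records per
bin), with sparse and boundary flags, summarised by Pearson and Spearman
correlations of the paired modes (requiring at least three eligible
species).

## The synthetic archive generator

`generate_archive()` emulates the statistical structure the analysis
assumes: 16 country blocks; ten substrate classes with strongly uneven
effort weights proportional to realistic per-substrate record totals
(11,411 : 3,618 : … : 27); NB-overdispersed cell counts ($k = 1$) with
species ($\sigma = 1$) and country ($\sigma = 0.5$) intercepts on the log
scale; an expected archive size of 34,588 records (the baseline intercept
is solved from the moment identity of the log-normal effects); sparse
elevation (18% of rows) from species-specific Gaussian modes truncated to
[0, 2500] m (defaults: modes uniform on [100, 1800] m, spread 150 m,
stored as zero-width min/max bounds); near-absent pH (0.44% of rows) drawn
per band from uniforms on (3.35, 5], (5, 7], (7, 10] with a mid-band
dominated mixture; and per-field missingness applied independently per row
(missing completely at random: substrate 36.38%, coordinates 28.73%,
species 0.27%). Verbatim descriptors are drawn from an unambiguous pool per
class so generated archives round-trip harmonisation without loss. Planted
indicator taxa are generated only at cells of their assigned substrate and
are never blanked, so their perfect specificity survives into the
analysable subset.

What the generator does *not* emulate — and hence what passing tests do not
show about real archives: temporal trends and collector turnover across the
1857–2025 window; residual duplicate records; spatially structured
sampling; missingness that correlates with substrate, country or period
(real completeness is almost surely not MCAR); taxonomic revision noise;
and any coupling between pH and community composition (pH bands are
assigned independently of taxa, which is also what makes the screening
null-calibration test meaningful).

## Problem sizes used by the test suite

The suite keeps every statistical check at the smallest size that still
measures the property: fixed-effect recovery runs 200 replicates of
16-country × 9-substrate × 200-species frames through the fixed-effects
ZTNB path (the zero-random-effect regime in which the mixed fit provably
reduces to it, an equivalence asserted separately), plus a mixed-model
recovery at 40 species with nonzero random-effect SDs; elevational-mode
coverage uses 100 simulations of a 300-record species (Gaussian intensity,
mode 800 m, spread 200 m) with 200 bootstrap replicates each;
cross-validation calibration coverage uses 30 simulated frames of 8
countries × 80 species; rank bootstraps in tests use tens of replicates
where production analyses would use 2,000. Reported coverages are asserted
against the bands these designs imply, never point values.

## Known limitations

* The descriptor→class rule set is a faithful English reading of the class
  definitions; multilingual archives need an extended vocabulary (the YAML
  hook exists).
* The effort offset is within-cell and self-referential; substrate effects
  that scale an entire community proportionally are not identifiable from
  archive data alone (see the note above), and rate ratios should be read
  as composition-of-records contrasts.
* Wald intervals on mixed-model contrasts ignore dispersion-parameter
  uncertainty; the parametric-bootstrap paths exist where that matters.
* The pH screening outputs inherit the sparsity of measured pH; they rank
  candidates, nothing more.
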