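---
title: "Methods: entropy weighting, coupling coordination, and fsQCA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: entropy weighting, coupling coordination, and fsQCA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eshcoord)
```

This vignette is the package's own account of its models: what each stage
assumes, which tunable parameters matter and why their defaults are what
they are, how degenerate inputs and ties are resolved, and what the
synthetic generators do and do not emulate.

## The indicator system

The evaluation scheme (`esh_scheme()`) has 20 county-level indicators
grouped into eight subsystems and three systems: economy (Z1 economic
aggregate, Z2 structure, Z3 efficiency; indicators x1–x7), society (Z4
public investment, Z5 social security, Z6 social assistance; x8–x12) and
healthcare (Z7 accessibility, Z8 fairness; x13–x20). All indicators
default to positive direction — larger values indicate stronger systems —
because the scheme contains no cost-type indicator; the reversed min-max
formula is nevertheless implemented and selectable per indicator
(`direction = "negative"`), since user-supplied schemes may include, say,
mortality-type measures.

County *name* is the join key across panel, region and fixture files:
published county tables carry no numeric identifiers. Names are matched
after trimming, case-folding and apostrophe/space stripping, so
"Pan'an" and "Panan" unify.

## Entropy-weight scoring

**Normalization.** Min-max scaling per indicator. The scope of the
max/min is tunable:

* `pooling = "per_year"` (default): extrema within each year, exactly as
  the weighting formulas index them. Each year's frontier county scores 1.
* `pooling = "pooled"`: common extrema across all years. Cross-year score
  *trends* are then directly interpretable, at the cost of no longer
  guaranteeing a 0 and a 1 in every yearly column.

**Weights.** Entropy $E_{jt} = -\frac{1}{\ln m}\sum_i p_{ijt}\ln p_{ijt}$
with the convention $0\ln 0 = 0$, then $w_{jt} \propto 1 - E_{jt}$. The
normalization block of the weights is tunable because the summation range
of the published formula is ambiguous:

* `scope = "per_system"` (default): weights sum to 1 inside each system
  block. This guarantees each system score $U \in [0,1]$, which the
  ten-grade CCD scale presumes ($D \in [0,1]$ requires $T \in [0,1]$).
* `scope = "global"`: weights sum to 1 over all 20 indicators, in which
  case $U$ sums are bounded by each block's total weight instead.

No additive shift is applied before the proportion step: min-max output
is already nonnegative, so the common "+0.0001" variant is unnecessary;
a `shift` parameter exists purely to replicate analyses that used one.

**Degenerate columns.** A constant indicator column cannot be min-max
scaled and carries no discriminating information. It is normalized to 0,
flagged with a warning, assigned entropy 1 and hence weight 0. If *every*
indicator in a weight block is degenerate there is no information to
weight and the scoring stops with an error.

## Coupling coordination

The published statement of the model repeats the society score where the
healthcare score belongs, in both the coupling product and the composite
index; the accompanying prose defines three distinct systems, and a
two-term reading would make the healthcare system irrelevant to its own
coordination index. The package therefore uses three distinct terms:

$$C = 3\left\{\frac{U_{EC} U_{SO} U_{HE}}{(U_{EC}+U_{SO}+U_{HE})^3}\right\}^{1/3},
\qquad T = \alpha U_{EC} + \beta U_{SO} + \gamma U_{HE},
\qquad D = \sqrt{C\,T}.$$

$C$ is permutation-symmetric, attains 1 exactly on the positive diagonal
(by the AM–GM inequality), and is defined as 0 when any score — or the
denominator — is 0. The weights default to $1/3$ each and must sum to 1
(tolerance $10^{-9}$).

**Grade boundaries.** The published grade table prints closed-looking
brackets on every row, which would assign boundary values to two grades
at once. `classify_ccd()` uses half-open intervals $[\ell, \ell+0.1)$
with the top interval closed at 1, so the ten grades partition $[0,1]$
and classification is a function. A value of exactly 0.7 is therefore
*Intermediate coordination*, not *Primary coordination*.

**Summary conventions.** Medians average the two middle order statistics
for even counts; the standard deviation uses the $n-1$ denominator by
default (a population switch exists, since published tables rarely state
the estimator); report tables round to 3 decimals *half away from zero*
(`round_half_up()`), matching yearbook-style tables rather than IEEE
banker's rounding. Full-precision values are available by passing
`digits = NULL`.

The published regional summary table appears to transpose its two
dispersion columns: the values under its "CV" header match group
standard deviations, those under "Std" match std/mean, and the narrative
CV figures match the latter. The packaged copy of that table therefore
stores the two columns under neutral names (`printed_cv_col`,
`printed_std_col`), and the package's own summaries always label `std`
and `cv` unambiguously.

## fsQCA

**Calibration.** Direct method with quartile anchors: full membership at
the 75th percentile, crossover at the 50th, non-membership at the 25th.
Percentiles use linear interpolation between order statistics (rank
$1+(n-1)p/100$; R's default quantile type 7) — stated explicitly because
quartile values depend on the convention. The log-odds transform is
piecewise linear with slope scaled so the anchors map to
$\mathrm{plogis}(\pm 3) \approx 0.953/0.047$; a `log19` mode maps them to
exactly 0.95/0.05 for compatibility with tools that use that convention.
Anchors must be strictly ordered; heavy ties raise an error naming the
condition rather than silently producing a flat calibration.

**Ties.** A membership of exactly 0.5 belongs to neither a set nor its
complement and would leave a case unassigned in the truth table. Such
values are nudged to $0.5 + 10^{-3}$ at calibration, and again when an
outcome is negated for the analysis of the outcome's absence. The nudge
is recorded (`tie_adjusted` attribute) so analysts can see which cases
were affected.

**Necessity.** Standard fuzzy inclusion ratios
($\Sigma\min(x,y)/\Sigma y$ for consistency, $/\Sigma x$ for coverage),
evaluated for every condition and its negation, flagged necessary at
consistency ≥ 0.9 *and* coverage ≥ 0.5. The published account states the
thresholds but not the formulas; these are the formulas those thresholds
were defined for in the configurational-methods literature.

**Truth table.** Each case's membership in a corner's conjunction is the
minimum over the $k$ literal memberships; because no membership is
exactly 0.5, each case exceeds 0.5 in exactly one corner, so corner case
counts always sum to the number of cases. Observed rows (count ≥
frequency threshold, default 1) are coded 1 when raw consistency ≥ 0.80
and PRI ≥ the PRI cutoff, else 0; unobserved rows are logical
remainders. Contradictory rows — substantially consistent with both the
outcome and its negation — fail the PRI screen and code 0; no separate
simultaneous-subset test is applied.

**Natural-break PRI cutoff.** "Natural break" is operationalized as the
midpoint of the largest gap between consecutive sorted observed PRI
values whose midpoint lies in $[0.5, \text{consistency threshold}]$;
when no such gap exists (all PRI values equal, or all gaps outside the
window) a documented fallback of 0.70 is used. A numeric cutoff can
always be supplied instead.

**Minimization.** Textbook Quine–McCluskey: iterative pairwise merging to
all prime implicants, then exact minimal covering of the coded-1 corners
via Petrick's method with absorption (exact is cheap at $k \le 5$; a
guard caps $k$ at 12). Ties between minimal covers are broken by fewer
total literals, then lexicographically in condition order, making every
solution deterministic.

**Solution triple.** Complex = no remainders admitted; parsimonious =
all remainders admitted; intermediate = only "easy counterfactuals"
admitted, i.e. remainder corners whose literals agree with the stated
directional expectation wherever one is stated. With no expectations at
all, the intermediate solution equals the complex one — assuming nothing
admits nothing. The default pipeline expectation is `present` for all
five conditions for the high outcome (each system is theorized to promote
coordination) and no expectation for the negated outcome, both
overridable.

**Core vs peripheral.** A literal of an intermediate recipe is *core*
when it appears in a parsimonious recipe subsuming that recipe, otherwise
*peripheral*. The chart renderer distinguishes four marks: ● core
present, • peripheral present, ⊗ core absent, ⊘ peripheral absent (the
published chart's bold-vs-plain ⊗ distinction, read as core-absent vs
peripheral-absent — an interpretive assumption, since that table carries
no legend).

**Statistics.** Recipe membership is the min over its literals, solution
membership the max over recipes; consistency and raw coverage are the
inclusion ratios above; unique coverage of a recipe is the solution
coverage minus the coverage with that recipe deleted. Duplicate recipes
therefore have zero unique coverage, and a single recipe's unique
coverage equals its raw coverage.

**Robustness.** The scan re-runs the truth table and minimization at each
consistency threshold (default {0.75, 0.80, 0.85}; the baseline is always
included) and flags whether the parsimonious + intermediate recipe sets
are identical to the baseline's.

**Condition set.** The default conditions are the five subsystem values
Z1, Z5, Z6, Z7, Z8 with the CCD as outcome, reflecting the analysis
design this package operationalizes (the economy-structure, efficiency
and public-investment subsystems are dropped to keep the condition count
proportionate to small yearly case sets); "multi-stage" analysis is
exactly per-year cross-sections run side by side and compared
descriptively. The outcome is calibrated with the same quartile rule as
the conditions by default, with per-variable anchor overrides.

## Synthetic data and what passing tests mean

`generate_panel()` draws log-normal indicators with a negative
log-location shift for the mountain/island stratum on the economy and
healthcare blocks (half on society), mild year-on-year drift (default
0.05/yr), and per-county-indicator-year noise (default sd 0.35). The
defaults mirror the study structure: 86 counties, 25 in the
disadvantaged stratum, years 2020–2022, all 20 indicators positive. The
generator reproduces the *structure* of such panels — two strata with a
persistent gap, skewed positive indicators, yearly cross-sections — and
deliberately not the magnitudes of any real yearbook, nor spatial
autocorrelation, indicator cross-correlations beyond the stratum effect,
or reporting artifacts of real statistical systems. Tests passing on
synthetic data therefore certify the *machinery* (weights sum to one,
planted orderings and recipes are recovered, robustness holds at zero
noise), not empirical claims about any real region.

`generate_qca_cases()` draws condition memberships uniformly on
$[0.05, 0.95]$ and sets the outcome to the max-min evaluation of the
planted recipes, optionally plus truncated-normal noise clipped to
$[0.001, 0.999]$. At zero noise the planted configuration is recoverable
exactly, and `recovery_harness()` checks this end to end, along with a
crisp contradiction count (corners whose assigned cases straddle the
outcome's 0.5 crossover — provably zero for noise-free plants).

Both generators fix the RNG kind (Mersenne-Twister, inversion) so a seed
pins results across platforms. Test and example problem sizes (panels of
10–30 counties, case sets of 25–100, 200 random truth tables at
$k \le 5$) were chosen as the smallest sizes at which each property is
non-trivial.

## Packaged fixtures

* `table4_ccd.csv` — the published 86-county × 3-year CCD matrix,
  checksummed at load. All regional/temporal headline statistics in
  `fixture_headline_stats()` and `scripts/acceptance.R` are recomputed
  from it at run time.
* `region_groups_reconstructed.csv` — a **synthetic, non-authoritative**
  reconstruction of the 25-county mountain/island roster, which the
  source material never enumerates. It was selected by exhaustive search
  over plausible 25-subsets containing every county named as
  mountain/island, minimizing distance to the published group summary
  statistics. Use `read_region_groups()` with a user-supplied file
  whenever the true roster is available.

## Known limitations

* Raw yearbook indicator values are not shipped, so published
  entropy-weight, system-score and configurational *numeric* results are
  not reproducible here; only the CCD-matrix statistics and the method
  guarantees are.
* The roster reconstruction matches published group statistics closely
  but cannot be verified county by county.
* The intermediate-solution rule admits a remainder on expectation
  agreement alone; it does not additionally require the remainder to be
  covered by the parsimonious solution, which some software variants do.
* No spatial statistics (autocorrelation, Theil/Gini decompositions) and
  no map rendering.
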