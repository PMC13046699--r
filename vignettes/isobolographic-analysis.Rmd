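---
title: "Isobolographic analysis of fixed-ratio drug combinations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Isobolographic analysis of fixed-ratio drug combinations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isobolr)
```

## The problem

When two cytostatic drugs are combined, the central pharmacological
question is whether the mixture is more potent than the two drugs'
individual potencies predict (synergy), less potent (antagonism), or
exactly as potent (additivity). isobolr implements the classical
isobolographic answer to that question for fixed-ratio two-drug
combinations assayed by MTT viability plates, end to end: raw optical
densities in, interaction calls and figures out.

The null model is Loewe additivity: two drugs are additive if each can
be regarded as a dilution of the other, so doses can be exchanged at
the rate set by their IC50s. In component-dose coordinates the set of
additive dose pairs producing 50% inhibition — the 50% isobole — is
the straight segment joining the two single-drug IC50s whenever the
two concentration–response curves are parallel on the probit scale.

## From wells to curves

MTT optical density is proportional to the number of viable cells.
For each well the package computes

viability% = 100 · (OD − mean blank OD) / (mean control OD − mean blank OD),

and inhibition% = 100 − viability%. Per-well values falling outside
[0, 100] (noise below the blank or above the control mean) are clamped
to the boundary with a warning rather than dropped: dropping wells
would unbalance replicate counts across concentrations and silently
reweight the downstream fit, while clamping keeps the design balanced
and the warning preserves auditability. The blank correction uses the
plate-wide blank mean, the standard MTT reduction when no per-column
blank structure exists. Per-concentration viability is also compared
against control by one-way ANOVA with Tukey's HSD, with the usual
four-tier star codes at strict p < 0.05 / 0.01 / 0.001 / 0.0001.

The concentration–response relationship curve (CRRC) is modelled as a
straight line on probit–log10 axes:

probit(inhibition fraction) = b · (log10 c − μ),

so μ = log10(IC50) and b is the slope in probit units per decade of
concentration. Per-concentration mean inhibition fractions are
probit-transformed and fitted by weighted least squares. Two numerical
choices matter here:

* **Working weights.** The probit transform amplifies noise enormously
  in the tails: for plate noise of roughly constant variance on the
  inhibition scale, Var(probit(p̂)) ∝ 1/φ(probit(p))², where φ is the
  standard normal density. Each concentration therefore receives the
  classical probit-analysis working weight n · φ(probit(p̂))². With
  flat weights the extreme concentrations dominate the residual
  variance and the regression standard errors stop tracking the true
  sampling variability of the slope and of μ; with working weights the
  reported SEM matches the empirical sampling SD of the IC50 estimate
  in simulation (both ≈ 0.013 on the 0.2 µM selumetinib-like scenario
  exercised in the test suite).
* **Extreme-response exclusion.** Concentrations whose mean inhibition
  lies outside [0.5%, 99.5%] are excluded from the regression, echoing
  the Litchfield–Wilcoxon practice of discarding extreme responses.
  Exclusion rather than winsorising keeps the fit exact on noiseless
  probit-generated data for any slope; pinning extremes to the bounds
  would bias both b and μ whenever the design spans doses beyond the
  probit-reliable range.

The linear-scale estimate is IC50 = 10^μ with the first-order
delta-method standard error SEM = ln(10) · IC50 · SE(μ). The reported value is therefore a
symmetric IC50 ± SEM on the linear scale, the form used in published
MTT panels.

The effective sample size attached to an IC50 — used later for
Welch–Satterthwaite degrees of freedom — follows Litchfield and
Wilcoxon's N′: the number of *wells* at concentrations whose mean
response lies in the 16–84% window (probit ± 1), floored at 2. N′
counts experimental units carrying IC50 information, not dose levels;
counting levels instead collapses the Welch df to ≈ 3 for a triplicate
7-dose design and makes the comparison so conservative that its
smallest attainable p-value on calibrated data is ≈ 0.1.

## Parallelism and the additive prediction

Two CRRCs with equal slopes justify a single additivity line. The
package tests slope equality with
t = (b_A − b_B)/√(SE_A² + SE_B²) on Welch–Satterthwaite df built from
the component regression dfs (n_points − 2 each), at α = 0.05.

For the fixed-ratio design, "1:1" is the IC50-fraction convention: the
mixture ray satisfies a/IC50_A = b/IC50_B, so drug A's share is
f = 0.5 of the IC50-normalised dose. Along that ray:

* **Parallel curves** give a single additive point A with total
  IC50_add = f · IC50_A + (1 − f) · IC50_B and variance
  f² SEM_A² + (1 − f)² SEM_B² (independent single-drug experiments).
* **Nonparallel curves** have no single additivity line. Dose
  equivalence through the two probit lines gives a curved 50% isobole
  in each reference direction: with r = b_A/b_B the B-referenced
  isobole is b = IC50_B · (1 − (a/IC50_A)^r), and the A-referenced one
  uses 1/r. Intersecting each with the 1:1 ray reduces to the scalar
  root of s + s^r = 1 on (0, 1) (solved by bracketed bisection to
  1e-10; the two directions' roots satisfy s(r) + s(1/r) = 1 exactly).
  The two intersections give a lower and an upper additive total,
  A′ and A″, bounding the additivity region; at r = 1 both collapse to
  the parallel point. This power-isobole construction was chosen
  because it produces exactly two bounding additivity points from the
  two fitted curves, which is what a nonparallel isobologram displays;
  published nonparallel corrections differ across the methodological
  literature and none is uniquely canonical.

SEM for A′/A″ is propagated by seeded Monte Carlo (default 10,000
draws): component IC50s, and slopes when their standard errors are
available, are drawn from independent normals truncated at zero
(redrawn rather than clamped, to avoid a point mass at zero), the
points recomputed, and the sample SD reported. For parallel mode the
analytic formula is used; the Monte-Carlo path reproduces it and, on a
fixed-slope toy, matches a finite-difference delta-method oracle
within 5%.

## Calling the interaction

The experimental mixture curve is fitted exactly like a single drug on
the total-concentration scale, giving point M = IC50_mix ± SEM. The
comparison against the additive expectation is an unpaired t-test with
Welch's correction:

t = (IC50_add − IC50_mix) / √(SEM_add² + SEM_mix²),

with Satterthwaite df from the two SEMs and their effective n (additive
side: the smaller of the two components' N′). Positive t means the
mixture is more potent than additivity predicts. The interaction index
is γ = IC50_mix / IC50_add.

Labels follow a two-tier rule. Significant comparisons (p < α) are
*synergistic* (γ < 1) or *antagonistic* (γ > 1). Non-significant
comparisons are labelled a *tendency* when M falls outside
IC50_add ± k · SEM_add, and *additive* otherwise. The band width k = 1
is a package decision — "tendency" has no standard operational
definition — and is exposed as `tendency_k` so a stricter analysis can
widen it. For nonparallel pairs the additive reference for the test is
the midpoint of A′/A″ with the half-width of the bound interval folded
into SEM_add in quadrature, so genuinely ambiguous additivity widens,
never narrows, the test. At γ = 1 the direction of an interaction is
undefined and the call is never synergistic or antagonistic; a
relative tolerance of 1e-9 treats numerically coincident estimates as
additive. No multiplicity correction is applied across pairs by
default (`holm = TRUE` re-labels from Holm-adjusted p-values as a
sensitivity analysis).

Summaries follow the field's conventions: a *polygonogram* per cell
line (complete graph over the drugs; green solid = synergy, green
dashed = tendency to synergy, black = additive, red dashed = tendency
to antagonism, red solid = antagonism) and a pair × cell-line code
matrix ("S" = synergy or its tendency, "A" = the antagonism direction,
"0" = additive; pairs uniform across lines collapse to one symbol).

## The synthetic-data generator

The raw absorbance data behind published melanoma-panel studies are
typically unavailable, so validation runs on simulated plates with
known ground truth. `synthetic_config()` emulates a triplicate 96-well
MTT experiment: mean inhibition at concentration c is
100 · Φ(b · (log10 c − log10 IC50)); per-well Gaussian noise (default
SD 5 percentage points) is added on the inhibition scale and mapped
back to optical density through a control/blank model (controls at
OD 1.0, blanks at 0.08, OD noise SD 0.02, truncated at 0). The default
design uses 7 log-spaced concentrations spanning IC50/16 to 16 · IC50,
which guarantees several doses inside the informative 16–84% window,
and 3 replicate wells per concentration.

Mixtures respond as a probit curve in total concentration with true
IC50 = κ · (f · IC50_A + (1 − f) · IC50_B) and slope equal to the
f-weighted mean of the component slopes (the mixture-slope model is
not empirically constrained; it is configurable). κ = 1 encodes exact
Loewe additivity, κ < 1 synergy, κ > 1 antagonism. `sham_pair()`
builds the classical validity check — the same compound combined with
itself under two unit labels, additive by construction — and
`scenario_study_defaults()` returns a four-cell-line, five-drug
melanoma panel whose true IC50s equal published MTT values (docetaxel
in nM, the rest in µM) with all ten pairs at f = 0.5. True probit
slopes are not published; the default 2.0 is an explicit placeholder.

What the simulation does *not* emulate: plate edge effects and optical
crosstalk, non-Gaussian outliers, partial-efficacy (Emax < 100%)
compounds, and any cell-biology mechanism behind an interaction.
Passing tests therefore demonstrate that the statistical machinery is
correct and calibrated under idealised MTT noise, not that any
particular real combination is synergistic.

## Calibration results the test suite reproduces

With the default noise model (SD 5, triplicate, 7 doses), the suite
verifies, among others:

* noiseless profiles round-trip (slope, IC50) to 1e-6 relative error,
  and the fitted optimum matches a brute-force grid search of the
  weighted least-squares objective within one 1e-3 grid step;
* sham self-combinations are called significant at a rate inside the
  95% binomial band around the nominal 5% (500 seeded simulations),
  and their slopes are judged parallel in ≥ 94/100 runs;
* the estimated interaction index γ regresses on the true κ over
  {0.5, 0.75, 1, 1.5, 2} with slope within [0.8, 1.2], and κ = 0.5 is
  called synergistic in ≥ 80/100 runs;
* a ± 2 SEM interval covers the true IC50 in ≥ 90/100 runs — the
  honest floor for a pivot that is approximately t with ~5 residual
  degrees of freedom, P(|t₅| < 2) ≈ 0.90, rather than the ≈ 95% a
  large-sample z-interval would promise.

Simulation sizes (500 shams, 20 seeds per κ, 100-seed power runs) were
chosen as the smallest runs whose binomial/regression error is clearly
inside the asserted bands.

## Worked example

```{r example, eval = FALSE}
library(isobolr)

# additive prediction from published single-drug IC50s
cis <- ic50_estimate(1.29, 0.34, "uM", agent = "cisplatin")
mtx <- ic50_estimate(0.04, 0.02, "uM", agent = "mitoxantrone")
additive_parallel(cis, mtx, f = 0.5)
#> <additive_prediction> mode: parallel, f = 0.5
#>   A: total = 0.665 uM +/- 0.17029  (a = 0.645, b = 0.02, s = 0.5)

# a complete simulated study on the default melanoma panel
report <- run_pipeline(scenario_study_defaults(), seed = 17, n_mc = 2000)
report$matrix
```

## Known limitations

* The log-probit line assumes full-range (0–100%) response; compounds
  plateauing below 100% inhibition need an Emax-style model that is
  out of scope here.
* The delta-method SEM is first-order and symmetric on the linear
  scale; for very steep or very shallow curves a profile-likelihood
  interval would be asymmetric.
* The nonparallel additive bounds follow the dose-equivalence
  power-isobole construction; other published nonparallel corrections
  may produce numerically different A′/A″.
* Only two-drug, single-effect-level (50%) fixed-ratio designs are
  supported; Bliss independence, Chou–Talalay combination indices and
  response-surface models are deliberately not implemented.
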