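---
title: "Modeling and analyzing microdroplet HDX deuterium ladders"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling and analyzing microdroplet HDX deuterium ladders}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hdxladder)
```

## The problem and the model

Ambient ionization mass spectrometry records a metabolic profile in seconds
but cannot tell isobaric ions apart: two compounds with the same molecular
formula produce one indistinguishable peak. Spraying the sample from a
deuterated solvent (methanol/D₂O) changes that. During the microsecond
flight of the charged microdroplets, labile protons — hydroxyl, phenol,
amine, imine, amide, carboxyl hydrogens, and the charging proton itself —
exchange for deuterium. Each incorporation shifts the ion by
m(²H) − m(¹H) = 1.006277 u, so a compound with *n* exchangeable sites shows
a ladder of deuterated channels D₀ … D (*n*+1 channels when the charge-site
deuteron participates). Isobars with different site counts, or the same
count but different functional groups, give different ladders.

`hdxladder` models the observed channel intensities as

> I(k) = Σ_{d + j = k} P(D = d) · A(j)

where P(D = d) is the probability of incorporating *d* deuteriums and A(j)
is the ion's natural isotope abundance at nominal offset *j* (¹³C, ²H, ¹⁵N,
¹⁸O…). The two layers reflect two physical facts:

1. **Exchange is site-wise Bernoulli.** Each labile proton exchanges
   independently with its own probability, so the deuterium count follows a
   Poisson-binomial distribution, computed exactly by iterative convolution
   (`deuterium_distribution()`). The charging proton of a proton-bearing
   adduct ([M+H]⁺, [2M+H]⁺) is one extra Bernoulli trial; a sodiated ion has
   none, which is how a [M+H]⁺/[M+Na]⁺ pair from *different* metabolites can
   be unmasked (sphingosine vs. palmitoylethanolamide in the fixture set).
   For [2M+H]⁺ dimers both monomer units exchange, so the site list is
   doubled.
2. **The instrument merges channels at unit mass.** At resolving power
   120,000 (FWHM ≈ 0.002 u at m/z 300) a deuterium replacement is not
   separated from a ¹³C or ¹⁵N substitution, so the deuterium distribution
   must be convolved with the ion's nominal-mass natural pattern
   (`ion_natural_pattern()`, per-element polynomial convolution over a
   pinned IUPAC 2021 mass/abundance table). The same reasoning inverts:
   `natural_correction()` solves the triangular convolution system by
   forward substitution to recover the deuterium-count distribution from an
   observed ladder, clipping small negative solutions produced by noise.

## Exchange probabilities and their calibration

Per-site probabilities are class defaults (`exchange_rate_defaults()`,
shipped as a YAML config) referenced to the 7:3 methanol/D₂O spray:

| class | p | class | p |
|---|---|---|---|
| hydroxyl | 0.45 | amide N–H | 0.30 |
| amine / imine N–H | 0.50 | carboxyl | 0.60 |
| phenol | 0.20 | charge site | 0.25 |

Under liquid-phase conditions the effective probability is
`p_class × (d2o_fraction / 0.3) × back_exchange_factor`; gas-phase exchange
is fast and back-exchange-free, so every probability becomes 1 — which is
exactly why gas-phase ladders of isobars with equal site counts coincide
while liquid-phase ladders keep the functional-group fingerprint.

These numbers are calibration constants of the simulator, not measured rate
constants. They were fixed, once, to reproduce the qualitative behaviour of
the reference compound panel simultaneously: hydroxyl exchanging faster than
phenol; a zero-site compound (hydrocodone) showing exactly one deuterated
peak from the charge deuteron; naloxone's base peak moving to D₁ while
6-acetylmorphine's stays at D₀ (this bounds the charge-site probability from
above — a larger value drags every base peak to D₁ once the ~20% natural A+1
of a C₁₈–C₁₉ ion is convolved in); glucose peaking at D₂ and inositol at D₃
(this pins the hydroxyl class into [0.43, 0.50)). Morphine is the one
compound that cannot be captured by class defaults at all: it shares the
{phenol, hydroxyl} site-class set with naloxone yet keeps its base peak at
D₀ with three visible deuterium peaks. Its fixture therefore carries
explicit per-site probabilities (phenol 0.13, hydroxyl 0.20) — a
compound-specific attenuation consistent with the stronger liquid-phase
back exchange that distinguishes morphine from norcodeine in practice.

Channel flagging (`judge_deuteration()`) marks channel k as deuterated when
the corrected deuterium mass at k is at least 1% *of the largest corrected
mass* (base-peak-relative). A threshold on absolute probability mass would
make "three deuterium peaks with base peak D₀" mathematically impossible
for a three-trial compound: requiring P(all three exchange) ≥ 0.01 forces
P(exactly one)/P(none) > 0.81, at which point the convolved channel 1
always overtakes channel 0.

## Noise, replicates and detection

Channel intensities receive multiplicative log-normal noise with a chosen
CV (mean-one parameterization; `instrument_model()`), seeded per simulation
so that every generator is a pure function of its seed. The default CV of
0.05 keeps the relative abundance of a deuterium channel within a
day-to-day RSD of 15% over replicate simulations, matching the
reproducibility the ion source sustains under fixed pH and D₂O fraction.

Detection (`find_ladder()`) walks up from the precursor in 1.006277-u steps
and accepts a peak at channel k within k × 0.0002 u — the per-step window
1.0063 ± 0.0002 accumulated linearly, the conservative reading when only a
per-step tolerance is stated. A ¹³C neighbor at +1.0075 u falls outside the
first window and is rejected. Compound lookup against the shipped table
uses a 5.0 ppm mass tolerance (`ppm_match()`).

## Two-component mixtures and quantitation

For an isobaric pair measured together, the mixed ladder is the linear
combination I(k) = N_g·I_g(k) + N_i·I_i(k) of the pure per-mole patterns
(`mix_patterns()`), under the explicit assumption of near-equal ionization
efficiencies; patterns are then base-peak-normalized
(I_rel = 100·I_abs/I_BP, `to_relative()`) and compared with the mean
absolute deviation over the common channel range
(`pattern_loss()`, in percent units). `estimate_composition()` minimizes
that loss over the mole-fraction simplex by a 0.001 grid search plus
golden-section refinement — the objective is piecewise linear, so
derivative-based optimization is inappropriate, and the procedure is
deterministic. The divisor of the loss is the number of channels compared
(n+1), the only reading under which the divisor matches the summand count.

One isobar can still be quantified absolutely when it owns a *signature
channel* — the lowest deuterium channel flagged for the target but not for
its interferent (`signature_channel()`; D₂ for codeine over hydrocodone).
The response is the raw absolute signature-channel intensity ratioed to the
internal standard's strongest deuterium channel; ratioing to the IS already
removes the run-to-run scale, and base-peak renormalization would bend the
line. The interferent's heavy natural isotopologues do leak a constant
offset into the signature channel (hydrocodone's D₁ + ¹³C species sits at
D₂); it lands in the intercept of the ordinary-least-squares calibration
(`fit_calibration()`) and leaves the Pearson linearity untouched.

## Cohort profiling

`generate_cohort()` emulates a urine-like case/control study: the
twelve-compound panel plus 30 non-deuterating decoy ions in m/z 50–300,
per-sample log-normal abundance scatter (CV 0.40), TIC normalization to a
total of 100, and — for the designated marker ions urea and creatinine — a
group difference in exchange (back-exchange factor 0.3 in cases vs. 1.0 in
controls) plus a mild 1.2× abundance multiplier. Each sample is "measured"
twice, pre-HDX (plain profile, natural isotopes only) and post-HDX, sharing
its abundance draws. The effect sizes are calibrated to the experiment's
qualitative outcome: the inter-group difference in the markers' deuterium
peaks should be visible on averaged spectra, while the plain-profile
abundance difference stays inside biological scatter.

`build_features()` turns spectra into a samples × features matrix: one
feature per observable ion (isobaric pairs share one precursor m/z and
hence one column) holding the D₀ intensity, plus — in the deuterium-aware
mode — one feature per deuterium channel judged real on the cohort-average
spectrum. Restricting the extra features to judged channels keeps
natural-isotope tails, which carry no exchange information, out of the
matrix. PCA (`hdx_pca()`) autoscales features to unit variance (intensities
span orders of magnitude) and fixes component signs by making the dominant
loading positive. Group separation is summarized by the mean silhouette
width over PC1–PC2 (`separation_score()`), a quantitative stand-in for
"the score plot separates cleanly": the plain-profile matrix hovers near 0
while the deuterium-augmented matrix typically reaches 0.3–0.5, and the
improvement holds across seeds.

## Problem sizes and numerical choices

The shipped tests and the acceptance script run entirely on synthetic data
at desk scale, chosen as the smallest sizes at which the claims are
meaningful: 100 seeds × 3 ratios for mixture recovery, 10 replicates for
the RSD bound, 20 cohort realizations of 30 cases + 9 controls for the
profiling comparison, enumeration oracles up to n = 10 Bernoulli sites and
≤ 12-atom molecules. Tolerances: exact-arithmetic identities at 1e−12
(Poisson-binomial DP vs. subset enumeration, convolution vs. double loop),
forward/inverse round trips at 1e−9 (clipping and renormalization make the
inverse only almost exact), published values at their printed precision.
Degenerate inputs fail loudly: all-zero spectra cannot be normalized,
collinear pure patterns are non-identifiable, identical flag sets have no
signature channel, a singular natural pattern stops the correction.

## What the simulations do and do not show

The generators reproduce the *structure* the analysis assumes — Bernoulli
site exchange, unit-mass channel merging, log-normal intensity noise,
compositional TIC effects, marker-specific group differences. They do not
reproduce real urine: no matrix suppression, no correlated metabolite
biology, no pH-dependent kinetics (group differences enter as a
back-exchange factor, not a pH law), no in-source fragmentation, and decoy
ions are deuteration-free by construction. Passing tests therefore
demonstrate that the pipeline is correct and self-consistent under its
stated model, not that the model captures every property of clinical data.

Two quantitative limitations are worth stating plainly. First, glucose and
inositol differ by a single hydroxyl of the same class, so their pure
ladders are similar; at 3% channel noise the single-spectrum mole-fraction
estimate scatters with a standard deviation near 0.05 even though it is
unbiased — the Monte-Carlo mean recovers the truth to well under ±0.01,
but an individual fit can be off by ~0.1. Averaging replicate spectra
before fitting is the practical remedy. Second, the morphine fixture's
per-site overrides illustrate a general caveat: class-level exchange
probabilities cannot capture every compound, so quantitative ladder
predictions for a new molecule should be re-calibrated against a standard
before being trusted.

## A worked example

```{r example, eval = FALSE}
lib <- fixture_library()
nlx <- lib[["naloxone"]]
lad <- simulate_ladder(nlx$formula, nlx$adduct, nlx$sites,
                       instrument = instrument_model(noise_cv = 0))
print(lad)                         # relative ladder, base peak at D1
judge_deuteration(lad, nlx$formula, nlx$adduct)  # flags D1..D3, 2 sites

gen <- generate_mixture_samples(noise_cv = 0.03, seed = 1)
lad <- find_ladder(gen$spectra[[1]], gen$precursor_mz, max_k = 9)
fit <- estimate_composition(lad, gen$pure$glucose, gen$pure$inositol)
summary(fit)
```
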