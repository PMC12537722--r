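---
title: "Methods: porewater geochemistry and community analysis around the SMTZ"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: porewater geochemistry and community analysis around the SMTZ}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smtz)
```

## Scope

`smtz` implements the computational chain used to study how long-term
warming reshapes the sulfate–methane transition zone (SMTZ) in coastal
sediments: conversion of headspace gas-chromatograph readings to total
porewater methane, sulfate diffusive fluxes by Fick's first law with a
porosity/tortuosity correction, estimation of the depth of no sulfate
(DNS), seasonal and between-bay comparison statistics, and family-level
community analyses (Bray–Curtis, PCoA, PERMANOVA) on amplicon count
tables. A synthetic-data generator emulates all of the study's data streams
with known ground truth, so every stage is testable end to end without
external downloads.

## Headspace equilibration

A jar holds bulk sediment (volume $V_s$, porosity $\varphi$), added
distilled water $V_w$, and a gas headspace $V_{hs}$. After shaking, the
methane originally dissolved in the porewater partitions between the
headspace and the aqueous phase. From a measured headspace mixing ratio
$x$ (ppm), at pressure $P$ and temperature $T$:

$$n_{hs} = \frac{x\,10^{-6}\,P\,V_{hs}}{RT}, \qquad
  n_{aq} = K_H(T)\, x\,10^{-6} P\,(V_w + \varphi V_s),$$

and the total porewater concentration is
$C = (n_{hs} + n_{aq}) / (\varphi V_s)$, reported in mM. $K_H$ is the
methane Henry solubility, $1.4\times10^{-3}$ mol L$^{-1}$ atm$^{-1}$ at
298.15 K with a van 't Hoff temperature parameter of 1700 K. Salinity is
neglected because the jars receive distilled water, and the biocide added
in the field is assumed to stop microbial production/consumption entirely.
The equilibration temperature (294.15 K, a 21 °C lab) and pressure (1 atm)
are configuration fields, as the field protocol fixes neither. Whether the
aqueous fraction is counted is itself a config flag
(`include_dissolved`, default on): at these volumes it contributes about
5 % of the total, so both conventions are offered and the generator and
converter must simply agree.

The generator's `generate_headspace_samples()` is the exact algebraic
inverse (both phases are linear in ppm), which gives the package a strong
invariant: generate-then-convert is the identity to floating-point
precision, checked across the 0.001–0.8 mM working range.

## Sulfate gradients, DNS and diffusive fluxes

Sulfate in an AOM-dominated sulfate reduction zone decreases
quasi-linearly from the seafloor to the depth of no sulfate. Per core we
fit ordinary least squares of concentration on depth over the window from
the **depth of maximum sulfate** down to the **last strictly positive**
measurement. Starting at the maximum rather than the surface protects the
fit from winter profiles whose surface layer is depressed (a subsurface
peak at 5–10 cm): above the peak the steady-state linear-diffusion
assumption does not hold. The DNS is the x-intercept
$-\,\hat\beta_0/\hat\beta_1$; it is undefined (an error, and an excluded
core in the pipeline) when the fitted slope is non-negative.

The flux follows the diagenetic form of Fick's first law,

$$J = -\varphi\, D_s\, \frac{dC}{dx}, \qquad
  D_s = \frac{D_0}{1 - \ln \varphi^2},$$

converted to mmol m$^{-2}$ d$^{-1}$ (the factor is
$10^{-3} \cdot 86400 \cdot 10^4$ from mM cm$^{-1}$ and cm$^2$ s$^{-1}$).
The porosity factor is the standard convention for fluxes across the
sediment–water interface; a config flag drops it for the bare
$J = -D\,dC/dx$ form. $D_0$ uses a linear-in-temperature parameterisation
$(m_0 + m_1 T)\times10^{-6}$ cm$^2$ s$^{-1}$ with $m_0 = 4.88$,
$m_1 = 0.232$ from standard seawater tabulations; both coefficients are
configurable because diffusion-coefficient sources differ at the few-percent
level. The temperature entering $D_0$ is the bay/season mean of the logger
series. A positive $J$ is sulfate diffusing downward; in an AOM-dominated
system the same magnitude is the implied upward methane flux consumed at
the SMTZ.

Cores with clearly non-linear sulfate profiles violate the steady-state
assumption and are excluded. "Clearly non-linear" is made operational as
$R^2 < 0.90$; the threshold is a package choice (the field criterion is
qualitative) and is exposed in the configuration. Bay/season summaries
average included cores only and keep groups with no usable core as
missing-value rows.

Depths are always positive cm below the seafloor (slice midpoints);
concentrations in mM. The code does not attempt unit inference.

## Seasonal and bay comparisons

Season windows default to 1 June–22 September (summer) and 21 December–20
March (winter). Summaries are the arithmetic mean, sample SD, min and max
of all logger observations in the window. The bay contrast uses a Welch
(unequal-variance) t-test; two identical constant samples return
$t = 0, p = 1$ by convention.

Methane fold changes divide concentrations matched at a requested depth
(nearest match within ±1 cm; jar intervals make "4 cm" the 2–6 cm
midpoint). A detection floor, default $10^{-4}$ mM — below the smallest
concentration the GC method resolves — replaces values below it in **both**
numerator and denominator; this keeps ratios finite and strictly positive
(a floored zero numerator would otherwise give a zero "fold") and every
floored record is flagged. For the season contrast each site is its own
match across seasons. For the bay contrast the bays contain different
sites, so each site in the numerator bay is compared against the
denominator bay's mean at the matched depth and season; this is a package
convention, made explicit here because no within-pair matching exists
across bays. Summaries report the maximum fold ("up to"), the mean of
per-site ratios, and the ratio of mean concentrations, because an "average
fold change" is ambiguous between the last two.

## Community analyses

All community operations work on a samples × ASVs count matrix with a
taxonomy (domain…family) and sample metadata. Aggregation to a rank sums
counts over ASVs sharing the rank label and conserves per-sample totals.
Relative abundances keep the `top_k` (default 15) taxa by mean relative
abundance — ties broken lexicographically so results are deterministic —
and pool the rest as `Other_Families`.

Bray–Curtis dissimilarity
$d(x,y) = \sum_i |x_i - y_i| / \sum_i (x_i + y_i)$ is computed on
per-sample relative abundances by default, so library-size differences are
not mistaken for community turnover (raw-count mode is a flag). PCoA is
classical metric scaling: Gower-centre $-\tfrac12 D^2$, eigendecompose,
scale eigenvectors by $\sqrt{\lambda}$. Negative eigenvalues (possible for
non-Euclidean dissimilarities) are reported but excluded from the
coordinates, with no Lingoes/Cailliez correction — the simplest defensible
convention, and the one that keeps Euclidean-embeddable input exactly
reproducible (a tested invariant).

PERMANOVA partitions the total sum of squares of the Gower-centred matrix
via hat matrices of sequentially added model terms (sequential/Type-I sums
of squares), i.e. $SS_k = \mathrm{tr}[(H_k - H_{k-1})G]$, with pseudo-$F$
per term and $p = (\#\{F^\pi \ge F\} + 1)/(B + 1)$ under free permutation
of samples. Sequential SS means term order matters in unbalanced designs;
the order is deliberately a user input rather than a default. The
permutation p-value can never drop below $1/(B+1)$. The implementation is
written from first principles (it is the package's own statistical core)
and is cross-checked in the test suite against an exhaustive enumeration
oracle at $n = 6$, against the closed-form two-group pseudo-$F$, and
term-by-term against an independent implementation.

## The synthetic-data generator

The generator defines the study conditions the package is exercised under;
it is parametric shape emulation, not a reaction–transport solution.

* **Sulfate**: a line from `sulfate_surface` at 0 cm to zero at the true
  DNS; observed values are $\max(0,\ \text{line} + \varepsilon)$ with
  Gaussian $\varepsilon$. The truncation is applied once, after the noise,
  so depths below the DNS read zero rather than half-positive — this is
  what makes the DNS estimator recover the truth without bias (tested:
  mean over 500 noisy cores within 2 %). An optional surface depression
  (winter) subtracts a wedge tapering to zero at 10 cm, producing the
  subsurface peak the regression window is designed around.
* **Methane**: zero above a transition depth 5 cm above the DNS, then a
  linear (optionally logistic) ramp to `methane_deep` at the 32 cm
  reference depth.
* **Temperature**: an annual sinusoid (mean 10 °C, amplitude 9.5 °C,
  peaking around day 205) plus logger noise; the heated bay adds a
  constant 5.1 °C offset.
* **Community**: expected family proportions
  $\propto \exp(\text{base} + \text{slope}\cdot\text{depth} +
  \text{bay effect}\cdot \mathbb{1}[\text{heated}])$, counts drawn
  Dirichlet-multinomial at a fixed library size (20 000 by default),
  each family split over 3 ASVs with a fixed within-family profile.

Default study scenario: 6 mM surface sulfate (brackish Baltic coastal
water; open-ocean values near 28 mM appear only as explicit test
parameters), DNS of 25/37 cm (control summer/winter) and 22/30 cm (heated)
— the control values are the emulated system's reported seasonal pattern,
the heated values our choice to express a warming-thinned sulfate zone —
deep methane 0.8 mM (control) and 0.7 mM (heated), concentration noise
0.3 mM (a choice: the emulated system reports no replicate variance),
porosity 0.8 throughout, summer slices every 2 cm and winter every 4 cm,
and 3 cores per bay and season. With these conditions the pipeline's
summer control flux comes out near 1 mmol m$^{-2}$ d$^{-1}$, the magnitude
typical of coastal Baltic sulfate fluxes.

What the generator deliberately does **not** emulate: methane above the
transition depth is exactly zero, so near-seafloor fold changes in
synthetic data are detection-floor artefacts (flagged as such) — real
sediments hold small but non-zero surface methane; profile noise is
i.i.d. Gaussian with no depth correlation; the community model has no
season effect on most families and no overdispersion structure beyond the
Dirichlet. Passing tests therefore demonstrate the correctness of the
calculations, not field realism of every feature.

All generators take explicit seeds, draw from a private RNG stream, and
restore the caller's RNG state; identical seeds give byte-identical
outputs.

## Numerical choices and degenerate inputs

* Perfectly collinear profiles give $R^2 = 1$ exactly; constant profiles
  give slope 0 with $R^2$ reported as `NA` and are treated as "no sulfate
  depletion".
* Cores whose regression window has fewer than 3 points (e.g. sulfate
  increasing to the bottom) are flagged `unusable sulfate profile` rather
  than crashing the pipeline.
* PCoA's positive-eigenvalue cutoff is `max(|lambda|) * 1e-8`.
* PERMANOVA refuses rank-deficient designs and names the aliased columns.
* The exhaustive-enumeration and type-I-error tests run at small $n$
  (6 and 10 samples, 99–999 permutations, 500 null draws); the pipeline's
  factorial PERMANOVA runs at 60 samples and 999 permutations. All sizes
  are package choices balancing statistical resolution against a test
  suite that runs in well under a minute per file.

## Known limitations

* Fluxes assume steady state; no bioirrigation, compaction or
  non-local transport corrections.
* The DNS extrapolates a linear fit; where sulfate tails off
  asymptotically the x-intercept overestimates the true depletion depth.
* The flux's temperature enters only through $D_0$; porewater temperature
  is taken equal to the bottom-water logger mean for the season.
* PERMANOVA's free permutation is appropriate for the factorial design
  used here but offers no restricted-permutation strata for nested or
  repeated-measures designs.
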