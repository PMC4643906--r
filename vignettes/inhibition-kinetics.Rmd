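---
title: "Characterising enzyme inhibition: mixed-model fits, Dixon median intersections, and ligand depletion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Characterising enzyme inhibition: mixed-model fits, Dixon median intersections, and ligand depletion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(inhibkin)
```

## The measurement and its models

The package analyses steady-state inhibition assays of the kind used to
characterise inhibitors of fatty acid amide hydrolase (FAAH): a tissue
homogenate hydrolyses a radiolabelled substrate (anandamide, AEA) at a
handful of substrate concentrations spanning roughly 0.5–4 µM, in the
presence of a small grid of inhibitor concentrations, with 3–4 replicate
wells per condition. Three questions recur:

1. **How potent is the inhibitor?** Answered on the percent-of-control
   scale by the four-parameter logistic ("log(inhibitor) vs response,
   variable slope"),

   $$R = \mathrm{bottom} + \frac{\mathrm{top}-\mathrm{bottom}}
   {1 + 10^{(\mathrm{pIC_{50}} + \log_{10} c)\, n_H}},$$

   with the top fixed at 100 % and the bottom either fixed to zero or
   floated, the choice made by Akaike's criterion (`fit_potency()`).
   `pIC50` is on the molar scale; all other concentrations in the package
   are micromolar, so the conversion is $IC_{50}\,[\mu M] = 10^{6 -
   \mathrm{pIC_{50}}}$.

2. **What is the mode of inhibition?** Answered by globally fitting the
   velocity surface with the linear mixed-inhibition model

   $$v = \frac{V_{max}^{app}}{1 + K_m^{app}/[S]}, \qquad
   V_{max}^{app} = \frac{V_{max}}{1 + [I]/(\alpha K_i)}, \qquad
   K_m^{app} = K_m\,\frac{1 + [I]/K_i}{1 + [I]/(\alpha K_i)},$$

   and with its competitive special case ($\alpha \to \infty$), the two
   compared by AIC (`fit_inhibition_kinetics()`). $\alpha$ measures how
   much more weakly the inhibitor binds the enzyme–substrate complex than
   the free enzyme: $\alpha = 1$ is pure noncompetitive, $\alpha \to
   \infty$ pure competitive.

3. **Do two inhibitors bind the same site?** Answered by the
   multiple-inhibitor (Yonetani–Theorell) experiment at fixed substrate:
   Dixon plots of $1/v$ against one inhibitor, one line per concentration
   of the other, are parallel for mutually exclusive binders and form a
   "V" when the two sites are occupied cooperatively
   (`exclusivity_analysis()`).

A fourth, auxiliary model explains a recurring artifact: when the assay
medium contains fatty acid-free serum albumin, lipophilic inhibitors are
partly sequestered, the free concentration is no longer proportional to
the added one, and refitting on the added-concentration axis returns Hill
slopes well above 1 (`free_concentration()`, `apparent_hill_slope()`).

## The Dixon construction and the median-intersection estimator

Because $1/v$ is *exactly* linear in $[I]$ at fixed $[S]$ under the mixed
model, the Dixon plot is not an approximation: the line at substrate
concentration $S$ has slope $(K_m/S + 1/\alpha)/(V_{max} K_i)$ and
intercept $(1 + K_m/S)/V_{max}$, and every pair of such lines crosses at
$([I], 1/v) = (-K_i,\,(1-1/\alpha)/V_{max})$. With $n$ substrate
concentrations there are $\binom{n}{2}$ pairwise intersections — 28 for
the eight-point design. On noisy lines the intersections scatter (pairs
of nearly parallel lines scatter violently), so the package projects the
*median* of the intersection abscissae onto the axis,
$\hat K_i = -\mathrm{median}(x)$, in the same spirit as the direct linear
plot of Eisenthal and Cornish-Bowden. The median tolerates up to half the
intersections going wild before it breaks, which the mean does not; the
test suite quantifies this by corrupting 3 of the 28 intersections and
comparing the two estimators' errors.

Line fitting for Dixon plots uses iteratively reweighted least squares
with the Tukey bisquare loss (tuning constant 4.685, MAD scale) via
`MASS::rlm`, falling back to ordinary least squares below four points or
when the robust scale degenerates (exactly collinear data). Only the line
*location* matters downstream, so the precise bounded-influence loss is
an implementation choice, not a scientific one.

## Fitting machinery and numerical choices

All nonlinear fits use Levenberg–Marquardt least squares
(`minpack.lm::nls.lm`) with:

* **log-parameterisation** of $K_m$, $V_{max}$, $K_i$, $\alpha$ and $n_H$,
  which enforces positivity without constrained optimisation and makes
  the reported standard errors delta-method back-transforms of the
  log-scale curvature errors;
* a **multi-start grid** — $3\times3\times3$ over log-spaced initial
  $K_m$, $K_i$, $\alpha$ for the mixed model ($3\times3$ for the
  competitive one), initial $V_{max}$ scaled from the largest observed
  velocity — keeping the best residual sum of squares. On exact
  model-generated data every estimator returns the generating parameters
  to optimizer tolerance, which the tests assert;
* **unweighted residuals** on the velocity scale (velocity units are
  arbitrary; all estimates except $V_{max}$ are equivariant to rescaling
  the velocity axis, also asserted by a test);
* the **Gaussian-RSS Akaike criterion** $AIC = n\ln(RSS/n) + 2(k+1)$,
  with the small-sample (AICc) correction available but off by default.
  Ties below $10^{-9}$ resolve toward fewer parameters, which also
  handles the zero-RSS comparisons that arise on noiseless data.

Two places deviate from "plain least squares on what was measured", both
deliberately. First, the exclusivity F-test compares shared-slope and
free-slope *linear* models of $1/v$; multiplicative velocity noise makes
the reciprocal heteroskedastic ($\mathrm{sd}(1/v) \propto 1/v$), which
inflates the F-test's size far above its nominal level. Both linear
models are therefore fit with inverse-variance weights proportional to
$v^2$, which restores the nominal 5 % level. Second, the free-slope model
only counts against exclusivity when it beats the shared-slope model by
an AIC margin of 2 — the conventional threshold below which two models
have essentially equivalent support — in addition to the F-test
rejecting; without the margin, the three extra slope parameters win the
AIC comparison on pure noise often enough to erode the verdict's
specificity.

One structural limitation of AIC selection is worth stating plainly: the
competitive model sits on the $\alpha \to \infty$ boundary of the mixed
model, so on competitive-generated data the spurious RSS gain from
freeing $\alpha$ follows roughly a half-and-half mixture of zero and
$\chi^2_1$ *regardless of the noise level*. With AIC's penalty of 2 the
mixed model therefore over-wins with probability near
$P(\chi^2_1 > 2)/2 \approx 8\,\%$ however clean the data, and the
selection accuracy for a true competitive mechanism plateaus around the
low 90s rather than approaching 100 %. This is a property of Akaike
selection itself, not of the optimiser; a heavier (BIC-like) penalty
would trade it against sensitivity to genuinely mixed mechanisms.

Near-parallel Dixon line pairs (relative slope difference below
$10^{-6}$) are excluded from the intersection census rather than allowed
to produce numerically explosive abscissae; the census always satisfies
kept + excluded $= \binom{n}{2}$.

## The albumin depletion model

The depletion model treats albumin as a single class of identical,
independent sites: total site concentration `capacity` (albumin
concentration × sites per molecule) and site dissociation constant `kd`,
both in µM. The free inhibitor concentration is the positive root of

$$F^2 + F(\mathrm{capacity} - T + k_d) - k_d T = 0,$$

evaluated in a cancellation-safe form, and satisfies mass balance
$F + \mathrm{capacity}\cdot F/(k_d+F) = T$ to $10^{-10}$ relative. This
is the minimal mechanism that produces the observed artifact: when
capacity exceeds the true IC50 and binding is tight, the free
concentration stays near zero until the sites fill, then rises steeply,
so the response collapses over a narrow band of *added* concentration
and the refitted Hill slope inflates (values near 3 are reached in the
regime the tests probe). The assay's own albumin comes from the
substrate mix, delivered at a roughly 1:4.5 substrate:albumin molar
ratio — `assay_albumin_model()` computes the implied capacity (2.25 µM
at 0.5 µM substrate). Multi-class sites, substrate sequestration by the
same albumin, and fitting `kd` from data are all out of scope; the
convention of treating the *added* substrate concentration as $[S]$ is
retained.

## What the synthetic generator emulates — and what it does not

`simulate_velocity_table()` produces
$v_{obs} = v_{model}(S, I_{free})\,(1+\varepsilon_m) + \varepsilon_a$
with $\varepsilon_m \sim N(0, \mathrm{CV})$ multiplicative and an
optional additive floor $\varepsilon_a$, truncated at zero (flagged,
since measured hydrolysis cannot be negative). The multiplicative form
matches the roughly signal-proportional scatter of replicate assay data;
the defaults — 8 substrate points spanning 0.5–4 µM, inhibitor levels
0/0.5/1/2 µM, 3 replicates, 5 % CV — mirror the kinetic design the
package targets. The generating constants $K_m = 1$ µM (mid-range of the
substrate span), $V_{max} = 10$ (arbitrary units), $K_i = 0.8$ µM and
$\alpha = 3.2$ are a representative mixed-inhibition parameter set for
this enzyme–inhibitor class; the two-inhibitor design fixes substrate at
0.5 µM with a second inhibitor bracketing $K_2 = 30$ µM, emulating a
weak co-inhibitor against a potent one.

Everything is driven by one integer seed and is bit-reproducible. What
the generator does **not** emulate: radiochemical counting statistics,
extraction efficiency, plate-position or day effects, correlated
replicate errors, substrate depletion over the incubation, and
enzyme-preparation variability. Passing recovery tests on these
simulations therefore demonstrates that the estimators are correct and
well-calibrated *under the stated noise model*, not that real-homogenate
estimates carry the same precision.

Problem sizes used by the test suite and the acceptance script — 200
simulated tables for parameter recovery and for each
model-discrimination and exclusivity cell, 100 paired seeds for the
robustness comparison — are chosen so that Monte-Carlo error on a
proportion is about ±2 percentage points, small against every margin
tested.

## Pipeline and formats

Tables travel as long-format CSV (columns `substrate_uM`,
`inhibitor_uM`, optional `inhibitor2_uM`, `replicate`, `velocity`;
micromolar throughout, with `units = "nM"`/`"M"` conversion on ingest).
`run_pipeline()` chains the stages — potency, kinetics with model
selection, Dixon, exclusivity — on a file or a simulation block and
writes a JSON report in which every number is traceable to one of the
operations above; an identical configuration and seed reproduce the
report except for its timestamp.
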