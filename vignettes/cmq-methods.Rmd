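---
title: "Quasi-color modeling of bifacial leaves: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quasi-color modeling of bifacial leaves: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(leafcmq)
```

## The model

Leaves with strong dorsiventral pigment distribution carry different colors
on their two surfaces, so neither surface alone reflects the blade's
pigment content. The conceptual midpoint quasi-color (CMQ) combines both:
its coordinates are the per-axis means of the CIELab coordinates measured
at antipodal points on the adaxial (D) and abaxial (B) surfaces,

$$ qL^* = \tfrac{L^*_D + L^*_B}{2}, \quad
   qa^* = \tfrac{a^*_D + a^*_B}{2}, \quad
   qb^* = \tfrac{b^*_D + b^*_B}{2}, $$

with chroma $qC^* = \sqrt{qa^{*2} + qb^{*2}}$ and hue
$qh^\circ = \mathrm{atan2}(qb^*, qa^*)$ exactly as in CIELab. The CMQ is a
notional color, not a visible one; its value is that it associates cleanly
with whole-leaf pigment content where single-surface color does not. When
the two surfaces are identical, the CMQ coincides with the surface color.

Pigment content enters through two nondestructive transmittance-meter
indices, transformed to improve normality and put the two pigments on
comparable scales: SR-S $= \sqrt{\mathrm{SPAD}}$ for chlorophylls and
Lb-A $= \log_2 \mathrm{ACI}$ for anthocyanins, each averaged over the two
surfaces. Averaging is done in the transformed units — the scale on which
all downstream modeling operates; the measurement protocol does not fix the
order, and averaging after transformation keeps every quantity in the model
on one scale.

The predictor is a feed-forward network with two inputs, three hyperbolic-
tangent hidden units, and three linear outputs:

$$ H_j = \tanh\!\big[s\,(b_j + w_{j1}\,\mathrm{SRS} + w_{j2}\,\mathrm{LbA})\big],
   \qquad \hat y = B + W_\mathrm{out} H, $$

with pre-activation scale $s = 0.5$. The published coefficients
(`published_cmq_network()`) are stored exactly at their printed four-decimal
precision, with $s$ kept as an explicit field rather than folded into the
weights, so the object mirrors the printed equations bit-for-bit. The
worked predictions confirm that the inputs are raw SR-S/Lb-A values with no
internal standardization. Since $|\tanh| \le 1$, each output is confined to
bias $\pm \sum |$output weights$|$ (`output_bounds()`): quasi-lightness,
for instance, can never leave $[27.9, 125.8]$ no matter the inputs.

### Hue conventions

Hue is always computed with the quadrant-aware two-argument arctangent (a
one-argument $\arctan(b/a)$ is quadrant-ambiguous). Statistical work uses
the *wrapped* scale $(-180^\circ, 180^\circ]$, obtained by subtracting
$360^\circ$ from angles above $180^\circ$: leaf hues never fall in the
cyan–teal band near $180^\circ$, so wrapping makes them a contiguous
interval on which means are meaningful (the mean of $350^\circ$ and
$16^\circ$ is $3^\circ$, not $183^\circ$). Angles at exactly $180^\circ$
are kept unchanged (half-open convention; the point is unpopulated in
practice). Reported summaries convert back to the familiar
$[0^\circ, 360^\circ)$ scale, and tables emit both columns to prevent
convention mistakes downstream.

### Surface inference

Because the CMQ is a mean, one observed surface plus the pigment-predicted
CMQ determines the other surface exactly:
$\mathrm{hidden} = 2\,\widehat{\mathrm{CMQ}} - \mathrm{known}$. The
relation is symmetric in the surfaces and is an involution; the implied
midpoint of the known and inferred surfaces reproduces the predicted CMQ to
machine precision (an identity the test suite checks at $10^{-9}$).
Inferred lightness outside $[0, 100]$ is flagged, never silently clipped —
out-of-range estimates mean the observed surface and the pigment readings
are inconsistent under the model.

## Fitting networks

`fit_cmq_network()` minimizes squared error summed over the three
responses, each standardized to unit variance during optimization (so
$qL^*$, whose spread is several times that of $qa^*$, does not dominate)
and back-transformed afterwards. A ridge penalty on the hidden and output
weights (not the biases) stabilizes the fit; `penalty = "auto"` selects
from $\{0, 10^{-4}, 10^{-3}, 10^{-2}, 10^{-1}\}$ by validation likelihood
on an internal 80/20 split. Optimization is BFGS with an analytic gradient,
relative tolerance $10^{-8}$, and multiple seeded random restarts (default
10): tanh networks have permutation- and sign-symmetric optima plus genuine
local minima, and restarts are the practical defense. Initial weights are
drawn $N(0, 0.5^2)$; output biases start at zero (the standardized-response
mean). All randomness flows from one integer seed, so fits are exactly
reproducible. Fitting refuses sample counts at or below the free-parameter
count $6h + 3$.

Recovering weights is not a goal — only the prediction surface is
identified (hidden units can be permuted and sign-flipped); the test suite
accordingly checks surface recovery, not coefficient recovery.

### Model selection

`select_hidden_nodes()` scores candidate hidden-layer sizes by a summed
Gaussian negative log-likelihood (`cmq_nll()`): per response, the residual
variance is the plug-in mean squared residual (floored at `var_floor`,
default $10^{-8}$, to keep perfect fits finite), and the three per-response
log-likelihoods are added. Each repeat draws one random 9:1
training:validation split — the fold size of 10-fold CV, applied as
repeated single splits; a full rotation through all ten folds per repeat is
available via `method = "kfold"`. Validation NLLs are averaged over repeats
(default 20), and the selected size is the smallest whose mean lies within
one standard error of the minimum — a parsimony tie-break in the spirit of
the usual one-SE rule, needed because NLL differences between adequate
sizes are small relative to split-to-split variation. On data generated by
the published three-node network with realistic noise, this procedure
recovers three nodes as the modal choice over independent runs (an
acceptance-level test; a sweep over sizes 1–8 with 20 repeats takes under a
minute per run at $n = 480$ on one CPU).

One caveat: on exactly noiseless data the plug-in NLL is unbounded below
as residuals shrink, so the statistic ends up resolving optimizer noise
rather than fit quality and the one-SE rule degenerates; raising
`var_floor` to the measurement resolution (CIELab coordinates are read at
0.1 units, i.e. `var_floor = 0.01`) bounds the scale but cannot produce
exact ties. Selection is therefore meaningful only for data with
observation noise — which any measured dataset has.

### Parametric baselines

Three nested least-squares baselines (`fit_cmq_parametric()`, via `lm` per
response) provide the comparison standard: full factorial
$\{1, S, A, SA\}$, quadratic polynomial $\{1, S, A, S^2, A^2\}$, and
response surface $\{1, S, A, SA, S^2, A^2\}$ — the standard term sets for
these design families, chosen so both smaller sets nest inside the response
surface (the nesting shows up as a training-error ordering the tests
verify). `model_comparison()` tabulates $R^2$ and RMSE per coordinate on a
train/test split for all four models side by side;
`train_test_split(..., sizes = c(480, 124))` mirrors the 604-leaf reference
split exactly.

## Agreement metrics

Pearson's $r$ measures closeness to the best-fit line; Lin's concordance
$\rho_c = 2 s_{xy} / (s_x^2 + s_y^2 + (\bar x - \bar y)^2)$ additionally
penalizes departure from the identity line. The package uses Lin's original
population-moment (divide-by-$n$) estimator, so $|\rho_c| \le |r|$ with
equality exactly when means and variances match.

`variable_importance()` approximates the relative impact of the two inputs
per response as Monte-Carlo total-effect (Sobol-style, Jansen estimator)
sensitivity over independent uniform inputs on the calibrated ranges. This
is an explicit approximation of an unspecified reference procedure and is
intended for directionality, not exact percentages: it confirms that
anthocyanins dominate quasi-lightness, but the split it assigns for $qa^*$
(roughly 56% SR-S / 39% Lb-A) differs from reference values computed by
unknown means, so only the $qL^*$ direction is asserted in tests.

## Gamut mapping

`compute_gamut()` evaluates the network over a regular pigment grid
(defaults: SR-S $\in [0, 9.7]$, Lb-A $\in [0, 8.0]$, step 0.1 — the full
span over all tested species at a resolution where refining further changes
attainable ranges by less than the display precision). From the table,
`attainable_range()` reads the span of any coordinate with one pigment
fixed, and `hue_extremes()` averages hue (on the wrapped scale, then
converted back) over the single-pigment corners, defined as the outer 10%
of each axis. The model's structure shows up clearly: $qb^*$ at SR-S 5 can
range from about 0 to 45 depending on anthocyanins; peak chroma occurs only
where one pigment is nearly absent; the high/high corner is dark and dull.
The chlorophyll-only corner averages a green hue near $126^\circ$. The
anthocyanin-only corner averages $\approx 353^\circ$ — inside the
purple–red band, though about 13° above the $\sim$340° that has been read
off rendered figures of the same surface; the package reports what the
network actually predicts.

## Synthetic data

`simulate_leaf_data()` exists so that training, model selection, evaluation
and inference are fully testable without the original measurements. Its
defaults emulate the reference lettuce dataset's summary structure:

* **Pigments**: truncated normal marginals with the reported means (SR-S
  5.8 on $[0, 8.6]$; Lb-A 3.6 on $[0.1, 7.8]$) and sd = range/4 (the
  reported summaries give only ranges and means; range/4 puts ~95% of an
  untruncated normal inside the range). Independent by default — the real
  joint distribution is unreported — with a correlation knob for
  sensitivity studies.
* **True CMQ**: the published network's prediction (the generator's ground
  truth is the model family itself, which is what makes recovery tests
  interpretable).
* **Observation noise**: independent Gaussian per coordinate, sds
  1.81/1.23/1.71 — the published network's training RMSEs on the real
  data, so the synthetic signal-to-noise matches the real benchmark. Noise
  is added to the CMQ (the modeling target), not to each surface
  independently, matching the error structure the fitting assumes.
* **Surfaces**: placed at observed CMQ $\pm \tfrac{d}{2} u$ with direction
  $u$ uniform on the sphere in $(L, a, b)$ and $d$ exponential with mean
  10.3 — the reported mean surface-to-surface $\Delta E$, whose observed
  maximum (46.4, 4.5× the mean) implies a heavy right tail that the
  exponential reproduces. By construction the surface midpoint equals the
  observed CMQ exactly.

What the generator does *not* emulate: any dependence of asymmetry on leaf
color (red leaves plausibly more asymmetric), non-normal pigment
distributions (the real data's narrower truncated-normal tails cap the
synthetic $qL^*$ spread at roughly 28–75 versus the reported 25.5–86, so
synthetic $R^2$ ceilings for $qL^*$ run slightly below the real
benchmark's), correlated observation errors between coordinates, or
species effects. Passing recovery tests on this generator therefore shows
the estimation machinery works under the stated conditions; it does not
certify accuracy on real leaves outside them.

## Numerical choices and limitations

* Comparisons against printed reference values are made at the printed
  precision (one decimal; nearest degree for hue); internal computation is
  full double precision. Reference inputs printed at one decimal propagate
  to about $\pm 0.1$–0.2 in the outputs, which is the tolerance used where
  it applies.
* Hue is undefined at zero chroma; the corresponding entries are `NA`, and
  `hue_angle()` errors on $(0, 0)$ rather than returning an arbitrary
  angle.
* Pigment inputs outside the calibrated range (SR-S > 9.7, Lb-A outside
  $[0, 8]$) warn and proceed: the reference use of the model deliberately
  extrapolates (e.g. mondo grass lies outside the lettuce training range),
  so out-of-range inputs are legal but flagged.
* Problem sizes in the tests ($n = 604$ comparisons; three CV sweeps at
  $n = 480$, sizes 1–8, 20 repeats) were chosen to exercise the procedures
  at the reference dataset's scale while keeping the whole suite in a few
  minutes of CPU time.
* The exact reference values for the model-comparison table are not
  reproducible without the original raw measurements and their unrecorded
  random split; the package substitutes property-level checks (accuracy
  bounds, nesting order, architecture recovery) on synthetic data.
* Training supports only the single-hidden-layer tanh family with three
  linear outputs; no deeper architectures, classification, or conversion
  of meter indices to absolute pigment concentrations.
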