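---
title: "Models and methods behind optoflow"
author: "optoflow authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind optoflow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(optoflow)
```

optoflow quantifies light-controlled gene expression circuits from flow
cytometry. This vignette describes the models it fits, the measurement
conventions it encodes, the assumptions built into its synthetic-data
generators, and the numerical choices that make the pipeline
deterministic and testable.

## Measurement model

A cytometry sample is a table of events (forward scatter, side scatter,
fluorescence channels in arbitrary instrument units). Three processing
stages turn it into one number per sample:

**Density gating.** Cell populations are selected by keeping the fraction
of events (default 0.5) with the highest estimated density in the
(FSC, SSC) plane. We estimate density with a product-Gaussian kernel on
linear scatter values using the normal-reference bandwidth, evaluate it
on a 256×256 grid (`MASS::kde2d`) and interpolate bilinearly back to the
events. Exactly `round(fraction · n)` events are kept; ties at the
boundary break by ascending event index, so the count contract is exact
and the gate is a pure function of its input. The gridded estimate agrees
with the exact pairwise kernel density to well within the gate's
resolution (the suite checks ≥95% overlap of retained sets on small
samples, and ≥99% cluster purity against a uniform background).

**Bead calibration.** Rainbow calibration beads with known MEFL/MEAP
values are measured alongside each experiment. We find the modes of the
log10 channel histogram by kernel density, refine each mode to the median
of its assigned events (this restores sub-grid accuracy: noise-free peaks
are recovered exactly), pair modes with the assigned values in increasing
order, and fit `log10(MEFL) = a + b·log10(channel)` by least squares. The
mapping must be strictly increasing; finding fewer modes than assigned
values is an error that names the count found. An optional saturation
threshold excludes events within 1% of the instrument maximum. Tables
track a `raw → calibrated` state machine; calibrating twice is an error.

**Summarization and subtraction.** Cell fluorescence is the median of
gated, calibrated events (even counts: mean of the two middle values).
Reporter fluorescence subtracts the cell fluorescence of a reporter-free
control strain measured the same day; the manifest validator enforces the
same-day linkage before any computation. Subtraction can produce negative
values — these are resolved by the detection rule, never by flooring.

**Detection and comparison.** A replicate set is "detected" when a
one-sample, one-sided t-test against zero gives p < 0.05; otherwise it is
reported N.D. with its mean ± sd regardless. Zero-variance replicates
take the t-distribution limit (p → 0 for positive mean, else 1), flagged
as degenerate. Between-condition comparisons use Welch's
unequal-variances test with Welch–Satterthwaite degrees of freedom,
implemented from the defining formulas (and checked against
`stats::t.test` to 1e-10). Fold changes default to per-day ratios
summarized as mean ± sd, because replicates run on separate days pair
naturally; `ratio_of_means` with first-order error propagation is
available when pairing is not meaningful. Which of the two the ± on
published fold changes corresponds to is genuinely ambiguous; by-day is
our documented default, not a fact about any particular dataset.

## Steady-state transfer function

Output versus input dose follows the Hill form
$$y = y_0 + \Delta y \frac{x^n}{x^n + K_{1/2}^n},$$
with basal output $y_0$, span $\Delta y$, Hill coefficient $n$ and
half-maximum dose $K_{1/2}$. All replicate points are pooled and fitted
simultaneously by Levenberg–Marquardt (`minpack.lm::nls.lm`), minimizing
$\sum_i (\log y_i - \log \hat y_i)^2$. Log residuals are essential over a
dynamic range spanning decades: absolute residuals would let the
saturated branch dominate and ignore the basal branch entirely.

Numerical choices:

* Parameters are optimized as their logarithms, which enforces
  positivity without hard bounds and makes the optimizer scale-free; the
  Hill ratio itself is computed as `exp(n·(log x − log K))` to avoid
  overflow at extreme doses. Estimates are reported on the natural scale
  with delta-method standard errors from the damped-least-squares
  covariance approximation.
* Initial guesses are scale-free: `y0 = min(y)`, `dy = max(y) − min(y)`,
  `K` = geometric median of the positive doses, `n = 1`.
* Convergence tolerances are 1e-10 (relative objective reduction and
  parameter change), max 1024 iterations. The tight tolerance lets
  noise-free datasets be recovered to better than 1e-6 relative error in
  all four parameters, which the suite asserts.
* `x = 0` points participate (the model value there is `y0`);
  non-positive *y* values are an error instructing the caller to resolve
  them (e.g. drop N.D. conditions), never silently floored.
* Weighting is uniform across points, as the plain log-residual
  objective implies.

The fit is invariant to point order (pooled objective), and scaling all
outputs by a constant scales `y0`, `dy` and leaves `n`, `K` unchanged —
both are property-tested, and a dense 4-D grid search of the same
objective serves as an independent oracle for the optimizer's minimum.

## Step-response kinetics

The response to an instantaneous light switch is modeled as a linear
cascade with a transport delay:
$$\frac{dp}{dt} = k_p(c - p), \qquad
  \frac{dg}{dt} = k_g(p(t-\tau) - g), \qquad
  \frac{dG}{dt} = k_d(g - G),$$
with production rate $p$, immature reporter $g$, mature observed reporter
$G$, drive $c$ set by the light input, and delay $\tau$ before a change
in production takes effect. Units are normalized so that at steady state
$c = p = g = G$; the step starts from the $c_0$ steady state with
constant history $p(t) = c_0$ for $t \le 0$ and drive $c_1$ thereafter.
ON steps use $(c_0, c_1) = (y_0, y_0 + \Delta y)$ from the transfer
function fit; OFF steps the reverse.

**Closed form.** Because the pre-step system is at steady state, the
delayed stages see nothing until $\tau$ elapses: $g(t) = G(t) = c_0$ for
$t \le \tau$. For $t > \tau$, substituting $s = t - \tau$ reduces the
system to the non-delayed cascade, whose step response is the
partial-fraction sum of exponentials
$$G = c_1 + (c_0 - c_1)\sum_{i} e^{-k_i s} \prod_{j \ne i}
      \frac{k_j}{k_j - k_i}.$$
When any two rates agree to better than a relative gap of 1e-6 we switch
to a matrix-exponential evaluation of the shifted cascade, which is exact
in the confluent limit — no confluent case enumeration, no lost
precision. An independent numeric route (`deSolve::dede`, method of
steps) agrees with the closed form to < 1e-6 relative error over 100
random parameter draws, which is asserted at full scale in the suite.

**Identifiability.** The step response $G(t)$ from steady state is
symmetric under *any* permutation of $(k_p, k_g, k_d)$ — the cascade's
transfer function is $\prod_i k_i/(s+k_i)$, and the uniform shift by
$\tau$ hides which stage is delayed. Individual rate constants are
therefore not identifiable from $G$ alone. Fits report $k_g \le k_d$ as a
sorted pair with an explicit exchange-symmetry flag, and the quantity to
compare across fits is the half-time $t_{1/2}$ — the first crossing of
$(c_0+c_1)/2$ — which is permutation-invariant. Half-times are located by
bracketed root finding on the closed form (absolute tolerance 1e-6 min);
monotonicity of the step response makes the crossing unique.

**Fitting.** Same pooled log-residual Levenberg–Marquardt machinery as
the Hill fit; the model is evaluated exactly at the observed times via
the closed form, so there is no interpolation error. $\tau$ is
parameterized as $\log(\tau + 10^{-6})$ to keep it non-negative while
allowing effectively zero delay. Initial guesses derive from the observed
midpoint crossing: $\tau_0 = \max(0.15\,t_{50}, 1)$ min and rates
staggered around $\ln 2/(t_{50}-\tau_0)$ (staggering keeps the starting
point away from the confluent manifold). A boundary with
$c_0 = c_1$ is rejected up front with a flat-signal diagnostic.

## 5′ mRNA structure recoding

Poorly translated heterologous genes often fold a stable secondary
structure between the ribosome binding site and the early coding
sequence. The recoding heuristic replaces each of the first 15 codons by
the synonymous codon minimizing the scoring tuple (GC count ascending, A
count descending, T/U count descending, codon string ascending). The
tuple is a deterministic formalization of "reduce GC, increase AU, prefer
A over U": the preference statement alone is not a total order, and the
lexicographic reading (A preferred at otherwise-tied GC counts) is the
one we adopt and document. The start codon is never altered — GTG/TTG
starts are functional as initiators, not synonyms — the protein is always
preserved, stop codons can never be introduced (no sense codon is
synonymous with a stop), and ORFs shorter than 15 codons recode all
complete codons except a final stop. Recoding is idempotent.

Windows are scored from the transcription start site (+1) through ORF
nucleotide 90 (shorter ORFs truncate). The default folding backend is a
deliberately simple nested-pairing minimum-energy model — pair energies
GC −3, AU −2, GU −1 kcal/mol, minimum hairpin loop 3, no pseudoknots,
minimized by interval dynamic programming — which equals exhaustive
enumeration of nested structures on small windows (asserted against an
independently written recursion). It ranks pairing potential; it is *not*
a thermodynamic model: loop entropies, stacking and dangling ends are
absent, so its energies are comparable only with each other. For
thermodynamic energies the backend is pluggable: `"vienna"` calls
`RNAfold` when installed, and any `function(rna) -> energy` can be
supplied. Recoding reduces GC pairing potential but is not guaranteed to
raise the window energy for every sequence — the suite checks the
directional claim on a population of GC-rich ORFs (≥90%), not per
sequence.

## Synthetic data: what it emulates, and what it does not

The generators produce every input the pipeline consumes, with explicit
integer seeds (RNG state is saved and restored, never leaked) and known
ground truth:

* **Events** are lognormal around a target median — parameterized by
  median and CV, so `meanlog = log(median)`,
  `sdlog = sqrt(log(1+cv²))` — with autofluorescence added at the event
  level, matching the convention that reporter medians are defined after
  subtraction. Default event CV 0.35 is our assumption of a typical
  bacterial reporter distribution width; no acquisition-noise
  distribution is a measured fact here. Scatter is one elliptical
  Gaussian cluster plus an optional uniform background fraction.
* **Bead samples** place lognormal peaks at
  `offset + gain · value^exponent` in channel units and return the true
  mapping for round-trip tests.
* **Dose-response series** put each sample median at
  `Hill(truth, dose) × LogNormal(median = 1, cv)`. Median-1
  multiplicative noise is symmetric on the log scale the fit minimizes,
  so recovered parameters center on the truth; it also respects the
  decades-spanning dynamic range the way day-to-day spread does.
* **Step timecourses** evaluate the closed-form `G(t)` and apply the same
  multiplicative noise. The default kinetic truth
  (kp = 0.02, kg = 0.05, kd = 0.03 min⁻¹, τ = 15 min) was chosen once to
  put the half-time on the ~100 min scale typical of fluorescent-reporter
  optogenetic circuits; published work reports fitted half-times, not
  rate constants, so these are modeling choices, not literature values.

What the generators deliberately do not emulate: instrument-specific FCS
binary quirks, doublet/debris physics beyond the uniform background,
spectral spillover, growth dilution, or the biphasic dose-response shapes
that appear when high sensor expression depletes the chromophore pool.
Passing the recovery suite therefore demonstrates correctness of the
estimation machinery under the stated noise model — not robustness to
every artifact of real cytometry data.

## Validation scales

The test suite runs the recovery studies at the scales chosen for each
claim: 100 random parameter draws for the closed-form/integrator
equivalence (horizon 600 min); 20 noise-free Hill datasets for the
exact-fit limit (< 1e-6 relative); 50 seeded noisy dose-response datasets
(8 doses, 3 replicates, 10% CV) scoring the median fitted `n` and `K`
within 10%; 25 ON + 25 OFF kinetic experiments at 5% CV scoring median
half-times within 5%; 10,000 null trials for the 5% ± 1% type-I
calibration of the detection rule; and 1000 random ORFs for the recoding
invariants. End-to-end pipeline tests use smaller event counts
(1200–1500 events, 6 doses) since they exercise plumbing, not asymptotics.
`scripts/acceptance.R` re-runs the dose-response recovery study from
scratch at the full scale and writes the medians as JSON.

## Known limitations

* Individual kinetic rate constants are reported but not identifiable
  from `G(t)` alone (see above); only `t½` and the trajectory are.
* The built-in folding model is ordinal, not thermodynamic.
* The bead model assumes a log-log-linear channel mapping; a nonzero
  channel offset departs from it and is not fitted.
* Arbitrary time-varying light programs (ramps, sines) are out of scope;
  only steps between steady states are modeled.
* Mixed-light drives are supported only at the saturating endpoints
  (`c = y0` or `y0 + Δy`); mapping intermediate green intensities through
  the fitted Hill function is the documented extension point.
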