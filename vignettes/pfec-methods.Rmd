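---
title: "Methods: from polarized pulse trains to sample composition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from polarized pulse trains to sample composition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pfec)
```

This vignette is the package's own account of the science it implements:
the measurement model, the estimators, the synthetic data generator, the
numerical choices, and what the tests do and do not demonstrate about
real instrument data.

## Measurement model

A flow-through prototype measures one particle at a time. Backscattered
laser light is split into four polarization channels whose intensities
`(I1, I2, I3, I4)` jointly encode the Stokes vector of the scattered
light, plus a long-pass fluorescence channel `F`. A particle transit
produces a synchronized bell-like pulse on all five channels; the pulse
width is the transit time, the amplitudes carry the particle's optical
signature.

The Stokes vector is recovered per sample through the instrument matrix:

$$ S = (I, Q, U, V)^\top = A \,(I_1, I_2, I_3, I_4)^\top $$

with normalized components $q = Q/I$, $u = U/I$, $v = V/I$, each in
$[-1, 1]$, and degree of polarization
$\mathrm{DOP} = \sqrt{q^2 + u^2 + v^2} \in [0, 1]$ (0 unpolarized, 1
fully polarized).

## Calibration

`estimate_instrument_matrix()` solves

$$ \hat A = \arg\min_A \sum_k \lVert S^{(k)}_{\mathrm{ref}} - A\, m^{(k)} \rVert^2
        = S_{\mathrm{ref}} M^\top (M M^\top)^{-1}, $$

where the columns of $S_{\mathrm{ref}}$ are reference Stokes states (as
read by a reference polarimeter) and the columns of $M$ the measured
component vectors. With exactly four states this is the plain inverse
relation $\hat A = S_{\mathrm{ref}} M^{-1}$; with more states the
least-squares form reduces noise. At least four rank-spanning states are
required; the default state set starts from the canonical polarimetric
states (unpolarized, horizontal/vertical, ±45° linear, left/right
circular, one partially polarized state), which keep the design matrix
well conditioned.

Under the simulated calibration procedure used in the tests (8 states,
0.5 % multiplicative Gaussian channel noise, ground-truth matrices with
condition number below 50, 100 replicates) the median relative Frobenius
error of $\hat A$ is about 0.9 %, comfortably within the few-percent
calibration accuracy such analyzers are specified to.

Physicality handling after calibration: samples with recovered $I \le 0$
are flagged non-physical and dropped from traces; samples with
$Q^2+U^2+V^2 > I^2$ are projected back onto the physical ball and
counted in QC output. Both occur legitimately under noise and the
estimators should not silently propagate them.

## Pulse segmentation

The record's baseline and noise scale are estimated robustly (median and
MAD) on a trigger channel (`I1` by default, the channel most similar to
total intensity). Candidate pulses are contiguous runs above
`baseline + threshold_sigma × scale` (default 5), padded outward to the
nearest samples back at baseline level so the pulse flanks are retained,
merged across gaps shorter than `min_gap` (default 3 samples) and kept
when at least `min_width` (default 5) samples long. Coordinates are
0-based, half-open everywhere. Coincident particles are not
deconvolved — the instrument's scattering volume is designed for the
single-particle regime — and the simulator places pulses without overlap
unless its coincidence stress flag is set.

Each window is converted to a Stokes-domain trace by baseline
subtraction, application of $A$, and sample-wise normalization. Samples
whose recovered intensity falls below 10 % of the pulse peak
(`floor_frac`) are excluded from all four traces: dividing by a small
$I$ makes $q, u, v$ arbitrarily noisy, and the floor bounds the relative
error of the division. All four traces are restricted to the same
above-floor samples, so they stay aligned and equally long. The
per-pulse DOP is computed from intensity-weighted means of $q, u, v$
rather than from per-sample DOPs: one DOP is reported per particle, and
weighting suppresses exactly the low-intensity samples where the
normalized components are least reliable. `F` is the plain mean of the
fluorescence channel over the full window minus its baseline, matching
the convention of averaging the fluorescence pulse into a single value;
the fluorescence baseline is subtracted because the ambient/dark level
would otherwise bias low-fluorescence categories upward.

## Pulse features

Eight statistics are computed per trace $X$ with population ($1/N$)
moments, no Bessel correction:

| statistic | formula |
|---|---|
| peak-to-peak | $\max X - \min X$ |
| variance | $\tfrac1N \sum (X_i - \mu)^2$ |
| standard deviation | $\sqrt{\mathrm{var}}$ |
| RMS | $\sqrt{\tfrac1N \sum X_i^2}$ |
| skewness | $\tfrac1N \sum (X_i-\mu)^3 / \sigma^3$ |
| kurtosis | $\tfrac1N \sum (X_i-\mu)^4 / \sigma^4$ |
| waveform factor | $\mathrm{RMS}/\mu$ |
| clearance factor | $(\max X - \min X)/\mu^2$ |

The clearance factor is implemented exactly as the instrument's feature
table defines it — peak-to-peak over squared mean — although the
conventional clearance factor of vibration analysis divides by
$(\tfrac1N\sum\sqrt{|X_i|})^2$; the conventional form is available via
`pulse_statistics(x, clearance = "conventional")`, but the verbatim form
is the default and the tested one. Note the formula is not
dimensionless: it scales as 1/amplitude, which is deliberate here.

Degenerate traces (constant, or zero-mean) yield undefined statistics;
these are imputed with their defined limits — skewness 0, kurtosis 3
(the Gaussian reference value), waveform factor 1, clearance factor 0 —
and counted in a `qc_imputed` column, because the downstream classifier
requires finite inputs.

The 38-dimensional feature vector is the six averages
$(\bar I, \bar q, \bar u, \bar v, \mathrm{DOP}, F)$ plus the eight
statistics of each of the four *Stokes-domain* traces $I, q, u, v$ (not
the raw channels): the instrument's own diagnostic plots present
$I_{\mathrm{var}}, q_{\mathrm{var}}, u_{\mathrm{sk}}, v_{\mathrm{ku}}$
and so on in the Stokes domain, so that is taken as the intended
construction. The averages are plain means of the traces. Column order
is fixed and documented by `feature_names()`.

### What amplitude statistics can and cannot see

All eight statistics are moments of the *sample values* of a trace — the
amplitude-occupation distribution — not moments of time. Two
consequences matter and are asserted as properties in the test suite:

* they are exactly invariant under time reversal of the pulse, so the
  skewness of a trace does **not** measure the left/right asymmetry of
  the transit envelope (a symmetric Gaussian bell has value-skewness
  ≈ +0.15, not 0, once windowed at 5 % of peak);
* they respond strongly to the envelope's *flatness*: a flat-topped
  transit spends most samples near the peak (negative value-skewness,
  waveform factor near 1), a cusp-like transit spends most samples low
  (positive skewness, large waveform and clearance factors).

This is why the simulator's envelope family includes a flatness
parameter (below), and why the pulse-shape-vs-average comparison panels
are built from flatness contrasts rather than asymmetry contrasts.

## The synthetic instrument simulator

The simulator is a forward model of the measurement, not of the optics:
archetypes are phenomenological. A `species_archetype` specifies the
mean Stokes response $(I_{\mathrm{scale}}, q, u, v)$, particle-to-particle
dispersions, transit-envelope parameters, and a fluorescence level
relative to scattered intensity.

The transit envelope is an asymmetric generalized-Gaussian bell
$\exp(-|t/s_\pm|^\beta)$ with side-dependent scales (asymmetry =
log-ratio of trailing to leading scale) and flatness exponent $\beta$
($\beta = 2$ Gaussian bell, large $\beta$ flat-top, $\beta < 1$ cusp),
sampled over the support above 5 % of peak. Real transits are bell-like
but not a fixed functional form; this family spans plateau-like transits
of large cells through spike-like transits of small ones, and — per the
previous section — flatness is the single envelope parameter the printed
features can actually resolve, which makes it the right axis of
pulse-shape diversity for a generator whose purpose is to exercise those
features.

Per particle, the amplitude is drawn log-normally, $(q,u,v)$ normally
(clipped back to the physical ball $q^2+u^2+v^2 \le 1$, so the
noise-free DOP never exceeds 1), and the channel-space pulse is obtained
through $A_{\mathrm{true}}^{-1}$ — deliberately, so the calibration
pathway is exercised end to end. Noise is multiplicative log-normal
(relative detector-gain noise keeps intensities positive); calibration
sets use multiplicative Gaussian noise $(1 + \varepsilon)$ as that is
the convention of the calibration error analysis. Streams draw particle
counts from a Poisson law, categories from a mixture vector, and place
pulses uniformly without overlap (expected occupancy must stay below 1;
a coincidence flag exists as a stress condition). All randomness flows
through explicit seeds via a local RNG, so identical seeds give
bit-identical output and callers' RNG streams are untouched.

The default `demo_panel()` emulates four categories — two microalgal
phyla, one cyanobacteria category with high fluorescence, one non-algal
suspended-particulate category with low fluorescence — with illustrative
parameter values. The instrument's sampling rate, pulse-duration
statistics and SNR are not published quantities; the defaults (widths of
40-90 samples, 2 % channel noise, baseline 5 % of a typical amplitude)
are exposed as configuration and must not be read as measured values.

`shape_contrast_panel()` is the construction behind the
pulse-feature-vs-average comparison: categories share identical mean
Stokes components, DOP and fluorescence, and their peak amplitudes are
rescaled by each envelope's form factor so the mean in-pulse intensity
matches too — the six averages then carry essentially no class
information by design, while flatness contrasts (default
$\beta \in \{8, 2, 0.8\}$) separate the amplitude-distribution
statistics cleanly. On this panel the averages-only classifier performs
at chance while the 38-feature classifier exceeds it by tens of accuracy
points; with the roles reversed (classes differing only in $\bar q$),
the two perform equivalently. Both directions are asserted in the tests.

## Classifier

The reference architecture is retained: five hidden layers of
64, 128, 256, 128, 64 neurons. The source description stops at the
architecture and split, so the remaining choices are standard small-MLP
practice, all exposed in `mlp_config()`: ReLU activations, softmax
cross-entropy, Adam (learning rate $10^{-3}$), minibatch 64, at most 300
epochs with early stopping on validation loss (patience 20). Features
are z-scored with training-split statistics only — intensities and
bounded ratios differ by orders of magnitude and unscaled training does
not converge reliably. Splits are stratified 60/20/20 with exact
per-class quotas (largest-remainder rounding) and seeded permutation;
argmax ties break to the lowest class index for determinism. The
network is implemented in the package in base-R matrix code (no
multi-hidden-layer network implementation exists among the package's
dependencies); its gradients are verified against finite differences in
the test suite, and training is bit-reproducible under fixed seeds.
Classes are assumed approximately balanced, as in the reference
database design; imbalanced use should downsample or reweight upstream.

Evaluation follows the confusion-matrix conventions: rows actual,
columns predicted, overall accuracy = trace/total, per-class
one-vs-rest TP/FN/FP/TN exposed. Reported accuracies are always
test-set accuracies.

## Composition, dominance, correlation

Per-particle predictions aggregate to per-sample counts and proportions
in a fixed category order. Removing the non-algal category and
renormalizing the three phyla preserves their ratios and is idempotent.
Dominance labels over the microalgae + cyanobacteria pool use the field
thresholds with the boundary convention taken from their wording —
"exceeds 10 %" is strict, so exactly 10 % is *common*, and the
"1 % to 10 %" range is inclusive at both ends. Pearson's $r$ is
computed with population moments (the ratio is identical under either
moment convention, which the tests cross-check against `stats::cor`).
No retrieval of absolute cell density from proportions is attempted;
only the correlation arithmetic is provided.

## Numerical choices and problem sizes

* intensity floor 10 % of pulse peak; envelope support cut at 5 % of
  peak; detection threshold 5 robust SDs, minimum width 5 samples,
  minimum gap 3;
* DOP clipping tolerance $10^{-6}$; singularity guard `rcond` $< 10^{-12}$;
  standardization floor $10^{-8}$ on feature SDs;
* statistics use population moments throughout; feature-oracle agreement
  is asserted to $10^{-10}$ relative on 1000 random vectors of moderate
  dynamic range (at mean/SD ratios above $\sim 10^4$ the third central
  moment itself loses that many digits to cancellation in double
  precision, for any implementation);
* test and acceptance problem sizes, chosen as the smallest that leave
  the stochastic assertions with comfortable margins: streams of
  $0.5$–$1.5 \times 10^5$ samples (a few hundred particles), 100
  calibration replicates, 300 particles per class and 120 epochs for the
  pulse-shape comparison, $n = 5000$ particles for composition
  recovery.

## Limitations

The simulator emulates Poisson arrivals, bell-shaped transits,
species-dependent Stokes responses and relative detector noise. It does
not emulate optical physics (no Mie/Mueller scattering from cell
geometry), flow-rate drift, fluorescence bleed-through, detector
saturation, correlated baseline drift, or the within-phylum biological
variability of real assemblages. Passing tests therefore demonstrate
the correctness of the estimators and the internal consistency of the
pipeline — not field-level classification accuracy, which depends on
instrument data that is not redistributable. The headline accuracies of
the reference study are consequently not asserted anywhere in this
package; the qualitative structure (pulse features outperforming pulse
averages when shape information is present) is.
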