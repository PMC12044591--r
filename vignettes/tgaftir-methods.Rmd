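---
title: "Methods: identifying and quantifying plastics from TGA-FTIR evolved-gas data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: identifying and quantifying plastics from TGA-FTIR evolved-gas data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The measurement and its model

A TGA-FTIR run heats a milligram-scale sample at a constant rate (default
10 °C/min) while an FTIR spectrometer continuously measures the infrared
absorbance of the evolved pyrolysis gases carried through a heated
transfer line. The data bundle per run is: a thermogravimetric curve TG(T)
(mass remaining, %), its negative derivative DTG(T) = −dTG/dT (stored as a
positive loss rate, %/°C), a Gram–Schmidt trace of total infrared
intensity, and a few hundred spectra S(T, ν̃) on a common wavenumber grid.
Polymers appear in this data twice over: as DTG peaks at characteristic
decomposition temperatures, and as characteristic gas-phase band patterns.
Everything in this package exploits that joint signature.

Two instrument artefacts are handled up front. First, the gas evolved at
furnace temperature T reaches the gas cell only after the transfer-line
dwell time, during which the furnace advances by
`dwell_time_s × heating_rate / 60` degrees (0.42 °C at the defaults); the
recorded FTIR temperatures are reduced by exactly that product. The TG
temperatures are left untouched — the mass reading is instantaneous — which
resolves an ambiguity the underlying protocol leaves open. Second, the
CO₂ (2200–2400 cm⁻¹) and OH (3150–3500 cm⁻¹) windows are excluded rather
than corrected: atmospheric leakage makes them uninformative, and the mask
is enforced everywhere (correlation, feature selection, training,
MCR). Because derivative filters have finite support, masked gaps are
bridged by linear interpolation *before* differentiation; without this,
values inside a masked window would leak into the derivatives of
neighbouring unmasked points and violate the exclusion guarantee (the test
suite checks bit-identical results under masked-region perturbation).

## Preprocessing choices

* **Baseline.** Adaptive smoothness penalised least squares (asPLS): a
  Whittaker smoother with logistic residual weights and a per-point
  smoothness relaxation under peaks. Defaults: λ = 10⁶, ≤ 50 iterations.
  The literature leaves the convergence criterion unspecified; we declare
  convergence when the baseline moves by less than `baseline_tol` (1%) of
  the spectrum's dynamic range per iteration, damp the weight updates by
  one half, and freeze the adaptive smoothness vector after five
  iterations. The plain update rule provably never settles on noise-only
  spectra (the baseline random-walks at ~0.3% of the noise range forever),
  which would turn every blank-region spectrum into a warning; the damped,
  frozen variant converges there while leaving peak heights intact (the
  suite asserts ≤ 2% peak-height error on a Gaussian-on-ramp oracle).
* **SNV** uses the population (n) standard deviation over unmasked points;
  masked points are zeroed. SNV is applied at matching/training time, not
  during preprocessing, since Pearson correlation is affine-invariant
  anyway (also a tested property).
* **DTG** is computed by central differences and smoothed with a
  Savitzky–Golay filter (window 11, order 2).
* The pipeline order is fixed: mask → crop to 800–4000 cm⁻¹ → temperature
  offset → crop to 150–750 °C → baseline → TG alignment → Gram–Schmidt.
  The Gram–Schmidt trace is implemented as the root-sum-square of the
  baseline-corrected unmasked absorbance; with blank-corrected spectra
  this is equivalent in effect to the classical orthogonalisation against
  pre-run background interferograms, which are not available in tabular
  exports.

## Spectral matching

The hit quality of a data spectrum against one reference spectrum is

r_final = (r₀ + r₁)/2 · exp(−ΔT²/2σ²)

with r₀ the Pearson correlation of the SNV spectra, r₁ that of their
Savitzky–Golay first derivatives, and ΔT the temperature difference to
*that* reference spectrum (each reference carries its own temperature; the
penalty is per spectrum, not per library entry). The printed form of the
penalty in the source protocol is not machine-readable; the Gaussian form
above (σ = 50 °C) is our reconstruction, and a linear variant
max(0, r − k·|ΔT|) is selectable by configuration — both are single-point,
difference-based, reduce r monotonically in |ΔT| and leave r untouched at
ΔT = 0, which is the stated contract. Penalisation is applied after the
r₀/r₁ averaging ("penalise last"), matching the description of the penalty
as an adjustment of r.

The derivative filter for r₁ uses a 7-point window (not the 11-point DTG
default): on a 4 cm⁻¹ grid, a 44 cm⁻¹ window flattens exactly the narrow
fingerprint bands whose derivatives make near-collinear spectra (the
classic PE/PP pair, raw r > 0.9) separable, defeating the purpose of the
r₁ term.

Matching a spectrum scores it against every reference; if the best
penalised score exceeds the threshold (0.7), the accepted reference is
scaled by a non-negative least-squares coefficient, subtracted in SNV
space, and the residual re-matched. Already-accepted classes are excluded
from later iterations, which — together with the strictly decreasing
residual norm — guarantees termination within `max_components` (default 4,
the evaluation's mixture ceiling). Ties in r_final break toward the
smaller |ΔT|, then library order.

## Machine-learning pipeline

Training data are the library's region-of-interest (ROI) spectra
(positives for their class), plus out-of-ROI spectra and blank-run spectra
as negatives. One labelling subtlety matters in practice: spectra just
outside a nominal ROI still contain real decomposition signal (peak
tails), and SNV rescales even weak signal to full variance, so labelling
them "negative" teaches every classifier systematic false positives.
Same-run negatives are therefore drawn only outside the ROI inflated by a
factor (`negative_roi_buffer`, default 2), i.e. from genuinely signal-free
regions — blanks are unaffected.

The split is 75/25 at the *sample* level, stratified by class, which is
stricter than a spectrum-level split (spectra of one run are strongly
dependent); classes represented by a single sample fall back to a
spectrum-level split, since grouping is impossible there. EMSA
augmentation (below) is applied to the training portion only. Features are
the 200 unmasked wavenumbers with the largest one-way ANOVA F statistic
across class groups, plus the spectrum temperature. The "second scaling
pass" is per-feature standardisation with training-set statistics stored
in the model (temperature scaled jointly); re-applying literal
per-spectrum SNV after appending a 150–750-valued temperature feature
would crush all spectral information, and the feature-spec contract
("per-feature statistics") points to column scaling.

**EMSA** perturbs source spectra as `a + b·x + c·l + d·l² + ε` with
l the wavenumber axis rescaled to [−1, 1]: multiplicative factor
b ∈ [0.9, 1.1], offset |a| ≤ 0.02, polynomial wobble ≤ 2% of the signal
range, noise SD 0.5% of the maximum, ±2 °C temperature jitter. The
published ranges are not printed anywhere, so these are documented,
configurable defaults; the suite verifies that augmentation never costs
more than 0.02 of held-out macro F1.

Four model kinds are supported — kNN, single-hidden-layer MLP, random
forest, linear squared-hinge SVC — each as one-vs-rest binary classifiers
with probabilistic outputs (neighbour vote fractions, sigmoid output
units, tree vote fractions, Platt-scaled decision values respectively).
No classifier library ships with the target runtime, so these are
implemented in-package with plain matrix algebra; grids are small,
documented defaults (the published tuned values are unavailable) and
3-fold grid-search CV maximises multilabel macro F1. The probability
threshold for a positive label defaults to 0.5 — the protocol states that
a threshold exists but never prints it — and is recorded in the model.

## The synthetic world, and what a green test proves

The fixture generator defines twelve parametric pseudo-polymers: Gaussian
band sets (centre, width, intensity) and Gaussian DTG decomposition events
(T_max, width, mass share, plus a residual char fraction). The defaults
encode the features that make the real problem hard at its stated
difficulty: PE and PP share the dominant aliphatic CH-stretch doublet
(raw Pearson > 0.9 at their decomposition peaks — the suite asserts this)
and differ only in narrow fingerprint bands and an ~30 °C peak offset;
PMMA, PVC, PUR and CEL have multiple decomposition events; PET carries a
strong but non-distinctive carbonyl band; band amplitudes are modulated by
the DTG envelope so spectra fade into noise between events. Runs are
simulated over 40–1000 °C with one spectrum per 2.4 °C, reproducing the
~250 spectra per 150–750 °C analysis window of the instrument protocol;
noise SD is 0.005 of a unit peak band, with a gentle per-spectrum baseline
and a CO₂-window artefact to exercise masking. Coarser spacings (6 °C in
the benchmark criterion, 12 °C in module tests) are used purely for
runtime and are flagged as such.

Mixtures are exact fraction-weighted sums of component runs (flat
Dirichlet fractions, 2–4 distinct classes, classes sampled uniformly),
with the overall absorbance rescaled by a global log-uniform factor in
[0.5, 2] — mass bookkeeping (TG) is never rescaled, and conservation is
asserted to 1e-9. What the generator does *not* emulate: the
decomposition-temperature shifts real mixtures sometimes show (available
as an off-by-default ±10 °C flag), matrix interferences, weathering, and
instrument drift. A green benchmark on this world therefore establishes
the correctness and internal consistency of the pipeline at a realistic
separability level — not instrument-grade performance on environmental
samples.

On a seeded 100-mixture world the thermogram-level results mirror the
qualitative structure of the published comparison: the SVC is maximally
precise but loses recall on minor components, the SMA trades a little
precision headroom for the best recall, and both clear macro F1 0.9 /
Hamming accuracy 0.8 (the acceptance criterion). The count of unique
class combinations is reported, not asserted: whether the published
"unique combinations" counts class sets or fraction bins is unknowable
from the text, so we count class sets.

## Quantification

Consecutive spectra with identical positive-label sets form segments;
empty-label spans are "unassigned". Each temperature point carries its
trapezoidal integration weight times the DTG value, so assigned +
unassigned mass loss equals the total window loss exactly (asserted to
1e-6). Mixed segments are apportioned by MCR-ALS with non-negativity on
both factors, initialised from unit-norm library mean spectra of the
candidate classes. Plain ALS is rotationally ambiguous and drifts under
noise, so updated component spectra are accepted only while they stay
correlated (r ≥ 0.95) with their library initialisation — an equality-style
constraint that is natural here because the references are known. Segment
mass is split by the DTG-weighted mean of the per-spectrum contribution
fractions (the per-temperature weighting is our resolution of an
unspecified averaging step). Residual char mass is deliberately *not*
corrected for, mirroring the protocol's own stated limitation; on fixture
archetypes with residual mass the recovered composition estimates
f·v/Σf·v (v = volatile fraction), not f, and the tests' oracles account
for that.

## Numerical and degenerate-input policy

Constant spectra fail SNV and Pearson with explicit errors; libraries with
unknown class labels or missing bundle keys fail schema validation naming
the offence; a class with fewer than three spectra refuses to train; grid
mismatches between a model and a run suggest resampling; MCR
non-convergence warns and falls back to the last iterate (equal split only
when concentrations degenerate). All stochastic stages take explicit
seeds; training, augmentation, splitting and mixture generation are
bit-reproducible under a fixed seed (tested), including the CLI demo
pipeline whose artifacts embed the package version, seed and a hash of
the resolved configuration.

## Known limitations

* The Gaussian temperature penalty is a reconstruction of an illegible
  printed formula; both shipped forms satisfy the described behaviour, but
  neither is guaranteed to be the original.
* The classifiers are minimal reference implementations; they reproduce
  the behaviour class of the originals (probabilistic one-vs-rest
  outputs), not any specific tuned instance.
* Composition estimates inherit the protocol's own caveats: no residual
  mass correction, and MCR spectral contributions are used as mass-fraction
  proxies within mixed segments.
* Vendor binary formats are out of scope; use tabular exports (CSV
  matrix or JCAMP-DX).
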