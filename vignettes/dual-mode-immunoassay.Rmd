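---
title: "Dual-mode vertical-flow immunoassay quantification: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual-mode vertical-flow immunoassay quantification: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dualvfa)
```

# The measurement problem

A multiplexed vertical-flow immunoassay cartridge carries a sensing membrane
with 16 reaction spots: four for cardiac troponin I (cTnI), three each for
CK-MB and NT-proBNP, two positive controls (anti-IgG, a universal signal) and
four negative controls (buffer only). One cartridge is imaged in two optical
modalities: a colorimetric image under green illumination (gold-nanoparticle
absorption, read from the green channel) and a chemiluminescent (CL) image in
darkness (luminol/HRP emission, read from the blue channel). The CL channel
reaches sub-pg/mL cTnI but saturates at high concentration; the colorimetric
channel covers the upper decades. Together the two modalities span roughly
six orders of magnitude of cTnI.

`dualvfa` implements the computational path from membrane images to reported
concentrations: spot segmentation and background-normalised absorption
signals, a 3σ digital quality-control step on the control spots, power-law
and four-parameter-logistic calibration with limit-of-blank/limit-of-detection
estimation, and a cascaded pair of shallow neural networks per biomarker
(range classifier followed by range-specific quantifier) with an
agreement-based "undetermined" label. Because the underlying clinical dataset
is not public, the package ships a synthetic-data generator that reproduces
the statistical structure of such a study, so that every stage is testable
end to end.

# Signal model

For spot repeat $j$ of condition $i$ in modality $m$, with post-assay mean
ROI intensity $s$ and pre-assay background intensity $b$, the absorption
signal is

$$X_m^{i,j} = 1 - s_m^{i,j} / b_m^{i,j},$$

and alike spots are averaged per condition, giving the ten-element feature
vector $\bar X_m^i$ (5 conditions × 2 modalities). Negative values of $X$
(spot brighter than background) are retained, not clipped: the QC rule and
the classifiers are meant to see the raw distribution. Extraction is *not*
invariant to adding a constant to both images — the definition is a ratio —
and the tests assert the exact definition rather than a shift invariance
that does not hold.

Spot locations are found by rigid integer-pixel registration of the known
wax layout against the image (the geometry is fixed by fabrication; blob
detection fails at low signal). Measurement ROIs use 0.7× the printed spot
radius to avoid wax-edge pixels; ROI means are unweighted with no outlier
rejection. Images use 0-based pixel coordinates, origin top-left. If an
image shows no spot contrast at all, registration falls back to the nominal
grid with a warning; a best shift on the search boundary is treated as a
segmentation failure.

# The synthetic generator and what it emulates

The generator is first-class, tested code. Its defaults encode the study
conditions the package is validated under:

* **Forward models.** Signal = $a\,c^k$ per supported channel, with the
  published calibration constants: CK-MB colorimetric
  $0.0002\,c^{0.6901}$, NT-proBNP colorimetric $0.0001\,c^{0.6752}$, cTnI
  CL $0.0742\,c^{0.2744}$ and cTnI colorimetric $0.0179\,c^{0.2739}$
  (concentrations in pg/mL).
* **CL saturation.** The cTnI CL channel follows the power law exactly up
  to an onset of $10^4$ pg/mL, then approaches a plateau (default 0.95
  absorption) exponentially in $\log c$, with the decay rate fixed by slope
  continuity at the onset. This C1 construction keeps the pre-saturation
  curve exactly the printed model — a plain Hill curve with the printed
  exponent would bend visibly below the onset — and makes signals at
  $10^5$ and $10^6$ pg/mL differ by far less than 5% of the plateau.
* **Replicate noise.** Multiplicative lognormal per spot. The
  `replicate_cv` parameter (4.5% cTnI, 3.0% CK-MB, 1.5% NT-proBNP) is
  defined on the scale assay precision is conventionally reported: the
  *expected sample CV of triplicates*. A sample SD of $n$ draws
  underestimates the underlying dispersion by the factor
  $c_4(n) = \sqrt{2/(n-1)}\,\Gamma(n/2)/\Gamma((n-1)/2)$ ($c_4(3) \approx
  0.8862$), so the generator uses lognormal dispersion
  $\sigma = \mathrm{cv}/c_4(3)$. Consequently triplicate experiments
  reproduce the configured CV in expectation, while the large-sample
  dispersion is larger by $1/c_4(3)$; the property tests assert exactly
  this designed relationship.
* **Matrix effects.** One lognormal factor per cartridge multiplying all
  test and positive-control spots, emulating serum-composition differences.
  No matrix SD is published directly, but the duplicate-cartridge precision
  of quantification is (CVs of 8.6% for CK-MB and 7.9% for cTnI), and that
  pins the cartridge-level noise scale. The default (7%) is back-calculated
  from the CK-MB value: a duplicate concentration CV of 8.6% corresponds to
  an underlying per-cartridge dispersion of $8.6/c_4(2) \approx 10.8\%$,
  i.e. $10.8 \times 0.69 \approx 7.4\%$ in signal units, of which the
  3-spot replicate average contributes 1.96%, leaving
  $\sqrt{7.4^2 - 1.96^2} \approx 7\%$ for the shared cartridge factor. A
  smaller factor understates the inter-cartridge variability that motivates
  multivariate correction in the first place.
* **Cohort.** Per-biomarker concentrations are log-uniform over
  clinically-spanning ranges (cTnI 4–21 000, CK-MB 50–20 000, NT-proBNP
  10–30 000 pg/mL), with expected fractions 20/92, 58/92 and 33/92 of
  patients below the reference-assay reporting limits (4, 50, 10 pg/mL);
  censored patients draw a true value below the limit. Each patient yields
  two duplicate cartridges sharing concentrations.
* **Calibration grids.** The spiked concentrations are not published;
  defaults are 8 log-spaced CK-MB points over 500–10^5, 8 NT-proBNP points
  over 40–4·10^4, and 10 cTnI points over 1–10^6 pg/mL, spanning the
  quoted 2/3/~6 orders of magnitude.
* **Controls and blanks.** Positive controls sit at a configurable constant
  absorption (default 0.5) with a 3% CV convention matching the replicate
  noise; negative controls and zero-analyte spots sit at a blank baseline
  (mean 0.01, additive SD 0.003, so negative absorptions occur). The true
  control intensity scale is not published; these are declared defaults.
* **Rendering.** Optionally, cartridges are rendered as pre/post image
  pairs: uniform background (0.85) plus Gaussian pixel noise (SD 0.005),
  with each spot's ROI darkened to $b(1-X)$ in the modality's channel.
  Round-tripping render → extract recovers the programmed signals within
  pixel-noise tolerance, which is the oracle the extraction tests use.

For conc = 0 the forward model returns the blank baseline; for conc > 0 it
returns the pure power term without an additive blank. The jump at zero is a
deliberate simplification so that noise-free calibration grids re-fit the
printed models exactly; at the lowest grid concentrations the power term is
already comparable to the blank, so the discontinuity is small.

What the generator does **not** emulate: optical physics of the reader,
spatial flow non-uniformity within a membrane, spot-shape irregularities,
cross-reactivity chemistry, drift between batches, and any real-serum
deviation from an exact power-law mean response. Tests passing on this
generator therefore validate the pipeline's mechanics and statistical
behaviour under the declared noise model — not clinical performance.

# Quality control

Per control channel (positive/negative × colorimetric/CL) a reference mean
and sample SD (n−1) are fit over the batch; a cartridge fails if any channel
leaves the closed interval mean ± 3σ. The interval is closed so boundary
points cannot flip on float rounding; channels with σ = 0 fail on any
deviation and pass on exact equality. The reference includes the cartridge
under test by default (batch statistics); a leave-one-out mode is available.
Under Gaussian controls the per-cartridge false-exclusion probability is
$1 - (1 - 2\Phi(-3))^4 \approx 1.08\%$, which the Monte-Carlo tests verify.

# Calibration, LoB/LoD, CV

Power models are fit by linear least squares of $\log_{10}$ signal on
$\log_{10}$ concentration (convex, reproducible; the headline $R^2$ is on
that scale). The 4-PL $y = D + (A-D)/(1+(x/C)^B)$ is fit by
Levenberg–Marquardt with multi-start initialisation — a quantile grid on
$C$, a logit-linearised slope estimate in both signs, and a start derived
from the power fit itself, which guarantees the sigmoid never scores worse
than the power model on the same points. Inversion is closed-form in both
families; 4-PL inversion is restricted to the open interval between the
asymptotes.

The limit of blank is mean + 1.645 SD of the blank *signals*, converted to
concentration through the calibration curve; the limit of detection adds
1.645 × the SD of the lowest-concentration replicates *after* inverting each
replicate signal to concentration units. Both terms live in concentration
space before combining — the published wording mixes domains, and since
concentrations are explicitly derived from the calibration curves, the
concentration-domain reading is implemented. CV is 100·SD/mean with the
sample SD. The published detection limits themselves (409, 40, 0.12 pg/mL)
depend on unpublished replicate data and are out of scope; the formulas and
their monotonicity properties are what the package guarantees.

# The cascade

Each biomarker has a shallow fully-connected classifier that assigns a
concentration range — CK-MB <500 / ≥500, NT-proBNP <125 / ≥125, cTnI <40 /
40–1000 / >1000 pg/mL — and one quantifier per range. CK-MB <500 and
NT-proBNP <125 are reported *negative* without quantification (those ranges
sit well below the 5000 and at the 125 pg/mL clinical cut-offs); cTnI is
always quantified because all its thresholds exceed the clinical decision
range, so negativity is left to clinical judgement. A quantified value more
than 5% outside its assigned range boundary (relative to the boundary value;
bounds at 0 or ∞ cannot be violated) is labelled *undetermined* and the
concentration withheld. Ground-truth classes use closed lower bounds
(conc ≥ 500 is "≥500"; 40 ≤ conc ≤ 1000 is the middle cTnI class).

Architectures and regimen: classifiers use hidden layers (128, 64, 32) for
CK-MB, (64, 32) for NT-proBNP, (128, 64) for cTnI, batch normalisation with
batch size 4, ReLU, dropout 0.6/0.4/0.4, categorical cross-entropy, Adam at
initial learning rates 1e-3/1e-2/3e-3 attenuated ×0.99 every 10 epochs, L2
α = 1e-3. Quantifiers use (128, 64) (cTnI) or (128, 32) (CK-MB, NT-proBNP),
dropout 0.1/0.3/0.4, batch size 20, Adam at 1e-3 halved every 50 epochs;
MSE for CK-MB and cTnI, and for NT-proBNP the log-domain loss as printed in
its source description — whose per-sample root cancels the square, making it
the mean absolute log1p error (natural log) rather than conventional RMSLE;
the conventional batch-level form is available behind a flag in
`rmsle_loss()`. Inputs are standardised to zero mean/unit variance with
statistics frozen from each model's training subset. Targets are scaled by
1/500 (CK-MB), 1/125 (NT-proBNP) or z-scored (cTnI). Quantifiers stop early
when the training loss fails to improve by 1e-4 over 200 consecutive epochs
(cap 5000); classifiers, whose stopping rule is not published, train for a
fixed 2000-epoch budget. Both return the checkpoint with the lowest training
loss. Samples censored below a reporting limit join classifier training in
the lowest class but are excluded from quantifier training.

Numerical choices worth recording:

* **Output-layer initialisation.** With targets scaled to magnitudes of
  ~40–240, Adam's per-parameter step is bounded by the learning rate, and
  under the halving schedule the total parameter movement is ~0.2 — a
  unit-scale initial output layer can never reach the target range, and
  training demonstrably stalls far from the data. The output layer is
  therefore initialised at the location/scale of the transformed training
  targets: mean/SD for the MSE models, and the geometric centre
  $\exp(\overline{\log(1+y)})-1$ for the log-domain NT-proBNP loss, whose
  gradients are damped by $1/(1+y')$ and need a log-space-sensible start.
  Hidden layers keep the standard uniform fan-in scheme. This is the
  package's own design choice where the published description is silent
  and the naive reading is unworkable.
* **Minibatching.** Classifiers drop a final partial batch (batch-norm
  statistics are undefined on tiny remainders); quantifiers keep it.
* **Batch norm at inference** uses running statistics (momentum 0.1),
  the usual resolution of a batch-size-4 training rule applied to single
  cartridges.
* **Cross-entropy** clips probabilities at 1e-12; its printed source form
  contains an obvious typo (the model's probability must appear inside the
  log) and the standard definition is implemented.
* **Determinism.** All randomness (init, shuffling, dropout) flows from one
  integer seed through a dedicated Mersenne-Twister in the compiled core;
  two runs with one seed produce identical loss traces and weights.

Default feature subsets are the full condition sets (the 5 colorimetric
conditions for CK-MB/NT-proBNP models; the 6 dual-mode cTnI conditions).
Published per-model optimal subsets are data-bound results of a particular
clinical cohort; they are representable via `apply_subset()` and
reproducible via `backward_eliminate()`, but they are not hard-coded
defaults.

# Feature selection

Greedy backward elimination: train on the full set, then per round retrain
every leave-one-out subset of the surviving subset and keep the best, down
to single features — exactly $p(p+1)/2$ trainings for $p$ starting features.
The selected subset is the *global* best over all evaluated subsets.
Classifiers are scored by training accuracy, quantifiers by training loss;
no validation split is used (with small cohorts a held-out sliver would
itself overfit, the same reasoning the assay's developers give). Every
candidate trains from the same seed so criterion differences reflect
features, not initialisation; ties prefer the smaller subset, then
lexicographic order, for reproducibility.

# Evaluation and the power-fit baseline

Reports include per-biomarker range accuracy with a confusion matrix,
Pearson r between predicted and true concentrations on the quantifiable
subset (quantified predictions with uncensored truth; negatives and
undetermineds counted separately), and the duplicate-cartridge CV. r is
computed on linear concentrations by default, matching the convention of
the assay's published scatter plots, with a log10 option because the values
span decades. The comparator is the traditional single-signal calibration:
invert the biomarker's designated averaged signal (colorimetric for CK-MB
and NT-proBNP, CL for cTnI) through a power fit trained on the same
samples. The baseline has no access to the control spots, so it cannot
correct cartridge-level matrix effects — which is precisely where the
multivariate cascade earns its advantage.

# Problem sizes and reproducibility

The package's own validation runs at desk scale, chosen so the full suite
trains in minutes on one CPU: the end-to-end study uses 200 synthetic
patients (duplicate cartridges, default noise), split ~65/35 by patient so
duplicates never straddle the split; the replicate-CV recovery uses 1000
Monte-Carlo repetitions of triplicates at each calibration concentration;
QC false-exclusion uses 10^5 simulated cartridges. Under these conditions
the trained cascade reaches held-out Pearson r ≥ 0.95 per biomarker with at
most 10% undetermined labels, and it exceeds the single-signal baseline's r
for cTnI and on the cohort average. For CK-MB and NT-proBNP the generator's
mean response is exactly the power law the baseline inverts, so the baseline
is near-oracle there and the two estimators are statistically tied (the
cascade matches it within 0.01 in r); on real data, where single signals
deviate from a clean power law, the multivariate cascade is expected to
separate further. These are the quantitative claims asserted (and
recomputed) by the test suite, not quoted from elsewhere.

# Known limitations

* The generator's mean response is an exact power law; real calibration
  data bend at both ends, which is why the 4-PL exists. Fits to synthetic
  data are therefore cleaner than fits to real assays.
* The printed training regimen at these cohort sizes gives only a few
  optimizer steps per epoch; quantifier accuracy is limited by that budget,
  not by network capacity, and inherits its variance across seeds.
* The registration search is integer-pixel and rigid; rotation, scale, and
  illumination gradients are out of scope.
* Detection limits and clinical accuracies depend on unpublished data and
  are deliberately not reproduced as numbers — only their defining formulas
  and qualitative behaviour (e.g. the synthetic CK-MB LoD falling below the
  5000 pg/mL cut-off) are asserted.
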