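---
title: "Calibrating and validating NIR phytohormone models with phytoNIR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calibrating and validating NIR phytohormone models with phytoNIR}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phytoNIR)
```

## The problem

Quantifying endogenous phytohormones — indole-3-acetic acid (IAA),
gibberellic acid (GA), salicylic acid (SA) and kinetin — normally requires
chromatography/mass spectrometry. Near-infrared (NIR) spectroscopy offers a
rapid, non-destructive alternative: the 10000–4000 cm⁻¹ absorption spectrum
of a methanolic leaf extract carries C–H, O–H and N–H overtone and
combination bands whose intensities are, by Beer–Lambert linearity,
proportional to analyte concentrations. Because those bands overlap heavily,
a multivariate calibration is required. `phytoNIR` implements the full
chemometric workflow: partial least squares (PLS1) calibration on standard
solutions, preprocessing and wavelength-window selection, external
validation, prediction of unknown extracts with unit conversion to
µg g⁻¹ fresh weight, and population-level comparison statistics.

## The calibration model

For one hormone, let $X$ be the $n \times p$ matrix of preprocessed
calibration spectra and $y$ the concentrations (µM). PLS1 extracts latent
factors that maximize the covariance between spectra and concentration.
The NIPALS implementation column-centers $X$ and $y$ and, for each factor
$a$: computes the weight $w_a \propto X_{c}' y_c$ (normalized), scores
$t_a = X_c w_a$, loadings $p_a = X_c' t_a / t_a' t_a$ and
$q_a = y_c' t_a / t_a' t_a$, then deflates
$X_c \leftarrow X_c - t_a p_a'$ and $y_c \leftarrow y_c - q_a t_a$. For a
single response the weight iteration is stationary after one pass; the
iteration guard (tolerance $10^{-12}$, 500 iterations) only matters for
numerically degenerate windows. Absorbance columns are centered but not
autoscaled — they share units, the standard convention in NIR work.
Predictions use the folded regression vector
$B_a = W_a (P_a' W_a)^{-1} q_{1:a}$, and the per-factor explained
X-variance is $100\,\|t_a p_a'\|^2 / \|X_c\|^2$.

Model quality is tracked with three errors sharing one formula,
$\sqrt{\sum_i (y_i - \hat y_i)^2 / n}$: RMSEC on the training set, RMSECV
over cross-validation folds (each fold refits the preprocessing statistics
— MSC reference and centering — so no information leaks from left-out
samples), and RMSEP on the held-out external test set. $R^2$ is
$1 - SS_{res}/SS_{tot}$ and can be negative; a negative prediction $R^2$
means the external validation fits worse than the mean, which is exactly
how invalid candidates are recognized.

## Preprocessing candidates and selection

Each candidate is a (window, pre-treatment) pair, windowed first:

* **none** — windowed absorbance as measured.
* **msc** — multiplicative scatter correction: each spectrum is regressed
  on the mean calibration spectrum, $x = a + b\,r + e$, and corrected to
  $(x - a)/b$. The reference is frozen in the fitted model and reused for
  validation and unknowns.
* **sg1d** — Savitzky–Golay smoothed first derivative (default 13 points,
  quadratic; the quadratic is the standard chemometric choice for first
  derivatives). Edges are truncated to the valid convolution region rather
  than padded, because padding fabricates data exactly where scatter is
  worst.

The default grid holds six candidates per hormone: the three treatments on
the full 4000–10000 cm⁻¹ range and on a hormone-specific reduced window
(4000–6000 cm⁻¹ for IAA/SA/kinetin with `none`/`msc`, 4000–5000 cm⁻¹ for
the IAA derivative, 4000–7000 cm⁻¹ for GA throughout and for the kinetin
derivative).

Two selection decisions are deliberately parsimony-first:

* **Factor count.** The RMSECV curve over 1–7 factors is scanned for the
  smallest count whose RMSECV is statistically indistinguishable from the
  minimum, judged by an F-ratio on the cross-validated squared errors at
  $\alpha = 0.25$ (the Haaland–Thomas convention). A plain argmin
  systematically overfits whenever the curve is flat, and with
  floating-point RMSECVs an exact tie never occurs, so a literal
  "ties go to fewer factors" rule would never engage.
* **Candidate choice.** After a validity filter ($R^2_{pred} > 0$),
  candidates within a factor 1.2 of the minimal RMSEP are treated as
  statistical ties — RMSEP is itself estimated from roughly 19 test
  samples, and 1.2 is about the F-ratio at the 0.25 level for that size —
  and resolved toward fewer factors, then lower RMSEP, then lower RMSEC.
  The bundled worked example (`reference_candidate_metrics()`) shows the
  validity filter doing real work: the salicylic-acid block contains a
  scatter-corrected candidate with the lowest RMSEP (0.988 µM) but a
  prediction $R^2$ of −6.94, and the rule correctly discards it in favor
  of the raw full-spectrum model.

Low factor counts are not only aesthetics. A PLS regression vector built
from many factors acquires components that cancel the calibration set's
noise structure; those components respond unpredictably to spectral
features never seen in calibration — such as the bands of *other* hormones
in a real extract. The one- and two-factor models the selection rule
prefers behave like matched filters on the analyte's own bands and remain
accurate on mixtures.

## The synthetic-data generator

No spectra were deposited for this kind of study, so validation uses a
simulator with known ground truth. Design choices, and what they do and do
not emulate:

* **Band library.** Gaussian bands at the literature positions (e.g. GA
  4500/4700/5200/7150, IAA 4150/4500/5200/5900/7100/9100, SA
  4150/5000/5200/7100, kinetin 4400/5100/6700/8800 cm⁻¹). Widths are
  σ = 40 cm⁻¹ for combination-region and dominant bands and 80 cm⁻¹ for
  minor overtone bands. Amplitudes follow a separability rule: each
  hormone keeps one dominant band no other analyte shares (IAA 5900, GA
  4700, SA 5000, kinetin 6700 cm⁻¹) at relative amplitude 1; every other
  assigned band, being shared with or adjacent to another analyte's bands,
  enters at 0.005. This keeps the between-analyte spectral cross-talk
  (normalized inner products of the unit-concentration spectra, in both
  the raw and the derivative domain) well below 1%, which is what makes
  single-analyte calibrations valid for mixture prediction. The binding
  constraint is the GA(4700)–SA(5000) pair at only 300 cm⁻¹ separation.
  Signatures are scaled so a 250 µM solution peaks near 1 AU.
* **Matrix interferent.** A broad methanol/matrix signature (bands near
  4300, 5150, 6900 cm⁻¹, 0.1 AU) is added to every spectrum at a fixed
  level. Because it is constant it is absorbed by centering; its modest
  size also means the MSC reference is signal-dominated, which makes MSC's
  known concentration-dependent slope distortion visible (see below).
* **Noise model.** Per spectrum: multiplicative gain
  $b \sim \mathrm{lognormal}(0, 0.002)$, additive offset
  $a \sim N(0, 0.002)$ AU, a smooth random baseline drift with pointwise
  sd 0.005 AU realized as a linear tilt plus band-limited cosine curvature
  approximating a Gaussian process with ≈130 cm⁻¹ correlation length, and
  white noise of 0.003 AU. The smooth drift is the structured corruption:
  it is far too high-dimensional for a ≤7-factor model on raw spectra to
  reject, while the first derivative suppresses it structurally. Under
  these defaults the derivative candidates win model selection for every
  hormone with a clear RMSEP margin, MSC candidates fail decisively
  (their slope fit is distorted by the analyte signal itself and, on
  extracts, absorbs foreign-hormone absorbance), and raw-spectrum
  candidates trail the derivative. What the simulator does *not* emulate:
  instrument line shapes and detector nonlinearity, temperature/solvent
  shifts of band positions, analyte–analyte chemical interactions, and
  wavelength-dependent multiplicative scatter — so passing the closed-loop
  study demonstrates the correctness and internal consistency of the
  workflow, not instrument-grade accuracy on real extracts.
* **Standards and extracts.** 65 levels per hormone, log-spaced over
  0.1–250 µM (three and a half decades; linear spacing available), one
  hormone per standard plus interferent and noise — 260 standards in all.
  Extract panels take a population × hormone truth matrix (µM), build the
  Beer–Lambert mixture of all hormones plus interferent, and add noise per
  replicate. Everything is seeded and bit-reproducible.

## Splitting, units, population statistics

The 70/30 calibration/validation split is stratified on concentration rank
(one test sample drawn from each of 19 consecutive concentration blocks)
with the extreme levels forced into the training set, so external
validation never extrapolates; 70% of 65 rounds half-up to 46/19.

Concentrations convert to tissue content as
$\mu g\,g^{-1}\,FW = c_{\mu M} \cdot M \cdot V_{extract} / m_{tissue}$ with
default molar masses IAA 175.18, GA₃ 346.37, SA 138.12, kinetin
215.21 g/mol, extract volume 0.010 L and 1.0 g fresh tissue. The extract
volume is the one quantity with no canonical value — reports should always
state the context used, and `unit_context()` makes it explicit rather than
burying it in a constant. Negative predictions are flagged, never silently
clipped (clipping is available as an option).

Population comparisons use classic one-way ANOVA with Tukey HSD
(Tukey–Kramer for unequal sizes), accepting either raw replicates or
published summary triples (mean, SE, n); the summary path reconstructs the
within-group sum of squares through $s^2 = n \cdot SE^2$, an exact
identity. Multivariate structure is summarized with Bray–Curtis
dissimilarities on the raw (unstandardized) profiles — the profiles are
abundance-like and share units, and an optional range-scaling flag exists —
followed by nonmetric multidimensional scaling (Kruskal stress-1, vegan's
monotone-regression engine, classical-scaling start plus seeded random
restarts, best of 8 kept).

## Numerical and degenerate-input policy

Wavenumber grids must be uniform to a relative 10⁻⁶ and are normalized to
ascending order on read, so derivative signs have a single convention.
Windows are closed intervals over exact grid points — no interpolation.
Mismatched grids are rejected rather than resampled. Factor extraction
stops early (recording the achieved count) when the deflated matrix runs
out of variance, which prevents NaN weights on zero-variance windows.
MSC refuses constant references and near-zero slopes. Aggregation with a
single replicate reports SE 0 with a flag. The isotonic step in nMDS uses
the primary (averaging) tie treatment; convergence is declared at a
stress change below 10⁻⁸ or 300 iterations.

## Scope of the closed-loop validation

The acceptance workflow (see `scripts/acceptance.R`) treats the bundled
thirteen-population reference profiles as ground truth: it converts them
to µM, simulates standards and three-replicate extract panels, calibrates
and selects a model per hormone, predicts, converts back, and compares.
With the default generator this recovers the strongest population's
hormone contents to within a few percent and reproduces the qualitative
structure of the reference data — the within-population hormone ordering
wherever the printed ordering has a clear (>10%) margin, the identity of
the most extreme population for all four hormones, and the two most
dissimilar populations in the Bray–Curtis sense. Problem sizes throughout
(65 standards per hormone, 13 × 3 extract spectra, 3001-point grid) match
the study design the package targets and keep a full closed loop under ten
seconds on a laptop.

## Known limitations

Single-analyte calibrations can never fully reject unseen interferents;
the simulator's separability rule makes this safe, but on real extracts a
calibration-set design that spans the interference space (mixture
standards) would be required. MSC is implemented in its classical form and
is the right tool only when chemical variation is small relative to
scatter; the workflow surfaces its failure through the validity filter
instead of patching it. JCAMP-DX support covers uncompressed
`(X++(Y..Y))` blocks only. Prediction uncertainty (per-sample intervals)
is out of scope.
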