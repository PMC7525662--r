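---
title: "From rodent time-activity curves to corrected clinical dose predictions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From rodent time-activity curves to corrected clinical dose predictions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(petdosim)
```

## The problem

Before a new PET radiotracer reaches first-in-human studies, its radiation
burden has to be predicted from animal data. The standard route is the MIRD
schema: integrate each source organ's time-activity curve (TAC) into a
residence time $\tau_S$ (MBq·h per MBq injected), optionally rescale the rat
kinetics onto human anatomy, and fold the residence times through a phantom's
S-value matrix,

$$D_T \;=\; \sum_S \tau_S \, S(T \leftarrow S), \qquad
  E \;=\; \sum_T w_T \, D_T,$$

where $S(T \leftarrow S)$ is the absorbed dose in target $T$ per unit
cumulated activity in source $S$ (mGy/(MBq·h)) and $w_T$ are tissue weighting
factors summing to 1. These predictions are known to be systematically biased
relative to clinical measurements, and the bias depends on choices that have
nothing to do with the tracer: the image-reconstruction algorithm and whether
organ masses were normalised across species. `petdosim` implements the whole
chain plus the bias quantification, so the systematic error can be measured
on reference tracers and corrected on new ones.

## Residence times

Each organ's $\tau$ is the area under its non-decay-corrected TAC (activity
as a fraction of injected dose, time in hours), computed with the trapezoid
rule on frame midpoints, plus a tail term for the unobserved time after the
scan. Beyond the last sample only the physical half-life of fluorine-18
(109.77 min by default, configurable in `decay_constants()`) is assumed, so
the tail integral is $A_\mathrm{end}/(100\,\lambda)$, independent of when
the scan ended:

```{r}
tail_residence(100, decay_constants(109.77))  # hours; equals 1/lambda
```

Numerical choices that matter, and their defaults:

* **Anchoring.** Frames carry start/end times; integration abscissae are the
  midpoints. A $t = 0$ point is prepended: organ curves anchor at 0 %ID and
  the whole-body curve at 100 %ID, because the activity arrives as an
  intravenous bolus. Whether the original analysis did this is not
  documented anywhere we could check, so `residence_times(anchor = FALSE)`
  integrates from the first midpoint instead. The difference is one
  half-frame wedge, below 0.2% of the whole-body residence time on the
  default schedule.
* **Decay handling.** Whether exported TACs are decay-corrected is an
  explicit flag on the data. If a curve is flagged corrected,
  `uncorrect_decay()` runs automatically (with a message) before
  integration; silently guessing wrong would corrupt $\tau$ by up to a
  factor of two over a 240-min scan.
* **Remainder.** The remainder compartment is whole-body $\tau$ minus the
  summed organ $\tau$s. Overlapping VOIs can push the sum slightly past the
  whole-body value; a deficit under 2% of whole-body $\tau$ is clamped to
  zero with a warning, anything larger is treated as corrupt input and
  raises an error.
* **Physical bound.** No physically valid whole-body curve can integrate
  above $1/\lambda$ (2.6394 h for fluorine-18); inputs exceeding the bound
  by more than the 5% measurement tolerance are rejected.

## Interspecies normalisation

Residence times measured in the rat are rescaled per organ by

$$\frac{b_r}{o_r} \cdot \frac{o_h}{b_h},$$

the ratio of the human organ's body-mass fraction to the rat's, with
$b_r = 332.67$ g and $b_h = 73{,}000$ g (adult male) or $60{,}000$ g (adult
female). The whole-body residence time is deliberately **not** scaled: total
cumulated activity is fixed by the decay physics and the factor is defined
per organ. The remainder is recomputed after scaling under the same clamping
rule. Applying normalisation twice is an error (the set carries a
`normalised` flag). Allometric power-law alternatives are out of scope.

## The dose engine

`absorbed_doses()` is an exact label-joined matrix–vector product; organ
order in the S-matrix never matters. The remainder is an explicit source
column — the mass-weighted internal remainder correction that some dosimetry
programs apply is *not* re-derived, since it requires phantom internals that
are not part of the declared inputs; this is a documented divergence. The
urinary bladder is treated as a static source (no voiding model). Units are
fixed — $\tau$ in hours, S in mGy/(MBq·h), doses in mGy/MBq — and never
inferred. For positron/photon emitters the radiation weighting factor is 1,
so the effective dose in mSv/MBq is numerically the weighted sum of organ
mGy/MBq values.

The S-value matrices shipped by `synthetic_svalue_matrix()` are **synthetic**:
diagonally dominant (self-dose inversely proportional to target mass), small
symmetric cross-organ terms, a strong intestine-to-LLI-wall term, and a weak
uniform remainder contribution. They preserve the structure the engine
assumes but cannot reproduce reference phantom numerics; supply real S-value
tables via `read_svalue_matrix()` for that. The default tissue-weight file
follows the classic ICRP-60-style scheme over the modelled targets, with an
`other tissues` target absorbing the balance so the sum is exactly 1
(enforced at load).

## Bias quantification and correction

For a reference tracer with published clinical doses, predicted organ doses
are regressed on true ones (pairs matched by organ label). The fit includes
an intercept by default — matching common graphing-software defaults, and
only the slope enters the summary — with a `through_origin` option. The
scalar bias summary is $|1 - \text{slope}| \times 100$; a model differs from
the line of identity when 1 falls outside the slope's 95% t-based confidence
interval (inclusive bounds). Bland–Altman agreement uses limits at
mean ± 1.96 SD of the differences.

Normalised residence times with FBP reconstruction underestimate clinical
doses consistently; pooling those models' biases gives the headline
correction: mean 42% (range 22–58%) when computed from the published
model-comparison slopes:

```{r}
cf <- correction_factor(mean_percent_bias(c(0.5956, 0.7793, 0.4166, 0.5404)))
cf$rounded_percent
cf$range
```

`apply_correction()` offers the exact form (divide by the fitted slope) and
the simplified field rule (divide by $1 - \text{bias}/100$) for
underestimating models.

Two pluggable definitions were genuinely open:

* **LLI precision.** Excluding the lower large intestine wall (rat and human
  gut anatomy differ; rats lack a gallbladder) improves every model's
  precision, but "precision" has no published numeric definition. We
  operationalise the improvement as the ratio of mean percent biases
  (with / without the LLI pair) in `lli_sensitivity()`.
* **Per-organ averaging.** Doses are averaged per organ across subjects
  before fitting; the fit is unweighted (no inverse-variance weighting),
  since nothing more specific is specified.

Reconstruction comparison (`compare_reconstructions()`) regresses iterative
residence times on FBP ones over matched organ/subject pairs; a slope near
1.6 reproduces the systematic inflation iterative reconstruction introduces.

## What the synthetic generator emulates — and what it does not

`generate_scan()` simulates one subject under both reconstructions:

* **Frame schedule.** The 13-frame re-binning template (7 × 1, 2 × 5,
  4 × 10 min) covers the first 57 min; 10-min frames are appended to span
  the full 240-min scan, with a short closing frame landing exactly on
  240 min.
* **Kinetics.** Each organ follows a peak-normalised biexponential
  $f\,(e^{-k_\mathrm{out}t} - e^{-k_\mathrm{up}t})$ under the physical-decay
  envelope. The default `peptide_kinetics()` preset is kidney-dominant
  (fractional uptake 0.25 in kidneys, 0.10 bladder, rates in 1/min chosen so
  uptake peaks within the first hour and washout is slow), emulating a
  glomerularly filtered radiopeptide.
* **Whole body.** Anaesthetised rats do not void during the scan, so the
  default excreted fraction is 0 and the whole-body curve is the noiseless
  pure-decay envelope; an `excreted_fraction`/`excretion_rate` pair models
  voiding if wanted.
* **Noise.** Multiplicative mean-1 lognormal per frame (activities are
  positive; CV 0.1 by default). No published noise model exists; this is the
  package's choice.
* **Reconstruction bias.** The iterative scan's organ activities are scaled
  by $\rho$ (default 1.6), the whole-body VOI being shared, so organ
  $\tau_\mathrm{iter} \approx \rho\,\tau_\mathrm{FBP}$ by linearity of the
  integral.
* **Determinism.** All randomness flows through the spec's single seed;
  identical seeds give bit-identical scans, and every fixture file records
  its seed in a header comment.

What it deliberately does **not** model: image-domain effects (spill-over,
partial volume, scatter — reconstruction bias enters only as the scalar
$\rho$), inter-subject kinetic variability beyond the noise term, biological
tail kinetics after the scan (the tail rule is decay-only by construction),
and anatomical phantom geometry. Passing tests on generated data therefore
demonstrate the correctness of the arithmetic chain and the recoverability
of its parameters — not that any particular real tracer satisfies the
kinetic model.

Study-scale quantities that depend on the unreleased animal scans and true
phantom S-values (absolute organ doses, the published r² values, the
1.611/1.617/1.590 τ-ratio means, the 1.001–3.054 LLI improvement range) are
covered by structural property tests — linearity, physical bounds,
direction of the LLI effect on constructed outliers — rather than numeric
reproduction.

## Worked example

```{r}
dir <- file.path(tempdir(), "bundle")
paths <- generate_fixture_bundle(dir, seed = 1)

scan <- read_tac_file(paths$tac_S01_fbp)
sv <- read_svalue_matrix(paths$svalues_adult_male, paths$tissue_weights,
                         phantom = "adult male")
report <- run_dosimetry_model(
  scan, sv, normalise = TRUE,
  rat_masses = read_organ_masses(paths$masses_rat),
  human_masses = read_organ_masses(paths$masses_adult_male))
rank_organs(report, 3)
report$effective
```

Problem sizes used throughout the test-suite simulations — 3 subjects,
200 Monte-Carlo replicates of 12 dose pairs, 6-subject reconstruction
cohorts, 0.1-min oracle sampling — are the package's chosen demonstration
scale: large enough that the stochastic recoveries are within a few
Monte-Carlo standard errors of their targets, small enough to run as
ordinary unit tests.

## Known limitations

* Organ-level MIRD only: no voxel dosimetry, no Monte-Carlo transport.
* Static bladder source; no dynamic voiding model.
* The remainder compartment is a plain S-matrix column; programs that apply
  a mass-weighted remainder correction will differ accordingly.
* Activity must already be %ID; converting Bq/mL × VOI volume is upstream
  work.
* The shipped S-values, organ masses (beyond the body-mass constants) and
  clinical reference doses are synthetic fixtures for pipeline demonstration.
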