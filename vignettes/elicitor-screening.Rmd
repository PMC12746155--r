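---
title: "Methods: differential metabolomics for elicitor screens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: differential metabolomics for elicitor screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hitescreen)
```

This vignette documents the models, the tunable parameters, the numerical
choices, and the scope of what the synthetic-data generators do and do not
emulate. It is the package's reference for *why* each stage works the way it
does; the README shows *how* to run it.

## The screening model

A high-throughput elicitor screen observes, per well, a list of LC-MS
features (m/z, retention time, intensity). Wells are either elicitor wells
(one library compound at a fixed sub-MIC concentration, default 16 µM) or
vehicle controls. The analysis asks, per ion, which elicitors induce it.

**Alignment** (`align_features()`) groups features across wells by greedy
single linkage: the most intense unassigned feature seeds a group and claims
everything within the m/z tolerance (default 10 ppm) and RT tolerance
(default 0.2 min). Seeding by intensity makes the result invariant to well
order and deterministic; a greedy pass is adequate because the downstream
statistics aggregate per group, and mis-splits only dilute — never fabricate —
induction signal. Retention-time warping is deliberately out of scope; the
generators apply no RT drift, and real data with severe drift would need
external alignment first.

**Differential map** (`differential_map()`). For aligned ion $f$ and
elicitor $e$ with replicate wells $W_e$ and controls $W_c$:

$$\Delta I(f,e) = \max\!\big(0,\ \mathrm{med}_{w \in W_e} I_{fw} -
\overline{I}_{f,W_c}\big), \qquad
F(f,e) = \frac{I_{fe} + c}{\overline{I}_{f,W_c} + c}.$$

Choices worth recording:

* *Median over elicitor replicates, mean over controls.* Medians are robust
  at the 1–3 replicates a screen affords; the control mean uses all control
  wells and is stable.
* *Pseudo-count* $c$ = 5% of the plate's median positive control intensity.
  It bounds fold changes for ions absent from controls (a control mean of
  zero otherwise gives infinite fold) while perturbing well-measured ions by
  under 5%. It scales with the data, so scaling all intensities by $k$
  scales $\Delta I$ by $k$ and leaves $F$ unchanged.
* *Flooring $\Delta I$ at zero.* The analysis targets induced metabolites;
  suppression is a non-goal and negative values would only add noise to
  ranking.

**Hit calling** (`call_hits()`) requires the best elicitor of an ion to pass
a fold threshold (default 3), a $\Delta I$ threshold, and — when an FDR is
requested — a Benjamini–Hochberg-adjusted one-sided test. The per-cell
p-value compares $\log(I_{fe}+c)$ against the feature's control
log-intensity distribution ($z$-score with the control SD inflated by
$\sqrt{1+1/n_c}$ for the single-well observation). Two caveats are
deliberate: the normal tail is an approximation whose miscalibration with
few control wells is absorbed by the fold/ΔI gates, which do the heavy
lifting for specificity; and BH across all feature × elicitor cells is the
standard screening choice here even though the original bioassay context
used Bonferroni — that correction belonged to a different (wet-lab)
testing problem.

## Dose–response

`fit_4pl()` fits $r(x) = b + (t-b)/(1+(x/m)^s)$ by Levenberg–Marquardt
least squares (via `minpack.lm`). Determinism comes from a rule-based start:
$b,t$ from the response extremes, $m$ by log-interpolating the dose
bracketing the half-range, $|s|=1$ with sign from the dose-response trend. A
fixed ladder of three fallback starts (slope ×1.2, midpoint ×2 and ×1/2)
guards against the occasional singular numeric gradient on exact data; the
ladder is tried in order, so fits remain reproducible. Zero doses are
offset by half the smallest nonzero dose for initialization only — the model
itself evaluates $x=0$ exactly ($r(0)=t$ for $s>0$). Fits are reported in
canonical form $b \le t$ (swapping $b,t$ and negating $s$ is an exact
symmetry). Flat data and non-convergence set flags instead of raising, so
plate-scale batch fitting never aborts.

`induction_profile()` classifies the per-dose fold series: *flat* when no
dose reaches 1.5-fold; *biphasic* when the maximum is interior and the top
dose has fallen to ≤ half of it; *monotone* otherwise. The biphasic class is
the shape of interest: production that peaks at growth-inhibitory elicitor
doses.

## Mass chemistry

All mass arithmetic uses a bundled isotope/atomic-weight table (IUPAC 2021
values; deuterium is a first-class element symbol `D` that counts with
hydrogen in RDBE and valence checks). The proton delta is 1.007276 Da and
electron mass is ignored throughout adduct arithmetic — a sub-ppm convention
at m/z 100–800.

`enumerate_formulas()` does exhaustive bounded enumeration: a grid over
non-hydrogen element counts with hydrogen solved from the mass residual
(±1 candidate), filtered by ppm window, integer RDBE ≥ 0 and the nitrogen
rule applied to the neutral formula (the screen's ions are even-electron
protonated species). Default tolerances are 10 ppm at MS1 and 15 ppm for
fragments: the reference ions' observed-vs-theoretical gaps run ~7 ppm, so
tighter defaults would reject the very measurements the assignments rest
on. Candidates are ranked by |ppm| with ties broken toward fewer atoms. At
10 ppm and generous CHNO bounds a ~350 Da query typically admits more than
one candidate — formula assignment is a ranking, not an oracle, which is
why user-supplied element bounds and the ppm ranking are both part of the
interface, and why tests validate the enumeration against an independent
brute-force oracle rather than asserting uniqueness.

## Family inference

`detect_homolog_series()` first collapses features into *rungs* (m/z within
0.01 Da; same-mass features ≥ 0.3 min apart are RT-resolved isomers sharing
a rung), then single-links rungs whose spacing matches the repeat unit
(default CH2 = 14.01565 Da) within 0.01 Da. The 0.01 Da / 0.3 min pair was
chosen so that a 0.0002 Da same-nominal-mass pair lands in one rung while
chromatographically resolved isomers stay distinct. `infer_acyl_carbons()`
then anchors one rung to an assigned formula, propagates ±CH2 along the
ladder, and subtracts the conserved core (default the Ser-Gly dipeptide,
C5H10N2O4, 5 carbons), enforcing the exact sum rule
*formula carbons − core carbons = acyl carbons* per member. Branch type
(iso/anteiso) is **never** inferred from mass: branch isomers are
mass-identical, so the branch slot is filled only by labeling evidence
(`bcaa_route()`) or user annotation. RT-resolved same-mass pairs
(`pair_isomers()`) are reported neutrally — distinguishing conformers from
configurational isomers needs orthogonal (e.g. variable-temperature NMR)
evidence and is out of computational scope.

## Labeling

`expected_shift()` implements the position-loss rule $k = n - L$: a
uniformly deuterated precursor with $n$ deuteria loses $L$ labeled positions
along its catabolic route, the default $L=1$ being the α-proton lost in
transamination. How many further exchangeable deuteria are lost in vivo is
not quantifiable from first principles, so $L$ stays a user input.
`detect_shift()` searches the labeled spectrum at $+k \times 1.006277$ Da
($k \le$ 12 by default) above a noise floor (5% of the base peak) and
reports the single best-supported $k$ — the M+k readout of such experiments —
rather than fitting an isotopologue distribution, which would require
natural-abundance deconvolution that is out of scope.

## What the generators emulate — and what they do not

`simulate_screen_plate()` draws a log-normal baseline metabolome (defaults:
200 ions/well, meanlog = log 10⁴, sdlog = 1), observes every ion in every
well under multiplicative log-normal technical noise (CV 0.2), and injects
CH2-laddered families whose members are amplified by their true fold (the
5–12× elicitation range) in responsive-elicitor wells. Defaults mirror the
screen scale: 400 elicitors, 8 vehicle controls, one well per elicitor.
Baseline m/z collisions with injected members are redrawn (warned if
unresolvable). The generators deliberately omit: chromatographic peak
shapes, RT drift (an optional concern handled upstream), isotope patterns
and fine structure, ion suppression, and any biological regulation — so
passing recovery tests demonstrates the statistics are correct under the
stated noise model, not that the pipeline is robust to every instrumental
pathology of real data.

`simulate_dose_series()` composes a falling growth 4PL (defaults IC50 4.6
µM, Hill 1.5) with a rising induction logistic, modelling realized intensity
as *induction × growth fraction*. This is phenomenological, not mechanistic;
it reproduces the observed shape in which ~12-fold peak induction occurs
near sub-inhibitory doses and collapses as growth fails. The rising
component's asymptote (default 25) is therefore larger than the realized
peak (~12-fold) by construction.

`simulate_labeling()` places a single isotopologue at the exact shifted mass
with abundance proportional to the incorporation fraction — no
natural-abundance envelope.

## Problem sizes and determinism

Every generator is a pure function of its config and one integer seed;
identical seeds give identical datasets and the pipeline writes
byte-identical outputs (timings are logged separately for this reason). The
test suite validates screen recovery on ten seeded 400-elicitor × ~215-ion
plates with five injected families plus three null plates, dose-response
recovery over twenty seeded series, and formula enumeration against an
independent nested-loop oracle on lattices up to ~10³ points — sizes chosen
to exercise the full screening geometry while keeping the suite fast enough
to run on every change.

## Package shape

The pipeline stages are plain functions over light S3 containers (a plate
dataset, an aligned-feature set, a differential map), matching how the
field's analysis packages expose multi-stage workflows; the one genuinely
model-like component, the 4PL fit, is instead a classic classed model object
with `coef`/`predict`/`residuals`/`summary`/`plot` methods, because that is
the idiom users expect from a curve fit. `run_pipeline()` ties the stages
together under one seed and a hashed config; since the package is driven
from R, no shell executable is shipped.

## Known limitations

* Alignment is greedy and tolerance-based; heavily overlapping isobars
  within tolerance merge into one consensus ion.
* The hit-calling p-value is a normal approximation; with very few control
  wells its calibration rests on the fold/ΔI gates.
* Formula enumeration covers CHNOSP(D) with single charges and no
  isotope-pattern scoring; element ratios and valence heuristics beyond
  RDBE/nitrogen rule are the caller's responsibility via bounds.
* mzML ingestion is a convenience reduction (tolerance-linked traces, apex
  features), not a research-grade peak picker; the canonical input is the
  long-format feature CSV.
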