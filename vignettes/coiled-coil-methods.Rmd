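---
title: "Models and methods behind coilspect"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind coilspect}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coilspect)
```

coilspect analyses α-helical coiled-coil bundles: it fits superhelical
geometry and heptad register from coordinates, detects core packing and
interhelical electrostatics, validates crosslinking-MS restraints, computes
per-heptad composition statistics, analyses CD spectra and thermal melts,
and models stepwise hetero-oligomer assembly. This vignette explains the
underlying models, the parameters that matter, and the choices made where
the design was genuinely open.

## The Crick builder as ground-truth generator

The reference structure for the honeybee silk heterotetramer is a predicted
atomic model without deposited coordinates, so there is no golden file to
test against. The package therefore treats an ideal Crick-parameterized
bundle as its ground-truth generator: every quantity the fitting stack
reports (radius, pitch, handedness, orientation, stagger, register) is
known exactly by construction, and correctness is established by parameter
recovery rather than file comparison.

The builder's defaults are the study conditions: superhelical radius
5.8 Å, pitch 153 Å, four 168-residue chains (24 heptads), antiparallel
U/U/D/D orientations placed so the cyclic arrangement reads clockwise
F1-F3-F2-F4 from the positive axis end. The helix-level constants are the
canonical coiled-coil values — minor radius 2.26 Å, rise 1.51 Å per
residue, 3.5 residues per turn in the supercoil frame, left-handed
supercoil — because the silk study does not report them and they are the
established canon for heptad coiled coils.

Two deliberate simplifications:

* **CB pseudo-atoms are placed purely radially**, 1.53 Å from the CA along
  the outward normal from the local helix axis, without the small
  tetrahedral tilt of a real Cβ. This is sufficient for knob/hole topology
  and register work; absolute packing distances on synthetic bundles are
  coarser than on real side chains, which is why test fixtures that need
  charged atoms decorate the bundle explicitly.
* **Antiparallel chains are rigid 180° rotations** of an up-chain rather
  than sign-flipped propagation. A rigid motion cannot change chirality,
  so helix handedness and supercoil handedness are automatically preserved;
  the rotated chain is re-seated on the same superhelical track so `phase0`
  and `stagger` keep their meaning.

What the generator does *not* emulate: backbone irregularity, sequence-
dependent local geometry, bent or fragmented coils, side-chain rotamers,
missing density. Passing recovery tests on these bundles shows the
estimators are correct on their model class and robust to isotropic noise;
it does not certify behaviour on distorted experimental models.

## Geometry fitting

**Local axis.** Each chain's CA trace is smoothed with a sliding window of
7 consecutive residues. At 3.5 residues per turn a 7-residue window covers
exactly two helical turns, so the centroid lies on the local helix axis up
to supercoil curvature; the construction is also robust to noise. Three
residues at each end have no full window and carry no Crick phase.

**Axis, radius, pitch.** The superhelical axis is the first principal
direction of the pooled axis points, signed so chain 1 runs N→C positive.
The radius is the mean perpendicular distance of axis points to this line,
divided by the analytic shrinkage factor of a 7-point centroid on a curved
track, `(1 + 2·Σₖ cos(k·ω0))/7` (k = 1..3), with ω0 estimated from the
fitted azimuth slope — about 0.8% at the silk pitch, but over 2% at pitch
100 Å, which is why the correction is applied rather than ignored. The
pitch is `2π/|dθ/ds|` from the per-chain regression of unwrapped azimuth on
axial coordinate; the slope sign gives handedness. Slopes below the
equivalent of a 2000 Å pitch are treated as "no supercoil": handedness
`none`, pitch undefined.

**Conventions.** "Clockwise" is defined for an observer at the positive
axis end looking back along the axis; with the axis anchored to chain 1's
N→C direction this makes the reported cyclic arrangement reproducible.
Because of that anchoring, chain 1 is always labelled U; a bundle supplied
with its first chain running the other way gets globally flipped labels
and negated staggers, which is the same physical answer in the mirrored
frame. The reported radius is a mean over the rod, not a mid-rod value.

**Register.** The Crick phase of a residue is the signed angle, in the
plane normal to the local tangent, between the direction from the helix
axis point to the superhelical axis and the direction to the CA. All seven
cyclic offsets of the periodic a–g assignment are scored by the mean
cosine of the phase over the residues labelled a or d — the core must face
the bundle axis — and the best offset wins, ties to the smallest offset.
The winning periodic assignment is extrapolated over the whole chain,
including the three window-trimmed residues at each end where no phase is
defined: the register is periodic by construction, and this is what lets a
168-residue chain report its full 24 complete heptads. Register is
assigned per chain independently; cross-chain consistency is something to
inspect, not an enforced constraint. `n_heptads` counts complete
consecutive a..g periods and is deliberately independent of the fitted rod
extent — the two are reported side by side without asserting the canonical
rise-per-residue relation between them.

## Packing detection

Side-chain centers are the mean of non-backbone heavy atoms (CB alone when
that is all there is). A knob is a residue whose center sees at least four
centers of one single other chain within 7 Å; its hole is those four
nearest residues. This is a side-chain-center simplification of the
classic all-atom knobs-into-holes criterion — adequate for core topology,
not for complementarity typing, which is out of scope. On ideal
silk-parameter bundles the detected knobs occupy positions a, d, e and g
and never the solvent-facing b, c, f — consistent with an antiparallel
tetramer, where the core-flanking e/g positions pack against neighbouring
helices. `layer_summary()` therefore stratifies a/d knobs by default when
asking whether core layers alternate (they do, strictly, on the ideal
tetramer).

Salt bridges use the common literature convention of 4 Å between charged
heavy atoms (Lys NZ; Arg NH1/NH2/NE; Asp OD1/OD2; Glu OE1/OE2); histidine
is excluded from the basic set. Position classes join the two registers
with the basic residue first ("g-c"). Intra-chain bridges are computed but
reported separately from the interhelical ones that matter for assembly.

## Crosslink restraints

An amine-reactive bis-NHS linker bridges lysine side chains and protein
N-termini. Distances are anchored at Lys NZ when the side chain is
present, the backbone N for a chain's first residue, and CA otherwise —
the linker geometry does not fix a unique atom pair, so the physical amine
nitrogen is preferred with a robust fallback. The restraint is strict:
`distance < 30 Å`, so a link at exactly 30.0 Å is violated. Uniqueness of
links is unordered residue-pair identity with observation counts summed.
Surface exposure means both registers in {b, c, e, f, g}.

## CD spectra and melts

Simulated helix spectra are a phenomenological sum of three Gaussian bands
(positive near 192 nm, negative at 209 and 222 nm). Only ratios and
additivity are meaningful — absolute band shapes are not modelled. The
222 nm band amplitude is solved exactly from a linear equation so the
spectrum's 222/209 ellipticity ratio equals the requested value despite
band overlap. The diagnostic ratio is evaluated at 222/209 nm (the
conventional pair for this diagnostic, fixed here even though minima are
sometimes quoted at 220 nm), with linear interpolation to the exact
wavelengths; a ratio above 0.9 is called coiled coil, and mixtures are
combined as mean-residue-ellipticity weighted by molar fraction (an
equal-concentration assumption; a residue-count weighting toggle handles
equal-mass mixtures).

Melts follow the two-state model: folded fraction
`f(T) = 1/(1 + exp((T − Tm)/w))` between linear folded/unfolded baselines.
Fitting is nonlinear least squares (Levenberg–Marquardt) multi-started
over a 5 °C grid of Tm values to avoid local minima, with Tm bounded to
the observed range and width positive. "Cooperative" is operationalized as
R² ≥ 0.98 with width < 15 °C — thresholds defined by this package to make
the qualitative sigmoidal/non-cooperative language testable; a fitted
transition amplitude below 10% of the data range is reported as no
transition. A superposition of two well-separated transitions fails the R²
criterion, which is the intended behaviour for mixtures of species with
different stabilities.

## Assembly stoichiometry

The assembly model is the strong-binding (infinite-affinity) limit of the
sequential pathway: dimer = min(F2, F4), trimer = min(dimer, F3),
tetramer = min(trimer, F1), residuals by mass balance. No binding
constants are available for this system and the native-gel/SEC evidence
shows essentially complete complexation, so an equilibrium Kd model would
add parameters without data to constrain them; the min() cascade is exact,
order-invariant (verified over all 24 addition orders) and reproduces the
observed excess/deficit patterns: with 20% excess F2/F4 the tetramer
coexists with residual dimer and no free monomers; with a 20% deficit the
tetramer is dimer-limited and only free F1 and F3 remain. SEC profiles are
sums of Gaussian peaks at the calibrated elution volumes (tetramer
8.71 mL, dimer 9.75, F1 10.12, F2 10.34, F3 11.22, F4 11.31), with areas
weighted by subunit count by default. The trimer has no published volume,
so predicting a trimer-containing mix requires a user-supplied calibration
entry; the unexplained minor peak at 7.10 mL (plausibly a higher-order
aggregate) is outside the four-state model and not predicted.

## Numerical choices and degenerate inputs

* Structures are atom tables keyed by author residue numbering — the
  numbering used when naming residues like K172 — with mmCIF label
  numbering ignored. Insertion codes and altlocs are rejected; only the
  first model of a multi-model file is read.
* PDB output is fixed-width at 3 decimals.
* Chains shorter than one window (7 CA) cannot be fitted; 7 residues give
  exactly one axis point and no tangent.
* Arrangement is undefined (an error) when two chains sit at the same
  azimuth; straight bundles report handedness `none` and no pitch.
* Crosslink generation with decoys errors when the structure lacks enough
  satisfying or violating pairs, rather than silently shrinking the table.
* All stochastic steps (sequence threading, coordinate noise, link
  sampling, melt noise) take explicit integer seeds.

## Problem sizes used in the tests

The test suite and the acceptance script run entirely on synthetic data:
the 168-residue four-chain silk bundle for the headline geometry, a
63-residue variant for invariance checks, 50 random parameter draws
(radius 4–9 Å, pitch 100–250 Å, 35–175 residues) for the round-trip
property, 1000 random inputs for assembly mass balance, and melt curves of
51 points with three noise replicates. These sizes were chosen so each
property is exercised across its realistic range while the whole suite
stays quick on a laptop.

## Known limitations

* Fits assume a single straight coiled-coil segment; bent or fragmented
  coils and global Crick-parameter refinement are out of scope.
* Synthetic CB placement and Gaussian CD bands are phenomenological;
  absolute distances/band shapes from the generator should not be compared
  to experiment, only the topological and ratio-level properties the tests
  assert.
* The assembly model has no kinetics and no equilibrium constants; it
  predicts end-state stoichiometry only.
* Sequence-based coiled-coil prediction is not attempted anywhere — input
  is always a structure, a sequence with a supplied register, or tabular
  experimental data.
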