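# coilspect

Characterization toolkit for α-helical coiled-coil bundles, built around the
honeybee silk heterotetramer — a four-protein (F1–F4) antiparallel coiled
coil whose assembly proceeds stepwise through an F2+F4 dimer and an
F2F3F4 trimer before the tetramer locks in place.

The package is aimed at structural bioinformaticians working on coiled-coil
models (predicted or experimental) who need to quantify superhelical
geometry, verify register and core packing, confront a model with
crosslinking-MS restraints, and interpret CD/thermal-melt and
size-exclusion evidence about oligomer assembly.

## What it computes

**Crick-parameter synthetic bundles.** An ideal n-helix bundle (n = 2–4) is
generated in closed form from the Crick parameterization. With α =
atan(2π·R0/P), ω0 = ±2π·(rise·cos α)/P and ω1 = 2π/3.5 per residue, the CA
of residue *i* on a chain at supercoil azimuth θᵢ = ω0·i + φ0 and Crick
phase φᵢ = ω1·i + φ1 sits at

    x = R0·cosθ + r1(cosθ·cosφ − cosα·sinθ·sinφ)
    y = R0·sinθ + r1(sinθ·cosφ + cosα·cosθ·sinφ)
    z = rise·cosα·i − r1·sinα·sinφ

where R0 is the superhelical radius, P the pitch and r1 the α-helix radius.
Antiparallel (D) chains are rigid 180° rotations of U chains, preserving
chirality. Every build carries its ground truth (parameters, threaded
heptad register, sequence), which makes the whole analysis stack testable
offline.

**Geometry fitting.** Local helix axes from sliding window-of-7 CA
centroids; total-least-squares superhelical axis; radius (with an analytic
correction for centroid shrinkage on a curved track), pitch and handedness
from the azimuth-versus-axial regression; per-chain U/D orientation;
cyclic arrangement viewed from the positive axis end; axial stagger; rod
extent; and per-residue Crick phase, from which the heptad register a–g is
assigned by scoring all seven cyclic offsets (the a/d core must face the
bundle axis).

**Packing and electrostatics.** Knobs-into-holes contacts from side-chain
centers (a knob's side chain sees ≥ 4 side-chain centers of one other
chain within 7 Å), core-layer alternation along the axis, and interhelical
salt bridges (charged heavy atoms within 4 Å) classified by the heptad
positions of their partners (e.g. c-c, g-c, b-b).

**Crosslinking-MS restraints.** Crosslink tables (CSV) mapped onto a model
with the amine-linker distance restraint (distance < 30 Å, strict), typed
intra/inter, annotated with heptad registers and surface exposure
(positions b, c, e, f, g), and summarised over unique residue pairs.

**CD and thermal melts.** Additive mixture spectra, the 222/209 nm
ellipticity ratio (≈ 0.8 for isolated helices; > 0.9 calls a coiled coil),
and two-state melt fitting — logistic folded fraction with linear
baselines, multi-started nonlinear least squares — reporting Tm and a
cooperativity call.

**Assembly stoichiometry.** The strong-binding sequential model
F2+F4 → dimer, +F3 → trimer, +F1 → tetramer: a min() cascade with exact
mass balance, invariant to the order of addition, plus Gaussian-peak SEC
profile prediction calibrated at the observed elution volumes.

## Worked example

```r
library(coilspect)

# ideal antiparallel silk tetramer: R0 = 5.8 A, P = 153 A, 168 res/chain
model <- build_bundle(silk_params(), seed = 1)
fit <- fit_coiled_coil(model)
fit
#> <cc_fit> coiled-coil geometry fit
#>   radius 5.80 A, pitch 153.0 A, handedness left
#>   chains: F1(U) F2(U) F3(D) F4(D)
#>   arrangement (clockwise from +axis): F1-F3-F2-F4
#>   extent 236.5 A, heptads per chain: 24, 24, 24, 24
```

The fit recovers the generative radius and pitch to well under 1%, labels
the chains U/D/U/D, reads the clockwise F1-F3-F2-F4 arrangement, and counts
24 complete heptads per 168-residue chain.

```r
# crosslink validation: 100 links, a quarter of them decoys beyond 30 A
links <- sample_crosslinks(model, n_links = 100, decoy_fraction = 0.25,
                           seed = 5)
report <- restraint_report(map_crosslinks(links, model, fit))
report$summary
#> # A tibble: 1 x 6
#>   n_unique n_inter n_intra satisfied_fraction surface_fraction n_errors
#>      <int>   <int>   <int>              <dbl>            <dbl>    <int>
#> 1      100      81      19               0.75             0.81        0

# stepwise assembly with a 20% excess of F2 and F4
assemble(1, 1.2, 1, 1.2)
#> # A tibble: 1 x 7
#>      F1    F2    F3    F4  F2F4 F2F3F4 F1F2F3F4
#>   <dbl> <dbl> <dbl> <dbl> <dbl>  <dbl>    <dbl>
#> 1     0     0     0     0   0.2      0        1
```

The satisfied fraction equals the planted 75% exactly, and the excess
mixture leaves only tetramer plus residual dimer — no free monomers, which
is the SEC signature of the real system.

A thin command-line wrapper over the same functions lives at
`inst/cli/coilspect.R` (subcommands `build`, `fit`, `xlms`, `pipeline`).

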