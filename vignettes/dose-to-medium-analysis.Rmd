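---
title: "Comparing dose-to-medium and dose-to-water: models, parameters and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing dose-to-medium and dose-to-water}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dosemedium)
```

## The problem

Monte Carlo dose engines score absorbed dose to the local medium (Dm): each
voxel's energy deposition is divided by the mass of that voxel's actual
tissue. Decades of clinical experience, beam calibration protocols, and
detector readings are, however, referenced to dose-to-water (Dw). The two
quantities differ wherever the medium's electron stopping power differs from
water's — noticeably in cortical bone, marginally in lung and soft tissue —
so a clinic adopting a Monte Carlo planning system must know how large the
Dm/Dw discrepancy is for its plan evaluation indices and its patient-specific
QA passing rates.

`dosemedium` implements that comparison as a reusable pipeline: voxel-wise
Bragg–Gray conversion through density-indexed stopping-power ratios,
dose-volume-histogram (DVH) indices with paired cohort statistics,
prescription-normalised 3-D difference maps, and a local-normalisation
gamma-index engine — exercised entirely on synthetic phantoms with known
ground truth, since no patient data ship with the package.

## The conversion model

Under Bragg–Gray cavity theory, the dose to a small water cavity embedded in
medium *med* is

$$ D_w = D_m \cdot s_{w,med}, $$

where $s_{w,med}$ is the mean unrestricted mass collision stopping-power
ratio of water to the medium over the local electron fluence spectrum.
Evaluating the fluence-weighted integral per voxel requires the particle
spectra a transport engine tracks internally; clinical systems instead apply
a pre-calculated ratio indexed by mass density, and this package does the
same deliberately: `spr_model()` is a piecewise-linear table in density,
clamped outside its anchors. Direct spectral evaluation is out of scope.

The default anchors place tissue-like media at their published ratios near
1 MeV: air (0.0012 g/cm³) at 1.113, lung (0.26) at 0.999, adipose (0.95) at
0.986, water exactly at 1, trabecular bone (1.20) at 1.034, cortical bone
(1.85) at 1.118. Two qualitative facts follow and are enforced by tests: the
ratio stays within 1% of unity for lung-like densities, and exceeds 1.10 for
cortical bone and air. For a structure sitting entirely in cortical bone the
relative D50% shift is $(1 - 1/1.118)\times100 \approx 10.6\%$ on the Dw
scale ($11.8\%$ relative to Dm) — the "up to ~10% in bone" regime reported
for Bragg–Gray conversions. The table is user-replaceable (CSV via
`read_table_csv()`); anchors must be strictly increasing in density, contain
(1.0, 1.0) exactly, and stay within the physically plausible [0.9, 1.3].

Clamping rather than extrapolating outside the table is a safety choice:
metal artefacts or detector materials must not generate unphysical ratios.

CT calibration is the standard two-step chain: a piecewise-linear HU to
relative-electron-density table (`ct_calibration()`, water anchored at
HU = 0), then a continuous electron-density to mass-density fit. The shipped
defaults are a conventional bilinear HU curve with knots at (−1000, 0),
(0, 1), (1000, 1.55), (3000, 2.5) and a density fit that is the identity up
to ED 1 and steepens towards cortical bone (ED 1.695 → 1.85 g/cm³); both are
stand-ins for a scanner-specific table and are documented as replaceable.

## DVH computation and cohort statistics

`compute_dvh()` resamples dose trilinearly onto a 1 mm cubic grid restricted
to the ROI bounding box (nearest-neighbour for the mask, preserving binary
membership) and accumulates a cumulative histogram with a fixed 1 cGy bin
width. $D_{x\%}$ is the smallest dose still covering $x\%$ of the volume,
interpolated linearly between bracketing bin edges; plateaus resolve to the
smallest qualifying dose, the conservative choice for targets. All DVH
tolerances in the tests are one bin (0.01 Gy), since sub-bin behaviour of
clinical systems is not standardised.

Per-index cohort comparison uses the per-plan relative difference

$$ \mathrm{Diff}(\%) = \frac{(D_{x\%})_w - (D_{x\%})_m}{(D_{x\%})_w} \times 100 $$

and reports the cohort mean ± SD of the per-case values (the convention of
per-plan reporting); the difference of cohort means is emitted alongside for
transparency, since the two coincide only approximately. Significance comes
from a two-sided paired t-test on the absolute differences via
`stats::t.test`; zero-variance cohorts are flagged degenerate instead of
producing an undefined statistic. The 0.05 threshold is reported, never used
to gate any computation.

## Difference maps and the gamma engine

The plan-subtraction view is `dose_diff_map()`:
$\mathrm{diff}(\%) = (D_w - D_m)/D_p \times 100$ with $D_p$ the prescription
dose, so maps from different prescriptions share a scale.

`gamma_map()` implements the local-normalisation gamma index: for each
reference voxel at or above the low-dose threshold (default 10% of the
reference maximum; a percent-of-prescription mode is available since
protocols differ),

$$ \gamma = \min_r \sqrt{ \frac{|r - r_{ref}|^2}{\mathrm{DTA}^2} +
   \frac{(D_e(r) - D_r)^2}{(\mathrm{DD} \cdot D_r / 100)^2} }, $$

with the evaluated dose interpolated trilinearly and a voxel passing when
$\gamma \le 1$ (the boundary passes, making a uniform 3% offset under
3%&3 mm a clean closed-form boundary case: 100% at 3%&3 mm, 0% at 2%&2 mm).

Numerically the minimisation is a dense lattice search followed by a bounded
refinement:

* a coarse pass on a lattice of pitch DTA/5 within a search radius of
  2 × DTA (beyond which the distance term alone gives $\gamma \ge 2$, so the
  cap cannot change pass/fail), scanned nearest-first so voxels whose running
  minimum is below the next distance term drop out — an exact cut;
* a refinement pass that revisits every coarse cell whose candidate value,
  minus the largest possible within-cell change of both terms, could still
  undercut the voxel's current best. The dose-term change is bounded by a
  cell-local Lipschitz bound on the trilinear interpolant (dilated one cell
  for soundness), which keeps the trigger set small in flat dose regions
  where local normalisation would otherwise make a global bound useless.
  Triggered cells are searched exhaustively at pitch DTA/50 (2-D; DTA/25 in
  3-D, where map accuracy at the detector-plane level is not required).

This makes the default configuration agree with an exhaustive brute-force
search at pitch DTA/50 to better than $10^{-3}$ in $\gamma$ on the planar
instances the test suite checks. Candidate positions outside the evaluated
grid are skipped, not zero-filled; cells whose centre is off-grid but which
straddle the boundary are still refined under a distance-only bound.

## The synthetic study conditions

`phantom_preset()` ships four conditions chosen to mirror the cohorts such a
clinical comparison covers, on a 3 mm cubic dose grid:

* `water` — a homogeneous tank; the null condition under which the entire
  pipeline must return exact zeros and 100% passing rates;
* `npc` — head-like anatomy, 70 Gy, nine equally spaced beams, cortical bone
  (1.85 g/cm³) abutting the target, cord/parotid OARs;
* `lung` — thorax, 65 Gy, seven beams, 0.26 g/cm³ lungs with the target in
  lung;
* `bone-met` — vertebral metastasis, 25 Gy, five-to-seven-beam class, target
  in trabecular bone (1.2 g/cm³) with a cortical shell.

`make_dose()` is an analytic beam superposition — flat apertures matched to
the PTV projection, Gaussian penumbra (5 mm), exponential depth attenuation
(0.004/mm, a 6 MV-like effective coefficient) — normalised so the PTV D50%
equals the prescription within 0.5%. It is deliberately not a transport
simulation: the analysis stages need realistic conformal dose shapes with
known ground truth, not transport fidelity. Optional multiplicative Gaussian
noise (e.g. 3%, the typical per-control-point Monte Carlo statistical
uncertainty) emulates MC noise; every random draw flows through one explicit
seed and generators restore the caller's RNG state.

What the phantoms do not emulate: CT texture and artefacts, chemical
composition beyond density, beam modelling (MLC sequences, scatter,
build-up), detector-array sampling. Passing tests therefore demonstrate the
correctness of the *analysis* — conversion, DVH, statistics, gamma — under
controlled conditions, not the clinical magnitude of Dm/Dw differences for
any particular patient, which depends on anatomy and planning system.

`perturb_measurement()` turns a plan's detector plane into a pseudo
measurement (rigid in-plane shift, global scale error, seeded noise) so that
QA-style gamma sweeps have something realistic to disagree about.

## Sizes, tolerances and other numerical choices

* Grids are stored x-fastest with voxel-centre geometry in mm; all pairwise
  operations require identical geometry and refuse silently mismatched
  grids (`resample_to()` makes any mismatch explicit).
* Test phantoms run at 24–32 voxels per axis; the acceptance script uses
  32 × 32 × 12–14. These sizes keep every property independent of grid
  extent while the full suite stays fast.
* The type-I calibration of the paired t-test uses the index-noise model
  directly (true value, 3% multiplicative noise in both arms, n = 10, 1000
  replicates, 99% binomial acceptance band) rather than 10,000 full phantom
  pipeline runs; the pipeline's null behaviour is covered separately by the
  water-identity condition, so the calibration isolates the statistic.
* DVH bin width is fixed at 1 cGy and the sampling grid at 1 mm (0.1 cm),
  matching common planning-system conventions; both are arguments where a
  user needs otherwise.
* NRRD is the persisted format (attached or detached header, raw or ascii
  encoding, axis-aligned `space directions` only); the dose/density unit
  travels in a `dosemedium:unit` key. Masks rasterise from planar contour
  polygons under the voxel-centre even-odd rule, so nested contours carve
  holes, as in RT-STRUCT semantics.

## Known limitations

* The stopping-power ratio is density-indexed only; two media with equal
  density but different composition get the same ratio. This is the
  pre-calculated-table approximation the package models, not a bug, but it
  bounds fidelity in exotic materials.
* Whether a planning system applies the conversion below some density cutoff
  (air cavities) varies; this implementation clamps to the air anchor.
* The gamma low-dose threshold convention (of maximum versus of
  prescription) differs between clinics; both are supported, default
  percent-of-maximum.
* Planar measurement geometry is generic: no detector spacing, volume
  averaging, or array calibration is modelled.
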