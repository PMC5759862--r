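---
title: "Planning model and methods in ionplan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Planning model and methods in ionplan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`ionplan` is a desk-scale treatment-planning pipeline for comparing proton
and helium-ion pencil-beam-scanning plans on synthetic intracranial
phantoms: stylized meningioma-like geometries with a planning target volume
(PTV) hemmed in by serial organs at risk (OARs) such as brainstem, chiasm,
optic nerves and eyes. This vignette is the package's own account of its
models, parameters and design choices.

## The planning problem

Pencil beam scanning delivers dose as a weighted sum of narrow beams
("spots"), one weight per spot, each characterized by a lateral position in
the beam's-eye view and an energy layer (a Bragg-peak range in water).
Planning means choosing non-negative spot weights so that the
biologically weighted dose meets a prescription in the PTV
(1.8 Gy(RBE) per fraction here, over 28-30 fractions) while respecting
dose-volume constraints on the OARs. All dose bookkeeping is per fraction;
reported DVH parameters are scaled to the full treatment dose (prescribed
fraction dose times the number of fractions).

The pipeline mirrors a two-stage clinical workflow:

1. **Stage 1** optimizes a proton plan under the fixed clinical RBE of 1.1.
   Its achieved per-OAR D5 values (the minimum dose to the hottest 5% of
   each OAR) are frozen as caps.
2. **Stage 2** re-optimizes, under those identical caps, proton and
   helium plans with a variable, LET-dependent RBE model. The helium plan
   uses a ripple filter by default.

Two advantages motivate the staging: the stage-1 plan is directly
comparable to fixed-RBE clinical practice, and the derived caps transfer a
consistent sparing level to both ions. D5 (rather than D2) defines the
maximum-dose statistic throughout; this choice originates in the
statistical robustness of D5 under Monte-Carlo dose noise and is kept here,
although the analytic engine is noise-free, for comparability.

## Synthetic phantoms

`make_case()` builds four case templates on a voxel grid of
64 x 64 x 40 voxels at 1 x 1 x 3 mm^3 (defaults; anatomy scales with the
grid so reduced grids can be used in tests). A water-like elliptical body
(relative stopping power 1 +/- 2% voxel noise, seeded) surrounds an
ellipsoidal PTV and stylized OARs (spheres, z-cylinders, capsules):

- **A** — two opposed fields (180 degrees), 29 fractions; brainstem,
  temporal lobes, optical system.
- **B** — two fields 75 degrees apart, 30 fractions; brainstem, chiasm,
  both optic nerves, an ear-region nerve. The field pair is oriented
  (255 and 330 degrees) so that neither field's exit path crosses a serial
  OAR — the standard clinical criterion for angle selection, and the role
  the out-of-plane second field plays in the corresponding clinical
  configuration that the coplanar approximation replaces.
- **C** — two fields 32 degrees apart, 30 fractions; brainstem, chiasm,
  right optic nerve.
- **D** — a single field, 28 fractions; a small shallow ocular PTV whose
  proximal surface sits about 11 mm deep, with the left optic nerve
  partially inside the PTV (a declared overlap) and the eye adjacent.

Every template keeps at least one OAR within 5 mm of the PTV. Tissue
radiosensitivity is assigned per ROI as the photon alpha/beta ratio:
3.7 Gy for the PTV (a meningioma-typical value) and 2.0 Gy for all normal
tissue and OARs.

What the phantoms emulate is the *proximity structure* of the clinical
cases — abutting serial OARs, entrance/exit channel relations, a shallow
single-field ocular case — not patient anatomy: there is no bone or air
heterogeneity by default (a bone shell is available as an option), no CT
calibration, and the geometry is convex and smooth. Results on these
phantoms therefore demonstrate the planning *mechanics* (constraint
satisfaction, the differential-RBE effect, the sign structure of
helium-versus-proton DVH differences), not patient-specific dosimetry.

## Analytic beam model

The depth-dose of a single pencil beam uses the classical power-law
range-energy parameterization: an unstraggled curve proportional to
`(R - z)^(1/p - 1) + k (R - z)^(1/p)` with `p = 1.77`, convolved with a
Gaussian range-spread. The spread combines intrinsic straggling
(`0.012 (R/10)^0.935` cm, halved for helium) with a beamline
momentum-spread floor (0.8 mm protons, 0.4 mm helium). The floor matters:
at the shallow ranges of these fields (20-45 mm) the intrinsic straggling
alone is only ~0.2-0.4 mm, and 2 mm energy-layer spacing would otherwise
produce ~8% SOBP ripple that no clinical plan exhibits. The smaller helium
floor preserves the measured ordering that helium distal falloffs
(80%-20%) are roughly half the proton ones at equal range. A fixed-point
correction nudges the nominal range until the curve's distal 80% point
(R80) matches the requested range within one 0.5 mm grid step.

Helium curves add an exponential fragmentation tail beyond the peak, 2% of
the peak dose decaying over 30 mm. Deep high-energy helium fields show
tails up to 5-10%, but at 40-70 MeV/u (the energies of these shallow
fields) the integrated nuclear-interaction probability is small; 2% is
representative there. Protons carry no tail. The ripple filter is modelled
as convolution of the depth-dose with a 2 mm Gaussian; it is applied to
helium by default (its narrow peaks otherwise leave target dose ripple at
2 mm layer spacing) and accepted with a warning for protons, where it has
no clinical role. Energy layers are an arithmetic sequence of ranges
covering the PTV's water-equivalent depth interval at 2 mm spacing (1 mm
is the documented tighter option for shallow helium targets).

Dose-averaged LET versus depth is an analytic monotone template,
`LET(z) = L_e + (L_p - L_e) (z/R)^6` up to the peak: flat through the
plateau, rising sharply near the peak. Defaults (configurable, inside
published therapeutic brackets of ~1-10 keV/um for protons and
~4-40 keV/um for helium): protons 2 -> 9 keV/um — the entrance value
appropriate for the low beam energies of shallow fields — and helium
4 -> 40 keV/um. Past the peak, the helium LET relaxes over ~5 mm toward
0.1 x the peak value: the tail dose is carried by light fast fragments
whose dose-averaged LET is a few keV/um. The proton curve holds its peak
value there, which is inconsequential since the proton tail dose vanishes.

Lateral spread grows with depth as
`sigma(z) = sqrt(sigma0^2 + (c R (z/R)^1.8)^2)` with `c = 0.05` for
protons and half that for helium, so helium spots are strictly narrower at
any positive depth at equal range; the surface spot sigma defaults to
3 mm.

## Influence matrices and mixed-field composition

A deterministic ray-cast plus Gaussian-kernel engine replaces Monte-Carlo
transport. Water-equivalent depth (WED) is the path integral of relative
stopping power, ray-marched per voxel with trilinear sampling at 0.5 mm
steps (compiled code). Each influence entry is
`depth-dose(WED) x 2-D lateral Gaussian(off-axis distance; sigma(WED))`;
entries beyond 3.5 lateral sigmas or below 1e-4 of their column maximum
are dropped for sparsity (both cutoffs configurable). Spots cover the
PTV's beam's-eye-view projection plus one lateral sigma margin at 4 mm
spacing.

Three sparse stores share one sparsity pattern: physical dose `D`,
LET-weighted dose `L = D x LET`, and alpha-weighted dose
`A = D x (alpha/alpha_x)` evaluated with the receiving voxel's tissue
alpha/beta. Accumulation is the mixed-field contract: physical dose is
linear in the weights, while per-voxel dose-averaged LET and
alpha/alpha_x are the dose-weighted means `(L w)/(D w)` and
`(A w)/(D w)` where dose is positive. The beta term uses the constant-beta
closure `beta = beta_x` (the model needs only the alpha/beta ratio, and
constant beta is the simplest consistent completion; `rbe_weighted_dose()`
accepts any beta-ratio grid if an alternative averaging is wanted).

## Biological dose

The variable RBE model is of the phenomenological linear-quadratic class:
`alpha/alpha_x = 1 + lambda_ion * LET_d / (alpha_x/beta_x)` with
`lambda_p = 0.08` and `lambda_He = 0.15` Gy um/keV, beta unchanged. The
RBE-weighted dose per voxel inverts the photon iso-effect equation

    alpha_x D_RBE + beta_x D_RBE^2 = (alpha/alpha_x) alpha_x d + beta_x d^2

giving `D_RBE = (-r + sqrt(r^2 + 4 r a d + 4 d^2))/2` with
`r = alpha_x/beta_x`, `a = alpha/alpha_x`. Only the alpha/beta ratio
enters. RBE is reported only at dosed voxels (it is undefined at zero
dose). The fixed clinical proton weighting `D_RBE = 1.1 d` is a separate
mode, rejected for helium. These coefficient choices put mid-SOBP RBE
around 1.05-1.1 for protons and 1.35-1.45 for helium at the 1.8 Gy(RBE)
fraction dose, with entrance-channel normal-tissue RBE near 1.03 (p) and
1.2-1.25 (He).

The *differential effect* — the tumour-to-normal-tissue RBE contrast that
favours ions in the target — is quantified by
`differential_rbe_ratio()`: the median per-voxel RBE in the PTV (alpha/beta
3.7 Gy, in-field LET and dose) divided by the median RBE in a proximal
normal-tissue shell (alpha/beta 2.0 Gy, its LET and dose). The shell is
the entrance-channel tissue 5-20 mm upstream of the PTV inside each
field's footprint, excluding PTV and OARs; the 5 mm gap keeps it clear of
the proximal SOBP shoulder so that it genuinely represents low-LET
surrounding tissue. On the synthetic templates the helium ratio exceeds
the proton ratio by roughly 15-22% with the default coefficients.

## Optimization

The objective is a sum of quadratic penalties on per-fraction biological
dose, each a mean over its voxel set: PTV deviation from the prescription
(weight 100), PTV overdose above 107% of the prescription (weight 1000),
per-OAR overshoot of the D5 cap on the hottest-5% voxel set (weight 50),
and a per-OAR low-dose term (weight 1) that shrinks the dosed OAR volume.
The D5 point constraint is non-differentiable, so its smooth surrogate
penalizes the voxels of the frozen hottest-5% set, re-identified each
outer iteration. Declared PTV-overlap regions follow PTV priority: OAR
penalties act only on the OAR voxels outside the PTV. The weights were
fixed once against the stated plan-quality goals (D5_PTV at most 107%,
median PTV dose within 2% of prescription) across the four templates.

The solver is projected bound-constrained quasi-Newton (L-BFGS-B, weights
bounded below by zero, gradient tolerance 1e-6). Outer iterations freeze
the per-voxel effective RBE and hot sets and solve the smooth subproblem;
for variable-RBE plans the effective RBE is recomputed from the current
weights with a 0.5 damping to stabilize the fixed point, warm-started from
the stage-1 solution where available. Steps are accepted only while the
true objective is non-increasing; the trace is stored on the plan.
Initialization is deterministic (uniform weights scaled to reach the
prescription at the PTV's central voxel), so the whole pipeline is a pure
function of the case seed. The fixed-RBE subproblem is convex; random
restarts agree to 1e-4 relative in the tests.

Stage-2 caps equal the stage-1 achieved D5 values with one amendment: a
floor of 0.15 x the fraction prescription. Without it, an OAR that the
stage-1 proton plan happens to leave essentially undosed (e.g. distal to a
field, where protons stop completely) would carry an accidental near-zero
cap that forbids the helium fragment tail outright and pushes the helium
plan into clinically worse entrance channels; a tolerance-level floor
keeps the two stage-2 plans comparable. If a stage-2 plan still exceeds a
cap by more than 5%, that cap is relaxed in multiplicative 5% steps (at
most three, each logged in the cap provenance).

## Evaluation

`compute_dvh()` bins cumulative dose-volume histograms (default bin
0.05 Gy(RBE); voxel volumes are uniform so counting suffices). Dx is the
minimum dose to the hottest x% of an ROI, computed as a sorted-voxel
quantile with linear interpolation between voxel ranks (the convention is
stated because published tables rarely specify theirs). Tables report
D5, D10, D20, D33, D50, D66, D75, D95 at full treatment dose;
difference tables subtract elementwise (first-named plan minus second) and
can be rendered with one decimal and a comma decimal mark. Dose-level
masks threshold at >10/20/50/80/95/107% of the prescribed dose (nested by
construction); dose-difference maps threshold each direction of the
plan-to-plan difference at >3/6/9/12/15/18 Gy(RBE) with disjoint supports.

## Numerical choices and degenerate inputs

Depth curves live on a 0.5 mm grid; WED sampling steps are 0.5 mm with
voxel-center trilinear interpolation (boundary ownership by voxel center).
The range-correction loop stops at 0.2 mm. Rays that miss the grid return
zero WED with a warning. Empty ROI masks, negative weights, out-of-range
Dx percentages, non-positive alpha/beta and unknown template labels are
rejected with explicit messages. L-BFGS-B results are clamped at the zero
bound to absorb solver rounding. Zero-dose voxels are excluded from RBE
and LET maps (reported as 0).

## Problem sizes

Defaults were chosen so a full template runs in well under a minute on one
core: 64 x 64 x 40 voxels, 4 mm spot spacing, 2 mm layer spacing give
500-1600 spots and 3-6 million influence entries per ion. Unit tests use
48 x 48 x 20 grids with identical anatomy proportions.

## Known limitations

- The transport engine has no nuclear halo, no heterogeneity-induced range
  perturbation beyond WED scaling, and Gaussian-only lateral profiles.
- The RBE coefficients are a documented parameterization of the stated
  functional class, not a fit to any published cell-survival dataset;
  absolute RBE values should be read comparatively, not clinically.
- The phantoms are convex water bodies; all statements about OAR sparing
  are statements about proximity structure, not anatomy.
- Out-of-plane (couch-kicked) fields are approximated coplanar, which is
  why template B's angles are rotated to keep exit channels clear.
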