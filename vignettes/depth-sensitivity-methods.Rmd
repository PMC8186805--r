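---
title: "Methods: simulating DOT depth sensitivity on layered head phantoms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating DOT depth sensitivity on layered head phantoms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Functional near-infrared spectroscopy (fNIRS) and diffuse optical
tomography (DOT) measure cerebral haemodynamics from source-detector
optode pairs ("channels") on the scalp.  How deeply a channel samples
the head — and how that depth profile changes with the source-detector
separation distance — governs sensor placement and anatomical
interpretation, and it changes with head anatomy across development.
`dotsens` implements the full simulation chain needed to characterise
these depth-sensitivity profiles on synthetic layered head phantoms:

1. **Phantoms** (`make_slab_phantom`, `make_layered_head_phantom`):
   voxelised label grids with age-parameterised layer thicknesses.
2. **Photon transport** (`simulate_fluence`): voxel Monte Carlo with
   Henyey-Greenstein scattering, continuous Beer-Lambert weight
   attenuation, Fresnel boundaries and 50 x 0.1 ns time gates.
3. **Optode geometry** (`construct_10_10`, `construct_10_5`,
   `enumerate_all_pairs`, `centered_adjacent_channels`): virtual
   10-10/10-5 montages built from seven cranial fiducials on the
   discrete scalp surface.
4. **Sensitivity profiles** (`pmdf`, `depth_profile`, `hwhm_location`,
   `profile_experiment`): channel sensitivity volumes (the photon
   measurement density function, PMDF) binned by sampling depth, with
   between-channel variance and half-width-half-maximum (HWHM)
   summaries per separation distance.
5. **Orchestration** (`experiment_config`, `run_experiment`): seeded,
   cached, manifest-logged end-to-end runs.

# Phantoms: what they emulate and what they do not

The spherical phantoms are concentric shells — skin, skull, dura, CSF,
gray matter, white-matter core — on an isotropic voxel grid (1 mm by
default).  Layer boundaries quantise to the nearest voxel edge so that
1 mm voxels reproduce integer thicknesses exactly.  The presets fix the
extracerebral (scalp-to-cortex) distance at 8 mm for the 3-month preset
and 13 mm for the adult preset, the two values with direct literature
anchors; the neonate (7 mm) and 2-year (10 mm) presets interpolate
plausibly and are configurable rather than claimed as anatomical truth.
Outer radii (55/65/75/85 mm) correspond to head circumferences of
roughly 35-53 cm.

Spheres reproduce the *layered* structure that dominates depth
sensitivity (a low-scattering CSF layer between skull and cortex, an
absorbing white-matter core) but not cortical folding, local thickness
variation, or left-right/front-back asymmetry.  Consequently the
between-channel variance measured on a phantom reflects Monte Carlo
noise and within-window separation spread, not anatomical variability;
passing the variance-ordering tests demonstrates the machinery, not a
population prediction.  Full spheres (not hemispheres) keep every
optode's inward normal well defined and make scalp geodesics closed
curves, matching the closed-head topology.

# Optical media

The shipped media table holds per-tissue absorption `mu_a`, scattering
`mu_s`, anisotropy `g` and refractive index `n` at 690 nm, one
wavelength only (the wavelength is metadata, not an input to the
physics).  All tissues share `n = 1.37`, so internal interfaces are
index-matched and Fresnel reflection happens only at the tissue-air
boundary; eyes carry the water-like CSF row and non-myelinated axons
the white-matter row, so the minimal sphere presets omit them without
loss.  Air is non-interacting and traversed ballistically.

**Similarity scaling.**  The extracerebral tissues are extremely
forward-scattering (`mu_s` 80-100 mm^-1 with `g = 0.99`), which makes
the mean Monte Carlo step 0.01 mm: tens of thousands of steps per
photon.  `similarity_scale()` replaces `(mu_s, g)` by
`(mu_s (1 - g), 0)`, the similarity relation of transport theory, which
preserves the reduced scattering `mu_s'` that governs diffuse light and
accelerates CPU runs by roughly two orders of magnitude at the cost of
fidelity within a transport length of the source.  The package's
desk-scale experiments use it (it is a configuration flag); all physics
validation (diffusion slope, reciprocity, Beer-Lambert, conservation)
runs on the unscaled table.

# The Monte Carlo kernel

Photons launch with unit weight at an optode, along the inward surface
normal.  Free paths are sampled against the local `mu_s`; the weight
decays continuously as `exp(-mu_a s)` along each voxel-traversal
segment (the "albedo-weight" scheme used by the voxel Monte Carlo
family, which has lower variance than discrete absorption events).
Each segment deposits the exact weight integral
`w (1 - exp(-mu_a s)) / mu_a` into the traversed voxel and the time
gate of the segment's start (gates are 0.1 ns; a segment is at most a
voxel diagonal, ~0.01 ns, so gate smearing is negligible).  Fluence is
normalised per launched photon and per voxel volume (mm^-2): the
standard unbiased track-length estimator of the 2-point Green's
function.

Scattering angles come from the Henyey-Greenstein inverse transform
(`sample_scatter_cos`), azimuth uniform.  At a tissue-air interface the
photon reflects specularly with the unpolarised Fresnel probability
(total internal reflection included) or escapes; a `matched` boundary
mode disables reflection for oracle comparisons.  Photon time advances
as `s n / c`; photons end by escape, by the 5 ns window, or by Russian
roulette below weight 1e-4 with survival probability 0.1 (survivors'
weights are divided by 0.1, keeping the estimator unbiased).

**Bookkeeping.**  Every run returns `absorbed`, `escaped`,
`alive_at_tmax`, `roulette_killed` and `roulette_boost`;
`absorbed + escaped + alive + killed - boost` equals the launched count
to floating-point rounding (~1e-12 relative), asserted on every test
run.  The generator is a self-contained PCG32 stream, so a seed plus a
configuration reproduces output bit for bit on any platform.

**Validation.**  Three independent oracles check the kernel: (i)
ballistic Beer-Lambert attenuation in an absorbing, non-scattering
slab; (ii) the extrapolated-boundary dipole solution for a homogeneous
semi-infinite medium (`diffusion_cw_oracle`), against which the
log-fluence-versus-distance slope on a gray-matter half-space agrees
within a few percent at 1e6 photons (the acceptance band is 15%); and
(iii) source-detector reciprocity between a top-face and a side-face
launch in an asymmetric block, within 3 Monte Carlo standard errors.

# The montage and its shipped enumeration

The 10-10 construction follows the standard proportional-arc recipe
from seven fiducials (Nz, Iz, Vz, LPA, RPA, LMa, RMa): the sagittal
curve Nz-Vz-Iz and coronal curve LPA-Vz-RPA subdivided at 10%, a closed
outer ring through Nz/LPA/Iz/RPA, a closed circumferential ring through
Fpz/T7/Oz/T8, and six transverse rows (AF, F, FC, CP, P, PO) spanning
the circumferential ring — 81 positions, forced by the curve table.

The published 10-5 montage this package targets contains 358 positions
and 251 centred channels per tier, but its exact curve enumeration is
not published in sufficient detail to re-derive uniquely.  `dotsens`
therefore ships a fixed, deterministic reconstruction whose counts are
forced by construction and verified, not assumed:

* **10-5 set (358)** — every curve subdivided at half spacing (sagittal
  and coronal 21 each, closed rings 40 each, transverse rows 17 each),
  plus eight intermediate transverse rows (AFp through POO, 17 each),
  an intermediate lateral ring between the outer and circumferential
  rings (40), and a 13-position mastoid arc LMa-to-RMa around the
  occiput.  Shared anchors are counted once; the total is
  81 + 277 = 358 distinct positions.
* **Centred channels (251 per tier)** — for each 10-10 position, the
  flanking pairs along every montage curve through it, along the six
  meridional chains, and along the oblique (unit-diagonal and
  knight-step) chains of the montage grid: 254 symmetric combinations,
  minus the three centred on the nasion and preauricular fiducial
  positions, whose pairs would span the face and the ears.  At the
  10-10 tier the flanking pair are the adjacent 10-10 electrodes; at
  the 10-5 tier the adjacent 10-5 electrodes, halving the separation —
  which reproduces the ~2:1 ratio of mean separations between the two
  tiers.

Channels centred on a 10-10 position trace their scalp path through
that position; `midpoint_offset_mm` (half the arm-length difference)
records how far combinatorial centring deviates from geometric
centring.  On spherical phantoms the oblique combinations deviate by up
to ~25% of the path (montage rows compress toward the front and back),
so no midpoint filter is applied by default; a strict `tolerance`
argument is available.

**Separation distance.**  The package defines a channel's separation as
the full scalp geodesic between its optodes, which makes the mean
separations of the two centred tiers land in a ~2:1 ratio as published;
a `separation = "half"` switch in `enumerate_all_pairs` preserves the
alternative half-path reading.

# Scalp geodesics

The scalp surface is the set of air-facing voxel face centres, joined
by edges up to 3.2 voxel lengths (a third-order neighbourhood).  This
keeps the shortest-path metric within a few tenths of a percent of true
geodesics and — importantly — stops shortest paths from drifting
laterally off symmetry planes, which coarser neighbourhoods allow
(a chamfer-metric artifact: off-plane diagonal moves can undercut
in-plane ones).  Optodes are placed by interpolating along a curve at
exact arc length, then snapping to the nearest surface point; the
montage therefore requires the local inter-optode spacing (about 4% of
a curve length) to exceed roughly one voxel, which the shipped presets
satisfy at 1-2.5 mm voxels.  Ties between equal-length paths resolve
deterministically by graph construction order.

# Profiles, variance and HWHM

A channel's sensitivity volume is the voxelwise product of its source
and detector gate-summed fluence volumes (the PMDF / 3-point Green's
function), deliberately *not* normalised by the source fluence near the
detector.  Sampling depth is the Euclidean distance from the channel
location (the halfway point of the scalp path) to each voxel centre;
profiles average the PMDF over head voxels in 1 mm bins `(k-1, k]` for
k = 1..100.  Averaging across channels happens on the linear scale by
default — the log transform is applied for display — with
`average = "log"` exposing the alternative order of operations; the
per-bin statistic is the mean, with `statistic = "sum"` as the
alternative.  The HWHM location scans from the profile peak for the
first bin *strictly* below half the maximum, without interpolation (the
1 mm bin already matches the profile resolution); flat profiles report
"no crossing" rather than a value.  HWHM is computed per channel and
then averaged (the default), or on the channel-averaged profile.

On the adult-preset sphere at desk scale (2 mm voxels, 1e5 photons per
optode, similarity-scaled media, an apex source with detector arcs
along four meridians) the experiment reproduces the canonical
separation-distance patterns: the profile peak falls monotonically by
almost six orders of magnitude from 10 to 60 mm separation while the
mean HWHM location grows from ~6 to ~26 mm, and on the infant preset
the between-channel spread of the log profiles at 50 mm separation is
about three times that at 20 mm.  These are the quantities the test
suite asserts; no numbers beyond what the tests and the acceptance
script compute are claimed.

# Problem sizes and numerical choices

The package's own experiments run at deliberately modest sizes chosen
as a workstation-scale design point: montage geometry on 2-2.5 mm
voxel spheres (~20k-35k surface faces), physics oracles at 1e6 photons
on a 90 x 90 x 45 mm half-space, profile experiments at 1e5 photons per
optode over 45 optodes.  The cluster-scale reference configuration
(`make_demo_config("cluster")`: full 358-optode montage, 1e8 photons,
1 mm voxels, unscaled media) is expressed in the same configuration
object and is intended for batch hardware.

Other numerical choices: log base 10 for sensitivity display (the base
only rescales, never reorders); launch direction along the inward
surface normal; detection floor 1e-12 in `log_sensitivity` (flagged,
not silently clamped); roulette threshold 1e-4 with survival 0.1;
per-optode seeds are `base seed + stable optode ordinal`, so extending
an optode set never perturbs existing simulations; the fluence cache is
keyed by a hash of the full configuration and refuses to mix
configurations.

# Known limitations

* Spherical phantoms carry no cortical geometry; tissue-resolved
  sensitivity fractions and image reconstruction are out of scope.
* The 10-5 enumeration is a reconstruction calibrated to the published
  montage sizes; individual intermediate-position labels are systematic
  rather than canonical nomenclature.
* Internal air cavities are treated as escape surfaces (with Fresnel
  reflection); the shipped phantoms contain none.
* Specular reflection at photon entry is neglected (sources sit on the
  tissue surface).
* Segment time-gating uses the gate of the segment start; at 0.1 ns
  gates and sub-voxel segments the misassignment is negligible.
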