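# dotsens

Depth-sensitivity profiling for diffuse optical tomography (DOT) on
synthetic layered head phantoms.

fNIRS/DOT channels measure cerebral haemodynamics from pairs of scalp
optodes; how deeply a channel samples the head depends on the
source-detector separation distance and on the head's layered anatomy,
which changes dramatically from infancy to adulthood.  `dotsens` is for
researchers who need those depth-sensitivity profiles without access to
cluster-scale forward-modelling pipelines: it simulates near-infrared
photon transport through segmented head volumes with a voxel Monte
Carlo kernel, places virtual 10-10/10-5 optode montages from seven
cranial fiducials, and characterises channel sensitivity versus
sampling depth as a function of separation distance.

The quantities at the core of the package:

* **Fluence** `phi_s(r)` — the 2-point Green's function of one optode,
  estimated per voxel and 0.1 ns time gate by a track-length estimator
  (weight x path length per launched photon per voxel volume), with
  Henyey-Greenstein scattering (anisotropy `g`), continuous
  Beer-Lambert weight attenuation (`mu_a`), free paths against `mu_s`,
  and unpolarised Fresnel reflection at the tissue-air boundary.
* **Channel sensitivity (PMDF)** `S(r) = phi_source(r) x phi_detector(r)`
  — the 3-point Green's function, unnormalised.
* **Depth profile** — the mean of `S` over head voxels in 1 mm
  sampling-depth shells `(k-1, k]` around the channel location (the
  halfway point of the scalp geodesic between the optodes), with
  between-channel standard errors and the **HWHM location**: the first
  depth at which the profile drops strictly below half its maximum.

The montage construction is geometry-forced: 81 positions from the
10-10 curves, 358 from the 10-5 refinement, 63,903 = C(358, 2) scalp
paths from all-pairs enumeration, and 251 channels per tier centred on
10-10 electrode locations.

## Worked example

A workstation-scale experiment on the adult-preset sphere phantom
(85 mm radius, 13 mm scalp-to-cortex, 2 mm voxels): an apex source with
detector arcs along four meridians, 1e5 photons per optode,
similarity-scaled optical media:

```r
library(dotsens)
cfg <- experiment_config(phantom = "adult", voxel_size = 2,
                         photons = 1e5, seed = 5, n_meridians = 4,
                         out_dir = "run_adult")
res <- run_experiment(cfg)
res$experiment$hwhm
```

```
   separation_mm  hwhm_mm         peak n_channels
1             10  5.70000 1.805047e-04         40
2             15  8.02500 1.980868e-05         40
3             20 10.65217 3.983090e-06         46
4             25 13.89286 6.585753e-07         56
5             30 15.50000 1.895079e-07         58
6             35 18.83333 6.344538e-08         48
7             40 21.01613 2.466137e-08         62
8             45 23.17045 8.946730e-09         88
9             50 24.62000 3.736687e-09         50
10            55 25.17045 1.506213e-09         88
11            60 25.58889 7.506035e-10         90
```

Reading the table: as the source-detector separation grows from 10 to
60 mm, the peak of the mean sensitivity profile falls by almost six
orders of magnitude (signal loss), while the HWHM location deepens from
~6 to ~26 mm (the same fractional sensitivity reaches deeper tissue) —
the fundamental depth-versus-signal trade-off that governs separation
choices in fNIRS probe design.  `run_experiment` also writes tidy CSVs
(`profiles.csv`, `hwhm.csv`, `channels.csv`) and a manifest, and caches
one fluence volume per optode so interrupted runs resume.

Montage construction on any segmented head volume with fiducials:

```r
ph   <- make_layered_head_phantom("adult", voxel_size = 2)
surf <- extract_scalp_surface(ph$volume)
m10  <- construct_10_10(surf, ph$fiducials)   # 81 positions
m5   <- construct_10_5(surf, m10)             # 358 positions
ch   <- centered_adjacent_channels(m5, "10-10")  # 251 channels
ap   <- enumerate_all_pairs(m5)               # 63,903 scalp paths
```

A thin command-line front end is included at `inst/cli/dotsens.R`
(`phantom`, `optodes`, `simulate`, `run` subcommands).

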