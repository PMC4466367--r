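---
title: "Geometric modelling of direct DNA strand breaks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Geometric modelling of direct DNA strand breaks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dnabreaksim)
```

## The scientific question

When ionizing particles traverse chromatin, the probability that an
individual energy-deposition event breaks a DNA strand is, to first order,
a *geometric* quantity: the chance that the event lands inside a
sugar-phosphate group. This package isolates that geometry. It models the
A-, B- and Z-DNA double helices with their distinct dimensions, packs them
identically into nucleosomes, chromatin fibers and an annular region of
interest (ROI), and scores strand breaks for synthetic event fields. No
radiation chemistry (OH• attack) and no electron/ion transport physics is
simulated; damage here is *direct* damage only, and yields are meaningful
relatively (across conformations and beam parameters), not absolutely.

## The hierarchical geometry

Five organisation levels, all lengths in nm and angles in degrees:

1. **Target.** Each strand of each base pair owns one target: an angular
   sector of a hollow cylinder coaxial with the helix, inner radius at the
   base-pair core (`bp_diameter/2`), outer radius at the helix surface
   (`dna_diameter/2`), aperture and height per conformation. The target
   height is deliberately smaller than the axial step so that consecutive
   targets cannot touch when the helix bends. The sector volume
   `(α/360)·π·(r_max²−r_min²)·h` gives 0.12 / 0.13 / 0.10 nm³ for A/B/Z.
2. **Double helix.** Strand 1 targets advance by the signed twist
   `±360/bp_per_turn` per base pair (negative, i.e. left-handed, for Z).
   The helix angle is implemented as a single-valued function of arc
   length around the closed nucleosome loop, and strand 2 is that same
   function rotated 180° about the helix axis and translated along it by
   the tabulated inter-strand axial shift. This reading of the axial shift
   (its published definition is ambiguous) is the only one of the
   candidates we examined that keeps the two strands' targets disjoint for
   all three conformations; wherever opposite-strand targets overlap in
   height their sector centres are then ≥160° apart, and the loop-closure
   twist defect (one loop's total twist is not a multiple of 360°) is
   confined consistently to the arc origin for both strands.
3. **Nucleosome.** The base pairs wrap two circular loops whose radius
   follows from arc length: `bp_per_nucleosome·step/(4π)` ≈ 5.2 nm for
   every conformation (the bp counts 286/198/172 were chosen to keep this
   radius common). The two loop planes sit ±2.625 nm from the nucleosome
   centre.
4. **Fiber level.** Six nucleosomes per 10.5 nm axial level of the 30 nm
   fiber, equally spaced about the fiber axis, the slot pattern rotating
   by 30° (configurable) per level.
5. **ROI.** 900 straight vertical fiber fragments, each 500 levels tall,
   tile an annulus of 10 μm central diameter, 30 nm radial thickness (the
   fiber diameter; see below) and 5.25 μm height, as 900 equal 0.4°
   sectors. Everything is water at 1.06 g/cm³, giving an ROI mass of
   5.24×10⁻¹⁵ kg, so 100 Gy correspond to ≈3.3×10⁶ eV deposited.

### Design choices that were genuinely open

* **ROI radial thickness.** The source material specifies the annulus by
  central diameter and height only. We reconstruct the thickness as the
  fiber diameter, 30 nm — the natural choice for a single-fiber-thick
  shell — and note that it reproduces the published target/ROI volume
  ratios 0.038/0.029/0.018 (our exact values: 0.0388/0.0291/0.0185).
* **Nucleosome slot radius and tiers.** A naive coplanar arrangement of
  six nucleosomes at slot radius 9.75 nm would let adjacent DNA loops
  (radius ≈5.2 nm plus helix radius ≈1.2 nm) interpenetrate and poke
  ~1.3 nm outside the fiber. We instead set the slot radius to
  `fiber_radius − loop_radius − r_max` (≈8.5–8.9 nm depending on
  conformation) and alternate nucleosomes between two axial tiers
  2.625 nm apart. A short clearance argument (ring-to-ring distance is
  bounded below by the tier separation wherever loop circles cross in
  plan view, and 2.625 nm exceeds the largest helix diameter 2.55 nm)
  guarantees **pairwise disjoint targets fully contained in the ROI**,
  which the test suite verifies by locating sampled interior points of
  every target of a nucleosome back to their own address. None of the
  published totals, volumes or ratios depend on this choice.
* **Z-DNA periodicity.** The dinucleotide zigzag of Z-DNA is not
  modelled; a uniform −30°/bp twist is used, since the tabulated aperture
  and height already average over the repeat.
* **Boundary determinism.** All membership tests are half-open
  ([low, high) in radius, angle, arc height); a point on a shared
  boundary belongs to the lower-indexed target, and angle arithmetic is
  modular on [0°, 360°), making the 0/360° seam exact.

## The event locator

The locator inverts the placement transform analytically: azimuth →
fragment sector, height → level, then for each of the 6 nucleosomes × 2
loops the toroidal coordinates (distance from the loop circle, sector
angle, arc position) decide membership for both strands. It is the exact
inverse of `target_placement()` on target interiors — a property tested
over thousands of random addresses with interior points pushed within
10⁻⁷ of every face, including the angular seam, index extremes and the
left-handed Z geometry — and it is mirror-consistent: reflecting both the
geometry and the points through a plane containing the fiber axis swaps
handedness and preserves every hit/miss decision.

## Synthetic event fields

The generators supply event lists with the statistical structure the
analysis assumes, *not* a physics simulation — no stopping-power
evolution, charge transfer or electron slowing-down exists here.

* **Uniform mode.** Events i.i.d. uniform in the annulus (uniform in
  height, azimuth and squared radius). Used for the consistency check
  that the measured hit fraction equals the predicted volume ratio.
* **Track mode.** Complete vertical histories at uniform annulus
  positions are generated until the cumulative in-ROI dose reaches the
  target (default 100 Gy); the final history is always completed, which
  avoids the truncation bias a dose cut-off would introduce. Candidate
  events occur along the trajectory with Poisson linear density
  `LET/ε̄`; with probability 0.70 an event belongs to a secondary-electron
  cluster (geometric size, mean 3) displaced laterally by an isotropic
  exponential distance (scale 5 nm) and spread about its centre with an
  exponential scale of 2 nm, comparable to the few-nm range of ~50 eV
  electrons in water. Events landing outside the annulus are discarded
  from the set, the dose, and every later denominator.

Parameters, defaults and their reasoning:

| parameter | default | why |
|---|---|---|
| `mean_event_energy_ev` (ε̄) | 55 eV | mean deposit per inelastic event is quasiconstant for light ions; secondary-electron mean energy ≈50 eV |
| `min_event_energy_ev` | 9 eV | minimum inelasticity; every event can therefore break a strand (threshold 8.23 eV) |
| `electron_event_fraction` | 0.70 | published fraction of inelastic events carried by secondary electrons |
| `electron_dose_fraction` | 0.61 | published dose fraction; together these fix class mean energies 47.9 eV (electrons) and 71.5 eV (primaries) through a shifted-exponential energy law |
| `electron_radial_scale_nm` | 5 | free parameter (no published value); nanometric lateral spread of low-energy δ-rays |
| `electron_cluster_radius_nm` | 2 | free parameter; intra-cluster spread, of the order of the sub-10 nm ionization cluster size |

Because event placement is (apart from boundaries) translation invariant,
the *expected* track-mode site-hit probability equals the volume ratio;
the measured excess above it comes from electron events leaking across
the annulus boundaries — events are lost preferentially where target
density is low, enriching the survivors. The surrogate reproduces this
enrichment only weakly (≈+1 % versus the ≈+5 % a transport code shows,
whose δ-rays travel much farther than 5 nm), so the corresponding
acceptance property is tested on means over 60 replicate runs.

## Damage scoring and statistics

* **SSB:** every located event with energy ≥8.23 eV (inclusive); a target
  hit *n* times contributes *n* SSBs.
* **DSB:** greedy pairing per nucleosome — scan SSBs in (bp, strand)
  order, pair each unpaired SSB with the nearest unpaired opposite-strand
  SSB within 10 bp, ties to the lower bp. The pairing rule of the original
  analysis is unspecified; our greedy count is verified against an
  exhaustive maximum-matching oracle on all tested clusters of ≤8 SSBs,
  so a 4-SSB cluster counts as two adjacent DSBs. Cross-nucleosome DSBs
  cannot form (no linker DNA is modelled) — a documented limitation.
* **Yields:** `n_X / (dose · total_bp)`, in breaks·bp⁻¹·Gy⁻¹. The TSB
  yield also equals (site-hit probability)·(events per dose)/(bp), an
  identity used as a cross-check.
* **Uncertainties:** one standard deviation of the mean of per-batch
  ratios — 10 equal batches in uniform mode, one batch per history in
  track mode (the batching scheme is our choice and is echoed in the
  results).

## Problem sizes and numerical choices

The validation suite uses 10⁵ uniform events per conformation for the
Monte Carlo hit fractions (standard error ≈6×10⁻⁴), 60 replicate
100 Gy track runs per conformation (≈6×10⁴ events each) for the
clustering and ordering properties, and 10 seeds per LET point for the
LET sweep {10, 60, 150, 235} keV/μm. Rejection sampling with 2–3×10⁵
points checks the analytic sector volume to three MC standard errors.
All randomness flows from R's default Mersenne-Twister generator seeded
once per run; fixed seeds give byte-identical event sets and results.

## What passing tests do and do not show

The generators emulate the *densities and fractions* of a track-structure
calculation, so the tests demonstrate that the geometric model, locator
and scoring rules are internally consistent and reproduce the published
geometry-determined quantities (volumes, totals, volume-ratio
probabilities, orderings, LET trend of DSB yield). They do not validate
absolute yields per gray against experiment or transport codes: real
secondary-electron spectra, ranges and end-of-track clustering are not
modelled, indirect (chemical) damage is excluded by design, and linker
DNA, histone content and fiber curvature within a fragment are ignored.
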