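---
title: "Monte Carlo dosimetry of shielding-disc misalignment in IOERT: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Monte Carlo dosimetry of shielding-disc misalignment in IOERT: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

In breast intraoperative electron radiotherapy (IOERT) a single large dose
(typically 21-23 Gy at the depth of maximum dose) is delivered to the tumour
bed during surgery through a cylindrical applicator docked to the tissue. A
two-layer shielding disc - aluminium on the beam side to moderate electrons
and absorb backscatter, lead behind it to stop the residue - is slipped
between the target and the chest wall to protect healthy tissue. The disc is
invisible once in place, so two setup errors matter clinically: lateral
misalignment relative to the beam axis, and wrong orientation (the disc
flipped 180 degrees, lead face toward the beam). `iortsim` simulates a
mobile-linac electron beamline into a voxelized water phantom with the disc
in an arbitrary pose and computes the dosimetric quantities used to assess
such errors:

* percentage depth-dose (PDD) and lateral profile (PPD) curves with
  reference parameters R100, R90, R50, R30, R10 and the practical range Rp;
* beam-quality energies from the standard relations
  \(\bar E_0 = 2.33\, R_{50}\) (TRS-398, R50 in cm) and
  \(E_{0p} = 0.22 + 1.98\,R_p + 0.0025\,R_p^2\) (AAPM report 32, Rp in cm);
* the shielding factor \(\mathrm{SF} = 100\,(1 - D_d/D_{nd})\), where
  \(D_d\) and \(D_{nd}\) are the integrated doses in the normal-tissue
  region with and without the disc;
* the backscattering factor (BSF), the ratio of depth-dose values with and
  without the disc just proximal to its face;
* the maximum leakage dose (MLD), the largest window-averaged normal-tissue
  dose scaled to the prescription at R100;
* cumulative dose-volume histograms (DVH) of the treatment zone and the
  fraction of it receiving less than 80% of the maximum dose;
* a radiochromic-film style misalignment estimate (distance between the 50%
  isodose centroid on a film at the disc face and the film-border centre).

## Geometry and coordinates

The beam axis is x, with x = 0 at the phantom surface and the source plane
at x = -SSD (default SSD 1000 mm). The beamline is a titanium exit window
followed by two PMMA cylinders: an accelerator-head cylinder and a secondary
collimator of 100 mm inner diameter ending just above the phantom (IOERT
applicators are hard-docked). The water phantom is a 200 mm cube; the
sensitive detector is a 70 x 150 x 150 mm box at the phantom-surface centre,
scored at 0.5 mm isotropic voxels (half-open intervals, centres at
\((i+0.5)\,\Delta\)).

The manufacturer's head internals are not public; the defaults (window
thickness 0.06 mm, head cylinder radii 40/50 mm, collimator wall 7 mm, end
2 mm above the surface) are declared assumptions, all configurable in the
`[geometry]` block. The disc (default Al 4 mm + Pb 2 mm, diameter 120 mm)
is posed by depth of its proximal face, lateral shift along y, tilt about
the z-diameter through its centre, and a flipped flag. Two tested poses
exceed the phantom: a 42 mm shift puts the rim 2 mm past the phantom wall,
and 30-degree tilts raise the rim above the water surface. In both cases
the rim is truncated by the phantom boundary; the truncated portions are
tens of millimetres outside the detector and the beam.

## Physics model

The transport core is a class-I condensed-history scheme - deliberately a
surrogate for a general-purpose Monte Carlo code, chosen so the package is
reproducible at desk scale without external data files:

* **Collision stopping power**: the Bethe formula for electrons
  (Berger-Seltzer form) with the Sternheimer-Peierls density-effect
  parameterisation computed from the material's mean excitation energy and
  plasma energy. Against standard tabulations this is accurate to well
  under 1% for water at 1 MeV.
* **Radiative stopping power**: \(S_{rad} = S_{col}\,Z_{eff}E/800\). The
  often-quoted complete-screening form \(E/X_0\) overestimates radiative
  losses several-fold at MeV energies; the classic \(ZE/800\) ratio rule is
  within tens of percent of tabulations from 0.1-15 MeV, which suffices for
  the percent-level leakage observables targeted here.
* **Multiple scattering**: Gaussian polar deflection per step with the
  Highland standard deviation
  \(\theta_0 = \frac{13.6\,\mathrm{MeV}}{\beta c p}\sqrt{t/X_0}\,
  [1 + 0.038\ln(t/X_0)]\), clamped at zero and capped at 1.4 rad.
* **Energy-loss straggling** (default on): per-step loss sampled from a
  Gamma distribution with the Bohr variance
  \(\Omega^2 = 0.1569\,(Z/A)\,\rho\,s\) (MeV^2, s in cm). A Gamma rather
  than a clamped Gaussian because at 0.25 mm steps the Bohr sigma is
  comparable to the mean loss; clamping a Gaussian at zero would inflate
  the mean several percent, a Gamma matches both moments on positive
  support. Without straggling the distal falloff is unphysically sharp.
* **Bremsstrahlung** (default on): below a 50 keV emission cutoff the
  radiative loss deposits along the track; above it discrete photons are
  emitted forward, with energies sampled from the 1/k spectrum at a rate
  that reproduces \(S_{rad}\) in expectation. A one-photon-per-step model
  carrying the radiative step loss was rejected: at 0.25 mm steps such
  photons are ~keV-scale and are absorbed within a millimetre, leaving no
  transmission through the disc - precisely the observable (MLD, SF floor)
  the photon model exists for. Photons travel in single exponential
  flights using tabulated total attenuation coefficients (a small frozen
  mu/rho table from standard compilations, log-log interpolated) and
  deposit at the interaction point (kerma approximation).
* **Steps**: length = min(material step cap, exact distance to the next
  boundary, the distance losing 5% of the energy). The cap is
  0.25 mm/density (so ~0.25 mm in water, 22 um in lead, ~100 mm in air),
  which keeps the energy lost per step roughly constant across materials.
  Electron cutoffs are set directly in energy - 25 keV in light media and
  12 keV in lead, the values corresponding to the 0.01 mm range cut of the
  reference simulation setup - because range-cut conversion is not
  reproducible from published information.

Delta-ray production, positrons, Rayleigh scattering, atomic relaxation and
angular bremsstrahlung distributions are deliberately out of scope.

Energy is conserved exactly per history: injected = deposited in the grid +
deposited outside the detector + escaped through the world boundary, and
every run asserts the balance to 1e-6 relative.

## Source model and calibration

Primaries are sampled at the exit-window plane from independent Gaussians:
energy \(N(\bar E, \sigma_E)\) truncated at the tracking cutoff, transverse
positions \(N(0, \sigma_Y), N(0, \sigma_Z)\), and polar angle
\(|N(0, \sigma_M)|\) with uniform azimuth. \(\sigma_M\) is read as the
polar-angle standard deviation; that interpretation is isolated in
`sample_primaries()`. Four presets (10.1, 8.3, 6.3, 4.8 MeV, all with
\(\sigma_E = 0.5\) MeV, \(\sigma_{Y,Z} = 1\) mm, \(\sigma_M = 6^\circ\))
reproduce the tuned parameters of the reference beamline model.

`calibrate_source()` is a deterministic coordinate descent over a
user-declared grid, minimising the rms relative difference of PDD reference
points against a reference set, with profile symmetry/homogeneity as
tie-breakers; all evaluations share one seed (common random numbers), so
the search is reproducible and self-calibration against a self-generated
reference recovers the generating parameters exactly at the matching grid
point. The pass thresholds follow the reference protocol: rms <= 2%,
symmetry diff <= 3%, homogeneity diff <= 5%.

Because the surrogate physics transports less collimator-scattered material
than the real beamline, the presets penetrate deeper than the published
curves; the acceptance protocol therefore calibrates the 10 MeV preset's
mean energy against the published simulated R-points before computing
shielding quantities (landing near 8.0-8.3 MeV, which reproduces R50 to
about a millimetre). Two desk-scale protocol choices are documented
here deliberately:

* the calibration aperture is 20-30 mm rather than the 2 x 2 mm diode
  emulation - at 2e5 histories only ~100 electrons traverse a 2 mm column,
  while the published curves used 160e6 histories;
* R100 is excluded from the acceptance calibration reference: the surrogate
  depth-dose plateau is nearly flat over 0-25 mm, so the R100 location
  jitters by +-10 mm between seeds and would randomise the fit, while R90,
  R50, R30 and Rp are well conditioned.

## Analysis conventions

* **Regions.** The treatment zone is the collimator-radius cylinder from
  the surface to the disc's proximal plane; normal tissue is every detector
  voxel distal to the disc's distal plane. Both planes come from the
  reference (nominal, untilted) pose even for shifted/tilted runs, so
  with/without pairs integrate identical volumes and SF stays well defined.
  Dd/Dnd are energy integrals (proportional to dose integrals in
  homogeneous water); region integrals from runs with different history
  counts must be normalized per history before taking ratios.
* **Reference parameters.** Rx values are distal linear-interpolation
  crossings; Rp intersects the tangent at the steepest distal point
  (searched between the 80% and 20% crossings for noise immunity) with a
  line fitted through the last 10% of depths, after discarding rare photon
  spikes above 3x the tail median. Curves are smoothed with a centred
  moving average (default 3 points; disable for analytic fixtures). For
  gentle sigmoids the tangent construction puts Rp slightly proximal to
  R10, so the ordering invariant is enforced on the crossing-based points.
* **Profiles.** Field size is the 50% full width; symmetry and homogeneity
  are IEC-style ratio definitions over the flattened region
  (|y| <= 0.8 x half field size): max over mirror pairs of
  D(y)/D(-y) ratios, and Dmax/Dmin, both x100. The benchmark tables state
  no formula; their values (100-104.5%) are consistent with these ratio
  forms.
* **BSF.** Ratio of per-history depth-dose values with/without disc at the
  same depth, proximal to the disc; `bsf_max` is the maximum over the 5 mm
  before the face. Depth bins partially covered by the disc are excluded -
  a straddling voxel mixes dense in-disc deposits into the "proximal" dose
  and inflates the ratio ~40%. Both curves keep the no-disc absolute basis;
  self-normalizing the with-disc curve would hide backscatter.
* **MLD.** The averaging volume is a 1 mm-side cube (2x2x2 voxels); the
  reference description ("a 0.5 mm3 volume") is dimensionally ambiguous
  between a 0.5 mm-side cube (a single voxel - no averaging) and a literal
  0.5 mm3 (4 voxels); the window is an argument, so both readings are one
  call away. MLD is exactly linear in the prescription dose.
* **DVH.** Cumulative volume fraction vs dose over the treatment zone
  (a z = 0 planar option reproduces central-plane figures). At desk-scale
  statistics per-voxel noise is tens of percent, so `rebin` block-averages
  the grid first and `max_stat = "p98"` uses the 98th percentile as the
  near-maximum reference; with the literal maximum of a noisy grid the
  underdosed fraction saturates at ~100% regardless of geometry.
* **Film.** The film is the detector slice just proximal to the disc face,
  cropped to the disc footprint and centred on the (shifted) disc. The 50%
  isodose region is thresholded against the maximum (analytic films) or a
  99th-percentile near-maximum after 4x rebinning (Monte Carlo films), and
  the centroid offset from the film centre estimates the misalignment.

## What the synthetic generator emulates - and what it does not

`generate_fixture()` produces: electron-like depth-dose curves (sinusoidal
build-up, logistic falloff with exact R50 after normalization, flat
bremsstrahlung tail), flat-top lateral profiles with controllable linear
asymmetry and noise, uniform-background grids with Gaussian hot spots, and
circular top-hat films. These carry their own ground truth, so every
analysis operation is tested without transport. They do not emulate
collimator-scatter horns, the energy-dependence of penumbra, or correlated
voxel noise; a green fixture test establishes the analysis algebra, not the
transport physics. Transport itself is validated separately: CSDA
self-consistency (scattering off, path length vs the range integral to 1%),
energy conservation, moment tests on the source, and the paired-run
shielding observables.

## Desk scale vs the published scale

The published results used 160e6 histories per run; the acceptance pipeline
here uses 2e5 (paired SF runs) down to 6e4 (trend series), i.e. roughly
1000x fewer. Consequences: per-voxel maps are noisy (hence the rebinned
DVH/film conventions above), profile metrics at depth carry percent-level
noise, and stochastic acceptance checks carry tolerances of a few absolute
points. Integral quantities (SF, distal dose fraction, BSF) are stable at
the percent level. The tilt-angle underdosed-volume trend is asserted as an
increase from 0 to 30 degrees with a positive overall trend rather than
strict pairwise monotonicity, which per-seed noise of ~1-2 points cannot
guarantee at this scale.

## Known limitations

* The beamline upstream of the phantom is an assumption-driven
  simplification; absolute output and the detailed build-up region (R100)
  are not reproduced, only falloff-anchored observables after calibration.
* The kerma approximation deposits photon energy locally; distal photon
  dose is therefore slightly too compact, which biases MLD behind the disc
  conservatively upward.
* BSF for the flipped disc is qualitative: the condensed-history albedo of
  lead underestimates single-collision large-angle backscatter. The
  package asserts flipped > proper, not a specific value - the published
  "27.8" figure is not consistent with the ratio definition of BSF and is
  not hard-coded.
* Config arrays are flat; nested tables and string escapes are outside the
  supported TOML subset.
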