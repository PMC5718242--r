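# iortsim

Desk-scale Monte Carlo dosimetry of shielding-disc misalignment in
intraoperative electron radiotherapy (IOERT).

In breast IOERT a mobile linac delivers a single 21-23 Gy electron dose to
the tumour bed during surgery. A two-layer disc - aluminium toward the beam,
lead behind - is placed between target and chest wall to protect healthy
tissue; once sutured in it is invisible, so lateral misalignment and wrong
orientation (lead face up-beam) are real clinical risks. `iortsim` is an R
package for medical physicists who want to quantify what such setup errors
do to the dose distribution. It provides:

* a condensed-history Monte Carlo electron/photon transport engine (Rcpp
  core) through a parametric beamline - titanium exit window, PMMA
  collimation, water phantom - with the Al-Pb disc in arbitrary pose
  (depth, lateral shift, tilt, 180-degree flip), scoring energy on a
  0.5 mm voxel grid over a 70 x 150 x 150 mm detector;
* a Gaussian source model at the exit window (presets for 10.1, 8.3, 6.3,
  4.8 MeV tuned beams) with deterministic grid calibration against
  reference depth-dose curves;
* the dosimetric metric set used in disc-misalignment studies:

  | quantity | definition |
  |---|---|
  | PDD / PPD | depth-dose and profile curves, R100..R10, Rp, field size, symmetry, homogeneity |
  | E0bar, E0p | `2.33 R50` (TRS-398) and `0.22 + 1.98 Rp + 0.0025 Rp^2` (AAPM 32), R in cm |
  | SF | `100 (1 - Dd/Dnd)`, integrated normal-tissue dose with/without disc |
  | BSF | ratio of depth-dose with/without disc just proximal to its face |
  | MLD | max window-averaged normal-tissue dose scaled to the prescription at R100 |
  | DVH | cumulative treatment-zone dose-volume histogram, underdosed (<80%) fraction |
  | film check | offset of the 50% isodose centroid on a film at the disc face |

* MetaImage (MHD/RAW) grid I/O, a strict TOML-subset run configuration,
  synthetic fixture generators, and an `iortsim` command line
  (`simulate` / `analyze` / `calibrate` / `film-check` / `fixtures` /
  `describe`, see `exec/iortsim`).

The physics is an intentionally self-contained analytic surrogate (Bethe
collision stopping power with density effect, a documented radiative-loss
rule, Highland scattering, Bohr straggling, 1/k bremsstrahlung, kerma-style
photon deposition) - reproducible anywhere without external physics data.
See the methods vignette (`vignettes/iortsim-methods.Rmd`) for the model,
its assumptions and its limits.

## Worked example

Paired runs with and without the disc at the 10 MeV R90 depth (24.5 mm),
shielding factor and backscatter (1e5 histories, ~40 s):

```r
library(iortsim)

src <- list(mean_energy = 8.0, sigma_e = 0.5, sigma_y = 1,
            sigma_z = 1, sigma_m = 6)   # calibrated 10 MeV beam
with_disc <- list(source = src, disc = list(enabled = TRUE, depth = 24.5))

nodisc <- run_simulation(list(source = src), n_histories = 1e5, seed = 1)
disc   <- run_simulation(with_disc,          n_histories = 1e5, seed = 2)

geom <- build_geometry(with_disc)
nt   <- region_spec("normal_tissue", geom)   # detector distal to the disc
dnd  <- region_dose(nodisc$grid, nt) / 1e5   # per-history integrals
dd   <- region_dose(disc$grid,  nt) / 1e5

shielding_factor(dd, dnd)
#> [1] 94.96093

rp <- reference_points(extract_pdd(nodisc, aperture = 20))
rp
#> R100=2.25 R90=27.17 R50=35.12 R30=37.35 R10=40.66 Rp=39.72 mm
mean_energy_from_r50(rp$R50)
#> [1] 8.182038

backscatter_factor(extract_pdd(disc, 150), extract_pdd(nodisc, 150),
                   disc_depth = 24.5)$bsf_max
#> [1] 1.020437

100 * dnd * 1e5 / sum(nodisc$grid$values)  # dose fraction past the disc plane
#> [1] 13.63199
```

Reading: the aligned disc removes ~95% of the dose that would otherwise
reach tissue behind it (the published figure at full scale is ~96%); without
a disc ~15% of the delivered dose lands beyond R90 + disc thickness; the
aluminium face returns only a few percent backscatter (BSF <= 1.1), while
flipping the disc (lead up-beam) roughly triples that enhancement - run
`disc = list(enabled = TRUE, depth = 24.5, flipped = TRUE)` to see it.

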