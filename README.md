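# climatch

Quantitative monitoring of the match line between adjacent photon and
electron radiotherapy fields from Cherenkov luminescence images (CLI).

## The problem

In breast radiotherapy the breast or chest wall is treated with photon
fields and the nodal regions with an abutting electron field. Patient motion
shifts the junction between the two fields on the skin, causing local under-
or over-dosage. The Cherenkov light emitted where the beams enter tissue
makes both fields — and their junction — visible to a CCD camera during
treatment, with no extra imaging dose. This package implements the full
analysis chain that turns those images into a millimeter-scale matching
measurement, together with a synthetic CLI generator that emulates the
phantom acquisitions (beam energies and dose rates, gantry obliquity, tissue
color, CCD noise and sparkle impulses) so every stage is testable against
known ground truth.

## The estimator

For a couch shift of magnitude $s$ along the superior–inferior axis:

- each condition is denoised by background subtraction, a per-pixel temporal
  median over three repeated frames (removing sparkle impulses from direct
  x-ray hits on the CCD), and a 10 × 10 running median;
- the zero-shift photon + electron sum forms the *reference* composite, and
  the shifted field's image plus the other zero-shift image the *shifted*
  composite;
- the absolute difference of the composites leaves a band of width $s$ at
  the junction; the FWHM of its Y-averaged ROI profile, converted to mm via
  a ruler-image pixel calibration, is the **measured matching value**, and
  `measured − |s|` the **discrepancy**.

A signal-to-noise gate (default SNR ≥ 2 against the background-frame
residuals) flags conditions — such as dark tissue — where the band cannot be
measured.

## Worked example

```r
library(climatch)

yellow   <- tissue_spec("yellow")
photon   <- beam_spec("photon", 6)          # 6 MV, 600 MU/min, AP
electron <- beam_spec("electron", 8)        # 8 MeV

p0 <- simulate_condition(photon,   yellow, rng_seed = 1)  # zero shift
e0 <- simulate_condition(electron, yellow, rng_seed = 2)
p5 <- simulate_condition(photon, yellow,                  # 5 mm inferior
                         shift = shift_spec(5, "inferior", "photon"),
                         rng_seed = 3)

scale <- calibrate_pixel_scale(make_ruler_image(), tick_spacing_mm = 10)
print(scale)
#> <pixel_scale> 3.6000 px/mm (15 ticks, residual 0.000 px)

fit <- cli_match(p0, e0, photon_shifted = p5, scale = scale)
summary(fit)
#> Cherenkov field-matching measurement
#>   introduced shift : +5.0 mm (photon)
#>   measured matching: 5.09 mm
#>   discrepancy      : +0.09 mm
#>   SNR              : 31.7
#>   band peak 3369.0, half level 1688.2, baseline 7.4 (grayscale)
#>   scale 3.600 px/mm; ROI 30 x 30 mm at (-15, -15)
```

The ruler calibrates to 3.6 px/mm (36 pixels per 10 mm); the 5 mm introduced
shift is recovered as 5.09 mm, a +0.09 mm discrepancy at SNR 31.7. `plot(fit)`
draws the difference-band profile with the half-maximum level and measured
span. `run_experiment(scenario_grid_ap(), seeds = 1:3)` sweeps the full
photon/electron × shift × direction grid and reports per-group statistics
(mean ± SD of |discrepancy|, fraction within 1 mm, maximum).

A thin command-line wrapper with `simulate` / `calibrate` / `analyze` / `run`
subcommands is installed at `inst/scripts/climatch.R`; stacks travel as
multi-page 16-bit TIFFs with JSON sidecars, scenarios as YAML.

## The methods vignette

`vignettes/field-matching-methods.Rmd` documents the acquisition model and
its calibration (edge widths, yields, noise levels, tissue absorption), the
numerical conventions (even-kernel median anchoring, baseline and FWHM
rules, ROI resolution), the detectability gate, and what the synthetic
phantom does and does not say about real tissue.
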