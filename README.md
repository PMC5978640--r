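# tomoqa

Automated image-quality analysis for a digital breast tomosynthesis (DBT)
quality-assurance phantom, in R.

Medical physicists monitoring DBT systems image a multi-purpose phantom and
need the same battery of measurements from every scan: is the phantom
positioned correctly, how much tissue is lost at the chest wall, how thick
and how evenly spaced are the reconstructed slices, how sharp is the
in-plane point response, how uniform and how noisy is the image, and how
detectable are low-contrast objects. tomoqa computes all of these from a
reconstructed volume, fully automatically, and also ships a synthetic
phantom renderer with ground-truth records so the entire analysis chain can
be validated without scanner data.

## What it measures

| family | model / statistic |
|---|---|
| positioning | marker centroids + orthogonal Procrustes -> roll, pitch, yaw (deg) |
| chest wall | stair-step gauges, 12 x 0.5 mm: missing tissue = 6.0 - visible extent (mm) |
| slice width | SSP(z) sampled by folded bead ramps (0.18 mm beads, 0.25 mm z-steps); FWHM by half-maximum interpolation |
| slice increment | mean shift of SSP peak z between consecutive slices |
| z geometry | through-slice peaks of three 5 mm Al beads, nominally 10 mm apart |
| ASF | normalized x/y profiles of a bead across slice offsets |
| PSF / MTF | FT of bead point-source patches; MTF(x), MTF(y); optional bead-size deconvolution |
| uniformity | regional (two 10 mm ROIs, per-slice trend) and global (five 5 mm ROIs, max mean difference as % of grand mean) |
| SNR / CNR | net signal over noise SD; CNR over the Al square; SD = a * mAs^b fit (b about -0.5) |
| contrast-detail | SD of circle means vs diameter, hyperbolic fit SD = k/d |

## Worked example

Render a synthetic phantom volume and run the full pipeline:

```r
library(tomoqa)

geom <- default_geometry()
acq  <- acquisition_model(pixel_spacing_xy = 0.2, seed = 7)
vol  <- render(geom, acq)          # ~4 s at 0.2 mm pixels

report <- run_pipeline(pipeline_config(volume = vol, geometry = geom,
                                       out_dir = "qa_out"))
print(report)
```

```
QA report: 26 records
  positioning     roll = 2.225e-06 deg; pitch = -0.0003178 deg; yaw = 3.313e-05 deg; ...
  chest_wall      gauge1_missing = 0 mm; ... mean_missing_tissue = 0 mm
  slice_width     fwhm_left = 1.04 mm; fwhm_right = 1.179 mm
  slice_increment increment = 0.9975 mm
  z_geometry      bead_spacings = 10.01,9.99 mm; mean_spacing = 10 mm
  asf             fwhm_x = 4.872 mm; fwhm_y = 4.86 mm
  mtf             f50_x = 1.23 cycles/mm; f50_y = NA cycles/mm
  uniformity      regional_trend_anterior = -6.544e-05 units/mm; ... global_uniformity = 0.03321 percent
  snr_cnr         snr = 98.37 ratio; cnr = 15.37 ratio
  low_contrast    n_detected = 8 count; smallest_detected_mm = 1 mm
```

Reading this: the simulator placed the phantom with zero pose error and no
chest-wall crop, and the analysis agrees (angles ~0, 0 mm missing tissue);
the 1 mm nominal slices measure 1.0-1.2 mm FWHM with a 1.0 mm increment;
the 5 mm beads sit 10.0 mm apart; global uniformity of a flat background is
0.03%; SNR is ~100 (background 100, noise SD ~1); and at this noise level
every sphere down to 1 mm is flagged detectable while the 0.8 mm sphere is
not. `qa_out/report.json` and `report.csv` contain the same numbers with
per-metric provenance; reruns are byte-identical.

Real volumes come in the same way from disk: `read_volume("scan.dcm")`
(multi-frame DICOM), a directory of single-frame DICOM files, or a stacked
TIFF with a JSON sidecar. A thin command-line front end is installed at
`system.file("cli", "tomoqa", package = "tomoqa")` with `analyze` and
`simulate` subcommands.

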