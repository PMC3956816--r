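# ctxa: DXA-equivalent hip densitometry from quantitative CT

`ctxa` converts a calibrated 3D quantitative-CT (QCT) volume of the
proximal femur into the 2D areal bone mineral density (aBMD, g/cm²)
measurement that clinical DXA reports, and adds what DXA cannot do:
splitting every hip region into cortical and trabecular compartments.
It is aimed at bone-densitometry researchers and image-analysis
developers who need a transparent, fully testable implementation of
projected hip QCT.

The measurement chain:

1. **Calibration** — rods of known aqueous K₂HPO₄ equivalent density in
   the scan map HU to mg/cm³ by ordinary least squares
   (`fit_calibration`, `apply_calibration`), with a QA check against the
   200.0 mg/cm³ reference and an opt-in beam-hardening slope correction
   (`qa_check`).
2. **Segmentation** — a three-parameter adaptive threshold (floor
   −250 mg/cm³, 5-pixel local-mean neighborhood, seed 120 mg/cm³;
   `segment_bone`) followed by cortical-envelope filling so everything
   within the outer cortex, marrow included, belongs to the bone
   (`fill_cortical_envelope`).
3. **Standard pose** — the femoral shaft is rotated vertical and the
   neck axis horizontal in the axial plane
   (`estimate_standard_rotation`, `apply_rotation`).
4. **Projection** — anteroposterior ray sums produce a DXA-like image:
   per pixel, mineral mass (g), bone path volume (cm³), and
   aBMD = mass / pixel area (`project_coronal`).
5. **ROIs and compartments** — femoral neck, trochanter and
   intertrochanter are placed automatically on the silhouette (Total Hip
   is their exact union), every landmark is operator-adjustable, and a
   350 mg/cm³ threshold splits cortical from trabecular bone
   (`auto_place_rois`, `measure_hip_rois`, `split_compartments`).

Two support modules make the package self-contained: a
constructive-solid-geometry digital femur phantom with an independent
analytic projection oracle (`digital_femur_spec`, `generate_phantom`,
`oracle_projection`), and the densitometry statistics used to validate
such systems — long-term RMS-SD precision (√mean of per-patient visit
variances), interobserver comparison, cross-device regression with
SEE = √(RSS/(n−2)), Welch t-tests and Anderson–Darling normality
(`rms_precision`, `interobserver_compare`, `regress_with_see`,
`welch_t`, `anderson_darling_normality`).

## Worked example

Analyze a synthetic femur with a known answer:

```r
library(ctxa)
spec <- digital_femur_spec()            # stylized femur + rod insert
ph   <- generate_phantom(spec)          # HU volume, ground truth, mask
cfg  <- analysis_config(output_dir = "report",
                        box_mm = list(lo = c(5, 5, 3), hi = c(95, 63, 123)))
res  <- run_analysis(cfg, volume = ph$hu)
res$qa
subset(res$results, compartment == "integral")
```

```
<qa_result> measured 200.00 vs nominal 200.0 mg/cm3: +0.00% [PASS at +/-2.0%]
  suggested beam-hardening slope factor: 1.0000
              roi compartment abmd_gcm2 vbmd_mgcm3    mass_g  area_cm2 volume_cm3
1    femoral_neck    integral 0.8222654   409.9951  3.189857  3.879352   7.780231
2      trochanter    integral 0.8891608   396.1717  7.039747  7.917294  17.769433
3 intertrochanter    integral 0.8344455   406.3567  8.530492 10.222946  20.992617
4       total_hip    integral 0.8519729   403.0764 18.760095 22.019592  46.542281
```

The QA row says the calibration reproduces the 200 mg/cm³ reference
exactly (the phantom is noise-free). Each ROI row reads like a DXA
report — aBMD in g/cm², plus the volumetric BMD, mass, projected area
and bone volume that the 3D data make available. The cortical rows of
`res$results` additionally report the cortical mass fraction (0.783 for
Total Hip here, against 0.775 from the analytic oracle of the same
geometry). `run_analysis` writes `results.csv`, `results.json` with all
parameters and a config hash, an annotated projection PNG, and a log.

The statistics module works from plain CSV tables:

```r
ser <- generate_longitudinal_cohort(22, 3, mean = 0.647, within_sd = 0.012,
                                    seed = 42)
rms_precision(ser)
#> <precision_result> RMS-SD 0.0110 g/cm2, grand mean 0.653 g/cm2, CV 1.7% (22 patients)
```

A thin CLI wraps the same functions:
`Rscript inst/cli/ctxa.R simulate|qa|analyze|stats ...`.

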