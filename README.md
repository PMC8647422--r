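# mrjet

Direct quantification of mitral regurgitation (MR) from 4D flow
cardiovascular MR by jet tracking, for imaging scientists and CMR
analysts who need a reproducible, testable implementation of the
method and of the conventional comparator it is evaluated against.

## What it computes

4D flow CMR yields a velocity vector **v**(x, t) in every voxel at
every cardiac timeframe. For each frame in which a regurgitant jet is
present in the left atrium, the package places a multiplanar-reformat
(MPR) plane at the peak velocity within the jet, oriented
perpendicular to the local jet direction, segments the jet
cross-section Ω on the through-plane velocity raster, and computes the
regurgitant flow rate

    Q(t) = Σ_{p ∈ Ω} v_tp(p) · A_pix      [cm/s · mm² → mL/s],

re-deriving the plane independently at every frame so it tracks
eccentric, direction-varying jets. The flow-rate curve is
spline-interpolated, closed to baseline with zero-flow anchors half a
frame interval outside the sampled window, and integrated to the MR
volume; multiple jets are tracked independently and summed, and no
detected jet means an MR volume of zero.

The conventional indirect volumetric comparator is included:

    V_MR = (EDV − ESV) − V_Ao = LV stroke volume − aortic forward flow,

with EDV/ESV from a contoured LV volume curve, forward flow as the
positive-part trapezoidal integral of the aortic rate curve, and
optional BSA indexing (Mosteller, √(height·weight/3600)). MR volumes
grade as none (< 10 mL), mild (10–30), moderate (30–60), severe
(≥ 60). The agreement battery provides ICC(2,1) (two-way random,
single measures, absolute agreement) with its F-test p-value,
Bland–Altman bias and limits of agreement (mean ± 1.96 SD), Cohen's
kappa on severity grades with the Fleiss large-sample p-value, the
paired Wilcoxon signed-rank test (exact up to 25 nonzero differences),
median [IQR] summaries, and the standard interpretation bands.

Because clinical 4D flow datasets are rarely shareable, the package
ships a digital jet phantom (`generateJetPhantom()`): an eccentric,
mid-to-late-systolic jet with a half-sine orifice flow pulse of known
integral, configurable noise, optional aliasing beyond VENC and an
optional second jet, together with ventricle/aorta curves that are
consistent with the jet truth by construction. Preprocessing utilities
cover velocity-aliasing unwrapping (neighbourhood-median, single wrap)
and eddy-current background offset correction (planar fit over static
tissue).

## Worked example

```r
library(mrjet)

## simulate a mild regurgitant jet (16 mL truth) with velocity noise
ph  <- generateJetPhantom(phantomConfig(noiseSd = 5, seed = 1))
res <- trackMitralRegurgitation(ph$field, atrialROI(ph$truth))
res
#> JetTrackResult: 1 jet(s), total MR volume 16.02 mL
#>   per-jet volumes (mL): 16.02
#>   MR frames: 6 - 12 (7 frames)
classifyMRSeverity(totalMRVolume(res))
#> [1] mild

## indirect comparator on phantom-matched ventricle/aorta curves
io <- generateIndirectInputs(ph$truth, forwardVolume = 79)
indirectVolumetricAnalysis(io$volumeCurve, io$flowCurve)
#> CardiacVolumes: EDV 134.0, ESV 39.0, SV 95.0 mL, EF 70.9%
#>   aortic forward 79.0 mL, indirect MR volume 16.0 mL

## agreement between two measurement series
pm <- pairedMeasurements(c(13, 4, 23, 38, 62, 8, 20, 31),
                         c(20, 12, 25, 30, 55, 3, 28, 41))
pm@labelsA <- as.character(classifyMRSeverity(pm@valuesA))
pm@labelsB <- as.character(classifyMRSeverity(pm@valuesB))
agreementBattery(pm)
#> AgreementResult (difference direction a-b ; n = 8 )
#>   ICC(2,1) 0.915 (strong), p = 0.0003353
#>   Bland-Altman bias -1.88, LOA [-16.52, 12.77]
#>   Cohen's kappa 0.636 (substantial), p = 0.003163
#>   Wilcoxon signed-rank p = 0.4062
```

The tracked 16.02 mL against the 16 mL ground truth (0.1% error on
this seed; within ±3% across seeds at 5 cm/s noise) and the exact
16 mL closed-loop recovery by the indirect method are the two core
validation results; the agreement example shows the battery on a small
paired series, with the interpretation bands attached to ICC and
kappa.

## Package layout

- `R/` — S4 classes (`VelocityField4D`, `MPRPlane`, `PlaneSample`,
  `JetTrackResult`, `PhantomTruth`, `CardiacVolumes`,
  `AgreementResult`, …) and the pipeline stages.
- `vignettes/mrjet-methods.Rmd` — the model, parameter rationale,
  phantom design, numerical choices and limitations.
- `tests/testthat/` — unit, property and acceptance tests with
  independent oracles (brute-force flux summation, ANOVA
  decomposition, exhaustive sign enumeration).
- `scripts/acceptance.R` — see above.
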