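# TumorHabitats

Multiparametric PET/MRI habitat analysis for preclinical tumor studies, in R.

Tumors are heterogeneous: a single mean ADC or mean SUV hides subregions
that respond to therapy before the tumor shrinks. This package implements a
voxel-wise pipeline that turns co-registered quantitative imaging into
*habitats* — spatially mapped clusters of voxels with a shared physiological
signature — and tracks their composition over time:

1. **Parametric mapping** — apparent diffusion coefficient from multi-b-value
   DWI (`fitADC`, with artifact-slice exclusion), saturation-recovery T1 from
   a variable-TR series (`fitT1`), Extended Tofts pharmacokinetics
   (Ktrans, ve, vp) from DCE-MRI with a muscle-calibrated population AIF
   (`calibrateAIF`, `fitExtendedTofts`, `filterDceVoxels`), and PET
   standardized uptake values (`computeSUV`). The Extended Tofts model is

   `Ct(t) = vp Cp(t) + Ktrans \int_0^t Cp(tau) exp(-(Ktrans/ve)(t - tau)) dtau`

   with voxels excluded when Ktrans ∉ [0,5] min⁻¹, ve or vp ∉ [0,1], or
   enhancement < 25% over baseline.
2. **Coregistration** — slice reframing, anti-aliased down-sampling and
   affine Mattes mutual-information registration with regular-step gradient
   descent (`reframeSlices`, `downsampleAntialias`, `registerAffineMI`),
   quantified by the Dice coefficient.
3. **Habitat discovery** — pooling the five features (ADC, Ktrans, ve,
   FDG-SUV, FLT-SUV) across subjects and timepoints, z-normalization, Ward
   agglomerative clustering with silhouette-based selection of k from 2–8,
   median-split high/low signatures and phenotype naming (HV, HRSP, TZ,
   ATMR, RSP), longitudinal composition tables and spatial remapping
   (`assembleFeatures`, `clusterHabitats`, `selectK`,
   `characterizeHabitats`, `habitatComposition`, `remapHabitats`).
4. **Spatial statistics** — multiregional spatial interaction (MSI): the
   fraction of neighboring voxel pairs per habitat pair, compared to a
   size-preserving randomized null via z-scores (`computeMSI`).
5. **Histology habitats** — box-kernel smoothing and bilinear down-sampling
   of stain density maps (H&E nuclei, CD31, Ki67, GLUT1), Ward clustering,
   and pimonidazole colocalization (`densityFeatures`, `clusterHistology`,
   `hypoxiaColocalization`).
6. **Validation statistics** — exhaustive permutation matching of histology
   to imaging habitats, central-slice selection, Pearson correlation,
   exact Mann–Whitney and ANOVA + Tukey HSD (`matchByPermutation`,
   `selectCentralSlice`, `compareGroups`, `anovaTukey`).

Because no public dataset accompanies the method, the package ships a
first-class **digital phantom** (`generatePhantom` and the `simulate*`
functions) that plants habitats with known parameters, a ~37% non-enhancing
necrotic core, acquisition noise, cross-scanner misalignment and matched 2D
histology sections, so every stage is testable against ground truth.

## Worked example

```r
library(TumorHabitats)
report <- runPipeline(pipelineConfig(nSubjects = 8L), seed = 1)
report$selectedK        # 5
report$habitatNames     # "HV" "TZ" "ATMR" "HRSP" "RSP"
report$pooledARI        # 1
report$msiMeanDiagonalZ # 78.7
round(report$matchedR2, 2)  # 0.86 0.97 0.95 0.92 0.89
```

Here `runPipeline` simulated an 8-subject, two-timepoint cohort, pooled
~53,000 valid tumor voxels, selected k = 5 by mean silhouette from the range
2–8 and recovered the planted habitats exactly (adjusted Rand index 1). The
mean diagonal MSI z-score of ~79 says the discovered habitats are dozens of
standard deviations more self-contiguous than size-matched random
arrangements, and the per-habitat R² of 0.86–0.97 is the agreement between
each habitat's share of the imaging central slice and of the matched
histology section across subjects.

Single-stage use follows the same grammar, e.g.

```r
truth <- generatePhantom(c(64, 64, 10), nHabitats = 5,
                         necroticFraction = 0.37, seed = 7)
cfg   <- acquisitionConfig()            # b-values, TR list, 6.4 s DCE frames
dwi   <- simulateDWI(truth, cfg)
adc   <- excludeDwiSlices(fitADC(dwi, cfg@bValues), tumorMask(truth))
```

Volumes read and write as NIfTI-1 (`readVolume`/`writeVolume`); reports and
models serialize to JSON; composition tables are plain data.frames.

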