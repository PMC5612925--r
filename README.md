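# cardiomorph

Geometric morphometrics of left-ventricular (LV) motion: a complete R
pipeline for analyzing time-resolved 3D landmark models of the beating heart
and for asking whether — and how — disease changes the *trajectory* of LV
shape over the cardiac cycle, not just the shapes at end-diastole (ED) and
end-systole (ES).

The intended users are researchers working with population cardiac shape
models (cine-MR feature tracking, 3D echo): each case is a pair of landmark
surfaces (endocardium and epicardium, k homologous landmarks each) observed
at a variable number of frames through one heartbeat, plus an expert-marked
end-systolic phase. The package turns such data (or a built-in synthetic
substitute) into trajectory attributes, group tests, and classifier
benchmarks for disease status (Control vs. myocardial infarction, MI).

## The method

1. **Temporal registration.** Each raw cycle is normalized to 30 frames: a
   piecewise-linear time warp pins ES at 35% of the cycle (ED continuous at
   0/100%), every landmark coordinate is fitted as a cyclic signal with five
   Fourier harmonics at the warped phases, and the fits are resampled at
   phases (t−1)/30. Frame 1 is ED; the frame containing phase 0.35 is
   frame 11, the nominal ES. After registration, ES can be re-detected as
   the frame of minimal cavity volume (divergence-theorem integration over a
   triangulated surface with a basal cap).

2. **Procrustes alignment.** Generalized Procrustes analysis (GPA)
   superimposes configurations by translation and rotation — in
   *size-and-shape space* (SSS, size retained) — and optionally scale — in
   *shape space* (SS, unit centroid size CS(X) = √Σᵢ‖xᵢ − x̄‖²). Rotations
   are restricted to det = +1: anatomy must not mirror.

3. **Linear-Shift parallel transport.** GPA + PCA on raw cycles mixes
   inter-individual shape differences with within-cycle deformation. The
   Linear Shift removes the former: a common GPA defines the grand mean
   (common template CT); per-case GPAs define local templates (LT, each
   individual's mean shape); each LT is aligned to the CT by ordinary
   Procrustes analysis (OPA); every frame is OPA-aligned to its aligned LT;
   and the deformation d_t = frame_t − LT is transported as CT + d_t.
   A final common GPA and a joint PCA over all case-frames yield per-frame
   scores on shared axes. Two individuals undergoing the same deformation of
   different baseline shapes land on the same transported trajectory.

4. **Trajectory attributes.** Each case's 30-point path through the first 3
   PCs is a geometric object with **size** (centroid size of the path),
   **orientation** (four-quadrant angle of the ED→ES vector in the PC1/PC2
   and PC1/PC3 planes, degrees in [0°, 360°)) and **shape** (GPA-with-scaling
   over paths-as-configurations, PCA, first 15 shape scores). Group tests:
   one-way ANOVA with adjusted R² = 1 − (1 − R²)(n−1)/(n−g) as effect size,
   MANOVA (Wilks' Λ) on trajectory-shape scores, a permutation test of
   multivariate dispersion, and per-frame ANOVAs along the cycle with
   Benjamini–Hochberg flags.

5. **Classification.** Repeated stratified random splits (defaults: 200
   train + 100 test per class, 1,000 repeats; smaller cohorts use 2/3–1/3
   splits), features z-scored on the training set, linear SVM (cost 1),
   mean accuracy / specificity / sensitivity (Control = negative,
   MI = positive) and ROC AUC from the continuous decision values. Feature
   sets cover both surfaces and both spaces: ED→ES angles, trajectory size,
   15 trajectory-shape PCs, PC1/PC2/PC3 at all 30 times, PC1–PC10 at all
   times, plus traditional indicators EDV, ESV, EF = (EDV − ESV)/EDV.

6. **Synthetic cohorts.** `generateCohort()` builds two nested
   truncated-ellipsoid surfaces per case with a smooth cyclic contraction
   (group-specific amplitude and sphericity change, optional septal
   akinesia), inter-individual baseline variation, variable raw frame counts
   and raw ES phases, rigid jitter, landmark noise, and exact volume ground
   truth — so every stage of the pipeline can be validated without any
   external data.

## Worked example

```r
library(cardiomorph)

cases <- generateCohort(simulationSpec(nPerGroup = 10, seed = 1))
regs  <- lapply(cases, function(cs) registerSequence(cs@endo, registrationSpec()))
tds   <- runLSPCA(regs, mode = "SSS")
tds
#> LVTransportedDataset (endo, SSS): 20 cases x 30 frames, 109 landmarks
#>   PC1..3 variance fractions: 0.970 0.007 0.000
#>   final-GPA diagnostics: max rotation 2.47e-04 rad, CT drift 7.52e-05

ind <- computeTraditionalIndicators(regs, cases[[1]]@mesh)
aggregate(cbind(edv, esv, ef) ~ group, ind, function(v) round(mean(v), 3))
#>     group     edv    esv    ef
#> 1 Control  95.236 13.853 0.855
#> 2      MI 111.345 49.537 0.555

at  <- trajectoryAttributes(tds)
res <- anovaAdjusted(at$trajSize, at$group)
sprintf("F = %.1f, p = %.3g, adj R2 = %.3f",
        res$statistic, res$pValue, res$rSquaredAdj)
#> "F = 915.6, p = 6.89e-17, adj R2 = 0.980"

fs  <- buildFeatureSets(list(tds), clinical = ind)
runRepeatedSVM(fs$endo_sss_pc1_10_all_times$matrix,
               fs$endo_sss_pc1_10_all_times$labels, nRuns = 100, seed = 2)
#> ClassificationReport 'features' (100 runs, seed 2)
#>   accuracy specificity sensitivity auc
#> 1        1           1           1   1
```

Reading: PC1 of the transported deformations carries 97% of the variance in
SSS (it is essentially the size change of contraction); the trajectory-size
ANOVA detects the programmed contraction deficit of the MI group with a very
large effect size; and the PC1–PC10-at-all-times feature set separates the
two groups perfectly on this clean synthetic cohort. `runPipeline()` chains
all stages (both surfaces × both spaces) and writes attribute, test and
classification tables to a directory.

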