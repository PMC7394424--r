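# ncctangio

Cerebral vessels are nearly invisible on non-contrast head CT (NCCT):
unenhanced blood (~40-45 HU) is barely denser than brain parenchyma
(~30 HU). Patients who cannot receive iodinated contrast therefore cannot
get a CT angiography (CTA). `ncctangio` implements a pipeline that learns
to see the vessels anyway: from paired NCCT/CTA examinations it derives
weak vessel labels, trains a convolutional segmentation network to predict
those labels from the NCCT alone, and evaluates by whole-examination Dice.
It is aimed at medical-image-analysis researchers reproducing or extending
contrast-free angiography experiments.

## What is inside

**Weak-label generation.** Contrast-filled vessels (120-500 HU) overlap
bone (200-3000 HU) in radiodensity, so neither thresholds cleanly from a
CTA alone. With an aligned pair, thresholding *both* scans strictly above
120 HU gives a bone mask (NCCT) and a bone+vessel mask (CTA); subtracting
the first from the second and removing small isolated components leaves a
binary vessel label:

```
label = denoise( (CTA > 120) \ dilate(NCCT_aligned > 120) )
```

**Rigid registration.** A 6-DOF (three rotations about the fixed volume's
centre, three translations) alignment of NCCT to CTA by Nelder-Mead
maximization of normalized cross-correlation over a smoothed
multiresolution pyramid (mutual information and windowed local correlation
are selectable).

**Segmentation network.** A U-Net variant with a four-stage residual
encoder, one gated self-attention block at the deepest stage, and a
pixel-shuffle decoder with ICNR (sub-pixel convolution) initialization;
a plain U-Net baseline; training with Adam (weight decay 1e-2) under the
1cycle learning-rate policy on the generalized Dice loss

```
GDL = 1 - 2 * sum_l w_l sum_n r_ln p_ln / sum_l w_l sum_n (r_ln + p_ln),
w_l = 1 / (sum_n r_ln)^2
```

with flip/rotate/zoom augmentations applied jointly to image and mask.
The network and its training loop are implemented in the package itself
(RcppArmadillo), deterministic given their seeds.

**Evaluation.** Whole-examination Dice `2TP/(2TP+FP+FN)` from confusion
counts pooled over the full volume, patient-level k-fold
cross-validation, a training-set-size experiment harness, and an exact
Mann-Whitney rank-sum test for subgroup comparisons.

**Phantom generator.** Paired NCCT/CTA head phantoms with a textured
elliptical skull shell, noisy parenchyma, a branching vessel tree with
known voxel ground truth, optional aneurysms and optional known rigid
misalignment, acquired through a simulated scanner PSF. Every stage of
the pipeline is testable against these phantoms without clinical data.

## A worked example

```r
library(ncctangio)

pair <- generatePhantomPair(phantomSpec(seed = 7))
pair
#> PhantomPair patient phantom (F): 32x64x64, 2849 vessel voxels

label <- generateVesselLabel(pair@ncct, pair@cta)
diceCoefficient(label, pair@truth)
#> TP 2849, FP 7, FN 0 -> dice 0.9988
```

The weak label recovers 2849 of 2849 true vessel voxels with 7 false
positives: on phantoms the threshold/subtract/denoise pipeline is almost
exact, which is the self-consistency the clinical pipeline relies on.

```r
mis <- rigidTransform(rotations = c(5, 0, 0), translations = c(3, -2, 1.5))
pm  <- generatePhantomPair(phantomSpec(seed = 2, misalignment = mis))
registerRigid(pm@ncct, pm@cta)
#> RigidTransform: rot (z,y,x) = (-4.979, 0.078, 2.489) deg,
#>                 t = (-3.012, 2.139, -1.323) mm
pm@trueTransform
#> RigidTransform: rot (z,y,x) = (-5.000, -0.000, 0.000) deg,
#>                 t = (-3.000, 2.123, -1.320) mm
```

Translations are recovered to ~0.01 mm and the in-plane rotation to
0.02 degrees; the out-of-plane rotation (here 2.5 degrees off) is the
method's documented weak axis — see the vignette. Labeling the realigned
pair still reaches a Dice of 0.994 against the phantom truth.

Training on phantoms (desk scale, ~4 minutes) and predicting a held-out
patient:

```r
cohort <- makeCohort(20, phantomSpec(), seed = 42)
fit <- trainModel(buildModel(modelConfig(base_width = 16)),
                  cohort[1:16], preprocPreset("simple-multi"),
                  trainConfig())
pred <- predictVolume(fit$model, cohort[[17]]@ncct)
diceCoefficient(pred, cohort[[17]]@truth)$dice
```

A command-line front end over the same functions (DICOM conversion,
phantom cohorts, registration, labeling, training, cross-validation)
lives in `inst/cli/ncctangio.R`.

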