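# oarseg

Slice-wise segmentation of thoracic organs at risk (OARs) in CT, built for
the hardest of them: the esophagus, a thin tube whose wall contrast against
the surrounding mediastinum is often below 30 HU. The package provides, in
plain R + RcppArmadillo with no deep-learning framework dependency:

* a U-Net variant with a **ResNet34 or SEResNeXt50 encoder**, a
  **group-normalized dual-branch decoder with spatial attention modules
  (SAM)**, and an **atrous spatial pyramid pooling (ASPP) bottleneck** —
  forward *and* analytic backward passes, finite-difference-verified;
* the **combined training objective** `L = 0.9 * Dice + 0.1 * weighted-CE`
  with the per-class weights of the four-organ (esophagus, heart, trachea,
  aorta; P = 5) and six-organ (P = 7) configurations;
* CT preprocessing: NIfTI I/O, Hounsfield windowing (`(-400, 400)` /
  `(-1000, 400)`), axial slice extraction, flip/rotate/elastic
  augmentation;
* evaluation metrics in mm: **Dice, Hausdorff distance and HD95** over
  anisotropic voxel surfaces, tested for exact agreement with brute-force
  oracles;
* **STAPLE** expectation–maximization label fusion of the K-fold models'
  predictions (per-class decompose / fuse / reassemble) plus a
  majority-voting baseline;
* a deterministic **phantom generator** (low-contrast tube + organ analogs
  in noisy HU background) so the whole pipeline trains and evaluates
  end-to-end on a CPU in minutes, with no external data.

## The model in brief

Encoder stages output (64, 64, 128, 256, 512) channels for ResNet34 and
(64, 256, 512, 1024, 2048) for SEResNeXt50; decoder stages output
(256, 128, 64, 32, 16) for both. Each decoder stage upsamples ×2,
concatenates the encoder skip, and sums two branches:
`2 x [3x3 Conv -> GN -> ReLU] -> SAM` and `1x1 Conv -> GN`. The SAM gate is

    F_rs = (F ⊗ S(F)) ⊗ A_s(F ⊗ S(F)),

with `S(F) = sigmoid(spatial mean + spatial max)` per channel (C×1×1) and
`A_s` a sigmoid-activated 7×7 convolution over the concatenated
channel-mean/max maps (1×H×W). GroupNorm replaces BatchNorm throughout, so
inference is bit-identical across batch sizes. STAPLE estimates, per
foreground class, the consensus probability field and each fold model's
sensitivity/specificity by EM, and the fused volume takes the
highest-posterior class above 0.5.

## Worked example

Train four fold models on an 8-patient synthetic phantom dataset and fuse
their predictions (about 15 minutes on one CPU core; this is the same run
the acceptance script performs):

```r
library(oarseg)

dat <- write_phantom_dataset("phantoms", n_patients = 8, seed = 17)
asg <- kfold_split(dat$patient_id, 4, seed = 17)
cfg <- train_config(dat, folds = 4, epochs = 5, lr = 1e-3, batch_size = 4,
                    seed = 17)
cks <- sprintf("fold%d.rds", 1:4)
for (f in 1:4) train_fold(cfg, asg, f, cks[f], verbose = TRUE)
#> fold 1 epoch 1: loss 0.5021 val dice 0.6348
#> fold 1 epoch 2: loss 0.3800 val dice 0.7739
#> ...
#> fold 1 epoch 4: loss 0.2002 val dice 0.9353

vol  <- read_volume(dat$image[1])
gt   <- read_volume(dat$labels[1], labels = TRUE, num_classes = 5)
fused <- run_fold_fusion(as.list(cks), vol)
evaluate_segmentation(fused, gt, patient_id = "patient01")
```

The metrics table reports one row per foreground class (1 = esophagus
analog, 2 = heart, 3 = trachea, 4 = aorta) with columns `dice`, `hd`,
`hd95` (mm). The low-contrast tube is the hard class: on this run the
single-fold models average esophagus-analog Dice 0.909 across the eight
patients while the STAPLE-fused prediction averages 0.920, beating the
per-fold mean on 7 of 8 patients — the fusion gain the post-processing
step exists for. The bright organ analogs saturate near Dice 0.95+.

A shell front end with `synth` / `train` / `predict` / `fuse` / `evaluate`
subcommands is installed at `inst/cli/oarseg.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/oarseg.R", package="oarseg"))')" \
    synth --out phantoms --patients 8 --seed 17
```

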