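# cwdistill

Channel-wise knowledge distillation for fine-grained segmentation of the
three great vessels — pulmonary artery (PA), aorta (AO) and superior vena
cava (SVC) — in fetal-heart ultrasound three-vessel views.

The three vessels occupy only a small fraction of a full-size scan, and
the SVC in particular is small enough that conventionally trained
segmentation networks miss it or draw rough boundaries. `cwdistill`
implements a teacher–student remedy:

1. a **teacher** network trains on crops of the annotated vessel region
   (the ROI, padded 50 px per edge and resized to a square input), so it
   sees vessels at high effective resolution;
2. crop-space teacher logits are **restored** to full-image coordinates
   with exactly recorded crop boxes;
3. a **student** trains on full-size images with a combined objective

   L = α·L_CE + β·L_Dice + γ·L_KD,   α = β = 1,

   where L_KD is the channel-wise distillation loss: each class channel of
   the logits is turned into a spatial probability distribution by a
   temperature softmax over pixels,

   φ(y)_{c,i} = exp(y_{c,i}/τ) / Σ_{i'} exp(y_{c,i'}/τ),

   and teacher and student distributions are aligned per channel with a KL
   divergence scaled by τ²/C (γ = 3, τ = 4 in the student's second stage;
   γ = 0 for the teacher and the baseline).

Training is two-stage (frozen encoder at lr 5e-4, then full network at
5e-5, decaying by 0.92 per epoch, Adam, early stopping on validation
loss). Evaluation reports per-class and mean IoU, PA and Dice, where PA is
implemented exactly as the clinical method defines it: |Sa∩Sb|/|Sa|,
intersection over *predicted* area.

Because the clinical dataset is private, the package ships a synthetic
**three-vessel speckle phantom** generator (bright-rimmed ellipses, gamma
speckle, Gaussian blur, SVC strictly smallest) that reproduces the
statistical regime the method assumes, plus a small DeepLab-style
encoder–decoder (strided encoder, atrous spatial pyramid, skip-connection
decoder) with forward/backward passes implemented in the package itself.

## Worked example

A two-minute run on synthetic phantoms (100 train / 10 val / 10 test at
64×64): generate data, train a teacher on ROI crops, and train a full-size
segmenter with the γ = 0 objective.

```r
library(cwdistill)

cfg <- phantom_config(image_size = 64, seed = 11)
man <- generate_dataset(cfg, 100, 10, 10, "data")

mcfg <- model_config(base_width = 8, depth = 2, seed = 1)
stages <- function(seed) list(
  stage_config(1, lr_init = 2e-3, batch_size = 8, max_epochs = 16,
               patience = 3, seed = seed),
  stage_config(2, lr_init = 2e-4, batch_size = 2, max_epochs = 8,
               patience = 3, seed = seed + 1))

teacher <- train_teacher(man, mcfg, stages(5), "runs/teacher", roi_pad = 6)
model <- train_student(man, NULL, mcfg, stages(7), "runs/base", roi_pad = 6)
evaluate_dataset(model, man, split = "test")
```

Each training epoch appends a JSON line —

```
{"stage":2,"epoch":8,"lr":0.0001115693202,"train_ce":0.03365870915,
 "train_dice":0.2308640304,"train_kd":0,"train_total":0.2645227396,
 "val_total":0.19941459,"n_train_used":100}
```

(`lr` follows `lr_init * 0.92^(epoch-1)`; `train_kd` is nonzero only while
distilling) — and `evaluate_dataset()` prints the per-class table:

```
                            IoU (%)   PA (%) Dice (%)
Pulmonary artery (PA)          85.4     95.1     92.1
Aorta (AO)                     89.8     95.6     94.6
Superior vena cava (SVC)       56.9     87.3     72.5
Mean                           77.4     92.7     86.4
(micro aggregation over 10 images)
```

Rows are the three vessel classes; the mean row averages them (background
never enters), and the small SVC is, as expected, the hard class. A metric
with a zero denominator prints `n/a` rather than a silent 0 or 100.

The full paired distillation study — one shared stage-1 model per seed
branched into γ = 0 and γ = 3 stage-2 arms — is
`run_distillation_experiment()` (about 13 minutes on one CPU core). With
the default conditions it prints

```
  seed     role mean_iou  mean_pa mean_dice
1    1 baseline 85.69327 92.27120  92.17415
2    1  student 84.36171 88.90682  91.47125
3    2 baseline 85.88210 90.35017  92.34312
4    2  student 80.83920 89.94693  89.29528
5    3 baseline 87.58470 92.37727  93.29397
6    3  student 84.00667 89.09785  91.17246
```

— on these easy phantoms the equal-budget baseline stays ahead of the
distilled student; see the methods vignette for why, and for what that
does and does not say about the clinical setting.

The same pipeline is scriptable from a shell via `exec/cwdistill` with
`gen-data`, `train --role {teacher,student,baseline}`, `eval` and
`compare` subcommands driven by a YAML config (see `run_cli()`).

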