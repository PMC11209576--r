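# mammocross

Per-breast cancer classification from bilateral four-view screening
mammograms (left/right × CC/MLO), for researchers building or probing
multi-view computer-aided-diagnosis models. The package implements a
complete, CPU-runnable pipeline — preprocessing, case assembly, model,
training, evaluation, explanation — plus a synthetic phantom generator
so every stage is testable without clinical data or downloads.

## The model

For a case with right/left MLO and CC views `(R_m, R_c, L_m, L_c)` and
per-breast labels `y_L, y_R ∈ {0,1}`, the two views of each breast are
concatenated (CC above MLO, 1280 × 640) and passed through a *shared*
stride-32 convolutional extractor `f`, giving feature maps
`F_L, F_R ∈ R^{1280×40×20}`.

**Cross-mammogram dual-pathway attention.** Each map is flattened to
`L = 800` tokens; a per-breast linear branch maps tokens to `3C`
channels, cut into `M = 8` head segments of width `d = 3C/M`. For head
`i`, the own-side segment is the Query and the contralateral segment is
Key and Value:

    F_L'' = merge_i [ softmax(Q_L,i K_R,iᵀ / √d) V_R,i ]   (and symmetrically for F_R'')

so each local feature attends over the contralateral breast's global
region, and the reconstructed maps keep the `C × H × W` layout.

**Bilateral patch-wise contrastive joint loss.** `F_L''` and `F_R''`
are cut into non-overlapping `k × k` patches (k = 5 at full scale,
N = 32 patches). With eps-stabilised cosine similarity `Sim`, each left
patch `X_i` selects its most similar (`j(i) = argmax_j Sim(X_i, Y_j)`)
and least similar right patch; with temperature `t = 0.5`:

    L_sim = (1/N) Σ_i exp(−Sim(X_i, Y_j(i))/t)                                  if both breasts normal
    L_sim = (1/2N) Σ_i [ exp(−Sim(X_i, Y_j(i))/t) + exp(Sim(X_i, Y_j'(i))/t) ]  otherwise

**Heads and objective.** Global average pooling and non-shared
fully-connected heads give per-breast scores; with per-breast binary
cross-entropy `L_cls` the training objective is

    L_total = u1 · L_sim + u2 · (L_cls,left + L_cls,right),   u1 = 5/6, u2 = 1/6.

Training uses Adam with a balanced patient sampler (each batch half
both-normal, half cancer-involved cases, after whole-case upsampling of
the cancer scenarios) and a reduce-on-plateau schedule. Evaluation is
per breast: accuracy, confusion counts, ROC, and rank-statistic AUC.
Grad-CAM heatmaps explain per-breast predictions.

The neural network is implemented natively (C++ convolutions via Rcpp,
exact hand-derived backward passes, verified against finite differences);
image operations use EBImage.

## Worked example

Generate a synthetic cohort, train the desk-scale model, evaluate, and
explain one prediction:

```r
library(mammocross)

spec  <- synthSpec(nCases = 150, seed = 2024)     # 256 x 256 views
cases <- generateCases(spec)
sp    <- splitCases(cases, 1/3, seed = 2024)       # 100 train / 50 test

cfg <- deskConfig(patchK = 8)                      # 512 x 256 inputs, C = 256
model <- buildModel(cfg, seed = 301)
flips <- augmentConfig(pHflip = 0.5, pVflip = 0.5, pCrop = 0,
                       pAffine = 0, pJitter = 0, pErase = 0)
fit <- trainModel(model, upsampleTraining(sp$train),
                  trainConfig(lr = 3e-3, maxEpochs = 10, seed = 301),
                  augment = flips)
report <- evaluateModel(fit$model, sp$test)
report
#> MetricsReport: 100 breasts | TP 29 TN 60 FP 1 FN 10 | ACC 89.00% | AUC 0.8865

p   <- prepareCase(sp$test[[1]], cfg)
cam <- gradCam(fit$model, p$xL, p$xR, side = "left")
gradCamOverlay(p$xL, cam$heatmap, "cam_left.png")
```

The report counts every breast separately (two per case): here 89% of
the 100 held-out breasts are classified correctly at threshold 0.5, and
the rank AUC over the predicted probabilities is 0.887 (other training
seeds land a few points higher; the packaged three-seed experiment in
the test suite averages 0.93). The heatmap PNG
shows which regions of the concatenated CC/MLO input drove the left
breast's cancer score.

A thin command-line front end over the same functions is installed at
`inst/cli/mammocross.R` (`synth`, `preprocess`, `split`, `upsample`,
`train`, `evaluate`, `explain`).

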