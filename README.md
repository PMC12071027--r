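# milanova

Weakly supervised multiclass classification of whole-slide-image patch
bags, plus the complete statistical pipeline for asking which of the
classifier's hyperparameters actually matter.

## Who this is for

Computational pathology groups (and anyone doing multiple-instance
learning over embedded patches) who want (a) a transparent, dependency-light
implementation of the WELDON/CHOWDER-style MinMax bag classifier with
negative evidence, and (b) a principled alternative to trial-and-error
hyperparameter tuning: a factorial experiment analyzed with Type III
ANOVA and Fisher LSD range tests, with outlier screening and assumption
diagnostics built in.

## The model

Each slide is a bag $X \in \mathbb{R}^{n\times d}$ of patch embeddings
($d = 768$ for a ViT-base encoder) with a single 3-class label
(benign / atypical / malignant). The classifier:

1. scores every patch per class with a stack of five shared-weight 1-D
   convolutions (kernel width 1 along the patch axis — a per-patch MLP),
   producing attention scores that double as class-activation-map values;
2. keeps, per class, the $N_t$ highest and $N_b$ lowest scores (MinMax
   selection: salient instances plus *negative evidence*);
3. classifies the concatenated selections with an MLP head (depth level
   Ly, dropout Dp) and softmax, trained with Adam under cross-entropy
   plus an L2 weight-decay penalty (Wd).

Gradients flow only through selected patches — the gradient of the loss
with respect to any unselected patch's score is exactly zero.

The sensitivity pipeline runs the full factorial grid over
Wd ∈ {0, 0.1}, Ly ∈ {1, 2, 3}, Dp ∈ {0.2, 0.5, 0.8},
Nt ∈ {5, 10, 20, 40}, Nb ∈ {0, 5, 10, 20}; records macro F1, one-vs-rest
AUC and wall-clock time per run; screens gross failures (AUC < 0.65 or
F1 < 0.45, with studentized values, MAD-based modified Z-scores and
Grubbs' test in the audit report); and analyzes each response (AUC on the
logit scale) with a sum-to-zero-coded main-effects model, Type III sums
of squares, least-squares means and Fisher LSD contrasts with
homogeneous-group letters.

Everything is testable offline: `generateBagDataset()` simulates
class-conditional bags in which a minority of patches carry class signal
along orthonormal prototype directions, and `generateResultsTable()`
builds factorial results tables with known injected effects and outliers.

## Worked example

```r
library(milanova)

## train the classifier on synthetic separable bags
train   <- generateBagDataset(20, nPatches = 60, featureDim = 64,
                              signalStrength = 5, seed = 1)
heldout <- generateBagDataset(10, nPatches = 60, featureDim = 64,
                              signalStrength = 5, seed = 2, prototypeSeed = 1)
cfg   <- milConfig(Nt = 10, Nb = 5, Ly = 2, dropout = 0.2, weightDecay = 0,
                   convWidths = c(32L, 16L, 3L), epochs = 25L,
                   learningRate = 3e-3, seed = 1L)
model <- trainMIL(train, cfg)
model
#> MILModel: conv 64 -> 32 -> 16 -> 3, MinMax(Nt=10, Nb=5), MLP 128,64 -> 3
#>   trained 25 epochs, final loss 0.0008
res <- evaluateModel(model, heldout)
round(c(F1 = res$F1, AUC = res$AUC), 3)
#>  F1 AUC
#>   1   1
```

Held-out macro F1 and one-vs-rest AUC of 1 mean every one of the 30
held-out bags is classified correctly and ranked perfectly — expected at
signal strength 5, where the diagnostic patches are well separated from
background.

```r
## sensitivity analysis on a factorial results table with a known effect:
## Nt = 5 depressed by 0.04 relative to the other levels
grid <- factorLevels(replicates = 3)             # 288 cells x 3 = 864 runs
eff  <- effectSpec("F1", baseline = 0.62,
                   factorEffects = list(Nt = c(`5` = -0.03, `10` = 0.01,
                                               `20` = 0.01, `40` = 0.01)),
                   noiseSd = 0.01)
tab  <- generateResultsTable(grid, list(eff,
          effectSpec("AUC", 0.85, noiseSd = 0.01),
          effectSpec("T", 490, noiseSd = 1)), seed = 1)
fit  <- fitMainEffects(tab, "F1", c("Wd", "Ly", "Dp", "Nt", "Nb"))
type3Anova(fit)
#> Type III Sums of Squares
#>             Source       SumSq  Df      MeanSq          F      p
#>                 Wd 2.20938e-04   1 2.20938e-04   2.047563 0.1528
#>                 Ly 8.89024e-05   2 4.44512e-05   0.411956 0.6625
#>                 Dp 2.07211e-04   2 1.03605e-04   0.960173 0.3832
#>                 Nt 2.55812e-01   3 8.52707e-02 790.255082 <1e-04
#>                 Nb 3.33932e-04   3 1.11311e-04   1.031583 0.3778
#>           Residual 9.19331e-02 852 1.07903e-04         NA     NA
#>  Total (corrected) 3.48596e-01 863          NA         NA     NA
rangeTest(fit, "Nt")$means
#>   factor level      mean           se     lower     upper groups
#> 1     Nt     5 0.5900234 0.0007067884 0.5886362 0.5914107      a
#> 2     Nt    10 0.6302536 0.0007067884 0.6288664 0.6316409      b
#> 3     Nt    20 0.6291124 0.0007067884 0.6277252 0.6304997      b
#> 4     Nt    40 0.6298833 0.0007067884 0.6284960 0.6312705      b
```

Only the factor with the injected effect (Nt) is significant; the LSD
letters show Nt = 5 in its own group (`a`) while 10, 20 and 40 share `b`
— the "plateau beyond a minimal number of top instances" pattern this
analysis is designed to reveal.

`runPipeline(pipelineConfig(...))` chains all stages — simulate, grid,
screen, ANOVA, range tests — and writes every table as CSV plus a
manifest with MD5 content hashes. A thin command-line wrapper with
`simulate / grid / screen / analyze / report` subcommands lives in
`inst/scripts/milanova-pipeline.R`.

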