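# Shared fixtures, all generated in code.

# Small separable bag datasets sharing one prototype seed, for training
# checks. 64-dim features keep the trainer fast while preserving the
# multiple-instance structure (few signal patches per bag).
separableTrainSet <- function(nPerClass = 20, seed = 11) {
  generateBagDataset(nPerClass, nPatches = 60, featureDim = 64,
                     signalFraction = 0.2, signalStrength = 5, noiseSd = 1,
                     seed = seed, prototypeSeed = 11)
}

separableEvalSet <- function(nPerClass = 10, seed = 12) {
  generateBagDataset(nPerClass, nPatches = 60, featureDim = 64,
                     signalFraction = 0.2, signalStrength = 5, noiseSd = 1,
                     seed = seed, prototypeSeed = 11)
}

fastConfig <- function(...) {
  args <- list(Nt = 10, Nb = 5, Ly = 2, dropout = 0.2, weightDecay = 0,
               convWidths = c(32L, 16L, 3L), epochs = 15L, batchSize = 8L,
               learningRate = 3e-3, seed = 1L)
  do.call(milConfig, utils::modifyList(args, list(...)))
}

# An untrained model with seeded random weights, for structural checks.
randomModel <- function(featureDim = 8, Nt = 3, Nb = 2, seed = 5,
                        convWidths = c(6L, 3L), Ly = 2, dropout = 0) {
  cfg <- milConfig(Nt = Nt, Nb = Nb, Ly = Ly, dropout = dropout,
                   convWidths = convWidths, seed = seed)
  set.seed(seed)
  milanova:::.initMILModel(cfg, featureDim)
}

# Full five-factor grid with known injected effects on every response.
syntheticStudyTable <- function(replicates = 3, noiseSd = 0.01, seed = 1,
                                ntEffect = c(`5` = 0.05, `10` = -0.05 / 3,
                                             `20` = -0.05 / 3, `40` = -0.05 / 3)) {
  g <- factorLevels(replicates = replicates)
  effects <- list(
    effectSpec("F1", 0.62, factorEffects = list(Nt = ntEffect), noiseSd = noiseSd),
    effectSpec("AUC", 0.85, noiseSd = noiseSd),
    effectSpec("T", 490, noiseSd = 1))
  generateResultsTable(g, effects, seed = seed)
}
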