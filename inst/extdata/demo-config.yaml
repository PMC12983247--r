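# Demo pipeline configuration.
#
# Schema (all entries optional; defaults in parentheses):
#   stages: ordered list of stages to run
#     simulate | preprocess | train-repgeno | train | transfer | attribute |
#     evaluate
#   environment: phenotype environment used for training/evaluation (first)
#   simulate:
#     nSamples (300), nMarkers (200), nPopulations (3), divergence (0.15),
#     ldBlockSize (10), baseMaf (0.3), mutationRate (0.1), nChromosomes (5)
#     trait:
#       nAdditive (5), betaSd (1), nEpistatic (0), thetaSd (1),
#       polygenicVar (0), targetH2 (0.7), intercept (0),
#       envCorrelation (unset; when set, two environments with this genetic
#       correlation are simulated)
#   preprocess: mafMin (0.01), ldWindowBp (2000), ldStepBp (1000),
#               ldR2Max (0.95)
#   repgeno: embedDim (16), hidden (32), margin (0.3), epsilon (1),
#            batchSize (128), epochs (10), lr (1e-3)
#   train: veChannels (2), poolLen (8), headHidden ([32, 16]),
#          batchSize (128), epochs (15), lr (1e-3)
#   transfer: environment (last), fraction (0.10), epochs (20)
#   attribute: steps (64)

stages:
  - simulate
  - preprocess
  - train-repgeno
  - train
  - attribute
  - evaluate

simulate:
  nSamples: 300
  nMarkers: 200
  nPopulations: 3
  trait:
    nAdditive: 5
    targetH2: 0.7

repgeno:
  embedDim: 16
  epochs: 10

train:
  veChannels: 2
  epochs: 15
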