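# Canonical configuration of the synthetic reference experiment.
# Identical to paperDefaultConfig(); the surround N0 is derived from the
# anchor that the surround's per-day decline is 25-fold the bundle's on the
# first observed day (N0_surround = 25 * N0_bundle *
# (1 - 2^(-1/5.5)) / (1 - 2^(-1/0.9))).
seed: 1
phantom:
  lengthPx: 220
  diameterPx: 15
  bundleWidthPx: 5
  hillockPx: 10
  growthconePx: 10
  backgroundLevel: 50.0
binsPhantom:
  lengthPx: 220
  diameterPx: 25
  bundleWidthPx: 10
  hillockPx: 10
  growthconePx: 10
  backgroundLevel: 50.0
acquisition:
  gaussianReadNoiseSd: 10.0
  poissonNoise: true
  psfSigmaPx: 0.0
cohort:
  nCells: 30
  cellCv: 0.10
  days: [2, 4, 7, 14]
kinetics:
  bundle:
    N0: 1000.0
    halfLifeDays: 5.5
    start: 2
    end: 14
    additive: true
  surround:
    N0: 5511.868418
    earlyHalfLifeDays: 0.9
    lateHalfLifeDays: 5.7
    breakDay: 4
    start: 2
    end: 14
bins:
  days: [4, 7, 14]
  N0: 1000.0
  spatialProfile: [0.7, 0.85, 1.0, 0.85, 0.7]
  halfLives:
    center: 6.5
    interior: 6.2
    edge: 6.7
  start: 4
  end: 14
earlyLate:
  nCells: 30
  earlyDay: 2
  lateDay: 4
  lateIncorporation: 0.35
  lateSpatialProfile: [1.3, 1.1, 0.2, 1.1, 1.3]
bleach:
  nCells: 5
  preDay: 4.99
  bleachDay: 5
  recoveredDay: 5.5
  regionStartPx: 80
  regionEndPx: 140
  efficiency: 0.95
  surroundRecoveryFraction: 0.92
  bundleRecoveryFraction: 0.0
  recoveryDelayDays: 0.5
fit:
  breakpointDay: 4
  bootstrapReps: 0
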