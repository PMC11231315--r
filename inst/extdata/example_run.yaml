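# Full-scenario example run: spectrin lattice fenced by stress fibers,
# myosin linkers + stochastic rods, focal adhesions pulled together for
# the first half of the run.
scenario: full_with_myosin
seed: 1
params:
  dt: 0.02
  Ttot: 600
  tS: 300
geometry:
  nRows: 10
  nCols: 20
  nSegments: 8
  nRodsInit: 5
run:
  snapshotEvery: 60
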