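# Desk-scale T2W smoke configuration: 64 x 64 single slice, ETL 8, NEX 2,
# 256 EMI characterization windows, standard broadband + 50 Hz-harmonic
# EMI world. Runs end to end in a few minutes with canceller: cnn, or in
# seconds with canceller: linear.
phantom:
  gridShape: [64, 64, 1]
  voxelSize: [2, 2, 10]
protocol:
  preset: t2w
  matrixSize: [64, 64, 1]
  etl: 8
  nex: 2
  charCount: 16
  elliptic: false
emiWorld: standard
canceller: linear
padFactors: [2, 2, 1]
seed: 1
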