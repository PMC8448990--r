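# Desk-scale configuration for the canalseg CLI: reduced channel widths and
# 16x32x32 patches so the generate -> train -> predict -> evaluate pipeline
# runs in minutes on one CPU. Omitted keys keep the package defaults
# (protocol-faithful full-scale settings).
network:
  encoderChannels: [8, 16, 32, 64]
  nPool: 3
  variant: sequential_spatial_first
training:
  patchSize: [16, 32, 32]
  batchSize: 2
  learningRate: 0.001
  maxSteps: 300
  validationInterval: 100
  seed: 1
sliding:
  patchSize: [16, 32, 32]
  steps: [8, 16, 16]
  threshold: 0.5
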