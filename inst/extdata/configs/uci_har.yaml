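name: uci_har
notes: >
  Published hyperparameters for the UCI-HAR configuration: input (9, 128),
  64 filters, stem kernel 4, dilated kernels (4, 2), dilation rates
  (1, 2, 4, 6), two residual blocks, two GRU layers, 6 classes, batch 155,
  learning rate 5e-4, 100 epochs. The classifier hidden width (fc_width) and
  the squeeze-excitation bottleneck (se_width) are not published; they are the
  unique pair of positive integers for which the per-layer parameter ledger
  totals the published 239,846 trainable parameters (solve
  total = base + 2*filters*se_width + se_width + filters
        + (2*filters + 1)*fc_width + (n_classes + 1)*fc_width ... for the
  assembled architecture; see the methods vignette for the layer formulas).
model:
  n_channels: 9
  window_length: 128
  n_classes: 6
  filters: 64
  n_residual_blocks: 2
  n_gru_layers: 2
  stem_kernel: 4
  dilated_kernels: [4, 2]
  dilation_rates: [1, 2, 4, 6]
  paddings: [2, 4, 8, 10]
  se_width: 28
  fc_width: 869
  dropout_rate: 0.5
train:
  epochs: 100
  batch_size: 155
  learning_rate: 5.0e-4
  seed: 1
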