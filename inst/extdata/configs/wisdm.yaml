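name: wisdm
notes: >
  Published hyperparameters for the WISDM configuration: input (3, 100),
  75 filters, stem kernel 5, dilated kernels (3, 2), dilation rates
  (1, 2, 4, 6), two residual blocks, two GRU layers, 6 classes, batch 256,
  learning rate 1e-3, 100 epochs. fc_width and se_width are not published;
  they are the unique positive-integer pair for which the per-layer parameter
  ledger totals the published 303,939 trainable parameters (same derivation
  as the uci_har profile).
model:
  n_channels: 3
  window_length: 100
  n_classes: 6
  filters: 75
  n_residual_blocks: 2
  n_gru_layers: 2
  stem_kernel: 5
  dilated_kernels: [3, 2]
  dilation_rates: [1, 2, 4, 6]
  paddings: [2, 4, 8, 10]
  se_width: 4
  fc_width: 979
  dropout_rate: 0.5
train:
  epochs: 100
  batch_size: 256
  learning_rate: 1.0e-3
  seed: 1
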