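name: opportunity
notes: >
  Published hyperparameters for the OPPORTUNITY configuration: input
  (113, 60), 110 filters, stem kernel 7, dilated kernels (3, 5), dilation
  rates (1, 2, 4, 6), two residual blocks, two GRU layers, 17 gesture
  classes, batch 256, learning rate 1e-3, 100 epochs. fc_width and se_width
  are not published; several integer pairs reproduce the published 524,482
  trainable parameters for this geometry, and the profile fixes the pair
  whose bottleneck is closest to filters/4 (the customary squeeze-excitation
  reduction). Derivation as in the uci_har profile.
model:
  n_channels: 113
  window_length: 60
  n_classes: 17
  filters: 110
  n_residual_blocks: 2
  n_gru_layers: 2
  stem_kernel: 7
  dilated_kernels: [3, 5]
  dilation_rates: [1, 2, 4, 6]
  paddings: [2, 4, 8, 10]
  se_width: 24
  fc_width: 175
  dropout_rate: 0.5
train:
  epochs: 100
  batch_size: 256
  learning_rate: 1.0e-3
  seed: 1
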