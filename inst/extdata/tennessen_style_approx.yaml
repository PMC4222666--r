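# SYNTHETIC, user-supplied approximation (illustrative only).
# A history in the style of exome-sequencing-based African models: long
# ancestral equilibrium, an ancient step expansion, then strong recent
# exponential growth.  Epoch values are round numbers for demonstration;
# replace them with your own calibrated history before any real analysis.
reference_size: 7310.0
label: step-plus-recent-growth approximation (user-supplied, illustrative)
epochs:
- duration_generations: 8000.0
  mode: constant
  size_start_relative: 1.0
  rate_scaled: 0.0
- duration_generations: 5300.0
  mode: constant
  size_start_relative: 2.0
  rate_scaled: 0.0
- duration_generations: 620.0
  mode: exponential
  size_start_relative: 2.0
  rate_scaled: 60.0
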