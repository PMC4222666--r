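# SYNTHETIC, user-supplied approximation (illustrative only).
# A piecewise-constant history in the style of IBS-tract-based inferences for
# an African population: ancient equilibrium, a moderate contraction, then
# recovery and recent expansion.  Epoch values here are round numbers chosen
# for demonstration; replace them with your own calibrated history before any
# real analysis.
reference_size: 10000.0
label: piecewise-constant approximation (user-supplied, illustrative)
epochs:
- duration_generations: 10000.0
  mode: constant
  size_start_relative: 1.0
  rate_scaled: 0.0
- duration_generations: 4000.0
  mode: constant
  size_start_relative: 0.6
  rate_scaled: 0.0
- duration_generations: 2000.0
  mode: constant
  size_start_relative: 1.2
  rate_scaled: 0.0
- duration_generations: 1000.0
  mode: constant
  size_start_relative: 2.5
  rate_scaled: 0.0
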