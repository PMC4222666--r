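# Exponential growth at population-scaled rate 1 for 13000 generations,
# from an ancestral equilibrium at N0 = 10000 diploids.  This is the
# package's working non-equilibrium history for examples and simulations.
reference_size: 10000.0
label: growth r=1 t=13000
epochs:
- duration_generations: 13000.0
  mode: exponential
  size_start_relative: 1.0
  rate_scaled: 1.0
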